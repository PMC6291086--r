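test_that("the moment objective is zero at self-matched targets and
           bit-stable under common random numbers", {
  p <- preset("elephant_wild")
  bank <- make_draw_bank(1010 * p$q, seed = 8)
  tr <- simulate_sleep(p, days = 1000, bank = bank)
  spec <- calibration_spec(p, c("xi", "sigma"),
                           target_mean = mean(tr$daily_hours),
                           target_sd = pop_sd(tr$daily_hours),
                           sim_days = 1000, bank = bank)
  expect_equal(moment_objective(c(p$xi, p$sigma), spec), 0)
  o1 <- moment_objective(c(5, 0.1), spec)
  o2 <- moment_objective(c(5, 0.1), spec)
  expect_identical(o1, o2)
})

test_that("infeasible candidates draw a large finite penalty", {
  spec <- calibration_spec(preset("elephant_wild"), c("xi", "sigma"),
                           2.2, 1.03, sim_days = 1000, seed = 4)
  pen <- moment_objective(c(-1, -0.5), spec)
  expect_true(is.finite(pen))
  expect_gt(pen, 1e5)
  # penalty grows with the violation, guiding the simplex back
  expect_gt(moment_objective(c(-2, -0.5), spec), pen)
})

test_that("spec constructor enforces its contracts", {
  p <- preset("elephant_wild")
  expect_error(calibration_spec(p, c("xi", "sigma", "lam"), 2, 1,
                                seed = 1), "exactly two")
  expect_error(calibration_spec(p, c("xi", "bogus"), 2, 1, seed = 1),
               "exactly two")
  expect_error(calibration_spec(p, c("xi", "sigma"), 30, 1, seed = 1),
               "targets")
  expect_error(calibration_spec(p, c("xi", "sigma"), 2, 1, sim_days = 10,
                                seed = 1), "sim_days")
  expect_error(calibration_spec(p, c("xi", "sigma"), 2, 1,
                                bank = make_draw_bank(5, 1)), "too short")
})

test_that("known parameters are recovered from their own moments", {
  base <- unclass(preset("elephant_wild"))[sleepcost:::.param_fields]
  truth <- do.call(model_params, modifyList(base,
                                            list(xi = 4, sigma = 0.08)))
  bank <- make_draw_bank(5010 * truth$q, seed = 14)
  tr <- simulate_sleep(truth, days = 5000, bank = bank)
  spec <- calibration_spec(truth, c("xi", "sigma"),
                           target_mean = mean(tr$daily_hours),
                           target_sd = pop_sd(tr$daily_hours),
                           sim_days = 5000, bank = bank)
  res <- calibrate_moments(spec)
  expect_true(res$converged)
  expect_equal(unname(res$fitted["xi"]), 4, tolerance = 0.05)
  expect_equal(unname(res$fitted["sigma"]), 0.08, tolerance = 0.05)
  expect_equal(res$n_evals, length(res$trace))
  expect_lte(min(res$trace), res$objective + 1e-12)
})

test_that("a zero-SD target drives sigma to its lower bound", {
  spec <- calibration_spec(preset("elephant_wild"), c("xi", "sigma"),
                           target_mean = 2.2, target_sd = 0,
                           sim_days = 1000, seed = 9)
  res <- calibrate_moments(spec, maxit = 300)
  expect_lt(unname(res$fitted["sigma"]), 0.02)
})

test_that("the sensitivity runner recalibrates captive then wild stages", {
  tab <- run_sensitivity(scenarios = "A", species = "elephant",
                         sim_days = 1500, seed = 6, maxit = 150)
  expect_equal(nrow(tab), 1)
  expect_named(tab, c("scenario", "description", "species", "xi",
                      "sigma_wild", "asymptote", "captive_converged",
                      "wild_converged"))
  # captive stage recovers a sleeping asymptote near the published one and
  # the wild opportunity cost lands well above the captive normalization
  expect_equal(tab$asymptote, -0.9056, tolerance = 0.15)
  expect_gt(tab$xi, 2)
})
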
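test_that("the compiled kernel agrees with the per-period R primitives", {
  p <- preset("elephant_wild")
  n <- 3 * p$q
  bank <- make_draw_bank(n, seed = 21)
  ref <- step_oracle(p, bank$draws)
  tr <- simulate_sleep(p, days = 3, bank = bank, burn_in_days = 0)
  expect_identical(tr$A, ref$A)
  expect_equal(tr$H, ref$H, tolerance = 1e-12)
  expect_equal(tr$z, ref$z, tolerance = 1e-12)
  expect_equal(tr$U, ref$U, tolerance = 1e-12)
})

test_that("the same draw bank reproduces trajectories bit-exactly", {
  p <- preset("sloth_wild")
  bank <- make_draw_bank(40 * p$q, seed = 3)
  t1 <- simulate_sleep(p, days = 30, bank = bank)
  t2 <- simulate_sleep(p, days = 30, bank = bank)
  expect_identical(t1$A, t2$A)
  expect_identical(t1$H, t2$H)
  expect_identical(t1$U, t2$U)
})

test_that("input contracts are enforced", {
  p <- preset("elephant_captive")
  expect_error(simulate_sleep(p, days = 100,
                              bank = make_draw_bank(10, seed = 1)),
               "too short")
  expect_error(simulate_sleep(p, days = 0, seed = 1), "days")
  expect_error(simulate_sleep(p, days = 2, seed = 1,
                              xi_schedule = rep(1, 7)), "length q")
  expect_error(simulate_sleep(p, days = 2), "seed")
})

test_that("a noiseless run matches the stylized limit cycle", {
  base <- unclass(preset("elephant_wild"))[sleepcost:::.param_fields]
  p0 <- do.call(model_params, modifyList(base, list(sigma = 0)))
  day <- simulate_stylized(p0)
  expect_equal(day$period_days, 1L)
  tr <- simulate_sleep(p0, days = 1, bank = make_draw_bank(41 * p0$q, 1),
                       burn_in_days = 40)
  expect_identical(tr$A, day$A)
  expect_equal(tr$H, day$H, tolerance = 1e-9)
})

test_that("stylized cycles are exactly periodic once converged", {
  for (nm in c("elephant_wild", "sloth_wild")) {
    day <- simulate_stylized(preset(nm))
    k <- day$period_days
    q <- day$params$q
    tr <- simulate_sleep(
      do.call(model_params,
              modifyList(unclass(preset(nm))[sleepcost:::.param_fields],
                         list(sigma = 0))),
      days = 2 * k, bank = make_draw_bank((2 * k + 40) * q, 1),
      burn_in_days = 40)
    expect_identical(tr$A[1:(k * q)], tr$A[(k * q + 1):(2 * k * q)])
  }
})

test_that("stylized non-convergence is reported with context", {
  p <- preset("sloth_wild")
  expect_error(simulate_stylized(p, max_days = 30, max_period = 1),
               "no limit cycle")
  err <- tryCatch(simulate_stylized(p, max_days = 30, max_period = 1),
                  error = identity)
  expect_s3_class(err, "sleepcost_no_convergence")
  expect_true(!is.null(err$last_days))
})

test_that("mean daily sleep falls as the opportunity cost rises", {
  base <- unclass(preset("elephant_wild"))[sleepcost:::.param_fields]
  hours <- vapply(c(1, 3, 6.619, 12), function(xi) {
    p <- do.call(model_params, modifyList(base, list(xi = xi, sigma = 0)))
    mean(simulate_stylized(p)$daily_hours)
  }, numeric(1))
  expect_true(all(diff(hours) <= 0))
})

test_that("episode count falls as the switching cost rises", {
  base <- unclass(preset("elephant_wild"))[sleepcost:::.param_fields]
  eps <- vapply(c(0.02, 0.1, 0.2, 0.5), function(lam) {
    p <- do.call(model_params, modifyList(base, list(lam = lam, sigma = 0)))
    stylized_episode_count(simulate_stylized(p))
  }, numeric(1))
  expect_true(all(diff(eps) <= 0))
})

test_that("environmental noise creates day-to-day variability", {
  base <- unclass(preset("elephant_wild"))[sleepcost:::.param_fields]
  sds <- vapply(c(0, 0.06, 0.12172), function(s) {
    p <- do.call(model_params, modifyList(base, list(sigma = s)))
    pop_sd(simulate_sleep(p, days = 300, seed = 5)$daily_hours)
  }, numeric(1))
  expect_equal(sds[1], 0, tolerance = 1e-12)
  expect_true(all(diff(sds) > 0))
})

test_that("scheduled opportunity cost reduces to the plain model and
           shifts sleep into the zero-cost half", {
  p <- preset("elephant_wild")
  bank <- make_draw_bank(40 * p$q, seed = 13)
  plain <- simulate_sleep(p, days = 30, bank = bank)
  neutral <- simulate_scheduled(p, rep(1, p$q), days = 30, bank = bank)
  expect_identical(neutral$A, plain$A)
  base <- unclass(p)[sleepcost:::.param_fields]
  p0 <- do.call(model_params, modifyList(base, list(xi = 0)))
  zero <- simulate_scheduled(p, rep(0, p$q), days = 30, bank = bank)
  off <- simulate_sleep(p0, days = 30, bank = bank)
  expect_identical(zero$A, off$A)
  expect_error(simulate_scheduled(p, rep(1, 10), days = 5, bank = bank),
               "length q")
  # cost positive 6am-6pm only: sleep concentrates in the free half
  sched <- as.numeric(circadian(0:(p$q - 1), p$q) > 0)
  tr <- simulate_scheduled(p, sched, days = 100, bank =
                             make_draw_bank(110 * p$q, seed = 17))
  daytime <- circadian(tr$t %% p$q, p$q) > 0
  expect_gt(mean(tr$A[!daytime]), mean(tr$A[daytime]))
})
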
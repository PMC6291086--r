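test_that("waking utility scales with capacity, state and curvature", {
  p1 <- model_params(mu_W = 1, mu_S = -1, eta = 1, gamma = 1, xi = 1)
  expect_equal(waking_utility(1, 0, p1), 0)
  expect_equal(waking_utility(1, 3, p1), 0)
  expect_equal(waking_utility(0, 0, p1), 1)
  p2 <- model_params(mu_W = 1, mu_S = -1, eta = 1, gamma = 0.8, xi = 1)
  expect_equal(waking_utility(0.5, 0, p2), 0.5^0.8)
  # strictly decreasing in H, increasing in z
  expect_gt(waking_utility(0.2, 0, p2), waking_utility(0.4, 0, p2))
  expect_gt(waking_utility(0.2, 0.5, p2), waking_utility(0.2, 0, p2))
  expect_error(waking_utility(1.5, 0, p2), "mu_W")
})

test_that("circadian penalty is a symmetric non-negative loss", {
  p <- model_params(chi = 10, kappa = 2)
  expect_equal(circadian_penalty(0.3, 0.3, p), 0)
  expect_equal(circadian_penalty(0.5, 0, p), 2.5)
  expect_equal(circadian_penalty(-0.2, 0.7, p),
               circadian_penalty(0.7, -0.2, p))
})

test_that("action utility composes production, penalty and switching cost", {
  p <- preset("elephant_captive")
  ctx <- choice_context(H_prev = 0.5, A_prev = 0, y = -1, z = 0)
  # independent arithmetic for each term
  aW <- exp(-24 / (8 * 144)); aS <- aW
  Hw <- 1 + (0.5 - 1) * aW
  Hs <- -0.9056 + (0.5 + 0.9056) * aS
  U0 <- (exp(0) * 1 * (1 - 0.5)^1)^0.8 - 10 * abs(Hw - (-1))^2
  U1 <- -10 * abs(Hs - (-1))^2 - 0.2
  expect_equal(action_utility(ctx, 0, p), U0)
  expect_equal(action_utility(ctx, 1, p), U1)
  # no switching term when staying put
  ctx1 <- choice_context(0.5, 1, -1, 0)
  expect_equal(action_utility(ctx1, 1, p), U1 + 0.2)
  expect_error(action_utility(ctx, 2, p), "invalid action")
})

test_that("penalty-free sleep dominates when it lands on the cycle", {
  # xi = 0, lam = 0 and sleeping moves H onto y: sleeping is optimal
  p <- model_params(xi = 0, lam = 0, mu_W = 1, mu_S = -1)
  y <- homeostat_step(0.5, TRUE, 1, -1, 8, 8, 144)
  ctx <- choice_context(0.5, 0, y = y, z = 0)
  res <- choose_action(ctx, p)
  expect_equal(res$U_sleep, 0)
  expect_equal(res$A, 1L)
  expect_gte(res$U_sleep, res$U_wake)
})

test_that("choice equals the two-action brute-force argmax", {
  set.seed(99)
  p <- preset("elephant_wild")
  for (i in 1:400) {
    ctx <- choice_context(H_prev = runif(1, p$mu_S, p$mu_W),
                          A_prev = sample(0:1, 1),
                          y = runif(1, -1, 1), z = rnorm(1, 0, 0.5))
    res <- choose_action(ctx, p)
    u <- c(action_utility(ctx, 0, p), action_utility(ctx, 1, p))
    expect_equal(res$U, max(u))
    expect_equal(res$U_wake, u[1])
    expect_equal(res$U_sleep, u[2])
    expect_equal(res$U, u[res$A + 1])
  }
})

test_that("a huge opportunity cost forces waking", {
  p <- model_params(xi = 1e6)
  ctx <- choice_context(0.5, 1, y = -1, z = 0)
  expect_equal(choose_action(ctx, p)$A, 0L)
})

test_that("exact ties keep the previous action", {
  # fully symmetric setup: mu_W = -mu_S, equal decay, y = 0, H = 0, xi = 0,
  # lam = 0 makes both branches identical in absolute value
  p <- model_params(xi = 0, lam = 0, mu_W = 1, mu_S = -1)
  for (a0 in 0:1) {
    ctx <- choice_context(0, a0, y = 0, z = 0)
    res <- choose_action(ctx, p)
    expect_equal(res$U_wake, res$U_sleep)
    expect_equal(res$A, a0)
  }
})

test_that("raising xi never flips a wake choice to sleep", {
  set.seed(7)
  base <- unclass(preset("elephant_wild"))[sleepcost:::.param_fields]
  for (i in 1:100) {
    ctx <- choice_context(runif(1, base$mu_S, base$mu_W), sample(0:1, 1),
                          runif(1, -1, 1), rnorm(1, 0, 0.3))
    last_awake <- FALSE
    for (xi in c(0.5, 2, 6.619, 20)) {
      p <- do.call(model_params, modifyList(base, list(xi = xi)))
      awake <- choose_action(ctx, p)$A == 0L
      if (last_awake) expect_true(awake)
      last_awake <- awake
    }
  }
})

test_that("a steep circadian penalty recovers the two-process band", {
  p <- model_params(kappa = 40, xi = 0, lam = 0.01, mu_W = 1,
                    mu_S = -0.9056, sigma = 0)
  day <- simulate_stylized(p)
  expect_lt(max(abs(day$H - day$y)), 1.1)
})
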
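new_trajectory <- function(core, p, days, burn_in, seed, rho_convention,
                           class_extra = character()) {
  structure(list(t = seq_len(days * p$q) - 1L,
                 A = core$A, H = core$H, z = core$z, U = core$U, y = core$y,
                 daily_hours = core$daily_hours,
                 params = p, n_days = days, burn_in = burn_in, seed = seed,
                 rho_convention = rho_convention),
            class = c(class_extra, "sleep_trajectory"))
}

run_core <- function(p, days, eps, burn_in, H0, A0, z0, xi_schedule,
                     rho_convention, full_output = TRUE) {
  .sim_core(eps, p$q, as.integer(days), as.integer(burn_in),
            p$kappa, p$eta, p$gamma,
            rho_per_period(p$rho, p$q, rho_convention),
            decay_factor(p$nu_W, p$q), decay_factor(p$nu_S, p$q),
            p$mu_W, p$mu_S, p$lam, p$chi, p$xi, p$sigma,
            H0, as.integer(A0), z0,
            if (is.null(xi_schedule)) numeric(0) else xi_schedule,
            full_output)
}

#' Simulate the generalized sleep model
#'
#' Drives the myopic per-period choice of [choose_action()] through time.
#' Within each period the environmental state advances first and the choice
#' then sees the current-period `z`, `y`. Draws are consumed from the bank in
#' order, burn-in first, so a given bank always maps to the same trajectory
#' (bit-exact reproducibility); the returned series exclude the burn-in.
#'
#' @param p A `model_params` object.
#' @param days Days to keep after burn-in (>= 1).
#' @param bank A `draw_bank` with at least `q * (days + burn_in_days)` draws,
#'   or `NULL` to build one from `seed`.
#' @param seed Integer seed used when `bank` is `NULL`.
#' @param H0,A0 Initial homeostat level and action (defaults: 0, awake, at a
#'   midnight phase).
#' @param burn_in_days Days discarded before recording (default 10; initial
#'   conditions decay geometrically, so this suffices for all presets).
#' @param xi_schedule Optional length-`q` vector of per-period multipliers on
#'   `xi` (see [simulate_scheduled()]).
#' @param rho_convention Passed to [rho_per_period()].
#' @return A `sleep_trajectory`: per-period vectors `t`, `A`, `H`, `z`, `U`,
#'   `y` plus `daily_hours`, the parameters and run metadata. Convert with
#'   [as.data.frame()].
#' @export
#' @examples
#' tr <- simulate_sleep(preset("elephant_captive"), days = 30, seed = 1)
#' mean(tr$daily_hours)
simulate_sleep <- function(p, days, bank = NULL, seed = NULL, H0 = 0,
                           A0 = 0, burn_in_days = 10, xi_schedule = NULL,
                           rho_convention = "per_hour") {
  stopifnot(inherits(p, "model_params"))
  if (!(is.numeric(days) && length(days) == 1 && days >= 1))
    stop("days must be >= 1", call. = FALSE)
  days <- as.integer(days)
  need <- p$q * (days + burn_in_days)
  if (is.null(bank)) {
    if (is.null(seed)) stop("supply either a draw bank or a seed",
                            call. = FALSE)
    bank <- make_draw_bank(need, seed)
  }
  stopifnot(inherits(bank, "draw_bank"))
  if (bank$length < need)
    stop("draw bank too short: need ", need, " draws, have ", bank$length,
         call. = FALSE)
  if (!is.null(xi_schedule) && length(xi_schedule) != p$q)
    stop("xi_schedule must have length q = ", p$q, call. = FALSE)
  core <- run_core(p, days, bank$draws, burn_in_days, H0, A0, 0,
                   xi_schedule, rho_convention)
  new_trajectory(core, p, days, burn_in_days, bank$seed, rho_convention)
}

#' Noise-free stylized day (deterministic limit cycle)
#'
#' Runs the model with `sigma = 0` (so `z` stays at 0) from `H0 = 0`, awake,
#' at midnight, until the wake/sleep pattern settles onto a limit cycle:
#' the smallest number of days `k` such that consecutive blocks of `k` days
#' have identical actions and homeostat levels within `tol`. Most presets
#' lock onto a one-day cycle; some (the wild-sloth benchmark) converge to an
#' exact multi-day cycle instead, so cycles up to `max_period` days are
#' detected and the cycle length is reported as `period_days`.
#'
#' @param p A `model_params` object (its `sigma` is ignored; 0 is used).
#' @param max_days Simulation horizon for convergence (>= 2).
#' @param tol Tolerance on `H` for cycle detection (actions must match
#'   exactly).
#' @param max_period Largest cycle length, in days, to look for.
#' @return A `sleep_trajectory` (also of class `stylized_cycle`) holding one
#'   full cycle of `period_days` days, starting at a midnight phase.
#' @export
#' @examples
#' day <- simulate_stylized(preset("elephant_wild"))
#' length(sleep_episodes(day, cyclic = TRUE)$start)
simulate_stylized <- function(p, max_days = 80, tol = 1e-9, max_period = 8) {
  stopifnot(inherits(p, "model_params"))
  if (!(is.numeric(max_days) && length(max_days) == 1 && max_days >= 2))
    stop("max_days must be >= 2", call. = FALSE)
  p0 <- do.call(model_params, modifyList(unclass(p)[.param_fields],
                                         list(sigma = 0)))
  core <- run_core(p0, as.integer(max_days), numeric(max_days * p0$q),
                   0, 0, 0, 0, NULL, "per_hour")
  q <- p0$q
  Am <- matrix(core$A, nrow = q)
  Hm <- matrix(core$H, nrow = q)
  nd <- ncol(Am)
  for (d in 2:nd) {
    for (k in seq_len(min(max_period, d %/% 2))) {
      blk <- (d - k + 1):d
      prev <- blk - k
      if (identical(Am[, blk], Am[, prev]) &&
          max(abs(Hm[, blk] - Hm[, prev])) < tol) {
        idx <- as.vector(outer(seq_len(q), (blk - 1) * q, `+`))
        cyc <- list(A = core$A[idx], H = core$H[idx], z = core$z[idx],
                    U = core$U[idx], y = core$y[idx],
                    daily_hours = core$daily_hours[blk])
        out <- new_trajectory(cyc, p0, k, d - k, NA_integer_, "per_hour",
                              class_extra = "stylized_cycle")
        out$period_days <- k
        return(out)
      }
    }
  }
  last2 <- lapply(list(A = Am, H = Hm), function(m) m[, (nd - 1):nd])
  stop(structure(class = c("sleepcost_no_convergence", "error", "condition"),
                 list(message = paste0("no limit cycle of period <= ",
                                       max_period, " days within ", max_days,
                                       " days"),
                      call = sys.call(-1), last_days = last2)))
}

#' Simulate with a scheduled opportunity cost
#'
#' Like [simulate_sleep()] but with the opportunity-cost scale modulated by
#' time of day: `xi_t = xi * schedule[t mod q]`. A schedule of ones
#' reproduces [simulate_sleep()] exactly; a schedule that is positive by day
#' and zero by night concentrates sleep in the zero-cost half of the day.
#' Demonstration only -- scheduled runs are excluded from calibration.
#'
#' @inheritParams simulate_sleep
#' @param xi_schedule Numeric vector of length `q`, non-negative multipliers.
#' @return A `sleep_trajectory`.
#' @export
simulate_scheduled <- function(p, xi_schedule, days, bank = NULL,
                               seed = NULL, burn_in_days = 10,
                               rho_convention = "per_hour") {
  if (length(xi_schedule) != p$q)
    stop("xi_schedule must have length q = ", p$q, call. = FALSE)
  simulate_sleep(p, days, bank = bank, seed = seed,
                 burn_in_days = burn_in_days, xi_schedule = xi_schedule,
                 rho_convention = rho_convention)
}

#' @export
print.sleep_trajectory <- function(x, ...) {
  cat("<sleep_trajectory>", x$n_days, "day(s) x", x$params$q, "periods;",
      "mean sleep", round(mean(x$daily_hours), 3), "h/day")
  if (inherits(x, "stylized_cycle"))
    cat(" [stylized limit cycle, period", x$period_days, "day(s)]")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.sleep_trajectory <- function(x, ...) {
  q <- x$params$q
  data.frame(day = x$t %/% q, period = x$t %% q, t = x$t,
             y = x$y, z = x$z, H = x$H, A = x$A, U = x$U)
}
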
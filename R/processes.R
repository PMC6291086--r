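#' Circadian cycle
#'
#' The single-cosine circadian signal, `y = -cos(2 * pi * t / q)`. Period
#' index 0 is midnight, where the cycle is at its trough (-1); it peaks (+1)
#' at midday. Periodic with period `q` exactly.
#'
#' @param t Period index (vectorized; any integer, negative allowed).
#' @param q Periods per day (>= 2).
#' @return Circadian level in `[-1, 1]`.
#' @export
#' @examples
#' circadian(c(0, 36, 72), 144)
circadian <- function(t, q) {
  if (!(is.numeric(q) && length(q) == 1 && q >= 2))
    stop("q must be a single number >= 2", call. = FALSE)
  -cos(2 * pi * t / q)
}

#' Circadian thresholds of the classic two-process model
#'
#' Upper and lower switching bounds tied to the circadian level:
#' `H_u = Hbar_u + a * y`, `H_l = Hbar_l - a * y`.
#'
#' @param y Circadian level (vectorized).
#' @param p A `classic_params` object (see [classic_params()]).
#' @return List with numeric components `H_u` and `H_l`.
#' @export
classic_bounds <- function(y, p) {
  stopifnot(inherits(p, "classic_params"))
  list(H_u = p$Hbar_u + p$a * y, H_l = p$Hbar_l - p$a * y)
}

#' Per-period homeostatic decay factor
#'
#' Converts a decay constant quoted in hours into the per-period geometric
#' factor `exp(-1 / nu_tilde)` with `nu_tilde = nu * q / 24` periods. The
#' constant is treated as an e-folding time (the update equations apply
#' `exp(-1/nu)` directly), not as a ln(2)-scaled half-life; the alternative
#' factor is `decay_factor(nu / log(2), q)`.
#'
#' @param nu_hours Decay constant in hours (> 0).
#' @param q Periods per day.
#' @return Per-period decay factor in (0, 1).
#' @export
decay_factor <- function(nu_hours, q) {
  stopifnot(nu_hours > 0, q >= 2)
  exp(-24 / (nu_hours * q))
}

#' One homeostatic update step
#'
#' Exponential approach of sleep pressure toward the asymptote selected by
#' the current action: `H' = upper + (H - upper) * exp(-1/nu_tilde_W)` while
#' awake, `H' = lower + (H - lower) * exp(-1/nu_tilde_S)` while asleep. A
#' contraction: trajectories started inside `(lower, upper)` never leave it.
#'
#' @param H Current homeostat level, in `[lower, upper]`.
#' @param asleep Logical or 0/1 action flag (1 = asleep).
#' @param upper,lower Asymptotes (`upper > lower`).
#' @param nu_W,nu_S Decay constants in hours.
#' @param q Periods per day.
#' @return Updated homeostat level.
#' @export
#' @examples
#' homeostat_step(0, asleep = FALSE, upper = 1, lower = 0,
#'                nu_W = 8, nu_S = 8, q = 144)
homeostat_step <- function(H, asleep, upper, lower, nu_W, nu_S, q) {
  stopifnot(upper > lower)
  if (any(H < lower - 1e-12) || any(H > upper + 1e-12))
    stop("H outside [lower, upper]", call. = FALSE)
  a <- as.logical(asleep)
  ifelse(a,
         lower + (H - lower) * decay_factor(nu_S, q),
         upper + (H - upper) * decay_factor(nu_W, q))
}

#' Per-period autoregressive coefficient of the environmental state
#'
#' The persistence `rho` is quoted per hour; with `q/24` periods per hour the
#' per-period coefficient is `rho^(24/q)` (`convention = "per_hour"`, the
#' default). The alternative `"per_day_root"` reading, `rho^(1/q)`, treats
#' the exponent as one over the periods in a day and yields far stronger
#' persistence; it is retained for comparison.
#'
#' @param rho Persistence in `[0, 1)`.
#' @param q Periods per day.
#' @param convention `"per_hour"` or `"per_day_root"`.
#' @return Per-period AR(1) coefficient.
#' @export
rho_per_period <- function(rho, q,
                           convention = c("per_hour", "per_day_root")) {
  convention <- match.arg(convention)
  stopifnot(rho >= 0, rho < 1, q >= 2)
  if (convention == "per_hour") rho^(24 / q) else rho^(1 / q)
}

#' One step of the environmental state
#'
#' AR(1) update of the log-productivity state:
#' `z' = rho_pp * z + sigma * eps`, with `rho_pp` from [rho_per_period()].
#' With `sigma = 0` the state decays geometrically to 0 from any start; the
#' stationary standard deviation is `sigma / sqrt(1 - rho_pp^2)`.
#'
#' @param z Current state.
#' @param eps Standard-normal draw.
#' @param rho Per-hour persistence in `[0, 1)`.
#' @param sigma Innovation standard deviation (>= 0).
#' @param q Periods per day.
#' @param rho_convention Passed to [rho_per_period()].
#' @return Updated state.
#' @export
env_step <- function(z, eps, rho, sigma, q, rho_convention = "per_hour") {
  stopifnot(sigma >= 0)
  rho_per_period(rho, q, rho_convention) * z + sigma * eps
}

#' Reproducible bank of standard-normal draws
#'
#' A fixed, ordered series of N(0, 1) variates reused verbatim across every
#' simulation of a calibration run (common random numbers), so the moment
#' objective is a deterministic function of the parameters. The same seed and
#' length always reproduce bitwise-identical draws; the caller's RNG state is
#' left untouched.
#'
#' @param length Number of draws (> 0).
#' @param seed Integer seed.
#' @return A `draw_bank`: list with `draws`, `seed`, `length`.
#' @export
#' @examples
#' b <- make_draw_bank(1000, seed = 1)
#' mean(b$draws)
make_draw_bank <- function(length, seed) {
  stopifnot(length > 0)
  draws <- withr::with_seed(as.integer(seed), rnorm(length))
  structure(list(draws = draws, seed = as.integer(seed),
                 length = as.integer(length)),
            class = "draw_bank")
}

#' @export
print.draw_bank <- function(x, ...) {
  cat("<draw_bank> length", x$length, "seed", x$seed, "\n")
  invisible(x)
}
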
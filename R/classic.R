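#' Parameters of the classic two-process model
#'
#' The deterministic threshold-switching baseline: sleep pressure `H` rises
#' toward `mu` while awake and falls toward `lower` (0 in the textbook
#' normalization) while asleep, switching state when it crosses the circadian
#' bounds of [classic_bounds()].
#'
#' The defaults are illustrative only -- no normative parameter values exist
#' for this baseline -- and are chosen to produce a clean mono- or biphasic
#' pattern at `q = 144`.
#'
#' @param Hbar_u,Hbar_l Mean upper and lower bounds (`Hbar_u > Hbar_l`).
#' @param a Circadian bound amplitude (>= 0).
#' @param mu Waking asymptote (> 0).
#' @param lower Sleeping asymptote (default 0).
#' @param nu_W,nu_S Decay constants in hours.
#' @param q Periods per day.
#' @return A `classic_params` object.
#' @export
classic_params <- function(Hbar_u = 0.8, Hbar_l = 0.2, a = 0.15, mu = 1,
                           lower = 0, nu_W = 8, nu_S = 8, q = 144) {
  stopifnot(Hbar_u > Hbar_l, a >= 0, mu > lower, nu_W > 0, nu_S > 0, q >= 2)
  structure(list(Hbar_u = Hbar_u, Hbar_l = Hbar_l, a = a, mu = mu,
                 lower = lower, nu_W = nu_W, nu_S = nu_S, q = as.integer(q)),
            class = "classic_params")
}

#' Simulate the classic two-process model
#'
#' Deterministic threshold switching: the subject wakes until `H` first
#' reaches the upper bound `H_u(t)`, sleeps until `H` first reaches the lower
#' bound `H_l(t)`, with `H` following the exponential updates of
#' [homeostat_step()] in between. In discrete time the switch happens at the
#' first period at-or-beyond the bound, so crossing times are resolved to one
#' period.
#'
#' @param p A `classic_params` object.
#' @param days Number of days to simulate (>= 1).
#' @param H0 Initial homeostat level, within `[Hbar_l - a, Hbar_u + a]`.
#' @param asleep0 Initial state (default awake).
#' @return A `classic_trajectory`: list with integer `t`, numeric `H`,
#'   `H_u`, `H_l`, integer `asleep` and the parameters.
#' @export
#' @examples
#' tr <- simulate_classic(classic_params(), days = 3)
#' mean(tr$asleep)
simulate_classic <- function(p, days, H0 = p$Hbar_l, asleep0 = FALSE) {
  stopifnot(inherits(p, "classic_params"))
  if (!(is.numeric(days) && length(days) == 1 && days >= 1))
    stop("days must be >= 1", call. = FALSE)
  if (H0 < p$Hbar_l - p$a - 1e-12 || H0 > p$Hbar_u + p$a + 1e-12)
    stop("H0 outside the attainable band", call. = FALSE)
  n <- as.integer(days) * p$q
  aW <- decay_factor(p$nu_W, p$q)
  aS <- decay_factor(p$nu_S, p$q)
  y <- circadian(0:(p$q - 1), p$q)
  H <- numeric(n); A <- integer(n); Hu <- numeric(n); Hl <- numeric(n)
  h <- H0; a <- as.integer(asleep0)
  for (t in seq_len(n) - 1L) {
    yt <- y[t %% p$q + 1L]
    hu <- p$Hbar_u + p$a * yt
    hl <- p$Hbar_l - p$a * yt
    if (a == 0L && h >= hu) a <- 1L
    else if (a == 1L && h <= hl) a <- 0L
    h <- if (a == 1L) p$lower + (h - p$lower) * aS
         else p$mu + (h - p$mu) * aW
    H[t + 1L] <- h; A[t + 1L] <- a; Hu[t + 1L] <- hu; Hl[t + 1L] <- hl
  }
  structure(list(t = seq_len(n) - 1L, H = H, H_u = Hu, H_l = Hl,
                 asleep = A, params = p),
            class = "classic_trajectory")
}

#' @export
print.classic_trajectory <- function(x, ...) {
  cat("<classic_trajectory>", length(x$t), "periods,",
      length(x$t) / x$params$q, "days; asleep fraction",
      round(mean(x$asleep), 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.classic_trajectory <- function(x, ...) {
  data.frame(t = x$t, H = x$H, H_u = x$H_u, H_l = x$H_l, asleep = x$asleep)
}
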
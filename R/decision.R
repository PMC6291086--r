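#' Utility from waking activity
#'
#' Foraging (and all other productive waking activity) yields
#' `[exp(z) * xi * (mu_W - H_prev)^eta]^gamma`: productivity scales with the
#' environmental state, with the opportunity-cost level `xi`, and with the
#' remaining waking capacity `mu_W - H_prev` -- a tired animal (high sleep
#' pressure) forages poorly, and at `H_prev = mu_W` waking yields nothing.
#' Utility while asleep is zero by construction, so this term only enters the
#' wake branch of [action_utility()].
#'
#' @param H_prev Homeostat level entering the period (<= `mu_W`).
#' @param z Environmental state.
#' @param p A `model_params` object.
#' @return Non-negative utility value.
#' @export
#' @examples
#' waking_utility(0.5, 0, model_params(gamma = 0.8))
waking_utility <- function(H_prev, z, p) {
  if (any(H_prev > p$mu_W + 1e-12))
    stop("H_prev > mu_W", call. = FALSE)
  cap <- pmax(p$mu_W - H_prev, 0)
  (exp(z) * p$xi * cap^p$eta)^p$gamma
}

#' Circadian adherence penalty
#'
#' The loss `chi * |H_next - y|^kappa` for the homeostat straying from the
#' circadian cycle. Large `kappa` makes the band `|H - y| < 1` nearly free
#' and its exterior prohibitively costly, recovering the hard thresholds of
#' the classic two-process model as a limiting case.
#'
#' @param H_next Homeostat level after the candidate update.
#' @param y Circadian level.
#' @param p A `model_params` object.
#' @return Non-negative penalty (a loss; it enters utility negatively).
#' @export
circadian_penalty <- function(H_next, y, p) {
  p$chi * abs(H_next - y)^p$kappa
}

#' Decision context entering a period
#'
#' @param H_prev Homeostat level entering the period.
#' @param A_prev Previous action (1 = asleep, 0 = awake).
#' @param y Circadian level this period.
#' @param z Environmental state this period.
#' @return A `choice_context` list.
#' @export
choice_context <- function(H_prev, A_prev, y, z) {
  stopifnot(A_prev %in% c(0, 1))
  structure(list(H_prev = H_prev, A_prev = as.integer(A_prev), y = y, z = z),
            class = "choice_context")
}

#' Utility of a candidate action
#'
#' Evaluates one branch of the per-period objective. The candidate homeostat
#' update `H_next(A)` (the branch of [homeostat_step()] matching `A`) feeds
#' the circadian penalty; the waking branch additionally earns
#' [waking_utility()] computed at the *incoming* stock `H_prev`; switching
#' state costs `lam`:
#' `U(A) = (1 - A) * U_w(H_prev, z) - circadian_penalty(H_next(A), y)
#'   - lam * |A - A_prev|`.
#'
#' @param ctx A `choice_context`.
#' @param A Candidate action, 0 (awake) or 1 (asleep).
#' @param p A `model_params` object.
#' @return Utility value of taking action `A`.
#' @export
action_utility <- function(ctx, A, p) {
  if (!A %in% c(0, 1)) stop("invalid action: A must be 0 or 1", call. = FALSE)
  H_next <- homeostat_step(ctx$H_prev, asleep = (A == 1),
                           upper = p$mu_W, lower = p$mu_S,
                           nu_W = p$nu_W, nu_S = p$nu_S, q = p$q)
  base <- -circadian_penalty(H_next, ctx$y, p) - p$lam * abs(A - ctx$A_prev)
  if (A == 0) base + waking_utility(ctx$H_prev, ctx$z, p) else base
}

#' Myopic sleep/wake choice
#'
#' Evaluates [action_utility()] for both actions and returns the argmax --
#' the animal takes whichever of sleeping or waking yields the greater
#' utility this period, with no lookahead. On an exact tie the previous
#' action is kept: any infinitesimal switching cost would resolve the tie
#' that way, and it keeps the simulator deterministic.
#'
#' @param ctx A `choice_context`.
#' @param p A `model_params` object.
#' @return A `choice_result`: list with the chosen action `A`, the updated
#'   homeostat `H_next`, the realized utility `U = max(U_wake, U_sleep)`,
#'   and both candidate utilities.
#' @export
#' @examples
#' ctx <- choice_context(H_prev = 0.5, A_prev = 0, y = -1, z = 0)
#' choose_action(ctx, preset("elephant_captive"))$A
choose_action <- function(ctx, p) {
  U_wake <- action_utility(ctx, 0, p)
  U_sleep <- action_utility(ctx, 1, p)
  A <- if (U_sleep > U_wake) 1L else if (U_wake > U_sleep) 0L else ctx$A_prev
  H_next <- homeostat_step(ctx$H_prev, asleep = (A == 1L),
                           upper = p$mu_W, lower = p$mu_S,
                           nu_W = p$nu_W, nu_S = p$nu_S, q = p$q)
  structure(list(A = A, H_next = H_next, U = max(U_wake, U_sleep),
                 U_wake = U_wake, U_sleep = U_sleep),
            class = "choice_result")
}
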
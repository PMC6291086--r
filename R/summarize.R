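traj_actions <- function(x, q = NULL) {
  if (inherits(x, "sleep_trajectory")) list(A = x$A, q = x$params$q)
  else {
    if (is.null(q)) stop("supply q when passing a raw action vector",
                         call. = FALSE)
    if (!all(x %in% c(0, 1))) stop("actions must be 0/1", call. = FALSE)
    list(A = as.integer(x), q = as.integer(q))
  }
}

#' Sleep episodes of a trajectory
#'
#' Decomposes the asleep indicator into maximal runs of consecutive asleep
#' periods. Each episode records its starting period, length, duration in
#' hours (`length * 24 / q`) and the day containing its first period --
#' episodes crossing midnight are counted once, attributed to the day they
#' start in. With `cyclic = TRUE` the series is treated as circular (for
#' stylized limit cycles): a sleep run spanning the end/start boundary is a
#' single episode starting at its wrapped position.
#'
#' @param x A `sleep_trajectory`, or a 0/1 action vector (then give `q`).
#' @param q Periods per day, when `x` is a raw vector.
#' @param cyclic Treat the series as circular.
#' @return A data frame with columns `start` (0-based period index),
#'   `length`, `duration_hours`, `day` (0-based); zero rows if always awake.
#' @export
#' @examples
#' sleep_episodes(c(0, 1, 1, 0, 1, 0), q = 6)
sleep_episodes <- function(x, q = NULL, cyclic = FALSE) {
  ta <- traj_actions(x, q)
  A <- ta$A
  n <- length(A)
  empty <- data.frame(start = integer(0), length = integer(0),
                      duration_hours = numeric(0), day = integer(0))
  if (n == 0 || !any(A == 1)) return(empty)
  r <- rle(A)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L
  st <- starts[keep] - 1L   # 0-based
  len <- r$lengths[keep]
  if (cyclic && A[1] == 1L && A[n] == 1L && !all(A == 1L)) {
    # merge the wrap-around run: it starts at the tail position
    k <- length(st)
    len[k] <- len[k] + len[1]
    st <- st[-1]; len <- len[-1]
  }
  data.frame(start = st, length = as.integer(len),
             duration_hours = len * 24 / ta$q,
             day = as.integer(st %/% ta$q))
}

#' Daily sleep summary
#'
#' Hours of sleep per day (asleep-period count times `24/q`, day boundaries
#' every `q` periods from the trajectory start), their mean and across-day
#' standard deviation, and episodes per day (attributed to the day an
#' episode starts in). The SD uses the population formula (divide by the
#' number of days): with the long horizons used here the sample/population
#' distinction is negligible, and the population form makes one-day
#' summaries well-defined.
#'
#' @param x A `sleep_trajectory`, or a 0/1 action vector (then give `q`).
#' @param q Periods per day, when `x` is a raw vector.
#' @return A `daily_summary`: list with `n_days`, `mean_hours`, `sd_hours`,
#'   `mean_episodes_per_day` and a `per_day` data frame (`day`, `hours`,
#'   `episodes`).
#' @export
#' @examples
#' daily_summary(rep(c(1, 0, 0, 0), 6), q = 12)
daily_summary <- function(x, q = NULL) {
  ta <- traj_actions(x, q)
  n <- length(ta$A)
  if (n %% ta$q != 0)
    stop("trajectory length is not a whole number of days; trim the ",
         "partial trailing day first", call. = FALSE)
  n_days <- n %/% ta$q
  hours <- colSums(matrix(ta$A, nrow = ta$q)) * 24 / ta$q
  ep <- sleep_episodes(ta$A, ta$q)
  ep_per_day <- tabulate(ep$day + 1L, nbins = n_days)
  structure(list(
    n_days = n_days,
    mean_hours = mean(hours),
    sd_hours = sqrt(mean((hours - mean(hours))^2)),
    mean_episodes_per_day = mean(ep_per_day),
    per_day = data.frame(day = seq_len(n_days) - 1L, hours = hours,
                         episodes = ep_per_day)),
    class = "daily_summary")
}

#' @export
print.daily_summary <- function(x, ...) {
  cat("<daily_summary>", x$n_days, "day(s): mean",
      round(x$mean_hours, 3), "h, SD", round(x$sd_hours, 3), "h,",
      round(x$mean_episodes_per_day, 2), "episodes/day\n")
  invisible(x)
}

#' Range of per-period utility over a stylized cycle
#'
#' The difference between the highest and lowest realized per-period utility
#' over a converged noise-free cycle -- a gauge of how strong the within-day
#' utility swings are relative to, say, the switching cost.
#'
#' @param day A converged `stylized_cycle` from [simulate_stylized()].
#' @return `max(U) - min(U)` over the cycle.
#' @export
utility_range <- function(day) {
  if (!inherits(day, "stylized_cycle"))
    stop("utility_range requires a converged stylized cycle from ",
         "simulate_stylized()", call. = FALSE)
  max(day$U) - min(day$U)
}

#' Deterministic wake/sleep fixture
#'
#' Builds a binary action series with exactly the requested episode
#' structure, for testing [sleep_episodes()] and [daily_summary()]
#' independently of the simulator. Episodes are given as a data frame of
#' (0-based) `day`, `start` (period within the day, 0-based) and `length`
#' (periods); each must fit inside its day and episodes must be separated by
#' at least one awake period.
#'
#' @param spec Data frame with columns `day`, `start`, `length`.
#' @param days Total days in the series.
#' @param q Periods per day.
#' @return A `sleep_trajectory` carrying only the action series (no
#'   homeostat, environment or utility components).
#' @export
#' @examples
#' fx <- make_fixture(data.frame(day = 0, start = c(0, 20), length = 9),
#'                    days = 1, q = 144)
#' daily_summary(fx)$mean_hours
make_fixture <- function(spec, days, q) {
  stopifnot(is.data.frame(spec), all(c("day", "start", "length")
                                     %in% names(spec)), days >= 1, q >= 2)
  n <- as.integer(days) * as.integer(q)
  A <- integer(n)
  if (nrow(spec)) {
    if (any(spec$length < 1)) stop("episode length must be >= 1",
                                   call. = FALSE)
    if (any(spec$start < 0 | spec$start + spec$length > q))
      stop("episode overflows its day", call. = FALSE)
    if (any(spec$day < 0 | spec$day >= days))
      stop("episode day out of range", call. = FALSE)
    for (i in seq_len(nrow(spec))) {
      idx <- spec$day[i] * q + spec$start[i] + seq_len(spec$length[i])
      lo <- max(1, min(idx) - 1); hi <- min(n, max(idx) + 1)
      if (any(A[lo:hi] == 1L))
        stop("episodes overlap or touch (no separating awake period)",
             call. = FALSE)
      A[idx] <- 1L
    }
  }
  structure(list(t = seq_len(n) - 1L, A = A, H = NULL, z = NULL, U = NULL,
                 y = NULL, daily_hours = colSums(matrix(A, nrow = q)) * 24 / q,
                 params = list(q = as.integer(q)), n_days = as.integer(days),
                 burn_in = 0L, seed = NA_integer_, rho_convention = NA),
            class = "sleep_trajectory")
}
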
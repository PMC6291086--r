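#' Write and read trajectory CSV files
#'
#' Trajectories are exchanged as plain CSV with the fixed column order
#' `day, period, t, y, z, H, A, U` (no domain standard exists for simulated
#' sleep trajectories, and a fixed order keeps files diffable). Numeric
#' columns are written with enough digits for a lossless round-trip.
#'
#' @param traj A `sleep_trajectory`.
#' @param path Output / input file path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a `sleep_trajectory` (action series and per-period columns;
#'   model parameters other than `q` are not stored in the file).
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "sleep_trajectory"))
  df <- as.data.frame(traj)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                scientific = FALSE,
                                                trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- tryCatch(read.csv(path), error = function(e)
    stop("malformed trajectory CSV ", path, ": ", conditionMessage(e),
         call. = FALSE))
  cols <- c("day", "period", "t", "y", "z", "H", "A", "U")
  if (!identical(names(df), cols))
    stop("trajectory CSV must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  bad <- which(!(df$A %in% c(0, 1)))
  if (length(bad))
    stop("non-binary action in ", path, " at data line ", bad[1],
         call. = FALSE)
  if (nrow(df) == 0) {
    return(structure(list(t = integer(0), A = integer(0), H = numeric(0),
                          z = numeric(0), U = numeric(0), y = numeric(0),
                          daily_hours = numeric(0),
                          params = list(q = NA_integer_), n_days = 0L,
                          burn_in = NA_integer_, seed = NA_integer_,
                          rho_convention = NA),
                     class = "sleep_trajectory"))
  }
  q <- max(df$period) + 1L
  n_days <- nrow(df) %/% q
  structure(list(t = df$t, A = as.integer(df$A), H = df$H, z = df$z,
                 U = df$U, y = df$y,
                 daily_hours = if (nrow(df) %% q == 0)
                   colSums(matrix(df$A, nrow = q)) * 24 / q else numeric(0),
                 params = list(q = q), n_days = n_days,
                 burn_in = NA_integer_, seed = NA_integer_,
                 rho_convention = NA),
            class = "sleep_trajectory")
}
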
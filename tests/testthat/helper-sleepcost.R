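# Reference stepper: drives the exported per-period primitives
# (env_step + choose_action) through time in plain R. Used as the
# independent oracle for the compiled simulation kernel.
step_oracle <- function(p, eps, H0 = 0, A0 = 0L,
                        rho_convention = "per_hour") {
  n <- length(eps)
  z <- 0; h <- H0; a <- A0
  A <- integer(n); H <- numeric(n); Z <- numeric(n); U <- numeric(n)
  for (t in seq_len(n)) {
    z <- env_step(z, eps[t], p$rho, p$sigma, p$q, rho_convention)
    y <- circadian(t - 1, p$q)
    res <- choose_action(choice_context(h, a, y, z), p)
    a <- res$A; h <- res$H_next
    A[t] <- a; H[t] <- h; Z[t] <- z; U[t] <- res$U
  }
  list(A = A, H = H, z = Z, U = U)
}

stylized_episode_count <- function(day) {
  nrow(sleep_episodes(day, cyclic = TRUE)) / day$period_days
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
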
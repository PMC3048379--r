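# Shared fixtures, built in code at test time.

REF_GROUPS <- c("AT", "DAT", "NoAT")

# Noiseless synthetic participant at the reference parameters of `group`.
noiseless_participant <- function(group, seed = 1L) {
  generate_participant(build_paper_schedule(group, seed = seed),
                       group_params_default(group),
                       noise_sd = 0, outlier_rate = 0,
                       participant = group, group = group)
}

# One noiseless participant per group.
noiseless_cohort <- function() {
  out <- lapply(REF_GROUPS, noiseless_participant)
  names(out) <- REF_GROUPS
  out
}

# The simulation layout with 120 pre-rotation movements.
fig_layout <- function(rotation_block = "rotation_strategy", n_rot = 322) {
  lens <- c(baseline = 120)
  lens[rotation_block] <- n_rot
  build_custom_schedule(lens)
}

# Independent affine-map oracle for the full dynamic-strategy recursion:
# propagates (x_hat, s) through per-trial 2x2 matrices instead of the
# package's scalar stepping, and returns the per-trial target error.
matrix_oracle <- function(schedule, params) {
  A <- params$A; B <- params$B; E <- params$E
  K <- params$K; F <- params$F; sstar <- params$s_star
  v <- c(0, 0)
  n <- nrow(schedule)
  e <- numeric(n)
  prev_rot <- FALSE
  for (i in seq_len(n)) {
    b <- schedule$block[i]
    r <- schedule$rotation_deg[i]
    if (b == "rotation_strategy" && !prev_rot) v[2] <- sstar
    else if (b == "strategy_only") v[2] <- sstar
    else if (b != "rotation_strategy") v[2] <- 0
    prev_rot <- b == "rotation_strategy"
    e[i] <- r - v[1] + v[2]
    if (schedule$feedback[i]) {
      if (b == "rotation_strategy") {
        M <- rbind(c(A - B, B * (1 - K)), c(F, E - F))
        cvec <- c(B * r, -F * r)
        v <- as.vector(M %*% v + cvec)
      } else if (b == "strategy_only") {
        # veridical feedback on the aim: learning error is -x_hat
        v[1] <- (A - B) * v[1]
      } else {
        # no strategy in use: error signal is r - x_hat
        v[1] <- A * v[1] + B * (r - v[1])
      }
    }
  }
  e
}

# Closed-form state after n rotation+strategy trials from (0, s_star),
# using matrix powers through an eigendecomposition.
matrix_power_state <- function(params, n_trials) {
  A <- params$A; B <- params$B; E <- params$E
  K <- params$K; F <- params$F
  r <- params$r_mag
  M <- rbind(c(A - B, B * (1 - K)), c(F, E - F))
  cvec <- c(B * r, -F * r)
  eg <- eigen(M)
  Mp <- eg$vectors %*% diag(eg$values^n_trials) %*% solve(eg$vectors)
  v0 <- c(0, params$s_star)
  as.vector(Re(Mp %*% v0 + (diag(2) - Mp) %*% solve(diag(2) - M, cvec)))
}
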
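MODEL_VARIANTS <- c("standard", "feedthrough_target_error",
                    "feedthrough_fixed_strategy",
                    "feedthrough_fixed_strategy_K", "full_dynamic")

#' Model parameters for the setpoint state-space family
#'
#' @param A Retention factor of the internal model, in \[0, 1\].
#' @param B Adaptation rate on the (aiming) error input, in \[0, 1\].
#' @param E Retention factor of the strategy state, in \[0, 1\].
#' @param K Availability/certainty weight on the instructed aiming
#'   location, in \[0, 1\] (bounded below by 0.1 when produced by fitting).
#' @param F Strategy adjustment rate on target error, in \[0, 1\].
#' @param s_star Instructed strategy angle in degrees (default +45,
#'   clockwise positive).
#' @param r_mag Rotation magnitude in degrees (default -45,
#'   counter-clockwise negative).
#' @return A `model_params` list.
#' @examples
#' p <- model_params(A = 1, B = 0.02, K = 1, F = 0)
#' @export
model_params <- function(A = 0.991, B = 0.012, E = 0.999, K = 0.985,
                         F = 0.023, s_star = 45, r_mag = -45) {
  p <- list(A = A, B = B, E = E, K = K, F = F,
            s_star = s_star, r_mag = r_mag)
  for (nm in c("A", "B", "E", "K", "F")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("parameter ", nm, " must be a single value in [0, 1]")
  }
  structure(p, class = "model_params")
}

#' Reference parameter sets for the three landmark-availability groups
#'
#' Group-level estimates of the full dynamic-strategy model: retention `A`,
#' adaptation rate `B` and strategy retention `E` shared across groups;
#' aiming-location availability `K` and strategy adjustment rate `F` per
#' group (`K` decreasing and drift correspondingly weaker from AT to DAT to
#' NoAT). Used as the defaults of the synthetic-cohort generator.
#'
#' @param group Optional single group label; if given, that group's
#'   `model_params` is returned instead of the full list.
#' @return Named list of `model_params` (or a single `model_params`).
#' @export
group_params_default <- function(group = NULL) {
  ps <- list(
    AT   = model_params(A = 0.991, B = 0.012, E = 0.999, K = 0.985, F = 0.023),
    DAT  = model_params(A = 0.991, B = 0.012, E = 0.999, K = 0.409, F = 0.002),
    NoAT = model_params(A = 0.991, B = 0.012, E = 0.999, K = 0.195, F = 0.725)
  )
  if (is.null(group)) return(ps)
  if (!group %in% names(ps)) stop("unknown group label: '", group, "'")
  ps[[group]]
}

block_code_of <- function(block) {
  ifelse(block == "strategy_only", 1L,
         ifelse(block == "rotation_strategy", 2L, 0L))
}

#' Simulate a model variant over a trial schedule
#'
#' Runs the deterministic trial-by-trial recursion from the zero state
#' (`x_hat = 0`, `s = 0`). Per trial the target error is
#' `e = r - x_hat + s`, the aiming error `ehat = r - x_hat + (1 - K) * s`
#' (the aiming location is the current strategy state -- re-aiming
#' recenters the setpoint -- weighted by its availability `K`), and the
#' hand angle is `h = e - r`. The internal-model update is
#' `x_hat' = A * x_hat + B * err`, where `err` is the target error for the
#' `standard` and `feedthrough_target_error` variants and the aiming error
#' otherwise. For `full_dynamic` the strategy state follows
#' `s' = E * s - F * e` during the rotation-plus-strategy block, starting
#' from `s = s_star` at the block's first trial and reset to 0 afterwards
#' (washout); for the fixed-strategy variants `s` equals the instructed
#' angle on strategy-instructed trials and 0 elsewhere. No state is updated
#' on no-feedback trials. During strategy-only practice the feedback is
#' veridical and centred on the aim, so the learning error is the true
#' aim-referenced error (the availability weight only matters once cursor
#' and hand are dissociated by the rotation).
#'
#' @param schedule A `trial_schedule`.
#' @param params A `model_params`.
#' @param variant One of `standard`, `feedthrough_target_error`,
#'   `feedthrough_fixed_strategy` (aiming-error driven, K forced to 1),
#'   `feedthrough_fixed_strategy_K` (as before but using `params$K`) or
#'   `full_dynamic` (strategy adjusted by target error).
#' @return A `model_trajectory` data frame: `index`, `block`, `x_hat`, `s`,
#'   `target_error`, `aiming_error`, `hand_angle`.
#' @examples
#' sched <- build_custom_schedule(c(baseline = 120, rotation_strategy = 322))
#' p <- model_params(A = 1, B = 0.02, K = 1)
#' tr <- simulate_model(sched, p, "feedthrough_fixed_strategy")
#' tr$target_error[121]   # 0: immediate compensation by the strategy
#' @export
simulate_model <- function(schedule, params,
                           variant = c("full_dynamic", "standard",
                                       "feedthrough_target_error",
                                       "feedthrough_fixed_strategy",
                                       "feedthrough_fixed_strategy_K")) {
  stopifnot(inherits(schedule, "trial_schedule"))
  if (!inherits(params, "model_params")) params <- do.call(model_params, params)
  variant <- match.arg(variant)
  vcode <- match(variant, MODEL_VARIANTS) - 1L
  m <- .sp_simulate_cpp(block_code_of(schedule$block), schedule$rotation_deg,
                        schedule$strategy_instructed, schedule$feedback,
                        params$A, params$B, params$E, params$K, params$F,
                        params$s_star, vcode)
  out <- data.frame(index = schedule$index, block = schedule$block,
                    as.data.frame(m), stringsAsFactors = FALSE)
  structure(out, variant = variant, params = params,
            class = c("model_trajectory", "data.frame"))
}

#' Advance the model by a single trial
#'
#' Reference single-step implementation of the recursion used by
#' [simulate_model()]. Mostly useful for inspection and testing; for whole
#' sessions use [simulate_model()].
#'
#' @param state List with elements `x_hat` and `s` (degrees).
#' @param params A `model_params`.
#' @param trial One-row data frame (or list) with `block`, `rotation_deg`,
#'   `strategy_instructed`, `feedback`.
#' @param variant Model variant, see [simulate_model()].
#' @return List with `state` (the next state) and `record` (x_hat, s,
#'   target_error, aiming_error, hand_angle for this trial).
#' @export
step_model <- function(state, params,
                       trial, variant = "full_dynamic") {
  if (!inherits(params, "model_params")) params <- do.call(model_params, params)
  variant <- match.arg(variant, MODEL_VARIANTS)
  stopifnot(is.finite(state$x_hat), is.finite(state$s))
  r <- trial$rotation_deg
  instr <- isTRUE(trial$strategy_instructed)
  sstar <- if (variant == "standard") 0 else if (instr) params$s_star else 0

  s <- if (variant == "standard") 0
  else if (variant != "full_dynamic") sstar
  else if (identical(trial$block, "rotation_strategy")) state$s
  else if (instr) params$s_star   # strategy-only practice: pinned at the aim
  else 0

  e <- r - state$x_hat + s
  Keff <- switch(variant,
    feedthrough_fixed_strategy_K = params$K,
    full_dynamic = params$K,
    1)
  if (identical(trial$block, "strategy_only")) Keff <- 1
  ehat <- r - state$x_hat + s - Keff * s
  err <- switch(variant,
    standard = e,
    feedthrough_target_error =
      if (identical(trial$block, "strategy_only")) ehat else e,
    ehat)

  rec <- list(x_hat = state$x_hat, s = s, target_error = e,
              aiming_error = ehat, hand_angle = e - r)
  nxt <- state
  nxt$s <- s
  if (isTRUE(trial$feedback)) {
    nxt$x_hat <- params$A * state$x_hat + params$B * err
    if (variant == "full_dynamic" && identical(trial$block, "rotation_strategy"))
      nxt$s <- params$E * s - params$F * e
  }
  list(state = nxt, record = rec)
}

#' Steady state of the setpoint model
#'
#' Solves the linear fixed-point equations
#' `x_hat = A*x_hat + B*(r - x_hat + (1 - K)*s)` and (for the dynamic
#' strategy) `s = E*s - F*(r - x_hat + s)` exactly, returning the
#' equilibrium internal-model estimate, strategy state and target error
#' `e = r - x_hat + s`. With a fixed strategy, `s` is held at `s_star`.
#'
#' @param params A `model_params`.
#' @param r Rotation in degrees (default `params$r_mag`).
#' @param s_star Instructed strategy angle (default `params$s_star`).
#' @param strategy `"dynamic"` (strategy follows its update equation),
#'   `"fixed"` (strategy held constant at `s_star`) or `"none"` (`s = 0`).
#' @return List with `x_hat`, `s`, `e`. A singular system (e.g. `A = 1`
#'   with `K < 1` and a fixed strategy) stops with "no finite equilibrium".
#' @examples
#' # drift limit of the fixed-strategy model: e -> s_star
#' fixed_point(model_params(A = 1, B = 0.02, K = 1, F = 0), strategy = "fixed")
#' @export
fixed_point <- function(params, r = params$r_mag, s_star = params$s_star,
                        strategy = c("dynamic", "fixed", "none")) {
  if (!inherits(params, "model_params")) params <- do.call(model_params, params)
  strategy <- match.arg(strategy)
  A <- params$A; B <- params$B; E <- params$E
  K <- params$K; F <- params$F
  tol <- 1e-12
  if (strategy %in% c("fixed", "none")) {
    s <- if (strategy == "fixed") s_star else 0
    denom <- 1 - A + B
    if (abs(denom) < tol) stop("no finite equilibrium")
    x <- B * (r + (1 - K) * s) / denom
    return(list(x_hat = x, s = s, e = r - x + s))
  }
  # dynamic strategy: solve the 2x2 linear system
  M <- rbind(c(1 - A + B, -B * (1 - K)),
             c(-F, 1 - E + F))
  b <- c(B * r, -F * r)
  if (abs(det(M)) < tol) stop("no finite equilibrium")
  xs <- solve(M, b)
  list(x_hat = xs[1], s = xs[2], e = r - xs[1] + xs[2])
}

#' Export a simulated trajectory as CSV
#'
#' Columns: `index, block, x_hat, s, target_error, aiming_error, hand_angle`.
#'
#' @param trajectory A `model_trajectory` from [simulate_model()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  df <- as.data.frame(trajectory)[, c("index", "block", "x_hat", "s",
                                      "target_error", "aiming_error",
                                      "hand_angle")]
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "index"
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
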
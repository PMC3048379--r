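#' Configuration for a synthetic cohort
#'
#' Defines the study conditions emulated by the generator: three
#' landmark-availability groups of `n_per_group` participants, each running
#' the default 490-trial session, with group-level model parameters jittered
#' per participant, additive Gaussian motor noise on the observed endpoint,
#' and rare outlier trials on which the strategy is implemented in the
#' wrong direction.
#'
#' @param n_per_group Participants per group (default 10).
#' @param group_params Named list of `model_params`, one per group
#'   (defaults: [group_params_default()]).
#' @param motor_noise_sd SD of trial-to-trial endpoint noise in degrees
#'   (default 4).
#' @param between_subject_sd Named numeric vector of per-participant
#'   parameter jitter SDs; jittered values are clipped back to \[0, 1\].
#'   Defaults are scaled to each parameter's working range: the retention
#'   factors sit within ~0.01 of 1 and drift over a 320-trial block is
#'   extremely sensitive to them, so their jitter is an order of magnitude
#'   smaller than that of `K` and `F`. The scales are chosen so that a
#'   default cohort preserves the between-group drift ordering the groups
#'   are defined by.
#' @param outlier_rate Per-trial outlier probability (default 0.005).
#' @param outlier_mode `"strategy_sign_flip"` (the strategy contribution is
#'   negated, i.e. the participant aimed counter-clockwise instead of
#'   clockwise) or `"uniform_large_error"` (a uniform 30-90 degree deviate
#'   of random sign is added).
#' @param seed Master seed; all participant-level randomness derives from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = 10,
                          group_params = group_params_default(),
                          motor_noise_sd = 4,
                          between_subject_sd = c(A = 0.003, B = 0.003,
                                                 E = 0.001, K = 0.05,
                                                 F = 0.02),
                          outlier_rate = 0.005,
                          outlier_mode = c("strategy_sign_flip",
                                           "uniform_large_error"),
                          seed = 1L) {
  outlier_mode <- match.arg(outlier_mode)
  stopifnot(n_per_group >= 1, motor_noise_sd >= 0,
            outlier_rate >= 0, outlier_rate <= 1,
            all(between_subject_sd >= 0))
  structure(list(n_per_group = as.integer(n_per_group),
                 group_params = group_params,
                 motor_noise_sd = motor_noise_sd,
                 between_subject_sd = between_subject_sd,
                 outlier_rate = outlier_rate,
                 outlier_mode = outlier_mode,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

new_participant_dataset <- function(df, participant, group) {
  df$participant <- participant
  df$group <- group
  rownames(df) <- NULL
  structure(df, class = c("participant_dataset", "data.frame"))
}

#' Generate one synthetic participant
#'
#' Simulates the `full_dynamic` setpoint model deterministically over the
#' schedule and adds observation noise: the observed target error is the
#' model target error plus iid Gaussian noise; the model's internal states
#' evolve on the noiseless path. Outlier trials (strategy-instructed trials
#' only, for `strategy_sign_flip`) replace the strategy contribution with
#' its negation, emulating a movement aimed 45 degrees in the wrong
#' direction.
#'
#' @param schedule A `trial_schedule`.
#' @param params A `model_params`.
#' @param noise_sd Endpoint noise SD in degrees.
#' @param outlier_rate,outlier_mode See [cohort_config()].
#' @param seed Integer seed.
#' @param participant,group Labels stored in the dataset.
#' @return A `participant_dataset`: the schedule columns plus observed
#'   `hand_angle` and `target_error` (degrees), and the noiseless
#'   `model_error` for reference.
#' @export
generate_participant <- function(schedule, params, noise_sd = 4,
                                 outlier_rate = 0.005,
                                 outlier_mode = "strategy_sign_flip",
                                 seed = 1L, participant = "P01",
                                 group = attr(schedule, "group")) {
  stopifnot(inherits(schedule, "trial_schedule"))
  tr <- simulate_model(schedule, params, "full_dynamic")
  n <- nrow(tr)
  obs <- withr_seed(seed, {
    e <- tr$target_error + stats::rnorm(n, 0, noise_sd)
    if (outlier_rate > 0) {
      out <- stats::runif(n) < outlier_rate
      if (outlier_mode == "strategy_sign_flip") {
        out <- out & schedule$strategy_instructed
        e[out] <- e[out] - 2 * tr$s[out]
      } else {
        e[out] <- e[out] + sample(c(-1, 1), sum(out), replace = TRUE) *
          stats::runif(sum(out), 30, 90)
      }
    }
    e
  })
  df <- as.data.frame(schedule)
  df$hand_angle <- obs - df$rotation_deg
  df$target_error <- obs
  df$model_error <- tr$target_error
  new_participant_dataset(df, participant,
                          if (is.null(group)) NA_character_ else group)
}

#' Generate a full synthetic cohort
#'
#' `n_per_group` participants per group, each with group parameters plus
#' truncated-Gaussian jitter and an independent sub-seed derived from the
#' master seed. Reproducible: the same config yields the same cohort.
#'
#' @param config A [cohort_config()].
#' @param schedule_seed Seed for the shared target-order randomization.
#' @return List of `participant_dataset`, length `n_per_group` times the
#'   number of groups.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_per_group = 2, seed = 7))
#' length(cohort)
#' @export
generate_cohort <- function(config = cohort_config(), schedule_seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  groups <- names(config$group_params)
  n <- config$n_per_group
  draws <- withr_seed(config$seed, {
    list(seeds = sample.int(.Machine$integer.max - 1L, n * length(groups)),
         jitter = stats::rnorm(n * length(groups) * 5))
  })
  jit <- matrix(draws$jitter, ncol = 5, byrow = TRUE)
  colnames(jit) <- c("A", "B", "E", "K", "F")
  sds <- config$between_subject_sd
  out <- vector("list", n * length(groups))
  k <- 0L
  for (g in groups) {
    sched <- build_paper_schedule(g, seed = schedule_seed)
    base <- config$group_params[[g]]
    for (i in seq_len(n)) {
      k <- k + 1L
      p <- base
      for (nm in colnames(jit)) {
        sd_nm <- if (nm %in% names(sds)) sds[[nm]] else 0
        p[[nm]] <- min(1, max(0, base[[nm]] + sd_nm * jit[k, nm]))
      }
      id <- sprintf("%s%02d", g, i)
      out[[k]] <- generate_participant(
        sched, p, noise_sd = config$motor_noise_sd,
        outlier_rate = config$outlier_rate,
        outlier_mode = config$outlier_mode,
        seed = draws$seeds[k], participant = id, group = g)
      attr(out[[k]], "params") <- p
    }
  }
  names(out) <- vapply(out, function(d) d$participant[1], character(1))
  out
}

#' Split a cohort list by group
#'
#' @param cohort List of `participant_dataset`.
#' @return Named list of lists, one per group.
#' @export
split_by_group <- function(cohort) {
  groups <- vapply(cohort, function(d) d$group[1], character(1))
  lapply(split(seq_along(cohort), groups), function(i) cohort[i])
}
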
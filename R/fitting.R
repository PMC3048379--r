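FIT_PARAMS <- c("A", "B", "E", "K", "F")

#' Fitting configuration
#'
#' @param bounds Named list of `c(lo, hi)` per parameter. Defaults: `A`,
#'   `B`, `E`, `F` in \[0, 1\]; `K` in \[0.1, 1\] (the lower bound keeps the
#'   simplex away from a `K = 0` local minimum that can trap fits to
#'   low-drift groups).
#' @param init Named numeric start values (default all 0, clipped into the
#'   bounds).
#' @param fitted_blocks Blocks entering the loss; familiarization and
#'   strategy-only practice are excluded by default.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap resampling.
#' @param s_star Instructed strategy angle assumed by the model (degrees).
#' @param maxit,reltol,n_restart Simplex settings: iteration cap, relative
#'   tolerance on the loss, and maximum number of restarts from the best
#'   vertex (restarting stops early once the loss stalls).
#' @return A `fit_config` list.
#' @export
fit_config <- function(bounds = NULL, init = NULL,
                       fitted_blocks = c("baseline", "rotation_probe",
                                         "rotation_strategy",
                                         "no_feedback_aftereffect",
                                         "washout"),
                       n_boot = 1000L, seed = 1L, s_star = 45,
                       maxit = 5000L, reltol = 1e-8, n_restart = 10L) {
  b <- list(A = c(0, 1), B = c(0, 1), E = c(0, 1), K = c(0.1, 1),
            F = c(0, 1))
  b[names(bounds)] <- bounds
  i <- stats::setNames(rep(0, 5), FIT_PARAMS)
  i[names(init)] <- unlist(init)
  for (nm in FIT_PARAMS) {
    i[nm] <- min(max(i[nm], b[[nm]][1]), b[[nm]][2])
    if (b[[nm]][1] > b[[nm]][2]) stop("invalid bounds for ", nm)
  }
  structure(list(bounds = b, init = i, fitted_blocks = fitted_blocks,
                 n_boot = as.integer(n_boot), seed = as.integer(seed),
                 s_star = s_star, maxit = as.integer(maxit),
                 reltol = reltol, n_restart = as.integer(n_restart)),
            class = "fit_config")
}

# Smooth logistic reparameterization keeping the simplex unconstrained:
# theta = lo + (hi - lo) * plogis(z). Hard clipping would create flat
# regions that stall Nelder-Mead.
to_unconstrained <- function(theta, bounds) {
  z <- numeric(length(theta))
  for (j in seq_along(theta)) {
    lo <- bounds[[j]][1]; hi <- bounds[[j]][2]
    f <- (theta[j] - lo) / (hi - lo)
    z[j] <- stats::qlogis(min(max(f, 1e-3), 1 - 1e-3))
  }
  # optim's Nelder-Mead scales its initial simplex by max(|par|); snap
  # rounding dust to zero so a mid-bounds start is not degenerate
  z[abs(z) < 1e-9] <- 0
  z
}

to_bounded <- function(z, bounds) {
  theta <- numeric(length(z))
  for (j in seq_along(z)) {
    lo <- bounds[[j]][1]; hi <- bounds[[j]][2]
    theta[j] <- lo + (hi - lo) * stats::plogis(z[j])
  }
  theta
}

fitted_mask <- function(dataset, config) {
  mask <- dataset$block %in% config$fitted_blocks
  if (!any(mask)) stop("no trials fall in the fitted blocks")
  mask
}

#' Root-mean-square loss of the full dynamic-strategy model
#'
#' Simulates the `full_dynamic` variant on the dataset's schedule and
#' returns the RMS of observed minus predicted target error over the
#' fitted blocks only.
#'
#' @param params A `model_params` (or coercible list).
#' @param dataset A `participant_dataset` or group-averaged series with
#'   the schedule columns and observed `target_error`.
#' @param config A [fit_config()].
#' @return RMS error in degrees.
#' @export
sp_loss <- function(params, dataset, config = fit_config()) {
  if (!inherits(params, "model_params")) params <- do.call(model_params, params)
  mask <- fitted_mask(dataset, config)
  .sp_rms_cpp(block_code_of(dataset$block), dataset$rotation_deg,
              dataset$strategy_instructed, dataset$feedback,
              params$A, params$B, params$E, params$K, params$F,
              config$s_star, dataset$target_error, mask)
}

#' Average a set of participant datasets trial-by-trial
#'
#' Participants must share the same schedule (block structure, rotation and
#' feedback flags); observed target errors and hand angles are averaged by
#' trial index. Trials missing from some participants (e.g. removed as
#' outliers) are averaged over the participants that retain them.
#'
#' @param datasets List of `participant_dataset`.
#' @return A group-averaged series with the same schedule columns.
#' @export
group_average <- function(datasets) {
  stopifnot(length(datasets) >= 1)
  idx <- sort(unique(unlist(lapply(datasets, `[[`, "index"))))
  n <- length(idx)
  em <- hm <- matrix(NA_real_, n, length(datasets))
  tmpl <- datasets[[1]][match(idx, datasets[[1]]$index), ]
  for (k in seq_along(datasets)) {
    d <- datasets[[k]]
    pos <- match(d$index, idx)
    em[pos, k] <- d$target_error
    hm[pos, k] <- d$hand_angle
    mism <- which(!is.na(tmpl$block[pos]) & tmpl$block[pos] != d$block)
    if (length(mism))
      stop("participants must share the same schedule")
    fill <- which(is.na(tmpl$block))
    if (length(fill)) {
      repl <- match(idx[fill], d$index)
      ok <- !is.na(repl)
      tmpl[fill[ok], ] <- d[repl[ok], ]
    }
  }
  avg <- tmpl
  avg$index <- idx
  avg$target_error <- rowMeans(em, na.rm = TRUE)
  avg$hand_angle <- rowMeans(hm, na.rm = TRUE)
  avg$participant <- "group_average"
  rownames(avg) <- NULL
  avg
}

# Simplex minimization with restarts from the best vertex until the loss
# stalls, repeated from a small deterministic set of starting points (the
# configured start plus extra spread starts); the best final vertex wins.
# A single zero start can strand the simplex in a local minimum (the same
# pathology that motivates the 0.1 lower bound on K), so the extra starts
# cover the mid-bounds point and a high-retention regime typical of
# adaptation fits.
nm_minimize <- function(fn, z0, config, extra_starts = list()) {
  ctl <- list(maxit = config$maxit, reltol = config$reltol)
  run <- function(z) {
    res <- stats::optim(z, fn, method = "Nelder-Mead", control = ctl)
    for (i in seq_len(config$n_restart)) {
      res2 <- stats::optim(res$par, fn, method = "Nelder-Mead",
                           control = ctl)
      if (res2$value >= res$value - 1e-10) {
        res <- res2
        break
      }
      res <- res2
    }
    res
  }
  best <- run(z0)
  for (z in extra_starts) {
    cand <- run(z)
    if (cand$value < best$value) best <- cand
  }
  if (best$convergence != 0) {
    polish <- stats::optim(best$par, fn, method = "Nelder-Mead",
                           control = list(maxit = 2L * config$maxit,
                                          reltol = config$reltol))
    if (polish$value <= best$value) best <- polish
  }
  best
}

# Extra deterministic starting points, recycled to the parameter layout of
# `bounds` (A, B, E then K, F per group). The mid start is the exact
# midpoint of every bound range (z = 0, giving optim's default simplex
# step); the two retention starts reflect the high-retention regime
# typical of adaptation fits, with the strategy either nearly fixed
# (low F) or strongly target-error-driven (high F).
spread_starts <- function(bounds) {
  ret <- function(Fv) {
    theta <- vapply(names(bounds), function(nm) {
      v <- switch(substr(nm, 1, 1),
                  A = 0.9, B = 0.1, E = 0.9, K = 0.5, F = Fv)
      min(max(v, bounds[[nm]][1]), bounds[[nm]][2])
    }, numeric(1))
    to_unconstrained(theta, bounds)
  }
  list(mid = rep(0, length(bounds)),
       retention_low_F = ret(0.1),
       retention_high_F = ret(0.9))
}

finish_fit <- function(theta, dataset, config, convergence) {
  theta <- unname(theta)
  p <- model_params(A = theta[1], B = theta[2], E = theta[3],
                    K = theta[4], F = theta[5], s_star = config$s_star)
  mask <- fitted_mask(dataset, config)
  sched <- new_trial_schedule(
    as.data.frame(dataset)[, c("index", "block", "rotation_deg",
                               "strategy_instructed", "feedback",
                               "target_deg")],
    strategy_deg = config$s_star)
  tr <- simulate_model(sched, p, "full_dynamic")
  obs_h <- dataset$hand_angle[mask]
  pred_h <- tr$hand_angle[mask]
  r <- if (stats::sd(obs_h) == 0 || stats::sd(pred_h) == 0) NA_real_
       else stats::cor(pred_h, obs_h)
  structure(list(params = p,
                 rms = sp_loss(p, dataset, config),
                 pearson_r = r,
                 converged = convergence == 0,
                 trajectory = tr),
            class = "fit_result")
}

#' Fit the setpoint model to one observed series
#'
#' Bounded Nelder-Mead minimization of [sp_loss()] for the five free
#' parameters, with bounds enforced through a smooth logistic
#' reparameterization. Deterministic given the start values.
#'
#' @param series A `participant_dataset` or group-averaged series.
#' @param config A [fit_config()].
#' @return A `fit_result`: `params` (point estimate), `rms` (degrees),
#'   `pearson_r` (predicted vs observed hand angle over the fitted
#'   trials), `converged` flag and the fitted model `trajectory`.
#' @export
fit_single <- function(series, config = fit_config()) {
  bounds <- config$bounds[FIT_PARAMS]
  mask <- fitted_mask(series, config)
  bc <- block_code_of(series$block)
  obj <- function(z) {
    th <- to_bounded(z, bounds)
    .sp_rms_cpp(bc, series$rotation_deg, series$strategy_instructed,
                series$feedback, th[1], th[2], th[3], th[4], th[5],
                config$s_star, series$target_error, mask)
  }
  z0 <- to_unconstrained(config$init[FIT_PARAMS], bounds)
  res <- nm_minimize(obj, z0, config, spread_starts(bounds))
  finish_fit(to_bounded(res$par, bounds), series, config, res$convergence)
}

#' Joint fit with shared learning parameters across groups
#'
#' Minimizes the summed per-group loss on group-averaged series over
#' `(A, B, E)` shared across groups plus `(K, F)` per group, mirroring the
#' constraint that internal-model retention, adaptation rate and strategy
#' retention are common while landmark availability and strategy
#' adjustment differ between groups.
#'
#' @param cohort List of `participant_dataset` (any mix of groups), or a
#'   named list of pre-averaged group series.
#' @param config A [fit_config()].
#' @param init_theta Optional warm start: full parameter vector
#'   `(A, B, E, K_1, F_1, ...)` on the bounded scale. When supplied, the
#'   simplex starts there (with restarts until the loss stalls) and the
#'   spread starts are skipped; used to speed up bootstrap refits.
#' @return List with `shared` (named A, B, E), `groups` (per-group
#'   `fit_result`), `theta` (full parameter vector), `loss` (summed RMS)
#'   and `converged`.
#' @export
fit_groups_shared <- function(cohort, config = fit_config(),
                              init_theta = NULL) {
  series <- if (is.data.frame(cohort[[1]])) {
    if (!is.null(cohort[[1]]$participant)) {
      by_g <- split_by_group(cohort)
      lapply(by_g, group_average)
    } else cohort
  } else stop("cohort must be a list of datasets")
  groups <- names(series)
  if (length(groups) == 0) stop("no groups found in cohort")

  bounds3 <- config$bounds[c("A", "B", "E")]
  boundsKF <- config$bounds[c("K", "F")]
  all_bounds <- c(bounds3, rep(boundsKF, length(groups)))
  masks <- lapply(series, fitted_mask, config = config)
  bcs <- lapply(series, function(s) block_code_of(s$block))

  obj <- function(z) {
    th <- to_bounded(z, all_bounds)
    tot <- 0
    for (gi in seq_along(groups)) {
      s <- series[[gi]]
      kf <- th[3 + 2 * (gi - 1) + 1:2]
      tot <- tot + .sp_rms_cpp(bcs[[gi]], s$rotation_deg,
                               s$strategy_instructed, s$feedback,
                               th[1], th[2], th[3], kf[1], kf[2],
                               config$s_star, s$target_error, masks[[gi]])
    }
    tot
  }
  if (is.null(init_theta)) {
    # initialize the shared parameters and per-group (K, F) from
    # independent per-group fits; the joint simplex then reconciles the
    # shared (A, B, E)
    singles <- lapply(series, fit_single, config = config)
    init <- c(mean(vapply(singles, function(f) f$params$A, 0)),
              mean(vapply(singles, function(f) f$params$B, 0)),
              mean(vapply(singles, function(f) f$params$E, 0)),
              unlist(lapply(singles, function(f) c(f$params$K, f$params$F))))
    extra <- c(list(to_unconstrained(
      c(config$init[c("A", "B", "E")],
        rep(config$init[c("K", "F")], length(groups))), all_bounds)),
      spread_starts(all_bounds))
    res <- nm_minimize(obj, to_unconstrained(init, all_bounds), config,
                       extra)
  } else {
    res <- nm_minimize(obj, to_unconstrained(init_theta, all_bounds), config)
  }
  th <- stats::setNames(to_bounded(res$par, all_bounds),
                        joint_param_names(groups))

  shared <- stats::setNames(unname(th[1:3]), c("A", "B", "E"))
  fits <- list()
  for (gi in seq_along(groups)) {
    kf <- th[3 + 2 * (gi - 1) + 1:2]
    theta <- c(shared, K = kf[1], F = kf[2])
    fits[[groups[gi]]] <- finish_fit(theta, series[[gi]], config,
                                     res$convergence)
  }
  list(shared = shared, groups = fits, theta = th, loss = res$value,
       converged = res$convergence == 0)
}

# Parameter vector names of the joint fit, e.g. K_AT, F_AT, ...
joint_param_names <- function(groups)
  c("A", "B", "E", as.vector(rbind(paste0("K_", groups), paste0("F_", groups))))

#' Participant-resampling bootstrap of the joint fit
#'
#' Resamples participants with replacement within each group, averages each
#' resample, refits the joint shared-parameter model, and collects the
#' parameter vectors. Estimates are reported as bootstrap means with
#' percentile 95% confidence intervals, plus two-sided bootstrap p-values
#' for all between-group contrasts of `K` and `F`.
#'
#' @param cohort List of `participant_dataset` covering >= 1 group with
#'   >= 2 participants each (single-participant groups degenerate to the
#'   point fit).
#' @param config A [fit_config()]; `n_boot` and `seed` control the
#'   resampling.
#' @return A `bootstrap_fit` list: `point` (full-sample joint fit),
#'   `samples` (n_boot x parameter matrix), `estimate`, `ci95`,
#'   `contrasts` (data frame of pairwise K and F contrasts with p-values).
#' @export
bootstrap_fit <- function(cohort, config = fit_config()) {
  by_g <- lapply(split_by_group(cohort), sort_by_participant)
  groups <- names(by_g)
  point <- fit_groups_shared(cohort, config)

  nb <- config$n_boot
  samples <- matrix(NA_real_, nb, 3 + 2 * length(groups),
                    dimnames = list(NULL, joint_param_names(groups)))
  idx <- withr_seed(config$seed, {
    lapply(seq_len(nb), function(b)
      lapply(by_g, function(g) sample.int(length(g), replace = TRUE)))
  })
  for (b in seq_len(nb)) {
    res <- lapply(groups, function(g)
      group_average(by_g[[g]][idx[[b]][[g]]]))
    names(res) <- groups
    fit <- fit_groups_shared(res, config, init_theta = point$theta)
    samples[b, ] <- fit$theta[colnames(samples)]
  }

  est <- colMeans(samples)
  ci <- apply(samples, 2, stats::quantile, probs = c(0.025, 0.975),
              names = FALSE)
  contrasts <- NULL
  if (length(groups) >= 2) {
    pairs <- utils::combn(groups, 2)
    contrasts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      g1 <- pairs[1, j]; g2 <- pairs[2, j]
      do.call(rbind, lapply(c("K", "F"), function(pn) {
        d <- samples[, paste0(pn, "_", g1)] - samples[, paste0(pn, "_", g2)]
        data.frame(parameter = pn, group1 = g1, group2 = g2,
                   delta = mean(d), p = bootstrap_p(d),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(point = point, samples = samples, estimate = est,
                 ci95 = ci, contrasts = contrasts, n_boot = nb,
                 seed = config$seed),
            class = "bootstrap_fit")
}

#' Two-sided bootstrap p-value for a contrast
#'
#' `p = 2 * min(P(d <= 0), P(d >= 0))` over bootstrap samples of the
#' contrast `d`, with +1 smoothing in numerator and denominator, capped
#' at 1.
#'
#' @param d Numeric vector of bootstrap contrast samples.
#' @return p-value in (0, 1\].
#' @export
bootstrap_p <- function(d) {
  n <- length(d)
  p <- 2 * min((1 + sum(d <= 0)) / (n + 1), (1 + sum(d >= 0)) / (n + 1))
  min(p, 1)
}
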
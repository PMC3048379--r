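#' Remove outlier movements per block
#'
#' Single-pass removal of trials whose movement heading (hand angle) lies
#' more than three standard deviations from the mean of its block. Blocks
#' with fewer than three trials are left untouched with a warning.
#'
#' @param dataset A `participant_dataset`.
#' @return List with `data` (cleaned dataset), `removed` (count) and
#'   `fraction` removed.
#' @export
remove_outliers <- function(dataset) {
  keep <- rep(TRUE, nrow(dataset))
  skipped <- character(0)
  for (b in unique(dataset$block)) {
    i <- which(dataset$block == b)
    if (length(i) < 3) {
      skipped <- c(skipped, b)
      next
    }
    h <- dataset$hand_angle[i]
    dev <- abs(h - mean(h))
    keep[i[dev > 3 * stats::sd(h)]] <- FALSE
  }
  if (length(skipped))
    warning("block(s) with fewer than 3 trials not screened: ",
            paste(skipped, collapse = ", "))
  list(data = dataset[keep, , drop = FALSE],
       removed = sum(!keep),
       fraction = sum(!keep) / max(nrow(dataset), 1))
}

#' Bin a trial series with rotation-onset and strategy-onset exclusions
#'
#' Averages target error over contiguous bins within each block. The two
#' rotation-probe trials (rotation on, strategy not yet instructed) and the
#' first two trials of the rotation-plus-strategy block never enter a bin;
#' each pair is averaged separately. Partial final bins average the
#' available trials.
#'
#' @param dataset A `participant_dataset` or group-averaged series.
#' @param width Bin width in trials (default 10).
#' @return A `binned_series` list: `bins` (data frame with `block`, `bin`,
#'   `n`, `mean_error`, within-block movement-number `center`, and for the
#'   rotation block `center_rot`, the movement number counted from rotation
#'   onset) and `pairs` (rotation-onset and strategy-onset pair means).
#' @export
bin_series <- function(dataset, width = 10) {
  stopifnot(width >= 1)
  bins <- list()
  pairs <- list()
  n_probe <- sum(dataset$block == "rotation_probe")
  for (b in intersect(BLOCKS, unique(dataset$block))) {
    rows <- which(dataset$block == b)
    e <- dataset$target_error[rows]
    pos <- seq_along(rows)
    if (b == "rotation_probe") {
      pairs$rotation_onset <- mean(e)
      next
    }
    if (b == "rotation_strategy" && length(rows) >= 2) {
      pairs$strategy_onset <- mean(e[1:2])
      e <- e[-(1:2)]
      pos <- pos[-(1:2)]
    }
    if (!length(e)) next
    g <- ceiling(seq_along(e) / width)
    df <- data.frame(
      block = b, bin = seq_len(max(g)),
      n = as.vector(table(g)),
      mean_error = as.vector(tapply(e, g, mean)),
      center = as.vector(tapply(pos, g, mean)),
      stringsAsFactors = FALSE
    )
    if (b == "rotation_strategy") df$center_rot <- df$center + n_probe
    bins[[b]] <- df
  }
  bins <- if (length(bins)) {
    all_cols <- c("block", "bin", "n", "mean_error", "center", "center_rot")
    do.call(rbind, lapply(bins, function(d) {
      for (cc in setdiff(all_cols, names(d))) d[[cc]] <- NA_real_
      d[all_cols]
    }))
  } else NULL
  if (!is.null(bins)) rownames(bins) <- NULL
  structure(list(bins = bins, pairs = pairs, width = width),
            class = "binned_series")
}

# Directly computed (non-bootstrap) peak drift of one averaged series:
# the most clockwise-positive 10-trial bin of the rotation block, ties
# broken by the earliest bin.
peak_drift_stat <- function(series, width = 10) {
  bs <- bin_series(series, width)
  rb <- bs$bins[bs$bins$block == "rotation_strategy", , drop = FALSE]
  if (is.null(rb) || nrow(rb) == 0) stop("empty rotation block")
  i <- which.max(rb$mean_error)
  c(magnitude = rb$mean_error[i], time = rb$center_rot[i])
}

boot_indices <- function(n_participants, n_boot, seed) {
  withr_seed(seed, lapply(seq_len(n_boot), function(b)
    sample.int(n_participants, replace = TRUE)))
}

# Canonical participant order, so bootstrap draws do not depend on how the
# caller happened to arrange the list.
sort_by_participant <- function(datasets) {
  ids <- vapply(datasets, function(d) as.character(d$participant[1]),
                character(1))
  datasets[order(ids)]
}

bootstrap_stat <- function(datasets, n_boot, seed, stat_fun) {
  datasets <- sort_by_participant(datasets)
  template <- stat_fun(group_average(datasets))
  idx <- boot_indices(length(datasets), n_boot, seed)
  res <- vapply(idx, function(i) stat_fun(group_average(datasets[i])),
                template)
  if (is.null(dim(res)))
    matrix(res, ncol = 1, dimnames = list(NULL, names(template)))
  else t(res)
}

#' Bootstrap estimate of peak drift for a group
#'
#' Per resample: draw participants with replacement, average trial-by-trial,
#' bin the rotation block by `width` movements (probe and strategy-onset
#' pairs excluded), and take the bin with the largest clockwise error. The
#' time of peak drift is the movement number at the middle of that bin,
#' counted from rotation onset.
#'
#' @param datasets List of `participant_dataset` from one group.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Resampling seed.
#' @param width Bin width (default 10).
#' @return A `peak_drift_estimate`: `magnitude` and `time` (bootstrap
#'   means), percentile `ci95_magnitude` / `ci95_time`, `samples`.
#' @export
peak_drift <- function(datasets, n_boot = 1000L, seed = 1L, width = 10) {
  stopifnot(length(datasets) >= 1)
  s <- bootstrap_stat(datasets, n_boot, seed,
                      function(d) peak_drift_stat(d, width))
  structure(list(magnitude = mean(s[, "magnitude"]),
                 time = mean(s[, "time"]),
                 ci95_magnitude = stats::quantile(s[, "magnitude"],
                                                  c(0.025, 0.975), names = FALSE),
                 ci95_time = stats::quantile(s[, "time"], c(0.025, 0.975),
                                             names = FALSE),
                 n_boot = n_boot, samples = s),
            class = "peak_drift_estimate")
}

#' Peak drift split by target direction
#'
#' As [peak_drift()], but the rotation-block series is split by target
#' direction and binned per direction (default: 10 bins of 4 movements,
#' covering the 40 movements per target of the default schedule).
#'
#' @inheritParams peak_drift
#' @param width Bin width in movements per direction (default 4).
#' @param n_bins Number of bins kept per direction (default 10).
#' @return Data frame with one row per target direction: bootstrap mean
#'   `magnitude`, `ci_lo`, `ci_hi`.
#' @export
peak_drift_by_direction <- function(datasets, n_boot = 1000L, seed = 1L,
                                    width = 4, n_bins = 10) {
  dirs <- sort(unique(datasets[[1]]$target_deg))
  stat <- function(avg) {
    rot <- avg[avg$block == "rotation_strategy", , drop = FALSE]
    vapply(dirs, function(td) {
      e <- rot$target_error[rot$target_deg == td]
      e <- e[seq_len(min(length(e), width * n_bins))]
      g <- ceiling(seq_along(e) / width)
      max(tapply(e, g, mean))
    }, numeric(1))
  }
  s <- bootstrap_stat(datasets, n_boot, seed, stat)
  data.frame(target_deg = dirs,
             magnitude = colMeans(s),
             ci_lo = apply(s, 2, stats::quantile, 0.025, names = FALSE),
             ci_hi = apply(s, 2, stats::quantile, 0.975, names = FALSE))
}

#' Bootstrap estimate of the aftereffect
#'
#' Mean target error over the first eight trials of the no-feedback block
#' (rotation and strategy both off, no endpoint feedback), bootstrapped
#' over participants as in [peak_drift()]. Clockwise-positive values
#' indicate residual implicit adaptation.
#'
#' @inheritParams peak_drift
#' @return An `aftereffect_estimate`: `magnitude`, `ci95`, `samples`.
#' @export
aftereffect <- function(datasets, n_boot = 1000L, seed = 1L) {
  stat <- function(avg) {
    rows <- which(avg$block == "no_feedback_aftereffect")
    if (!length(rows)) stop("no no-feedback aftereffect trials present")
    c(magnitude = mean(avg$target_error[rows[seq_len(min(8, length(rows)))]]))
  }
  s <- bootstrap_stat(datasets, n_boot, seed, stat)
  structure(list(magnitude = mean(s[, "magnitude"]),
                 ci95 = stats::quantile(s[, "magnitude"], c(0.025, 0.975),
                                        names = FALSE),
                 n_boot = n_boot, samples = s[, "magnitude"]),
            class = "aftereffect_estimate")
}

# Least-squares fit of y_t = a * exp(-lambda * t), t = 1..n, lambda >= 0.
fit_exponential <- function(y) {
  t <- seq_along(y)
  if (all(abs(y) < 1e-10))
    return(list(a = 0, lambda = 0, identifiable = FALSE))
  a0 <- if (abs(y[1]) > 1e-8) y[1] else y[which.max(abs(y))]
  pos <- sign(y) == sign(a0) & abs(y) > 1e-8
  lam0 <- 0.05
  if (sum(pos) >= 3) {
    sl <- stats::coef(stats::lm(log(abs(y[pos])) ~ t[pos]))[2]
    lam0 <- max(-sl, 1e-4)
  }
  sse <- function(p) sum((y - p[1] * exp(-p[2] * t))^2)
  fit <- stats::optim(c(a0 * exp(lam0), lam0), sse, method = "L-BFGS-B",
                      lower = c(-Inf, 0), upper = c(Inf, Inf))
  list(a = fit$par[1], lambda = fit$par[2],
       identifiable = abs(fit$par[1]) > 1e-6)
}

#' Bootstrap estimate of the washout decay rate
#'
#' Fits the exponential `e_t = a * exp(-lambda * t)` (t = trial number
#' within the washout block, starting at 1; no offset term) to the
#' group-averaged washout target errors of each bootstrap resample.
#'
#' @inheritParams peak_drift
#' @return A `washout_fit`: `a` (degrees), `lambda` (per trial), percentile
#'   `ci95_a` / `ci95_lambda`, `identifiable` flag (FALSE with infinite CI
#'   when the amplitude is indistinguishable from zero) and `samples`.
#' @export
washout_rate <- function(datasets, n_boot = 1000L, seed = 1L) {
  stat <- function(avg) {
    y <- avg$target_error[avg$block == "washout"]
    if (!length(y)) stop("no washout trials present")
    f <- fit_exponential(y)
    c(a = f$a, lambda = f$lambda)
  }
  direct <- fit_exponential(
    group_average(datasets)$target_error[
      group_average(datasets)$block == "washout"])
  s <- bootstrap_stat(datasets, n_boot, seed, stat)
  ident <- direct$identifiable
  structure(list(a = mean(s[, "a"]), lambda = mean(s[, "lambda"]),
                 ci95_a = stats::quantile(s[, "a"], c(0.025, 0.975),
                                          names = FALSE),
                 ci95_lambda = if (ident)
                   stats::quantile(s[, "lambda"], c(0.025, 0.975),
                                   names = FALSE)
                 else c(0, Inf),
                 identifiable = ident, n_boot = n_boot, samples = s),
            class = "washout_fit")
}

#' Bootstrap contrast between two groups' estimates
#'
#' Pairs the bootstrap samples of two estimates (equal `n_boot` required)
#' and returns the two-sided bootstrap p-value of their difference.
#'
#' @param a,b Numeric vectors of bootstrap samples.
#' @return List with `delta` (mean difference) and `p`.
#' @export
bootstrap_contrast <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  list(delta = mean(d), p = bootstrap_p(d))
}

#' One-way ANOVA across groups
#'
#' Thin convenience wrapper around [stats::aov()] for simple between-group
#' comparisons of per-participant summary values.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of the same length.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
group_anova <- function(values, groups) {
  a <- summary(stats::aov(values ~ factor(groups)))[[1]]
  list(F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2], p = a$`Pr(>F)`[1])
}
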
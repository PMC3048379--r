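#' @useDynLib setpointadapt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Canonical block order of the protocol. Angles are degrees throughout the
# package, clockwise positive and counter-clockwise negative.
BLOCKS <- c("familiarization", "strategy_only", "baseline", "rotation_probe",
            "rotation_strategy", "no_feedback_aftereffect", "washout")

GROUPS <- c("AT", "DAT", "NoAT")

DEFAULT_BLOCK_LENGTHS <- c(
  familiarization = 40L, strategy_only = 40L, baseline = 40L,
  rotation_probe = 2L, rotation_strategy = 320L,
  no_feedback_aftereffect = 8L, washout = 40L
)

#' Target directions used in the reaching task
#'
#' Eight directions on a virtual ring, starting at 22.5 degrees and spaced
#' 45 degrees apart (none at the cardinal axes).
#'
#' @return Numeric vector of eight angles in degrees.
#' @export
target_directions <- function() 22.5 + 45 * (0:7)

# Balanced pseudo-random target sequence: an independent permutation of the
# eight directions per 8-trial sub-cycle; a trailing partial cycle takes the
# first trials of one more permutation.
balanced_targets <- function(n) {
  if (n == 0L) return(numeric(0))
  dirs <- target_directions()
  cycles <- ceiling(n / 8)
  out <- unlist(lapply(seq_len(cycles), function(i) sample(dirs)))
  out[seq_len(n)]
}

new_trial_schedule <- function(df, group = NA_character_,
                               rotation_deg = -45, strategy_deg = 45) {
  df$index <- seq_len(nrow(df))
  rownames(df) <- NULL
  structure(df,
            group = group,
            rotation_deg = rotation_deg,
            strategy_deg = strategy_deg,
            class = c("trial_schedule", "data.frame"))
}

#' Build the default experimental schedule
#'
#' Constructs the 490-trial session used in the behavioral study: 40
#' familiarization trials, 40 strategy-only practice trials, 40 baseline
#' trials, 2 rotation probes (rotation on, strategy not yet instructed),
#' 320 rotation-plus-strategy trials, 8 no-feedback aftereffect trials
#' (one per target direction) and 40 washout trials. The rotation is -45
#' degrees (counter-clockwise) and the instructed strategy is to aim +45
#' degrees (clockwise).
#'
#' @param group Group label, one of `"AT"` (aiming targets always visible),
#'   `"DAT"` (aiming targets disappear at movement onset) or `"NoAT"` (no
#'   aiming targets). Stored as an attribute; the schedule itself is the
#'   same for all groups.
#' @param seed Integer seed for the balanced pseudo-random target order.
#' @param rotation_deg Rotation magnitude in degrees (default -45).
#' @param strategy_deg Instructed strategy angle in degrees (default +45).
#' @return A `trial_schedule` data frame with columns `index`, `block`,
#'   `rotation_deg`, `strategy_instructed`, `feedback`, `target_deg`.
#' @examples
#' sched <- build_paper_schedule("AT")
#' nrow(sched)                       # 490
#' sum(sched$rotation_deg != 0)      # 322 rotation trials
#' @export
build_paper_schedule <- function(group = c("AT", "DAT", "NoAT"), seed = 1L,
                                 rotation_deg = -45, strategy_deg = 45) {
  if (length(group) == 1L && !group %in% GROUPS)
    stop("unknown group label: '", group, "' (expected AT, DAT or NoAT)")
  group <- match.arg(group)
  build_custom_schedule(DEFAULT_BLOCK_LENGTHS, rotation_deg = rotation_deg,
                        strategy_deg = strategy_deg, seed = seed,
                        group = group)
}

#' Build a schedule with custom block lengths
#'
#' Same block semantics as [build_paper_schedule()] but with arbitrary
#' (possibly zero) block lengths, e.g. the 120-baseline / 322-rotation
#' layout used for model simulations.
#'
#' @param block_lengths Named integer vector; names must be a subset of
#'   `familiarization, strategy_only, baseline, rotation_probe,
#'   rotation_strategy, no_feedback_aftereffect, washout`. Blocks are laid
#'   out in that canonical order.
#' @inheritParams build_paper_schedule
#' @param group Optional group label attribute.
#' @return A `trial_schedule` data frame.
#' @examples
#' s <- build_custom_schedule(c(baseline = 120, rotation_strategy = 322))
#' s$rotation_deg[120:121]   # rotation switches on at trial 121
#' @export
build_custom_schedule <- function(block_lengths, rotation_deg = -45,
                                  strategy_deg = 45, seed = 1L,
                                  group = NA_character_) {
  block_lengths <- unlist(block_lengths)
  if (is.null(names(block_lengths)) && length(block_lengths) > 0)
    stop("block_lengths must be named by block")
  unknown <- setdiff(names(block_lengths), BLOCKS)
  if (length(unknown))
    stop("unknown block name(s): ", paste(unknown, collapse = ", "))
  if (any(block_lengths < 0)) stop("block lengths must be non-negative")
  lens <- ifelse(is.na(block_lengths[BLOCKS]), 0L,
                 as.integer(block_lengths[BLOCKS]))
  names(lens) <- BLOCKS

  block <- rep(BLOCKS, times = lens)
  n <- length(block)
  rot <- ifelse(block %in% c("rotation_probe", "rotation_strategy"),
                rotation_deg, 0)
  strat <- block %in% c("strategy_only", "rotation_strategy")
  fb <- block != "no_feedback_aftereffect"

  targets <- withr_seed(seed, {
    unlist(lapply(BLOCKS, function(b) balanced_targets(lens[[b]])))
  })
  if (n == 0L) targets <- numeric(0)

  df <- data.frame(
    index = seq_len(n), block = block, rotation_deg = rot,
    strategy_instructed = strat, feedback = fb,
    target_deg = targets, stringsAsFactors = FALSE
  )
  new_trial_schedule(df, group = group, rotation_deg = rotation_deg,
                     strategy_deg = strategy_deg)
}

# Evaluate `expr` under a local RNG seed without disturbing the caller's
# RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Write / read a trial schedule as CSV
#'
#' The interchange format has exactly the columns `index, block,
#' rotation_deg, strategy_instructed, feedback, target_deg`.
#'
#' @param schedule A `trial_schedule`.
#' @param path File path.
#' @return `read_schedule` returns a `trial_schedule`; `write_schedule`
#'   returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  df <- as.data.frame(schedule)[, c("index", "block", "rotation_deg",
                                    "strategy_instructed", "feedback",
                                    "target_deg")]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("index", "block", "rotation_deg", "strategy_instructed",
            "feedback", "target_deg")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schedule file missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$block), BLOCKS)
  if (length(bad)) stop("unknown block label(s): ", paste(bad, collapse = ", "))
  df$strategy_instructed <- as.logical(df$strategy_instructed)
  df$feedback <- as.logical(df$feedback)
  rot <- unique(df$rotation_deg[df$rotation_deg != 0])
  new_trial_schedule(df[, need],
                     rotation_deg = if (length(rot) == 1) rot else -45)
}
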
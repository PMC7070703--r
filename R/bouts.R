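#' Run-length encode a binary state sequence
#'
#' Partitions the sequence into maximal runs of constant state. Start
#' positions are 0-based epoch indices, matching the epoch CSV convention.
#'
#' @param states A 0/1 vector (or a `"binary_series"`).
#' @return A data frame with columns `state`, `start`, `length`; run
#'   lengths sum to the sequence length.
#' @export
run_lengths <- function(states) {
  if (inherits(states, "binary_series")) states <- states$states
  states <- as.integer(states)
  if (length(states) < 1L) stop("empty sequence", call. = FALSE)
  r <- rle(states)
  data.frame(
    state = r$values,
    start = cumsum(c(0L, r$lengths[-length(r$lengths)])),
    length = r$lengths
  )
}

#' Extract human movement bouts and their dog-precedence class
#'
#' A movement bout is a maximal run of human moving state (1). Each bout is
#' classified by whether the dog was moving in the minute immediately before
#' bout onset: `"yes"` if the dog state at `start - 1` is 1, `"no"` if 0,
#' and `"undefined"` for bouts starting at the first epoch of the night
#' (no prior minute exists).
#'
#' @param night A [dyad_night()].
#' @return A data frame with columns `dyad_id`, `night_id`, `start_epoch`
#'   (0-based), `length_min` and `preceded_by_dog`
#'   (factor yes/no/undefined). Zero rows if the human never moved.
#' @export
classify_movement_bouts <- function(night) {
  stopifnot(inherits(night, "dyad_night"))
  rl <- run_lengths(night$human_states)
  rl <- rl[rl$state == 1L, , drop = FALSE]
  preceded <- ifelse(
    rl$start == 0L, "undefined",
    ifelse(night$dog_states[rl$start] == 1L, "yes", "no")
  )
  data.frame(
    dyad_id = rep(night$dyad_id, nrow(rl)),
    night_id = rep(night$night_id, nrow(rl)),
    start_epoch = rl$start,
    length_min = rl$length,
    preceded_by_dog = factor(preceded, levels = c("yes", "no", "undefined")),
    stringsAsFactors = FALSE
  )
}

#' Compare dog-preceded and non-preceded bout durations
#'
#' Two-sided Wilcoxon rank-sum test of bout durations between bouts whose
#' onset was immediately preceded by dog movement and bouts whose onset was
#' not. Bouts with undefined precedence (night-initial) are excluded. Bout
#' lengths are small integers with heavy ties, so the default test is the
#' normal approximation with tie correction; the exact distribution is used
#' automatically only for tiny untied samples.
#'
#' The statistic follows the Mann-Whitney U convention by default (rank sum
#' of the dog-preceded group minus its minimum possible value); set
#' `convention = "rank-sum"` for the raw rank sum of that group.
#'
#' @param bouts A bout data frame from [classify_movement_bouts()] (rows
#'   from many nights may be concatenated with `rbind`).
#' @param convention `"mann-whitney"` (default) or `"rank-sum"`.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact test;
#'   `NULL` (default) uses exact only when `n1 + n2 <= 12` and there are
#'   no ties.
#' @return A list with `statistic`, `p_value`, `n1`, `n2`, `mean1`,
#'   `mean2` (mean durations in minutes, dog-preceded group first) and
#'   `convention`.
#' @export
compare_bout_durations <- function(bouts,
                                   convention = c("mann-whitney", "rank-sum"),
                                   exact = NULL) {
  convention <- match.arg(convention)
  stopifnot(is.data.frame(bouts),
            all(c("length_min", "preceded_by_dog") %in% names(bouts)))
  x <- bouts$length_min[bouts$preceded_by_dog == "yes"]
  y <- bouts$length_min[bouts$preceded_by_dog == "no"]
  if (length(x) == 0L || length(y) == 0L) {
    stop("both precedence groups must be non-empty", call. = FALSE)
  }
  if (is.null(exact)) {
    exact <- (length(x) + length(y)) <= 12L && !anyDuplicated(c(x, y))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  u <- unname(wt$statistic) # Mann-Whitney U of the first group
  stat <- if (convention == "mann-whitney") {
    u
  } else {
    u + length(x) * (length(x) + 1) / 2
  }
  list(
    statistic = stat,
    p_value = unname(wt$p.value),
    n1 = length(x), n2 = length(y),
    mean1 = mean(x), mean2 = mean(y),
    convention = convention
  )
}
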
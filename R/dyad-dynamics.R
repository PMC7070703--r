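#' Canonical ordering of the four dyadic movement states
#'
#' Joint minute-level state of the pair: both moving, human only, dog only,
#' or neither. This ordering is used for all transition-table rows and
#' columns and all serialized output.
#'
#' @export
DYAD_STATES <- c("Both", "HumanOnly", "DogOnly", "Neither")

#' Map aligned binary sequences to the four-state dyadic sequence
#'
#' Elementwise mapping: (human=1, dog=1) -> Both, (1,0) -> HumanOnly,
#' (0,1) -> DogOnly, (0,0) -> Neither.
#'
#' @param night A [dyad_night()].
#' @return An object of class `"dyadic_states"`: a list with `dyad_id`,
#'   `night_id` and `states`, a factor over [DYAD_STATES].
#' @export
dyadic_states <- function(night) {
  stopifnot(inherits(night, "dyad_night"))
  h <- night$human_states
  d <- night$dog_states
  if (length(h) != length(d)) stop("state sequences differ in length",
                                   call. = FALSE)
  idx <- 4L - (2L * h + d) # (1,1)->1 Both, (1,0)->2, (0,1)->3, (0,0)->4
  structure(
    list(
      dyad_id = night$dyad_id,
      night_id = night$night_id,
      states = factor(DYAD_STATES[idx], levels = DYAD_STATES)
    ),
    class = "dyadic_states"
  )
}

#' Cross-tabulate simultaneous human and dog movement
#'
#' Pools same-epoch (no lag) movement states over all nights into a 2x2
#' table with dog movement on the rows (no/yes) and human movement on the
#' columns (no/yes), plus percentages computed within each human-movement
#' column.
#'
#' @param nights A list of [dyad_night()] objects (a single one is
#'   accepted).
#' @return An object of class `"crosstab"`: list with `counts` (2x2 integer
#'   matrix), `col_pct` (column percentages) and `total`.
#' @export
crosstab_movement <- function(nights) {
  if (inherits(nights, "dyad_night")) nights <- list(nights)
  stopifnot(length(nights) >= 1L)
  h <- unlist(lapply(nights, `[[`, "human_states"))
  d <- unlist(lapply(nights, `[[`, "dog_states"))
  counts <- matrix(0L, 2L, 2L,
                   dimnames = list(dog = c("no", "yes"),
                                   human = c("no", "yes")))
  for (dd in 0:1) for (hh in 0:1) {
    counts[dd + 1L, hh + 1L] <- sum(d == dd & h == hh)
  }
  col_tot <- colSums(counts)
  col_pct <- sweep(counts, 2L, pmax(col_tot, 1L), "/") * 100
  structure(list(counts = counts, col_pct = col_pct,
                 total = sum(counts)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  cat("<crosstab> simultaneous movement,", x$total, "epochs\n")
  disp <- matrix(sprintf("%d (%.1f%%)", x$counts, x$col_pct), 2L, 2L,
                 dimnames = dimnames(x$counts))
  print(disp, quote = FALSE)
  invisible(x)
}

#' Pearson chi-square test of a 2x2 co-occurrence table
#'
#' Pearson chi-square without continuity correction, 1 degree of freedom.
#'
#' @param crosstab A `"crosstab"` or a plain 2x2 count matrix.
#' @return A list with `statistic`, `df` (always 1) and `p_value`.
#' @export
chi_square_2x2 <- function(crosstab) {
  counts <- if (inherits(crosstab, "crosstab")) crosstab$counts else crosstab
  counts <- as.matrix(counts)
  stopifnot(identical(dim(counts), c(2L, 2L)) || identical(dim(counts), c(2, 2)))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("chi-square requires all row and column marginals > 0",
         call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = 1L,
       p_value = unname(ct$p.value))
}

#' Count within-night transitions between dyadic states
#'
#' Tabulates (state at t-1, state at t) pairs pooled over sequences.
#' Transitions never span night boundaries: each night's chain restarts, so
#' a night contributes `length - 1` transitions. Probabilities are
#' row-normalized counts; rows never visited are `NaN`.
#'
#' @param sequences A list of `"dyadic_states"` objects (or one such
#'   object). Sequences of length < 2 contribute nothing.
#' @return An object of class `"transition_table"`: list with `counts`
#'   (4x4 integer matrix, from-state rows in [DYAD_STATES] order), `row_n`
#'   and `probs`.
#' @export
transition_counts <- function(sequences) {
  if (inherits(sequences, "dyadic_states")) sequences <- list(sequences)
  counts <- matrix(0L, 4L, 4L, dimnames = list(from = DYAD_STATES,
                                               to = DYAD_STATES))
  contributed <- FALSE
  for (s in sequences) {
    st <- as.integer(s$states)
    n <- length(st)
    if (n < 2L) next
    contributed <- TRUE
    tab <- table(factor(st[-n], levels = 1:4), factor(st[-1L], levels = 1:4))
    counts <- counts + as.integer(tab)
  }
  if (!contributed) {
    stop("no sequence of length >= 2; transition table would be empty",
         call. = FALSE)
  }
  as_transition_table(counts)
}

#' Build a transition table from counts or probabilities
#'
#' Either from a 4x4 count matrix (probabilities are row-normalized counts)
#' or from an already row-normalized 4x4 probability matrix together with
#' per-row observation counts `row_n` — the latter form is how a printed
#' transition-probability table is re-entered for downstream arithmetic.
#'
#' @param counts 4x4 non-negative count matrix (rows = from-state in
#'   [DYAD_STATES] order), or `NULL` when `probs` is given.
#' @param probs Optional 4x4 row-stochastic matrix.
#' @param row_n Per-row totals, required with `probs`.
#' @return A `"transition_table"`.
#' @export
as_transition_table <- function(counts = NULL, probs = NULL, row_n = NULL) {
  if (is.null(probs)) {
    counts <- as.matrix(counts)
    stopifnot(all(dim(counts) == 4L), all(counts >= 0))
    dimnames(counts) <- list(from = DYAD_STATES, to = DYAD_STATES)
    row_n <- rowSums(counts)
    probs <- sweep(counts, 1L, ifelse(row_n > 0, row_n, NA_real_), "/")
  } else {
    probs <- as.matrix(probs)
    stopifnot(all(dim(probs) == 4L), !is.null(row_n), length(row_n) == 4L)
    dimnames(probs) <- list(from = DYAD_STATES, to = DYAD_STATES)
    row_n <- as.numeric(row_n)
    counts <- NULL
  }
  structure(list(counts = counts, row_n = stats::setNames(row_n, DYAD_STATES),
                 probs = probs),
            class = "transition_table")
}

#' @export
print.transition_table <- function(x, digits = 3, ...) {
  cat("<transition_table> from-state rows, to-state columns\n")
  print(cbind(n = x$row_n, round(x$probs, digits)))
  invisible(x)
}

#' Probability that the human starts moving, by prior dog state
#'
#' From the four-state transition table: given that at t-1 only the dog was
#' moving (row DogOnly) or neither was moving (row Neither), the probability
#' that the human is moving at t is the row sum over the destination states
#' in which the human moves (Both + HumanOnly).
#'
#' @param table A `"transition_table"` (or a 4x4 row-stochastic matrix with
#'   [DYAD_STATES] dimnames).
#' @return Named numeric vector `c(p_dog_moving, p_dog_still)`.
#' @export
human_transition_prob_given_dog <- function(table) {
  partner_onset_probs(table, mover = "human")
}

#' Probability that the dog starts moving, by prior human state
#'
#' Mirror of [human_transition_prob_given_dog()]: rows HumanOnly and
#' Neither, destination states in which the dog moves (Both + DogOnly).
#'
#' @inheritParams human_transition_prob_given_dog
#' @return Named numeric vector `c(p_human_moving, p_human_still)`.
#' @export
dog_transition_prob_given_human <- function(table) {
  partner_onset_probs(table, mover = "dog")
}

partner_onset_probs <- function(table, mover = c("human", "dog")) {
  mover <- match.arg(mover)
  probs <- if (inherits(table, "transition_table")) table$probs else as.matrix(table)
  row_n <- if (inherits(table, "transition_table")) table$row_n else NULL
  if (mover == "human") {
    rows <- c("DogOnly", "Neither")
    cols <- c("Both", "HumanOnly")
    nms <- c("p_dog_moving", "p_dog_still")
  } else {
    rows <- c("HumanOnly", "Neither")
    cols <- c("Both", "DogOnly")
    nms <- c("p_human_moving", "p_human_still")
  }
  if (!is.null(row_n) && any(row_n[rows] == 0)) {
    stop("transition table has an empty ", paste(rows, collapse = "/"),
         " row", call. = FALSE)
  }
  p <- rowSums(probs[rows, cols, drop = FALSE])
  if (anyNA(p)) stop("transition probabilities undefined for rows ",
                     paste(rows, collapse = "/"), call. = FALSE)
  stats::setNames(as.numeric(p), nms)
}

#' Raw transition-odds multiplier
#'
#' Ratio of the onset probability when the partner was active at t-1 to the
#' onset probability when the partner was still. Returned at full precision;
#' round only for display.
#'
#' @param p_active Onset probability given partner movement at t-1.
#' @param p_baseline Onset probability given partner stillness at t-1.
#' @return `p_active / p_baseline`.
#' @export
raw_transition_odds <- function(p_active, p_baseline) {
  stopifnot(is.numeric(p_active), is.numeric(p_baseline))
  if (any(p_baseline <= 0)) {
    stop("baseline transition probability must be > 0", call. = FALSE)
  }
  p_active / p_baseline
}
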
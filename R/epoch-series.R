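#' Per-minute activity series for one subject and one sleep period
#'
#' An `epoch_series` holds the per-epoch activity summaries exported by the
#' device software for a single subject (human wrist or dog collar) over one
#' sleep period. Human values are signal vector magnitude in g-units times
#' minutes (SVM_gs); dog values are activity counts per minute (cpm). Epochs
#' are fixed 60-second bins, ordered by `epoch_index` starting at 0.
#'
#' @param subject_id Character scalar identifying the wearer.
#' @param species Either `"human"` or `"dog"`; selects the movement
#'   threshold applied downstream.
#' @param dyad_id Character scalar identifying the human-dog pair.
#' @param night_id Character scalar identifying the sleep period.
#' @param values Numeric vector of non-negative per-epoch activity values,
#'   in file order (epoch 0 first).
#' @param epoch_length_s Epoch length in seconds; only 60 is supported.
#'
#' @return An object of class `"epoch_series"`.
#' @export
epoch_series <- function(subject_id, species, dyad_id, night_id, values,
                         epoch_length_s = 60L) {
  species <- match.arg(species, c("human", "dog"))
  if (!identical(as.integer(epoch_length_s), 60L)) {
    stop("epoch_length_s must be 60 seconds", call. = FALSE)
  }
  values <- as.numeric(values)
  if (length(values) < 1L) {
    stop("an epoch series needs at least one epoch", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("activity values must be non-negative and non-missing", call. = FALSE)
  }
  structure(
    list(
      subject_id = as.character(subject_id),
      species = species,
      dyad_id = as.character(dyad_id),
      night_id = as.character(night_id),
      epoch_length_s = 60L,
      values = values
    ),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %s (%s), dyad %s night %s: %d x 60s epochs\n",
    x$subject_id, x$species, x$dyad_id, x$night_id, length(x$values)
  ))
  invisible(x)
}

#' @export
length.epoch_series <- function(x) length(x$values)

#' Aligned binary movement states for one dyad-night
#'
#' Combines the thresholded human and dog series for one night into a single
#' paired object. Both state vectors must already be aligned (same length,
#' same dyad and night).
#'
#' @param human,dog Objects of class `"binary_series"` (see
#'   [binarize_series()]) or plain 0/1 vectors.
#' @param dyad_id,night_id Identifiers; taken from `human` when it is a
#'   `binary_series` and not supplied.
#'
#' @return An object of class `"dyad_night"` with elements `dyad_id`,
#'   `night_id`, `human_states`, `dog_states` and `n_epochs`.
#' @export
dyad_night <- function(human, dog, dyad_id = NULL, night_id = NULL) {
  grab <- function(x, what) {
    if (inherits(x, "binary_series")) {
      list(states = x$states, dyad = x$dyad_id, night = x$night_id)
    } else {
      list(states = as.integer(x), dyad = NULL, night = NULL)
    }
  }
  h <- grab(human)
  d <- grab(dog)
  if (is.null(dyad_id)) dyad_id <- h$dyad %||% "dyad"
  if (is.null(night_id)) night_id <- h$night %||% "night"
  if (!is.null(h$dyad) && !is.null(d$dyad) &&
      (!identical(h$dyad, d$dyad) || !identical(h$night, d$night))) {
    stop("human and dog series belong to different dyad-nights", call. = FALSE)
  }
  hs <- as.integer(h$states)
  ds <- as.integer(d$states)
  if (length(hs) != length(ds)) {
    stop("human and dog state sequences differ in length; align first",
         call. = FALSE)
  }
  if (!all(hs %in% c(0L, 1L)) || !all(ds %in% c(0L, 1L))) {
    stop("states must be 0/1", call. = FALSE)
  }
  structure(
    list(
      dyad_id = as.character(dyad_id),
      night_id = as.character(night_id),
      human_states = hs,
      dog_states = ds,
      n_epochs = length(hs)
    ),
    class = "dyad_night"
  )
}

#' @export
print.dyad_night <- function(x, ...) {
  cat(sprintf(
    "<dyad_night> dyad %s night %s: %d epochs (human moving %.1f%%, dog %.1f%%)\n",
    x$dyad_id, x$night_id, x$n_epochs,
    100 * mean(x$human_states), 100 * mean(x$dog_states)
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
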
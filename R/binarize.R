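#' Species-specific movement thresholds
#'
#' Default cut-points for classifying a 60-second epoch as movement:
#' 91 SVM_gs for the human wrist device (1.1 METs, just above quiet lying
#' and well below the 217 SVM_gs sedentary/light boundary) and 400 cpm for
#' the dog collar device (a full head-and-body repositioning while lying
#' down, below the 1352 cpm sedentary/light boundary). Comparison is
#' inclusive: a value exactly at the threshold counts as movement.
#'
#' @param human_svm Positive threshold in SVM_gs (g-min) for humans.
#' @param dog_cpm Positive threshold in counts per minute for dogs.
#' @return An object of class `"threshold_config"`.
#' @export
threshold_config <- function(human_svm = 91, dog_cpm = 400) {
  if (!is.numeric(human_svm) || human_svm <= 0 ||
      !is.numeric(dog_cpm) || dog_cpm <= 0) {
    stop("thresholds must be positive numbers", call. = FALSE)
  }
  structure(list(human_svm = human_svm, dog_cpm = dog_cpm),
            class = "threshold_config")
}

#' Read thresholds from a YAML config file
#'
#' Looks for `thresholds.human_svm` and `thresholds.dog_cpm`; missing keys
#' fall back to the defaults of [threshold_config()].
#'
#' @param path Path to a YAML file.
#' @return A `"threshold_config"` object.
#' @export
read_threshold_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- cfg$thresholds %||% list()
  threshold_config(
    human_svm = thr$human_svm %||% 91,
    dog_cpm = thr$dog_cpm %||% 400
  )
}

#' Threshold an epoch series into binary movement states
#'
#' Epoch `t` is in the moving state (1) when its activity value is greater
#' than or equal to the species' threshold, otherwise still (0).
#'
#' @param series An [epoch_series()].
#' @param config A [threshold_config()]; the series' `species` field selects
#'   which threshold applies.
#' @return An object of class `"binary_series"` with fields `subject_id`,
#'   `species`, `dyad_id`, `night_id`, `states` (integer 0/1, same length
#'   as the input values) and `threshold_used`.
#' @export
binarize_series <- function(series, config = threshold_config()) {
  stopifnot(inherits(series, "epoch_series"),
            inherits(config, "threshold_config"))
  thr <- switch(series$species, human = config$human_svm,
                dog = config$dog_cpm)
  structure(
    list(
      subject_id = series$subject_id,
      species = series$species,
      dyad_id = series$dyad_id,
      night_id = series$night_id,
      states = as.integer(series$values >= thr),
      threshold_used = thr
    ),
    class = "binary_series"
  )
}

#' @export
print.binary_series <- function(x, ...) {
  cat(sprintf(
    "<binary_series> %s (%s), dyad %s night %s: %d epochs, %.1f%% moving (threshold %g)\n",
    x$subject_id, x$species, x$dyad_id, x$night_id, length(x$states),
    100 * mean(x$states), x$threshold_used
  ))
  invisible(x)
}

#' Convert METs to SVM_gs through the two-point device anchor
#'
#' Linear map through the anchor pair (1.1 METs, 91 SVM_gs) and
#' (1.5 METs, 217 SVM_gs): `svm = 315 * mets - 255.5`. This is a
#' convenience interpolation between the two operative anchor points, not a
#' published full calibration curve; 91 SVM_gs remains the operative human
#' threshold regardless.
#'
#' @param mets Numeric vector of MET values; guarded to the plausible
#'   nighttime range 0.9-3.0.
#' @return SVM_gs values (g-min per 60-s epoch).
#' @export
mets_to_svm <- function(mets) {
  if (!is.numeric(mets) || anyNA(mets) || any(mets < 0.9 | mets > 3.0)) {
    stop("mets must lie in the guard range [0.9, 3.0]", call. = FALSE)
  }
  315 * mets - 255.5
}

#' Fraction of epochs spent in the moving state
#'
#' @param states A 0/1 vector, a `"binary_series"`, or a `"dyad_night"`
#'   component.
#' @return The mean of the states, a proportion in \[0, 1\].
#' @export
movement_fraction <- function(states) {
  if (inherits(states, "binary_series")) states <- states$states
  states <- as.numeric(states)
  if (length(states) < 1L) {
    stop("cannot take the movement fraction of an empty sequence",
         call. = FALSE)
  }
  if (!all(states %in% c(0, 1))) stop("states must be 0/1", call. = FALSE)
  mean(states)
}
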
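#' Read an epoch-level activity CSV
#'
#' The epoch file holds one row per 60-second epoch per subject per night,
#' with columns `dyad_id,night_id,subject_id,species,epoch_index,activity`.
#' `epoch_index` must be contiguous from 0 within each night; activity must
#' be non-negative.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param species Which species' rows to load (`"human"` or `"dog"`).
#'
#' @return A named list of [epoch_series()] objects, one per
#'   (dyad_id, night_id), named `"<dyad_id>:<night_id>"`, values in
#'   `epoch_index` order.
#' @export
read_epoch_csv <- function(path, species = c("human", "dog")) {
  species <- match.arg(species)
  if (!file.exists(path)) stop("epoch file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("dyad_id", "night_id", "subject_id", "species",
                "epoch_index", "activity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("epoch file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[df$species == species, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop("no rows for species '", species, "' in ", path, call. = FALSE)
  }
  if (anyNA(df$activity) || any(df$activity < 0)) {
    stop("activity values must be non-negative and non-missing",
         call. = FALSE)
  }
  keys <- paste(df$dyad_id, df$night_id, sep = ":")
  out <- lapply(split(df, keys), function(g) {
    g <- g[order(g$epoch_index), , drop = FALSE]
    idx <- g$epoch_index
    if (!identical(as.integer(idx), seq_len(nrow(g)) - 1L)) {
      stop(sprintf(
        "epoch_index gap in dyad %s night %s: indices must run 0..%d",
        g$dyad_id[1L], g$night_id[1L], nrow(g) - 1L
      ), call. = FALSE)
    }
    epoch_series(
      subject_id = g$subject_id[1L], species = species,
      dyad_id = g$dyad_id[1L], night_id = g$night_id[1L],
      values = g$activity
    )
  })
  out[order(names(out))]
}

#' Write epoch series to CSV
#'
#' Inverse of [read_epoch_csv()]. Activity values are written with 17
#' significant digits so that a read/write round trip reproduces them
#' exactly.
#'
#' @param series A single [epoch_series()], a list of them, or a data frame
#'   already in the epoch CSV schema.
#' @param path Output file path.
#' @param header_comment Optional character vector of lines written as
#'   `#`-prefixed comments before the header.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series, path, header_comment = NULL) {
  if (is.data.frame(series)) {
    df <- series
  } else {
    if (inherits(series, "epoch_series")) series <- list(series)
    df <- do.call(rbind, lapply(series, function(s) {
      data.frame(
        dyad_id = s$dyad_id, night_id = s$night_id,
        subject_id = s$subject_id, species = s$species,
        epoch_index = seq_along(s$values) - 1L,
        activity = s$values, stringsAsFactors = FALSE
      )
    }))
  }
  df$activity <- sprintf("%.17g", as.numeric(df$activity))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sleep-diary CSV
#'
#' One row per (dyad_id, night_id), with the morning diary fields: reported
#' sleep minutes, estimated dog-in-bed minutes, a 1-5 sleep-quality rating,
#' awakening count, and disturbance flags for dog and other humans.
#'
#' @param path Path to a UTF-8 CSV with header
#'   `dyad_id,night_id,reported_sleep_min,dog_in_bed_min,rating,n_awakenings,dog_disturbance,human_disturbance`.
#' @return A data frame with one validated row per diary entry; `rating`
#'   is integer 1-5, disturbance flags are logical.
#' @export
read_diary_csv <- function(path) {
  if (!file.exists(path)) stop("diary file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("dyad_id", "night_id", "reported_sleep_min", "dog_in_bed_min",
                "rating", "n_awakenings", "dog_disturbance",
                "human_disturbance")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("diary file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$rating <- as.integer(df$rating)
  if (anyNA(df$rating) || any(!df$rating %in% 1:5)) {
    stop("diary ratings must be integers in 1..5", call. = FALSE)
  }
  for (col in c("reported_sleep_min", "dog_in_bed_min")) {
    if (anyNA(df[[col]]) || any(df[[col]] < 0)) {
      stop("diary column ", col, " must be non-negative", call. = FALSE)
    }
  }
  df$n_awakenings <- as.integer(df$n_awakenings)
  df$dog_disturbance <- as.logical(df$dog_disturbance)
  df$human_disturbance <- as.logical(df$human_disturbance)
  df[order(df$dyad_id, df$night_id), required]
}

#' Write a sleep-diary CSV
#'
#' @param diary Data frame as returned by [read_diary_csv()].
#' @param path Output file path.
#' @param header_comment Optional `#`-prefixed comment lines.
#' @return `path`, invisibly.
#' @export
write_diary_csv <- function(diary, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) writeLines(paste0("# ", header_comment), con)
  utils::write.csv(diary, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Full-night bedsharing screen
#'
#' A night is analyzed only if the dog stayed on the bed essentially the
#' whole sleep period: the reported dog-in-bed time must meet or exceed the
#' reported sleep time, or fall short of it by 15 minutes or fewer. The
#' boundary is inclusive — a shortfall of exactly 15 minutes passes.
#'
#' @param diary A diary data frame (vectorized over rows) or a single-row
#'   entry.
#' @param max_shortfall_min Allowed shortfall in minutes (default 15).
#' @return Logical vector, `TRUE` for nights that pass the screen.
#' @export
screen_full_night <- function(diary, max_shortfall_min = 15) {
  diary$dog_in_bed_min >= diary$reported_sleep_min - max_shortfall_min
}

#' Align a human and a dog epoch series for the same night
#'
#' Devices stop recording at slightly different times, so the two series for
#' a night may differ by a few epochs. Both are truncated to the shorter
#' length; a warning is emitted if more than `max_silent_trunc` epochs are
#' dropped.
#'
#' @param human,dog [epoch_series()] objects for the same dyad and night.
#' @param max_silent_trunc Truncations larger than this many epochs warn.
#' @return A list with elements `human` and `dog`, both truncated to the
#'   common length.
#' @export
align_dyad <- function(human, dog, max_silent_trunc = 5L) {
  stopifnot(inherits(human, "epoch_series"), inherits(dog, "epoch_series"))
  if (!identical(human$dyad_id, dog$dyad_id) ||
      !identical(human$night_id, dog$night_id)) {
    stop(sprintf(
      "cannot pair series from (%s, %s) with (%s, %s)",
      human$dyad_id, human$night_id, dog$dyad_id, dog$night_id
    ), call. = FALSE)
  }
  n <- min(length(human$values), length(dog$values))
  if (n < 1L) {
    stop("empty overlap between human and dog series for dyad ",
         human$dyad_id, " night ", human$night_id, call. = FALSE)
  }
  dropped <- max(length(human$values), length(dog$values)) - n
  if (dropped > max_silent_trunc) {
    warning(sprintf(
      "alignment dropped %d epochs for dyad %s night %s",
      dropped, human$dyad_id, human$night_id
    ), call. = FALSE)
  }
  human$values <- human$values[seq_len(n)]
  dog$values <- dog$values[seq_len(n)]
  list(human = human, dog = dog)
}
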
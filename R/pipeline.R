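#' Pipeline configuration
#'
#' Collects paths and analysis options for the end-to-end pipeline. All
#' analysis stages read their tuning from here, never from globals.
#'
#' @param epochs Path to the epoch activity CSV (both species).
#' @param diary Path to the sleep-diary CSV.
#' @param out_dir Output directory for tables and reports.
#' @param thresholds A [threshold_config()].
#' @param screen Apply the full-night bedsharing screen (default `TRUE`)?
#' @param ci_level Confidence level for transition-model intervals
#'   (default 0.99).
#' @param ranksum_convention `"mann-whitney"` or `"rank-sum"` for the bout
#'   comparison statistic.
#' @param seed Integer seed used by [run_simulate()].
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(epochs = "epochs.csv", diary = "diary.csv",
                            out_dir = "dyadsleep-out",
                            thresholds = threshold_config(),
                            screen = TRUE, ci_level = 0.99,
                            ranksum_convention = "mann-whitney",
                            seed = 1L) {
  if (ci_level <= 0.5 || ci_level >= 1) {
    stop("ci_level must lie in (0.5, 1)", call. = FALSE)
  }
  ranksum_convention <- match.arg(ranksum_convention,
                                  c("mann-whitney", "rank-sum"))
  structure(
    list(epochs = epochs, diary = diary, out_dir = out_dir,
         thresholds = thresholds, screen = isTRUE(screen),
         ci_level = ci_level, ranksum_convention = ranksum_convention,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `epochs`, `diary`, `out_dir`, `screen`, `ci_level`,
#' `ranksum_convention`, `seed`, and `thresholds.human_svm` /
#' `thresholds.dog_cpm`. Missing keys take the [pipeline_config()]
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- cfg$thresholds %||% list()
  pipeline_config(
    epochs = cfg$epochs %||% "epochs.csv",
    diary = cfg$diary %||% "diary.csv",
    out_dir = cfg$out_dir %||% "dyadsleep-out",
    thresholds = threshold_config(human_svm = thr$human_svm %||% 91,
                                  dog_cpm = thr$dog_cpm %||% 400),
    screen = cfg$screen %||% TRUE,
    ci_level = cfg$ci_level %||% 0.99,
    ranksum_convention = cfg$ranksum_convention %||% "mann-whitney",
    seed = cfg$seed %||% 1L
  )
}

# hash of the analysis options only (not file locations), so identical
# inputs analyzed from different directories yield identical outputs
config_hash <- function(config) {
  opts <- unclass(config)
  opts$epochs <- opts$diary <- opts$out_dir <- NULL
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(deparse(opts), collapse = ""), tf)
  unname(tools::md5sum(tf))
}

output_header <- function(config) {
  sprintf("dyadsleep %s config=%s",
          as.character(utils::packageVersion("dyadsleep")),
          config_hash(config))
}

write_table_csv <- function(df, path, header) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Simulate a study and write it to disk
#'
#' Thin orchestration over [simulate_study()] and [write_study()]: writes
#' `epochs.csv`, `diary.csv` and `truth.json` into the configured output
#' directory.
#'
#' @param config A [pipeline_config()]; `out_dir` and `seed` are used.
#' @param params A [sim_params()] object.
#' @return Paths of the three written files, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), params = sim_params()) {
  stopifnot(inherits(config, "pipeline_config"))
  study <- simulate_study(params, seed = config$seed)
  paths <- write_study(study, config$out_dir)
  message("wrote ", length(paths), " files to ", config$out_dir)
  invisible(paths)
}

#' One-character-per-epoch raster of a dyad-night
#'
#' Plain-text encoding of the four dyadic states, one character per
#' one-minute epoch: `.` neither moving, `h` human only, `d` dog only,
#' `B` both moving.
#'
#' @param night A [dyad_night()].
#' @return A single string of length `n_epochs`.
#' @export
state_raster <- function(night) {
  st <- dyadic_states(night)$states
  paste(c(B = "B", H = "h", D = "d", N = ".")[as.integer(st)],
        collapse = "")
}

#' Run the full analysis pipeline
#'
#' Reads the epoch and diary files, applies the full-night screen, aligns
#' and binarizes each dyad-night, and writes the complete analysis bundle
#' into `config$out_dir`:
#'
#' * `table_crosstab.csv` — simultaneous-movement 2x2 counts and column
#'   percentages, with the chi-square test;
#' * `table_transitions.csv` — four-state transition counts and
#'   probabilities (3 dp plus full precision);
#' * `table_hazards.csv` — transition-model odds ratios with CIs;
#' * `bouts.csv` — per-bout rows with dog-precedence class;
#' * `night_summaries.csv` — per-night proportions and ratings;
#' * `model.json` — transition-model, rank-sum, correlation, LME and
#'   variance-decomposition results plus screening log;
#' * `rasters.txt` — one text raster per night (see [state_raster()]).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all computed result objects.
#' @export
run_analyze <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- output_header(config)
  stage <- function(expr) {
    tryCatch(expr, error = function(e) {
      message("stage skipped: ", conditionMessage(e))
      NULL
    })
  }

  diary <- read_diary_csv(config$diary)
  keep <- if (config$screen) screen_full_night(diary) else
    rep(TRUE, nrow(diary))
  screened_out <- diary[!keep, c("dyad_id", "night_id"), drop = FALSE]
  if (nrow(screened_out) > 0L) {
    message("screened out ", nrow(screened_out),
            " night(s) without full-night bedsharing")
  }
  diary <- diary[keep, , drop = FALSE]
  if (nrow(diary) == 0L) {
    stop("no nights survive the full-night bedsharing screen",
         call. = FALSE)
  }

  humans <- read_epoch_csv(config$epochs, "human")
  dogs <- read_epoch_csv(config$epochs, "dog")
  wanted <- paste(diary$dyad_id, diary$night_id, sep = ":")
  keys <- intersect(intersect(names(humans), names(dogs)), wanted)
  if (length(keys) == 0L) {
    stop("no screened night has epoch data for both species",
         call. = FALSE)
  }
  nights <- lapply(keys, function(k) {
    pair <- align_dyad(humans[[k]], dogs[[k]])
    dyad_night(binarize_series(pair$human, config$thresholds),
               binarize_series(pair$dog, config$thresholds))
  })
  message("analyzing ", length(nights), " nights from ",
          length(unique(vapply(nights, `[[`, "", "dyad_id"))), " dyads")

  # simultaneous co-occurrence
  ct <- crosstab_movement(nights)
  chi <- tryCatch(chi_square_2x2(ct), error = function(e) NULL)
  ct_df <- data.frame(
    dog_movement = c("No", "Yes", "TOTAL"),
    human_no = c(sprintf("%d (%.1f%%)", ct$counts[, 1], ct$col_pct[, 1]),
                 sprintf("%d (100%%)", sum(ct$counts[, 1]))),
    human_yes = c(sprintf("%d (%.1f%%)", ct$counts[, 2], ct$col_pct[, 2]),
                  sprintf("%d (100%%)", sum(ct$counts[, 2])))
  )
  write_table_csv(ct_df, file.path(config$out_dir, "table_crosstab.csv"),
                  header)

  # four-state transitions
  seqs <- lapply(nights, dyadic_states)
  tt <- transition_counts(seqs)
  tt_df <- data.frame(from = DYAD_STATES, n = tt$row_n,
                      round(tt$probs, 3),
                      check.names = FALSE)
  names(tt_df)[3:6] <- paste0("p_", DYAD_STATES)
  full <- tt$probs
  colnames(full) <- paste0("p_full_", DYAD_STATES)
  tt_df <- cbind(tt_df, full)
  write_table_csv(tt_df, file.path(config$out_dir, "table_transitions.csv"),
                  header)
  human_onset <- stage(human_transition_prob_given_dog(tt))
  dog_onset <- stage(dog_transition_prob_given_human(tt))

  # transition model; degenerate inputs (e.g. a partner that never moves)
  # are recorded rather than aborting the bundle
  design <- build_design(nights)
  fit <- tryCatch(
    fit_transition_model(design, interaction = FALSE,
                         ci_level = config$ci_level),
    error = function(e) {
      message("transition model not fit: ", conditionMessage(e))
      structure(conditionMessage(e), class = "stage_error")
    }
  )
  lrt <- haz <- NULL
  if (!inherits(fit, "stage_error")) {
    fit_int <- stage(fit_transition_model(design, interaction = TRUE,
                                          ci_level = config$ci_level))
    if (!is.null(fit_int)) lrt <- interaction_lrt(fit_int, fit)
    haz <- hazard_table(fit)
    write_table_csv(haz, file.path(config$out_dir, "table_hazards.csv"),
                    header)
  }

  # bouts
  bouts <- do.call(rbind, lapply(nights, classify_movement_bouts))
  write_table_csv(bouts, file.path(config$out_dir, "bouts.csv"), header)
  ranksum <- tryCatch(
    compare_bout_durations(bouts, convention = config$ranksum_convention),
    error = function(e) NULL
  )

  # night level
  summaries <- summarize_nights(nights, diary)
  write_table_csv(summaries,
                  file.path(config$out_dir, "night_summaries.csv"), header)
  corr <- stage(pearson_correlation(summaries$human_moving_prop,
                                    summaries$dog_moving_prop))
  lme_move <- stage(suppressWarnings(fit_lme_movement(summaries)))
  lme_subj <- stage(fit_lme_subjective(summaries))
  slope_lrt <- stage(random_slope_lrt(summaries))
  vshares <- if (is.null(lme_subj)) NULL else
    variance_decomposition(lme_subj)
  disturb <- count_reported_disturbances(diary)

  model <- list(
    header = header,
    n_nights = length(nights),
    n_epochs = sum(vapply(nights, `[[`, 0L, "n_epochs")),
    mean_monitoring_hours = mean_monitoring_hours(
      sum(vapply(nights, `[[`, 0L, "n_epochs")), length(nights)),
    chi_square = chi,
    human_onset_prob = as.list(human_onset),
    human_raw_odds = if (!is.null(human_onset))
      stage(raw_transition_odds(human_onset[["p_dog_moving"]],
                                human_onset[["p_dog_still"]])),
    dog_onset_prob = as.list(dog_onset),
    dog_raw_odds = if (!is.null(dog_onset))
      stage(raw_transition_odds(dog_onset[["p_human_moving"]],
                                dog_onset[["p_human_still"]])),
    hazards = haz,
    transition_model_error = if (inherits(fit, "stage_error"))
      unclass(fit),
    interaction_lrt = lrt,
    ranksum = ranksum,
    movement_correlation = corr,
    lme_movement = if (!is.null(lme_move))
      list(coefficients = as.data.frame(lme_move$coefficients),
           note = lme_move$note),
    lme_subjective = if (!is.null(lme_subj))
      list(coefficients = as.data.frame(lme_subj$coefficients),
           note = lme_subj$note),
    random_slope_lrt = slope_lrt,
    variance_shares = if (!is.null(vshares))
      vshares[c("fixed_pct", "between_dyad_pct", "residual_pct")],
    disturbances = disturb[c("n_dog_disturbance", "total_nights")],
    screened_out = screened_out
  )
  jsonlite::write_json(model, file.path(config$out_dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", force = TRUE)

  raster_lines <- unlist(lapply(nights, function(ng) {
    c(sprintf("> %s %s", ng$dyad_id, ng$night_id), state_raster(ng))
  }))
  writeLines(c(paste0("# ", header), raster_lines),
             file.path(config$out_dir, "rasters.txt"))

  invisible(list(
    nights = nights, crosstab = ct, chi_square = chi,
    transition_table = tt,
    fit = if (inherits(fit, "stage_error")) NULL else fit,
    interaction_lrt = lrt,
    hazards = haz, bouts = bouts, ranksum = ranksum,
    summaries = summaries, correlation = corr,
    lme_movement = lme_move, lme_subjective = lme_subj,
    random_slope_lrt = slope_lrt, variance_shares = vshares,
    disturbances = disturb, model = model
  ))
}

#' Write a plain-text analysis report
#'
#' Condenses an existing `model.json` (produced by [run_analyze()]) into a
#' human-readable `report.txt` in the same directory.
#'
#' @param config A [pipeline_config()]; `out_dir` must contain
#'   `model.json`.
#' @return The report path, invisibly.
#' @export
run_report <- function(config) {
  path <- file.path(config$out_dir, "model.json")
  if (!file.exists(path)) {
    stop("model.json not found in ", config$out_dir,
         "; run run_analyze() first", call. = FALSE)
  }
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  lines <- c(
    paste0("# ", m$header),
    sprintf("Nights analyzed: %d (%.1f h mean monitoring)", m$n_nights,
            m$mean_monitoring_hours),
    sprintf("Human onset probability: %.3f after dog movement, %.3f otherwise (raw odds %.2f)",
            m$human_onset_prob$p_dog_moving, m$human_onset_prob$p_dog_still,
            m$human_raw_odds),
    sprintf("Dog onset probability: %.3f after human movement, %.3f otherwise (raw odds %.2f)",
            m$dog_onset_prob$p_human_moving, m$dog_onset_prob$p_human_still,
            m$dog_raw_odds),
    "Transition-model odds ratios:",
    sprintf("  %s, %s: OR %.2f [%.2f, %.2f]",
            m$hazards$covariate, m$hazards$transition, m$hazards$odds_ratio,
            m$hazards$ci_lower, m$hazards$ci_upper),
    if (!is.null(m$ranksum)) {
      sprintf("Bout durations: %.2f min (dog-preceded, n=%d) vs %.2f min (n=%d), W=%s, p=%.3g",
              m$ranksum$mean1, m$ranksum$n1, m$ranksum$mean2, m$ranksum$n2,
              format(m$ranksum$statistic), m$ranksum$p_value)
    },
    sprintf("Movement correlation over nights: r=%.2f, t(%d)=%.2f",
            m$movement_correlation$r, m$movement_correlation$df,
            m$movement_correlation$t),
    sprintf("Rating ~ dog movement slope: %.2f (SE %.2f)",
            m$lme_subjective$coefficients$Estimate[2],
            m$lme_subjective$coefficients$`Std..Error`[2]),
    sprintf("Variance shares: fixed %.1f%%, between-dyad %.1f%%, residual %.1f%%",
            m$variance_shares$fixed_pct, m$variance_shares$between_dyad_pct,
            m$variance_shares$residual_pct),
    sprintf("Dog-disturbance reports: %d of %d nights",
            m$disturbances$n_dog_disturbance, m$disturbances$total_nights)
  )
  out <- file.path(config$out_dir, "report.txt")
  writeLines(lines, out)
  invisible(out)
}
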
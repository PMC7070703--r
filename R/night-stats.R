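#' Night-level movement summaries joined to the sleep diary
#'
#' One row per dyad-night with the moving-time proportions of each partner
#' and, when available, the diary rating and dog-disturbance flag. Nights
#' without a matching diary entry get `NA` rating with a warning.
#'
#' @param nights A list of [dyad_night()] objects.
#' @param diary Optional diary data frame (see [read_diary_csv()]).
#' @return A data frame with columns `dyad_id`, `night_id`,
#'   `human_moving_prop`, `dog_moving_prop`, `rating`,
#'   `dog_disturbance`.
#' @export
summarize_nights <- function(nights, diary = NULL) {
  if (inherits(nights, "dyad_night")) nights <- list(nights)
  out <- do.call(rbind, lapply(nights, function(ng) {
    data.frame(
      dyad_id = ng$dyad_id,
      night_id = ng$night_id,
      human_moving_prop = movement_fraction(ng$human_states),
      dog_moving_prop = movement_fraction(ng$dog_states),
      stringsAsFactors = FALSE
    )
  }))
  out$rating <- NA_integer_
  out$dog_disturbance <- NA
  if (!is.null(diary)) {
    key <- paste(out$dyad_id, out$night_id, sep = ":")
    dkey <- paste(diary$dyad_id, diary$night_id, sep = ":")
    m <- match(key, dkey)
    if (anyNA(m)) {
      warning(sum(is.na(m)), " night(s) have no diary entry; rating set NA",
              call. = FALSE)
    }
    out$rating <- diary$rating[m]
    out$dog_disturbance <- diary$dog_disturbance[m]
  }
  out
}

#' Mean nightly monitoring period in hours
#'
#' @param total_epochs Total number of one-minute epochs across all nights.
#' @param n_nights Number of sleep periods.
#' @return Mean monitoring period per night, in hours.
#' @export
mean_monitoring_hours <- function(total_epochs, n_nights) {
  stopifnot(n_nights > 0)
  total_epochs / n_nights / 60
}

#' Pearson correlation with t test
#'
#' Sample Pearson correlation with the exact t transform
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and a two-sided p-value on
#' `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3), neither constant.
#' @return A list with `r`, `t`, `df` and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(
    r = unname(ct$estimate),
    t = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value)
  )
}

wrap_lme <- function(model, n, note = NULL) {
  sm <- summary(model)
  vc <- as.data.frame(lme4::VarCorr(model))
  structure(
    list(
      model = model,
      coefficients = stats::coef(sm),
      varcorr = vc,
      resid_var = stats::sigma(model)^2,
      loglik = as.numeric(stats::logLik(model)),
      n = n,
      groups = lme4::ngrps(model),
      note = note
    ),
    class = "dyad_lme"
  )
}

#' @export
print.dyad_lme <- function(x, ...) {
  cat("<dyad_lme> linear mixed model on", x$n, "nights,",
      x$groups, "dyads\n")
  print(round(x$coefficients, 4))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Mixed model: human movement predicted by dog movement
#'
#' Nightly human moving proportion regressed on nightly dog moving
#' proportion with a random intercept and random slope for dyad (REML by
#' default). Singular random-slope fits fall back to a random intercept
#' with a warning.
#'
#' @param summaries Data frame from [summarize_nights()].
#' @param reml Use REML (default) or ML.
#' @return A `"dyad_lme"` object; `coefficients` holds the fixed effects
#'   with SEs and t values.
#' @export
fit_lme_movement <- function(summaries, reml = TRUE) {
  stopifnot(all(c("human_moving_prop", "dog_moving_prop", "dyad_id") %in%
                  names(summaries)))
  if (length(unique(summaries$dyad_id)) < 2L) {
    stop("need at least 2 dyads", call. = FALSE)
  }
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(human_moving_prop ~ dog_moving_prop +
                 (1 + dog_moving_prop | dyad_id),
               data = summaries, REML = reml)
  ))
  note <- NULL
  if (lme4::isSingular(m, tol = 1e-4)) {
    warning("random-slope fit is singular; refitting with random ",
            "intercept only", call. = FALSE)
    m <- suppressMessages(suppressWarnings(
      lme4::lmer(human_moving_prop ~ dog_moving_prop + (1 | dyad_id),
                 data = summaries, REML = reml)
    ))
    note <- "singular random slope; intercept-only random effects reported"
  }
  wrap_lme(m, nrow(summaries), note)
}

#' Mixed model: subjective sleep rating predicted by dog movement
#'
#' Nightly 1-5 sleep-quality rating regressed on the dog's nightly moving
#' proportion with a random intercept for dyad. Ratings are modeled as
#' numeric; interpret variance components with the usual caution owed to
#' the ordinal 1-5 scale (recorded in the returned `note`).
#'
#' @param summaries Data frame from [summarize_nights()]; at least 80% of
#'   nights must carry a rating.
#' @param reml Use REML (default) or ML.
#' @return A `"dyad_lme"` object.
#' @export
fit_lme_subjective <- function(summaries, reml = TRUE) {
  stopifnot(all(c("rating", "dog_moving_prop", "dyad_id") %in%
                  names(summaries)))
  ok <- !is.na(summaries$rating)
  if (mean(ok) < 0.8) {
    stop("ratings present for fewer than 80% of nights", call. = FALSE)
  }
  d <- summaries[ok, , drop = FALSE]
  if (stats::var(d$rating) == 0) {
    stop("all ratings identical; model is degenerate", call. = FALSE)
  }
  m <- suppressMessages(suppressWarnings(
    lme4::lmer(rating ~ dog_moving_prop + (1 | dyad_id), data = d,
               REML = reml)
  ))
  wrap_lme(m, nrow(d),
           note = "ratings modeled as numeric despite ordinal 1-5 scale")
}

#' Likelihood-ratio test for a random slope on dog movement
#'
#' Compares the random-intercept rating model against one adding a random
#' slope for dog movement (2 extra parameters: slope variance and
#' intercept-slope covariance). Both models are refit with ML for the
#' comparison.
#'
#' @param summaries Data frame from [summarize_nights()].
#' @return A list with `statistic`, `df` (2) and `p_value`.
#' @export
random_slope_lrt <- function(summaries) {
  ok <- !is.na(summaries$rating)
  d <- summaries[ok, , drop = FALSE]
  m0 <- suppressMessages(suppressWarnings(
    lme4::lmer(rating ~ dog_moving_prop + (1 | dyad_id), data = d,
               REML = FALSE)
  ))
  m1 <- suppressMessages(suppressWarnings(
    lme4::lmer(rating ~ dog_moving_prop + (1 + dog_moving_prop | dyad_id),
               data = d, REML = FALSE)
  ))
  stat <- max(0, 2 * (as.numeric(stats::logLik(m1)) -
                        as.numeric(stats::logLik(m0))))
  list(statistic = stat, df = 2L,
       p_value = stats::pchisq(stat, 2L, lower.tail = FALSE))
}

#' Variance decomposition of a random-intercept mixed model
#'
#' Splits the response variance into the share explained by the fixed
#' effects (variance of the fixed-effect predictions), the between-dyad
#' share (random-intercept variance) and the residual share, each as a
#' percentage of their sum. This is the fixed-prediction-variance
#' (Nakagawa-style) convention.
#'
#' @param fit A `"dyad_lme"` from [fit_lme_subjective()] or
#'   [fit_lme_movement()] (intercept-only random effects).
#' @return A list with `fixed_pct`, `between_dyad_pct`, `residual_pct`
#'   (summing to 100) and the underlying `components`.
#' @export
variance_decomposition <- function(fit) {
  stopifnot(inherits(fit, "dyad_lme"))
  m <- fit$model
  pred_fixed <- drop(lme4::getME(m, "X") %*% lme4::fixef(m))
  v_fixed <- stats::var(pred_fixed)
  vc <- as.data.frame(lme4::VarCorr(m))
  v_between <- sum(vc$vcov[vc$grp != "Residual" &
                             vc$var1 == "(Intercept)" &
                             is.na(vc$var2)])
  v_resid <- vc$vcov[vc$grp == "Residual"]
  total <- v_fixed + v_between + v_resid
  list(
    fixed_pct = 100 * v_fixed / total,
    between_dyad_pct = 100 * v_between / total,
    residual_pct = 100 * v_resid / total,
    components = c(fixed = v_fixed, between_dyad = v_between,
                   residual = v_resid)
  )
}

#' Count diary-reported dog disturbances
#'
#' @param diary A diary data frame.
#' @return A list with `n_dog_disturbance`, `total_nights` and `per_dyad`
#'   (data frame of counts by dyad).
#' @export
count_reported_disturbances <- function(diary) {
  stopifnot(is.data.frame(diary), "dog_disturbance" %in% names(diary))
  per <- stats::aggregate(
    list(n_dog_disturbance = diary$dog_disturbance),
    by = list(dyad_id = diary$dyad_id), FUN = sum
  )
  list(
    n_dog_disturbance = sum(diary$dog_disturbance),
    total_nights = nrow(diary),
    per_dyad = per
  )
}
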
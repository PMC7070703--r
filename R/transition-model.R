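#' Build the lagged transition design from dyad-nights
#'
#' One row per epoch `t >= 1` per night (the first epoch of each night has
#' no lag and is excluded; chains never cross night boundaries). Columns:
#' the origin state `origin = h[t-1]`, the outcome `outcome = h[t]`, the
#' lagged partner state `dog_prev = d[t-1]`, and `night_prop = t / (T - 1)`,
#' the proportion of the sleep period elapsed, spanning exactly (0, 1].
#'
#' @param nights A list of [dyad_night()] objects (each of length >= 2).
#' @return A data frame of class `"transition_design"` with columns
#'   `dyad_id`, `night_id`, `t`, `origin`, `outcome`, `dog_prev`,
#'   `night_prop`.
#' @export
build_design <- function(nights) {
  if (inherits(nights, "dyad_night")) nights <- list(nights)
  rows <- lapply(nights, function(ng) {
    T_ <- ng$n_epochs
    if (T_ < 2L) stop("night ", ng$night_id, " has fewer than 2 epochs",
                      call. = FALSE)
    t <- seq_len(T_ - 1L) # destination epochs 1..T-1 (0-based)
    data.frame(
      dyad_id = ng$dyad_id,
      night_id = ng$night_id,
      t = t,
      origin = ng$human_states[t],
      outcome = ng$human_states[t + 1L],
      dog_prev = ng$dog_states[t],
      night_prop = t / (T_ - 1L),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("transition_design", "data.frame")
  out
}

# Newton-Raphson (IRLS) logistic fit; SEs from the observed information.
# Converges on the gradient sup-norm. Errors on separation/singularity.
logistic_irls <- function(X, y, label, tol = 1e-8, maxit = 100L) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    g <- drop(crossprod(X, y - p))
    if (max(abs(g)) < tol) break
    w <- p * (1 - p)
    H <- crossprod(X, X * w)
    step <- tryCatch(solve(H, g), error = function(e) {
      stop("singular information matrix in the ", label,
           " transition model (possible separation)", call. = FALSE)
    })
    # halve overly aggressive Newton steps
    while (max(abs(step)) > 10) step <- step / 2
    beta <- beta + step
    if (max(abs(beta)) > 30) {
      stop("separation detected in the ", label,
           " transition model: a coefficient is diverging", call. = FALSE)
    }
    if (max(abs(step)) < 1e-12) break # flat direction; gradient stalled
    if (it == maxit && max(abs(g)) > 1e-3) {
      stop("transition model for the ", label,
           " origin state did not converge in ", maxit, " iterations",
           call. = FALSE)
    }
  }
  p <- stats::plogis(drop(X %*% beta))
  w <- p * (1 - p)
  H <- crossprod(X, X * w)
  vcov <- tryCatch(solve(H), error = function(e) {
    stop("singular information at the optimum (", label, " origin); ",
         "possible separation", call. = FALSE)
  })
  eps <- .Machine$double.eps
  list(
    coef = stats::setNames(beta, colnames(X)),
    se = stats::setNames(sqrt(diag(vcov)), colnames(X)),
    vcov = vcov,
    loglik = sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps))),
    n = length(y),
    fitted_mean = mean(p),
    outcome_mean = mean(y)
  )
}

#' Fit the per-origin-state logistic transition model
#'
#' Discrete-time analog of a two-state Markov model with covariates: two
#' independent maximum-likelihood logistic regressions, one per origin
#' state. For epochs where the human was still at t-1 the outcome is moving
#' at t (onset, "No Move to Move"); for epochs where the human was moving
#' the outcome is stillness at t (settling, "Move to No Move"). Covariates
#' are lagged dog movement and the proportion of the night elapsed, with an
#' optional interaction. Fitting is Newton-Raphson to a gradient sup-norm
#' below 1e-8; standard errors come from the observed information.
#'
#' @param design A [build_design()] data frame.
#' @param interaction Include the dog-by-night-proportion interaction?
#' @param ci_level Confidence level for odds-ratio intervals (default 0.99,
#'   normal approximation, z = 2.5758 at 99%).
#' @return An object of class `"markov_fit"`: list with per-origin fits
#'   `onset` and `settle` (each: `coef`, `se`, `vcov`, `loglik`, `n`),
#'   plus `ci_level` and `interaction`.
#' @export
fit_transition_model <- function(design, interaction = FALSE,
                                 ci_level = 0.99) {
  stopifnot(is.data.frame(design),
            all(c("origin", "outcome", "dog_prev", "night_prop") %in%
                  names(design)))
  if (ci_level <= 0.5 || ci_level >= 1) {
    stop("ci_level must lie in (0.5, 1)", call. = FALSE)
  }
  if (!all(c(0L, 1L) %in% design$origin)) {
    stop("design must contain rows for both origin states", call. = FALSE)
  }
  make_X <- function(d) {
    X <- cbind(`(Intercept)` = 1, dog_prev = d$dog_prev,
               night_prop = d$night_prop)
    if (interaction) {
      X <- cbind(X, `dog_prev:night_prop` = d$dog_prev * d$night_prop)
    }
    X
  }
  fit_one <- function(origin_state, label) {
    d <- design[design$origin == origin_state, , drop = FALSE]
    y <- if (origin_state == 0L) d$outcome else 1L - d$outcome
    for (v in c("dog_prev", "night_prop")) {
      if (stats::var(d[[v]]) == 0) {
        stop("covariate ", v, " is constant among ", label,
             "-origin rows", call. = FALSE)
      }
    }
    logistic_irls(make_X(d), y, label)
  }
  structure(
    list(
      onset = fit_one(0L, "no-move"),
      settle = fit_one(1L, "move"),
      ci_level = ci_level,
      interaction = interaction
    ),
    class = "markov_fit"
  )
}

#' @export
print.markov_fit <- function(x, ...) {
  cat(sprintf("<markov_fit> per-origin logistic transition model (%d%% CIs)\n",
              round(100 * x$ci_level)))
  print(hazard_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Odds-ratio table for the fitted transition model
#'
#' One row per (covariate, transition): the odds ratio `exp(coef)` and its
#' normal-approximation confidence interval `exp(coef +/- z * SE)` at the
#' fit's CI level. Rows are ordered covariate-major with the onset
#' transition first, mirroring the conventional presentation.
#'
#' @param fit A `"markov_fit"`.
#' @return A data frame with columns `covariate`, `transition`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `coef`, `se`, `n`.
#' @export
hazard_table <- function(fit) {
  stopifnot(inherits(fit, "markov_fit"))
  z <- stats::qnorm(1 - (1 - fit$ci_level) / 2)
  covars <- setdiff(names(fit$onset$coef), "(Intercept)")
  rows <- list()
  for (cv in covars) {
    for (tr in c("onset", "settle")) {
      f <- fit[[tr]]
      rows[[length(rows) + 1L]] <- data.frame(
        covariate = switch(cv,
                           dog_prev = "Dog Movement Present",
                           night_prop = "Proportion of Night Passed",
                           `dog_prev:night_prop` = "Dog Movement x Proportion of Night",
                           cv),
        transition = if (tr == "onset") "No Move to Move" else "Move to No Move",
        odds_ratio = exp(f$coef[[cv]]),
        ci_lower = exp(f$coef[[cv]] - z * f$se[[cv]]),
        ci_upper = exp(f$coef[[cv]] + z * f$se[[cv]]),
        coef = f$coef[[cv]],
        se = f$se[[cv]],
        n = f$n,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Likelihood-ratio test for the interaction term
#'
#' Compares two [fit_transition_model()] fits on the same design, with and
#' without the dog-by-night-proportion interaction. The statistic is
#' `2 * (loglik_with - loglik_without)` summed over the two origin-state
#' fits; degrees of freedom equal the number of added coefficients.
#'
#' @param fit_with,fit_without Nested `"markov_fit"` objects on identical
#'   rows.
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
interaction_lrt <- function(fit_with, fit_without) {
  stopifnot(inherits(fit_with, "markov_fit"),
            inherits(fit_without, "markov_fit"))
  if (fit_with$onset$n != fit_without$onset$n ||
      fit_with$settle$n != fit_without$settle$n) {
    stop("models were fit on different rows; LRT requires nested fits on ",
         "identical data", call. = FALSE)
  }
  if (!all(names(fit_without$onset$coef) %in% names(fit_with$onset$coef))) {
    stop("models are not nested", call. = FALSE)
  }
  df <- (length(fit_with$onset$coef) - length(fit_without$onset$coef)) +
    (length(fit_with$settle$coef) - length(fit_without$settle$coef))
  ll_w <- fit_with$onset$loglik + fit_with$settle$loglik
  ll_0 <- fit_without$onset$loglik + fit_without$settle$loglik
  stat <- max(0, 2 * (ll_w - ll_0))
  if (df < 0L) stop("models are not nested", call. = FALSE)
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}
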
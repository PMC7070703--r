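#' Parameters for the coupled dyadic movement simulator
#'
#' Defines a study of coupled two-state movement chains: per minute, each
#' partner transitions between still (0) and moving (1) through logistic
#' kernels in which the partner's state at t-1 multiplies the transition
#' odds (cross-excitation), the human onset odds drift with the proportion
#' of night elapsed, and dyads differ through Gaussian effects on the onset
#' logits. Raw activity values are emitted from state-conditional
#' lognormals placed well clear of the movement thresholds, and diary
#' ratings follow a linear latent model in the dog's nightly moving
#' proportion.
#'
#' Baseline onset probabilities `p01_h`/`p01_d` default to values solved
#' numerically (see Details) so that the coupled chain's long-run moving
#' fractions hit `human_duty` and `dog_duty` with all couplings active; pass
#' them explicitly to override.
#'
#' @details The calibration averages the stationary distribution of the
#' joint four-state chain over the dyad-effect distribution and the
#' night-proportion covariate, then adjusts the baseline onset odds by
#' fixed-point iteration until the marginal duty cycles match their
#' targets. With cross-excitation multipliers of 1 and no night drift it
#' reduces to the two-state closed form of [calibrate_duty_cycle()].
#'
#' @param n_dyads,nights_per_dyad,epochs_per_night Study dimensions
#'   (defaults 12 dyads x 10 nights x 440 one-minute epochs).
#' @param human_duty,dog_duty Target long-run moving fractions (defaults
#'   0.045 and 0.124).
#' @param p10_h,p10_d Baseline per-minute settle probabilities (moving ->
#'   still); defaults 0.60 and 0.40, i.e. mean uninterrupted bouts of
#'   roughly 1.7 and 2.5 minutes.
#' @param p01_h,p01_d Baseline onset probabilities; `NULL` (default) means
#'   calibrate to the duty targets.
#' @param or_dog_on_human Odds multiplier of lagged dog movement on human
#'   onset (default 2.98).
#' @param or_settle Odds multiplier of lagged dog movement on human
#'   settling (default 0.64; values < 1 mean dog movement prolongs human
#'   movement).
#' @param or_nightprop Odds multiplier on human onset per unit of night
#'   elapsed (default 1.33).
#' @param or_human_on_dog Odds multiplier of lagged human movement on dog
#'   onset (default 2.04).
#' @param dyad_sd SD of the per-dyad Gaussian effects on the onset logits
#'   (default 0.25, one effect per species per dyad).
#' @param night_sd SD of the per-night Gaussian effects on the onset
#'   logits (default 0.45, one effect per species per night), capturing
#'   night-to-night variation beyond chain sampling noise (late walks,
#'   outside noise). Together with `dyad_sd` this reproduces realistic
#'   cross-night spread in nightly moving fractions while leaving enough
#'   within-dyad variation to identify night-level regressions.
#' @param rating_intercept,rating_slope,rating_dyad_sd,rating_resid_sd
#'   Latent diary-rating model: `intercept + slope * dog_prop + dyad effect
#'   + noise`, rounded and clamped to 1..5 (defaults 3.8, -3.51, 0.45,
#'   0.55; the variance components are solved so the *observed* discrete
#'   ratings split as roughly 7.1% fixed / 31.8% between-dyad / 61.1%
#'   residual, counting the rounding noise of about 1/12 toward the
#'   residual).
#' @param disturbance_prob Per-night probability that the diary flags a
#'   dog-caused awakening (default 22/124).
#' @param emission State-conditional lognormal emission parameters per
#'   species, `list(human = list(still = c(meanlog, sdlog), moving = ...),
#'   dog = ...)`. Defaults sit ~3 SD from the 91 SVM_gs / 400 cpm
#'   thresholds so binarization recovers the true states with > 99.5%
#'   fidelity.
#' @return An object of class `"sim_params"`.
#' @export
sim_params <- function(n_dyads = 12L, nights_per_dyad = 10L,
                       epochs_per_night = 440L,
                       human_duty = 0.045, dog_duty = 0.124,
                       p10_h = 0.60, p10_d = 0.40,
                       p01_h = NULL, p01_d = NULL,
                       or_dog_on_human = 2.98, or_settle = 0.64,
                       or_nightprop = 1.33, or_human_on_dog = 2.04,
                       dyad_sd = 0.25, night_sd = 0.45,
                       rating_intercept = 3.8, rating_slope = -3.51,
                       rating_dyad_sd = 0.45, rating_resid_sd = 0.55,
                       disturbance_prob = 22 / 124,
                       emission = default_emission()) {
  if (n_dyads < 1L || nights_per_dyad < 1L) {
    stop("n_dyads and nights_per_dyad must be >= 1", call. = FALSE)
  }
  if (epochs_per_night < 2L) {
    stop("epochs_per_night must be >= 2", call. = FALSE)
  }
  for (p in c(human_duty, dog_duty, p10_h, p10_d)) {
    if (!is.numeric(p) || p <= 0 || p >= 1) {
      stop("probabilities must lie in (0, 1)", call. = FALSE)
    }
  }
  for (m in c(or_dog_on_human, or_settle, or_nightprop, or_human_on_dog)) {
    if (!is.numeric(m) || m <= 0) {
      stop("odds multipliers must be > 0", call. = FALSE)
    }
  }
  p <- structure(
    list(
      n_dyads = as.integer(n_dyads),
      nights_per_dyad = as.integer(nights_per_dyad),
      epochs_per_night = as.integer(epochs_per_night),
      human_duty = human_duty, dog_duty = dog_duty,
      p10_h = p10_h, p10_d = p10_d,
      p01_h = p01_h, p01_d = p01_d,
      or_dog_on_human = or_dog_on_human, or_settle = or_settle,
      or_nightprop = or_nightprop, or_human_on_dog = or_human_on_dog,
      dyad_sd = dyad_sd, night_sd = night_sd,
      rating_intercept = rating_intercept, rating_slope = rating_slope,
      rating_dyad_sd = rating_dyad_sd, rating_resid_sd = rating_resid_sd,
      disturbance_prob = disturbance_prob,
      emission = emission
    ),
    class = "sim_params"
  )
  if (is.null(p$p01_h) || is.null(p$p01_d)) {
    base <- calibrate_coupled_baselines(p)
    p$p01_h <- p$p01_h %||% base[["p01_h"]]
    p$p01_d <- p$p01_d %||% base[["p01_d"]]
  }
  for (q in c(p$p01_h, p$p01_d)) {
    if (q <= 0 || q >= 1) stop("onset probabilities must lie in (0, 1)",
                               call. = FALSE)
  }
  p
}

default_emission <- function() {
  list(
    human = list(still = c(meanlog = log(8), sdlog = 0.8),
                 moving = c(meanlog = log(350), sdlog = 0.45)),
    dog = list(still = c(meanlog = log(40), sdlog = 0.75),
               moving = c(meanlog = log(1500), sdlog = 0.45))
  )
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_params> %d dyads x %d nights x %d epochs\n",
           "  duty targets: human %.3f dog %.3f ",
           "(baselines p01_h=%.4f p10_h=%.2f, p01_d=%.4f p10_d=%.2f)\n",
           "  couplings: dog->human %.2f, settle %.2f, night %.2f, ",
           "human->dog %.2f; onset-logit SD (dyad+night) %.2f\n"),
    x$n_dyads, x$nights_per_dyad, x$epochs_per_night,
    x$human_duty, x$dog_duty, x$p01_h, x$p10_h, x$p01_d, x$p10_d,
    x$or_dog_on_human, x$or_settle, x$or_nightprop, x$or_human_on_dog,
    sqrt(x$dyad_sd^2 + x$night_sd^2)
  ))
  invisible(x)
}

#' Two-state stationary duty-cycle calibration
#'
#' For an uncoupled two-state chain with onset probability `p01` and settle
#' probability `p10`, the long-run moving fraction is `p01 / (p01 + p10)`.
#' Inverting for the onset probability that achieves a target fraction:
#' `p01 = target * p10 / (1 - target)`.
#'
#' @param target_fraction Desired long-run moving fraction, in (0, 1).
#' @param p10 Per-minute settle probability, in (0, 1).
#' @return The onset probability `p01`.
#' @export
calibrate_duty_cycle <- function(target_fraction, p10) {
  stopifnot(target_fraction > 0, target_fraction < 1, p10 > 0, p10 < 1)
  p01 <- target_fraction * p10 / (1 - target_fraction)
  if (p01 >= 1) {
    stop("infeasible duty cycle: implied onset probability >= 1",
         call. = FALSE)
  }
  p01
}

# Transition-kernel probabilities for one step, given previous (h, d).
# Returns P(h_t = 1) and P(d_t = 1).
step_probs <- function(h, d, lo01h, lo10h, lo01d, lo10d,
                       l_dog, l_settle, l_np, l_hd, w) {
  ph1 <- if (h == 0) {
    stats::plogis(lo01h + l_dog * d + l_np * w)
  } else {
    1 - stats::plogis(lo10h + l_settle * d)
  }
  pd1 <- if (d == 0) {
    stats::plogis(lo01d + l_hd * h)
  } else {
    1 - stats::plogis(lo10d)
  }
  c(ph1, pd1)
}

# Stationary distribution of the joint 4-state chain at fixed dyad effects
# and night proportion. State order: (h,d) = (0,0),(0,1),(1,0),(1,1).
joint_stationary <- function(p, u_h, u_d, w) {
  lo01h <- stats::qlogis(p$p01_h) + u_h
  lo10h <- stats::qlogis(p$p10_h)
  lo01d <- stats::qlogis(p$p01_d) + u_d
  lo10d <- stats::qlogis(p$p10_d)
  l <- log(c(p$or_dog_on_human, p$or_settle, p$or_nightprop,
             p$or_human_on_dog))
  P <- matrix(0, 4L, 4L)
  states <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (s in 1:4) {
    pr <- step_probs(states[s, 1], states[s, 2], lo01h, lo10h, lo01d, lo10d,
                     l[1], l[2], l[3], l[4], w)
    ph1 <- pr[1]; pd1 <- pr[2]
    P[s, ] <- c((1 - ph1) * (1 - pd1), (1 - ph1) * pd1,
                ph1 * (1 - pd1), ph1 * pd1)
  }
  A <- rbind(t(diag(4) - P)[1:3, ], rep(1, 4))
  solve(A, c(0, 0, 0, 1))
}

# Marginal duty cycles of the coupled chain, averaged over the dyad-effect
# distribution and the night-proportion covariate.
coupled_duties <- function(p, n_u = 9L, n_w = 5L) {
  sigma <- sqrt(p$dyad_sd^2 + p$night_sd^2) # combined onset-logit spread
  if (sigma > 0) {
    u_nodes <- seq(-3, 3, length.out = n_u) * sigma
    u_wts <- stats::dnorm(u_nodes, sd = sigma)
    u_wts <- u_wts / sum(u_wts)
  } else {
    u_nodes <- 0
    u_wts <- 1
  }
  w_nodes <- seq(0, 1, length.out = n_w)
  duty_h <- 0; duty_d <- 0
  for (i in seq_along(u_nodes)) {
    for (j in seq_along(u_nodes)) {
      for (k in seq_along(w_nodes)) {
        pi4 <- joint_stationary(p, u_nodes[i], u_nodes[j], w_nodes[k])
        wgt <- u_wts[i] * u_wts[j] / length(w_nodes)
        duty_h <- duty_h + wgt * (pi4[3] + pi4[4])
        duty_d <- duty_d + wgt * (pi4[2] + pi4[4])
      }
    }
  }
  c(human = duty_h, dog = duty_d)
}

.calib_cache <- new.env(parent = emptyenv())

# Solve baseline onset probabilities so the coupled chain's average
# stationary duty cycles hit the targets. Deterministic; cached.
calibrate_coupled_baselines <- function(p, tol = 1e-6, maxit = 60L) {
  key <- paste(
    format(c(p$human_duty, p$dog_duty, p$p10_h, p$p10_d,
             p$or_dog_on_human, p$or_settle, p$or_nightprop,
             p$or_human_on_dog, p$dyad_sd, p$night_sd), digits = 15),
    collapse = "|"
  )
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  # closed-form uncoupled start
  q <- p
  q$p01_h <- calibrate_duty_cycle(p$human_duty, p$p10_h)
  q$p01_d <- calibrate_duty_cycle(p$dog_duty, p$p10_d)
  for (it in seq_len(maxit)) {
    duty <- coupled_duties(q)
    rel <- c(p$human_duty / duty[["human"]], p$dog_duty / duty[["dog"]])
    if (max(abs(rel - 1)) < tol) break
    # multiplicative update on the odds scale
    odds_h <- q$p01_h / (1 - q$p01_h) * rel[1]
    odds_d <- q$p01_d / (1 - q$p01_d) * rel[2]
    q$p01_h <- odds_h / (1 + odds_h)
    q$p01_d <- odds_d / (1 + odds_d)
  }
  out <- c(p01_h = q$p01_h, p01_d = q$p01_d)
  .calib_cache[[key]] <- out
  out
}

#' Simulate one night of coupled human-dog movement
#'
#' Runs the coupled transition kernels for one night, starting from the
#' joint stationary distribution at night proportion 0, and (optionally)
#' emits raw activity values from the state-conditional lognormals.
#'
#' @param params A [sim_params()] object.
#' @param dyad_effects Numeric `c(u_h, u_d)`: this dyad's effects on the
#'   onset logits (default both 0). An additional per-night effect with SD
#'   `params$night_sd` is drawn internally for each species.
#' @param n_epochs Night length in epochs; defaults to
#'   `params$epochs_per_night`.
#' @param dyad_id,night_id Identifiers stamped on the output.
#' @param seed Optional integer seed for this night's substream.
#' @param emit Emit raw activity values (default `TRUE`)?
#' @return A list of class `"sim_night"`: `human_states`, `dog_states`
#'   (integer 0/1), `human_values`, `dog_values` (or `NULL`), and the
#'   identifiers.
#' @export
simulate_dyad_night <- function(params, dyad_effects = c(0, 0),
                                n_epochs = params$epochs_per_night,
                                dyad_id = "dyad01", night_id = "night01",
                                seed = NULL, emit = TRUE) {
  stopifnot(inherits(params, "sim_params"), n_epochs >= 2L)
  if (!is.null(seed)) set.seed(seed)
  v <- if (params$night_sd > 0) stats::rnorm(2, 0, params$night_sd) else c(0, 0)
  u_h <- dyad_effects[1] + v[1]
  u_d <- dyad_effects[2] + v[2]
  T_ <- as.integer(n_epochs)
  w <- (seq_len(T_) - 1) / (T_ - 1)
  l_dog <- log(params$or_dog_on_human)
  l_settle <- log(params$or_settle)
  l_np <- log(params$or_nightprop)
  l_hd <- log(params$or_human_on_dog)
  lo01h <- stats::qlogis(params$p01_h) + u_h
  lo10h <- stats::qlogis(params$p10_h)
  lo01d <- stats::qlogis(params$p01_d) + u_d
  lo10d <- stats::qlogis(params$p10_d)
  # precompute onset probabilities: T x 2 (lagged dog still / moving)
  ph_onset <- cbind(stats::plogis(lo01h + l_np * w),
                    stats::plogis(lo01h + l_dog + l_np * w))
  ph_stay_moving <- 1 - c(stats::plogis(lo10h),
                          stats::plogis(lo10h + l_settle))
  pd_onset <- c(stats::plogis(lo01d), stats::plogis(lo01d + l_hd))
  pd_stay_moving <- 1 - stats::plogis(lo10d)
  # initial joint state from the stationary distribution at w = 0
  pi0 <- joint_stationary(params, u_h, u_d, 0)
  s0 <- findInterval(stats::runif(1), cumsum(pi0)) + 1L
  h <- integer(T_); d <- integer(T_)
  h[1L] <- c(0L, 0L, 1L, 1L)[s0]
  d[1L] <- c(0L, 1L, 0L, 1L)[s0]
  uh <- stats::runif(T_); ud <- stats::runif(T_)
  for (t in 2:T_) {
    hp <- h[t - 1L]; dp <- d[t - 1L]
    ph <- if (hp == 0L) ph_onset[t, dp + 1L] else ph_stay_moving[dp + 1L]
    pd <- if (dp == 0L) pd_onset[hp + 1L] else pd_stay_moving
    h[t] <- as.integer(uh[t] < ph)
    d[t] <- as.integer(ud[t] < pd)
  }
  hv <- dv <- NULL
  if (emit) {
    em <- params$emission
    zh <- stats::rnorm(T_); zd <- stats::rnorm(T_)
    pick <- function(states, e, z) {
      meanlog <- ifelse(states == 1L, e$moving[["meanlog"]],
                        e$still[["meanlog"]])
      sdlog <- ifelse(states == 1L, e$moving[["sdlog"]], e$still[["sdlog"]])
      exp(meanlog + sdlog * z)
    }
    hv <- pick(h, em$human, zh)
    dv <- pick(d, em$dog, zd)
  }
  structure(
    list(dyad_id = dyad_id, night_id = night_id,
         human_states = h, dog_states = d,
         human_values = hv, dog_values = dv),
    class = "sim_night"
  )
}

# Deterministic substream seeds below 2^31, fanned out from one study seed
# so that adding a dyad or night never perturbs earlier substreams.
substream_seed <- function(seed, dyad, night = 0L) {
  (as.numeric(seed) %% 97651 * 1000003 + dyad * 7919 + night * 104729) %%
    2147483629 + 1
}

#' Simulate a full dyadic co-sleeping study
#'
#' Generates `n_dyads x nights_per_dyad` nights of coupled movement chains
#' with raw activity emissions, plus a morning sleep diary whose ratings
#' follow the latent linear model in the dog's realized nightly moving
#' proportion. Every dyad and night runs in its own deterministic RNG
#' substream derived from `seed`.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer study seed (default 1).
#' @return An object of class `"synthetic_study"`: list with `epochs`
#'   (data frame in the epoch CSV schema, both species), `diary` (diary
#'   schema), `nights` (list of true-state [dyad_night()] objects) and
#'   `truth` (all generating parameter values, including the calibrated
#'   baselines and the seed).
#' @export
simulate_study <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  epochs <- vector("list", params$n_dyads * params$nights_per_dyad)
  diary <- vector("list", length(epochs))
  nights <- vector("list", length(epochs))
  k <- 0L
  for (i in seq_len(params$n_dyads)) {
    dyad_id <- sprintf("dyad%02d", i)
    set.seed(substream_seed(seed, i))
    u_h <- stats::rnorm(1, 0, params$dyad_sd)
    u_d <- stats::rnorm(1, 0, params$dyad_sd)
    b_rate <- stats::rnorm(1, 0, params$rating_dyad_sd)
    for (j in seq_len(params$nights_per_dyad)) {
      k <- k + 1L
      night_id <- sprintf("night%02d", j)
      sn <- simulate_dyad_night(
        params, dyad_effects = c(u_h, u_d),
        dyad_id = dyad_id, night_id = night_id,
        seed = substream_seed(seed, i, j)
      )
      T_ <- params$epochs_per_night
      epochs[[k]] <- data.frame(
        dyad_id = dyad_id, night_id = night_id,
        subject_id = rep(c(sprintf("H%02d", i), sprintf("D%02d", i)),
                         each = T_),
        species = rep(c("human", "dog"), each = T_),
        epoch_index = rep(seq_len(T_) - 1L, 2L),
        activity = c(sn$human_values, sn$dog_values),
        stringsAsFactors = FALSE
      )
      dog_prop <- mean(sn$dog_states)
      latent <- params$rating_intercept + params$rating_slope * dog_prop +
        b_rate + stats::rnorm(1, 0, params$rating_resid_sd)
      diary[[k]] <- data.frame(
        dyad_id = dyad_id, night_id = night_id,
        reported_sleep_min = T_,
        dog_in_bed_min = T_ + floor(stats::runif(1, 0, 31)),
        rating = min(5L, max(1L, as.integer(round(latent)))),
        n_awakenings = stats::rpois(1, 1),
        dog_disturbance = stats::runif(1) < params$disturbance_prob,
        human_disturbance = stats::runif(1) < 0.05,
        stringsAsFactors = FALSE
      )
      nights[[k]] <- dyad_night(sn$human_states, sn$dog_states,
                                dyad_id = dyad_id, night_id = night_id)
    }
  }
  truth <- unclass(params)
  truth$emission <- NULL
  truth$seed <- as.integer(seed)
  structure(
    list(
      epochs = do.call(rbind, epochs),
      diary = do.call(rbind, diary),
      nights = nights,
      truth = truth
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d nights, %d epoch rows (seed %d)\n",
    length(x$nights), nrow(x$epochs), x$truth$seed
  ))
  invisible(x)
}

#' Threshold a synthetic study's emitted activity back into dyad-nights
#'
#' Closed-loop bridge from the generator to the analysis: applies the
#' species thresholds to the *emitted* activity values (not the true
#' states), exactly as the pipeline would after reading the epoch CSV, and
#' returns aligned binary dyad-nights.
#'
#' @param study A [simulate_study()] result.
#' @param config A [threshold_config()].
#' @return A list of [dyad_night()] objects in the study's night order.
#' @export
binarize_study <- function(study, config = threshold_config()) {
  stopifnot(inherits(study, "synthetic_study"))
  key <- paste(study$epochs$dyad_id, study$epochs$night_id,
               study$epochs$species)
  values <- split(study$epochs$activity, key)
  lapply(study$nights, function(ng) {
    h <- values[[paste(ng$dyad_id, ng$night_id, "human")]]
    d <- values[[paste(ng$dyad_id, ng$night_id, "dog")]]
    dyad_night(as.integer(h >= config$human_svm),
               as.integer(d >= config$dog_cpm),
               dyad_id = ng$dyad_id, night_id = ng$night_id)
  })
}

#' Write a synthetic study to disk
#'
#' Writes `epochs.csv` (both species, epoch CSV schema), `diary.csv` and
#' `truth.json` (all generating parameters) into `dir`, enabling
#' closed-loop analysis of data with known truth.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Character vector of the three file paths, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("epochs.csv", "diary.csv", "truth.json"))
  write_epoch_csv(study$epochs, paths[1L])
  write_diary_csv(study$diary, paths[2L])
  jsonlite::write_json(study$truth, paths[3L], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
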
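# direct night-level simulator with known mixed-model structure
simulate_summaries <- function(n_dyads = 12, nights = 10, slope = 0.29,
                               dyad_int_sd = 0.02, dyad_slope_sd = 0,
                               resid_sd = 0.012, dog_mean = 0.124,
                               dog_sd = 0.06) {
  dyad <- rep(sprintf("dyad%02d", seq_len(n_dyads)), each = nights)
  u <- rnorm(n_dyads, 0, dyad_int_sd)[rep(seq_len(n_dyads), each = nights)]
  v <- rnorm(n_dyads, 0, dyad_slope_sd)[rep(seq_len(n_dyads), each = nights)]
  dog <- pmin(pmax(rnorm(n_dyads * nights, dog_mean, dog_sd), 0.001), 0.9)
  human <- pmin(pmax(0.01 + (slope + v) * dog + u +
                       rnorm(n_dyads * nights, 0, resid_sd), 0), 1)
  data.frame(
    dyad_id = dyad,
    night_id = rep(sprintf("night%02d", seq_len(nights)), n_dyads),
    human_moving_prop = human,
    dog_moving_prop = dog,
    rating = NA_integer_,
    dog_disturbance = NA
  )
}

test_that("night summaries compute proportions and join the diary once", {
  ng1 <- dyad_night(c(1, 0, 0, 0), c(1, 1, 0, 0), dyad_id = "d1",
                    night_id = "n1")
  ng2 <- dyad_night(c(0, 0), c(1, 1), dyad_id = "d1", night_id = "n2")
  diary <- data.frame(dyad_id = "d1", night_id = c("n1", "n2"),
                      rating = c(4L, 2L),
                      dog_disturbance = c(FALSE, TRUE))
  sm <- summarize_nights(list(ng1, ng2), diary)
  expect_equal(nrow(sm), 2L)
  expect_equal(sm$human_moving_prop, c(0.25, 0))
  expect_equal(sm$dog_moving_prop, c(0.5, 1))
  expect_equal(sm$rating, c(4L, 2L))

  # missing diary entry leaves NA with a warning, no row duplication
  expect_warning(sm2 <- summarize_nights(list(ng1, ng2), diary[1, ]),
                 "no diary entry")
  expect_equal(nrow(sm2), 2L)
  expect_true(is.na(sm2$rating[2]))
})

test_that("monitoring bookkeeping converts epochs to hours per night", {
  expect_equal(mean_monitoring_hours(120 * 440, 120), 440 / 60)
  expect_equal(round(mean_monitoring_hours(54533, 124), 1), 7.3)
})

test_that("Pearson correlation matches the closed form and brute force", {
  expect_equal(pearson_correlation(1:10, 1:10)$r, 1)
  res <- pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(res$r, 0.6)
  expect_equal(res$t, 0.6 * sqrt(2) / sqrt(1 - 0.36), tolerance = 1e-12)
  expect_equal(round(res$t, 4), 1.0607)
  expect_equal(res$df, 2)

  set.seed(79)
  for (i in 1:50) {
    x <- rnorm(sample(5:50, 1))
    y <- rnorm(length(x)) + 0.3 * x
    res <- pearson_correlation(x, y)
    expect_equal(res$r, brute_pearson(x, y), tolerance = 1e-12)
    expect_equal(res$t, res$r * sqrt(res$df) / sqrt(1 - res$r^2),
                 tolerance = 1e-12)
  }
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:2, 2:3), "at least 3")
})

test_that("movement mixed model recovers a known slope", {
  set.seed(83)
  sm <- simulate_summaries(slope = 0.29, dyad_slope_sd = 0.05)
  fit <- suppressWarnings(fit_lme_movement(sm))
  est <- fit$coefficients["dog_moving_prop", "Estimate"]
  expect_gt(est, 0.15)
  expect_lt(est, 0.43)

  # mean over repeated draws sits close to the generating slope
  est_many <- vapply(1:40, function(i) {
    suppressWarnings(
      fit_lme_movement(simulate_summaries(slope = 0.29))
    )$coefficients["dog_moving_prop", "Estimate"]
  }, 0)
  expect_equal(mean(est_many), 0.29, tolerance = 0.1 / 0.29)
})

test_that("movement mixed model covers zero under no coupling and is shift-equivariant", {
  set.seed(89)
  sm0 <- simulate_summaries(slope = 0)
  fit0 <- suppressWarnings(fit_lme_movement(sm0))
  est <- fit0$coefficients["dog_moving_prop", "Estimate"]
  se <- fit0$coefficients["dog_moving_prop", "Std. Error"]
  expect_lt(abs(est), 2.6 * se)

  sm <- simulate_summaries(slope = 0.29, dyad_slope_sd = 0.05)
  f1 <- suppressWarnings(fit_lme_movement(sm))
  sm_shift <- sm
  sm_shift$dog_moving_prop <- sm_shift$dog_moving_prop + 0.5
  f2 <- suppressWarnings(fit_lme_movement(sm_shift))
  expect_equal(f2$coefficients["dog_moving_prop", "Estimate"],
               f1$coefficients["dog_moving_prop", "Estimate"],
               tolerance = 1e-4)
})

test_that("subjective model recovers the rating slope and nulls out under shuffling", {
  set.seed(97)
  p <- sim_params()
  study <- simulate_study(p, seed = 7)
  sm <- summarize_nights(study$nights, study$diary)
  fit <- fit_lme_subjective(sm)
  est <- fit$coefficients["dog_moving_prop", "Estimate"]
  se <- fit$coefficients["dog_moving_prop", "Std. Error"]
  # single-study estimate within 3 SE of the generating slope
  expect_lt(abs(est - (-3.51)), 3 * se)
  expect_match(fit$note, "ordinal")

  sm_shuf <- sm
  sm_shuf$dog_moving_prop <- sample(sm_shuf$dog_moving_prop)
  fit_shuf <- fit_lme_subjective(sm_shuf)
  est_s <- fit_shuf$coefficients["dog_moving_prop", "Estimate"]
  se_s <- fit_shuf$coefficients["dog_moving_prop", "Std. Error"]
  expect_lt(abs(est_s), 3 * se_s)

  sm_const <- sm
  sm_const$rating <- 3L
  expect_error(fit_lme_subjective(sm_const), "identical")
  sm_na <- sm
  sm_na$rating[1:60] <- NA
  expect_error(fit_lme_subjective(sm_na), "80%")
})

test_that("random-slope LRT finds no heterogeneity when there is none", {
  set.seed(101)
  stats <- vapply(1:8, function(i) {
    dyad <- rep(sprintf("d%02d", 1:12), each = 10)
    dog <- pmax(rnorm(120, 0.124, 0.06), 0.001)
    rating <- pmin(5, pmax(1, round(3.8 - 3.51 * dog +
                                      rnorm(12, 0, 0.5)[rep(1:12, each = 10)] +
                                      rnorm(120, 0, 0.7))))
    sm <- data.frame(dyad_id = dyad, night_id = as.character(1:120),
                     dog_moving_prop = dog, human_moving_prop = 0.05,
                     rating = rating, dog_disturbance = FALSE)
    random_slope_lrt(sm)$statistic
  }, 0)
  expect_lt(median(stats), 3)
  # nesting: the statistic is never negative
  expect_true(all(stats >= 0))
})

test_that("variance decomposition sums to 100 and responds to structure", {
  set.seed(103)
  dyad <- rep(sprintf("d%02d", 1:12), each = 10)
  dog <- pmax(rnorm(120, 0.124, 0.06), 0.001)
  u <- rnorm(12, 0, 0.5)[rep(1:12, each = 10)]
  rating_raw <- 3.8 - 3.51 * dog + u + rnorm(120, 0, 0.7)
  sm <- data.frame(dyad_id = dyad, night_id = as.character(1:120),
                   dog_moving_prop = dog, human_moving_prop = 0.05,
                   rating = pmin(5L, pmax(1L, as.integer(round(rating_raw)))),
                   dog_disturbance = FALSE)
  fit <- fit_lme_subjective(sm)
  vs <- variance_decomposition(fit)
  expect_equal(vs$fixed_pct + vs$between_dyad_pct + vs$residual_pct, 100,
               tolerance = 1e-9)
  expect_gt(vs$fixed_pct, 0)
  expect_gt(vs$between_dyad_pct, 5)

  # no fixed effect -> no fixed share
  sm0 <- sm
  sm0$rating <- pmin(5L, pmax(1L, as.integer(round(
    3.5 + u + rnorm(120, 0, 0.7)))))
  sm0$dog_moving_prop <- rnorm(120, 0.124, 0.06) # independent of rating
  vs0 <- variance_decomposition(fit_lme_subjective(sm0))
  expect_lt(vs0$fixed_pct, 2)

  # shares invariant to rescaling the response
  sm2 <- sm
  sm2$rating <- sm$rating * 10L
  m2 <- suppressMessages(suppressWarnings(
    lme4::lmer(rating ~ dog_moving_prop + (1 | dyad_id), data = sm2)
  ))
  fit2 <- fit
  fit2$model <- m2
  vs2 <- variance_decomposition(fit2)
  expect_equal(vs2$fixed_pct, vs$fixed_pct, tolerance = 1e-6)
  expect_equal(vs2$between_dyad_pct, vs$between_dyad_pct, tolerance = 1e-6)
})

test_that("disturbance counts aggregate per dyad and overall", {
  diary <- data.frame(
    dyad_id = rep(c("d1", "d2"), each = 3),
    night_id = rep(1:3, 2),
    dog_disturbance = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  )
  res <- count_reported_disturbances(diary)
  expect_equal(res$n_dog_disturbance, 3L)
  expect_equal(res$total_nights, 6L)
  expect_equal(sum(res$per_dyad$n_dog_disturbance), res$n_dog_disturbance)
  none <- diary
  none$dog_disturbance <- FALSE
  expect_equal(count_reported_disturbances(none)$n_dog_disturbance, 0L)
})
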
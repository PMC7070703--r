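test_that("duty-cycle calibration inverts the two-state stationary law", {
  expect_equal(calibrate_duty_cycle(0.5, 0.3), 0.3) # symmetric case
  expect_equal(calibrate_duty_cycle(0.124, 0.35), 0.124 * 0.35 / 0.876)
  expect_error(calibrate_duty_cycle(0.95, 0.9), "infeasible")
  # round trip: duty of (p01, p10) chain recovers the target
  p01 <- calibrate_duty_cycle(0.124, 0.35)
  expect_equal(p01 / (p01 + 0.35), 0.124, tolerance = 1e-12)
})

test_that("an uncoupled chain attains its calibrated stationary duty", {
  p10 <- 0.35
  target <- 0.124
  p <- sim_params(p01_d = calibrate_duty_cycle(target, p10), p10_d = p10,
                  or_dog_on_human = 1, or_human_on_dog = 1, or_settle = 1,
                  or_nightprop = 1, dyad_sd = 0, night_sd = 0)
  sn <- simulate_dyad_night(p, n_epochs = 500000, seed = 5, emit = FALSE)
  expect_equal(mean(sn$dog_states), target, tolerance = 0.005 / target)
})

test_that("study generation is deterministic and correctly sized", {
  p <- small_params()
  s1 <- simulate_study(p, seed = 9)
  s2 <- simulate_study(p, seed = 9)
  expect_identical(s1$epochs, s2$epochs)
  expect_identical(s1$diary, s2$diary)
  expect_equal(length(s1$nights), 2 * 3)
  expect_equal(nrow(s1$epochs), 2 * 3 * 120 * 2) # both species
  expect_equal(nrow(s1$diary), 6L)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(s1, d1)
  write_study(simulate_study(p, seed = 9), d2)
  for (f in c("epochs.csv", "diary.csv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  s3 <- simulate_study(p, seed = 10)
  expect_false(identical(s1$epochs$activity, s3$epochs$activity))
})

test_that("adding a dyad never perturbs existing dyads' substreams", {
  p2 <- small_params()
  p3 <- sim_params(n_dyads = 3L, nights_per_dyad = 3L,
                   epochs_per_night = 120L)
  s2 <- simulate_study(p2, seed = 4)
  s3 <- simulate_study(p3, seed = 4)
  first_two <- s3$epochs$dyad_id %in% c("dyad01", "dyad02")
  expect_identical(s3$epochs[first_two, ], s2$epochs)
  expect_identical(s3$diary[s3$diary$dyad_id %in% c("dyad01", "dyad02"), ],
                   s2$diary)
})

test_that("activity emissions recover the true states with high fidelity", {
  p <- sim_params()
  study <- simulate_study(p, seed = 23)
  cfg <- threshold_config()
  agree <- vapply(seq_along(study$nights), function(k) {
    ng <- study$nights[[k]]
    sub <- study$epochs[study$epochs$dyad_id == ng$dyad_id &
                          study$epochs$night_id == ng$night_id, ]
    h <- as.integer(sub$activity[sub$species == "human"] >= cfg$human_svm)
    d <- as.integer(sub$activity[sub$species == "dog"] >= cfg$dog_cpm)
    mean(c(h == ng$human_states, d == ng$dog_states))
  }, 0)
  expect_gt(mean(agree), 0.99)
})

test_that("default study reproduces the target duty cycles and dog skew", {
  p <- sim_params()
  hd <- dd <- sk <- numeric(0)
  for (s in 1:3) {
    study <- simulate_study(p, seed = 300 + s)
    hprop <- vapply(study$nights, function(n) mean(n$human_states), 0)
    dprop <- vapply(study$nights, function(n) mean(n$dog_states), 0)
    hd[s] <- mean(hprop)
    dd[s] <- mean(dprop)
    sk[s] <- mean((dprop - mean(dprop))^3) / sd(dprop)^3
  }
  expect_equal(mean(hd), 0.045, tolerance = 0.1)
  expect_equal(mean(dd), 0.124, tolerance = 0.1)
  expect_gt(mean(sk), 0) # dog nightly moving time mildly right-skewed
})

test_that("observed rating variance splits near the calibrated shares", {
  p <- sim_params()
  shares <- t(vapply(1:25, function(s) {
    study <- simulate_study(p, seed = 600 + s)
    sm <- summarize_nights(study$nights, study$diary)
    v <- variance_decomposition(fit_lme_subjective(sm))
    c(v$fixed_pct, v$between_dyad_pct, v$residual_pct)
  }, numeric(3)))
  m <- colMeans(shares)
  expect_lt(abs(m[1] - 7.1), 5)
  expect_lt(abs(m[2] - 31.8), 5)
  expect_lt(abs(m[3] - 61.1), 5)
})

test_that("ratings are negatively linked to nightly dog movement", {
  p <- sim_params()
  signs <- vapply(1:10, function(s) {
    study <- simulate_study(p, seed = 400 + s)
    sm <- summarize_nights(study$nights, study$diary)
    cor(sm$rating, sm$dog_moving_prop) < 0
  }, NA)
  expect_gte(sum(signs), 9)
})

test_that("cross-excitation defaults show up in the empirical raw odds", {
  p <- sim_params(dyad_sd = 0, night_sd = 0)
  sn <- simulate_dyad_night(p, n_epochs = 200000, seed = 19, emit = FALSE)
  tt <- transition_counts(dyadic_states(
    dyad_night(sn$human_states, sn$dog_states)))
  hp <- human_transition_prob_given_dog(tt)
  odds <- raw_transition_odds(hp[["p_dog_moving"]], hp[["p_dog_still"]])
  # raw (marginal) odds are attenuated relative to the kernel OR 2.98 but
  # clearly exceed the null
  expect_gt(odds, 1.8)
})

test_that("cross-dyad state sequences are uncorrelated", {
  p <- small_params()
  study <- simulate_study(p, seed = 31)
  a <- study$nights[[1]] # dyad01 night01
  b <- study$nights[[4]] # dyad02 night01
  expect_lt(abs(cor(a$human_states, b$human_states)), 0.12)
  expect_lt(abs(cor(a$dog_states, b$dog_states)), 0.12)
})

test_that("simulation parameters are validated", {
  expect_error(sim_params(nights_per_dyad = 0), ">= 1")
  expect_error(sim_params(epochs_per_night = 1), ">= 2")
  expect_error(sim_params(p10_h = 1.5), "\\(0, 1\\)")
  expect_error(sim_params(or_dog_on_human = -2), "> 0")
})
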
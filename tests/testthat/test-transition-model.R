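# direct design simulator: logistic transitions with known odds ratios,
# bypassing the chain generator
simulate_design <- function(n_nights, T_, or_dog, or_settle, or_np,
                            p01 = 0.02, p10 = 0.6, p_dog = 0.124) {
  rows <- lapply(seq_len(n_nights), function(i) {
    t <- seq_len(T_ - 1L)
    w <- t / (T_ - 1L)
    dog <- rbinom(T_ - 1L, 1, p_dog)
    origin <- rbinom(T_ - 1L, 1, 0.045)
    p_on <- plogis(qlogis(p01) + log(or_dog) * dog + log(or_np) * w)
    p_off <- plogis(qlogis(p10) + log(or_settle) * dog)
    outcome <- ifelse(origin == 0L, rbinom(T_ - 1L, 1, p_on),
                      1L - rbinom(T_ - 1L, 1, p_off))
    data.frame(dyad_id = "d", night_id = as.character(i), t = t,
               origin = origin, outcome = outcome, dog_prev = dog,
               night_prop = w)
  })
  do.call(rbind, rows)
}

test_that("design construction excludes first epochs and scales night_prop", {
  ng <- dyad_night(c(0, 1, 0), c(1, 0, 0))
  d <- build_design(ng)
  expect_equal(nrow(d), 2L)
  expect_equal(d$origin, c(0L, 1L))
  expect_equal(d$outcome, c(1L, 0L))
  expect_equal(d$dog_prev, c(1L, 0L))
  expect_equal(d$night_prop, c(0.5, 1))

  long <- dyad_night(rbinom(441, 1, 0.1), rbinom(441, 1, 0.1))
  dl <- build_design(long)
  expect_equal(dl$night_prop[1L], 1 / 440)
  expect_equal(max(dl$night_prop), 1)

  nights <- replicate(10, random_night(44), simplify = FALSE)
  expect_equal(nrow(build_design(nights)), 10 * 43)
})

test_that("IRLS coefficients agree with glm to near machine precision", {
  set.seed(31)
  for (i in 1:5) {
    d <- simulate_design(4, 300, or_dog = 2, or_settle = 0.7, or_np = 1.3)
    fit <- fit_transition_model(d)
    for (part in c("onset", "settle")) {
      dd <- d[d$origin == (part == "settle"), ]
      y <- if (part == "onset") dd$outcome else 1L - dd$outcome
      ref <- glm(y ~ dog_prev + night_prop, data = dd, family = binomial())
      expect_equal(unname(fit[[part]]$coef), unname(coef(ref)),
                   tolerance = 1e-6)
      expect_equal(unname(fit[[part]]$se),
                   unname(summary(ref)$coefficients[, 2]),
                   tolerance = 1e-4)
      expect_equal(fit[[part]]$loglik, as.numeric(logLik(ref)),
                   tolerance = 1e-8)
    }
  }
})

test_that("the fitted coefficients maximize the likelihood on a brute grid", {
  set.seed(37)
  d <- simulate_design(2, 251, or_dog = 3, or_settle = 0.6, or_np = 1.3)
  fit <- fit_transition_model(d)
  dd <- d[d$origin == 0L, ]
  X <- cbind(1, dd$dog_prev, dd$night_prop)
  y <- dd$outcome
  ll <- function(b) {
    p <- plogis(drop(X %*% b))
    sum(y * log(p) + (1 - y) * log(1 - p))
  }
  b_hat <- unname(fit$onset$coef)
  ll_hat <- ll(b_hat)
  offsets <- expand.grid(d1 = c(-0.1, -0.01, -0.001, 0, 0.001, 0.01, 0.1),
                         d2 = c(-0.1, -0.001, 0, 0.001, 0.1),
                         d3 = c(-0.1, -0.001, 0, 0.001, 0.1))
  lls <- apply(offsets, 1L, function(o) ll(b_hat + as.numeric(o)))
  expect_true(all(lls <= ll_hat + 1e-10))
})

test_that("generating odds ratios are recovered from a large design", {
  set.seed(41)
  d <- simulate_design(500, 401, or_dog = 2.98, or_settle = 0.64,
                       or_np = 1.33)
  fit <- fit_transition_model(d)
  expect_gt(exp(fit$onset$coef[["dog_prev"]]), 2.7)
  expect_lt(exp(fit$onset$coef[["dog_prev"]]), 3.3)
  expect_equal(exp(fit$settle$coef[["dog_prev"]]), 0.64, tolerance = 0.15)
  expect_equal(exp(fit$onset$coef[["night_prop"]]), 1.33, tolerance = 0.15)
})

test_that("a permuted dog covariate yields an odds ratio near 1", {
  set.seed(43)
  d <- simulate_design(50, 401, or_dog = 2.98, or_settle = 0.64,
                       or_np = 1.33)
  d$dog_prev <- sample(d$dog_prev)
  fit <- fit_transition_model(d)
  haz <- hazard_table(fit)
  dog_rows <- haz[haz$covariate == "Dog Movement Present", ]
  expect_true(all(dog_rows$ci_lower < 1 & dog_rows$ci_upper > 1))
})

test_that("fitted probabilities are calibrated in the large", {
  set.seed(47)
  d <- simulate_design(20, 301, or_dog = 2.5, or_settle = 0.7, or_np = 1.2)
  fit <- fit_transition_model(d)
  for (part in c("onset", "settle")) {
    # MLE with an intercept: mean fitted prob == empirical outcome rate
    expect_equal(fit[[part]]$fitted_mean, fit[[part]]$outcome_mean,
                 tolerance = 1e-8)
  }
})

test_that("hazard table carries ORs, CIs and ordering", {
  set.seed(53)
  d <- simulate_design(20, 301, or_dog = 2.5, or_settle = 0.7, or_np = 1.2)
  fit <- fit_transition_model(d, ci_level = 0.99)
  haz <- hazard_table(fit)
  expect_equal(nrow(haz), 4L)
  expect_equal(haz$transition[1:2], c("No Move to Move", "Move to No Move"))
  expect_equal(haz$odds_ratio, exp(haz$coef))
  z <- qnorm(0.995)
  expect_equal(haz$ci_upper, exp(haz$coef + z * haz$se))
  expect_true(all(haz$ci_lower < haz$odds_ratio &
                    haz$odds_ratio < haz$ci_upper))
})

test_that("interaction LRT: zero on identical models, calibrated under the null, powerful under interaction", {
  set.seed(59)
  d <- simulate_design(20, 301, or_dog = 2.5, or_settle = 0.7, or_np = 1.2)
  base <- fit_transition_model(d)
  self <- interaction_lrt(base, base)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)

  with_int <- fit_transition_model(d, interaction = TRUE)
  lrt <- interaction_lrt(with_int, base)
  expect_equal(lrt$df, 2L)
  expect_gte(lrt$statistic, 0)

  # type-I error near nominal under the null
  rej <- vapply(1:120, function(i) {
    dn <- simulate_design(12, 301, or_dog = 2.5, or_settle = 0.7,
                          or_np = 1.2)
    f1 <- fit_transition_model(dn, interaction = TRUE)
    f0 <- fit_transition_model(dn)
    interaction_lrt(f1, f0)$p_value < 0.05
  }, NA)
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.13)

  # strong interaction on the onset kernel is detected
  rej_alt <- vapply(1:10, function(i) {
    dn <- simulate_design(125, 401, or_dog = 2.5, or_settle = 0.7,
                          or_np = 1.2)
    on0 <- dn$origin == 0L
    p_on <- plogis(qlogis(0.02) + log(2.5) * dn$dog_prev[on0] +
                     log(1.2) * dn$night_prop[on0] +
                     1.0 * dn$dog_prev[on0] * dn$night_prop[on0])
    dn$outcome[on0] <- rbinom(sum(on0), 1, p_on)
    f1 <- fit_transition_model(dn, interaction = TRUE)
    f0 <- fit_transition_model(dn)
    interaction_lrt(f1, f0)$p_value < 0.05
  }, NA)
  expect_gte(mean(rej_alt), 0.9)

  small <- fit_transition_model(d[seq_len(2000), ])
  expect_error(interaction_lrt(with_int, small), "different rows")
})
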
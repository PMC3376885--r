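test_that("learning model recovers an exact linear structure", {
  # noiseless construction: rt = 1000 - 250 g - 2 trial (no interaction)
  grid <- expand.grid(participant_id = sprintf("p%02d", 1:10),
                      trial = 1:20)
  grid$g <- seq(0.25, 1, length.out = 10)[as.integer(factor(
    grid$participant_id))]
  grid$rt <- 1000 - 250 * grid$g - 2 * grid$trial
  fit <- fit_learning_model(grid, "rt")
  expect_equal(unname(fit$coefficients["(Intercept)"]), 1000,
               tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["g"]), -250, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["trial"]), -2, tolerance = 1e-6)
  expect_equal(unname(fit$coefficients["g:trial"]), 0, tolerance = 1e-6)

  # zero true subject variance with residual noise: the singular fit falls
  # back to subject-clustered OLS and matches the normal equations
  set.seed(55)
  grid$rt2 <- 1000 - 250 * grid$g - 2 * grid$trial + rnorm(nrow(grid), 0, 1)
  fit2 <- fit_learning_model(grid, "rt2")
  if (fit2$backend == "ols_clustered") {
    X <- cbind(1, grid$g, grid$trial, grid$g * grid$trial)
    expect_equal(unname(fit2$coefficients), unname(oracle_ols(X, grid$rt2)),
                 tolerance = 1e-8)
    expect_true(all(fit2$anova$df1 == 1))
  }

  expect_error(fit_learning_model(grid[grid$participant_id == "p01", ],
                                  "rt"), "invalid-input")
})

test_that("learning-model fixed effects agree with an OLS oracle", {
  # with a diffuse random intercept the lmer fixed effects approach OLS;
  # check the clustered-OLS fallback against normal equations exactly
  set.seed(71)
  for (i in 1:5) {
    n <- 200
    d <- data.frame(participant_id = sample(sprintf("s%d", 1:10), n, TRUE),
                    g = runif(n), trial = sample(1:48, n, TRUE))
    d$rt <- 500 - 100 * d$g - d$trial + rnorm(n, 0, 5)
    X <- cbind(1, d$g, d$trial, d$g * d$trial)
    beta <- oracle_ols(X, d$rt)
    ols <- lm(rt ~ g * trial, data = d)
    expect_equal(unname(coef(ols)), unname(beta), tolerance = 1e-8)
  }
})

test_that("uniformity chi-square matches the closed form", {
  expect_equal(uniformity_chisq(rep(21, 7))$statistic, 0)
  r <- uniformity_chisq(c(143, 0, 0, 0, 0, 0, 0))
  expect_equal(r$statistic, 858, tolerance = 1e-12)
  expect_equal(r$df, 6)
  set.seed(81)
  for (i in 1:1000) {
    counts <- rmultinom(1, sample(20:200, 1), prob = runif(7, 0.1, 1))[, 1]
    expect_equal(uniformity_chisq(counts)$statistic, oracle_chisq(counts),
                 tolerance = 1e-9)
  }
  expect_error(uniformity_chisq(rep(0, 7)), "zero total")
  expect_error(uniformity_chisq(1:5), "invalid-input")
})

test_that("proportion histogram bins onto the 7-point lattice", {
  h <- proportion_histogram(c(0, 0, 1 / 6, 1, 1, 1))
  expect_equal(h, c(2L, 1L, 0L, 0L, 0L, 0L, 3L))
  expect_error(proportion_histogram(0.3), "lattice")
})

test_that("excess-score t-test matches the textbook formula", {
  z <- excess_score_test(rep(0, 40))
  expect_equal(z$t, 0)
  expect_equal(z$flag, "zero variance, zero mean")
  z <- excess_score_test(rep(1, 40))
  expect_true(is.infinite(z$t) && z$t > 0)
  expect_match(z$flag, "nonzero mean")
  set.seed(91)
  for (i in 1:1000) {
    x <- rbinom(sample(5:40, 1), 6, runif(1, 0.1, 0.9)) - 2
    if (sd(x) == 0) next
    r <- excess_score_test(x)
    expect_equal(r$t, oracle_t(x), tolerance = 1e-9)
    expect_equal(r$df, length(x) - 1)
  }
  expect_error(excess_score_test(1), "invalid-input")
})

test_that("mediation residuals behave analytically", {
  # y identical to x: both residual correlations collapse to zero
  x <- seq(0, 1, length.out = 50)
  m <- runif(50)
  r <- mediation_residuals(x, m, x)
  expect_equal(r$r_m_given_x$r, 0)
  expect_equal(r$r_m_given_x$flag, "degenerate")
  # the reverse direction is not degenerate: removing m from y = x leaves
  # residuals that still track x
  expect_gt(r$r_x_given_m$r, 0.9)

  # y = m + noise with m independent of x: partialling x leaves cor(y, m)
  set.seed(103)
  n <- 2000
  x <- runif(n)
  m <- runif(n)
  y <- m + rnorm(n, 0, 0.3)
  r <- mediation_residuals(x, m, y)
  expect_equal(r$r_m_given_x$r, cor(y, m), tolerance = 0.02)
  expect_lt(abs(r$r_x_given_m$r), 0.06)
  expect_error(mediation_residuals(1:2, 1:2, 1:2), "invalid-input")
})

test_that("recall regressions flag degenerate inputs", {
  sc <- data.frame(participant_id = sprintf("p%d", 1:20),
                   train_g = runif(20), recall_g = runif(20),
                   match_percent = 100, pred_prop = runif(20),
                   awareness = runif(20, 100, 400), flagged = FALSE)
  rr <- recall_regressions(sc)
  expect_equal(rr$correlations$flag[2], "constant column")
  expect_equal(rr$models$match_percent, "constant response")
  expect_s3_class(rr$models$recall_g, "summary.lm")
})

test_that("low-awareness subsetting filters and refits", {
  td <- default_trial_data()
  pa <- default_participants()
  expect_error(low_awareness_subset(td, pa, cutoff = 100),
               "empty-selection")
  expect_error(low_awareness_subset(td, pa, cutoff = 50), "invalid-input")
  # ratings clip at 400, so the widest admissible cutoff keeps everyone
  # strictly below it
  full <- low_awareness_subset(td, pa, cutoff = 400)
  keep <- pa$participant_id[pa$awareness < 400]
  ref <- fit_learning_model(td[td$participant_id %in% keep, ], "rt")
  expect_equal(full$coefficients, ref$coefficients, tolerance = 1e-8)
  # implicit learning: RT still improves with G over trials in the
  # low-awareness subset
  lo <- low_awareness_subset(td, pa, cutoff = 250)
  expect_gt(lo$n_selected, 5)
  expect_lt(unname(lo$coefficients["g:trial"]), 0)
})
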
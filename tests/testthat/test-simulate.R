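one_g1_seq <- function() symbol_sequence(rep(c(2, 1, 3, 4), 12), "training")

test_that("cohort assembly, sizing and determinism", {
  co <- default_cohort()
  expect_s3_class(co, "swg_cohort")
  expect_length(co, 143)  # 11 sequences x 13 agents

  expect_length(simulate_cohort(list(one_g1_seq()), n_per_sequence = 0),
                0)

  seqs <- list(a = one_g1_seq(),
               b = symbol_sequence(rep(c(1, 2, 4, 3), 12), "training"))
  c1 <- simulate_cohort(seqs, n_per_sequence = 2, seed = 9L)
  c2 <- simulate_cohort(seqs, n_per_sequence = 2, seed = 9L)
  expect_identical(cohort_events(c1), cohort_events(c2))
  expect_identical(cohort_samples(c1), cohort_samples(c2))
  expect_identical(cohort_participants(c1), cohort_participants(c2))
})

test_that("trial timing honors the 750-ms inter-stimulus contract", {
  p <- simulate_participant(one_g1_seq(), seed = 3L)
  tr <- p$trials
  expect_equal(nrow(tr), 48)
  expect_true(all(tr$click_ms >= tr$onset_ms))
  expect_equal(tr$onset_ms[-1], tr$click_ms[-48] + 750)
  expect_true(p$awareness >= 100 && p$awareness <= 400)
  # ISI samples precede each onset and lie within its 750-ms window
  for (i in c(1, 10, 48)) {
    s <- p$samples[p$samples$trial == i, ]
    expect_true(all(s$t_ms <= tr$onset_ms[i]))
    expect_true(all(s$t_ms >= tr$onset_ms[i] - 750))
  }
})

test_that("cursor stream has ~40 Hz cadence with bounded jitter", {
  p <- simulate_participant(one_g1_seq(), seed = 5L)
  gaps <- unlist(lapply(split(p$samples, p$samples$trial),
                        function(s) diff(s$t_ms)))
  expect_true(all(gaps > 0))
  expect_gte(median(gaps), 20)
  expect_lte(median(gaps), 30)
})

test_that("disabling wagers yields purely reactive streams", {
  prm <- agent_params(wager_threshold = 1.01)
  co <- simulate_cohort(list(one_g1_seq()), n_per_sequence = 4,
                        params = prm, seed = 21L)
  expect_true(!any(unlist(lapply(co, function(p) p$internal$wager))))
  ft <- trial_features(co)
  dfp <- ft$dist_from_prev[!is.na(ft$dist_from_prev)]
  expect_gte(mean(dfp < 275), 0.99)
})

test_that("a learnable sequence drives late-block wagering", {
  prm <- agent_params(wager_threshold = 0.8, smoothing_pseudocount = 0.1)
  p <- simulate_participant(one_g1_seq(), params = prm, seed = 11L)
  expect_gte(mean(p$internal$wager[43:48]), 0.8)
})

test_that("noiseless wagers with a correct model land on the target", {
  prm <- agent_params(motor_noise_sd = 0, encoding_noise = 0,
                      wager_threshold = 0.5, latency_noise_sd_ms = 0)
  p <- simulate_participant(one_g1_seq(), params = prm, seed = 2L)
  ft <- trial_features(cohort_events(list(p)), cohort_samples(list(p)))
  late <- ft[ft$trial > 40, ]
  expect_true(all(late$label == "predictive"))
  expect_true(all(late$dist_to_next < 1e-6))
})

test_that("RT regression on onset distance recovers the motor speed", {
  prm <- agent_params(implicit_gain = 0, latency_noise_sd_ms = 1,
                      motor_noise_sd = 0)
  seqs <- list(generate_sequence(0.55, seed = 7),
               one_g1_seq())
  co <- simulate_cohort(seqs, n_per_sequence = 5, params = prm, seed = 13L)
  ft <- trial_features(co)
  ev <- cohort_events(co)
  d <- merge(ev, ft[, c("participant_id", "trial", "dist_to_next")],
             by = c("participant_id", "trial"))
  d$rt <- d$click_ms - d$onset_ms
  slope <- coef(lm(rt ~ dist_to_next, data = d))["dist_to_next"]
  expect_lt(abs(slope - 1000 / prm$motor_speed) / (1000 / prm$motor_speed),
            0.1)
})

test_that("predictiveness and RT facilitation scale with regularity", {
  tab <- bundled_sequences(warn = FALSE)
  pick <- tab[tab$id %in% c("s025", "s055", "s100a"), ]
  fb_prop <- matrix(NA_real_, 20, 3)
  late_rt <- matrix(NA_real_, 20, 3)
  for (k in 1:20) {
    co <- simulate_cohort(pick, n_per_sequence = 5, seed = 1000L + k)
    ft <- trial_features(co)
    pa <- cohort_participants(co)
    ev <- cohort_events(co)
    ev$rt <- ev$click_ms - ev$onset_ms
    fb <- ft[ft$trial > 42, ]
    for (j in 1:3) {
      ids <- pa$participant_id[pa$sequence_id == pick$id[j]]
      fb_prop[k, j] <- mean(fb$label[fb$participant_id %in% ids] ==
                              "predictive")
      late_rt[k, j] <- mean(ev$rt[ev$participant_id %in% ids &
                                    ev$trial > 24])
    }
  }
  mp <- colMeans(fb_prop)
  mr <- colMeans(late_rt)
  expect_true(mp[1] <= mp[2] && mp[2] <= mp[3])
  expect_true(mr[1] >= mr[2] && mr[2] >= mr[3])
})

test_that("invalid agent parameters are rejected", {
  expect_error(agent_params(wager_stickiness = 1.2), "config-error")
  expect_error(agent_params(motor_speed = -1), "config-error")
  expect_error(agent_params(smoothing_pseudocount = 0), "config-error")
  expect_error(task_layout(margin_px = 5), "config-error")
  expect_error(simulate_participant(one_g1_seq(), params = list()),
               "config-error")
  expect_error(simulate_participant(c(1, 1, 2, 3)), "invalid-input")
})

test_that("cohort CSV round-trips to equal flat tables", {
  co <- simulate_cohort(list(one_g1_seq()), n_per_sequence = 2, seed = 4L)
  dir <- tempfile("cohort")
  write_cohort(co, dir)
  back <- read_cohort(dir)
  expect_equal(back$events, cohort_events(co), tolerance = 1e-12)
  expect_equal(back$samples, cohort_samples(co), tolerance = 1e-12)
  expect_equal(back$participants, cohort_participants(co),
               tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
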
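#' Task layout: canvas and target geometry
#'
#' Four circular targets in a 2x2 grid inside a square canvas, labelled
#' 1-4 in reading order. Defaults: 500x500-px canvas, 35-px-diameter
#' targets centred 100 px from each edge, giving 300-px centre spacing.
#' That spacing places the classification thresholds where they belong:
#' a committed movement onto any other target covers 300 px on at least
#' one axis (above the 275-px predictive threshold), while waiting at the
#' canvas centre stays at 150 px on both axes (well below it).
#'
#' Coordinates are in pixels with the origin at the top-left and y
#' increasing downward.
#'
#' @param canvas_px canvas side length.
#' @param margin_px distance from canvas edge to the nearest target centres.
#' @param target_radius_px target circle radius.
#' @return A `swg_layout` list with `canvas_px`, `target_radius_px`, and
#'   `centers` (4x2 matrix, rows = labels 1-4, cols = x, y).
#' @export
task_layout <- function(canvas_px = 500, margin_px = 100,
                        target_radius_px = 17.5) {
  lo <- margin_px
  hi <- canvas_px - margin_px
  centers <- rbind(c(lo, lo), c(hi, lo), c(lo, hi), c(hi, hi))
  dimnames(centers) <- list(1:4, c("x", "y"))
  if (any(centers - target_radius_px < 0) ||
      any(centers + target_radius_px > canvas_px)) {
    stop("config-error: targets extend outside the canvas", call. = FALSE)
  }
  d <- stats::dist(centers)
  if (any(d <= 2 * target_radius_px)) {
    stop("config-error: target circles overlap", call. = FALSE)
  }
  structure(list(canvas_px = canvas_px, target_radius_px = target_radius_px,
                 centers = centers),
            class = "swg_layout")
}

#' Behavioral parameters of a synthetic participant
#'
#' The agent maintains additively smoothed first-order transition counts
#' over the four positions. During each 750-ms inter-stimulus interval it
#' either *wagers* — commits a movement toward the position its internal
#' model considers most likely next — or behaves reactively, waiting at
#' the previous target or repositioning to the canvas centre. A wager is
#' triggered when the maximum smoothed successor probability reaches
#' `wager_threshold`; once wagering, the mode persists from trial to trial
#' with probability `wager_stickiness`.
#'
#' Click latency combines a base reaction time, proportional facilitation
#' by the agent's internal probability of the stimulus that actually
#' appeared (`implicit_gain`, the expectation-priming component that
#' operates whether or not the agent overtly wagers), and the travel time
#' from the cursor position at stimulus onset to the target at
#' `motor_speed`.
#'
#' `encoding_noise` is the probability that an observed transition is
#' mis-stored as a random other successor; it makes early wagers, formed
#' from one or two (possibly corrupted) observations, error-prone, while
#' accumulated counts wash the errors out later in training.
#'
#' @param wager_threshold smoothed probability needed to trigger a wager.
#'   Values above 1 (e.g. `1.01`) disable wagering entirely.
#' @param wager_stickiness per-trial probability of remaining in wager mode.
#' @param centering_propensity probability a reactive trial repositions to
#'   the canvas centre rather than waiting at the previous target.
#' @param motor_speed cursor speed, px/s.
#' @param motor_noise_sd isotropic per-sample positional noise, px.
#' @param base_latency_ms baseline reaction time, ms.
#' @param latency_noise_sd_ms reaction-time noise SD, ms.
#' @param smoothing_pseudocount additive smoothing for the internal
#'   transition estimates.
#' @param encoding_noise probability an observed transition is mis-stored.
#' @param implicit_gain proportional cut of `base_latency_ms` at internal
#'   probability 1 of the appearing stimulus (0 disables priming).
#' @param awareness_slope,awareness_offset logistic link coefficients
#'   mapping final-two-block predictive proportion to the 100-400
#'   awareness scale.
#' @param awareness_noise_sd awareness rating noise SD (scale units).
#' @return A validated `swg_agent_params` list.
#' @export
agent_params <- function(wager_threshold = 0.75,
                         wager_stickiness = 0.95,
                         centering_propensity = 0.5,
                         motor_speed = 600,
                         motor_noise_sd = 3,
                         base_latency_ms = 400,
                         latency_noise_sd_ms = 50,
                         smoothing_pseudocount = 0.1,
                         encoding_noise = 0.15,
                         implicit_gain = 0.5,
                         awareness_slope = 6,
                         awareness_offset = -3,
                         awareness_noise_sd = 120) {
  p <- list(wager_threshold = wager_threshold,
            wager_stickiness = wager_stickiness,
            centering_propensity = centering_propensity,
            motor_speed = motor_speed,
            motor_noise_sd = motor_noise_sd,
            base_latency_ms = base_latency_ms,
            latency_noise_sd_ms = latency_noise_sd_ms,
            smoothing_pseudocount = smoothing_pseudocount,
            encoding_noise = encoding_noise,
            implicit_gain = implicit_gain,
            awareness_slope = awareness_slope,
            awareness_offset = awareness_offset,
            awareness_noise_sd = awareness_noise_sd)
  probs <- c("wager_stickiness", "centering_propensity", "encoding_noise",
             "implicit_gain")
  for (nm in probs) {
    if (!is.numeric(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1) {
      stop("config-error: ", nm, " must be a probability in [0,1]",
           call. = FALSE)
    }
  }
  if (!is.numeric(wager_threshold) || wager_threshold <= 0) {
    stop("config-error: wager_threshold must be positive", call. = FALSE)
  }
  if (motor_speed <= 0) {
    stop("config-error: motor_speed must be positive", call. = FALSE)
  }
  for (nm in c("motor_noise_sd", "latency_noise_sd_ms",
               "awareness_noise_sd")) {
    if (p[[nm]] < 0) stop("config-error: ", nm, " must be >= 0",
                          call. = FALSE)
  }
  if (smoothing_pseudocount <= 0) {
    stop("config-error: smoothing_pseudocount must be positive",
         call. = FALSE)
  }
  if (base_latency_ms < 0) {
    stop("config-error: base_latency_ms must be >= 0", call. = FALSE)
  }
  structure(p, class = "swg_agent_params")
}

# ISI cursor stream: nominal 40 Hz (25-ms step) with bounded jitter,
# straight-line travel toward `goal` capped at the goal, isotropic noise
# on the recorded coordinates only.
isi_stream <- function(t0, onset, start, goal, speed, noise_sd) {
  n_max <- ceiling((onset - t0) / 20) + 2
  gaps <- 25 + stats::runif(n_max, -3, 3)
  t <- t0 + cumsum(gaps)
  t <- t[t <= onset]
  d <- sqrt(sum((goal - start)^2))
  if (d < 1e-12) {
    frac <- rep(0, length(t))
  } else {
    frac <- pmin(1, speed * (t - t0) / 1000 / d)
  }
  x <- start[1] + frac * (goal[1] - start[1])
  y <- start[2] + frac * (goal[2] - start[2])
  if (noise_sd > 0) {
    x <- x + stats::rnorm(length(t), 0, noise_sd)
    y <- y + stats::rnorm(length(t), 0, noise_sd)
  }
  end_pos <- if (d < 1e-12) start else {
    f <- min(1, speed * (onset - t0) / 1000 / d)
    start + f * (goal - start)
  }
  list(t = t, x = x, y = y, end_pos = end_pos)
}

#' Simulate one participant on a training sequence
#'
#' Runs the wager/reactive agent through 48 trials with a 750-ms
#' inter-stimulus interval, then generates a 24-item free recall by
#' sampling walks from the agent's learned transition table (start symbol
#' uniform), and an awareness rating linked logistically to the
#' final-two-block predictive proportion.
#'
#' @param seq a valid training `symbol_sequence` (or 48-vector).
#' @param params an [agent_params()] list.
#' @param layout a [task_layout()].
#' @param seed integer seed; the record is deterministic given it.
#' @param id participant identifier stored in the record.
#' @param sequence_id optional label of the assigned sequence.
#' @return A `swg_participant` list: `id`, `sequence_id`, `sequence`,
#'   `g` (training-sequence regularity), `trials` (data.frame: trial,
#'   symbol, onset_ms, click_ms), `samples` (data.frame: trial, t_ms, x,
#'   y — the ISI cursor stream preceding each onset), `recall`
#'   (`symbol_sequence`), `awareness`, and `internal` (wager flags,
#'   wagered targets, learned counts).
#' @export
simulate_participant <- function(seq, params = agent_params(),
                                 layout = task_layout(), seed = 1L,
                                 id = "p1", sequence_id = NA_character_) {
  if (!inherits(params, "swg_agent_params")) {
    stop("config-error: params must come from agent_params()", call. = FALSE)
  }
  items <- as.integer(unclass(seq))
  v <- validate_sequence(items, role = "training")
  if (!v$pass) {
    stop("invalid-input: not a valid training sequence: ",
         paste(v$violations, collapse = "; "), call. = FALSE)
  }
  old_seed <- withr_seed(seed)
  on.exit(restore_seed(old_seed), add = TRUE)

  n_trials <- length(items)
  ctr <- layout$centers
  canvas_mid <- c(layout$canvas_px / 2, layout$canvas_px / 2)
  counts <- matrix(0, 4, 4)
  alpha <- params$smoothing_pseudocount
  in_mode <- FALSE
  pos <- canvas_mid
  onset <- numeric(n_trials)
  click <- numeric(n_trials)
  wager <- logical(n_trials)
  wager_target <- rep(NA_integer_, n_trials)
  sample_list <- vector("list", n_trials)
  t_click_prev <- 0

  for (i in seq_len(n_trials)) {
    onset[i] <- t_click_prev + 750
    t0 <- onset[i] - 750
    # choose this trial's ISI behavior
    if (i == 1) {
      predictive <- FALSE
      goal <- pos
    } else {
      row <- counts[items[i - 1], ] + alpha
      p <- row / sum(row)
      pmax_v <- max(p)
      if (in_mode && stats::runif(1) < params$wager_stickiness) {
        predictive <- TRUE
      } else {
        predictive <- pmax_v >= params$wager_threshold
      }
      in_mode <- predictive
      if (predictive) {
        best <- which(p >= pmax_v - 1e-12)
        pick <- if (length(best) == 1) best else
          best[sample.int(length(best), 1)]
        wager_target[i] <- pick
        goal <- ctr[pick, ]
      } else {
        goal <- if (stats::runif(1) < params$centering_propensity)
          canvas_mid else pos
      }
    }
    wager[i] <- predictive
    str <- isi_stream(t0, onset[i], pos, goal, params$motor_speed,
                      params$motor_noise_sd)
    sample_list[[i]] <- data.frame(trial = i, t_ms = str$t, x = str$x,
                                   y = str$y)
    pos <- str$end_pos
    # internal expectation of the appearing stimulus (priming term)
    p_hat <- if (i == 1) 0 else {
      row <- counts[items[i - 1], ] + alpha
      row[items[i]] / sum(row)
    }
    travel <- sqrt(sum((ctr[items[i], ] - pos)^2)) / params$motor_speed * 1000
    rt <- params$base_latency_ms * (1 - params$implicit_gain * p_hat) +
      travel + stats::rnorm(1, 0, params$latency_noise_sd_ms)
    rt <- max(rt, 0)
    click[i] <- onset[i] + rt
    pos <- ctr[items[i], ]  # cursor ends on the clicked target
    t_click_prev <- click[i]
    # learning update, possibly mis-stored
    if (i >= 2) {
      stored <- items[i]
      if (params$encoding_noise > 0 &&
          stats::runif(1) < params$encoding_noise) {
        others <- setdiff(1:4, items[i])
        stored <- others[sample.int(3, 1)]
      }
      counts[items[i - 1], stored] <- counts[items[i - 1], stored] + 1
    }
  }

  # free recall: walk the learned (smoothed) table
  rec <- integer(24)
  rec[1] <- sample.int(4, 1)
  for (j in 2:24) {
    w <- counts[rec[j - 1], ] + alpha
    rec[j] <- sample.int(4, 1, prob = w / sum(w))
  }

  final_idx <- (n_trials - 11):n_trials
  p_pred <- mean(wager[final_idx])
  aware <- 100 + 300 * stats::plogis(params$awareness_slope * p_pred +
                                       params$awareness_offset) +
    stats::rnorm(1, 0, params$awareness_noise_sd)
  aware <- min(max(aware, 100), 400)

  structure(list(
    id = id,
    sequence_id = sequence_id,
    sequence = symbol_sequence(items, role = "training"),
    g = redundancy_g(items),
    trials = data.frame(trial = seq_len(n_trials), symbol = items,
                        onset_ms = onset, click_ms = click),
    samples = do.call(rbind, sample_list),
    recall = symbol_sequence(rec, role = "recall"),
    awareness = aware,
    internal = list(wager = wager, wager_target = wager_target,
                    counts = counts, p_pred_final = p_pred)
  ), class = "swg_participant")
}

#' Simulate a cohort of synthetic participants
#'
#' Assigns `n_per_sequence` independent agents to each training sequence
#' (mirroring random between-subject assignment) and simulates each with
#' its own seed drawn from the master seed, so the whole cohort is
#' reproducible.
#'
#' @param sequences a list of training sequences, or a data.frame with
#'   columns `id` and `sequence` (dash-separated) such as
#'   [bundled_sequences()] returns.
#' @param n_per_sequence participants per sequence (11 sequences x 13 =
#'   the 143-participant design).
#' @param params an [agent_params()] list shared by all agents.
#' @param layout a [task_layout()].
#' @param seed master integer seed.
#' @return A `swg_cohort`: list of `swg_participant` records with
#'   attributes `seed` and `params`.
#' @export
simulate_cohort <- function(sequences, n_per_sequence = 13,
                            params = agent_params(),
                            layout = task_layout(), seed = 42L) {
  if (is.data.frame(sequences)) {
    ids <- sequences$id
    seqs <- lapply(sequences$sequence, parse_sequence)
  } else {
    seqs <- sequences
    ids <- if (!is.null(names(sequences))) names(sequences) else
      sprintf("seq%02d", seq_along(sequences))
  }
  if (n_per_sequence < 0) {
    stop("invalid-input: n_per_sequence must be >= 0", call. = FALSE)
  }
  n_total <- length(seqs) * n_per_sequence
  if (n_total == 0) {
    return(structure(list(), class = "swg_cohort", seed = seed,
                     params = params))
  }
  old_seed <- withr_seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  restore_seed(old_seed)
  out <- vector("list", n_total)
  k <- 0
  for (s in seq_along(seqs)) {
    for (r in seq_len(n_per_sequence)) {
      k <- k + 1
      out[[k]] <- simulate_participant(
        seqs[[s]], params = params, layout = layout, seed = sub_seeds[k],
        id = sprintf("p%03d", k), sequence_id = ids[s])
    }
  }
  structure(out, class = "swg_cohort", seed = seed, params = params)
}

#' @export
print.swg_cohort <- function(x, ...) {
  cat(sprintf("<swg_cohort: %d participants, %d sequences>\n", length(x),
              length(unique(vapply(x, `[[`, "", "sequence_id")))))
  invisible(x)
}

#' Flat event, sample and participant tables of a cohort
#'
#' @param cohort a `swg_cohort`.
#' @return `cohort_events()`: data.frame (participant_id, trial, symbol,
#'   onset_ms, click_ms). `cohort_samples()`: data.frame (participant_id,
#'   trial, t_ms, x, y). `cohort_participants()`: data.frame
#'   (participant_id, sequence_id, sequence, g, awareness, recall as a
#'   dash-separated string).
#' @export
cohort_events <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    cbind(participant_id = p$id, p$trials)
  }))
}

#' @rdname cohort_events
#' @export
cohort_samples <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    cbind(participant_id = p$id, p$samples)
  }))
}

#' @rdname cohort_events
#' @export
cohort_participants <- function(cohort) {
  do.call(rbind, lapply(cohort, function(p) {
    data.frame(participant_id = p$id, sequence_id = p$sequence_id,
               sequence = paste(unclass(p$sequence), collapse = "-"),
               g = p$g, awareness = p$awareness,
               recall = paste(unclass(p$recall), collapse = "-"))
  }))
}

#' Write / read a cohort as flat CSV files
#'
#' `write_cohort()` writes `events.csv`, `samples.csv` and
#' `participants.csv` (UTF-8, header row, period decimal separator) to a
#' directory; `read_cohort()` loads them back into the same flat-table
#' form used by the downstream stages.
#'
#' @param cohort a `swg_cohort`.
#' @param dir output directory (created if missing).
#' @return `write_cohort()` the directory, invisibly; `read_cohort()` a
#'   list with `events`, `samples`, `participants` data.frames.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort_events(cohort), file.path(dir, "events.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_samples(cohort), file.path(dir, "samples.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_participants(cohort),
                   file.path(dir, "participants.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(events = utils::read.csv(file.path(dir, "events.csv"),
                                stringsAsFactors = FALSE),
       samples = utils::read.csv(file.path(dir, "samples.csv"),
                                 stringsAsFactors = FALSE),
       participants = utils::read.csv(file.path(dir, "participants.csv"),
                                      stringsAsFactors = FALSE))
}
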
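#' Cursor position at the end of the inter-stimulus interval
#'
#' Returns the cursor coordinates "just before the stimulus appeared":
#' the recorded sample at the largest time not exceeding the onset. When
#' sampling jitter leaves the onset strictly between two samples, the
#' position is linearly interpolated between the straddling pair.
#'
#' @param t_ms sample times, strictly increasing.
#' @param x,y sample coordinates, px.
#' @param onset_ms stimulus onset time.
#' @return Named numeric `c(x=, y=)`.
#' @export
isi_end_position <- function(t_ms, x, y, onset_ms) {
  if (length(t_ms) == 0 || all(t_ms > onset_ms)) {
    stop("missing-data: no cursor sample at or before onset", call. = FALSE)
  }
  i <- max(which(t_ms <= onset_ms))
  if (t_ms[i] == onset_ms || i == length(t_ms)) {
    return(c(x = x[i], y = y[i]))
  }
  # onset falls between samples i and i+1: interpolate
  w <- (onset_ms - t_ms[i]) / (t_ms[i + 1] - t_ms[i])
  c(x = x[i] + w * (x[i + 1] - x[i]),
    y = y[i] + w * (y[i + 1] - y[i]))
}

#' Initial distance to the next target
#'
#' Euclidean distance from the ISI-end cursor position to the centre of
#' the upcoming target. Zero for a perfect predictive movement.
#'
#' @param pos numeric length-2 `(x, y)` cursor position.
#' @param center numeric length-2 target centre.
#' @return Distance in px.
#' @export
initial_distance_to_next <- function(pos, center) {
  sqrt(sum((as.numeric(pos) - as.numeric(center))^2))
}

#' Initial distance from the previous target
#'
#' The maximum of the horizontal and vertical displacement of the ISI-end
#' cursor position from the previous target's centre (Chebyshev metric by
#' default). A movement committed to any other target registers the full
#' grid spacing on at least one axis, whereas waiting or centering does
#' not; `metric = "euclidean"` is available as a sensitivity alternative.
#'
#' @inheritParams initial_distance_to_next
#' @param metric `"chebyshev"` (default) or `"euclidean"`.
#' @return Distance in px.
#' @export
initial_distance_from_previous <- function(pos, center,
                                           metric = c("chebyshev",
                                                      "euclidean")) {
  metric <- match.arg(metric)
  d <- abs(as.numeric(pos) - as.numeric(center))
  if (metric == "chebyshev") max(d) else sqrt(sum(d^2))
}

#' Classify a trial as predictive or reactive
#'
#' A trial is *predictive* when the initial distance from the previous
#' target is at least `predictive_px` (275 px by default — substantial
#' movement away, likely toward another target), and *correct* when it is
#' predictive and ends within `correct_px` (a conservative 100 px) of the
#' upcoming target's centre. Both thresholds are inclusive.
#'
#' @param dist_from_prev initial distance from previous, px.
#' @param dist_to_next initial distance to next, px.
#' @param predictive_px predictive threshold (default 275).
#' @param correct_px correct-prediction threshold (default 100).
#' @return List with `label` (`"predictive"`/`"reactive"`) and `correct`
#'   (logical).
#' @export
classify_trial <- function(dist_from_prev, dist_to_next,
                           predictive_px = 275, correct_px = 100) {
  predictive <- dist_from_prev >= predictive_px
  list(label = ifelse(predictive, "predictive", "reactive"),
       correct = predictive & dist_to_next <= correct_px)
}

#' Trial-level trajectory features for a cohort
#'
#' For every trial, finds the ISI-end cursor position and computes the
#' two distance measures, then applies the threshold classification.
#' Trial 1 has no previous target: its distance-from-previous, label and
#' correct flag are `NA` and it is excluded from classification-based
#' analyses downstream. Trials whose ISI window contains no usable sample
#' are dropped with a message.
#'
#' @param events data.frame with columns `participant_id`, `trial`,
#'   `symbol`, `onset_ms` (and `click_ms`), as written by the simulator.
#' @param samples data.frame with columns `participant_id`, `trial`,
#'   `t_ms`, `x`, `y`.
#' @param layout a [task_layout()] giving the target centres.
#' @param predictive_px,correct_px classification thresholds, px.
#' @param metric distance-from-previous metric, see
#'   [initial_distance_from_previous()].
#' @return data.frame: `participant_id`, `trial`, `symbol`,
#'   `dist_to_next`, `dist_from_prev`, `label`, `correct`.
#' @export
trial_features <- function(events, samples, layout = task_layout(),
                           predictive_px = 275, correct_px = 100,
                           metric = "chebyshev") {
  if (inherits(events, "swg_cohort")) {
    cohort <- events
    samples <- cohort_samples(cohort)
    events <- cohort_events(cohort)
  }
  ctr <- layout$centers
  samp_split <- split(samples, samples$participant_id)
  out <- lapply(split(events, events$participant_id), function(ev) {
    ev <- ev[order(ev$trial), ]
    sm <- samp_split[[ev$participant_id[1]]]
    sm_by_trial <- split(sm, sm$trial)
    n <- nrow(ev)
    dtn <- rep(NA_real_, n)
    dfp <- rep(NA_real_, n)
    keep <- rep(TRUE, n)
    for (k in seq_len(n)) {
      tr <- ev$trial[k]
      s <- sm_by_trial[[as.character(tr)]]
      pos <- tryCatch(
        isi_end_position(s$t_ms, s$x, s$y, ev$onset_ms[k]),
        error = function(e) NULL)
      if (is.null(pos)) {
        keep[k] <- FALSE
        message("dropping participant ", ev$participant_id[1], " trial ",
                tr, ": no ISI sample")
        next
      }
      dtn[k] <- initial_distance_to_next(pos, ctr[ev$symbol[k], ])
      if (k > 1) {
        dfp[k] <- initial_distance_from_previous(pos,
                                                 ctr[ev$symbol[k - 1], ],
                                                 metric = metric)
      }
    }
    cls <- classify_trial(dfp, dtn, predictive_px, correct_px)
    cls$label[is.na(dfp)] <- NA_character_
    cls$correct[is.na(dfp)] <- NA
    data.frame(participant_id = ev$participant_id,
               trial = ev$trial, symbol = ev$symbol,
               dist_to_next = dtn, dist_from_prev = dfp,
               label = cls$label, correct = cls$correct)[keep, ]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Block summaries of predictive behavior
#'
#' Splits each participant's 48 trials into eight consecutive six-trial
#' blocks and reports, per block, the proportion of predictive trials
#' (denominator 6; trial 1, which has no previous-target measure, counts
#' toward the denominator but is never predictive) and the *excess score*
#' — the number of predictive trials minus the number of correct
#' predictive trials, an integer in 0..6 quantifying prediction ahead of
#' accurate knowledge.
#'
#' @param features output of [trial_features()].
#' @param block_size trials per block (default 6).
#' @param n_trials expected trials per participant (default 48).
#' @return data.frame: `participant_id`, `block`, `n_predictive`,
#'   `n_correct`, `prop_predictive`, `excess_score`.
#' @export
block_summaries <- function(features, block_size = 6, n_trials = 48) {
  out <- lapply(split(features, features$participant_id), function(ft) {
    ft <- ft[order(ft$trial), ]
    if (max(ft$trial) != n_trials || n_trials %% block_size != 0) {
      stop("shape-error: expected trials 1..", n_trials, " in blocks of ",
           block_size, call. = FALSE)
    }
    blk <- ceiling(ft$trial / block_size)
    agg <- lapply(split(ft, blk), function(b) {
      npred <- sum(b$label == "predictive", na.rm = TRUE)
      ncorr <- sum(b$correct, na.rm = TRUE)
      data.frame(participant_id = b$participant_id[1],
                 block = ceiling(b$trial[1] / block_size),
                 n_predictive = npred, n_correct = ncorr,
                 prop_predictive = npred / block_size,
                 excess_score = npred - ncorr)
    })
    do.call(rbind, agg)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Predictive proportion over the final trials
#'
#' Proportion of predictive trials among the last `n_last` trials (the
#' final two blocks, 12 trials, by default) for each participant — the
#' per-subject predictiveness covariate used in the recall and awareness
#' analyses.
#'
#' @param features output of [trial_features()].
#' @param n_last number of final trials (default 12).
#' @param n_trials trials per participant (default 48).
#' @return data.frame: `participant_id`, `pred_prop`.
#' @export
final_predictive_proportion <- function(features, n_last = 12,
                                        n_trials = 48) {
  sub <- features[features$trial > n_trials - n_last, ]
  agg <- vapply(split(sub, sub$participant_id), function(ft) {
    mean(ft$label == "predictive", na.rm = TRUE)
  }, numeric(1))
  data.frame(participant_id = names(agg), pred_prop = unname(agg))
}
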
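#' Regularity of a recall sequence
#'
#' Applies the same first-order transition-entropy statistic
#' ([redundancy_g()]) to a participant's 24-click free-recall output.
#' Recall sequences need not be balanced or repeat-free; symbols with no
#' observed successor contribute zero entropy.
#'
#' @param recall a recall `symbol_sequence` or integer vector of 24 labels.
#' @return G in `[0, 1]`.
#' @export
recall_regularity <- function(recall) {
  items <- as.integer(unclass(recall))
  if (length(items) != 24) {
    stop("invalid-input: recall must have 24 items", call. = FALSE)
  }
  redundancy_g(items)
}

#' Cross-recurrence match between training and recall sequences
#'
#' Builds the cross-recurrence matrix (cell `(i, j)` is 1 when training
#' item `i` equals recall item `j`) and scores the best diagonal
#' alignment: the maximum over lags of the number of matching positions,
#' as a percentage of the 24 recall items. With the default non-negative
#' lags, lag `d` aligns recall item `j` with training item `j + d`,
#' `d` in `0..(n_train - n_recall)`. A normalized longest-common-
#' subsequence variant (`variant = "lcs"`) is provided for sensitivity
#' analysis.
#'
#' @param training training sequence (48 items).
#' @param recall recall sequence (24 items).
#' @param variant `"diagonal"` (default) or `"lcs"`.
#' @param include_negative_lags also search lags aligning recall ahead of
#'   the training start (default `FALSE`).
#' @return Match percentage in `[0, 100]`.
#' @export
match_score <- function(training, recall,
                        variant = c("diagonal", "lcs"),
                        include_negative_lags = FALSE) {
  variant <- match.arg(variant)
  tr <- as.integer(unclass(training))
  rc <- as.integer(unclass(recall))
  n_r <- length(rc)
  if (variant == "lcs") {
    return(100 * lcs_length(tr, rc) / n_r)
  }
  lags <- 0:(length(tr) - n_r)
  if (include_negative_lags) lags <- c(-(seq_len(n_r - 1)), lags)
  best <- 0L
  for (d in lags) {
    j <- seq_len(n_r)
    i <- j + d
    ok <- i >= 1 & i <= length(tr)
    hits <- sum(tr[i[ok]] == rc[j[ok]])
    if (hits > best) best <- hits
  }
  100 * best / n_r
}

# classic O(nm) dynamic program
lcs_length <- function(a, b) {
  n <- length(a)
  m <- length(b)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L else
        max(prev[j + 1], cur[j])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Participant-level score table for the statistical stage
#'
#' Joins, per participant: training-sequence regularity, recall
#' regularity, cross-recurrence match to the assigned training sequence,
#' final-two-block predictive proportion, and the awareness rating.
#' Participants lacking a recall sequence are flagged and excluded from
#' the scored columns.
#'
#' @param participants data.frame as from [cohort_participants()] (needs
#'   `participant_id`, `sequence` and `recall` dash-separated strings,
#'   `g`, `awareness`).
#' @param features output of [trial_features()] for the same cohort.
#' @param match_variant passed to [match_score()].
#' @return data.frame: `participant_id`, `sequence_id` (if present),
#'   `train_g`, `recall_g`, `match_percent`, `pred_prop`, `awareness`,
#'   `flagged`.
#' @export
score_cohort <- function(participants, features,
                         match_variant = "diagonal") {
  if (inherits(participants, "swg_cohort")) {
    participants <- cohort_participants(participants)
  }
  pp <- final_predictive_proportion(features)
  n <- nrow(participants)
  recall_g <- rep(NA_real_, n)
  match_pct <- rep(NA_real_, n)
  flagged <- rep(FALSE, n)
  for (k in seq_len(n)) {
    rc <- participants$recall[k]
    if (is.na(rc) || !nzchar(rc)) {
      flagged[k] <- TRUE
      next
    }
    rc_items <- as.integer(strsplit(rc, "-", fixed = TRUE)[[1]])
    if (length(rc_items) != 24) {
      flagged[k] <- TRUE
      next
    }
    tr_items <- as.integer(strsplit(participants$sequence[k], "-",
                                    fixed = TRUE)[[1]])
    recall_g[k] <- recall_regularity(rc_items)
    match_pct[k] <- match_score(tr_items, rc_items, variant = match_variant)
  }
  out <- data.frame(participant_id = participants$participant_id,
                    train_g = participants$g,
                    recall_g = recall_g,
                    match_percent = match_pct,
                    awareness = participants$awareness,
                    flagged = flagged)
  if ("sequence_id" %in% names(participants)) {
    out$sequence_id <- participants$sequence_id
  }
  merge(out, pp, by = "participant_id", all.x = TRUE, sort = TRUE)
}
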
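#' Mixed-effects learning-curve model
#'
#' Fits `response ~ G + Trial + G:Trial` with a subject-level random
#' intercept (lme4 via lmerTest, Satterthwaite-approximate F tests per
#' term), the model used for reaction time and for both trajectory
#' distance measures. If the mixed fit fails or is singular, the function
#' falls back to ordinary least squares with subject-clustered
#' (CR0 sandwich) standard errors and flags the result.
#'
#' @param data data.frame with one row per trial; must contain the
#'   response column, `g`, `trial`, and `participant_id`.
#' @param response name of the response column (e.g. `"rt"`,
#'   `"dist_to_next"`, `"dist_from_prev"`).
#' @return A `swg_model_fit` list: `coefficients` (named fixed-effect
#'   estimates), `anova` (data.frame: term, F, df1, df2, p),
#'   `coef_table`, `n_obs`, `n_subjects`, `backend`
#'   (`"lmer"`/`"ols_clustered"`), `singular`.
#' @export
fit_learning_model <- function(data, response = "rt") {
  need <- c(response, "g", "trial", "participant_id")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("invalid-input: missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- data[stats::complete.cases(data[, need]), ]
  n_subj <- length(unique(data$participant_id))
  if (n_subj < 2 || nrow(data) < 4) {
    stop("invalid-input: need >= 2 subjects with >= 2 trials each",
         call. = FALSE)
  }
  fml <- stats::as.formula(paste0(response,
                                  " ~ g * trial + (1 | participant_id)"))
  # boundary warnings are expected on degenerate inputs; singularity is
  # detected and surfaced through the singular flag / fallback instead
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lmerTest::lmer(fml, data = data))),
    error = function(e) NULL)
  singular <- !is.null(fit) && lme4::isSingular(fit, tol = 1e-5)
  if (!is.null(fit) && !singular) {
    an <- suppressWarnings(suppressMessages(stats::anova(fit, type = 3)))
    an_df <- data.frame(term = rownames(an), F = an[["F value"]],
                        df1 = an$NumDF, df2 = an$DenDF,
                        p = an[["Pr(>F)"]], row.names = NULL)
    co <- lme4::fixef(fit)
    ct <- as.data.frame(summary(fit)$coefficients)
    backend <- "lmer"
  } else {
    ofml <- stats::as.formula(paste0(response, " ~ g * trial"))
    ols <- stats::lm(ofml, data = data)
    vc <- sandwich::vcovCL(ols, cluster = data$participant_id)
    ct <- lmtest::coeftest(ols, vcov. = vc)
    ct <- as.data.frame(unclass(ct))
    # per-term Wald F from the clustered covariance (1 df numerator)
    terms <- setdiff(rownames(ct), "(Intercept)")
    an_df <- data.frame(term = terms,
                        F = ct[terms, "t value"]^2,
                        df1 = 1,
                        df2 = n_subj - 1,
                        p = 2 * stats::pt(-abs(ct[terms, "t value"]),
                                          n_subj - 1),
                        row.names = NULL)
    co <- stats::coef(ols)
    backend <- "ols_clustered"
  }
  structure(list(coefficients = co, anova = an_df, coef_table = ct,
                 n_obs = nrow(data), n_subjects = n_subj,
                 backend = backend, singular = singular),
            class = "swg_model_fit")
}

#' @export
print.swg_model_fit <- function(x, ...) {
  cat(sprintf("<swg_model_fit: %s%s, %d obs, %d subjects>\n", x$backend,
              if (x$singular) " (singular)" else "", x$n_obs, x$n_subjects))
  print(x$anova, digits = 4)
  invisible(x)
}

#' Chi-square test of block-proportion uniformity
#'
#' Six-trial blocks admit exactly seven predictive proportions (0, 1/6,
#' ..., 1). This tests the observed histogram of per-subject proportions
#' in one block against a uniform distribution over those seven values
#' (Pearson chi-square, df = 6). Large statistics with mass piled at 0
#' and 1 are the signature of the reactive/predictive bimodality.
#'
#' @param counts integer vector of length 7: subjects per lattice value,
#'   in order 0, 1/6, ..., 1.
#' @return List: `statistic`, `df` (6), `p`.
#' @export
uniformity_chisq <- function(counts) {
  if (length(counts) != 7) {
    stop("invalid-input: need counts over the 7 attainable proportions",
         call. = FALSE)
  }
  if (sum(counts) <= 0) {
    stop("invalid-input: zero total count", call. = FALSE)
  }
  ht <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 7, 7)))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Bin block proportions onto the 7-point lattice
#'
#' @param props per-subject predictive proportions (multiples of 1/6).
#' @return Integer vector of counts over 0, 1/6, ..., 1.
#' @export
proportion_histogram <- function(props) {
  idx <- round(props * 6) + 1
  if (any(idx < 1 | idx > 7 | abs(props * 6 - round(props * 6)) > 1e-9)) {
    stop("invalid-input: proportions must lie on the lattice k/6",
         call. = FALSE)
  }
  tabulate(idx, nbins = 7)
}

#' One-sample t-test of block excess scores against zero
#'
#' The excess score (predictive minus correct-predictive trials in a
#' block) is positive when participants wager before their wagers are
#' accurate. Degenerate inputs (zero variance) are reported with a flag
#' instead of an error: t = 0 when all scores are 0, t = +/-Inf when all
#' scores equal a nonzero constant.
#'
#' @param scores numeric vector of per-subject excess scores for one block.
#' @return List: `t`, `df`, `p`, `mean`, `flag` (`NA` or a description).
#' @export
excess_score_test <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2) {
    stop("invalid-input: need n >= 2", call. = FALSE)
  }
  if (stats::sd(scores) == 0) {
    m <- mean(scores)
    if (m == 0) {
      return(list(t = 0, df = length(scores) - 1, p = 1, mean = 0,
                  flag = "zero variance, zero mean"))
    }
    return(list(t = sign(m) * Inf, df = length(scores) - 1, p = 0,
                mean = m, flag = "zero variance, nonzero mean"))
  }
  ht <- stats::t.test(scores, mu = 0)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), mean = mean(scores), flag = NA_character_)
}

#' Recall-memory regressions and correlations
#'
#' Reproduces the recall analysis stage on a scored cohort table:
#' Pearson correlations of training-sequence G with recall G and with
#' the cross-recurrence match percentage, and two multiple regressions
#' predicting the recall measures from the final-two-block predictive
#' proportion with training G as a covariate.
#'
#' @param scores table from [score_cohort()] (columns `train_g`,
#'   `recall_g`, `match_percent`, `pred_prop`; flagged rows are dropped).
#' @return List with `correlations` (data.frame: pair, r, p, flag) and
#'   `models` (named list of `lm` summaries for `match_percent` and
#'   `recall_g`).
#' @export
recall_regressions <- function(scores) {
  sc <- scores[!scores$flagged &
                 stats::complete.cases(scores[, c("train_g", "recall_g",
                                                  "match_percent",
                                                  "pred_prop")]), ]
  cor_row <- function(a, b, pair) {
    if (stats::sd(sc[[a]]) == 0 || stats::sd(sc[[b]]) == 0) {
      return(data.frame(pair = pair, r = NA_real_, p = NA_real_,
                        flag = "constant column"))
    }
    ht <- stats::cor.test(sc[[a]], sc[[b]])
    data.frame(pair = pair, r = unname(ht$estimate), p = ht$p.value,
               flag = NA_character_)
  }
  cors <- rbind(cor_row("train_g", "recall_g", "train_g~recall_g"),
                cor_row("train_g", "match_percent", "train_g~match"))
  fit_or_flag <- function(fml) {
    y <- all.vars(fml)[1]
    if (stats::sd(sc[[y]]) == 0) return("constant response")
    summary(stats::lm(fml, data = sc))
  }
  models <- list(
    match_percent = fit_or_flag(match_percent ~ pred_prop + train_g),
    recall_g = fit_or_flag(recall_g ~ pred_prop + train_g))
  list(correlations = cors, models = models, n = nrow(sc))
}

#' Residual-based mediation analysis
#'
#' Tests whether the predictor `m` (predictive proportion) mediates the
#' relation between `x` (sequence regularity G) and `y` (awareness):
#' regress `y` on `x` and correlate the residuals with `m`
#' (`r_m_given_x`); symmetrically, regress `y` on `m` and correlate the
#' residuals with `x` (`r_x_given_m`). Mediation is indicated when the
#' first correlation survives and the second collapses.
#'
#' @param x,m,y numeric vectors of equal length (n >= 3).
#' @return List of two rows: `r_m_given_x` and `r_x_given_m`, each with
#'   `r` and `p`.
#' @export
mediation_residuals <- function(x, m, y) {
  n <- length(y)
  if (n < 3 || length(x) != n || length(m) != n) {
    stop("invalid-input: x, m, y must have equal length >= 3",
         call. = FALSE)
  }
  res_x <- stats::resid(stats::lm(y ~ x))
  res_m <- stats::resid(stats::lm(y ~ m))
  cor_or_zero <- function(a, b) {
    if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
      return(list(r = 0, p = NA_real_, flag = "degenerate"))
    }
    ht <- stats::cor.test(a, b)
    list(r = unname(ht$estimate), p = ht$p.value, flag = NA_character_)
  }
  list(r_m_given_x = cor_or_zero(res_x, m),
       r_x_given_m = cor_or_zero(res_m, x))
}

#' Learning-curve model on the low-awareness subset
#'
#' Restricts the cohort to participants whose awareness rating is
#' strictly below `cutoff` (default 250, the midpoint of the 100-400
#' scale, i.e. below "somewhat patterned") and refits the reaction-time
#' learning model — the implicit-learning check: a G x Trial interaction
#' in participants who report little explicit pattern awareness.
#'
#' @param trial_data per-trial data.frame as for [fit_learning_model()]
#'   with an `rt` column.
#' @param participant_table data.frame with `participant_id` and
#'   `awareness`.
#' @param cutoff awareness cutoff in `[100, 400]`.
#' @param response response column (default `"rt"`).
#' @return A `swg_model_fit` with extra elements `n_selected` and
#'   `cutoff`.
#' @export
low_awareness_subset <- function(trial_data, participant_table,
                                 cutoff = 250, response = "rt") {
  if (cutoff < 100 || cutoff > 400) {
    stop("invalid-input: cutoff must lie in [100, 400]", call. = FALSE)
  }
  keep <- participant_table$participant_id[
    participant_table$awareness < cutoff]
  sub <- trial_data[trial_data$participant_id %in% keep, ]
  if (nrow(sub) == 0) {
    stop("empty-selection: no participants below cutoff ", cutoff,
         call. = FALSE)
  }
  fit <- fit_learning_model(sub, response = response)
  fit$n_selected <- length(unique(sub$participant_id))
  fit$cutoff <- cutoff
  fit
}
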
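# Hand-coded reference implementations, kept deliberately naive and
# independent of the package's code paths.

# regularity: explicit pair loop, explicit entropy term by term
oracle_g <- function(items) {
  tc <- matrix(0, 4, 4)
  for (i in seq_len(length(items) - 1)) {
    tc[items[i], items[i + 1]] <- tc[items[i], items[i + 1]] + 1
  }
  hbar <- 0
  for (s in 1:4) {
    tot <- sum(tc[s, ])
    h <- 0
    if (tot > 0) {
      for (t in 1:4) {
        if (tc[s, t] > 0) {
          p <- tc[s, t] / tot
          h <- h - p * log2(p)
        }
      }
    }
    hbar <- hbar + h / 4
  }
  1 - hbar / log2(4)
}

# best-diagonal match: exhaustive loop over every offset and position
oracle_match <- function(train, recall) {
  best <- 0
  for (d in 0:(length(train) - length(recall))) {
    hits <- 0
    for (j in seq_along(recall)) {
      if (train[j + d] == recall[j]) hits <- hits + 1
    }
    if (hits > best) best <- hits
  }
  100 * best / length(recall)
}

# textbook one-sample t
oracle_t <- function(x, mu = 0) {
  n <- length(x)
  (mean(x) - mu) / (sd(x) / sqrt(n))
}

# Pearson chi-square against equal expected counts
oracle_chisq <- function(counts) {
  e <- sum(counts) / length(counts)
  sum((counts - e)^2 / e)
}

# OLS by normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# random balanced no-repeat training sequence (sequential pool draw)
random_valid_training <- function(len = 48L) {
  per <- len %/% 4L
  repeat {
    pool <- rep(1:4, each = per)
    out <- integer(len)
    prev <- 0L
    ok <- TRUE
    for (i in seq_len(len)) {
      avail <- pool[pool != prev]
      if (length(avail) == 0) {
        ok <- FALSE
        break
      }
      pick <- avail[sample.int(length(avail), 1L)]
      out[i] <- pick
      pool <- pool[-match(pick, pool)]
      prev <- pick
    }
    if (ok) return(out)
  }
}
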
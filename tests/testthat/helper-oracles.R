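# Independent reference implementations used as oracles.  These deliberately
# re-derive each quantity from first principles (explicit sums, literal
# re-computation loops) rather than calling the code paths they check.

# closed-form OLS intercept from explicit sums
ols_intercept_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  mean(y) - (sxy / sxx) * mean(x)
}

# textbook Welch two-sample t-test: t statistic and Welch-Satterthwaite df
welch_p_oracle <- function(a, b) {
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / (va^2 / (length(a)^2 * (length(a) - 1)) +
                 vb^2 / (length(b)^2 * (length(b) - 1)))
  2 * stats::pt(-abs(t), df)
}

# literal re-computation of the elimination procedure: after every removal,
# every surviving probe's geometric mean is recomputed from scratch with
# prod()^(1/count)
score_probes_oracle <- function(p) {
  J <- nrow(p)
  live <- seq_len(J)
  score <- numeric(J)
  rank <- integer(J)
  step <- 0
  pc <- pmin(pmax(p, 1e-300), 1)
  while (length(live) > 2) {
    gms <- sapply(live, function(j) {
      vals <- c()
      for (k in setdiff(live, j)) vals <- c(vals, pc[j, k], pc[k, j])
      prod(vals)^(1 / length(vals))
    })
    best <- which(gms == min(gms))[1]
    pick <- live[best]
    step <- step + 1
    score[pick] <- min(gms)
    rank[pick] <- step
    live <- live[-best]
  }
  a <- live[1]; b <- live[2]
  fin <- prod(c(pc[a, b], pc[b, a]))^(1 / 2)
  score[c(a, b)] <- fin
  rank[a] <- step + 1
  rank[b] <- step + 2
  list(score = score, rank = rank)
}

# BH step-up adjusted p-values, written out literally
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    v <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- v
    prev <- v
  }
  adj
}

# two-sample KS statistic as the maximum ECDF gap over all observed points
ks_stat_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(sapply(pts, function(t) mean(x <= t) - mean(y <= t))))
}

# helper: tiny deterministic batch with an exact affine probe relation
make_exact_batch <- function(nA = 5, nB = 5, J = 4, nu = rep(0, J),
                             theta = seq_len(J), phi = NULL) {
  n <- nA + nB
  if (is.null(phi)) phi <- seq(100, 400, length.out = n)
  sample_ids <- sprintf("s%02d", seq_len(n))
  probe_ids <- sprintf("pr%02d", seq_len(J))
  values <- outer(theta, phi) + nu
  dimnames(values) <- list(probe_ids, sample_ids)
  groups <- stats::setNames(rep(c("A", "B"), c(nA, nB)), sample_ids)
  map <- data.frame(probe_set_id = "set1", probe_id = probe_ids,
                    stringsAsFactors = FALSE)
  list(intensities = values, map = map, groups = groups)
}
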
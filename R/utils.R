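# Internal helpers shared across modules.

# Smallest p-value the package ever reports; keeps log-space geometric means
# finite when a t-test underflows.
P_FLOOR <- 1e-300

clamp_p <- function(p) pmin(pmax(p, P_FLOOR), 1)

# Geometric mean computed in log space. Values are clamped to [P_FLOOR, 1]
# before taking logs so a zero cannot collapse the mean.
geometric_mean_p <- function(p) {
  exp(mean(log(clamp_p(p))))
}

# Wilson score interval for a binomial proportion.
wilson_ci <- function(k, n, conf = 0.95) {
  stopifnot(n > 0, k >= 0, k <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

# Area under the ROC curve for "low score predicts positive class", via the
# Mann-Whitney rank identity.
rank_auc <- function(scores_pos, scores_neg) {
  n1 <- length(scores_pos)
  n2 <- length(scores_neg)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  1 - u / (n1 * n2)
}

# Probe occurrences are keyed by (probe_set_id, probe_id); a probe may belong
# to several probe sets and each occurrence is scored independently.
probe_key <- function(probe_set_id, probe_id) {
  paste(probe_set_id, probe_id, sep = "\r")
}

condition_error <- function(class, message, call = sys.call(-1)) {
  stop(errorCondition(message, class = c(class, "badprobes_error"),
                      call = call))
}
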
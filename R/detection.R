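# Core detector: pooled-intercept pairwise ratio t-tests and iterative
# geometric-mean elimination.
#
# Signal model: the intensity of probe j on array i is
#   O_ij = nu_j + Phi_i * theta_j + error,
# with nu_j the baseline nonspecific-hybridization response, Phi_i the target
# abundance in sample i and theta_j the binding affinity of probe j.  Two
# probes of the same probe set therefore satisfy an affine relation
#   O_i2 = (nu_2 - nu_1 * theta_2/theta_1) + (theta_2/theta_1) * O_i1 + error,
# whose intercept does not involve Phi.  If a probe's affinity (or baseline)
# differs between the two sample groups, the slope differs between groups
# while the pooled intercept stays estimable from all samples together.

#' Ordinary-least-squares intercept of the pooled probe-pair relation
#'
#' Regresses the response probe's intensities on the predictor probe's over
#' all samples of both groups pooled, and returns the intercept (fluorescence
#' units).  Under the signal model the intercept is common to both groups even
#' when the slope is not, so it is estimated from the combined data.
#'
#' @param x predictor probe intensities over all samples.
#' @param y response probe intensities over all samples.
#' @return the OLS intercept (numeric scalar).
#' @export
estimate_intercept <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    condition_error("badprobes_invalid_input",
                    "x and y must have equal length >= 3")
  if (stats::var(x) == 0)
    condition_error("badprobes_degenerate_predictor",
                    "predictor probe has constant intensity; intercept undefined")
  unname(stats::lm.fit(cbind(1, x), y)$coefficients[1])
}

#' Two-group Welch t-test on intercept-corrected intensity ratios
#'
#' With the pooled intercept \code{beta} in hand, the per-sample ratio
#' (y_i - beta) / x_i estimates the affinity ratio theta_y / theta_x for
#' sample i.  Under the null it has the same distribution in both groups; a
#' probe with a group-specific affinity shifts it in one group.  The ratios
#' are compared with a two-sided Welch (unequal-variance) t-test and the
#' p-value clamped to [1e-300, 1].
#'
#' Degenerate inputs: if both groups' ratios have zero variance the p-value is
#' 1 when the group means agree (relative tolerance 1e-12) and 1e-300 when
#' they do not.
#'
#' @param x predictor probe intensities (strictly positive).
#' @param y response probe intensities.
#' @param beta pooled intercept from \code{\link{estimate_intercept}}.
#' @param groups group assignment for the samples, in sample order
#'   (see \code{\link{as_group_assignment}}).
#' @return two-sided p-value in [1e-300, 1].
#' @export
ratio_t_test <- function(x, y, beta, groups) {
  r <- (y - beta) / x
  g <- as.character(groups)
  lv <- unique(g)
  if (length(lv) != 2L)
    condition_error("badprobes_invalid_groups", "exactly two groups required")
  ra <- r[g == lv[1]]
  rb <- r[g == lv[2]]
  if (length(ra) < 2 || length(rb) < 2)
    condition_error("badprobes_insufficient_samples",
                    sprintf("need >= 2 samples per group, got %d and %d",
                            length(ra), length(rb)))
  degenerate_p <- function(tol) {
    scale <- max(abs(mean(ra)), abs(mean(rb)), 1e-300)
    if (abs(mean(ra) - mean(rb)) <= tol * scale) 1 else P_FLOOR
  }
  if (stats::var(ra) == 0 && stats::var(rb) == 0)
    return(degenerate_p(1e-12))
  # groups whose spread is at rounding level for the ratio computation chain
  # (far below any real array noise) are treated as constant at that scale
  near_const <- function(v)
    stats::sd(v) <= 1e-8 * max(abs(mean(v)), 1e-300)
  if (near_const(ra) && near_const(rb))
    return(degenerate_p(1e-8))
  p <- tryCatch(stats::t.test(ra, rb, var.equal = FALSE)$p.value,
                error = function(e) degenerate_p(1e-12))
  clamp_p(p)
}

#' All-pairs p-value matrix for one probe set
#'
#' For every ordered pair (j, k) of distinct probes in the set, estimates the
#' pooled intercept with probe j as predictor and probe k as response and
#' records the ratio t-test p-value at entry (j, k).  Both directions are
#' computed independently; the J x J matrix has an undefined (NA) diagonal and
#' J(J-1) defined entries, and is not symmetric in general.
#'
#' A pair whose predictor probe is constant contributes p = 1 (with a warning)
#' rather than aborting the probe set.
#'
#' @param intensities numeric matrix, the probe set's probes in rows and all
#'   samples in columns.
#' @param groups group assignment covering the matrix's samples.
#' @return object of class \code{pairwise_tests}: list with \code{probe_ids}
#'   and the J x J p-value matrix \code{p}.
#' @export
build_pairwise_matrix <- function(intensities, groups) {
  J <- nrow(intensities)
  if (is.null(J) || J < 2)
    condition_error("badprobes_invalid_input", "a probe set needs J >= 2 probes")
  groups <- as_group_assignment(groups, colnames(intensities))
  p <- matrix(NA_real_, J, J,
              dimnames = list(rownames(intensities), rownames(intensities)))
  for (j in seq_len(J)) {
    x <- intensities[j, ]
    for (k in seq_len(J)) {
      if (k == j) next
      y <- intensities[k, ]
      p[j, k] <- tryCatch({
        beta <- estimate_intercept(x, y)
        ratio_t_test(x, y, beta, groups)
      }, badprobes_degenerate_predictor = function(e) {
        warning(sprintf("constant predictor probe '%s'; recording p = 1 for pair (%s, %s)",
                        rownames(intensities)[j], rownames(intensities)[j],
                        rownames(intensities)[k]), call. = FALSE)
        1
      })
    }
  }
  structure(list(probe_ids = rownames(intensities), p = p),
            class = "pairwise_tests")
}

#' Iterative geometric-mean elimination scoring
#'
#' Summarises a probe set's pairwise p-value matrix into one quality score
#' (the mP-value) per probe:
#' \enumerate{
#'   \item for each surviving probe, take the geometric mean of every defined
#'     p-value involving it — its row \emph{and} its column among surviving
#'     probes (the probe as predictor and as response);
#'   \item the probe with the smallest geometric mean is removed: it receives
#'     that value as its quality score and the next elimination rank
#'     (rank 1 = first removed = most suspicious);
#'   \item repeat until only two probes remain; both receive the identical
#'     geometric mean of the two p-values connecting them, with the final two
#'     ranks (J-1, J) assigned by probe-index order.
#' }
#' Ties in the geometric mean are broken by the smallest within-set probe
#' index.  Geometric means are computed in log space with p-values clamped to
#' [1e-300, 1].
#'
#' @param pairwise a \code{pairwise_tests} object from
#'   \code{\link{build_pairwise_matrix}}, or a bare J x J p-value matrix with
#'   an NA diagonal.
#' @return data frame with columns \code{probe_id}, \code{quality_score},
#'   \code{elimination_rank}, in elimination order.
#' @export
score_probes <- function(pairwise) {
  p <- if (inherits(pairwise, "pairwise_tests")) pairwise$p else pairwise
  J <- nrow(p)
  if (is.null(J) || J < 2 || ncol(p) != J)
    condition_error("badprobes_invalid_input", "need a square p-value matrix with J >= 2")
  ids <- rownames(p)
  if (is.null(ids)) ids <- as.character(seq_len(J))
  lp <- log(clamp_p(p))
  live <- seq_len(J)
  score <- numeric(J)
  rank <- integer(J)
  step <- 0L
  while (length(live) > 2) {
    gm <- vapply(live, function(j) {
      others <- setdiff(live, j)
      mean(c(lp[j, others], lp[others, j]))
    }, numeric(1))
    pick <- live[which.min(gm)]           # which.min takes the first minimum:
    step <- step + 1L                     # ties go to the smallest probe index
    score[pick] <- exp(min(gm))
    rank[pick] <- step
    live <- setdiff(live, pick)
  }
  a <- live[1]; b <- live[2]
  final <- exp((lp[a, b] + lp[b, a]) / 2)
  score[c(a, b)] <- final
  rank[a] <- step + 1L
  rank[b] <- step + 2L
  out <- data.frame(probe_id = ids, quality_score = score,
                    elimination_rank = rank, stringsAsFactors = FALSE)
  out[order(out$elimination_rank), , drop = FALSE]
}

new_bad_mask <- function(scores, skipped = character(0), groups = NULL,
                         call = NULL) {
  rownames(scores) <- NULL
  structure(list(scores = scores, skipped = skipped, groups = groups,
                 call = call),
            class = "bad_mask")
}

#' Detect binding-affinity-different (BAD) probes
#'
#' The package's main fitting function.  For every analyzed probe set with at
#' least two probes it builds the matrix of all pairwise ratio t-tests
#' (\code{\link{build_pairwise_matrix}}) and reduces it by iterative
#' geometric-mean elimination (\code{\link{score_probes}}) to one quality
#' score per probe.  Low scores flag probes whose within-set signal relation
#' differs between the groups — typically caused by sequence polymorphisms in
#' the probe's target, isoform differences or group-specific
#' cross-hybridization.
#'
#' Scores are comparable only within one data set (they depend on sample size
#' and probe-set size); cutoffs must be chosen per data set, e.g. with
#' \code{plot.bad_mask}, \code{\link{overlap_masks}} or
#' \code{\link{score_distribution_test}}.
#'
#' Probe sets with a single probe are skipped with a warning.  The method has
#' adequate power from roughly five samples per group; a warning is issued
#' below that, and fewer than two samples per group is an error.
#'
#' @param intensities probe x sample matrix of linear-scale intensities (see
#'   \code{\link{validate_intensity_matrix}}).
#' @param map probe-set map (see \code{\link{validate_probe_set_map}}).
#' @param groups two-group sample assignment.
#' @param probe_sets optional character vector restricting analysis to these
#'   probe sets; an unknown id is an error.
#' @return object of class \code{bad_mask} with the score table in
#'   \code{$scores}; see \code{\link{write_mask}}, \code{\link{apply_mask}}.
#' @examples
#' sim <- simulate_batch(sim_config(n_probe_sets = 3, probes_per_set = 5,
#'                                  bad_fraction = 0.2, affinity_ratio = 2,
#'                                  seed = 1))
#' mask <- detect_bad(sim$intensities, sim$map, sim$groups)
#' head(as.data.frame(mask))
#' @export
detect_bad <- function(intensities, map, groups, probe_sets = NULL) {
  validate_intensity_matrix(intensities)
  map <- validate_probe_set_map(map)
  groups <- as_group_assignment(groups, colnames(intensities))
  gsz <- table(groups)
  if (any(gsz < 2))
    condition_error("badprobes_insufficient_samples",
                    "need at least 2 samples per group")
  if (any(gsz < 5))
    warning("fewer than 5 samples in a group; detection power may be low",
            call. = FALSE)
  all_sets <- unique(map$probe_set_id)
  if (!is.null(probe_sets)) {
    unknown <- setdiff(probe_sets, all_sets)
    if (length(unknown) > 0)
      condition_error("badprobes_unknown_probe_set",
                      paste0("unknown probe_set_id: ",
                             paste(unknown, collapse = ", ")))
    all_sets <- intersect(all_sets, probe_sets)
  }
  missing_probes <- setdiff(map$probe_id[map$probe_set_id %in% all_sets],
                            rownames(intensities))
  if (length(missing_probes) > 0)
    condition_error("badprobes_invalid_map",
                    paste0("probes in map but not in intensity matrix: ",
                           paste(utils::head(missing_probes, 5), collapse = ", ")))
  skipped <- character(0)
  res <- vector("list", length(all_sets))
  for (i in seq_along(all_sets)) {
    s <- all_sets[i]
    probes <- map$probe_id[map$probe_set_id == s]
    if (length(probes) < 2) {
      warning(sprintf("probe set '%s' has a single probe; skipped", s),
              call. = FALSE)
      skipped <- c(skipped, s)
      next
    }
    pw <- build_pairwise_matrix(intensities[probes, , drop = FALSE], groups)
    sc <- score_probes(pw)
    sc$probe_set_id <- s
    res[[i]] <- sc
  }
  scores <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(scores))
    scores <- data.frame(probe_id = character(0), quality_score = numeric(0),
                         elimination_rank = integer(0),
                         probe_set_id = character(0), stringsAsFactors = FALSE)
  scores <- scores[c("probe_set_id", "probe_id", "quality_score",
                     "elimination_rank")]
  new_bad_mask(scores, skipped = skipped, groups = groups,
               call = match.call())
}

#' @export
as.data.frame.bad_mask <- function(x, ...) x$scores

#' @export
print.bad_mask <- function(x, ...) {
  n_sets <- length(unique(x$scores$probe_set_id))
  cat(sprintf("BAD-probe quality mask: %d probes in %d probe sets\n",
              nrow(x$scores), n_sets))
  if (length(x$skipped) > 0)
    cat(sprintf("  (%d single-probe sets skipped)\n", length(x$skipped)))
  if (!is.null(x$groups))
    cat("  groups:", paste(sprintf("%s (n=%d)", names(table(x$groups)),
                                   table(x$groups)), collapse = " vs "), "\n")
  if (nrow(x$scores) > 0) {
    q <- stats::quantile(x$scores$quality_score, c(0, .01, .05, .25, .5, 1))
    cat("  quality-score quantiles:\n")
    print(signif(q, 3))
  }
  invisible(x)
}

#' @export
summary.bad_mask <- function(object, cutoffs = c(1e-6, 1e-4, 1e-3, 1e-2, 0.05),
                             ...) {
  s <- object$scores$quality_score
  below <- vapply(cutoffs, function(c) sum(s < c), integer(1))
  out <- data.frame(cutoff = cutoffs, n_below = below,
                    fraction_below = if (length(s)) below / length(s) else NA_real_)
  structure(list(n_probes = length(s),
                 n_sets = length(unique(object$scores$probe_set_id)),
                 table = out),
            class = "summary.bad_mask")
}

#' @export
print.summary.bad_mask <- function(x, ...) {
  cat(sprintf("%d scored probes in %d probe sets; probes below cutoff:\n",
              x$n_probes, x$n_sets))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot the quality-score distribution of a mask
#'
#' Histogram of log10 quality scores with the empirical CDF overlaid; the
#' standard aid for picking a data-set-specific cutoff by eye (a cluster of
#' very low scores separated from the bulk suggests a cutoff between them).
#'
#' @param x a \code{bad_mask}.
#' @param ... passed to \code{hist}.
#' @export
plot.bad_mask <- function(x, ...) {
  s <- clamp_p(x$scores$quality_score)
  op <- graphics::par(mar = c(5, 4, 3, 4))
  on.exit(graphics::par(op))
  h <- graphics::hist(log10(s), breaks = 40, col = "grey80", border = "white",
                      main = "Probe quality scores",
                      xlab = "log10 quality score (mP-value)", ...)
  e <- stats::ecdf(log10(s))
  xs <- seq(min(log10(s)), max(log10(s)), length.out = 200)
  graphics::lines(xs, e(xs) * max(h$counts), col = "firebrick", lwd = 2)
  graphics::axis(4, at = seq(0, max(h$counts), length.out = 5),
                 labels = sprintf("%.2f", seq(0, 1, length.out = 5)))
  graphics::mtext("ECDF", side = 4, line = 2.5)
  invisible(x)
}
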
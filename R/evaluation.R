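# Cutoff diagnostics against a reference BAD set, score-distribution tests,
# the stratified random-removal null, and per-probe inspection plots.

reference_keys <- function(reference) {
  if (is.data.frame(reference)) {
    if (!all(c("probe_set_id", "probe_id") %in% names(reference)))
      condition_error("badprobes_invalid_input",
                      "reference needs columns probe_set_id and probe_id")
    probe_key(as.character(reference$probe_set_id),
              as.character(reference$probe_id))
  } else {
    as.character(reference)
  }
}

split_mask_scores <- function(mask, reference) {
  m <- as.data.frame(mask)
  keys <- probe_key(m$probe_set_id, m$probe_id)
  is_ref <- keys %in% reference_keys(reference)
  list(ref = m$quality_score[is_ref], other = m$quality_score[!is_ref])
}

#' Sensitivity / false-positive curve against a reference BAD set
#'
#' When BAD status is known for a subset of probes (e.g. from sequence
#' polymorphisms between the groups), this tabulates, for each candidate
#' cutoff c: the sensitivity (fraction of reference probes with score < c),
#' the type 1 error (false-negative rate, 1 - sensitivity) and the type 2
#' error (false-positive rate: fraction of non-reference probes with
#' score < c), each with a Wilson score 95\% confidence interval.
#'
#' Note the error naming: here \emph{type 1 = false negatives} and
#' \emph{type 2 = false positives} — the convention of the masking literature
#' this package follows, which is reversed from the usual hypothesis-testing
#' usage.
#'
#' Only probes present in the mask count; the reference is intersected with
#' the mask's probes, and both the intersection and its complement must be
#' non-empty.
#'
#' @param mask a \code{bad_mask} (or its data frame).
#' @param reference data frame (probe_set_id, probe_id) of known-BAD probes.
#' @param cutoffs numeric vector of thresholds.
#' @param conf confidence level for the Wilson intervals (default 0.95).
#' @return object of class \code{cutoff_curve}: data frame with columns
#'   cutoff, sensitivity, sens_lo, sens_hi, type1, type2, type2_lo, type2_hi,
#'   plus attributes n_reference / n_other.
#' @export
overlap_masks <- function(mask, reference, cutoffs, conf = 0.95) {
  sp <- split_mask_scores(mask, reference)
  if (length(sp$ref) == 0)
    condition_error("badprobes_invalid_input",
                    "reference has no probes in common with the mask")
  if (length(sp$other) == 0)
    condition_error("badprobes_invalid_input",
                    "every mask probe is in the reference; false-positive rate undefined")
  cutoffs <- sort(cutoffs)
  rows <- lapply(cutoffs, function(c) {
    ks <- sum(sp$ref < c); ns <- length(sp$ref)
    kf <- sum(sp$other < c); nf <- length(sp$other)
    ci_s <- wilson_ci(ks, ns, conf)
    ci_f <- wilson_ci(kf, nf, conf)
    data.frame(cutoff = c,
               sensitivity = ks / ns, sens_lo = ci_s[["lo"]],
               sens_hi = ci_s[["hi"]],
               type1 = 1 - ks / ns,
               type2 = kf / nf, type2_lo = ci_f[["lo"]],
               type2_hi = ci_f[["hi"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("cutoff_curve", "data.frame"),
            n_reference = length(sp$ref), n_other = length(sp$other))
}

#' @export
print.cutoff_curve <- function(x, ...) {
  cat(sprintf("Cutoff curve over %d reference and %d other probes\n",
              attr(x, "n_reference"), attr(x, "n_other")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Plot a cutoff curve
#'
#' Sensitivity and false-positive (type 2) rate against the cutoff on a log
#' axis, with Wilson confidence bands.
#'
#' @param x a \code{cutoff_curve}.
#' @param ... passed to \code{matplot}.
#' @export
plot.cutoff_curve <- function(x, ...) {
  cx <- clamp_p(x$cutoff)
  graphics::matplot(cx, cbind(x$sensitivity, x$type2), type = "b", log = "x",
                    pch = c(19, 17), lty = 1,
                    col = c("forestgreen", "firebrick"),
                    xlab = "quality-score cutoff",
                    ylab = "rate", ylim = c(0, 1), ...)
  graphics::arrows(cx, x$sens_lo, cx, x$sens_hi, angle = 90, code = 3,
                   length = 0.03, col = "forestgreen")
  graphics::arrows(cx, x$type2_lo, cx, x$type2_hi, angle = 90, code = 3,
                   length = 0.03, col = "firebrick")
  graphics::legend("right", c("sensitivity", "type 2 error (FPR)"),
                   col = c("forestgreen", "firebrick"), pch = c(19, 17),
                   bty = "n")
  invisible(x)
}

#' Compare score distributions of reference vs other probes
#'
#' Two-sample Kolmogorov-Smirnov or Wilcoxon rank-sum test on the quality
#' scores of reference (known-BAD) vs remaining probes.  A non-significant
#' result warns that the scores do not discriminate the reference class in
#' this data set.
#'
#' @param mask a \code{bad_mask}.
#' @param reference data frame (probe_set_id, probe_id) of known-BAD probes.
#' @param method \code{"ks"} or \code{"wilcoxon"}.
#' @return the test p-value.
#' @export
score_distribution_test <- function(mask, reference,
                                    method = c("ks", "wilcoxon")) {
  method <- match.arg(method)
  sp <- split_mask_scores(mask, reference)
  if (length(sp$ref) < 2 || length(sp$other) < 2)
    condition_error("badprobes_invalid_input",
                    "need at least 2 probes in each class")
  if (method == "ks")
    suppressWarnings(stats::ks.test(sp$ref, sp$other)$p.value)
  else
    suppressWarnings(stats::wilcox.test(sp$ref, sp$other)$p.value)
}

#' ROC AUC of quality scores against a reference BAD set
#'
#' Convenience summary on top of \code{\link{overlap_masks}}: the probability
#' that a randomly chosen reference probe scores \emph{below} a randomly
#' chosen non-reference probe, computed from the Mann-Whitney rank identity.
#'
#' @param mask a \code{bad_mask}.
#' @param reference data frame (probe_set_id, probe_id) of known-BAD probes.
#' @return AUC in [0, 1]; 1 = reference probes always score lower.
#' @export
mask_auc <- function(mask, reference) {
  sp <- split_mask_scores(mask, reference)
  if (length(sp$ref) == 0 || length(sp$other) == 0)
    condition_error("badprobes_invalid_input",
                    "need probes in both classes")
  rank_auc(sp$ref, sp$other)
}

#' Per-probe-set removal profile of a probe list
#'
#' Counts how many probes a removal (e.g. all probes below a cutoff) takes
#' from each probe set — the stratification the random-removal null matches.
#'
#' @param probes data frame with columns \code{probe_set_id}, \code{probe_id}.
#' @param map probe-set map (supplies sets with zero removals).
#' @return named integer vector, one count per probe set of the map.
#' @export
removal_profile <- function(probes, map) {
  map <- validate_probe_set_map(map)
  sets <- unique(map$probe_set_id)
  counts <- stats::setNames(integer(length(sets)), sets)
  if (nrow(probes) > 0) {
    tb <- table(factor(probes$probe_set_id, levels = sets))
    counts[names(tb)] <- as.integer(tb)
  }
  counts
}

#' Random-probe-removal null for DE-status changes
#'
#' Does removing the flagged probes change differential-expression calls more
#' than removing \emph{the same number} of probes, with \emph{the same
#' distribution over probe sets}, at random?  Each iteration samples, within
#' every probe set, the profiled number of probes uniformly without
#' replacement, applies the removal, re-summarizes, re-runs the BH-corrected
#' t-test and records how many probe sets changed DE status relative to the
#' unmasked baseline.
#'
#' @param intensities probe x sample intensity matrix.
#' @param map probe-set map.
#' @param groups two-group sample assignment.
#' @param profile named integer vector of per-probe-set removal counts
#'   (\code{\link{removal_profile}}).
#' @param n_iter number of random-removal iterations.
#' @param alpha DE significance level on the BH-adjusted p-value.
#' @param min_probes passed to \code{\link{apply_mask}}.
#' @param seed integer seed; the run is reproducible given the same seed.
#' @return object of class \code{removal_null}: data frame with one row per
#'   iteration and columns \code{gained}, \code{lost}, \code{changed}; the
#'   baseline DE table is attached as attribute \code{baseline}.
#' @export
random_removal_null <- function(intensities, map, groups, profile,
                                n_iter = 1000, alpha = 0.01, min_probes = 1,
                                seed = 1) {
  map <- validate_probe_set_map(map)
  groups <- as_group_assignment(groups, colnames(intensities))
  sizes <- table(map$probe_set_id)
  over <- names(profile)[profile > as.vector(sizes[names(profile)])]
  if (length(over) > 0)
    condition_error("badprobes_invalid_input",
                    paste0("removal profile exceeds probe-set size for: ",
                           paste(over, collapse = ", ")))
  base_de <- differential_expression(summarize_expression(intensities, map),
                                     groups, alpha)
  base_status <- stats::setNames(base_de$is_DE, base_de$probe_set_id)
  active <- names(profile)[profile > 0]
  set.seed(seed)
  rows <- matrix(0L, nrow = n_iter, ncol = 3,
                 dimnames = list(NULL, c("gained", "lost", "changed")))
  for (it in seq_len(n_iter)) {
    picks <- lapply(active, function(s) {
      probes <- map$probe_id[map$probe_set_id == s]
      data.frame(probe_set_id = s,
                 probe_id = sample(probes, profile[[s]]),
                 stringsAsFactors = FALSE)
    })
    expl <- if (length(picks)) do.call(rbind, picks) else
      data.frame(probe_set_id = character(0), probe_id = character(0))
    mb <- apply_mask(intensities, map, explicit_probes = expl,
                     min_probes = min_probes)
    de <- differential_expression(summarize_expression(mb$intensities, mb$map),
                                  groups, alpha)
    status <- stats::setNames(de$is_DE, de$probe_set_id)
    common <- intersect(names(status), names(base_status))
    gained <- sum(status[common] & !base_status[common]) +
      sum(!names(status) %in% common & status)
    lost <- sum(!status[common] & base_status[common]) +
      sum(!names(base_status) %in% names(status) & base_status)
    rows[it, ] <- c(gained, lost, gained + lost)
  }
  out <- as.data.frame(rows)
  attr(out, "baseline") <- base_de
  class(out) <- c("removal_null", "data.frame")
  out
}

#' @export
print.removal_null <- function(x, ...) {
  cat(sprintf("Random-removal null over %d iterations\n", nrow(x)))
  print(summary(x$changed))
  invisible(x)
}

#' Inspect one probe against the rest of its probe set
#'
#' Scatter panels of the target probe's intensities (x axis) against every
#' other probe of its set, samples colored by group, with the pooled-intercept
#' fit (black) and the per-group slope lines through that intercept.  A BAD
#' probe shows group-separated slopes in most panels.
#'
#' @param intensities probe x sample intensity matrix.
#' @param map probe-set map.
#' @param probe_set_id,probe_id the probe occurrence to inspect.
#' @param groups two-group sample assignment.
#' @param output optional file path (.png or .pdf); when NULL, plots to the
#'   current device.
#' @return invisibly, the number of panels drawn.
#' @export
plot_probe <- function(intensities, map, probe_set_id, probe_id, groups,
                       output = NULL) {
  map <- validate_probe_set_map(map)
  groups <- as_group_assignment(groups, colnames(intensities))
  probes <- map$probe_id[map$probe_set_id == probe_set_id]
  if (!probe_id %in% probes)
    condition_error("badprobes_invalid_input",
                    sprintf("probe '%s' not found in probe set '%s'",
                            probe_id, probe_set_id))
  others <- setdiff(probes, probe_id)
  if (length(others) == 0)
    condition_error("badprobes_invalid_input",
                    "probe set needs at least 2 probes to plot")
  if (!is.null(output)) {
    ext <- tolower(tools::file_ext(output))
    switch(ext,
           png = grDevices::png(output, width = 1200, height = 900, res = 120),
           pdf = grDevices::pdf(output, width = 10, height = 7.5),
           svg = grDevices::svg(output, width = 10, height = 7.5),
           condition_error("badprobes_io",
                           sprintf("unsupported plot format '%s'", ext)))
    on.exit(grDevices::dev.off())
  }
  nc <- ceiling(sqrt(length(others)))
  nr <- ceiling(length(others) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  glv <- unique(groups)
  cols <- stats::setNames(c("dodgerblue3", "forestgreen"), glv)
  x <- intensities[probe_id, names(groups)]
  for (o in others) {
    y <- intensities[o, names(groups)]
    graphics::plot(x, y, col = cols[groups], pch = 19,
                   xlab = probe_id, ylab = o,
                   main = sprintf("%s: %s vs %s", probe_set_id, probe_id, o))
    beta <- tryCatch(estimate_intercept(x, y), error = function(e) NULL)
    if (!is.null(beta)) {
      slope_all <- mean((y - beta) / x)
      graphics::abline(beta, slope_all, col = "black", lwd = 2)
      for (g in glv) {
        i <- groups == g
        graphics::abline(beta, mean((y[i] - beta) / x[i]), col = cols[g],
                         lwd = 1.5, lty = 2)
      }
    }
  }
  invisible(length(others))
}
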
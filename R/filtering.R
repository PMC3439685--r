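# Pre-detection expression filtering and post-detection probe removal with
# probe-set redefinition.

#' Expression filter policy
#'
#' Detection is only meaningful for probe sets whose target is actually
#' expressed; probe sets picking up background show no usable within-set
#' signal correlation.  Three strategies are supported:
#' \describe{
#'   \item{presence_calls}{keep probe sets called Present ("P") in at least
#'     \code{presence_fraction} of samples \emph{in each group separately}
#'     (default 0.90); requires an external presence-call matrix.}
#'   \item{mean_threshold}{keep probe sets whose per-sample mean probe
#'     intensity reaches \code{intensity_threshold} (linear scale) in at least
#'     \code{presence_fraction} of samples of each group.}
#'   \item{explicit_list}{the user supplies the probe sets to analyze.}
#' }
#'
#' @param strategy one of \code{"presence_calls"}, \code{"mean_threshold"},
#'   \code{"explicit_list"}.
#' @param presence_fraction fraction in [0, 1]; default 0.90.
#' @param intensity_threshold linear-scale intensity used by
#'   \code{mean_threshold}.
#' @param probe_sets character vector used by \code{explicit_list}.
#' @return an \code{expression_filter_policy} list.
#' @export
expression_filter_policy <- function(strategy = c("presence_calls",
                                                  "mean_threshold",
                                                  "explicit_list"),
                                     presence_fraction = 0.90,
                                     intensity_threshold = NULL,
                                     probe_sets = NULL) {
  strategy <- match.arg(strategy)
  if (presence_fraction < 0 || presence_fraction > 1)
    condition_error("badprobes_invalid_input",
                    "presence_fraction must be in [0, 1]")
  if (strategy == "mean_threshold" &&
      (is.null(intensity_threshold) || intensity_threshold <= 0))
    condition_error("badprobes_invalid_input",
                    "mean_threshold needs a positive intensity_threshold")
  if (strategy == "explicit_list" && is.null(probe_sets))
    condition_error("badprobes_invalid_input",
                    "explicit_list needs probe_sets")
  structure(list(strategy = strategy, presence_fraction = presence_fraction,
                 intensity_threshold = intensity_threshold,
                 probe_sets = probe_sets),
            class = "expression_filter_policy")
}

#' Select expressed probe sets
#'
#' Applies an \code{\link{expression_filter_policy}} and returns the ids of
#' probe sets deemed expressed, i.e. eligible for BAD-probe detection.
#'
#' @param intensities probe x sample intensity matrix.
#' @param map probe-set map.
#' @param groups two-group sample assignment.
#' @param policy an \code{\link{expression_filter_policy}}.
#' @param calls presence-call matrix (probe sets x samples), required by the
#'   \code{presence_calls} strategy; every probe set of the map must appear.
#' @return character vector of probe_set_ids, in map order.
#' @export
select_expressed_probe_sets <- function(intensities, map, groups, policy,
                                        calls = NULL) {
  map <- validate_probe_set_map(map)
  groups <- as_group_assignment(groups, colnames(intensities))
  sets <- unique(map$probe_set_id)
  glv <- unique(groups)
  keep_per_group <- function(ok_by_sample) {
    # ok_by_sample: logical vector named by sample id
    all(vapply(glv, function(g) {
      idx <- names(groups)[groups == g]
      mean(ok_by_sample[idx]) >= policy$presence_fraction
    }, logical(1)))
  }
  switch(policy$strategy,
    presence_calls = {
      if (is.null(calls))
        condition_error("badprobes_invalid_input",
                        "presence_calls strategy requires a calls matrix")
      validate_presence_calls(calls)
      missing <- setdiff(sets, rownames(calls))
      if (length(missing) > 0)
        condition_error("badprobes_invalid_calls",
                        paste0("probe sets missing from calls matrix: ",
                               paste(utils::head(missing, 5), collapse = ", ")))
      missing_s <- setdiff(names(groups), colnames(calls))
      if (length(missing_s) > 0)
        condition_error("badprobes_invalid_calls",
                        paste0("samples missing from calls matrix: ",
                               paste(missing_s, collapse = ", ")))
      sets[vapply(sets, function(s) {
        keep_per_group(stats::setNames(calls[s, names(groups)] == "P",
                                       names(groups)))
      }, logical(1))]
    },
    mean_threshold = {
      sets[vapply(sets, function(s) {
        probes <- map$probe_id[map$probe_set_id == s]
        m <- colMeans(intensities[probes, names(groups), drop = FALSE])
        keep_per_group(m >= policy$intensity_threshold)
      }, logical(1))]
    },
    explicit_list = {
      unknown <- setdiff(policy$probe_sets, sets)
      if (length(unknown) > 0)
        condition_error("badprobes_unknown_probe_set",
                        paste0("unknown probe_set_id: ",
                               paste(unknown, collapse = ", ")))
      sets[sets %in% policy$probe_sets]
    })
}

#' Remove low-quality probes and redefine probe sets
#'
#' Removes probes scoring strictly below \code{cutoff} (so \code{cutoff = 0}
#' removes nothing), or an explicit probe list, then drops every probe set
#' left with fewer than \code{min_probes} probes; the surviving probes form
#' redefined probe sets usable by any downstream summarization.  Probe sets
#' never analyzed (absent from the mask) pass through untouched.
#'
#' @param intensities probe x sample intensity matrix.
#' @param map probe-set map.
#' @param mask a \code{bad_mask} (or its data frame); supply together with
#'   \code{cutoff}, and instead of \code{explicit_probes}.
#' @param cutoff quality-score threshold in [0, 1].
#' @param min_probes minimum number of probes a probe set must retain
#'   (default 1).
#' @param explicit_probes data frame with columns \code{probe_set_id},
#'   \code{probe_id} naming occurrences to remove; alternative to
#'   \code{mask}/\code{cutoff}.
#' @return object of class \code{masked_batch}: list with the restricted
#'   \code{intensities}, the redefined \code{map}, and a \code{removal_log}
#'   data frame (probe_set_id, probe_id, reason).
#' @export
apply_mask <- function(intensities, map, mask = NULL, cutoff = NULL,
                       min_probes = 1, explicit_probes = NULL) {
  validate_intensity_matrix(intensities)
  map <- validate_probe_set_map(map)
  if (min_probes < 1)
    condition_error("badprobes_invalid_input", "min_probes must be >= 1")
  use_mask <- !is.null(mask) || !is.null(cutoff)
  if (use_mask == !is.null(explicit_probes))
    condition_error("badprobes_invalid_input",
                    "supply exactly one of (mask + cutoff) or explicit_probes")
  if (use_mask) {
    if (is.null(mask) || is.null(cutoff))
      condition_error("badprobes_invalid_input",
                      "mask and cutoff must be supplied together")
    if (cutoff < 0 || cutoff > 1)
      condition_error("badprobes_invalid_input", "cutoff must be in [0, 1]")
    m <- as.data.frame(mask)
    hit <- m[m$quality_score < cutoff, c("probe_set_id", "probe_id"),
             drop = FALSE]
    reason <- "below_cutoff"
  } else {
    hit <- explicit_probes[c("probe_set_id", "probe_id")]
    reason <- "explicit"
  }
  key_map <- probe_key(map$probe_set_id, map$probe_id)
  key_hit <- probe_key(hit$probe_set_id, hit$probe_id)
  removed <- key_map %in% key_hit
  log1 <- data.frame(probe_set_id = map$probe_set_id[removed],
                     probe_id = map$probe_id[removed],
                     reason = if (any(removed)) reason else character(0),
                     stringsAsFactors = FALSE)
  surv <- map[!removed, , drop = FALSE]
  # drop probe sets that fell below min_probes; log their surviving probes too
  sizes <- table(surv$probe_set_id)
  had_removal <- unique(map$probe_set_id[removed])
  too_small <- intersect(names(sizes)[sizes < min_probes], had_removal)
  below <- surv$probe_set_id %in% too_small
  log2 <- data.frame(probe_set_id = surv$probe_set_id[below],
                     probe_id = surv$probe_id[below],
                     reason = if (any(below)) "probe_set_below_min" else character(0),
                     stringsAsFactors = FALSE)
  surv <- surv[!below, , drop = FALSE]
  rownames(surv) <- NULL
  keep_probes <- rownames(intensities) %in% surv$probe_id |
    !(rownames(intensities) %in% map$probe_id)
  structure(list(intensities = intensities[keep_probes, , drop = FALSE],
                 map = surv,
                 removal_log = rbind(log1, log2)),
            class = "masked_batch")
}

#' @export
print.masked_batch <- function(x, ...) {
  cat(sprintf("Masked batch: %d probes x %d samples, %d probe sets (%d probes removed)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$map$probe_set_id)), nrow(x$removal_log)))
  if (nrow(x$removal_log) > 0)
    print(table(x$removal_log$reason))
  invisible(x)
}

#' Summarize probe-level intensities to probe-set expression
#'
#' A deliberately simple summarizer — the mean over a probe set's probes of
#' the log2 intensities — producing the probe-set x sample expression table
#' the differential-expression step consumes.  Any other summarizer can be
#' substituted at this table interface.
#'
#' @param intensities probe x sample intensity matrix (linear scale).
#' @param map probe-set map.
#' @return numeric matrix, probe sets in rows (map order), samples in columns.
#' @export
summarize_expression <- function(intensities, map) {
  validate_intensity_matrix(intensities)
  map <- validate_probe_set_map(map)
  lg <- log2(intensities)
  sets <- unique(map$probe_set_id)
  out <- matrix(NA_real_, length(sets), ncol(intensities),
                dimnames = list(sets, colnames(intensities)))
  for (s in sets) {
    probes <- map$probe_id[map$probe_set_id == s]
    out[s, ] <- colMeans(lg[probes, , drop = FALSE])
  }
  out
}

#' Per-probe-set differential expression with BH correction
#'
#' Two-sided Welch t-test per probe set on the expression table, followed by
#' Benjamini-Hochberg adjustment over all tested sets; a set is called
#' differentially expressed when its adjusted p-value is below \code{alpha}
#' (default 0.01).
#'
#' @param expr probe-set x sample expression matrix
#'   (\code{\link{summarize_expression}}).
#' @param groups two-group sample assignment.
#' @param alpha significance level on the adjusted p-value.
#' @return data frame with columns \code{probe_set_id}, \code{p_value},
#'   \code{adjusted_p}, \code{is_DE}.
#' @export
differential_expression <- function(expr, groups, alpha = 0.01) {
  groups <- as_group_assignment(groups, colnames(expr))
  lv <- unique(groups)
  ia <- names(groups)[groups == lv[1]]
  ib <- names(groups)[groups == lv[2]]
  if (length(ia) < 2 || length(ib) < 2)
    condition_error("badprobes_insufficient_samples",
                    "need at least 2 samples per group")
  pv <- apply(expr, 1, function(e) {
    a <- e[ia]; b <- e[ib]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      scale <- max(abs(mean(a)), abs(mean(b)), 1e-300)
      return(if (abs(mean(a) - mean(b)) <= 1e-12 * scale) 1 else P_FLOOR)
    }
    tryCatch(stats::t.test(a, b, var.equal = FALSE)$p.value,
             error = function(e) 1)
  })
  adj <- stats::p.adjust(pv, method = "BH")
  data.frame(probe_set_id = rownames(expr), p_value = unname(pv),
             adjusted_p = unname(adj), is_DE = unname(adj < alpha),
             stringsAsFactors = FALSE)
}
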
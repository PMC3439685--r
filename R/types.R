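#' Validate a probe intensity matrix
#'
#' The package represents probe-level fluorescence data as a plain numeric
#' matrix on the \emph{linear} intensity scale: rows are probes (unique
#' rownames), columns are samples (unique colnames), every cell strictly
#' positive and finite.  The pooled-intercept model the detector fits is
#' affine in raw fluorescence, so log-scale data must be converted before use
#' (see \code{\link{read_intensity_matrix}}).
#'
#' @param values numeric matrix with rownames (probe ids) and colnames
#'   (sample ids).
#' @return the validated matrix, invisibly.
#' @export
validate_intensity_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    condition_error("badprobes_invalid_matrix", "intensities must be a numeric matrix")
  pid <- rownames(values); sid <- colnames(values)
  if ((is.null(pid) && nrow(values) > 0) ||
      (is.null(sid) && ncol(values) > 0))
    condition_error("badprobes_invalid_matrix",
                    "intensity matrix needs probe rownames and sample colnames")
  if (anyDuplicated(pid))
    condition_error("badprobes_invalid_matrix",
                    paste0("duplicate probe_id: ",
                           paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  if (anyDuplicated(sid))
    condition_error("badprobes_invalid_matrix",
                    paste0("duplicate sample_id: ",
                           paste(unique(sid[duplicated(sid)]), collapse = ", ")))
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    condition_error("badprobes_invalid_matrix",
                    sprintf("non-positive or non-finite intensity at probe '%s', sample '%s'",
                            pid[bad[1, 1]], sid[bad[1, 2]]))
  invisible(values)
}

#' Validate a probe-set map
#'
#' A probe-set map assigns probes to probe sets, the analog of an array's chip
#' description (CDF) table.  It is a data frame with character columns
#' \code{probe_set_id} and \code{probe_id}; row order is the within-set probe
#' order.  A probe may belong to several probe sets, but a
#' (probe_set_id, probe_id) pair may appear only once.
#'
#' @param map data frame with columns \code{probe_set_id}, \code{probe_id}.
#' @return the validated map (character columns, row names dropped), invisibly.
#' @export
validate_probe_set_map <- function(map) {
  if (!is.data.frame(map) || !all(c("probe_set_id", "probe_id") %in% names(map)))
    condition_error("badprobes_invalid_map",
                    "probe-set map needs columns probe_set_id and probe_id")
  map <- data.frame(probe_set_id = as.character(map$probe_set_id),
                    probe_id = as.character(map$probe_id),
                    stringsAsFactors = FALSE)
  key <- probe_key(map$probe_set_id, map$probe_id)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    condition_error("badprobes_invalid_map",
                    sprintf("duplicated (probe_set_id, probe_id) pair: %s",
                            gsub("\r", " / ", d, fixed = TRUE)))
  }
  invisible(map)
}

#' Coerce and validate a two-group sample assignment
#'
#' Accepts a named vector (names = sample ids, values = group labels) or a
#' two-column data frame (\code{sample_id}, \code{group}) and returns a named
#' character vector.  Exactly two distinct group labels are required, and when
#' \code{sample_ids} is given every one of them must be assigned.
#'
#' @param x named vector or data frame.
#' @param sample_ids optional character vector of sample ids that must all be
#'   covered (typically \code{colnames} of the companion intensity matrix).
#' @return named character vector mapping sample_id to group label.
#' @export
as_group_assignment <- function(x, sample_ids = NULL) {
  if (is.data.frame(x)) {
    if (!all(c("sample_id", "group") %in% names(x)))
      condition_error("badprobes_invalid_groups",
                      "group assignment data frame needs columns sample_id and group")
    g <- stats::setNames(as.character(x$group), as.character(x$sample_id))
  } else {
    g <- as.character(x)
    names(g) <- names(x)
  }
  if (is.null(names(g)) || anyDuplicated(names(g)))
    condition_error("badprobes_invalid_groups",
                    "group assignment needs unique sample_id names")
  if (length(unique(g)) != 2L)
    condition_error("badprobes_invalid_groups",
                    sprintf("exactly two distinct group labels required, got %d",
                            length(unique(g))))
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, names(g))
    if (length(missing) > 0)
      condition_error("badprobes_invalid_groups",
                      paste0("samples without group assignment: ",
                             paste(missing, collapse = ", ")))
    g <- g[sample_ids]
  }
  g
}

#' Validate a presence-call matrix
#'
#' Per probe set and sample detection calls (Present / Marginal / Absent)
#' produced by an external algorithm such as MAS5; the package consumes calls,
#' it never computes them.  Cells must be one of \code{"P"}, \code{"M"},
#' \code{"A"}.
#'
#' @param calls character matrix, rows = probe sets, columns = samples.
#' @return the validated matrix, invisibly.
#' @export
validate_presence_calls <- function(calls) {
  if (!is.matrix(calls) || is.null(rownames(calls)) || is.null(colnames(calls)))
    condition_error("badprobes_invalid_calls",
                    "presence calls must be a matrix with probe-set rownames and sample colnames")
  ok <- calls %in% c("P", "M", "A")
  if (!all(ok)) {
    bad <- which(!matrix(ok, nrow(calls)), arr.ind = TRUE)
    condition_error("badprobes_invalid_calls",
                    sprintf("presence call not in {P,M,A} at probe set '%s', sample '%s'",
                            rownames(calls)[bad[1, 1]], colnames(calls)[bad[1, 2]]))
  }
  invisible(calls)
}
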
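# Tab-delimited readers and writers for every on-disk representation.
# All formats are plain TSV so they can be produced and inspected with
# ordinary command-line tools.

read_tsv_strict <- function(path) {
  if (!file.exists(path))
    condition_error("badprobes_io", sprintf("file not found: %s", path))
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", fill = FALSE,
                    blank.lines.skip = FALSE)
}

#' Read a probe-level intensity matrix from TSV
#'
#' Expects a tab-delimited file with a header row of sample ids, probe ids in
#' the first column, and a numeric body.  The returned matrix is always on the
#' linear fluorescence scale: if the file holds log2 values, pass
#' \code{log_scale = TRUE} and they are exponentiated (base 2) on read, with a
#' message recording the transformation.
#'
#' @param path path to the TSV file.
#' @param log_scale logical; declare that the file stores log2 intensities.
#' @return numeric matrix, probes in rows, samples in columns.
#' @seealso \code{\link{write_intensity_matrix}}, \code{\link{validate_intensity_matrix}}
#' @export
read_intensity_matrix <- function(path, log_scale = FALSE) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    condition_error("badprobes_io", "intensity matrix needs a probe_id column and at least one sample")
  pid <- df[[1]]
  if (anyDuplicated(pid))
    condition_error("badprobes_io",
                    paste0("duplicate probe_id in ", path, ": ",
                           paste(unique(pid[duplicated(pid)]), collapse = ", ")))
  body <- df[-1]
  sid <- names(body)
  values <- matrix(NA_real_, nrow(df), ncol(body),
                   dimnames = list(pid, sid))
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v))
    if (length(bad) > 0)
      condition_error("badprobes_io",
                      sprintf("non-numeric intensity at probe '%s', sample '%s'",
                              pid[bad[1]], sid[j]))
    values[, j] <- v
  }
  if (log_scale) {
    message("read_intensity_matrix: exponentiating declared log2 values to linear scale")
    values <- 2^values
  }
  validate_intensity_matrix(values)
  values
}

#' Write a probe-level intensity matrix to TSV
#'
#' @param values numeric matrix (probes x samples) with dimnames.
#' @param path output file path.
#' @export
write_intensity_matrix <- function(values, path) {
  validate_intensity_matrix(values)
  df <- data.frame(probe_id = rownames(values),
                   format(values, digits = 15, trim = TRUE, scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-set map from TSV
#'
#' Two tab-delimited columns, \code{probe_set_id} and \code{probe_id}, with an
#' optional third column \code{probe_index}.  Within-set probe order is file
#' order, unless \code{probe_index} is present, in which case rows are ordered
#' by it within each probe set.
#'
#' @param path path to the TSV file.
#' @return data frame with columns \code{probe_set_id}, \code{probe_id}.
#' @export
read_probe_set_map <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("probe_set_id", "probe_id") %in% names(df)))
    condition_error("badprobes_io",
                    "probe-set map needs columns probe_set_id and probe_id")
  if ("probe_index" %in% names(df)) {
    idx <- suppressWarnings(as.numeric(df$probe_index))
    if (anyNA(idx))
      condition_error("badprobes_io", "non-numeric probe_index in probe-set map")
    df <- df[order(df$probe_set_id, idx), , drop = FALSE]
  }
  map <- data.frame(probe_set_id = df$probe_set_id, probe_id = df$probe_id,
                    stringsAsFactors = FALSE)
  validate_probe_set_map(map)
  rownames(map) <- NULL
  map
}

#' Write a probe-set map to TSV
#' @param map data frame with columns \code{probe_set_id}, \code{probe_id}.
#' @param path output file path.
#' @export
write_probe_set_map <- function(map, path) {
  validate_probe_set_map(map)
  utils::write.table(map[c("probe_set_id", "probe_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-group sample assignment from TSV
#'
#' Columns \code{sample_id} and \code{group}; exactly two distinct group
#' labels.
#'
#' @param path path to the TSV file.
#' @return named character vector (names = sample ids).
#' @export
read_group_assignment <- function(path) {
  df <- read_tsv_strict(path)
  if (!all(c("sample_id", "group") %in% names(df)))
    condition_error("badprobes_io",
                    "group assignment needs columns sample_id and group")
  as_group_assignment(df)
}

#' Write a two-group sample assignment to TSV
#' @param groups named character vector mapping sample_id to group.
#' @param path output file path.
#' @export
write_group_assignment <- function(groups, path) {
  groups <- as_group_assignment(groups)
  utils::write.table(data.frame(sample_id = names(groups), group = groups),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence-call matrix from TSV
#'
#' Probe sets in rows, samples in columns, cells in \{P, M, A\} as produced by
#' an external detection-call algorithm (e.g. MAS5).
#'
#' @param path path to the TSV file.
#' @return character matrix of calls.
#' @export
read_presence_calls <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2)
    condition_error("badprobes_io", "presence-call matrix needs a probe_set_id column and at least one sample")
  m <- as.matrix(df[-1])
  rownames(m) <- df[[1]]
  validate_presence_calls(m)
  m
}

#' Write a quality mask to TSV
#'
#' The mask is the central output of detection: one row per analyzed
#' (probe set, probe) occurrence with its quality score (the mP-value) and the
#' order in which the elimination procedure removed it (rank 1 = most
#' suspicious).  Rows are sorted by (probe_set_id, elimination_rank) and the
#' scores serialized in scientific notation with 12 significant digits, so a
#' write/read round trip preserves them to at least 10 significant digits.
#'
#' @param mask a \code{bad_mask} object (see \code{\link{detect_bad}}) or a
#'   data frame with columns \code{probe_set_id}, \code{probe_id},
#'   \code{quality_score}, \code{elimination_rank}.
#' @param path output file path.
#' @export
write_mask <- function(mask, path) {
  df <- as.data.frame(mask)
  cols <- c("probe_set_id", "probe_id", "quality_score", "elimination_rank")
  if (!all(cols %in% names(df)))
    condition_error("badprobes_io",
                    paste0("mask needs columns ", paste(cols, collapse = ", ")))
  df <- df[order(df$probe_set_id, df$elimination_rank), cols, drop = FALSE]
  out <- data.frame(probe_set_id = df$probe_set_id,
                    probe_id = df$probe_id,
                    quality_score = formatC(df$quality_score, format = "e", digits = 11),
                    elimination_rank = df$elimination_rank,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a quality mask from TSV
#' @param path path written by \code{\link{write_mask}}.
#' @return a \code{bad_mask} object.
#' @export
read_mask <- function(path) {
  df <- read_tsv_strict(path)
  cols <- c("probe_set_id", "probe_id", "quality_score", "elimination_rank")
  if (!all(cols %in% names(df)))
    condition_error("badprobes_io",
                    paste0("mask file needs columns ", paste(cols, collapse = ", ")))
  scores <- data.frame(probe_set_id = df$probe_set_id,
                       probe_id = df$probe_id,
                       quality_score = as.numeric(df$quality_score),
                       elimination_rank = as.integer(df$elimination_rank),
                       stringsAsFactors = FALSE)
  new_bad_mask(scores)
}

#' Write a differential-expression table to TSV
#' @param de data frame from \code{\link{differential_expression}}.
#' @param path output file path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a probe removal log to TSV
#' @param removal_log data frame with columns \code{probe_set_id},
#'   \code{probe_id}, \code{reason} (from \code{\link{apply_mask}}).
#' @param path output file path.
#' @export
write_removal_log <- function(removal_log, path) {
  utils::write.table(removal_log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cutoff curve to TSV
#' @param curve a \code{cutoff_curve} from \code{\link{overlap_masks}}.
#' @param path output file path.
#' @export
write_cutoff_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a run configuration file (YAML or JSON)
#'
#' A single file mirroring the command-line options; used by the CLI wrapper.
#' Format is chosen by extension (.yaml/.yml or .json).
#'
#' @param path configuration file path.
#' @return named list of options.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      condition_error("badprobes_io", "the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      condition_error("badprobes_io", "the jsonlite package is required to read JSON configs")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    condition_error("badprobes_io",
                    sprintf("unrecognized config extension '%s' (want yaml/yml/json)", ext))
  }
}
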
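# Synthetic-data generator implementing the probe signal model
#   O_ij = (nu_j + Phi_i * theta_j^{g(i)}) * (1 + eps_ij)
# with group-specific affinities theta for BAD probes.  It provides the
# ground truth used by every simulation-based test in the package.

#' Simulation configuration
#'
#' Parameters of the synthetic probe-level batch.  Baselines nu_j, affinities
#' theta_j and per-sample target abundances Phi are drawn log-normally;
#' defaults give a baseline around 50 fluorescence units, affinities around 1
#' and abundances around 500, i.e. specific signal roughly ten-fold above
#' background, with 10\% multiplicative noise — values typical of expressed
#' probe sets on a fluorescence intensity scale.
#'
#' @param n_probe_sets number of probe sets.
#' @param probes_per_set probes per set (J).
#' @param group_sizes integer vector (nA, nB).
#' @param nu_meanlog,nu_sdlog log-normal law of the baseline nu_j.
#' @param theta_meanlog,theta_sdlog log-normal law of the affinity theta_j.
#' @param phi_meanlog,phi_sdlog log-normal law of the abundance Phi (drawn
#'   per probe set and sample).
#' @param bad_fraction fraction of probes made BAD.  When
#'   \code{bad_fraction * probes_per_set <= 1} the BAD probes are spread at
#'   most one per probe set.
#' @param affinity_ratio multiplicative change of theta in group B for BAD
#'   probes (1 = no effect; the BAD truth set is then empty).
#' @param baseline_ratio optional multiplicative change of nu in group B for
#'   BAD probes (groups may also differ in background binding level).
#' @param de_fraction,de_log2fc fraction of probe sets with a true expression
#'   difference and its log2 fold change (Phi scaled in group B).
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   noise.
#' @param seed integer seed; generation is fully reproducible from it.
#' @return a validated \code{sim_config} list.
#' @export
sim_config <- function(n_probe_sets = 50, probes_per_set = 11,
                       group_sizes = c(10, 10),
                       nu_meanlog = log(50), nu_sdlog = 0.3,
                       theta_meanlog = 0, theta_sdlog = 0.5,
                       phi_meanlog = log(500), phi_sdlog = 0.4,
                       bad_fraction = 0, affinity_ratio = 1,
                       baseline_ratio = 1,
                       de_fraction = 0, de_log2fc = 0,
                       noise_cv = 0.1, seed = 1) {
  cfg <- list(n_probe_sets = as.integer(n_probe_sets),
              probes_per_set = as.integer(probes_per_set),
              group_sizes = as.integer(group_sizes),
              nu_meanlog = nu_meanlog, nu_sdlog = nu_sdlog,
              theta_meanlog = theta_meanlog, theta_sdlog = theta_sdlog,
              phi_meanlog = phi_meanlog, phi_sdlog = phi_sdlog,
              bad_fraction = bad_fraction, affinity_ratio = affinity_ratio,
              baseline_ratio = baseline_ratio,
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              noise_cv = noise_cv, seed = as.integer(seed))
  if (cfg$n_probe_sets < 1 || cfg$probes_per_set < 1)
    condition_error("badprobes_invalid_config",
                    "need at least one probe set and one probe per set")
  if (length(cfg$group_sizes) != 2 || any(cfg$group_sizes < 1))
    condition_error("badprobes_invalid_config",
                    "group_sizes must be two positive integers")
  if (cfg$bad_fraction < 0 || cfg$bad_fraction > 1 ||
      cfg$de_fraction < 0 || cfg$de_fraction > 1)
    condition_error("badprobes_invalid_config",
                    "bad_fraction and de_fraction must be in [0, 1]")
  if (cfg$affinity_ratio <= 0 || cfg$baseline_ratio <= 0)
    condition_error("badprobes_invalid_config",
                    "affinity_ratio and baseline_ratio must be positive")
  if (any(c(cfg$nu_sdlog, cfg$theta_sdlog, cfg$phi_sdlog) < 0) ||
      cfg$noise_cv < 0)
    condition_error("badprobes_invalid_config",
                    "spread parameters must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Simulate a probe-level two-group batch
#'
#' Draws baselines, affinities and abundances from the configured laws,
#' assigns BAD probes (group-B affinity multiplied by \code{affinity_ratio})
#' and true-DE probe sets (group-B abundance scaled by
#' \code{2^de_log2fc}), and emits intensities under the signal model with
#' multiplicative Gaussian noise, clamped to a 1e-6 positive floor.
#'
#' A probe is recorded as BAD in the truth table iff its group parameters
#' actually differ; with \code{affinity_ratio = 1} (and
#' \code{baseline_ratio = 1}) the BAD truth set is therefore empty regardless
#' of \code{bad_fraction}.
#'
#' @param config a \code{\link{sim_config}}.
#' @return object of class \code{sim_batch}: list with \code{intensities}
#'   (probe x sample matrix), \code{map}, \code{groups}, \code{truth} (list
#'   with per-probe table, per-set DE table and the Phi matrix) and the
#'   \code{config}.
#' @export
simulate_batch <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(config$seed)
  ns <- config$n_probe_sets
  J <- config$probes_per_set
  nA <- config$group_sizes[1]; nB <- config$group_sizes[2]
  n <- nA + nB
  set_ids <- sprintf("ps%04d", seq_len(ns))
  sample_ids <- sprintf("s%03d", seq_len(n))
  groups <- stats::setNames(rep(c("A", "B"), c(nA, nB)), sample_ids)

  map <- data.frame(
    probe_set_id = rep(set_ids, each = J),
    probe_id = paste0(rep(set_ids, each = J), "_p",
                      sprintf("%02d", rep(seq_len(J), ns))),
    stringsAsFactors = FALSE)
  np <- nrow(map)

  nu <- stats::rlnorm(np, config$nu_meanlog, config$nu_sdlog)
  theta <- stats::rlnorm(np, config$theta_meanlog, config$theta_sdlog)
  phi <- matrix(stats::rlnorm(ns * n, config$phi_meanlog, config$phi_sdlog),
                ns, n, dimnames = list(set_ids, sample_ids))

  # true expression differences: scale group-B abundance of selected sets
  n_de <- round(config$de_fraction * ns)
  de_sets <- if (n_de > 0) sample(set_ids, n_de) else character(0)
  if (n_de > 0 && config$de_log2fc != 0)
    phi[de_sets, groups == "B"] <- phi[de_sets, groups == "B"] *
      2^config$de_log2fc

  # BAD assignment: at most one per probe set when the expected count per set
  # is <= 1, matching the common one-polymorphic-probe situation
  n_bad <- round(config$bad_fraction * np)
  bad_idx <- integer(0)
  if (n_bad > 0) {
    if (config$bad_fraction * J <= 1 && n_bad <= ns) {
      sets_hit <- sample(seq_len(ns), n_bad)
      bad_idx <- (sets_hit - 1L) * J + sample(seq_len(J), n_bad, replace = TRUE)
    } else {
      bad_idx <- sample(np, n_bad)
    }
  }
  theta_B <- theta
  nu_B <- nu
  theta_B[bad_idx] <- theta[bad_idx] * config$affinity_ratio
  nu_B[bad_idx] <- nu[bad_idx] * config$baseline_ratio

  values <- matrix(NA_real_, np, n, dimnames = list(map$probe_id, sample_ids))
  set_of <- rep(seq_len(ns), each = J)
  isB <- groups == "B"
  for (p in seq_len(np)) {
    s <- set_of[p]
    mu <- ifelse(isB, nu_B[p] + phi[s, ] * theta_B[p],
                 nu[p] + phi[s, ] * theta[p])
    values[p, ] <- mu
  }
  if (config$noise_cv > 0)
    values <- values * (1 + matrix(stats::rnorm(np * n, 0, config$noise_cv),
                                   np, n))
  values <- pmax(values, 1e-6)

  truth_probes <- data.frame(
    probe_set_id = map$probe_set_id, probe_id = map$probe_id,
    nu = nu, theta_A = theta, theta_B = theta_B,
    is_bad = theta != theta_B | nu != nu_B,
    stringsAsFactors = FALSE)
  truth_sets <- data.frame(probe_set_id = set_ids,
                           is_true_DE = set_ids %in% de_sets &
                             config$de_log2fc != 0,
                           stringsAsFactors = FALSE)
  structure(list(intensities = values, map = map, groups = groups,
                 truth = list(probes = truth_probes, sets = truth_sets,
                              phi = phi),
                 config = config),
            class = "sim_batch")
}

#' @export
print.sim_batch <- function(x, ...) {
  cat(sprintf("Simulated batch: %d probes x %d samples (%d probe sets, J = %d)\n",
              nrow(x$intensities), ncol(x$intensities),
              x$config$n_probe_sets, x$config$probes_per_set))
  cat(sprintf("  BAD probes: %d (affinity ratio %.3g); true-DE sets: %d; noise CV %.3g\n",
              sum(x$truth$probes$is_bad), x$config$affinity_ratio,
              sum(x$truth$sets$is_true_DE), x$config$noise_cv))
  invisible(x)
}

#' Simulate a batch with one engineered DE-flip probe set
#'
#' Builds a background batch of null probe sets plus one target set whose
#' single BAD probe has a \emph{reciprocal} signal — its intensity moves in
#' the opposite direction to the rest of the set — so that masking flips the
#' set's differential-expression status:
#' \describe{
#'   \item{gain}{the target set has a true log2 fold change \code{de_log2fc},
#'     but the BAD probe's group-B affinity is scaled by
#'     \code{2^(-J * de_log2fc)}, cancelling the set-level mean shift:
#'     the set looks non-DE until the probe is removed.}
#'   \item{loss}{the target set has no true expression difference, but the
#'     BAD probe's group-B affinity is scaled by \code{2^(J * de_log2fc)},
#'     creating a spurious set-level shift that disappears on masking.}
#' }
#' Target-set baselines are drawn low (around 2 units) so the cancellation in
#' log2 expression is nearly exact.  The engineered fold change must be large
#' relative to the between-sample abundance spread for the set-level t-test
#' to resolve it, while the abundance spread itself gives the pairwise
#' regression the leverage it needs to estimate intercepts; the defaults
#' (log2 fold change 1, abundance log-sd 0.3, 15 samples per group) balance
#' the two.
#'
#' @param direction \code{"gain"} (DE only after masking) or \code{"loss"}
#'   (DE only before masking).
#' @param n_background number of additional null probe sets.
#' @param probes_per_set probes per set (J).
#' @param group_sizes integer vector (nA, nB).
#' @param de_log2fc log2 fold change used for the engineering (default 0.5).
#' @param phi_sdlog between-sample log-sd of the target transcript's
#'   abundance.
#' @param noise_cv multiplicative noise CV (default 0.05).
#' @param n_targets number of engineered target sets (all in the same
#'   direction).
#' @param seed integer seed.
#' @return a \code{sim_batch} with extra elements \code{target_set},
#'   \code{target_probe} (parallel vectors) and \code{direction}.
#' @export
simulate_flip_batch <- function(direction = c("gain", "loss"),
                                n_background = 40, probes_per_set = 8,
                                group_sizes = c(15, 15), de_log2fc = 1,
                                phi_sdlog = 0.3, noise_cv = 0.05,
                                n_targets = 1, seed = 1) {
  direction <- match.arg(direction)
  J <- as.integer(probes_per_set)
  bg_cfg <- sim_config(n_probe_sets = n_background, probes_per_set = J,
                       group_sizes = group_sizes, noise_cv = noise_cv,
                       seed = seed)
  bg <- simulate_batch(bg_cfg)
  n <- sum(group_sizes)
  isB <- bg$groups == "B"

  out <- bg
  out$target_set <- character(0)
  out$target_probe <- character(0)
  for (t in seq_len(n_targets)) {
    # engineered target set, appended to the background draws
    set_id <- sprintf("flipset%02d", t)
    probe_ids <- paste0(set_id, "_p", sprintf("%02d", seq_len(J)))
    nu <- stats::rlnorm(J, log(2), 0.3)
    theta <- stats::rlnorm(J, 0, 0.5)
    phi <- stats::rlnorm(n, log(500), phi_sdlog)
    theta_B <- theta
    if (direction == "gain") {
      phi[isB] <- phi[isB] * 2^de_log2fc          # true DE, hidden by the probe
      theta_B[1] <- theta[1] * 2^(-J * de_log2fc)
    } else {
      theta_B[1] <- theta[1] * 2^(J * de_log2fc)  # spurious DE from the probe
    }
    mu <- matrix(NA_real_, J, n, dimnames = list(probe_ids, names(bg$groups)))
    for (p in seq_len(J))
      mu[p, ] <- nu[p] + phi * ifelse(isB, theta_B[p], theta[p])
    if (noise_cv > 0)
      mu <- mu * (1 + matrix(stats::rnorm(J * n, 0, noise_cv), J, n))
    mu <- pmax(mu, 1e-6)

    out$intensities <- rbind(out$intensities, mu)
    out$map <- rbind(out$map, data.frame(probe_set_id = set_id,
                                         probe_id = probe_ids,
                                         stringsAsFactors = FALSE))
    out$truth$probes <- rbind(out$truth$probes, data.frame(
      probe_set_id = set_id, probe_id = probe_ids, nu = nu,
      theta_A = theta, theta_B = theta_B, is_bad = theta != theta_B,
      stringsAsFactors = FALSE))
    out$truth$sets <- rbind(out$truth$sets, data.frame(
      probe_set_id = set_id, is_true_DE = direction == "gain",
      stringsAsFactors = FALSE))
    out$target_set <- c(out$target_set, set_id)
    out$target_probe <- c(out$target_probe, probe_ids[1])
  }
  out$direction <- direction
  out
}

write_sim_batch <- function(batch, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_intensity_matrix(batch$intensities, file.path(dir, "intensities.tsv"))
  write_probe_set_map(batch$map, file.path(dir, "probe_map.tsv"))
  write_group_assignment(batch$groups, file.path(dir, "groups.tsv"))
  utils::write.table(batch$truth$probes, file.path(dir, "truth_probes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(batch$truth$sets, file.path(dir, "truth_sets.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write the canonical fixture suite
#'
#' Generates and writes the batches the test suite is built around: a null
#' batch (affinity ratio 1), one-BAD-probe-per-set batches at affinity ratios
#' 1.2, 1.5 and 2.0, and the two reciprocal-signal DE-flip batches.  Each
#' fixture is written in the package's TSV dialects together with its truth
#' tables, and a \code{manifest.yaml} records every fixture's configuration,
#' seed and per-file MD5 checksums, so regeneration with the same seeds
#' reproduces identical files.
#'
#' The DE-flip fixtures are verified at generation time: the target set must
#' change BH-adjusted DE status in the engineered direction once the BAD
#' probe is removed, otherwise generation aborts.
#'
#' @param output_dir directory to create the fixtures in.
#' @param seed base seed; each fixture derives its own seed from it.
#' @return invisibly, a data frame listing fixtures and directories.
#' @export
make_fixture_suite <- function(output_dir, seed = 20260921) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  specs <- list(
    null = list(kind = "batch",
                cfg = list(bad_fraction = 1 / 11, affinity_ratio = 1,
                           seed = seed + 1)),
    delta_1.2 = list(kind = "batch",
                     cfg = list(bad_fraction = 1 / 11, affinity_ratio = 1.2,
                                seed = seed + 2)),
    delta_1.5 = list(kind = "batch",
                     cfg = list(bad_fraction = 1 / 11, affinity_ratio = 1.5,
                                seed = seed + 3)),
    delta_2.0 = list(kind = "batch",
                     cfg = list(bad_fraction = 1 / 11, affinity_ratio = 2,
                                seed = seed + 4)),
    flip_gain = list(kind = "flip", cfg = list(direction = "gain",
                                               seed = seed + 5)),
    flip_loss = list(kind = "flip", cfg = list(direction = "loss",
                                               seed = seed + 6)))
  manifest <- c("fixtures:")
  rows <- list()
  for (nm in names(specs)) {
    sp <- specs[[nm]]
    batch <- if (sp$kind == "batch") simulate_batch(do.call(sim_config, sp$cfg))
             else do.call(simulate_flip_batch, sp$cfg)
    if (sp$kind == "flip") verify_flip_batch(batch)
    d <- file.path(output_dir, nm)
    write_sim_batch(batch, d)
    files <- list.files(d, full.names = TRUE)
    manifest <- c(manifest,
                  sprintf("  %s:", nm),
                  sprintf("    kind: %s", sp$kind),
                  vapply(names(sp$cfg), function(k)
                    sprintf("    %s: %s", k, sp$cfg[[k]]), character(1)),
                  "    files:",
                  vapply(files, function(f)
                    sprintf("      %s: %s", basename(f),
                            unname(tools::md5sum(f))), character(1)))
    rows[[nm]] <- data.frame(fixture = nm, dir = d, stringsAsFactors = FALSE)
  }
  writeLines(manifest, file.path(output_dir, "manifest.yaml"))
  invisible(do.call(rbind, rows))
}

verify_flip_batch <- function(batch, alpha = 0.01) {
  de0 <- differential_expression(
    summarize_expression(batch$intensities, batch$map), batch$groups, alpha)
  mb <- apply_mask(batch$intensities, batch$map,
                   explicit_probes = data.frame(
                     probe_set_id = batch$target_set,
                     probe_id = batch$target_probe))
  de1 <- differential_expression(
    summarize_expression(mb$intensities, mb$map), batch$groups, alpha)
  for (s in batch$target_set) {
    s0 <- de0$is_DE[de0$probe_set_id == s]
    s1 <- de1$is_DE[de1$probe_set_id == s]
    ok <- if (batch$direction == "gain") !s0 && s1 else s0 && !s1
    if (!ok)
      condition_error("badprobes_fixture_failure",
                      sprintf("flip fixture '%s' did not flip DE status of %s (before=%s after=%s)",
                              batch$direction, s, s0, s1))
  }
  invisible(TRUE)
}
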
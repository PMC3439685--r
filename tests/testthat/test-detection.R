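test_that("pooled intercept matches the closed-form OLS solution", {
  expect_equal(estimate_intercept(c(1, 2, 3, 4), c(3, 5, 7, 9)), 1.0)
  expect_equal(estimate_intercept(c(1, 2, 3), c(5, 5, 5)), 5.0)
  set.seed(21)
  for (i in 1:20) {
    x <- stats::rlnorm(20, log(300), 0.5)
    y <- 50 + 2 * x + stats::rnorm(20, 0, 30)
    expect_equal(estimate_intercept(x, y), ols_intercept_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_error(estimate_intercept(rep(3, 5), 1:5),
               class = "badprobes_degenerate_predictor")
  expect_error(estimate_intercept(1:2, 1:2), "length")
})

test_that("ratio t-test agrees with a textbook Welch implementation", {
  # fixed ratios with known group difference: recover them through x, y, beta
  ra <- c(1.0, 1.1, 0.9, 1.0, 1.0)
  rb <- c(2.0, 2.1, 1.9, 2.0, 2.0)
  x <- rep(10, 10)
  beta <- 7
  y <- beta + c(ra, rb) * x
  groups <- stats::setNames(rep(c("A", "B"), each = 5), paste0("s", 1:10))
  expect_equal(ratio_t_test(x, y, beta, groups), welch_p_oracle(ra, rb),
               tolerance = 1e-10)
  set.seed(31)
  for (i in 1:25) {
    x <- stats::rlnorm(12, log(100), 0.4)
    y <- stats::rlnorm(12, log(150), 0.4)
    beta <- stats::rnorm(1, 10, 5)
    g <- stats::setNames(rep(c("A", "B"), each = 6), paste0("s", 1:12))
    r <- (y - beta) / x
    expect_equal(ratio_t_test(x, y, beta, g),
                 welch_p_oracle(r[1:6], r[7:12]), tolerance = 1e-10)
  }
})

test_that("ratio t-test handles degenerate and undersized groups", {
  g <- stats::setNames(rep(c("A", "B"), each = 4), paste0("s", 1:8))
  x <- rep(2, 8)
  # identical constant ratios in both groups -> p = 1
  expect_equal(ratio_t_test(x, 1 + 3 * x, beta = 1, g), 1)
  # constant but different ratios -> floor
  y <- c(rep(7, 4), rep(13, 4))
  expect_equal(ratio_t_test(x, y, beta = 1, g), 1e-300)
  g2 <- stats::setNames(c("A", rep("B", 5)), paste0("s", 1:6))
  expect_error(ratio_t_test(1:6, 1:6 + 1, 0, g2),
               class = "badprobes_insufficient_samples")
})

test_that("pairwise matrix has J(J-1) entries, both directions independent", {
  set.seed(41)
  for (J in c(2, 5)) {
    b <- make_exact_batch(J = J)
    m <- b$intensities * (1 + matrix(stats::rnorm(length(b$intensities), 0, 0.05),
                                     nrow(b$intensities)))
    pw <- build_pairwise_matrix(m, b$groups)
    expect_true(all(is.na(diag(pw$p))))
    expect_equal(sum(!is.na(pw$p)), J * (J - 1))
  }
})

test_that("a strongly BAD probe yields small p-values in both directions", {
  sim <- simulate_batch(sim_config(n_probe_sets = 1, probes_per_set = 5,
                                   bad_fraction = 0.2, affinity_ratio = 2,
                                   noise_cv = 0.1, seed = 7))
  bad <- sim$truth$probes$probe_id[sim$truth$probes$is_bad]
  expect_length(bad, 1)
  pw <- build_pairwise_matrix(sim$intensities, sim$groups)
  j <- which(pw$probe_ids == bad)
  expect_false(isTRUE(all.equal(pw$p[j, -j], pw$p[-j, j])))
  expect_true(all(pw$p[j, -j] < 0.05))
  expect_true(all(pw$p[-j, j] < 0.05))
})

test_that("a constant predictor contributes p = 1 with a warning", {
  b <- make_exact_batch(J = 3)
  m <- b$intensities * (1 + matrix(stats::rnorm(length(b$intensities), 0, 0.05),
                                   nrow(b$intensities)))
  m[2, ] <- 42  # flat probe: useless as predictor
  w <- testthat::capture_warnings(pw <- build_pairwise_matrix(m, b$groups))
  expect_length(w, 2)  # one per pair with the flat probe as predictor
  expect_true(all(grepl("constant predictor", w)))
  expect_true(all(pw$p[2, -2] == 1))
})

test_that("elimination scoring matches arithmetic identities", {
  # all entries equal: every probe scores p, removal in probe-index order
  p <- matrix(0.3, 4, 4); diag(p) <- NA
  sc <- score_probes(p)
  expect_equal(sc$quality_score, rep(0.3, 4))
  expect_equal(sc$probe_id, as.character(1:4))
  expect_equal(sc$elimination_rank, 1:4)
  # J = 2: both probes get the geometric mean of the two connecting entries
  p2 <- matrix(c(NA, 0.25, 0.04, NA), 2, 2)
  sc2 <- score_probes(p2)
  expect_equal(sc2$quality_score, c(0.1, 0.1))
  expect_equal(sort(sc2$elimination_rank), 1:2)
})

test_that("elimination scoring equals the literal re-computation oracle", {
  set.seed(51)
  for (i in 1:50) {
    J <- 4
    p <- matrix(stats::runif(J * J), J, J,
                dimnames = list(paste0("p", 1:J), paste0("p", 1:J)))
    diag(p) <- NA
    sc <- score_probes(p)
    orc <- score_probes_oracle(p)
    idx <- match(sc$probe_id, paste0("p", 1:J))
    expect_equal(sc$quality_score, orc$score[idx], tolerance = 1e-12)
    expect_equal(sc$elimination_rank, orc$rank[idx])
  }
})

test_that("detect_bad skips single-probe sets and validates its subset", {
  sim <- simulate_batch(sim_config(n_probe_sets = 3, probes_per_set = 4,
                                   seed = 9))
  map <- rbind(sim$map, data.frame(probe_set_id = "solo",
                                   probe_id = sim$map$probe_id[1]))
  expect_warning(mask <- detect_bad(sim$intensities, map, sim$groups),
                 "single probe")
  expect_false("solo" %in% as.data.frame(mask)$probe_set_id)
  expect_equal(length(mask$skipped), 1L)
  expect_error(detect_bad(sim$intensities, sim$map, sim$groups,
                          probe_sets = "nosuchset"),
               class = "badprobes_unknown_probe_set")
  sub <- detect_bad(sim$intensities, sim$map, sim$groups,
                    probe_sets = "ps0002")
  expect_setequal(unique(as.data.frame(sub)$probe_set_id), "ps0002")
})

test_that("detect_bad warns below five samples per group, errors below two", {
  sim <- simulate_batch(sim_config(n_probe_sets = 2, probes_per_set = 3,
                                   group_sizes = c(4, 4), seed = 3))
  expect_warning(detect_bad(sim$intensities, sim$map, sim$groups),
                 "fewer than 5")
  sim2 <- simulate_batch(sim_config(n_probe_sets = 2, probes_per_set = 3,
                                    group_sizes = c(1, 5), seed = 3))
  expect_error(detect_bad(sim2$intensities, sim2$map, sim2$groups),
               class = "badprobes_insufficient_samples")
})

test_that("scores are deterministic and invariant to sample permutation", {
  sim <- simulate_batch(sim_config(n_probe_sets = 4, probes_per_set = 6,
                                   bad_fraction = 1 / 6, affinity_ratio = 1.5,
                                   seed = 13))
  m1 <- detect_bad(sim$intensities, sim$map, sim$groups)
  m2 <- detect_bad(sim$intensities, sim$map, sim$groups)
  expect_identical(as.data.frame(m1), as.data.frame(m2))
  perm <- sample(ncol(sim$intensities))
  m3 <- detect_bad(sim$intensities[, perm], sim$map, sim$groups[perm])
  expect_equal(as.data.frame(m1)$quality_score,
               as.data.frame(m3)$quality_score, tolerance = 1e-12)
})

test_that("noise-free non-BAD pairs score p = 1 even after per-sample scaling", {
  # negligible baseline: scaling a whole sample is a pure abundance change
  sim <- simulate_batch(sim_config(n_probe_sets = 3, probes_per_set = 4,
                                   nu_meanlog = log(1e-8), nu_sdlog = 0,
                                   noise_cv = 0, seed = 17))
  scaled <- sim$intensities
  scaled[, 3] <- scaled[, 3] * 5
  for (s in unique(sim$map$probe_set_id)) {
    probes <- sim$map$probe_id[sim$map$probe_set_id == s]
    pw <- build_pairwise_matrix(scaled[probes, ], sim$groups)
    expect_true(all(pw$p[!is.na(pw$p)] == 1))
  }
})
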
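make_filter_fixture <- function(seed = 61, n_sets = 6, J = 4,
                                nA = 5, nB = 5) {
  set.seed(seed)
  sim <- simulate_batch(sim_config(n_probe_sets = n_sets, probes_per_set = J,
                                   group_sizes = c(nA, nB), seed = seed))
  sim
}

test_that("presence-call filtering applies the per-group fraction rule", {
  sim <- make_filter_fixture()
  sets <- unique(sim$map$probe_set_id)
  calls <- matrix("P", length(sets), length(sim$groups),
                  dimnames = list(sets, names(sim$groups)))
  pol <- expression_filter_policy("presence_calls", presence_fraction = 0.9)
  expect_equal(select_expressed_probe_sets(sim$intensities, sim$map,
                                           sim$groups, pol, calls), sets)
  # 80% P in group A, 100% in group B -> excluded by the per-group rule
  a_samples <- names(sim$groups)[sim$groups == "A"]
  calls2 <- calls
  calls2[2, a_samples[1]] <- "A"
  kept <- select_expressed_probe_sets(sim$intensities, sim$map, sim$groups,
                                      pol, calls2)
  expect_false(sets[2] %in% kept)
  expect_setequal(kept, sets[-2])
  expect_error(select_expressed_probe_sets(sim$intensities, sim$map,
                                           sim$groups, pol,
                                           calls[-1, , drop = FALSE]),
               class = "badprobes_invalid_calls")
})

test_that("mean-threshold filtering equals a double-loop counting oracle", {
  sim <- make_filter_fixture(seed = 67)
  thr <- stats::median(sim$intensities)
  pol <- expression_filter_policy("mean_threshold", presence_fraction = 0.6,
                                  intensity_threshold = thr)
  kept <- select_expressed_probe_sets(sim$intensities, sim$map, sim$groups, pol)
  # oracle: explicit loops over sets, groups, samples
  sets <- unique(sim$map$probe_set_id)
  oracle <- c()
  for (s in sets) {
    probes <- sim$map$probe_id[sim$map$probe_set_id == s]
    ok_all <- TRUE
    for (g in unique(sim$groups)) {
      ids <- names(sim$groups)[sim$groups == g]
      n_ok <- 0
      for (i in ids)
        if (mean(sim$intensities[probes, i]) >= thr) n_ok <- n_ok + 1
      if (n_ok / length(ids) < 0.6) ok_all <- FALSE
    }
    if (ok_all) oracle <- c(oracle, s)
  }
  expect_setequal(kept, oracle)
  expect_gt(length(kept), 0)
  expect_lt(length(kept), length(sets))
})

test_that("explicit-list filtering is the identity on the supplied list", {
  sim <- make_filter_fixture()
  pol <- expression_filter_policy("explicit_list",
                                  probe_sets = c("ps0003", "ps0001"))
  expect_setequal(select_expressed_probe_sets(sim$intensities, sim$map,
                                              sim$groups, pol),
                  c("ps0001", "ps0003"))
  bad <- expression_filter_policy("explicit_list", probe_sets = "nope")
  expect_error(select_expressed_probe_sets(sim$intensities, sim$map,
                                           sim$groups, bad),
               class = "badprobes_unknown_probe_set")
})

test_that("apply_mask with cutoff 0 is the identity", {
  sim <- make_filter_fixture()
  mask <- suppressWarnings(detect_bad(sim$intensities, sim$map, sim$groups))
  mb <- apply_mask(sim$intensities, sim$map, mask = mask, cutoff = 0)
  expect_identical(mb$intensities, sim$intensities)
  expect_identical(mb$map, sim$map)
  expect_equal(nrow(mb$removal_log), 0)
})

test_that("apply_mask enforces min_probes and logs both removal reasons", {
  m <- make_exact_batch(J = 3)
  scores <- data.frame(probe_set_id = "set1",
                       probe_id = c("pr01", "pr02", "pr03"),
                       quality_score = c(1e-6, 1e-5, 0.9),
                       elimination_rank = 1:3, stringsAsFactors = FALSE)
  mask <- badprobes:::new_bad_mask(scores)
  mb <- apply_mask(m$intensities, m$map, mask = mask, cutoff = 1e-3,
                   min_probes = 2)
  expect_equal(nrow(mb$map), 0)  # 2 of 3 probes removed, set below minimum
  expect_setequal(mb$removal_log$reason[mb$removal_log$probe_id %in%
                                          c("pr01", "pr02")], "below_cutoff")
  expect_equal(mb$removal_log$reason[mb$removal_log$probe_id == "pr03"],
               "probe_set_below_min")
  # with min_probes = 1 the surviving probe keeps its (redefined) set
  mb2 <- apply_mask(m$intensities, m$map, mask = mask, cutoff = 1e-3,
                    min_probes = 1)
  expect_equal(mb2$map$probe_id, "pr03")
})

test_that("masking is strict at the cutoff, conservative and idempotent", {
  set.seed(71)
  sim <- make_filter_fixture(seed = 73, n_sets = 8, J = 5)
  mask <- suppressWarnings(detect_bad(sim$intensities, sim$map, sim$groups))
  df <- as.data.frame(mask)
  for (cutoff in c(0, stats::quantile(df$quality_score, c(.2, .6)), 1)) {
    mb <- apply_mask(sim$intensities, sim$map, mask = mask, cutoff = cutoff)
    # direct set-filter oracle for survivors
    removed_oracle <- df[df$quality_score < cutoff, ]
    key <- paste(sim$map$probe_set_id, sim$map$probe_id)
    survivors_oracle <- sim$map[!key %in% paste(removed_oracle$probe_set_id,
                                                removed_oracle$probe_id), ]
    expect_setequal(paste(mb$map$probe_set_id, mb$map$probe_id),
                    paste(survivors_oracle$probe_set_id,
                          survivors_oracle$probe_id))
    # conservation: survivors + removals = original, per probe set
    expect_equal(nrow(mb$map) + nrow(mb$removal_log), nrow(sim$map))
    # probes at exactly the cutoff survive (strict inequality)
    at_cut <- df[df$quality_score == cutoff, ]
    if (nrow(at_cut) > 0)
      expect_true(all(paste(at_cut$probe_set_id, at_cut$probe_id) %in%
                        paste(mb$map$probe_set_id, mb$map$probe_id)))
    # idempotence
    mb2 <- apply_mask(mb$intensities, mb$map, mask = mask, cutoff = cutoff)
    expect_identical(mb2$map, mb$map)
    expect_identical(mb2$intensities, mb$intensities)
  }
  expect_error(apply_mask(sim$intensities, sim$map, mask = mask, cutoff = 2),
               "cutoff")
  expect_error(apply_mask(sim$intensities, sim$map),
               "exactly one")
})

test_that("unanalyzed probe sets pass through masking untouched", {
  sim <- make_filter_fixture(seed = 79)
  mask <- suppressWarnings(
    detect_bad(sim$intensities, sim$map, sim$groups, probe_sets = "ps0001"))
  mb <- apply_mask(sim$intensities, sim$map, mask = mask, cutoff = 1,
                   min_probes = 3)
  untouched <- sim$map[sim$map$probe_set_id != "ps0001", ]
  expect_true(all(paste(untouched$probe_set_id, untouched$probe_id) %in%
                    paste(mb$map$probe_set_id, mb$map$probe_id)))
})

test_that("expression summarization is the mean of log2 intensities", {
  m <- matrix(c(4, 16, 8, 2), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  map1 <- data.frame(probe_set_id = "g", probe_id = c("a", "b"))
  expr <- summarize_expression(m, map1)
  expect_equal(expr["g", "s1"], (log2(4) + log2(16)) / 2)  # (2+4)/2 = 3
  expect_equal(expr["g", "s1"], 3)
  map2 <- data.frame(probe_set_id = c("ga", "gb"), probe_id = c("a", "b"))
  expr2 <- summarize_expression(m, map2)
  expect_equal(expr2["ga", ], log2(m["a", ]))
  # random fixture vs independent two-pass computation
  sim <- make_filter_fixture(seed = 83)
  expr3 <- summarize_expression(sim$intensities, sim$map)
  for (s in unique(sim$map$probe_set_id)) {
    probes <- sim$map$probe_id[sim$map$probe_set_id == s]
    for (i in colnames(sim$intensities)) {
      tot <- 0
      for (p in probes) tot <- tot + log2(sim$intensities[p, i])
      expect_equal(expr3[s, i], tot / length(probes))
    }
  }
})

test_that("differential expression calls nothing on duplicated data", {
  set.seed(91)
  half <- matrix(stats::rnorm(30, 8, 1), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("a", 1:6)))
  expr <- cbind(half, half)
  colnames(expr) <- paste0("s", 1:12)
  groups <- stats::setNames(rep(c("A", "B"), each = 6), colnames(expr))
  de <- differential_expression(expr, groups)
  expect_equal(de$p_value, rep(1, 5))
  expect_false(any(de$is_DE))
})

test_that("a 4 log2-unit shift at n=10 and sigma 0.2 is declared DE", {
  set.seed(97)
  expr <- matrix(stats::rnorm(20 * 20, 8, 0.2), 20, 20,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:20)))
  groups <- stats::setNames(rep(c("A", "B"), each = 10), colnames(expr))
  expr["g01", groups == "B"] <- expr["g01", groups == "B"] + 4
  de <- differential_expression(expr, groups, alpha = 0.01)
  expect_true(de$is_DE[de$probe_set_id == "g01"])
  expect_equal(sum(de$is_DE), 1)
})

test_that("BH adjustment matches the step-up oracle and preserves order", {
  set.seed(101)
  expr <- matrix(stats::rnorm(30 * 12, 8, 1), 30, 12,
                 dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:12)))
  groups <- stats::setNames(rep(c("A", "B"), each = 6), colnames(expr))
  de <- differential_expression(expr, groups)
  expect_equal(de$adjusted_p, bh_oracle(de$p_value))
  o <- order(de$p_value)
  expect_true(all(diff(de$adjusted_p[o]) >= 0))
})
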
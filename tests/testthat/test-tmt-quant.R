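test_that("log ratios use the geometric mean of reference channels", {
  d <- one_plex_design()
  tab <- make_reporter_table(list(
    c(channel_1 = 100, channel_9 = 100, channel_10 = 100),
    c(channel_1 = 400, channel_9 = 50, channel_10 = 200),
    c(channel_1 = 100) # both references missing -> dropped
  ))
  expect_message(r <- compute_log_ratios(tab, d), "1 PSM row")
  expect_equal(attr(r, "n_dropped"), 1)
  expect_equal(nrow(r), 2)
  # 100 vs (100, 100) -> 0; 400 vs (50, 200): log2 400 - (log2 50 + log2 200)/2 = 2
  expect_equal(r[["A_trt_1"]], c(0, 2))
  # reference columns are consumed
  expect_false(any(grepl("^channel_", names(r))))
})

test_that("recursive Dixon removal matches the hand-computed Q decisions", {
  # Q = (5.0 - 1.02)/(5.0 - 0.98) = 0.990 > 0.829 -> remove 5.0;
  # then Q = 0.5 < 0.970 at n = 3 -> stop
  expect_equal(dixon_outlier_filter(c(0.98, 1.00, 1.02, 5.0)),
               c(0.98, 1.00, 1.02))
  # degenerate and guard cases
  expect_equal(dixon_outlier_filter(c(1, 1, 1)), c(1, 1, 1))
  expect_equal(dixon_outlier_filter(c(1.0, 1.2)), c(1.0, 1.2))
  expect_equal(dixon_outlier_filter(numeric()), numeric())
  # low outliers are removed from the low end
  expect_equal(dixon_outlier_filter(c(-5, 0.98, 1.00, 1.02)),
               c(0.98, 1.00, 1.02))
  # recursion can remove more than one value
  expect_equal(dixon_outlier_filter(c(1.00, 1.01, 1.02, 6, 40)),
               c(1.00, 1.01, 1.02))
  # n > 30 falls back to 3-MAD trimming
  x <- c(rnorm(40, 0, 0.1), 50)
  expect_false(50 %in% dixon_outlier_filter(x))
  expect_error(dixon_outlier_filter(c(1, 2, 3), alpha = 0.1), "alpha")
})

test_that("median rollup is idempotent and chains through Dixon removal", {
  samples <- c("s1", "s2")
  v <- matrix(c(1.0, 1.2, 0.8, 0.6), 2, 2, dimnames = list(NULL, samples))
  r <- make_ratio_table(v, peptide = "pepA", protein = "P1")
  qm <- collapse_features(r, "protein")
  expect_equal(unname(qm$values["P1", ]), c(1.1, 0.7))

  # duplicating every PSM row leaves protein values unchanged
  r2 <- make_ratio_table(v[c(1, 1, 2, 2), ], peptide = "pepA", protein = "P1")
  qm2 <- collapse_features(r2, "protein")
  expect_equal(qm2$values, qm$values)

  # Dixon inside the rollup: peptide median after removal is 1.00
  v3 <- matrix(c(0.98, 1.00, 1.02, 5.0), 4, 1, dimnames = list(NULL, "s1"))
  qm3 <- collapse_features(make_ratio_table(v3, "pepB", "P2"), "protein")
  expect_equal(unname(qm3$values["P2", "s1"]), 1.00)

  # two peptides -> protein is the median of peptide medians
  r4 <- rbind(make_ratio_table(matrix(c(1, 1), 2, 1,
                                      dimnames = list(NULL, "s1")),
                               "pepC", "P3"),
              make_ratio_table(matrix(c(3, 3), 2, 1,
                                      dimnames = list(NULL, "s1")),
                               "pepD", "P3"))
  attr(r4, "samples") <- "s1"
  expect_equal(unname(collapse_features(r4, "protein")$values["P3", "s1"]), 2)

  # site level keys features by protein_site and keeps localization
  v5 <- matrix(c(0.5, 0.7), 2, 1, dimnames = list(NULL, "s1"))
  qm5 <- collapse_features(make_ratio_table(v5, "pepE", "P4", site = "T487",
                                            loc_prob = 0.91), "site")
  expect_equal(rownames(qm5$values), "P4_T487")
  expect_equal(qm5$feature_info$loc_prob, 0.91)

  expect_equal(nrow(collapse_features(make_ratio_table(
    v5, "pepF", "P5"), "site")$values), 0)
})

test_that("mixture alignment centers the density mode and equalizes spread", {
  set.seed(41)
  # already centered: shift near 0, joint scaling leaves scale near 1
  V <- matrix(rnorm(5000 * 4), 5000, 4)
  aligned <- align_and_scale(qm_from_matrix(V))
  expect_true(all(abs(aligned$norm_report$shift) < 0.05))
  expect_true(all(aligned$norm_report$scale > 0.9 &
                    aligned$norm_report$scale < 1.1))

  # planted bulk shift of 0.2 under a contaminating component:
  # oracle = grid search for the mode of the true mixture density
  x <- c(rnorm(4000, 0.2, 0.1), rnorm(1000, 2.0, 0.3))
  g <- seq(-1, 3, length.out = 40001)
  true_mode <- g[which.max(0.8 * dnorm(g, 0.2, 0.1) + 0.2 * dnorm(g, 2, 0.3))]
  expect_lt(abs(true_mode - 0.2), 0.01)
  al <- align_and_scale(qm_from_matrix(matrix(x, ncol = 1)))
  expect_lt(abs(al$norm_report$shift - true_mode), 0.05)

  # post-alignment the re-fitted density mode is at zero
  refit <- phosflow:::fit_gmm2(al$values[, 1])
  expect_lt(abs(phosflow:::gmm2_mode(refit)), 1e-3)

  # constant column: fallback path, shift = the constant, scale = 1
  cst <- align_and_scale(qm_from_matrix(matrix(2.5, 100, 1)))
  expect_equal(cst$norm_report$method, "median_mad")
  expect_equal(cst$norm_report$shift, 2.5)
  expect_equal(cst$norm_report$scale, 1)
  expect_true(all(cst$values == 0))
})

test_that("classical MDS reproduces known configurations", {
  # three samples on a line with distances (1, 1, 2) embed at (-1, 0, 1)
  V <- matrix(0, 5, 3, dimnames = list(paste0("f", 1:5), c("a", "b", "c")))
  V[1, ] <- c(0, 1, 2)
  co <- mds_embed(qm_from_matrix(V), k = 1)
  x <- sort(co[, 1])
  expect_equal(unname(x), c(-1, 0, 1), tolerance = 1e-8)

  # identical samples embed at distance zero
  V2 <- matrix(rnorm(20), 10, 2)
  V2 <- cbind(V2, V2[, 2])
  colnames(V2) <- c("a", "b", "b2")
  co2 <- mds_embed(qm_from_matrix(V2), k = 1)
  expect_lt(abs(co2["b", 1] - co2["b2", 1]), 1e-10)

  # full-rank embedding reproduces the input distances
  set.seed(5)
  V3 <- matrix(rnorm(100), 20, 5)
  co3 <- mds_embed(qm_from_matrix(V3), k = 4)
  expect_equal(as.numeric(dist(co3)), as.numeric(dist(t(V3))),
               tolerance = 1e-8)

  expect_error(mds_embed(qm_from_matrix(V3), k = 5), "k must")
})

test_that("planted outliers are removed at high recall on synthetic PSMs", {
  # a 4-log2 shift against 0.1 log2 per-channel noise is a >30-sigma
  # excursion: Dixon should catch nearly all single outliers (only
  # same-side double outliers within one 4-PSM group can mask)
  pn <- generate_prior_network(10, 8, seed = 21)
  tr <- simulate_perturbation(pn) # null data: outlier recovery only
  d <- one_plex_design()
  rs <- generate_reporter_tables(tr, d, noise_sd = 0.1, psm_per_peptide = 4,
                                 outlier_rate = 0.05, outlier_shift = 4,
                                 missing_rate = 0, seed = 22)
  m <- dixon_removal_rates(rs, d)
  # groups with a single planted outlier: essentially always caught
  expect_gte(m$outlier_recall_single, 0.95)
  # overall recall is masking-limited: ~13% of outliers share a group
  expect_gte(m$outlier_recall, 0.8)
  # clean loss sits at the Dixon false-rejection rate (~5% of peptide
  # groups, ~1.2-1.4% of clean values at 4 PSMs/peptide)
  expect_lt(m$clean_loss, 0.02)
})
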
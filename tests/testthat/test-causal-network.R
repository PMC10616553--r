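test_that("change direction extraction respects both thresholds and nests", {
  res <- diff_tbl(c("P1_S1", "P2_S2", "P3_S3", "P4_S4"),
                  b = c(1.2, -0.9, 0.3, 2.0),
                  adj_p = c(0.0005, 0.005, 0.0001, 0.05))
  ch <- infer_change_directions(res, fdr_cutoff = 0.001)
  expect_equal(setNames(ch$sites$direction, ch$sites$site_id),
               c(P1_S1 = 1)) # P2 fails p, P3 fails |b|, P4 fails p
  expect_equal(nrow(ch$measured), 4) # the measured universe is retained

  cutoffs <- c(0.1, 0.01, 0.001, 0.0001)
  sets <- lapply(cutoffs, function(cu)
    infer_change_directions(res, fdr_cutoff = cu)$sites$site_id)
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("edge emission follows the logical equation d = sign * activity", {
  # all 8 combinations of (sigma, a, d): exactly the 4 with d = sigma * a emit
  for (sg in c(1, -1)) for (a in c(1, -1)) for (d in c(1, -1)) {
    prior <- prior_tbl("K", ifelse(sg > 0, "phosphorylates", "dephosphorylates"),
                       "T", "S5", "u")
    ch <- change_set_of(site_dirs = c(T_S5 = d), protein_dirs = c(K = a))
    net <- match_causal_relations(prior, ch)
    expect_equal(nrow(net), as.integer(d == sg * a),
                 info = sprintf("sigma=%d a=%d d=%d", sg, a, d))
  }

  # observed site must match the prior site exactly
  prior <- prior_tbl("K", "phosphorylates", "T", "S200", "u")
  ch <- change_set_of(site_dirs = c(T_S100 = 1), protein_dirs = c(K = 1))
  expect_equal(nrow(match_causal_relations(prior, ch)), 0)

  # a kinase inferred inactive from its own activatory site explains a
  # reduced target site (CDK1 -> EZH2 T487 style)
  prior <- prior_tbl(c("CAK", "CDK1"), "phosphorylates",
                     c("CDK1", "EZH2"), c("T161", "T487"), c("a", "u"))
  ch <- change_set_of(site_dirs = c(CDK1_T161 = -1, EZH2_T487 = -1))
  net <- match_causal_relations(prior, ch)
  expect_true(any(net$source == "CDK1" & net$target == "EZH2" &
                    net$site == "T487" & net$source_activity == -1))

  # contradictory evidence excludes the source
  prior2 <- prior_tbl(c("X1", "X2", "K"), c("phosphorylates",
                                            "phosphorylates", "phosphorylates"),
                      c("K", "K", "T"), c("S1", "S2", "S9"),
                      c("a", "a", "u"))
  ch2 <- change_set_of(site_dirs = c(K_S1 = 1, K_S2 = -1, T_S9 = 1))
  net2 <- match_causal_relations(prior2, ch2)
  expect_false(any(net2$source == "K"))

  # site evidence takes priority over a conflicting protein direction
  prior3 <- prior_tbl(c("X1", "K"), "phosphorylates", c("K", "T"),
                      c("S1", "S9"), c("a", "u"))
  ch3 <- change_set_of(site_dirs = c(K_S1 = 1, T_S9 = 1),
                       protein_dirs = c(K = -1))
  expect_equal(nrow(match_causal_relations(prior3, ch3)), 1)
})

test_that("causal matching equals the brute-force oracle on small networks", {
  set.seed(31)
  for (rep in 1:300) {
    inst <- random_causal_instance()
    prior <- inst$prior
    got <- match_causal_relations(prior, inst$changes)
    want <- match_oracle(prior, inst$changes)
    expect_equal(paste(got$source, got$target, got$site, got$relation),
                 paste(want$source, want$target, want$site, want$relation))
  }
})

test_that("edge set shrinks when target changes shrink (fixed evidence)", {
  set.seed(33)
  pn <- generate_prior_network(6, 8, frac_inhibitory = 0.3,
                               frac_dephospho = 0.2, seed = 34)
  ids <- phosflow:::site_id(pn$target, pn$site)
  full_dirs <- setNames(sample(c(-1, 1), nrow(pn), TRUE), ids)
  pdirs <- setNames(sample(c(-1, 1), 6, TRUE), unique(pn$source))
  ch_full <- change_set_of(site_dirs = full_dirs, protein_dirs = pdirs)
  keep <- sample(length(full_dirs), 20)
  ch_small <- change_set_of(site_dirs = full_dirs[keep], protein_dirs = pdirs)
  e_full <- match_causal_relations(pn, ch_full)
  e_small <- match_causal_relations(pn, ch_small)
  key <- function(e) paste(e$source, e$target, e$site)
  expect_true(all(key(e_small) %in% key(e_full)))
  expect_lte(nrow(e_small), nrow(e_full))
})

test_that("permutation activity p-value matches the hypergeometric tail", {
  # 50 measured sites, 10 significant (all down), protein P regulating 6 of
  # them with 4 significant: under label permutation the consistent count
  # is Hypergeom(N = 50, K = 10, n = 6); p = P(X >= 4)
  targets <- paste0("T", 1:6)
  prior <- prior_tbl("P", "phosphorylates", targets, "S1", "u")
  sig <- c(paste0("T", 1:4), paste0("N", 1:6)) # 4 targets + 6 others
  all_prot <- c(targets, paste0("N", 1:44))
  dirs <- setNames(rep(-1, 10), paste0(sig, "_S1"))
  ch <- change_set_of(site_dirs = dirs,
                      measured_extra = paste0(setdiff(all_prot, sig), "_S1"))
  expect_equal(nrow(ch$measured), 50)

  calls <- test_protein_activities(prior, ch, B = 4000, seed = 42, fdr = 0.1)
  row <- calls[calls$protein == "P", ]
  expect_equal(row$direction, "inactivated")
  expect_equal(row$n_consistent, 4)
  expect_equal(row$n_measured_targets, 6)
  p_exact <- phyper(3, 10, 40, 6, lower.tail = FALSE)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(row$p - p_exact), 3 * mc_se + 2 / 4001)

  # no measured targets -> absent from output
  prior2 <- prior_tbl("Q", "phosphorylates", "ZZ", "S9", "u")
  expect_false("Q" %in% test_protein_activities(
    rbind(prior, prior2), ch, B = 1000, seed = 1)$protein)
  expect_error(test_protein_activities(prior, ch, B = 10), "B must be")
})

test_that("fdr_sweep composes the per-cutoff operations and fills the heatmap", {
  set.seed(35)
  pn <- generate_prior_network(4, 8, seed = 36)
  ids <- phosflow:::site_id(pn$target, pn$site)
  b <- ifelse(pn$source %in% c("KIN01", "KIN02"), -1, 0.1)
  res <- diff_tbl(ids, b = b, adj_p = ifelse(abs(b) > 0.5, 1e-4, 0.5))
  res <- res[!duplicated(res$feature), ]

  sw <- fdr_sweep(res, NULL, pn, cutoffs = c(0.05), B = 1000, seed = 3)
  direct <- test_protein_activities(
    pn, infer_change_directions(res, fdr_cutoff = 0.05), B = 1000, seed = 3)
  expect_equal(sw$per_cutoff[[1]]$calls, direct, ignore_attr = TRUE)

  sw2 <- fdr_sweep(res, NULL, pn, cutoffs = c(0.1, 0.001), B = 1000, seed = 3)
  expect_equal(names(sw2$per_cutoff), c("0.100", "0.001"))
  hm <- sw2$heatmap
  called <- direct$protein[direct$called]
  expect_true(all(called %in% rownames(hm)))
  # signed log10 adjusted p: inactivated proteins are negative entries
  ca <- sw2$per_cutoff[[1]]$calls
  for (p in rownames(hm)) {
    v <- hm[p, 1]
    if (!is.na(v)) {
      r <- ca[ca$protein == p, ]
      expect_equal(v, ifelse(r$direction == "activated", 1, -1) *
                     log10(r$adj_p))
    }
  }
  expect_error(fdr_sweep(res, NULL, pn, cutoffs = numeric()), "non-empty")
})

test_that("subgraph extraction is a breadth-first neighborhood", {
  net <- match_causal_relations(
    prior_tbl(c("PRKCA", "MARCKS"), "phosphorylates",
              c("MARCKS", "X"), c("S159", "S1"), c("u", "u")),
    change_set_of(site_dirs = c(MARCKS_S159 = 1, X_S1 = 1),
                  protein_dirs = c(PRKCA = 1, MARCKS = 1)))
  expect_equal(nrow(net), 2)
  sub1 <- extract_subgraph(net, "PRKCA", radius = 1)
  expect_equal(sort(unique(c(sub1$source, sub1$target))),
               c("MARCKS", "PRKCA"))
  expect_equal(nrow(sub1), 1)
  sub0 <- extract_subgraph(net, "PRKCA", radius = 0)
  expect_equal(nrow(sub0), 0) # no edge lies fully within {PRKCA}
  expect_warning(sub_none <- extract_subgraph(net, "NOPE", radius = 2),
                 "not in network")
  expect_equal(nrow(sub_none), 0)
})

test_that("network serialization round-trips byte-identically", {
  net <- match_causal_relations(
    prior_tbl("CDK1", "phosphorylates", "EZH2", "T487", "u"),
    change_set_of(site_dirs = c(EZH2_T487 = -1), protein_dirs = c(CDK1 = -1)))
  expect_equal(nrow(net), 1)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "net1")
  write_network(net, p1)
  expect_equal(readLines(paste0(p1, ".sif")),
               "CDK1\tphosphorylates\tEZH2")
  back <- read_network(p1)
  p2 <- file.path(dir, "net2")
  write_network(back, p2)
  expect_identical(readLines(paste0(p2, "_edges.tsv")),
                   readLines(paste0(p1, "_edges.tsv")))
  expect_identical(readLines(paste0(p2, ".sif")), readLines(paste0(p1, ".sif")))

  # empty network: empty SIF, header-only attribute files
  p3 <- file.path(dir, "net3")
  write_network(net[0, ], p3)
  expect_equal(length(readLines(paste0(p3, ".sif"))), 0)
  expect_equal(length(readLines(paste0(p3, "_edges.tsv"))), 1)
  back3 <- read_network(p3)
  expect_equal(nrow(back3), 0)
})
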
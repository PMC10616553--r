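#' Moderated two-sample t-statistics per feature
#'
#' For each feature, the treated-vs-vehicle contrast within one cell line:
#' `b = mean(treated) - mean(vehicle)`, pooled residual variance `s2` with
#' `d` degrees of freedom, and empirical-Bayes variance moderation
#' `s2_post = (d0*s0^2 + d*s2)/(d0 + d)`. The prior `(d0, s0^2)` is
#' estimated from the distribution of all per-feature `s2` by moment
#' matching on `log(s2)` against the scaled-F distribution
#' ([limma::fitFDist()]); `t = b / (s_post * sqrt(c))` with design constant
#' `c = 1/n_t + 1/n_v`, and p-values come from a t-distribution on
#' `d0 + d` degrees of freedom. Features with fewer than 2 complete
#' replicates in either condition are skipped (counted in attribute
#' `n_skipped`).
#'
#' @param qm A `quant_matrix` whose samples belong to one cell line.
#' @param design A [study_design()] (used for sample -> condition mapping).
#' @param d0,s02 Optional explicit prior degrees of freedom and prior
#'   variance, overriding estimation: `d0 = 0` gives the ordinary pooled
#'   t-test, `d0 = Inf` fully shrinks to `s0^2`.
#' @return Tibble (class `diff_result`): feature, level, protein, site,
#'   loc_prob, b, se, df, df_prior, s2_prior, t, p, adj_p.
#' @export
fit_moderated_t <- function(qm, design, d0 = NULL, s02 = NULL) {
  stopifnot(inherits(qm, "quant_matrix"))
  smp <- design_samples(design)
  smp <- smp[smp$sample %in% colnames(qm$values), ]
  trt <- smp$sample[smp$condition == "treated"]
  veh <- smp$sample[smp$condition == "vehicle"]
  if (!length(trt) || !length(veh))
    stop("design does not identify treated and vehicle samples among the matrix columns")
  Vt <- qm$values[, trt, drop = FALSE]
  Vv <- qm$values[, veh, drop = FALSE]

  nt <- rowSums(!is.na(Vt)); nv <- rowSums(!is.na(Vv))
  ok <- nt >= 2 & nv >= 2
  n_skipped <- sum(!ok)

  mt <- rowMeans(Vt, na.rm = TRUE); mv <- rowMeans(Vv, na.rm = TRUE)
  b <- mt - mv
  sst <- rowSums((Vt - mt)^2, na.rm = TRUE)
  ssv <- rowSums((Vv - mv)^2, na.rm = TRUE)
  d <- nt + nv - 2
  s2 <- (sst + ssv) / d
  cc <- 1 / nt + 1 / nv

  est <- ok & d > 0 & s2 > 0
  if (is.null(d0) || is.null(s02)) {
    if (sum(est) < 2)
      stop("too few features with positive residual variance to estimate the variance prior")
    fd <- limma::fitFDist(s2[est], d[est])
    d0 <- d0 %||% fd$df2
    s02 <- s02 %||% fd$scale
  }
  s2_post <- if (is.infinite(d0)) rep(s02, length(s2))
             else (d0 * s02 + d * s2) / (d0 + d)
  tt <- b / sqrt(s2_post * cc)
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(tt), df_total)

  out <- tibble::tibble(
    feature = rownames(qm$values), level = qm$level,
    protein = qm$feature_info$protein, site = qm$feature_info$site,
    loc_prob = qm$feature_info$loc_prob,
    b = unname(b), se = unname(sqrt(s2_post * cc)), df = unname(df_total),
    df_prior = d0, s2_prior = s02, t = unname(tt), p = unname(p)
  )[ok, ]
  out$adj_p <- bh_adjust(out$p)
  attr(out, "n_skipped") <- n_skipped
  class(out) <- c("diff_result", class(out))
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validates that p-values lie in [0, 1] and applies the BH step-up
#' procedure (monotone, tie-preserving, order-preserving).
#'
#' @param pvalues Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Adjust phosphosite fold-changes for parent-protein abundance
#'
#' Subtracts the protein-level estimate from each site-level estimate
#' (`b_adj = b_site - b_protein`), propagates the standard error
#' (`se = sqrt(se_site^2 + se_protein^2)`), combines degrees of freedom by
#' Satterthwaite's approximation, recomputes t/p and re-applies BH. Sites
#' whose parent protein lacks protein-level quantification are removed and
#' counted in attribute `n_removed_no_protein`.
#'
#' @param site_results,protein_results `diff_result` tibbles from
#'   [fit_moderated_t()] at site and protein level.
#' @return Adjusted site-level `diff_result`.
#' @export
adjust_phospho_for_protein <- function(site_results, protein_results) {
  idx <- match(site_results$protein, protein_results$feature)
  has <- !is.na(idx)
  n_removed <- sum(!has)
  if (n_removed) message(n_removed, " site(s) removed: no protein-level quantification")
  out <- site_results[has, ]
  pr <- protein_results[idx[has], ]

  b <- out$b - pr$b
  se <- sqrt(out$se^2 + pr$se^2)
  df <- se^4 / (out$se^4 / out$df + pr$se^4 / pr$df)
  tt <- b / se
  out$b <- b; out$se <- se; out$df <- df; out$t <- tt
  out$p <- 2 * stats::pt(-abs(tt), df)
  out$adj_p <- bh_adjust(out$p)
  attr(out, "n_removed_no_protein") <- n_removed
  out
}

#' Significance filter configuration
#'
#' Defaults: BH FDR 0.05; absolute log2 fold-change above
#' `log2fc_threshold(50)` = 0.58 (a +/-50\% fold change, chosen because MS2
#' TMT quantification compresses ratios); phosphosites additionally require
#' localization probability >= 0.75 and protein-level quantification.
#'
#' @param fdr_threshold BH-adjusted p-value cutoff.
#' @param abs_log2fc_threshold Absolute log2FC cutoff (strict inequality).
#' @param min_localization_probability Minimum site localization
#'   probability.
#' @param require_protein_quant Drop sites lacking protein quantification.
#' @return A `filter_config` list.
#' @export
filter_config <- function(fdr_threshold = 0.05,
                          abs_log2fc_threshold = log2fc_threshold(50),
                          min_localization_probability = 0.75,
                          require_protein_quant = TRUE) {
  stopifnot(fdr_threshold > 0, abs_log2fc_threshold > 0,
            min_localization_probability > 0)
  structure(list(fdr_threshold = fdr_threshold,
                 abs_log2fc_threshold = abs_log2fc_threshold,
                 min_localization_probability = min_localization_probability,
                 require_protein_quant = require_protein_quant),
            class = "filter_config")
}

#' Apply significance filters and build the volcano table
#'
#' Site-level rows failing the localization-probability filter (or, when
#' required, lacking protein quantification, as recorded by
#' [adjust_phospho_for_protein()]) are removed before testing and BH is
#' recomputed on the survivors. A feature is significant iff
#' `adj_p < fdr_threshold` and `|b| > abs_log2fc_threshold`; its direction
#' is `sign(b)` when significant and 0 otherwise (non-significant features
#' carry no direction into the causal analysis).
#'
#' @param results A `diff_result` tibble.
#' @param cfg A [filter_config()].
#' @return List with `results` (filtered tibble + `significant`,
#'   `direction` columns), `volcano` (feature, b, neg_log10_adj_p,
#'   significant) and `n_filtered` (named removal counts).
#' @export
apply_significance_filters <- function(results, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  res <- results
  n_loc <- 0L
  if (any(res$level == "site")) {
    bad_loc <- res$level == "site" & !is.na(res$loc_prob) &
      res$loc_prob < cfg$min_localization_probability
    n_loc <- sum(bad_loc)
    res <- res[!bad_loc, ]
    if (n_loc) res$adj_p <- bh_adjust(res$p)
  }
  sig <- res$adj_p < cfg$fdr_threshold &
    abs(res$b) > cfg$abs_log2fc_threshold
  res$significant <- sig
  res$direction <- ifelse(sig, sign(res$b), 0)
  volcano <- tibble::tibble(feature = res$feature, b = res$b,
                            neg_log10_adj_p = -log10(res$adj_p),
                            significant = sig)
  list(results = res, volcano = volcano,
       n_filtered = c(low_localization = n_loc))
}
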
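#' PSM-level log2 ratios against the in-plex reference channels
#'
#' Converts reporter-ion intensities to log2 ratios relative to the average
#' reference reporter intensity of the same PSM: for each sample channel,
#' `log2(intensity) - mean(log2(reference intensities))` (the geometric mean
#' of the references on the raw scale). Reference columns are consumed; rows
#' without at least one positive reference intensity are dropped and
#' counted.
#'
#' @param table A reporter table (one plex) as produced by
#'   [generate_reporter_tables()] or [read_reporter_table()].
#' @param design A [study_design()] mapping plex channels to samples.
#' @return Tibble with columns plex, psm, peptide, protein, site, loc_prob,
#'   ref_intensity (mean reference intensity of the row) and one log2-ratio
#'   column per non-reference sample. Attribute `n_dropped` counts removed
#'   rows.
#' @examples
#' # sample 400 against references 50 and 200:
#' # log2(400) - (log2(50) + log2(200))/2 = 2
#' @export
compute_log_ratios <- function(table, design) {
  stopifnot(inherits(design, "study_design"))
  px <- unique(table$plex)
  stopifnot(length(px) == 1)
  drows <- design[design$plex == px, ]
  if (!nrow(drows)) stop("plex ", px, " not in design")
  chan_col <- function(ch) paste0("channel_", ch)
  ref_ch <- drows$channel[drows$condition == "reference"]
  smp <- drows[drows$condition != "reference", ]

  refM <- as.matrix(table[, chan_col(ref_ch), drop = FALSE])
  refM[!is.na(refM) & refM <= 0] <- NA
  ref_log <- rowMeans(log2(refM), na.rm = TRUE)
  keep <- rowSums(!is.na(refM)) >= 1
  n_dropped <- sum(!keep)
  if (n_dropped) message(n_dropped, " PSM row(s) dropped: no usable reference intensity")

  smpM <- as.matrix(table[keep, chan_col(smp$channel), drop = FALSE])
  smpM[!is.na(smpM) & smpM <= 0] <- NA
  ratios <- log2(smpM) - ref_log[keep]
  colnames(ratios) <- smp$sample

  out <- cbind(
    table[keep, intersect(c("plex", "psm", "peptide", "protein", "site",
                            "loc_prob"), names(table))],
    tibble::tibble(ref_intensity = rowMeans(refM[keep, , drop = FALSE],
                                            na.rm = TRUE)),
    tibble::as_tibble(ratios)
  )
  attr(out, "n_dropped") <- n_dropped
  attr(out, "samples") <- smp$sample
  out
}

# Two-sided Dixon r10 (Q test) critical values, alpha = 0.05, n = 3..30.
.dixon_q05 <- c(
  0.970, 0.829, 0.710, 0.625, 0.568, 0.526, 0.493, 0.466, # n = 3..10
  0.444, 0.426, 0.410, 0.396, 0.384, 0.374, 0.365, 0.356, # n = 11..18
  0.349, 0.342, 0.337, 0.331, 0.326, 0.321, 0.317, 0.312, # n = 19..26
  0.308, 0.305, 0.301, 0.298)                             # n = 27..30

# Logical keep-mask version of the recursive Dixon filter.
dixon_keep <- function(x, alpha = 0.05) {
  keep <- !is.na(x)
  repeat {
    idx <- which(keep)
    n <- length(idx)
    if (n < 3) break
    if (n > 30) { # beyond the table: trim by robust z-score
      v <- x[idx]
      md <- stats::median(v); s <- stats::mad(v)
      if (s == 0) break
      z <- abs(v - md) / s
      if (max(z) <= 3) break
      keep[idx[which.max(z)]] <- FALSE
      next
    }
    v <- x[idx]
    o <- order(v)
    vs <- v[o]
    rng <- vs[n] - vs[1]
    if (rng == 0) break
    q_low <- (vs[2] - vs[1]) / rng
    q_high <- (vs[n] - vs[n - 1]) / rng
    q <- max(q_low, q_high)
    if (q <= .dixon_q05[n - 2]) break
    drop_pos <- if (q_high >= q_low) o[n] else o[1]
    keep[idx[drop_pos]] <- FALSE
  }
  keep
}

#' Recursive Dixon outlier removal
#'
#' Repeatedly applies Dixon's Q test (r10 statistic, two-sided alpha = 0.05
#' critical values) to the most extreme remaining value, removing it while
#' `Q = gap/range` exceeds the critical value for the current n, and
#' stopping when no rejection occurs or fewer than 3 values remain. Inputs
#' with fewer than 3 values, or zero range, are returned unchanged. For
#' n > 30 (beyond the tabulated critical values) values further than 3 MADs
#' from the median are trimmed instead.
#'
#' @param values Numeric vector of log2 ratios (NAs ignored and preserved
#'   out of the test).
#' @param alpha Significance level; only the tabulated 0.05 is supported.
#' @return The retained values, in input order.
#' @examples
#' dixon_outlier_filter(c(0.98, 1.00, 1.02, 5.0)) # drops 5.0
#' @export
dixon_outlier_filter <- function(values, alpha = 0.05) {
  if (!identical(alpha, 0.05))
    stop("only alpha = 0.05 is supported (tabulated critical values)")
  values[dixon_keep(values, alpha) & !is.na(values)]
}

#' Roll PSM ratios up to peptide, then protein or phosphosite medians
#'
#' Within each sample: PSM log2 ratios belonging to the same peptide are
#' filtered by recursive Dixon removal (peptides with more than two PSMs)
#' and summarized by their median; peptide values are then summarized by
#' their median per protein (level `"protein"`, non-phospho peptides) or
#' per phosphosite (level `"site"`, phosphopeptides). A feature is missing
#' in a sample when no PSM contributes.
#'
#' @param ratios PSM ratio table from [compute_log_ratios()], or a list of
#'   them (plexes are concatenated; sample columns are the union).
#' @param level `"protein"` or `"site"`.
#' @param dixon Apply recursive Dixon removal at the PSM->peptide step.
#' @return A `quant_matrix`: list with `values` (features x samples),
#'   `intensity` (mean reference intensity rolled up the same way),
#'   `feature_info` (feature, protein, site, loc_prob), `samples`, `level`.
#' @export
collapse_features <- function(ratios, level = c("protein", "site"),
                              dixon = TRUE) {
  level <- match.arg(level)
  if (is.data.frame(ratios)) ratios <- list(ratios)
  samples <- unique(unlist(lapply(ratios, attr, "samples")))

  parts <- lapply(ratios, function(r) {
    is_phos <- !is.na(r$site)
    r <- r[if (level == "site") is_phos else !is_phos, , drop = FALSE]
    r
  })
  parts <- parts[vapply(parts, nrow, 1L) > 0]
  if (!length(parts)) {
    return(empty_quant_matrix(level, samples))
  }

  pepM_list <- list(); meta_list <- list()
  for (r in parts) {
    scols <- intersect(attr(r, "samples") %||% samples, names(r))
    M <- as.matrix(r[, scols, drop = FALSE])
    groups <- split(seq_len(nrow(r)), r$peptide)
    pepM <- matrix(NA_real_, length(groups), length(samples),
                   dimnames = list(names(groups), samples))
    meta <- data.frame(peptide = names(groups), protein = NA_character_,
                       site = NA_character_, loc_prob = NA_real_,
                       ref_intensity = NA_real_, stringsAsFactors = FALSE)
    for (gi in seq_along(groups)) {
      idx <- groups[[gi]]
      sub <- M[idx, , drop = FALSE]
      pepM[gi, scols] <- apply(sub, 2, function(v) {
        if (dixon) v <- v[dixon_keep(v)]
        v <- v[!is.na(v)]
        if (length(v)) stats::median(v) else NA_real_
      })
      meta$protein[gi] <- r$protein[idx[1]]
      if (level == "site") meta$site[gi] <- r$site[idx[1]]
      if ("loc_prob" %in% names(r)) meta$loc_prob[gi] <- r$loc_prob[idx[1]]
      meta$ref_intensity[gi] <- stats::median(r$ref_intensity[idx], na.rm = TRUE)
    }
    pepM_list[[length(pepM_list) + 1L]] <- pepM
    meta_list[[length(meta_list) + 1L]] <- meta
  }
  pepM <- do.call(rbind, pepM_list)
  meta <- do.call(rbind, meta_list)

  key <- if (level == "site") site_id(meta$protein, meta$site) else meta$protein
  fgroups <- split(seq_along(key), key)
  feats <- names(fgroups)
  values <- matrix(NA_real_, length(feats), length(samples),
                   dimnames = list(feats, samples))
  inten <- values
  info <- data.frame(feature = feats, protein = NA_character_,
                     site = NA_character_, loc_prob = NA_real_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(feats)) {
    idx <- fgroups[[i]]
    sub <- pepM[idx, , drop = FALSE]
    values[i, ] <- apply(sub, 2, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
    inten[i, ] <- stats::median(meta$ref_intensity[idx], na.rm = TRUE)
    info$protein[i] <- meta$protein[idx[1]]
    info$site[i] <- meta$site[idx[1]]
    info$loc_prob[i] <- suppressWarnings(max(meta$loc_prob[idx], na.rm = TRUE))
    if (!is.finite(info$loc_prob[i])) info$loc_prob[i] <- NA_real_
  }
  new_quant_matrix(values, inten, info, level)
}

new_quant_matrix <- function(values, intensity, feature_info, level,
                             norm_report = NULL) {
  structure(list(values = values, intensity = intensity,
                 feature_info = feature_info, samples = colnames(values),
                 level = level, norm_report = norm_report),
            class = "quant_matrix")
}

empty_quant_matrix <- function(level, samples = character()) {
  m <- matrix(NA_real_, 0, length(samples),
              dimnames = list(character(), samples))
  new_quant_matrix(m, m, data.frame(feature = character(),
                                    protein = character(),
                                    site = character(), loc_prob = numeric()),
                   level)
}

#' @export
print.quant_matrix <- function(x, ...) {
  cat(sprintf("quant_matrix [%s]: %d features x %d samples (%.1f%% missing)%s\n",
              x$level, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values)),
              if (!is.null(x$norm_report)) ", normalized" else ""))
  invisible(x)
}

# ---- two-component Gaussian mixture ----------------------------------------

# EM fit of a two-component univariate Gaussian mixture.
# Init: means at the 25th/90th percentiles; tol on log-likelihood. The
# sigma floor scales with the data spread (never below 1e-3): mixture
# likelihoods are unbounded as a component variance shrinks onto a single
# observation, and a near-zero floor lets such a spike own the density
# mode, so components narrower than 5% of the sample SD are disallowed.
fit_gmm2 <- function(x, tol = 1e-8, maxit = 500, sigma_floor = NULL) {
  x <- x[!is.na(x)]
  n <- length(x)
  sigma_floor <- sigma_floor %||% max(1e-3, 0.05 * stats::sd(x))
  mu <- stats::quantile(x, c(0.25, 0.90), names = FALSE)
  s <- rep(max(stats::sd(x) / 2, sigma_floor), 2)
  pi1 <- 0.5
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    d1 <- pi1 * stats::dnorm(x, mu[1], s[1])
    d2 <- (1 - pi1) * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    g <- d1 / tot
    pi1 <- mean(g)
    if (pi1 < 1e-8 || pi1 > 1 - 1e-8) break
    mu[1] <- sum(g * x) / sum(g)
    mu[2] <- sum((1 - g) * x) / sum(1 - g)
    s[1] <- max(sqrt(sum(g * (x - mu[1])^2) / sum(g)), sigma_floor)
    s[2] <- max(sqrt(sum((1 - g) * (x - mu[2])^2) / sum(1 - g)), sigma_floor)
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(pi = pi1, mu = mu, sigma = s, converged = converged)
}

gmm2_density <- function(fit) {
  function(z) fit$pi * stats::dnorm(z, fit$mu[1], fit$sigma[1]) +
    (1 - fit$pi) * stats::dnorm(z, fit$mu[2], fit$sigma[2])
}

# Global mode of the fitted mixture density: dense grid over
# [min(mu) - 4*max(sigma), max(mu) + 4*max(sigma)], then golden-section
# refinement in the bracketing cell (a single golden-section search can
# land on the minor mode of a bimodal density).
gmm2_mode <- function(fit, grid_n = 2001) {
  f <- gmm2_density(fit)
  lo <- min(fit$mu) - 4 * max(fit$sigma)
  hi <- max(fit$mu) + 4 * max(fit$sigma)
  g <- seq(lo, hi, length.out = grid_n)
  i <- which.max(f(g))
  lo2 <- g[max(1, i - 1)]; hi2 <- g[min(grid_n, i + 1)]
  if (lo2 == hi2) return(g[i])
  stats::optimize(f, c(lo2, hi2), maximum = TRUE)$maximum
}

#' Mixture-based mode alignment and trimmed scaling normalization
#'
#' Per sample, fits a two-component Gaussian mixture to the log2 ratios by
#' EM and subtracts the global mode of the fitted density, so the maximum
#' of the likelihood sits at zero. All samples are then jointly scaled:
#' each sample's SD is computed on values lying within both the 5th-95th
#' percentile of its log-ratios and the 5th-95th percentile of the feature
#' reference intensities (trimming damps the influence of outliers in
#' either dimension), and each sample is divided by its trimmed SD relative
#' to the geometric mean of all samples' trimmed SDs, equalizing spread
#' across samples without changing the overall scale. Samples with fewer
#' than `min_n` values, zero spread, or a non-converged EM fall back to
#' median centering and unit scale, recorded in the report.
#'
#' @param qm A `quant_matrix` from [collapse_features()].
#' @param min_n Minimum non-missing values per sample for mixture fitting.
#' @return The `quant_matrix` with transformed values and a `norm_report`
#'   tibble (sample, shift, scale, pi, mu1, mu2, sigma1, sigma2, method).
#' @export
align_and_scale <- function(qm, min_n = 30) {
  stopifnot(inherits(qm, "quant_matrix"))
  V <- qm$values
  rep_rows <- vector("list", ncol(V))
  for (j in seq_len(ncol(V))) {
    x <- V[, j]
    obs <- x[!is.na(x)]
    fb <- length(obs) < min_n || stats::sd(obs) < 1e-12
    fit <- NULL
    if (!fb) {
      fit <- fit_gmm2(obs)
      if (!fit$converged) fb <- TRUE
    }
    if (fb) {
      shift <- if (length(obs)) stats::median(obs) else 0
      method <- "median_mad"
    } else {
      shift <- gmm2_mode(fit)
      method <- "gmm_mode"
    }
    V[, j] <- x - shift
    rep_rows[[j]] <- tibble::tibble(
      sample = colnames(V)[j], shift = shift, scale = NA_real_,
      method = method,
      pi = if (!fb) fit$pi else NA_real_,
      mu1 = if (!fb) fit$mu[1] else NA_real_,
      mu2 = if (!fb) fit$mu[2] else NA_real_,
      sigma1 = if (!fb) fit$sigma[1] else NA_real_,
      sigma2 = if (!fb) fit$sigma[2] else NA_real_)
  }
  report <- do.call(rbind, rep_rows)

  # trimmed SD per sample: values inside both 5-95% of ratios and intensities
  trimmed_sd <- rep(NA_real_, ncol(V))
  for (j in seq_len(ncol(V))) {
    v <- V[, j]; inten <- qm$intensity[, j]
    ok <- !is.na(v)
    if (sum(ok) < 3) next
    qv <- stats::quantile(v[ok], c(0.05, 0.95))
    keep <- ok & v >= qv[1] & v <= qv[2]
    if (any(!is.na(inten))) {
      qi <- stats::quantile(inten[ok], c(0.05, 0.95), na.rm = TRUE)
      keep <- keep & !is.na(inten) & inten >= qi[1] & inten <= qi[2]
    }
    s <- stats::sd(v[keep])
    if (is.finite(s) && s > 1e-12) trimmed_sd[j] <- s
  }
  # equalize spread across samples, preserving overall scale
  gm <- exp(mean(log(trimmed_sd[!is.na(trimmed_sd)])))
  sc <- ifelse(is.na(trimmed_sd) | !is.finite(gm), 1, trimmed_sd / gm)
  V <- sweep(V, 2, sc, "/")
  report$scale <- sc

  out <- qm
  out$values <- V
  out$norm_report <- report
  out
}

#' Classical metric MDS embedding of samples
#'
#' Euclidean distances between samples over complete-case features, then
#' classical (Torgerson) multidimensional scaling via [stats::cmdscale()].
#' Coordinates are defined up to sign and rotation.
#'
#' @param qm A `quant_matrix`.
#' @param k Embedding dimension, at most `n_samples - 1`.
#' @return Matrix of sample coordinates (samples x k).
#' @export
mds_embed <- function(qm, k = 2) {
  stopifnot(inherits(qm, "quant_matrix"))
  n <- ncol(qm$values)
  if (k >= n || k < 1) stop("k must satisfy 1 <= k <= n_samples - 1")
  cc <- stats::complete.cases(qm$values)
  if (!any(cc)) stop("no complete-case features for distance computation")
  d <- stats::dist(t(qm$values[cc, , drop = FALSE]))
  coords <- stats::cmdscale(d, k = k)
  if (ncol(coords) < k) { # rank-deficient configurations pad with zeros
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  }
  rownames(coords) <- colnames(qm$values)
  coords
}

#' Measure Dixon outlier-removal performance on synthetic data
#'
#' Replays the PSM -> peptide Dixon step on a generated `reporter_set` and
#' cross-references every removed value with the planted-outlier record:
#' recall = fraction of planted outlier cells removed; clean loss =
#' fraction of clean (non-outlier, observed) cells removed.
#'
#' Recall is also reported restricted to groups containing exactly one
#' planted outlier (`outlier_recall_single`): the r10 statistic tests the
#' single most extreme value, so two gross outliers inside one
#' peptide-sample group mask each other (a same-side pair leaves no gap, an
#' opposite-side pair doubles the range) — a known limitation of Dixon-type
#' tests, not an implementation artifact.
#'
#' @param rs A `reporter_set` from [generate_reporter_tables()].
#' @param design The matching [study_design()].
#' @return List with `outlier_recall`, `outlier_recall_single`,
#'   `clean_loss`, `n_outliers`, `n_clean`.
#' @export
dixon_removal_rates <- function(rs, design) {
  stopifnot(inherits(rs, "reporter_set"))
  removed <- list()
  n_clean <- 0L
  pep_of <- list()
  for (tab in rs$tables) {
    r <- compute_log_ratios(tab, design)
    scols <- attr(r, "samples")
    pep_of[[as.character(r$plex[1])]] <-
      stats::setNames(r$peptide, r$psm)
    groups <- split(seq_len(nrow(r)), r$peptide)
    for (idx in groups) {
      for (s in scols) {
        v <- r[[s]][idx]
        keep <- dixon_keep(v)
        out <- idx[!keep & !is.na(v)]
        if (length(out))
          removed[[length(removed) + 1L]] <- data.frame(
            plex = r$plex[1], psm = r$psm[out], sample = s)
      }
    }
    n_clean <- n_clean + sum(!is.na(r[, scols]))
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(plex = integer(), psm = integer(), sample = character())
  key <- function(d) paste(d$plex, d$psm, d$sample)
  out_key <- key(rs$outliers)
  rem_key <- key(removed)
  n_out <- length(out_key)
  n_clean <- n_clean - n_out
  hit <- rem_key %in% out_key
  # group planted outliers by (plex, peptide, sample) to find singletons
  out_pep <- vapply(seq_len(nrow(rs$outliers)), function(i)
    pep_of[[as.character(rs$outliers$plex[i])]][[
      as.character(rs$outliers$psm[i])]], "")
  gkey <- paste(rs$outliers$plex, out_pep, rs$outliers$sample)
  single <- gkey %in% names(which(table(gkey) == 1))
  rec_single <- if (any(single))
    mean(out_key[single] %in% rem_key) else NA_real_
  list(outlier_recall = if (n_out) sum(hit) / n_out else NA_real_,
       outlier_recall_single = rec_single,
       clean_loss = (nrow(removed) - sum(hit)) / n_clean,
       n_outliers = n_out, n_clean = n_clean)
}
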
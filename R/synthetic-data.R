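#' Generate a signed, site-specific prior kinase-substrate network
#'
#' Builds a synthetic prior of the kind curated pathway databases provide:
#' each relation says that a kinase (or phosphatase) source
#' phosphorylates/dephosphorylates a specific residue of a target protein,
#' and whether that site is activatory or inhibitory for the target.
#' Site positions are unique within each target protein and the
#' (source, target, site, relation) quadruple is unique in the network.
#'
#' @param n_kinases Number of source proteins.
#' @param targets_per_kinase Relations emitted per source.
#' @param frac_inhibitory Probability that a target site is inhibitory
#'   (effect `"i"`); the remainder are activatory (`"a"`).
#' @param frac_dephospho Probability that a relation is a dephosphorylation.
#' @param frac_unknown Probability that a site's effect is unannotated
#'   (`"u"`); drawn before the inhibitory/activatory split.
#' @param target_pool Number of distinct substrate proteins to draw targets
#'   from; defaults to `ceiling(n_kinases * targets_per_kinase / 1.5)` so
#'   some substrates are shared between kinases.
#' @param seed Integer seed; identical arguments give identical networks.
#' @return A `prior_network`: tibble with columns `source`, `relation`
#'   (`"phosphorylates"`/`"dephosphorylates"`), `target`, `site` (e.g.
#'   `"T487"`), `effect` (`"a"`/`"i"`/`"u"`).
#' @examples
#' pn <- generate_prior_network(5, 10, frac_inhibitory = 0.2, seed = 1)
#' nrow(pn) # 50
#' @export
generate_prior_network <- function(n_kinases, targets_per_kinase,
                                   frac_inhibitory = 0.2,
                                   frac_dephospho = 0,
                                   frac_unknown = 0,
                                   target_pool = NULL, seed = 1) {
  if (n_kinases < 0 || targets_per_kinase < 0)
    stop("counts must be non-negative")
  stopifnot(frac_inhibitory >= 0, frac_inhibitory <= 1,
            frac_dephospho >= 0, frac_dephospho <= 1,
            frac_unknown >= 0, frac_unknown <= 1)
  n_rel <- n_kinases * targets_per_kinase
  if (n_rel == 0) {
    out <- tibble::tibble(source = character(), relation = character(),
                          target = character(), site = character(),
                          effect = character())
    class(out) <- c("prior_network", class(out))
    return(out)
  }
  target_pool <- target_pool %||% max(1L, ceiling(n_rel / 1.5))
  with_seed(seed, {
    kin <- sprintf("KIN%02d", seq_len(n_kinases))
    subs <- sprintf("SUB%03d", seq_len(target_pool))
    src <- rep(kin, each = targets_per_kinase)
    # per kinase, targets are distinct substrates
    tgt <- unlist(lapply(seq_len(n_kinases), function(i)
      sample(subs, targets_per_kinase, replace = targets_per_kinase > target_pool)))
    relation <- ifelse(stats::runif(n_rel) < frac_dephospho,
                       "dephosphorylates", "phosphorylates")
    u <- stats::runif(n_rel)
    effect <- ifelse(u < frac_unknown, "u",
              ifelse(stats::runif(n_rel) < frac_inhibitory, "i", "a"))
    residue <- sample(c("S", "T", "Y"), n_rel, replace = TRUE,
                      prob = c(0.6, 0.3, 0.1))
    # unique positions within each target protein
    pos <- integer(n_rel)
    for (p in unique(tgt)) {
      idx <- which(tgt == p)
      pos[idx] <- sample(seq_len(2000), length(idx))
    }
    out <- tibble::tibble(source = src, relation = relation, target = tgt,
                          site = paste0(residue, pos), effect = effect)
  })
  out <- unique(out)
  class(out) <- c("prior_network", class(out))
  out
}

# +1 for phosphorylation, -1 for dephosphorylation
relation_sign <- function(relation) {
  ifelse(relation == "dephosphorylates", -1L, 1L)
}

# +1 activatory, -1 inhibitory, 0 unknown
effect_sign <- function(effect) {
  ifelse(effect == "a", 1L, ifelse(effect == "i", -1L, 0L))
}

site_id <- function(protein, site) paste(protein, site, sep = "_")

#' Write / read a prior network (tab-delimited relations)
#'
#' Columns: source, relation (phosphorylates|dephosphorylates), target,
#' site (e.g. T487), effect (a|i|u).
#'
#' @param network A `prior_network`.
#' @param path File path.
#' @return `read_prior_network` returns a `prior_network`.
#' @export
write_prior_network <- function(network, path) {
  write_tsv(as.data.frame(network), path)
}

#' @rdname write_prior_network
#' @export
read_prior_network <- function(path) {
  out <- tibble::as_tibble(read_tsv(path, colClasses = "character"))
  need <- c("source", "relation", "target", "site", "effect")
  if (!all(need %in% names(out)))
    stop("prior network file must have columns: ", paste(need, collapse = ", "))
  bad <- !grepl("^[STY][0-9]+$", out$site)
  if (any(bad)) stop("malformed site(s): ", paste(out$site[bad], collapse = ", "))
  class(out) <- c("prior_network", class(out))
  out
}

#' Plant kinase activity perturbations on a prior network
#'
#' Defines the simulation ground truth: each perturbed kinase `k` has an
#' activity direction `a(k)` of +1 (activated) or -1 (inhibited), and every
#' site it regulates is expected to change by `sign(relation) * a(k) * delta`
#' log2 units; sites of unperturbed kinases have expected change 0. If a
#' site is regulated by several perturbed kinases, contributions add.
#'
#' @param network A `prior_network`.
#' @param perturbed Named numeric vector of kinase activities in
#'   \{-1, +1\} (names must be sources in `network`); may be empty.
#' @param effect_size Effect size `delta` in log2 units (>= 0).
#' @return A `ground_truth` object: list with `activities` (named vector
#'   over all kinases, 0 = unperturbed), `effect_size`, and `sites`, a
#'   tibble of every prior target site with its expected log2 fold-change.
#' @examples
#' pn <- generate_prior_network(3, 4, seed = 1)
#' tr <- simulate_perturbation(pn, c(KIN01 = -1), effect_size = 1)
#' @export
simulate_perturbation <- function(network, perturbed = numeric(),
                                  effect_size = 1) {
  stopifnot(effect_size >= 0)
  kn <- unique(network$source)
  if (length(perturbed)) {
    if (is.null(names(perturbed)) || any(!nzchar(names(perturbed))))
      stop("'perturbed' must be a named vector")
    unknown <- setdiff(names(perturbed), kn)
    if (length(unknown))
      stop("unknown kinase(s): ", paste(unknown, collapse = ", "))
    stopifnot(all(perturbed %in% c(-1, 1)))
  }
  act <- stats::setNames(numeric(length(kn)), kn)
  act[names(perturbed)] <- perturbed
  sg <- relation_sign(network$relation)
  contrib <- sg * act[network$source] * effect_size
  agg <- stats::aggregate(contrib,
                          by = list(target = network$target, site = network$site),
                          FUN = sum)
  sites <- tibble::tibble(
    target = agg$target, site = agg$site,
    site_id = site_id(agg$target, agg$site),
    expected_log2fc = agg$x
  )
  sites <- sites[order(sites$site_id), ]
  structure(list(activities = act, effect_size = effect_size, sites = sites),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground truth: %d kinases (%d perturbed), %d target sites, delta = %g\n",
              length(x$activities), sum(x$activities != 0), nrow(x$sites),
              x$effect_size))
  invisible(x)
}

#' Simulate TMT reporter-ion tables with planted ground truth
#'
#' Generates one PSM-level reporter table per plex with the statistical
#' structure the downstream pipeline assumes. Each phosphosite maps to one
#' peptide of its target protein; each protein additionally gets
#' `peptides_per_protein` non-phospho peptides so protein-level rollup and
#' protein-abundance adjustment are exercised. Every peptide is observed as
#' `psm_per_peptide` PSM rows. Per-feature baseline abundances are
#' log-normal (log2 mean 20, sd 2); the planted treatment effect is added to
#' treated channels of perturbed plexes only; reference channels are the
#' within-plex geometric mean of the sample channels plus channel noise
#' (emulating a pooled reference aliquot). Gross outliers are planted as
#' additive +/-`outlier_shift` on single log2 intensities of sample
#' channels; missing values blank single sample-channel cells. Localization
#' probabilities for phosphopeptides are drawn 90\% from U(0.9, 1] and 10\%
#' from U(0.3, 0.75) so the localization filter is exercised.
#'
#' @param truth A `ground_truth` from [simulate_perturbation()].
#' @param design A [study_design()].
#' @param noise_sd Per-measurement log2 noise SD (> 0).
#' @param psm_per_peptide PSMs observed per peptide.
#' @param peptides_per_protein Non-phospho peptides per protein.
#' @param outlier_rate Fraction of sample-channel cells receiving a gross
#'   outlier shift (in [0, 1)).
#' @param outlier_shift Outlier magnitude in log2 units.
#' @param missing_rate Fraction of sample-channel cells set missing.
#' @param seed Integer seed.
#' @return A `reporter_set`: list with `tables` (one tibble per plex with
#'   columns plex, psm, peptide, protein, site, loc_prob,
#'   channel_1..channel_K), `design`, `truth_table` (feature-level expected
#'   log2FC per plex), `outliers` and `missing` (coordinates of planted
#'   artifacts).
#' @export
generate_reporter_tables <- function(truth, design = study_design(),
                                     noise_sd = 0.3, psm_per_peptide = 3,
                                     peptides_per_protein = 3,
                                     outlier_rate = 0.02, outlier_shift = 4,
                                     missing_rate = 0.02, seed = 1) {
  stopifnot(inherits(truth, "ground_truth"), inherits(design, "study_design"))
  if (length(unique(design$plex)) < 1) stop("design must contain >= 1 plex")
  stopifnot(noise_sd > 0, psm_per_peptide >= 1,
            outlier_rate >= 0, outlier_rate < 1,
            missing_rate >= 0, missing_rate < 1)

  sites <- truth$sites
  proteins <- sort(unique(sites$target))
  # feature table: phosphosites + protein peptides
  pep_site <- tibble::tibble(
    peptide = paste0("pep_", sites$site_id),
    protein = sites$target, site = sites$site,
    is_phospho = TRUE, expected = sites$expected_log2fc
  )
  pep_prot <- tibble::tibble(
    peptide = paste0("pep_", rep(proteins, each = peptides_per_protein), "_p",
                     rep(seq_len(peptides_per_protein), length(proteins))),
    protein = rep(proteins, each = peptides_per_protein),
    site = NA_character_, is_phospho = FALSE, expected = 0
  )
  peps <- rbind(pep_site, pep_prot)

  plexes <- unique(design$plex)
  with_seed(seed, {
    loc <- ifelse(stats::runif(nrow(peps)) < 0.9,
                  stats::runif(nrow(peps), 0.9, 1.0),
                  stats::runif(nrow(peps), 0.3, 0.75))
    peps$loc_prob <- ifelse(peps$is_phospho, round(loc, 3), NA_real_)
    base <- stats::rnorm(nrow(peps), mean = 20, sd = 2) # log2 abundance

    tables <- vector("list", length(plexes))
    out_rec <- list(); mis_rec <- list()
    for (pi in seq_along(plexes)) {
      px <- plexes[pi]
      drows <- design[design$plex == px, ]
      perturbed <- drows$perturbed[1]
      samp <- drows[drows$condition != "reference", ]
      refs <- drows[drows$condition == "reference", ]
      n_s <- nrow(samp); n_r <- nrow(refs)

      n_psm <- nrow(peps) * psm_per_peptide
      pep_idx <- rep(seq_len(nrow(peps)), each = psm_per_peptide)
      psm_off <- stats::rnorm(n_psm, 0, 0.5) # ionization variability per PSM
      mu <- base[pep_idx] + psm_off
      eff <- if (perturbed) peps$expected[pep_idx] else 0

      L <- matrix(mu, n_psm, n_s) +
        matrix(rep(ifelse(samp$condition == "treated", 1, 0), each = n_psm) *
                 eff, n_psm, n_s) +
        matrix(stats::rnorm(n_psm * n_s, 0, noise_sd), n_psm, n_s)
      # reference = geometric mean of (clean) sample channels + channel noise
      Lref <- matrix(rowMeans(L), n_psm, n_r) +
        matrix(stats::rnorm(n_psm * n_r, 0, noise_sd), n_psm, n_r)

      # gross outliers on sample channels
      ol <- matrix(stats::runif(n_psm * n_s) < outlier_rate, n_psm, n_s)
      if (any(ol)) {
        sgn <- sample(c(-1, 1), sum(ol), replace = TRUE)
        L[ol] <- L[ol] + sgn * outlier_shift
        w <- which(ol, arr.ind = TRUE)
        out_rec[[length(out_rec) + 1L]] <- tibble::tibble(
          plex = px, psm = w[, 1], sample = samp$sample[w[, 2]],
          shift = sgn * outlier_shift)
      }
      # missingness on sample channels only (reference stays observed)
      mis <- matrix(stats::runif(n_psm * n_s) < missing_rate, n_psm, n_s)
      L[mis] <- NA
      if (any(mis)) {
        w <- which(mis, arr.ind = TRUE)
        mis_rec[[length(mis_rec) + 1L]] <- tibble::tibble(
          plex = px, psm = w[, 1], sample = samp$sample[w[, 2]])
      }

      inten <- cbind(2^L, 2^Lref)
      chan <- c(samp$channel, refs$channel)
      inten <- inten[, order(chan), drop = FALSE]
      colnames(inten) <- paste0("channel_", sort(chan))
      tab <- tibble::tibble(
        plex = px, psm = seq_len(n_psm),
        peptide = peps$peptide[pep_idx], protein = peps$protein[pep_idx],
        site = peps$site[pep_idx], loc_prob = peps$loc_prob[pep_idx]
      )
      tables[[pi]] <- cbind(tab, tibble::as_tibble(inten))
    }
  })

  truth_table <- do.call(rbind, lapply(plexes, function(px) {
    perturbed <- design$perturbed[design$plex == px][1]
    tibble::tibble(
      plex = px,
      feature = c(sites$site_id, proteins),
      level = c(rep("site", nrow(sites)), rep("protein", length(proteins))),
      expected_log2fc = c(if (perturbed) sites$expected_log2fc
                          else rep(0, nrow(sites)),
                          rep(0, length(proteins)))
    )
  }))
  structure(list(
    tables = tables, design = design, truth_table = truth_table,
    outliers = if (length(out_rec)) do.call(rbind, out_rec) else
      tibble::tibble(plex = integer(), psm = integer(),
                     sample = character(), shift = numeric()),
    missing = if (length(mis_rec)) do.call(rbind, mis_rec) else
      tibble::tibble(plex = integer(), psm = integer(), sample = character()),
    params = list(noise_sd = noise_sd, psm_per_peptide = psm_per_peptide,
                  peptides_per_protein = peptides_per_protein,
                  outlier_rate = outlier_rate, outlier_shift = outlier_shift,
                  missing_rate = missing_rate, seed = seed)
  ), class = "reporter_set")
}

#' @export
print.reporter_set <- function(x, ...) {
  cat(sprintf("reporter set: %d plex(es), %d PSM rows/plex, %d planted outliers, %d missing cells\n",
              length(x$tables), nrow(x$tables[[1]]), nrow(x$outliers),
              nrow(x$missing)))
  invisible(x)
}

#' Write reporter tables and the truth file as TSV
#'
#' One `plex_<i>.tsv` per plex (columns plex, peptide, protein, site,
#' loc_prob, channel_1..channel_K; missing = empty field), plus
#' `truth.tsv` with every planted expected change.
#'
#' @param rs A `reporter_set`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_reporter_tables <- function(rs, dir) {
  stopifnot(inherits(rs, "reporter_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (i in seq_along(rs$tables)) {
    t <- rs$tables[[i]]
    p <- file.path(dir, sprintf("plex_%d.tsv", t$plex[1]))
    write_tsv(t[, setdiff(names(t), "psm")], p)
    paths <- c(paths, p)
  }
  tp <- file.path(dir, "truth.tsv")
  write_tsv(rs$truth_table, tp)
  invisible(c(paths, tp))
}

#' Read a single reporter table TSV
#' @param path Path to a plex TSV written by [write_reporter_tables()].
#' @return Tibble in reporter-table layout (a `psm` row index is added).
#' @export
read_reporter_table <- function(path) {
  t <- tibble::as_tibble(read_tsv(path))
  if (!all(c("plex", "peptide", "protein") %in% names(t)))
    stop("not a reporter table: ", path)
  t$psm <- seq_len(nrow(t))
  t[, c("plex", "psm", setdiff(names(t), c("plex", "psm")))]
}
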
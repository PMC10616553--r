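# Shared fixture builders. Everything is generated in code; no data files.

# A single-plex design: 4 treated + 4 vehicle + 2 reference channels.
one_plex_design <- function(cell_line = "A", perturbed = TRUE) {
  study_design(cell_lines = cell_line, perturbed = perturbed)
}

# Reporter table with explicit channel intensities, one row per list entry.
# Each entry: named list/vector channel_1..channel_10 (NA allowed).
make_reporter_table <- function(rows, peptide = "pep1", protein = "P1",
                                site = NA_character_, loc_prob = NA_real_) {
  n <- length(rows)
  chans <- paste0("channel_", 1:10)
  M <- do.call(rbind, lapply(rows, function(r) {
    v <- rep(NA_real_, 10)
    names(v) <- chans
    v[names(r)] <- unlist(r)
    v
  }))
  cbind(
    tibble::tibble(plex = 1L, psm = seq_len(n),
                   peptide = rep_len(peptide, n),
                   protein = rep_len(protein, n),
                   site = rep_len(site, n),
                   loc_prob = rep_len(loc_prob, n)),
    tibble::as_tibble(M)
  )
}

# PSM-ratio table in the layout compute_log_ratios() emits, built directly.
# values: matrix PSMs x samples of log2 ratios.
make_ratio_table <- function(values, peptide, protein,
                             site = NA_character_, loc_prob = NA_real_,
                             ref_intensity = 1000) {
  samples <- colnames(values)
  out <- cbind(
    tibble::tibble(plex = 1L, psm = seq_len(nrow(values)),
                   peptide = rep_len(peptide, nrow(values)),
                   protein = rep_len(protein, nrow(values)),
                   site = rep_len(site, nrow(values)),
                   loc_prob = rep_len(loc_prob, nrow(values)),
                   ref_intensity = rep_len(ref_intensity, nrow(values))),
    tibble::as_tibble(values)
  )
  attr(out, "samples") <- samples
  out
}

# quant_matrix wrapper around a plain values matrix.
qm_from_matrix <- function(values, level = "protein", intensity = NULL,
                           loc_prob = NA_real_) {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- paste0("f", seq_len(nrow(values)))
  if (is.null(intensity))
    intensity <- matrix(1000, nrow(values), ncol(values),
                        dimnames = dimnames(values))
  info <- data.frame(feature = rownames(values),
                     protein = sub("_[STY][0-9]+$", "", rownames(values)),
                     site = ifelse(grepl("_[STY][0-9]+$", rownames(values)),
                                   sub("^.*_([STY][0-9]+)$", "\\1",
                                       rownames(values)), NA_character_),
                     loc_prob = loc_prob, stringsAsFactors = FALSE)
  phosflow:::new_quant_matrix(values, intensity, info, level)
}

# Design whose sample names are s1..s8: 4 treated then 4 vehicle, for use
# with qm_from_matrix defaults.
plain_design8 <- function() {
  d <- study_design(cell_lines = "X")
  d$sample[d$condition != "reference"] <- paste0("s", 1:8)
  d
}

# Hand-built prior network tibble.
prior_tbl <- function(source, relation, target, site, effect) {
  out <- tibble::tibble(source = source, relation = relation,
                        target = target, site = site, effect = effect)
  class(out) <- c("prior_network", class(out))
  out
}

# Hand-built change set.
change_set_of <- function(site_dirs = numeric(), protein_dirs = numeric(),
                          measured_extra = character(), fdr = 0.1) {
  sid <- names(site_dirs) %||% character()
  split_id <- function(x) {
    m <- regmatches(x, regexec("^(.*)_([STY][0-9]+)$", x))
    list(protein = vapply(m, `[`, "", 2), site = vapply(m, `[`, "", 3))
  }
  sp <- split_id(sid)
  sites <- tibble::tibble(protein = sp$protein, site = sp$site,
                          site_id = sid, direction = unname(site_dirs))
  all_ids <- c(sid, measured_extra)
  ap <- split_id(all_ids)
  measured <- tibble::tibble(protein = ap$protein, site = ap$site,
                             site_id = all_ids,
                             direction = c(unname(site_dirs),
                                           rep(0, length(measured_extra))))
  proteins <- tibble::tibble(protein = names(protein_dirs) %||% character(),
                             direction = unname(protein_dirs))
  structure(list(sites = sites, proteins = proteins, measured = measured,
                 fdr_cutoff = fdr), class = "change_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal diff_result-shaped tibble for causal-stage tests.
diff_tbl <- function(feature, b, adj_p, level = "site",
                     loc_prob = 0.95) {
  m <- regmatches(feature, regexec("^(.*?)(_([STY][0-9]+))?$", feature))
  tibble::tibble(
    feature = feature, level = level,
    protein = vapply(m, `[`, "", 2),
    site = ifelse(level == "site", vapply(m, `[`, "", 4), NA_character_),
    loc_prob = ifelse(level == "site", loc_prob, NA_real_),
    b = b, se = 0.1, df = 10, df_prior = 4, s2_prior = 0.01,
    t = b / 0.1, p = adj_p, adj_p = adj_p)
}
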
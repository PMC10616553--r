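#' Significant change directions at an FDR cutoff
#'
#' Extracts the change directions that enter causal analysis: features with
#' `adj_p < fdr_cutoff` and `|b| > abs_log2fc_threshold` get direction
#' `sign(b)`; everything else is absent. The set of all measured sites
#' (significant or not) is retained, because the label-randomization
#' activity test permutes labels over the full measured universe.
#'
#' @param site_results Site-level `diff_result` (after protein adjustment
#'   and filtering, typically `apply_significance_filters(...)$results`).
#' @param protein_results Optional protein-level `diff_result` supplying
#'   total-protein abundance directions.
#' @param fdr_cutoff Adjusted-p cutoff for calling a change.
#' @param abs_log2fc_threshold Absolute log2FC cutoff.
#' @return A `change_set`: list with `sites` (tibble protein, site,
#'   site_id, direction), `proteins` (tibble protein, direction),
#'   `measured` (tibble of all measured sites with direction, 0 when not
#'   significant) and `fdr_cutoff`.
#' @export
infer_change_directions <- function(site_results, protein_results = NULL,
                                    fdr_cutoff = 0.1,
                                    abs_log2fc_threshold = log2fc_threshold(50)) {
  stopifnot(fdr_cutoff > 0)
  sig <- site_results$adj_p < fdr_cutoff &
    abs(site_results$b) > abs_log2fc_threshold
  measured <- tibble::tibble(
    protein = site_results$protein, site = site_results$site,
    site_id = site_results$feature,
    direction = ifelse(sig, sign(site_results$b), 0))
  sites <- measured[measured$direction != 0, ]
  proteins <- tibble::tibble(protein = character(), direction = numeric())
  if (!is.null(protein_results)) {
    psig <- protein_results$adj_p < fdr_cutoff &
      abs(protein_results$b) > abs_log2fc_threshold
    proteins <- tibble::tibble(
      protein = protein_results$feature[psig],
      direction = sign(protein_results$b[psig]))
  }
  structure(list(sites = sites, proteins = proteins, measured = measured,
                 fdr_cutoff = fdr_cutoff), class = "change_set")
}

#' @export
print.change_set <- function(x, ...) {
  cat(sprintf("change set @ FDR %g: %d significant sites (%d up, %d down), %d protein changes, %d measured sites\n",
              x$fdr_cutoff, nrow(x$sites), sum(x$sites$direction > 0),
              sum(x$sites$direction < 0), nrow(x$proteins),
              nrow(x$measured)))
  invisible(x)
}

# Inferred activity direction of each potential source protein.
# Evidence: the protein's own changed sites that are annotated
# activatory/inhibitory targets in the prior give a = effect * direction;
# a significant total-protein change gives a = its sign. Site evidence
# takes priority over protein evidence; contradictory evidence excludes
# the protein. Returns a named vector over evidenced proteins (+1/-1).
infer_source_activities <- function(prior, changes) {
  acts <- numeric(0)
  sources <- unique(prior$source)
  eff <- effect_sign(prior$effect)
  pr_site <- site_id(prior$target, prior$site)
  dir_of <- stats::setNames(changes$sites$direction, changes$sites$site_id)
  pdir <- stats::setNames(changes$proteins$direction, changes$proteins$protein)
  for (s in sources) {
    rel <- which(prior$target == s & eff != 0)
    ev <- numeric(0)
    if (length(rel)) {
      hit <- pr_site[rel] %in% names(dir_of)
      if (any(hit))
        ev <- eff[rel[hit]] * dir_of[pr_site[rel[hit]]]
    }
    if (!length(ev) && s %in% names(pdir)) ev <- pdir[[s]]
    ev <- unique(ev[ev != 0])
    if (length(ev) == 1) acts[s] <- ev
  }
  acts
}

#' Match prior relations to observed changes (causal edges)
#'
#' Emits a causal edge for a prior relation source -> target@site iff
#' (i) the exact target site (residue + position) changed significantly,
#' (ii) the source's activity direction `a` is evidenced (by its own
#' activatory/inhibitory site changes, with priority, or else its
#' total-protein change; contradictory evidence excludes the source), and
#' (iii) the target direction satisfies the logical consistency condition
#' `d = sign(relation) * a` (phosphorylation by an active kinase explains
#' an up site, dephosphorylation by an active phosphatase explains a down
#' site, and so on).
#'
#' @param prior A `prior_network`.
#' @param changes A `change_set`.
#' @return A `causal_network`: tibble source, relation, target, site,
#'   effect, source_activity, target_direction.
#' @export
match_causal_relations <- function(prior, changes) {
  acts <- infer_source_activities(prior, changes)
  dir_of <- stats::setNames(changes$sites$direction, changes$sites$site_id)
  pr_site <- site_id(prior$target, prior$site)

  a <- acts[prior$source]
  d <- dir_of[pr_site]
  sg <- relation_sign(prior$relation)
  emit <- !is.na(a) & !is.na(d) & d == sg * a
  out <- tibble::tibble(
    source = prior$source[emit], relation = prior$relation[emit],
    target = prior$target[emit], site = prior$site[emit],
    effect = prior$effect[emit],
    source_activity = unname(a[emit]), target_direction = unname(d[emit]))
  class(out) <- c("causal_network", class(out))
  out
}

#' Label-randomization test of protein activities
#'
#' For every protein with at least one measured prior target site and each
#' hypothesized activity direction `a` in \{+1, -1\}, the observed
#' statistic is the number of measured target sites whose direction
#' satisfies `d = sign(relation) * a`. The null distribution is built by
#' randomly permuting the direction labels over all measured sites (B
#' draws, preserving the global counts of up/down/unchanged labels);
#' `p = (#\{null >= observed\} + 1)/(B + 1)`. Activation and inactivation
#' are tested separately, BH-adjusted together, and each protein is
#' reported once with its smaller adjusted p (ties broken toward the larger
#' supporting target set). Calls are made at `adj_p < fdr`.
#'
#' @param prior A `prior_network`.
#' @param changes A `change_set` (supplies both labels and the measured
#'   universe).
#' @param B Number of label permutations (>= 1000).
#' @param seed Integer seed for the permutation generator.
#' @param fdr Adjusted-p threshold for an activity call (0.1, the
#'   conventional second-stage threshold).
#' @param collapse Report one row per protein (the default). With
#'   `collapse = FALSE` both direction hypotheses are returned per protein,
#'   which is what calibration diagnostics need (the per-protein minimum is
#'   a selected statistic and is not uniform under the null).
#' @return An `activity_calls` tibble: protein, direction ("activated" /
#'   "inactivated"), n_consistent, n_measured_targets, p, adj_p, called,
#'   plus null tie counts (n_null_gt, n_null_eq) for calibration
#'   diagnostics. Attribute `B` and `seed` record the run.
#' @export
test_protein_activities <- function(prior, changes, B = 10000, seed = 1,
                                    fdr = 0.1, collapse = TRUE) {
  if (B < 1000) stop("B must be >= 1000")
  measured <- changes$measured
  if (!nrow(measured))
    return(empty_activity_calls(B, seed))
  labels <- measured$direction
  msite <- measured$site_id
  pr_site <- site_id(prior$target, prior$site)
  in_meas <- pr_site %in% msite
  sg <- relation_sign(prior$relation)

  rows <- list()
  with_seed(seed, {
    perm <- matrix(0L, length(labels), B)
    for (bb in seq_len(B)) perm[, bb] <- sample(labels)
    for (prot in unique(prior$source)) {
      rel <- which(prior$source == prot & in_meas)
      if (!length(rel)) next
      tgt_idx <- match(pr_site[rel], msite)
      for (a in c(1, -1)) {
        want <- sg[rel] * a
        obs <- sum(labels[tgt_idx] == want)
        nullv <- colSums(perm[tgt_idx, , drop = FALSE] ==
                           matrix(want, length(rel), B))
        n_gt <- sum(nullv > obs); n_eq <- sum(nullv == obs)
        p <- (n_gt + n_eq + 1) / (B + 1)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          protein = prot,
          direction = if (a > 0) "activated" else "inactivated",
          n_consistent = obs, n_measured_targets = length(rel),
          p = p, n_null_gt = n_gt, n_null_eq = n_eq)
      }
    }
  })
  if (!length(rows)) return(empty_activity_calls(B, seed))
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  if (collapse) {
    # one row per protein: smaller adjusted p, ties -> larger target support
    out <- out[order(out$protein, out$adj_p, -out$n_consistent), ]
    out <- out[!duplicated(out$protein), ]
  }
  out$called <- out$adj_p < fdr
  out <- out[order(out$adj_p, out$protein), ]
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("activity_calls", class(out))
  out
}

empty_activity_calls <- function(B, seed) {
  out <- tibble::tibble(protein = character(), direction = character(),
                        n_consistent = integer(),
                        n_measured_targets = integer(), p = numeric(),
                        n_null_gt = integer(), n_null_eq = integer(),
                        adj_p = numeric(), called = logical())
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  class(out) <- c("activity_calls", class(out))
  out
}

#' Causal analysis across an FDR sweep
#'
#' Repeats change detection, causal matching, and the activity test at each
#' change-detection FDR cutoff (conventionally 0.1 down to 0.0001; the
#' activity test itself stays at FDR `activity_fdr`). Stricter cutoffs can
#' produce *more* activity calls, because cleaner up/down labels sharpen
#' the permutation null; no monotonicity is assumed. Also returns the
#' heatmap matrix of `sign(direction) * log10(adj_p)` per called-anywhere
#' protein per cutoff.
#'
#' @param site_results,protein_results `diff_result` tibbles.
#' @param prior A `prior_network`.
#' @param cutoffs Change-detection FDR cutoffs (non-empty; sorted
#'   descending internally).
#' @param B,seed Permutation settings for [test_protein_activities()].
#' @param activity_fdr FDR threshold of the activity test.
#' @param abs_log2fc_threshold Fold-change threshold for change detection.
#' @return List with `per_cutoff` (named list of `list(changes, network,
#'   calls)`) and `heatmap` (proteins x cutoffs matrix of signed log10
#'   adjusted p for called proteins; NA where not called).
#' @export
fdr_sweep <- function(site_results, protein_results = NULL, prior,
                      cutoffs = c(0.1, 0.01, 0.001, 0.0001),
                      B = 10000, seed = 1, activity_fdr = 0.1,
                      abs_log2fc_threshold = log2fc_threshold(50)) {
  if (!length(cutoffs)) stop("cutoff list must be non-empty")
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  per <- lapply(cutoffs, function(cu) {
    ch <- infer_change_directions(site_results, protein_results, cu,
                                  abs_log2fc_threshold)
    net <- match_causal_relations(prior, ch)
    calls <- test_protein_activities(prior, ch, B = B, seed = seed,
                                     fdr = activity_fdr)
    list(changes = ch, network = net, calls = calls)
  })
  names(per) <- format(cutoffs, scientific = FALSE, trim = TRUE)

  called <- unique(unlist(lapply(per, function(x)
    x$calls$protein[x$calls$called])))
  hm <- matrix(NA_real_, length(called), length(cutoffs),
               dimnames = list(called, names(per)))
  for (j in seq_along(per)) {
    ca <- per[[j]]$calls
    ca <- ca[ca$called & ca$protein %in% called, ]
    if (nrow(ca))
      hm[ca$protein, j] <- ifelse(ca$direction == "activated", 1, -1) *
        log10(ca$adj_p)
  }
  list(per_cutoff = per, heatmap = hm)
}

#' Neighborhood subgraph of a causal network
#'
#' Induced subgraph of all nodes within `radius` undirected hops of any of
#' the given genes.
#'
#' @param net A `causal_network`.
#' @param genes Gene symbols of interest; absent genes warn and contribute
#'   nothing.
#' @param radius Hop count (>= 0).
#' @return The induced `causal_network`.
#' @export
extract_subgraph <- function(net, genes, radius = 1) {
  stopifnot(radius >= 0)
  nodes <- unique(c(net$source, net$target))
  absent <- setdiff(genes, nodes)
  if (length(absent))
    warning("gene(s) not in network: ", paste(absent, collapse = ", "))
  genes <- intersect(genes, nodes)
  if (!length(genes) || !nrow(net)) {
    out <- net[0, ]
    class(out) <- class(net)
    return(out)
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$source, to = net$target), directed = FALSE,
    vertices = nodes)
  keep_nodes <- unique(unlist(lapply(
    igraph::ego(g, order = radius, nodes = genes), names)))
  out <- net[net$source %in% keep_nodes & net$target %in% keep_nodes, ]
  class(out) <- class(net)
  out
}

#' Write / read a causal network (SIF + attribute tables)
#'
#' Writes `<prefix>.sif` (source TAB relation TAB target), an edge
#' attribute TSV (`<prefix>_edges.tsv`: site, relation sign, site effect,
#' source activity, target direction) and a node attribute TSV
#' (`<prefix>_nodes.tsv`: activity direction and signed log10 adjusted p
#' when `calls` are supplied). `read_network()` round-trips the edges:
#' write -> read -> write is byte-identical.
#'
#' @param net A `causal_network`.
#' @param prefix Output path prefix.
#' @param calls Optional `activity_calls` for node attributes.
#' @return Invisibly, the written paths; `read_network` returns a
#'   `causal_network`.
#' @export
write_network <- function(net, prefix, calls = NULL) {
  sif <- file.path(paste0(prefix, ".sif"))
  writeLines(if (nrow(net))
    paste(net$source, net$relation, net$target, sep = "\t") else character(),
    sif)
  edges <- data.frame(
    source = net$source, relation = net$relation, target = net$target,
    site = net$site, effect = net$effect,
    source_activity = net$source_activity,
    target_direction = net$target_direction, stringsAsFactors = FALSE)
  ep <- paste0(prefix, "_edges.tsv")
  write_tsv(edges, ep)
  np <- paste0(prefix, "_nodes.tsv")
  nodes <- data.frame(node = unique(c(net$source, net$target)),
                      stringsAsFactors = FALSE)
  if (!is.null(calls) && nrow(calls) && nrow(nodes)) {
    i <- match(nodes$node, calls$protein)
    nodes$activity <- calls$direction[i]
    nodes$signed_log10_adj_p <- ifelse(
      is.na(i), NA,
      ifelse(calls$direction[i] == "activated", 1, -1) * log10(calls$adj_p[i]))
  } else {
    nodes$activity <- rep(NA_character_, nrow(nodes))
    nodes$signed_log10_adj_p <- rep(NA_real_, nrow(nodes))
  }
  write_tsv(nodes, np)
  invisible(c(sif, ep, np))
}

#' @rdname write_network
#' @param prefix Path prefix used by [write_network()].
#' @export
read_network <- function(prefix) {
  ep <- paste0(prefix, "_edges.tsv")
  e <- read_tsv(ep, colClasses = c(
    source = "character", relation = "character", target = "character",
    site = "character", effect = "character", source_activity = "numeric",
    target_direction = "numeric"))
  out <- tibble::as_tibble(e)
  class(out) <- c("causal_network", class(out))
  out
}
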
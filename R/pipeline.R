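#' Default pipeline configuration
#'
#' Assembles the configuration of a full synthetic run: study design,
#' prior-network and perturbation parameters, generator noise model,
#' significance filters, causal FDR sweep and permutation settings. All
#' randomness derives from `seed`. Any element can be overridden via
#' `...` (nested lists are replaced wholesale).
#'
#' @param seed Master integer seed.
#' @param ... Named overrides of top-level config entries.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, ...) {
  cfg <- list(
    mode = "synthetic",
    seed = seed,
    design = list(cell_lines = c("UM1", "UM2", "BRAF1"),
                  n_treated = 4, n_vehicle = 4, n_reference = 2,
                  perturbed = c(TRUE, TRUE, FALSE)),
    prior = list(n_kinases = 20, targets_per_kinase = 10,
                 frac_inhibitory = 0.2, frac_dephospho = 0.1),
    perturbation = list(kinases = c("KIN01", "KIN02", "KIN03", "KIN04",
                                    "KIN05"),
                        activity = -1, effect_size = 1),
    generator = list(noise_sd = 0.3, psm_per_peptide = 3,
                     peptides_per_protein = 3, outlier_rate = 0.02,
                     outlier_shift = 4, missing_rate = 0.02),
    filters = list(fdr_threshold = 0.05, min_localization_probability = 0.75,
                   require_protein_quant = TRUE),
    causal = list(cutoffs = c(0.1, 0.01, 0.001, 0.0001), B = 10000,
                  activity_fdr = 0.1),
    enrichment = list(w = 0.75, B = 1000),
    paths = list(reporter_dir = NULL, prior = NULL, signatures = NULL)
  )
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  do.call(pipeline_config, c(list(seed = raw$seed %||% 1),
                             raw[setdiff(names(raw), "seed")]))
}

# Kinase signature sets derived from a prior network: each kinase's targets,
# annotated "u" when activation of the kinase raises the site
# (phosphorylation) and "d" when it lowers it (dephosphorylation).
signatures_from_prior <- function(prior, min_size = 3) {
  sets <- lapply(split(seq_len(nrow(prior)), prior$source), function(idx) {
    mem <- tibble::tibble(
      site_id = site_id(prior$target[idx], prior$site[idx]),
      direction = ifelse(prior$relation[idx] == "phosphorylates", "u", "d"))
    mem <- mem[!duplicated(mem$site_id), ]
    structure(list(name = paste0("KINASE_", prior$source[idx[1]]),
                   category = "kinase", members = mem),
              class = "signature_set")
  })
  sets[vapply(sets, function(s) nrow(s$members), 1L) >= min_size]
}

#' Run the full pipeline
#'
#' Orchestrates generate -> quantify -> test -> infer -> enrich as a
#' seeded, logged run and writes every artifact (quant matrices,
#' normalization report, MDS coordinates, differential tables, volcano
#' tables, per-cutoff networks and activity calls, heatmap matrix,
#' enrichment tables, cross-cell-line overlap sets, run manifest) under
#' `outdir`. Each cell line is analyzed as an independent sub-run; overlap
#' sets report significant changes shared between cell lines in the same
#' direction. Every output table carries the config hash in a header
#' comment; the manifest records versions, seeds and the verbatim config.
#' On error, files created by the partial run are removed.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @param stages Last stage to run: one of `"simulate"`, `"quant"`,
#'   `"diff"`, `"causal"`, `"enrich"`, `"all"` (stages are cumulative).
#' @return Invisibly, a list of in-memory results per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = "phosflow_run",
                         stages = "all") {
  stopifnot(inherits(config, "pipeline_config"))
  stage_order <- c("simulate", "quant", "diff", "causal", "enrich")
  last <- if (identical(stages, "all")) "enrich" else match.arg(stages, stage_order)
  run_to <- match(last, stage_order)

  created <- !dir.exists(outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  on_fail <- function(e) {
    if (created) unlink(outdir, recursive = TRUE) else file.remove(
      written[file.exists(written)])
    stop(e)
  }
  tryCatch({
    cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                 digits = NA, null = "null")
    cfg_path <- file.path(outdir, "config.json")
    writeLines(cfg_json, cfg_path)
    written <- c(written, cfg_path)
    hash <- unname(tools::md5sum(cfg_path))
    hdr <- paste0("config_hash: ", hash)
    emit <- function(x, name, extra = character()) {
      p <- file.path(outdir, name)
      write_tsv(x, p, comments = c(hdr, extra))
      written <<- c(written, p)
      p
    }

    design <- do.call(study_design, config$design)
    res <- list(design = design)

    ## --- simulate -------------------------------------------------------
    if (config$mode == "synthetic") {
      prior <- do.call(generate_prior_network,
                       c(config$prior, list(seed = config$seed)))
      truth <- simulate_perturbation(
        prior,
        stats::setNames(rep(config$perturbation$activity,
                            length(config$perturbation$kinases)),
                        config$perturbation$kinases),
        config$perturbation$effect_size)
      rs <- do.call(generate_reporter_tables,
                    c(list(truth = truth, design = design,
                           seed = config$seed + 1), config$generator))
      message(sprintf("[simulate] %d relations, %d perturbed kinases, %d plexes, %d PSM rows/plex",
                      nrow(prior), sum(truth$activities != 0),
                      length(rs$tables), nrow(rs$tables[[1]])))
      sim_dir <- file.path(outdir, "synthetic")
      written <- c(written, write_reporter_tables(rs, sim_dir))
      pp <- file.path(sim_dir, "prior.tsv")
      write_prior_network(prior, pp)
      written <- c(written, pp)
      tables <- rs$tables
    } else {
      if (is.null(config$paths$prior))
        stop("config field 'paths$prior' is required in non-synthetic mode")
      if (is.null(config$paths$reporter_dir))
        stop("config field 'paths$reporter_dir' is required in non-synthetic mode")
      if (!file.exists(config$paths$prior))
        stop("missing input: ", config$paths$prior)
      prior <- read_prior_network(config$paths$prior)
      tfs <- list.files(config$paths$reporter_dir, pattern = "^plex_.*\\.tsv$",
                        full.names = TRUE)
      if (!length(tfs))
        stop("missing input: no plex_*.tsv under ", config$paths$reporter_dir)
      tables <- lapply(tfs, read_reporter_table)
      truth <- NULL
    }
    res$prior <- prior
    if (run_to < 2) return(invisible(res))

    ## --- quant ----------------------------------------------------------
    ratios <- lapply(tables, compute_log_ratios, design = design)
    qp <- align_and_scale(collapse_features(ratios, "protein"))
    qs <- align_and_scale(collapse_features(ratios, "site"))
    message(sprintf("[quant] %d proteins, %d sites, %d samples; %d PSM row(s) dropped",
                    nrow(qp$values), nrow(qs$values), ncol(qp$values),
                    sum(vapply(ratios, function(r) attr(r, "n_dropped"), 1L))))
    emit(cbind(feature = rownames(qp$values), as.data.frame(qp$values)),
         "quant_protein.tsv")
    emit(cbind(feature = rownames(qs$values), as.data.frame(qs$values)),
         "quant_site.tsv")
    emit(rbind(cbind(level = "protein", qp$norm_report),
               cbind(level = "site", qs$norm_report)), "normalization.tsv")
    k_mds <- min(2L, ncol(qp$values) - 1L)
    mds <- mds_embed(qp, k = k_mds)
    emit(cbind(sample = rownames(mds),
               as.data.frame(`colnames<-`(mds, paste0("dim", seq_len(k_mds))))),
         "mds_protein.tsv")
    res$quant <- list(protein = qp, site = qs, mds = mds)
    if (run_to < 3) return(invisible(res))

    ## --- diff (per cell line) -------------------------------------------
    fcfg <- filter_config(
      fdr_threshold = config$filters$fdr_threshold,
      min_localization_probability = config$filters$min_localization_probability,
      require_protein_quant = config$filters$require_protein_quant)
    cell_lines <- unique(design$cell_line)
    diff <- list()
    for (cl in cell_lines) {
      smp <- design_samples(design)
      smp <- smp$sample[smp$cell_line == cl]
      sub <- function(qm) {
        out <- qm
        out$values <- qm$values[, intersect(smp, colnames(qm$values)), drop = FALSE]
        out$intensity <- qm$intensity[, colnames(out$values), drop = FALSE]
        out$samples <- colnames(out$values)
        out
      }
      dp <- fit_moderated_t(sub(qp), design)
      ds <- fit_moderated_t(sub(qs), design)
      ds <- adjust_phospho_for_protein(ds, dp)
      fp <- apply_significance_filters(dp, fcfg)
      fs <- apply_significance_filters(ds, fcfg)
      message(sprintf("[diff:%s] %d proteins (%d significant), %d sites (%d significant), %d low-localization site(s) removed",
                      cl, nrow(fp$results), sum(fp$results$significant),
                      nrow(fs$results), sum(fs$results$significant),
                      fs$n_filtered[["low_localization"]]))
      emit(fp$results, sprintf("diff_protein_%s.tsv", cl))
      emit(fs$results, sprintf("diff_site_%s.tsv", cl))
      emit(fp$volcano, sprintf("volcano_protein_%s.tsv", cl))
      emit(fs$volcano, sprintf("volcano_site_%s.tsv", cl))
      diff[[cl]] <- list(protein = fp$results, site = fs$results)
    }
    # overlap sets: significant changes shared in the same direction
    if (length(cell_lines) > 1) {
      for (lv in c("protein", "site")) {
        sigs <- lapply(diff, function(d) {
          r <- d[[lv]][d[[lv]]$significant, c("feature", "direction")]
          stats::setNames(r$direction, r$feature)
        })
        pairs <- utils::combn(cell_lines, 2, simplify = FALSE)
        ov <- do.call(rbind, lapply(pairs, function(pr) {
          a <- sigs[[pr[1]]]; b <- sigs[[pr[2]]]
          shared <- intersect(names(a), names(b))
          shared <- shared[a[shared] == b[shared]]
          tibble::tibble(cell_line_1 = pr[1], cell_line_2 = pr[2],
                         n_1 = length(a), n_2 = length(b),
                         n_shared_same_direction = length(shared))
        }))
        emit(ov, sprintf("overlap_%s.tsv", lv))
      }
    }
    res$diff <- diff
    if (run_to < 4) return(invisible(res))

    ## --- causal (per cell line) -----------------------------------------
    causal <- list()
    for (cl in cell_lines) {
      sw <- fdr_sweep(diff[[cl]]$site, diff[[cl]]$protein, prior,
                      cutoffs = config$causal$cutoffs,
                      B = config$causal$B, seed = config$seed + 2,
                      activity_fdr = config$causal$activity_fdr)
      for (cu in names(sw$per_cutoff)) {
        pc <- sw$per_cutoff[[cu]]
        pre <- file.path(outdir, sprintf("network_%s_fdr%s", cl, cu))
        written <- c(written, write_network(pc$network, pre, pc$calls))
        emit(pc$calls, sprintf("activity_calls_%s_fdr%s.tsv", cl, cu))
      }
      hm <- sw$heatmap
      emit(cbind(protein = rownames(hm), as.data.frame(hm)),
           sprintf("activity_heatmap_%s.tsv", cl))
      n_called <- vapply(sw$per_cutoff, function(x) sum(x$calls$called), 1L)
      message(sprintf("[causal:%s] activity calls per cutoff: %s", cl,
                      paste(names(n_called), n_called, sep = "=",
                            collapse = ", ")))
      causal[[cl]] <- sw
    }
    res$causal <- causal
    if (run_to < 5) return(invisible(res))

    ## --- enrich (per cell line) -----------------------------------------
    sets <- if (!is.null(config$paths$signatures))
      load_signatures(config$paths$signatures)
    else signatures_from_prior(prior)
    enrich <- list()
    for (cl in cell_lines) {
      st <- diff[[cl]]$site
      stats_vec <- stats::setNames(st$t, st$feature)
      er <- permute_enrichment(stats_vec, sets, w = config$enrichment$w,
                               B = config$enrichment$B,
                               seed = config$seed + 3)
      message(sprintf("[enrich:%s] %d signatures scored, %d significant at adj p < 0.05",
                      cl, nrow(er), sum(er$adj_p < 0.05)))
      emit(er, sprintf("enrichment_%s.tsv", cl))
      enrich[[cl]] <- er
    }
    res$enrich <- enrich

    manifest <- list(
      package = "phosflow",
      version = as.character(utils::packageVersion("phosflow")),
      r_version = R.version.string,
      seed = config$seed,
      config_hash = hash,
      config = unclass(config),
      stages = stage_order[seq_len(run_to)],
      outputs = basename(written)
    )
    mp <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    invisible(res)
  }, error = on_fail)
}
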
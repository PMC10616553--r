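#' TMT study design
#'
#' Describes a multi-plex TMT experiment in which each cell line occupies its
#' own 10-channel plex: `n_treated` + `n_vehicle` sample channels plus
#' `n_reference` pooled reference channels that anchor ratios across plexes.
#' The default reproduces a 3-cell-line, 2-condition, 4-replicate screen:
#' 3 plexes x (4 treated + 4 vehicle + 2 reference) = 24 non-reference
#' samples in 30 channels.
#'
#' `perturbed` marks, per plex, whether the treatment is expected to engage
#' its target in that cell line; the synthetic-data generator only plants
#' treatment effects in perturbed plexes (emulating drug-sensitive versus
#' insensitive lines).
#'
#' @param cell_lines Character vector of cell line labels, one per plex.
#' @param n_treated,n_vehicle Replicates per condition within each plex.
#' @param n_reference Reference (pooled) channels per plex.
#' @param perturbed Logical vector, one per plex: does the treatment have a
#'   real effect in this cell line? Defaults to `TRUE` everywhere, except
#'   that the default three-line design marks its third (BRAF-driven,
#'   drug-insensitive) line `FALSE`.
#' @return A `study_design` object: a data frame with one row per channel
#'   (plex, cell_line, channel, sample, condition, replicate, perturbed).
#' @examples
#' d <- study_design()
#' table(d$condition)
#' @export
study_design <- function(cell_lines = c("UM1", "UM2", "BRAF1"),
                         n_treated = 4, n_vehicle = 4, n_reference = 2,
                         perturbed = NULL) {
  perturbed <- perturbed %||%
    if (identical(cell_lines, c("UM1", "UM2", "BRAF1"))) c(TRUE, TRUE, FALSE)
    else rep(TRUE, length(cell_lines))
  stopifnot(length(cell_lines) >= 1, n_treated >= 1, n_vehicle >= 1,
            n_reference >= 1, length(perturbed) == length(cell_lines))
  rows <- lapply(seq_along(cell_lines), function(i) {
    cl <- cell_lines[i]
    cond <- c(rep("treated", n_treated), rep("vehicle", n_vehicle),
              rep("reference", n_reference))
    repl <- c(seq_len(n_treated), seq_len(n_vehicle), seq_len(n_reference))
    data.frame(
      plex = i,
      cell_line = cl,
      channel = seq_along(cond),
      sample = paste(cl, ifelse(cond == "treated", "trt",
                         ifelse(cond == "vehicle", "veh", "ref")),
                     repl, sep = "_"),
      condition = cond,
      replicate = repl,
      perturbed = perturbed[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("study_design", "data.frame")
  out
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("TMT study design: %d plex(es), %d channels/plex, %d samples\n",
              length(unique(x$plex)), max(x$channel),
              sum(x$condition != "reference")))
  print.data.frame(x, ...)
  invisible(x)
}

# Non-reference rows of a design, optionally restricted to one plex.
design_samples <- function(design, plex = NULL) {
  d <- design[design$condition != "reference", , drop = FALSE]
  if (!is.null(plex)) d <- d[d$plex %in% plex, , drop = FALSE]
  d
}

design_reference_channels <- function(design, plex) {
  design$channel[design$plex == plex & design$condition == "reference"]
}
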
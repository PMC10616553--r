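#' Load directional site-signature sets (GMT dialect)
#'
#' Each line: set name, description, then members. A member is either a
#' bare site id `GENE_residuePosition` (direction "none") or
#' `GENE_residuePosition;u` / `;d` marking the direction the site moves
#' when the signature is active (kinase target up, perturbation-induced
#' down, ...). A member listed both as `u` and `d` in the same set is
#' contradictory and is excluded with a warning. Unparseable members
#' reject the whole line; the error lists the offending line numbers.
#' The set category is taken from the name prefix (`KINASE_`, `PERT_`,
#' `PATH_`) when present.
#'
#' @param path Path to the GMT-like file.
#' @return List of `signature_set`s: each a list with `name`, `category`,
#'   `members` (tibble site_id, direction).
#' @export
load_signatures <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty signature file: ", path)
  bad_lines <- integer()
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) { bad_lines <- c(bad_lines, i); next }
    memb <- f[-(1:2)]
    m <- regmatches(memb, regexec("^([A-Za-z0-9.-]+_[STY][0-9]+)(;([ud]))?$", memb))
    okm <- lengths(m) > 0
    if (!all(okm)) { bad_lines <- c(bad_lines, i); next }
    ids <- vapply(m, `[`, "", 2)
    dir <- vapply(m, `[`, "", 4)
    dir[dir == ""] <- "none"
    mem <- tibble::tibble(site_id = ids, direction = dir)
    # contradictory u+d annotations for a site: drop that site
    both <- intersect(mem$site_id[mem$direction == "u"],
                      mem$site_id[mem$direction == "d"])
    if (length(both)) {
      warning("set ", f[1], ": site(s) annotated both u and d excluded: ",
              paste(both, collapse = ", "))
      mem <- mem[!mem$site_id %in% both, ]
    }
    mem <- mem[!duplicated(mem$site_id), ]
    if (!nrow(mem)) { bad_lines <- c(bad_lines, i); next }
    cat_ <- if (grepl("^KINASE", f[1])) "kinase"
            else if (grepl("^PERT", f[1])) "perturbation"
            else if (grepl("^PATH", f[1])) "pathway" else "unspecified"
    sets[[length(sets) + 1L]] <- structure(
      list(name = f[1], category = cat_, members = mem),
      class = "signature_set")
  }
  if (length(bad_lines))
    stop("unparseable signature line(s): ", paste(bad_lines, collapse = ", "))
  sets
}

#' Write signature sets in the same GMT dialect
#' @param sets List of `signature_set`s.
#' @param path Output path.
#' @export
write_signatures <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    mem <- ifelse(s$members$direction == "none", s$members$site_id,
                  paste0(s$members$site_id, ";", s$members$direction))
    paste(c(s$name, s$category, mem), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

# Running-sum enrichment score for given hit positions in a ranked list.
# w_abs: |statistic|^w of every ranked position. Ties in max deviation
# resolve toward the positive value.
.es_core <- function(hit, w_abs) {
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0) return(NA_real_)
  wsum <- sum(w_abs[hit])
  inc <- numeric(n)
  if (wsum > 0) inc[hit] <- w_abs[hit] / wsum else inc[hit] <- 1 / nh
  if (nh < n) inc[!hit] <- -1 / (n - nh)
  rs <- cumsum(inc)
  i_max <- which.max(rs); i_min <- which.min(rs)
  # ties (within numerical accumulation error) resolve to the positive peak
  if (rs[i_max] >= abs(rs[i_min]) - 1e-12) rs[i_max] else rs[i_min]
}

#' Weighted running-sum enrichment score for one signature
#'
#' Sites are ranked by their signed statistic in decreasing order; members
#' annotated `"d"` have their statistic sign flipped beforehand (a
#' signature's "down" sites moving down is evidence *for* the signature).
#' Walking down the ranked list, the running sum gains
#' `|stat|^w / sum(|stat|^w over hits)` at member sites and loses
#' `1/(N - N_hits)` at non-members; the ES is the running-sum value of
#' maximal absolute deviation (ties resolve to the positive extreme).
#'
#' @param stats Named numeric vector: signed statistic per measured site.
#' @param set A `signature_set`.
#' @param w Weight exponent (0 = unweighted Kolmogorov-Smirnov-like, 0.75 =
#'   PTM signature convention).
#' @return The enrichment score in [-1, 1], or NA if no member matches.
#' @export
score_enrichment <- function(stats, set, w = 0.75) {
  stopifnot(length(stats) > 0, !is.null(names(stats)))
  mem <- set$members
  mem <- mem[mem$site_id %in% names(stats), ]
  if (!nrow(mem)) return(NA_real_)
  s <- stats
  flip <- mem$site_id[mem$direction == "d"]
  s[flip] <- -s[flip]
  ord <- order(-s, names(s)) # deterministic tie-break by site id
  hit <- names(s)[ord] %in% mem$site_id
  .es_core(hit, abs(s[ord])^w)
}

#' Permutation p-values and NES for a collection of signatures
#'
#' Builds the null by permuting the site labels of the statistic vector B
#' times per set. For sets without directional annotations this is
#' equivalent to (and computed as) placing the matched members at uniformly
#' random positions of the fixed ranked list; directional sets are rescored
#' from scratch because flipped member statistics re-rank the list.
#' `NES = ES / mean(|null ES| of the same sign)`;
#' `p = (#\{same-sign null with |ES| >= |observed|\} + 1) /
#' (#same-sign nulls + 1)`; BH across signatures. Sets with no matched
#' member are dropped and counted in attribute `n_unmatched`.
#'
#' @param stats Named numeric vector of signed site statistics.
#' @param sets List of `signature_set`s.
#' @param w Weight exponent.
#' @param B Number of label permutations (>= 1000).
#' @param seed Integer seed.
#' @return `enrichment_result` tibble: name, category, es, nes, p, adj_p,
#'   n_matched.
#' @export
permute_enrichment <- function(stats, sets, w = 0.75, B = 1000, seed = 1) {
  if (B < 1000) stop("B must be >= 1000")
  obs <- vapply(sets, function(st) score_enrichment(stats, st, w), numeric(1))
  matched <- !is.na(obs)
  n_matched <- vapply(sets, function(st)
    sum(st$members$site_id %in% names(stats)), integer(1))

  live <- which(matched)
  nulls <- matrix(NA_real_, B, length(sets))
  n_sites <- length(stats)
  ord0 <- order(-stats, names(stats))
  w_abs0 <- abs(stats[ord0])^w
  with_seed(seed, {
    nm <- names(stats)
    for (k in live) {
      st <- sets[[k]]
      mem <- st$members[st$members$site_id %in% nm, ]
      if (all(mem$direction != "d")) {
        m <- nrow(mem)
        for (bb in seq_len(B)) {
          hit <- logical(n_sites)
          hit[sample.int(n_sites, m)] <- TRUE
          nulls[bb, k] <- .es_core(hit, w_abs0)
        }
      } else {
        for (bb in seq_len(B)) {
          ps <- stats
          names(ps) <- sample(nm)
          nulls[bb, k] <- score_enrichment(ps, st, w)
        }
      }
    }
  })

  nes <- p <- rep(NA_real_, length(sets))
  for (k in live) {
    same <- nulls[, k][!is.na(nulls[, k]) & sign(nulls[, k]) == sign(obs[k])]
    nes[k] <- if (length(same)) obs[k] / mean(abs(same)) else NA_real_
    p[k] <- (sum(abs(same) >= abs(obs[k])) + 1) / (length(same) + 1)
  }
  out <- tibble::tibble(
    name = vapply(sets, `[[`, "", "name"),
    category = vapply(sets, `[[`, "", "category"),
    es = obs, nes = nes, p = p, adj_p = NA_real_, n_matched = n_matched
  )[matched, ]
  out$adj_p <- bh_adjust(out$p)
  attr(out, "n_unmatched") <- sum(!matched)
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "w") <- w
  class(out) <- c("enrichment_result", class(out))
  out
}
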
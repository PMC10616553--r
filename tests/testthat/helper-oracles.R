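# Independent oracles used by unit and acceptance tests. Each re-derives
# the expected result from the definition with plain loops, sharing no code
# with the package implementation.

# Step-up BH, computed literally from the sorted sequence.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, m * p[o[i]] / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Causal matching: enumerate evidence and the consistency condition.
match_oracle <- function(prior, changes) {
  site_dir <- setNames(changes$sites$direction, changes$sites$site_id)
  prot_dir <- setNames(changes$proteins$direction, changes$proteins$protein)
  eff_num <- c(a = 1, i = -1, u = 0)
  sgn_num <- c(phosphorylates = 1, dephosphorylates = -1)
  activity <- function(p) {
    ev <- c()
    for (i in seq_len(nrow(prior))) {
      if (prior$target[i] != p) next
      e <- eff_num[[prior$effect[i]]]
      if (e == 0) next
      id <- paste(prior$target[i], prior$site[i], sep = "_")
      if (!id %in% names(site_dir)) next
      ev <- c(ev, e * site_dir[[id]])
    }
    if (!length(ev) && p %in% names(prot_dir)) ev <- prot_dir[[p]]
    ev <- unique(ev[ev != 0])
    if (length(ev) == 1) ev else NA
  }
  hits <- logical(nrow(prior))
  for (i in seq_len(nrow(prior))) {
    a <- activity(prior$source[i])
    id <- paste(prior$target[i], prior$site[i], sep = "_")
    if (is.na(a) || !id %in% names(site_dir)) next
    hits[i] <- site_dir[[id]] == sgn_num[[prior$relation[i]]] * a
  }
  prior[hits, ]
}

# Running-sum enrichment score, computed with a literal walk.
es_oracle <- function(stats, members, directions = NULL, w = 0) {
  s <- stats
  if (!is.null(directions)) {
    flip <- members[directions == "d"]
    s[intersect(flip, names(s))] <- -s[intersect(flip, names(s))]
  }
  ord <- order(-s, names(s))
  nm <- names(s)[ord]
  v <- abs(s[ord])^w
  hit <- nm %in% members
  n <- length(nm); nh <- sum(hit)
  if (nh == 0) return(NA_real_)
  best <- 0; run <- 0
  wsum <- sum(v[hit])
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) {
      if (wsum > 0) v[i] / wsum else 1 / nh
    } else -1 / (n - nh)
    if (abs(run) > abs(best) + 1e-12 ||
        (abs(abs(run) - abs(best)) <= 1e-12 && run > best)) best <- run
  }
  unname(best)
}

sig_set <- function(name, ids, dir = "none") {
  structure(list(name = name, category = "kinase",
                 members = tibble::tibble(
                   site_id = ids, direction = rep_len(dir, length(ids)))),
            class = "signature_set")
}

# Random small causal instances for oracle-equivalence checks.
random_causal_instance <- function() {
  nodes <- c("A", "B", "C", "D")
  sites <- c("S1", "S2", "T3")
  n_rel <- sample(1:6, 1)
  prior <- prior_tbl(
    source = sample(nodes, n_rel, replace = TRUE),
    relation = sample(c("phosphorylates", "dephosphorylates"), n_rel, TRUE),
    target = sample(nodes, n_rel, replace = TRUE),
    site = sample(sites, n_rel, replace = TRUE),
    effect = sample(c("a", "i", "u"), n_rel, TRUE))
  prior <- unique(prior)
  ids <- unique(paste(prior$target, prior$site, sep = "_"))
  dirs <- sample(c(-1, 0, 1), length(ids), replace = TRUE)
  pdirs <- sample(c(-1, 0, 1), length(nodes), replace = TRUE)
  ch <- change_set_of(
    site_dirs = setNames(dirs[dirs != 0], ids[dirs != 0]),
    protein_dirs = setNames(pdirs[pdirs != 0], nodes[pdirs != 0]),
    measured_extra = ids[dirs == 0])
  list(prior = prior, changes = ch)
}
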
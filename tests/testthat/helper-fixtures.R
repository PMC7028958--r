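# Shared fixtures and independent oracles. Oracles are deliberately naive
# (dense scans, explicit branch enumeration, textbook formulas) and never
# call the implementation they check.

# small, fast scenario used by most synthetic-data tests
tiny_config <- function(seed = 3, ...) {
  scenario_config(n_donor_asvs = 60, n_environmental_asvs = 20,
                  n_per_group = 4, depth_mean = 8000, seed = seed, ...)
}

toy_table <- function(counts, samples = NULL, asvs = NULL) {
  counts <- as.matrix(counts)
  asv_table(counts,
            sample_ids = samples %||% rownames(counts) %||%
              paste0("s", seq_len(nrow(counts))),
            asv_ids = asvs %||% colnames(counts) %||%
              paste0("a", seq_len(ncol(counts))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracle: presence by dense scan ------------------------------------------
oracle_presence <- function(table, samples, min_count = 1) {
  m <- unclass(table)[samples, , drop = FALSE]
  keep <- logical(ncol(m))
  for (j in seq_len(ncol(m)))
    for (i in seq_len(nrow(m)))
      if (m[i, j] >= min_count) keep[j] <- TRUE
  colnames(m)[keep]
}

# --- oracle: UniFrac by explicit branch enumeration --------------------------
# walks every edge of the tree, collects its descendant tips by brute-force
# path tracing, and applies the definitions directly
oracle_unifrac_pair <- function(tree, counts_a, counts_b,
                                weighted = FALSE, normalized = FALSE) {
  tips <- tree$tip.label
  desc_tips <- function(node) {
    if (node <= length(tips)) return(tips[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, desc_tips))
  }
  pa <- counts_a / sum(counts_a); pb <- counts_b / sum(counts_b)
  num <- 0; den <- 0
  for (e in seq_len(nrow(tree$edge))) {
    l <- tree$edge.length[e]
    under <- desc_tips(tree$edge[e, 2])
    ma <- sum(pa[under]); mb <- sum(pb[under])
    in_a <- sum(counts_a[under]) > 0; in_b <- sum(counts_b[under]) > 0
    if (weighted) {
      num <- num + l * abs(ma - mb)
      den <- den + l * (ma + mb)
    } else {
      if (xor(in_a, in_b)) num <- num + l
      if (in_a || in_b) den <- den + l
    }
  }
  if (weighted && !normalized) num
  else if (den > 0) num / den else 0
}

# --- oracle: textbook chi-square ---------------------------------------------
oracle_chi2 <- function(observed) {
  n <- sum(observed)
  chi2 <- 0
  for (i in seq_len(nrow(observed)))
    for (j in seq_len(ncol(observed))) {
      e <- sum(observed[i, ]) * sum(observed[, j]) / n
      chi2 <- chi2 + (observed[i, j] - e)^2 / e
    }
  chi2
}

# random contingency table with positive marginals
random_contingency <- function(r = 3, c = 3) {
  repeat {
    m <- matrix(rpois(r * c, 20), r, c)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) return(m)
  }
}

# random abundance table on a random tree, for UniFrac property tests
random_tree_instance <- function(n_tips = 6, n_samples = 2) {
  tree <- ape::rtree(n_tips, tip.label = paste0("a", seq_len(n_tips)))
  counts <- matrix(rpois(n_samples * n_tips, 3), n_samples, n_tips)
  counts[rowSums(counts) == 0, 1] <- 1  # avoid empty communities
  list(tree = tree,
       table = toy_table(counts, asvs = tree$tip.label))
}
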
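#' Shannon diversity index (base 2)
#'
#' H = -sum p_i log2 p_i over the nonzero proportions of a sample's counts.
#' Log base 2 (bits) follows the convention of the amplicon pipeline the
#' study used; divide by `log2(exp(1))` for nats.
#'
#' @param sample_counts non-negative numeric vector of counts for one sample.
#' @return Shannon entropy in bits.
#' @examples
#' shannon(c(1, 1, 1, 1))  # 2 bits
#' @export
shannon <- function(sample_counts) {
  if (any(sample_counts < 0)) stop("negative counts")
  total <- sum(sample_counts)
  if (total <= 0) stop("all-zero sample")
  p <- sample_counts[sample_counts > 0] / total
  -sum(p * log2(p))
}

# edge-by-tip incidence: desc[e, t] is TRUE when tip t descends from edge e
edge_tip_incidence <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  desc <- matrix(FALSE, nrow(tree$edge), n_tip)
  # process edges child-first (postorder) accumulating tip sets per node
  tipsets <- vector("list", n_node)
  for (t in seq_len(n_tip)) tipsets[[t]] <- t
  ord <- ape::postorder(tree)
  for (e in ord) {
    child <- tree$edge[e, 2]
    parent <- tree$edge[e, 1]
    tips <- unlist(tipsets[[child]])
    desc[e, tips] <- TRUE
    tipsets[[parent]] <- c(tipsets[[parent]], list(tips))
  }
  desc
}

#' UniFrac phylogenetic beta diversity
#'
#' Unweighted UniFrac between two communities is the branch length unique to
#' either community divided by the branch length covered by at least one of
#' them. Weighted UniFrac is `sum_b l_b |p_A(b) - p_B(b)|` over branches,
#' where `p_X(b)` is the proportion of community X descending from branch b;
#' the normalized variant divides by its maximum attainable value,
#' `sum_b l_b (p_A(b) + p_B(b))`. Whether to normalize is exposed because
#' published pipelines differ; the default is the raw (unnormalized) value.
#'
#' @param table an [asv_table()]; every ASV with a nonzero count must be a
#'   tip of `tree`.
#' @param tree a rooted ape `phylo` with branch lengths.
#' @param weighted logical; abundance-weighted variant.
#' @param normalized logical; only meaningful when `weighted`.
#' @return symmetric samples-by-samples distance matrix with zero diagonal.
#' @export
unifrac <- function(table, tree, weighted = FALSE, normalized = FALSE) {
  stopifnot(inherits(table, "asv_table"), inherits(tree, "phylo"))
  used <- colnames(table)[colSums(unclass(table)) > 0]
  missing <- setdiff(used, tree$tip.label)
  if (length(missing))
    stop("ASV(s) missing from tree: ", paste(missing, collapse = ", "))
  # align table columns to tree tips (absent tips get zero counts)
  m <- matrix(0, nrow(table), length(tree$tip.label),
              dimnames = list(rownames(table), tree$tip.label))
  common <- intersect(colnames(table), tree$tip.label)
  m[, common] <- unclass(table)[, common]
  bl <- tree$edge.length
  if (is.null(bl)) stop("tree has no branch lengths")
  desc <- edge_tip_incidence(tree)
  # per-sample mass descending from each edge: samples x edges
  prop <- m / rowSums(m)
  mass <- prop %*% t(desc)
  pres <- (m %*% t(desc)) > 0
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (weighted) {
      num <- sum(bl * abs(mass[i, ] - mass[j, ]))
      d[i, j] <- if (normalized) {
        den <- sum(bl * (mass[i, ] + mass[j, ]))
        if (den > 0) num / den else 0
      } else num
    } else {
      shared <- pres[i, ] & pres[j, ]
      either <- pres[i, ] | pres[j, ]
      den <- sum(bl[either])
      d[i, j] <- if (den > 0) sum(bl[either & !shared]) / den else 0
    }
    d[j, i] <- d[i, j]
  }
  d
}

#' Pairwise Kruskal-Wallis tests with FDR correction
#'
#' Runs a rank-based Kruskal-Wallis test (tie-corrected H) for every pair of
#' groups and, when `fdr` is set, attaches Benjamini-Hochberg q-values
#' computed across all pairs. Pairs in which either group has fewer than two
#' values are flagged (`NA` statistics) rather than computed.
#'
#' @param groups named list of numeric vectors, one per group.
#' @param fdr logical; attach BH q-values.
#' @return data.frame with columns `group1`, `group2`, `H`, `p` and, with
#'   `fdr`, `q`.
#' @export
pairwise_kruskal <- function(groups, fdr = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2, !is.null(names(groups)))
  pairs <- utils::combn(names(groups), 2)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    H = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (r in seq_len(ncol(pairs))) {
    a <- groups[[pairs[1, r]]]; b <- groups[[pairs[2, r]]]
    if (length(a) < 2 || length(b) < 2) next  # degenerate: flagged, not computed
    kt <- stats::kruskal.test(list(a, b))
    out$H[r] <- unname(kt$statistic)
    out$p[r] <- kt$p.value
  }
  if (fdr) out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Clarke's R: all pairwise distances are ranked (average ranks on ties) and
#' R = (mean between-group rank - mean within-group rank) / (n(n-1)/4),
#' which lies in [-1, 1] and reaches 1 when every between-group distance
#' exceeds every within-group distance. Significance by label permutation:
#' p = (1 + #{R_perm >= R_obs}) / (1 + n_perm).
#'
#' @param dm symmetric distance matrix.
#' @param labels group label per sample (length `nrow(dm)`).
#' @param n_perm number of permutations (>= 99).
#' @param seed integer RNG seed for the permutations.
#' @return list with `R` and `p`.
#' @export
anosim <- function(dm, labels, n_perm = 999, seed = 1L) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) == ncol(dm), length(labels) == nrow(dm), n_perm >= 99)
  if (length(unique(labels)) < 2) stop("ANOSIM needs at least two groups")
  n <- nrow(dm)
  lower <- which(lower.tri(dm))
  rk <- rank(dm[lower])
  ij <- arrayInd(lower, dim(dm))
  stat <- function(lab) {
    within <- lab[ij[, 1]] == lab[ij[, 2]]
    (mean(rk[!within]) - mean(rk[within])) / (n * (n - 1) / 4)
  }
  r_obs <- stat(labels)
  hits <- 0L
  withr_seed(seed, {
    for (b in seq_len(n_perm))
      if (stat(sample(labels)) >= r_obs) hits <- hits + 1L
  })
  list(R = r_obs, p = (1 + hits) / (1 + n_perm))
}

#' Compare treated and control distance to the donor material
#'
#' For every chick sample at the given age, the mean distance to all TRPL
#' (donor) samples is computed; the treated and control vectors are compared
#' with a two-sample t test (pooled variance by default, the unannotated
#' "Student's t test" convention; set `var_equal = FALSE` for Welch).
#' Smaller mean distance means the arm is compositionally closer to the
#' donor community, the study's coarse signature of transplant success.
#'
#' @param dm distance matrix over all samples (chicks and TRPL).
#' @param frame a [sample_frame()] covering the samples of `dm`.
#' @param timepoint age in days posthatching.
#' @param var_equal pooled (TRUE) or Welch (FALSE) t test.
#' @return list with `mean_treated`, `mean_control`, `t`, `p`.
#' @export
donor_distance_test <- function(dm, frame, timepoint, var_equal = TRUE) {
  dm <- as.matrix(dm)
  trpl <- frame$sample_id[frame$treatment == "transplant"]
  if (!length(trpl)) stop("no TRPL samples in frame")
  arm <- function(tr) {
    ids <- frame$sample_id[frame$treatment == tr &
                             !is.na(frame$age_dph) &
                             frame$age_dph == timepoint]
    if (!length(ids)) stop("no ", tr, " samples at ", timepoint, " dph")
    rowMeans(dm[ids, trpl, drop = FALSE])
  }
  x <- arm("treated"); y <- arm("control")
  tt <- two_sample_t(x, y, var_equal)
  list(mean_treated = mean(x), mean_control = mean(y),
       t = tt$t, p = tt$p)
}

#' Principal-coordinate ordination of a distance matrix
#'
#' Convenience export of classical multidimensional scaling coordinates for
#' plotting; not part of the statistical surface.
#'
#' @param dm distance matrix.
#' @param k number of axes.
#' @return samples-by-k coordinate matrix.
#' @export
pcoa_coords <- function(dm, k = 2) {
  stats::cmdscale(stats::as.dist(dm), k = k)
}
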
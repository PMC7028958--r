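#' Build a balance tree by Ward clustering of correlated ASVs
#'
#' Re-creates the principal-balance dendrogram of the compositional
#' differential-abundance workflow: counts are closed to proportions after
#' adding a pseudocount, ASV-ASV dissimilarity is 1 - Pearson correlation of
#' the log-proportions across samples, and Ward linkage (`ward.D2`, the same
#' algorithm as SciPy's `ward` used by the original pipeline) produces a
#' strictly bifurcating tree. Each internal node is a balance; nodes are
#' labelled `y0, y1, ...` in level (breadth-first) order from the root, so
#' `y0` is the root split. Within a node, the child whose lexicographically
#' smallest leaf id sorts first is the numerator — a deterministic,
#' documented convention; balance labels are positional, not semantic.
#'
#' @param table a filtered [asv_table()] with at least two ASVs.
#' @param pseudocount positive number added to every count before closure.
#' @return an object of class `balance_tree`: a list of balances, each with
#'   `name`, `numerator` and `denominator` leaf-id sets, and `depth`
#'   (edges from the root).
#' @export
build_balance_tree <- function(table, pseudocount = 1) {
  stopifnot(inherits(table, "asv_table"), ncol(table) >= 2, pseudocount > 0)
  p <- (unclass(table) + pseudocount) / rowSums(unclass(table) + pseudocount)
  lp <- log(p)
  sds <- apply(lp, 2, stats::sd)
  bad <- is.na(sds) | sds == 0
  if (any(bad))
    stop("constant log-proportion vector for ASV(s) ",
         paste(colnames(table)[bad], collapse = ", "),
         "; correlation undefined - filter more aggressively")
  d <- stats::as.dist(1 - stats::cor(lp))
  hc <- stats::hclust(d, method = "ward.D2")
  balance_tree_from_hclust(hc)
}

# convert an hclust merge structure into level-order-labelled balances
balance_tree_from_hclust <- function(hc) {
  n <- length(hc$labels)
  leaves_of <- function(node) {  # node: merge-row index (positive) or -leaf
    if (node < 0) return(hc$labels[-node])
    c(leaves_of(hc$merge[node, 1]), leaves_of(hc$merge[node, 2]))
  }
  # breadth-first from the root (last merge row)
  queue <- list(list(node = n - 1L, depth = 0L))
  balances <- list()
  while (length(queue)) {
    cur <- queue[[1]]; queue <- queue[-1]
    kids <- hc$merge[cur$node, ]
    left <- sort(leaves_of(kids[1])); right <- sort(leaves_of(kids[2]))
    if (left[1] <= right[1]) { num <- left; den <- right }
    else { num <- right; den <- left }
    balances[[length(balances) + 1L]] <-
      list(name = sprintf("y%d", length(balances)),
           numerator = num, denominator = den, depth = cur$depth)
    for (k in kids) if (k > 0)
      queue[[length(queue) + 1L]] <- list(node = k, depth = cur$depth + 1L)
  }
  structure(balances, class = "balance_tree",
            leaves = sort(hc$labels))
}

#' @export
print.balance_tree <- function(x, ...) {
  cat(sprintf("<balance_tree> %d balances over %d ASVs\n",
              length(x), length(attr(x, "leaves"))))
  invisible(x)
}

#' Export a balance tree as Newick with internal labels
#'
#' @param tree a `balance_tree`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_balance_tree_newick <- function(tree, path) {
  # rebuild nested structure from leaf sets: a child of balance b is the
  # balance whose leaf set equals b's numerator (or denominator) side
  sets <- lapply(tree, function(b) sort(c(b$numerator, b$denominator)))
  key <- vapply(sets, paste, character(1), collapse = "\r")
  render <- function(leafset) {
    if (length(leafset) == 1) return(leafset)
    i <- match(paste(sort(leafset), collapse = "\r"), key)
    b <- tree[[i]]
    sprintf("(%s,%s)%s", render(b$numerator), render(b$denominator), b$name)
  }
  writeLines(paste0(render(attr(tree, "leaves")), ";"), path)
  invisible(path)
}

#' Isometric log-ratio transform over a balance tree
#'
#' For a balance with r numerator and s denominator leaves,
#' `y = sqrt(rs/(r+s)) * ln(g(num)/g(den))` where g is the geometric mean of
#' the closed proportions (pseudocount added first). The transform is
#' scale-invariant: multiplying all counts of a sample by a constant leaves
#' the balances unchanged (exactly so in the no-pseudocount limit).
#'
#' @param table an [asv_table()] containing every tree leaf.
#' @param tree a `balance_tree` from [build_balance_tree()].
#' @param pseudocount non-negative number added before closure; zero is
#'   allowed only when the table has no zero counts on the tree's leaves.
#' @return samples-by-balances numeric matrix.
#' @export
ilr_transform <- function(table, tree, pseudocount = 1) {
  stopifnot(inherits(table, "asv_table"), inherits(tree, "balance_tree"),
            pseudocount >= 0)
  leaves <- attr(tree, "leaves")
  missing <- setdiff(leaves, colnames(table))
  if (length(missing))
    stop("tree leaves absent from table: ", paste(missing, collapse = ", "))
  m <- unclass(table)[, leaves, drop = FALSE] + pseudocount
  if (any(m <= 0))
    stop("zero counts present; use a positive pseudocount")
  lp <- log(m / rowSums(m))
  out <- matrix(0, nrow(table), length(tree),
                dimnames = list(rownames(table),
                                vapply(tree, `[[`, character(1), "name")))
  for (b in seq_along(tree)) {
    r <- length(tree[[b]]$numerator); s <- length(tree[[b]]$denominator)
    gnum <- rowMeans(lp[, tree[[b]]$numerator, drop = FALSE])
    gden <- rowMeans(lp[, tree[[b]]$denominator, drop = FALSE])
    out[, b] <- sqrt(r * s / (r + s)) * (gnum - gden)
  }
  out
}

#' Multivariate OLS of balances on study covariates
#'
#' Fits ordinary least squares per balance with one shared design matrix
#' (intercept + encoded covariates; `treatment` is coded control = 0,
#' treated = 1, `age_dph` is numeric days posthatching). The overall fit is
#' R^2 = 1 - sum(SSE)/sum(SST) pooled over balances; each covariate's
#' variance fraction is the drop in overall R^2 when it is left out of the
#' design (leave-one-covariate-out).
#'
#' @param balances samples-by-balances matrix from [ilr_transform()].
#' @param frame a [sample_frame()] covering the rows of `balances`.
#' @param covariates character vector of frame columns (default
#'   `c("treatment", "age_dph")`).
#' @return an object of class `balance_regression`: list with `coef` and
#'   `p` (covariates-by-balances matrices), `r2`, `variance_fraction`
#'   (named by covariate) and the encoded `design`.
#' @export
regress_balances <- function(balances, frame,
                             covariates = c("treatment", "age_dph")) {
  stopifnot(is.matrix(balances))
  if (anyDuplicated(covariates))
    stop("duplicated covariate(s): ",
         paste(unique(covariates[duplicated(covariates)]), collapse = ", "))
  missing <- setdiff(covariates, names(frame))
  if (length(missing))
    stop("covariate(s) absent from frame: ", paste(missing, collapse = ", "))
  frame <- frame[match(rownames(balances), frame$sample_id), ]
  encode <- function(cv) {
    v <- frame[[cv]]
    if (cv == "treatment") {
      if (!all(v %in% c("control", "treated")))
        stop("treatment covariate requires control/treated samples only")
      as.numeric(v == "treated")
    } else if (is.numeric(v)) as.numeric(v)
    else stop("cannot encode covariate ", cv)
  }
  X <- cbind(`(intercept)` = 1,
             vapply(covariates, encode, numeric(nrow(balances))))
  if (nrow(X) <= ncol(X))
    stop("need more samples than covariates + 1")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design; collinear column(s): ",
         paste(colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]], collapse = ", "))
  fit_r2 <- function(Xd) {
    f <- stats::lm.fit(Xd, balances)
    res <- as.matrix(f$residuals)
    sst <- sum(scale(balances, scale = FALSE)^2)
    1 - sum(res^2) / sst
  }
  fit <- stats::lm.fit(X, balances)
  res <- as.matrix(fit$residuals)
  coefs <- as.matrix(fit$coefficients)
  dfree <- nrow(X) - ncol(X)
  XtXinv <- chol2inv(qr.R(qrX))
  sigma2 <- colSums(res^2) / dfree
  se <- sqrt(outer(diag(XtXinv), sigma2))
  pmat <- 2 * stats::pt(abs(coefs / se), dfree, lower.tail = FALSE)
  dimnames(pmat) <- dimnames(coefs)
  r2 <- fit_r2(X)
  vf <- vapply(covariates, function(cv)
    r2 - fit_r2(X[, setdiff(colnames(X), cv), drop = FALSE]), numeric(1))
  structure(list(coef = coefs, p = pmat, r2 = r2,
                 variance_fraction = vf, covariates = covariates,
                 design = X),
            class = "balance_regression")
}

#' @export
print.balance_regression <- function(x, ...) {
  cat(sprintf("<balance_regression> %d balances, overall R2 = %.3f\n",
              ncol(x$coef), x$r2))
  for (cv in x$covariates)
    cat(sprintf("  %s: variance fraction %.3f, %d balance(s) with p < 0.05\n",
                cv, x$variance_fraction[cv], sum(x$p[cv, ] < 0.05)))
  invisible(x)
}

#' Regression summary as a data frame
#'
#' @param result a `balance_regression`.
#' @return data.frame with one row per balance per covariate.
#' @export
regression_summary <- function(result) {
  stopifnot(inherits(result, "balance_regression"))
  cvs <- result$covariates
  do.call(rbind, lapply(cvs, function(cv)
    data.frame(balance = colnames(result$coef), covariate = cv,
               beta = result$coef[cv, ], p = result$p[cv, ],
               row.names = NULL)))
}

#' Classify ASVs into differential-abundance groups from significant balances
#'
#' Every balance significant for the `treatment` covariate at level `alpha`
#' assigns its numerator leaves toward the arm with the higher fitted log
#' ratio (treatment beta > 0 with treated coded 1 means numerator higher in
#' treated) and its denominator leaves the opposite way. An ASV claimed by
#' several significant balances is resolved by the shallowest
#' (closest-to-root) one; unclaimed ASVs are `not_differentially_abundant`.
#'
#' The original workflow also adjudicated some balances manually from a
#' heatmap; such judgment calls are irreproducible from data, so they are
#' accepted only as explicit `overrides`: a data.frame with columns
#' `balance` and `class`. A balance label may carry a `/num` or `/den`
#' suffix to address a single side; otherwise the override claims the whole
#' leaf set of the balance. Overrides take precedence over the automatic
#' rule and among themselves follow the same shallowest-balance resolution.
#'
#' @param result a `balance_regression`.
#' @param tree the `balance_tree` the balances came from.
#' @param alpha significance level for the treatment coefficient.
#' @param overrides optional data.frame(`balance`, `class`) with classes in
#'   `higher_in_treated`, `higher_in_control`, `not_differentially_abundant`.
#' @return named character vector over all tree leaves with the three-class
#'   assignment (an exhaustive, exclusive partition).
#' @export
classify_da <- function(result, tree, alpha = 0.05, overrides = NULL) {
  stopifnot(inherits(result, "balance_regression"),
            inherits(tree, "balance_tree"))
  if (!"treatment" %in% result$covariates)
    stop("regression has no treatment covariate")
  leaves <- attr(tree, "leaves")
  classes <- c("higher_in_treated", "higher_in_control",
               "not_differentially_abundant")
  names_b <- vapply(tree, `[[`, character(1), "name")
  depth_b <- vapply(tree, `[[`, integer(1), "depth")
  cls <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
  claim <- function(ids, class) {  # first claim wins; callers order by depth
    take <- is.na(cls[ids])
    cls[ids[take]] <<- class
  }
  # manual overrides take precedence over automatic claims; among overrides
  # (and among significant balances) the shallowest balance wins, ties by
  # listing order
  if (!is.null(overrides) && nrow(overrides)) {
    base <- sub("/(num|den)$", "", overrides$balance)
    i <- match(base, names_b)
    if (anyNA(i))
      stop("override names unknown balance: ",
           paste(unique(base[is.na(i)]), collapse = ", "))
    if (!all(overrides$class %in% classes))
      stop("override class must be one of: ", paste(classes, collapse = ", "))
    for (r in order(depth_b[i])) {
      side <- sub("^[^/]*", "", overrides$balance[r])
      ids <- switch(side,
                    "/num" = tree[[i[r]]]$numerator,
                    "/den" = tree[[i[r]]]$denominator,
                    c(tree[[i[r]]]$numerator, tree[[i[r]]]$denominator))
      claim(ids, overrides$class[r])
    }
  }
  sig <- which(result$p["treatment", names_b] < alpha)
  for (i in sig[order(depth_b[sig])]) {
    up <- result$coef["treatment", names_b[i]] > 0
    claim(tree[[i]]$numerator,
          if (up) "higher_in_treated" else "higher_in_control")
    claim(tree[[i]]$denominator,
          if (up) "higher_in_control" else "higher_in_treated")
  }
  cls[is.na(cls)] <- "not_differentially_abundant"
  cls
}
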
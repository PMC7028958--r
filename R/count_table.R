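#' ASV count table
#'
#' A samples-by-ASVs table of non-negative integer read counts, the basic
#' container the whole package operates on. Stored as a plain integer matrix
#' with sample identifiers on rows and ASV identifiers on columns; the tables
#' this package targets (hundreds of ASVs, tens to low hundreds of samples)
#' do not justify a sparse representation, but [read_counts_mtx()] and
#' [write_counts_mtx()] interoperate with sparse matrix-market files.
#'
#' @param counts integer matrix, samples in rows, ASVs in columns. Dimnames
#'   are taken as identifiers when `sample_ids`/`asv_ids` are not given.
#' @param sample_ids,asv_ids optional character vectors of unique identifiers.
#' @return An object of class `asv_table` (an integer matrix with dimnames).
#' @examples
#' tab <- asv_table(matrix(c(5L, 0L, 2L, 7L), 2, 2),
#'                  sample_ids = c("s1", "s2"), asv_ids = c("a1", "a2"))
#' n_samples(tab)
#' @export
asv_table <- function(counts, sample_ids = rownames(counts),
                      asv_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids) || is.null(asv_ids))
    stop("sample and ASV identifiers are required (dimnames or arguments)")
  if (anyDuplicated(sample_ids)) stop("duplicated sample identifiers")
  if (anyDuplicated(asv_ids)) stop("duplicated ASV identifiers")
  if (length(sample_ids) != nrow(counts) || length(asv_ids) != ncol(counts))
    stop("identifier lengths do not match table dimensions")
  if (anyNA(counts)) stop("counts must not contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, asv_ids)
  class(counts) <- c("asv_table", class(counts))
  counts
}

#' @rdname asv_table
#' @param x an `asv_table`.
#' @export
n_samples <- function(x) nrow(x)

#' @rdname asv_table
#' @export
n_asvs <- function(x) ncol(x)

#' @export
print.asv_table <- function(x, ...) {
  cat(sprintf("<asv_table> %d samples x %d ASVs, %s reads, %.1f%% zero cells\n",
              nrow(x), ncol(x), format(sum(as.numeric(x)), big.mark = ","),
              100 * mean(x == 0)))
  invisible(x)
}

# subsetting keeps the class and both dimensions
#' @export
`[.asv_table` <- function(x, i, j, ...) {
  y <- unclass(x)[i, j, drop = FALSE]
  class(y) <- c("asv_table", class(y))
  y
}

#' Per-sample metadata frame
#'
#' Builds the sample metadata used throughout: which experiment a sample
#' belongs to (`pilot`, `repeat`, or `donor` for the transplant material),
#' its treatment arm (`control`, `treated`, or `transplant`), and its age in
#' days posthatching (`NA` for the donor material). The group label is a
#' deterministic function of those three fields, following the study's
#' naming: experiment initial + treatment initial + age (e.g. `PC3`, `RT14`)
#' and `TRPL` for the donor pool.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param experiment one of `"pilot"`, `"repeat"`, `"donor"` per sample.
#' @param treatment one of `"control"`, `"treated"`, `"transplant"` per sample.
#' @param age_dph integer age in days posthatching; `NA` for donor samples.
#' @return a `data.frame` with columns `sample_id`, `experiment`, `treatment`,
#'   `age_dph`, `group`.
#' @export
sample_frame <- function(sample_id, experiment, treatment, age_dph) {
  experiment <- match.arg(experiment, c("pilot", "repeat", "donor"),
                          several.ok = TRUE)
  treatment <- match.arg(treatment, c("control", "treated", "transplant"),
                         several.ok = TRUE)
  if (anyDuplicated(sample_id)) stop("duplicated sample identifiers")
  n <- length(sample_id)
  experiment <- rep_len(experiment, n)
  treatment <- rep_len(treatment, n)
  age_dph <- rep_len(as.integer(age_dph), n)
  bad <- xor(treatment == "transplant", experiment == "donor")
  if (any(bad))
    stop("treatment 'transplant' must pair with experiment 'donor': ",
         paste(sample_id[bad], collapse = ", "))
  data.frame(sample_id = as.character(sample_id),
             experiment = experiment, treatment = treatment,
             age_dph = age_dph,
             group = group_label(experiment, treatment, age_dph),
             stringsAsFactors = FALSE)
}

#' Group label from experiment, treatment and age
#'
#' @param experiment,treatment,age_dph vectors as in [sample_frame()].
#' @return character vector of labels such as `"PC3"`, `"RT14"`, `"TRPL"`.
#' @export
group_label <- function(experiment, treatment, age_dph) {
  ifelse(treatment == "transplant", "TRPL",
         paste0(toupper(substr(experiment, 1, 1)),
                toupper(substr(treatment, 1, 1)), age_dph))
}

#' ASVs present in a set of samples
#'
#' Presence means a count of at least `min_count` in at least one of the
#' listed samples. The study defines presence as a single read
#' (`min_count = 1`); the threshold is exposed for sensitivity analysis.
#'
#' @param table an [asv_table()].
#' @param samples character vector of sample identifiers (subset of the
#'   table's samples).
#' @param min_count positive integer detection floor.
#' @return character vector of ASV identifiers (possibly empty).
#' @export
presence_set <- function(table, samples, min_count = 1L) {
  stopifnot(inherits(table, "asv_table"), min_count >= 1)
  unknown <- setdiff(samples, rownames(table))
  if (length(unknown))
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  sub <- table[samples, , drop = FALSE]
  colnames(sub)[apply(unclass(sub) >= min_count, 2, any)]
}

#' First-quartile abundance filter
#'
#' Computes each ASV's total frequency across all samples, sets the exclusion
#' threshold at the first quartile of those totals (linear interpolation
#' between order statistics, the default quantile convention), and retains
#' ASVs whose total is greater than or equal to the threshold — i.e. the
#' lowest-frequency quarter of ASVs is excluded and the boundary is kept.
#'
#' @param table an [asv_table()].
#' @return a list with `table` (the filtered [asv_table()]) and `threshold`
#'   (the first-quartile total frequency).
#' @export
quartile_filter <- function(table) {
  stopifnot(inherits(table, "asv_table"))
  if (ncol(table) == 0L || nrow(table) == 0L) stop("empty table")
  totals <- colSums(unclass(table))
  threshold <- unname(stats::quantile(totals, 0.25, type = 7))
  keep <- totals >= threshold
  list(table = table[, keep], threshold = threshold)
}

#' Rarefy a count table to an even depth
#'
#' Each sample with at least `depth` reads is subsampled without replacement
#' to exactly `depth` reads (one draw, no averaging over iterations); samples
#' below the depth are dropped with a warning. Deterministic given `seed`.
#'
#' @param table an [asv_table()].
#' @param depth positive integer target depth (the study used 5,000).
#' @param seed integer RNG seed.
#' @return an [asv_table()] whose rows all sum to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  stopifnot(inherits(table, "asv_table"), depth >= 1)
  totals <- rowSums(unclass(table))
  drop <- totals < depth
  if (any(drop))
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(rownames(table)[drop], collapse = ", ")))
  kept <- table[!drop, , drop = FALSE]
  out <- unclass(kept)
  out[] <- 0L
  withr_seed(seed, {
    for (i in seq_len(nrow(kept))) {
      pool <- rep.int(seq_len(ncol(kept)), unclass(kept)[i, ])
      draw <- sample(pool, depth, replace = FALSE)
      tb <- tabulate(draw, nbins = ncol(kept))
      out[i, ] <- as.integer(tb)
    }
  })
  asv_table(out)
}

# run expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}
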
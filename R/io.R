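#' Read and write ASV tables, metadata, taxonomy and trees
#'
#' Plain-text interchange in the dialects common to amplicon pipelines:
#'
#' * BIOM-compatible TSV: first line `#OTU ID<TAB>sample...`, one row per
#'   ASV — the classic tab-separated export of a BIOM table.
#' * Sparse matrix-market (`.mtx`) with sidecar row (sample) and column (ASV)
#'   identifier files, via the Matrix package.
#' * Metadata TSV with columns `sample_id`, `experiment`, `treatment`,
#'   `age_dph`, `group`.
#' * Taxonomy TSV in the QIIME2 two-column dialect: `Feature ID`, `Taxon`
#'   with semicolon-separated ranks.
#' * Newick trees via ape.
#'
#' All writers round-trip losslessly through their paired reader.
#'
#' @param table an [asv_table()].
#' @param path file path.
#' @return readers return the parsed object; writers return `path` invisibly.
#' @name ovoseed-io
NULL

#' @rdname ovoseed-io
#' @export
write_counts_tsv <- function(table, path) {
  stopifnot(inherits(table, "asv_table"))
  m <- t(unclass(table))  # BIOM-TSV is ASVs x samples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#OTU ID", colnames(m)), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_counts_tsv <- function(path) {
  m <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "",
                         check.names = FALSE, row.names = 1)
  asv_table(t(as.matrix(m)))
}

#' @rdname ovoseed-io
#' @export
write_counts_mtx <- function(table, path) {
  stopifnot(inherits(table, "asv_table"))
  Matrix::writeMM(Matrix::Matrix(unclass(table) * 1, sparse = TRUE), path)
  writeLines(rownames(table), paste0(path, ".rows"))
  writeLines(colnames(table), paste0(path, ".cols"))
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_counts_mtx <- function(path) {
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(path, ".rows"))
  colnames(m) <- readLines(paste0(path, ".cols"))
  asv_table(m)
}

#' @rdname ovoseed-io
#' @param frame a [sample_frame()].
#' @export
write_metadata_tsv <- function(frame, path) {
  utils::write.table(frame, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_metadata_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  sample_frame(df$sample_id, df$experiment, df$treatment, df$age_dph)
}

#' @rdname ovoseed-io
#' @param taxonomy named character vector, ASV id -> semicolon-separated
#'   lineage string.
#' @export
write_taxonomy_tsv <- function(taxonomy, path) {
  utils::write.table(
    data.frame(`Feature ID` = names(taxonomy), Taxon = unname(taxonomy),
               check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_taxonomy_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(df[["Taxon"]], df[["Feature ID"]])
}

#' Extract the family rank from a lineage string
#'
#' Family is the study's primary reporting rank. Accepts QIIME-style prefixed
#' ranks (`f__Lachnospiraceae`) inside a semicolon-separated lineage; lineages
#' with no family rank report `"unassigned"`.
#'
#' @param taxonomy named lineage vector as from [read_taxonomy_tsv()].
#' @return named character vector, ASV id -> family.
#' @export
taxonomy_family <- function(taxonomy) {
  fam <- vapply(strsplit(unname(taxonomy), ";\\s*"), function(ranks) {
    hit <- grep("^f__", ranks, value = TRUE)
    if (!length(hit) || hit[1] == "f__") return("unassigned")
    sub("^f__", "", hit[1])
  }, character(1))
  stats::setNames(fam, names(taxonomy))
}

#' @rdname ovoseed-io
#' @param tree an ape `phylo` object.
#' @export
write_tree_newick <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_tree_newick <- function(path) ape::read.tree(path)

#' @rdname ovoseed-io
#' @param dm a distance matrix as returned by [unifrac()].
#' @export
write_distance_tsv <- function(dm, path) {
  utils::write.table(cbind(sample_id = rownames(dm), as.data.frame(dm)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1)
  as.matrix(df)
}

#' @rdname ovoseed-io
#' @param ct a `ct_table` as from [ct_table()].
#' @export
write_ct_tsv <- function(ct, path) {
  df <- as.data.frame(ct)
  df$reference <- attr(ct, "reference")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname ovoseed-io
#' @export
read_ct_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ct_table(df$sample_id, df$target, df$replicate, df$ct,
           reference = df$reference[1])
}
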
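#' First appearance of each ASV in the treated and control arms
#'
#' Records, for one experiment, the earliest sampled age (days posthatching)
#' at which each ASV is present in the treated arm and in the control arm
#' (`Inf` when never present), together with whether the ASV is present in
#' the donor (transplant, TRPL) material. Following the study's protocol,
#' transplant presence is taken from the UNFILTERED table while chick
#' presence is taken from the same abundance-filtered table used for the
#' balance analysis — pass the filtered table as `table` and the unfiltered
#' one as `transplant_table` (they default to the same object).
#'
#' @param table [asv_table()] used for chick presence (normally the
#'   quartile-filtered table).
#' @param frame a [sample_frame()] covering both tables' samples.
#' @param experiment `"pilot"` or `"repeat"`; first-appearance logic runs on
#'   whatever timepoints exist for that experiment.
#' @param transplant_table [asv_table()] used for TRPL presence (normally
#'   unfiltered).
#' @param min_count detection floor passed to [presence_set()].
#' @return an object of class `first_appearance`: data.frame with columns
#'   `asv_id`, `treated_first`, `control_first`, `in_transplant`, covering
#'   the union of chick-present and transplant-present ASVs, with the
#'   per-group presence membership matrix attached as attribute
#'   `"membership"` and the experiment's timepoints as `"timepoints"`.
#' @export
first_appearances <- function(table, frame, experiment,
                              transplant_table = table, min_count = 1L) {
  stopifnot(inherits(table, "asv_table"), inherits(transplant_table, "asv_table"))
  chick <- frame[frame$experiment == experiment, , drop = FALSE]
  if (!nrow(chick)) stop("no samples for experiment '", experiment, "'")
  trpl_ids <- frame$sample_id[frame$treatment == "transplant"]
  if (!length(trpl_ids)) stop("no TRPL samples in frame")
  timepoints <- sort(unique(chick$age_dph))

  in_trpl <- presence_set(transplant_table, trpl_ids, min_count)
  groups <- split(chick$sample_id, list(chick$treatment, chick$age_dph),
                  sep = "@", drop = TRUE)
  pres <- lapply(groups, function(ids) presence_set(table, ids, min_count))

  asvs <- sort(unique(c(in_trpl, unlist(pres))))
  first_in <- function(arm) {
    out <- stats::setNames(rep(Inf, length(asvs)), asvs)
    for (tp in timepoints) {
      key <- paste0(arm, "@", tp)
      hit <- intersect(pres[[key]], asvs)
      out[hit] <- pmin(out[hit], tp)
    }
    out
  }
  fa <- data.frame(asv_id = asvs,
                   treated_first = unname(first_in("treated")),
                   control_first = unname(first_in("control")),
                   in_transplant = asvs %in% in_trpl,
                   stringsAsFactors = FALSE)
  membership <- vapply(pres, function(s) asvs %in% s,
                       logical(length(asvs)))
  membership <- cbind(membership, TRPL = asvs %in% in_trpl)
  rownames(membership) <- asvs
  # human-readable group columns, e.g. "RT3"
  arm_age <- strsplit(setdiff(colnames(membership), "TRPL"), "@")
  colnames(membership)[seq_along(arm_age)] <- vapply(
    arm_age, function(x) group_label(experiment, x[1], x[2]), character(1))
  structure(fa, membership = membership, timepoints = timepoints,
            class = c("first_appearance", "data.frame"))
}

#' Classify ASVs by transplant success
#'
#' Applies the study's presence-based rules to a [first_appearances()]
#' record:
#'
#' * successfully transplanted - present in the transplant material and in
#'   treated chicks at least one timepoint before control chicks (including
#'   the case where controls never acquire it);
#' * possibly transplanted - present in the transplant and in both arms at
#'   the same first timepoint;
#' * environmental - present in the transplant but only, or first, in
#'   control chicks; and every ASV not present in the transplant.
#'
#' ASVs present only in the transplant (never in any chick sample) are
#' removed from classification and returned as the `dropped` set.
#'
#' @param fa a `first_appearance` object.
#' @return an object of class `transplant_calls`: data.frame with columns of
#'   `fa` plus `class`, with attribute `dropped` (transplant-only ASV ids).
#' @export
classify_transplant <- function(fa) {
  stopifnot(inherits(fa, "first_appearance"))
  seen_chick <- is.finite(fa$treated_first) | is.finite(fa$control_first)
  dropped <- fa$asv_id[fa$in_transplant & !seen_chick]
  kept <- fa[seen_chick, , drop = FALSE]
  class_of <- function(in_trpl, tf, cf) {
    if (!in_trpl) return("environmental")
    if (tf < cf) return("successfully_transplanted")
    if (tf == cf) return("possibly_transplanted")
    "environmental"  # control-only or control-first
  }
  kept$class <- mapply(class_of, kept$in_transplant,
                       kept$treated_first, kept$control_first)
  structure(kept, dropped = dropped,
            class = c("transplant_calls", "data.frame"))
}

#' Exclusive intersections of per-group presence sets
#'
#' UpSet-style summary: every distinct non-empty combination of group
#' memberships (including TRPL) with the number of ASVs belonging exactly to
#' that combination. The transplant-only intersection is omitted from the
#' summary, as in the study's visualization; the counts of the remaining
#' rows therefore sum to the number of distinct ASVs minus the
#' transplant-only ones.
#'
#' @param fa a `first_appearance` object.
#' @return data.frame with columns `groups` (comma-separated labels) and
#'   `n_asvs`, sorted by decreasing count. The full logical membership
#'   matrix is attached as attribute `"membership"` for UpSet export.
#' @export
intersection_summary <- function(fa) {
  stopifnot(inherits(fa, "first_appearance"))
  m <- attr(fa, "membership")
  pattern <- apply(m, 1, function(r) paste(colnames(m)[r], collapse = ","))
  tab <- table(pattern[pattern != "TRPL" & pattern != ""])
  out <- data.frame(groups = names(tab), n_asvs = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_asvs, out$groups), ]
  rownames(out) <- NULL
  structure(out, membership = m)
}

#' Chi-square test of independence
#'
#' Pearson's chi-square on an observed contingency table, without continuity
#' correction: expected `e_ij = row_i * col_j / N`,
#' `chi2 = sum (o - e)^2 / e`, `df = (rows - 1)(cols - 1)`, p from the upper
#' tail of the chi-square distribution. In this package the observed table
#' is transplant class by differential-abundance class (3 x 3, df = 4), but
#' the computation is general.
#'
#' @param observed non-negative integer matrix with all row and column sums
#'   positive.
#' @return an object of class `contingency_result`: list with `observed`,
#'   `expected`, `chi2`, `df`, `p`.
#' @export
chi_square_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0) || any(observed != round(observed)))
    stop("observed must be non-negative integers")
  if (any(rowSums(observed) == 0) || any(colSums(observed) == 0))
    stop("zero marginal: expected frequencies undefined")
  expected <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> chi2 = %.4g, df = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Cross-tabulate transplant calls against differential-abundance classes
#'
#' Builds the observed 3 x 3 table (transplant class by DA class) and runs
#' [chi_square_independence()] on it.
#'
#' @param calls a `transplant_calls` object.
#' @param da named class vector from [classify_da()]; ASVs absent from
#'   `calls` are ignored, ASVs absent from `da` are an error.
#' @return a `contingency_result` with the observed table in class order
#'   environmental / possibly / successfully by control / NDA / treated.
#' @export
transplant_da_contingency <- function(calls, da) {
  stopifnot(inherits(calls, "transplant_calls"))
  common <- intersect(calls$asv_id, names(da))
  miss <- setdiff(calls$asv_id, names(da))
  if (length(miss))
    stop("no DA class for ASV(s): ", paste(utils::head(miss, 5), collapse = ", "))
  obs <- table(
    factor(calls$class[match(common, calls$asv_id)],
           c("environmental", "possibly_transplanted",
             "successfully_transplanted")),
    factor(da[common], c("higher_in_control", "not_differentially_abundant",
                         "higher_in_treated")))
  chi_square_independence(unclass(obs))
}

#' Taxonomy breakdown of transplant calls at the family level
#'
#' @param calls a `transplant_calls` object.
#' @param taxonomy named lineage vector (see [read_taxonomy_tsv()]) or a
#'   named family vector; must cover every classified ASV.
#' @return data.frame with columns `family`, `total`, `successfully`,
#'   `possibly`, `environmental`, sorted by decreasing total; row totals
#'   equal the per-family ASV counts by construction.
#' @export
taxonomy_breakdown <- function(calls, taxonomy) {
  stopifnot(inherits(calls, "transplant_calls"))
  fam <- if (any(grepl(";", taxonomy))) taxonomy_family(taxonomy) else taxonomy
  miss <- setdiff(calls$asv_id, names(fam))
  if (length(miss))
    stop("taxonomy missing for ASV(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  tab <- table(factor(fam[calls$asv_id]),
               factor(calls$class,
                      c("successfully_transplanted", "possibly_transplanted",
                        "environmental")))
  out <- data.frame(family = rownames(tab),
                    total = as.integer(rowSums(tab)),
                    successfully = as.integer(tab[, 1]),
                    possibly = as.integer(tab[, 2]),
                    environmental = as.integer(tab[, 3]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$total, out$family), ]
  rownames(out) <- NULL
  out
}

#' Export transplant calls and contingency results as TSV
#'
#' @param calls a `transplant_calls` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @param result a `contingency_result`.
#' @export
write_contingency_tsv <- function(result, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(cbind(cell = "observed", as.data.frame(result$observed)),
                     con, sep = "\t", quote = FALSE)
  utils::write.table(cbind(cell = "expected", as.data.frame(result$expected)),
                     con, sep = "\t", quote = FALSE, col.names = FALSE)
  writeLines(sprintf("chi2\t%.10g\ndf\t%d\np\t%.10g",
                     result$chi2, result$df, result$p), con)
  invisible(path)
}

#' @rdname write_calls_tsv
#' @param fa a `first_appearance` object.
#' @export
write_upset_tsv <- function(fa, path) {
  m <- attr(fa, "membership")
  utils::write.table(cbind(asv_id = rownames(m), as.data.frame(m * 1L)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
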
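#' Quantitative-PCR cycle-threshold table
#'
#' Long-format container for triplicate CT measurements: one row per
#' (sample, target, replicate). Non-detection (no amplification within 40
#' cycles) is a first-class `NA` flag, never a substituted ceiling value.
#' Exactly one target is designated the reference gene (the study used the
#' whole-community V4 region of the 16S rRNA gene).
#'
#' @param sample_id,target,replicate,ct parallel vectors; `ct` in (0, 40]
#'   when detected, `NA` when non-detected.
#' @param reference name of the reference target; must appear in `target`.
#' @return data.frame of class `ct_table` with attribute `reference`.
#' @export
ct_table <- function(sample_id, target, replicate, ct, reference = "V4") {
  df <- data.frame(sample_id = as.character(sample_id),
                   target = as.character(target),
                   replicate = as.integer(replicate),
                   ct = as.numeric(ct), stringsAsFactors = FALSE)
  if (!reference %in% df$target)
    stop("reference target '", reference, "' absent from table")
  bad <- !is.na(df$ct) & (df$ct <= 0 | df$ct > 40)
  if (any(bad)) stop("detected CT values must lie in (0, 40]")
  if (anyDuplicated(df[c("sample_id", "target", "replicate")]))
    stop("duplicated (sample, target, replicate) rows")
  structure(df, reference = reference,
            class = c("ct_table", "data.frame"))
}

#' Relative abundance as 40 - delta-CT
#'
#' Averages the detected replicates per (sample, target), computes
#' `delta_CT = mean(CT_target) - mean(CT_reference)` and reports
#' `40 - delta_CT`, so larger values mean more abundant. Targets with no
#' detected replicate in a sample carry the non-detected flag through
#' (`value = NA`, `non_detected = TRUE`); samples whose reference gene never
#' amplified are excluded entirely with a warning, mirroring the study's
#' exclusion of one failed sample.
#'
#' @param ct a [ct_table()].
#' @return data.frame with columns `sample_id`, `target`, `delta_ct`,
#'   `value` (40 - delta-CT) and `non_detected`.
#' @export
relative_abundance <- function(ct) {
  stopifnot(inherits(ct, "ct_table"))
  ref <- attr(ct, "reference")
  mean_ct <- stats::aggregate(ct$ct, list(sample_id = ct$sample_id,
                                          target = ct$target),
                              function(v) mean(v[!is.na(v)]))
  names(mean_ct)[3] <- "mean_ct"
  ref_ct <- mean_ct[mean_ct$target == ref, c("sample_id", "mean_ct")]
  dead <- ref_ct$sample_id[is.nan(ref_ct$mean_ct)]
  if (length(dead))
    warning("reference gene not detected; excluding sample(s): ",
            paste(dead, collapse = ", "))
  out <- mean_ct[mean_ct$target != ref & !(mean_ct$sample_id %in% dead), ]
  out$delta_ct <- out$mean_ct - ref_ct$mean_ct[match(out$sample_id,
                                                     ref_ct$sample_id)]
  out$value <- 40 - out$delta_ct
  out$non_detected <- is.nan(out$mean_ct)
  out$delta_ct[out$non_detected] <- NA_real_
  out$value[out$non_detected] <- NA_real_
  rownames(out) <- NULL
  out[c("sample_id", "target", "delta_ct", "value", "non_detected")]
}

#' Compare 40 - delta-CT between treated and control chicks
#'
#' Two-sample t test (pooled variance by default) on the relative-abundance
#' values of one target at one timepoint. When exactly one arm is entirely
#' non-detected the comparison is degenerate: no defensible test statistic
#' exists without inventing an imputation, so the result is flagged
#' (`status = "degenerate_one_arm_nondetected"`, `t` and `p` are `NA`)
#' rather than fabricated. When both arms are entirely non-detected the
#' status is `"not_comparable"`.
#'
#' @param values output of [relative_abundance()].
#' @param frame a [sample_frame()].
#' @param target target taxon.
#' @param timepoint age in days posthatching.
#' @param var_equal pooled (TRUE) or Welch (FALSE) t test.
#' @return list with `t`, `p`, `mean_treated`, `mean_control`,
#'   `n_detected` (named by arm) and `status` (`"ok"` or a flag).
#' @export
group_compare <- function(values, frame, target, timepoint,
                          var_equal = TRUE) {
  arm_values <- function(arm) {
    ids <- frame$sample_id[frame$treatment == arm &
                             !is.na(frame$age_dph) &
                             frame$age_dph == timepoint]
    v <- values$value[values$target == target &
                        values$sample_id %in% ids]
    v[!is.na(v)]
  }
  x <- arm_values("treated"); y <- arm_values("control")
  n <- c(treated = length(x), control = length(y))
  base <- list(t = NA_real_, p = NA_real_,
               mean_treated = if (length(x)) mean(x) else NA_real_,
               mean_control = if (length(y)) mean(y) else NA_real_,
               n_detected = n)
  if (!length(x) && !length(y)) return(c(base, status = "not_comparable"))
  if (!length(x) || !length(y))
    return(c(base, status = "degenerate_one_arm_nondetected"))
  if (length(x) < 2 || length(y) < 2)
    return(c(base, status = "insufficient_detected_replicates"))
  tt <- two_sample_t(x, y, var_equal)
  c(base[c("mean_treated", "mean_control", "n_detected")],
    list(t = tt$t, p = tt$p, status = "ok"))
}

# two-sample t test that tolerates zero-variance groups: stats::t.test
# refuses constant data, but equal constant groups are a meaningful t = 0
two_sample_t <- function(x, y, var_equal = TRUE) {
  s <- function(v) if (length(v) < 2) 0 else stats::sd(v)
  if (s(c(x, y)) == 0 || (s(x) == 0 && s(y) == 0)) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), p = tt$p.value)
}
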
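# compact builder for first-appearance records used in rule tests
fa_record <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(asv_id = r[[1]], treated_first = r[[2]],
               control_first = r[[3]], in_transplant = r[[4]],
               stringsAsFactors = FALSE)))
  structure(df, timepoints = c(0, 3, 7, 14),
            membership = matrix(TRUE, nrow(df), 1,
                                dimnames = list(df$asv_id, "TRPL")),
            class = c("first_appearance", "data.frame"))
}

test_that("classify_transplant applies the presence rules verbatim", {
  fa <- fa_record(
    list("succ_early",   3,   7,   TRUE),   # treated one timepoint before
    list("succ_only_t",  3,   Inf, TRUE),   # treated only: still earlier
    list("poss_same",    3,   3,   TRUE),   # same first timepoint
    list("env_not_trpl", 0,   0,   FALSE),  # not in transplant
    list("env_c_only",   Inf, 3,   TRUE),   # control only
    list("env_c_first",  7,   3,   TRUE),   # control before treated
    list("trpl_only",    Inf, Inf, TRUE))   # never in chicks: dropped
  calls <- classify_transplant(fa)
  got <- setNames(calls$class, calls$asv_id)
  expect_equal(got[["succ_early"]], "successfully_transplanted")
  expect_equal(got[["succ_only_t"]], "successfully_transplanted")
  expect_equal(got[["poss_same"]], "possibly_transplanted")
  expect_equal(got[["env_not_trpl"]], "environmental")
  expect_equal(got[["env_c_only"]], "environmental")
  expect_equal(got[["env_c_first"]], "environmental")
  expect_false("trpl_only" %in% calls$asv_id)
  expect_identical(attr(calls, "dropped"), "trpl_only")

  # deterministic and order-independent
  perm <- fa[sample(nrow(fa)), ]
  attr(perm, "timepoints") <- attr(fa, "timepoints")
  attr(perm, "membership") <- attr(fa, "membership")
  class(perm) <- class(fa)
  calls2 <- classify_transplant(perm)
  expect_equal(setNames(calls2$class, calls2$asv_id)[names(got)], got)
})

test_that("enlarging the transplant set never demotes an ASV", {
  set.seed(61)
  for (rep in 1:30) {
    tf <- sample(c(0, 3, 7, 14, Inf), 1)
    cf <- sample(c(0, 3, 7, 14, Inf), 1)
    if (!is.finite(tf) && !is.finite(cf)) next
    before <- classify_transplant(fa_record(list("x", tf, cf, FALSE)))$class
    after <- classify_transplant(fa_record(list("x", tf, cf, TRUE)))$class
    rank <- c(environmental = 0, possibly_transplanted = 1,
              successfully_transplanted = 2)
    expect_gte(rank[[after]], rank[[before]])
  }
})

test_that("first_appearances separates unfiltered TRPL from filtered chicks", {
  frame <- sample_frame(
    c("RT3_1", "RT7_1", "RC3_1", "RC7_1", "TRPL_1"),
    c(rep("repeat", 4), "donor"),
    c("treated", "treated", "control", "control", "transplant"),
    c(3L, 7L, 3L, 7L, NA))
  #              rare  shared  ctrl   chickonly
  full <- toy_table(rbind(
    RT3_1  = c(0L, 5L, 0L, 2L),
    RT7_1  = c(0L, 5L, 0L, 0L),
    RC3_1  = c(0L, 0L, 3L, 0L),
    RC7_1  = c(0L, 5L, 0L, 0L),
    TRPL_1 = c(1L, 9L, 4L, 0L)),
    asvs = c("rare", "shared", "ctrl", "chickonly"))
  filtered <- full[, c("shared", "ctrl", "chickonly")]
  fa <- first_appearances(filtered, frame, "repeat", transplant_table = full)
  # 'rare' survives only in the unfiltered transplant table
  expect_true(fa$in_transplant[fa$asv_id == "rare"])
  expect_equal(fa$treated_first[fa$asv_id == "shared"], 3)
  expect_equal(fa$control_first[fa$asv_id == "shared"], 7)
  expect_equal(fa$treated_first[fa$asv_id == "ctrl"], Inf)
  calls <- classify_transplant(fa)
  got <- setNames(calls$class, calls$asv_id)
  expect_equal(got[["shared"]], "successfully_transplanted")
  expect_equal(got[["ctrl"]], "environmental")
  expect_equal(got[["chickonly"]], "environmental")
  expect_identical(attr(calls, "dropped"), "rare")
  expect_error(first_appearances(filtered, frame, "pilot"), "pilot")
})

test_that("first appearances match the ground-truth schedule at high depth", {
  cfg <- scenario_config(n_donor_asvs = 40, n_environmental_asvs = 15,
                         n_per_group = 6, depth_mean = 3e5, sigma_log = 0.8,
                         seed = 13)
  sim <- simulate_study(cfg)
  fa <- first_appearances(sim$table, sim$frame, "repeat")
  tr <- sim$truth
  idx <- match(fa$asv_id, names(tr$treated_first))
  expect_equal(fa$treated_first, unname(tr$treated_first[idx]))
  expect_equal(fa$control_first, unname(tr$control_first[idx]))
})

test_that("intersection_summary partitions the observed ASVs", {
  frame <- sample_frame(
    c("RT3_1", "RC3_1", "TRPL_1"), c("repeat", "repeat", "donor"),
    c("treated", "control", "transplant"), c(3L, 3L, NA))
  tab <- toy_table(rbind(RT3_1 = c(1L, 0L, 1L, 0L),
                         RC3_1 = c(0L, 2L, 1L, 0L),
                         TRPL_1 = c(3L, 0L, 1L, 2L)),
                   asvs = c("t_only", "c_only", "all3", "trpl_only"))
  fa <- first_appearances(tab, frame, "repeat")
  out <- intersection_summary(fa)
  expect_false("TRPL" %in% out$groups)  # transplant-only row omitted
  expect_equal(sum(out$n_asvs), 3)      # total distinct minus transplant-only
  expect_equal(out$n_asvs[out$groups == "RC3,RT3,TRPL"], 1)
  # disjoint arms yield singleton intersections
  expect_true(all(c("RT3,TRPL", "RC3") %in% out$groups))
})

test_that("the TRPL + all-treated intersection is populated when spores survive", {
  sim <- simulate_study(tiny_config(seed = 14, spore_fraction = 0.5))
  fa <- first_appearances(sim$table, sim$frame, "repeat")
  m <- attr(intersection_summary(fa), "membership")
  treated_cols <- grep("^RT", colnames(m), value = TRUE)
  expect_gt(sum(m[, "TRPL"] & rowSums(m[, treated_cols]) == length(treated_cols)),
            0)
})

test_that("chi_square_independence matches hand formulas and validates input", {
  # proportional rows: independence exactly
  prop <- matrix(c(10, 20, 30, 60, 1, 2, 3, 6), 4, 2)
  expect_equal(chi_square_independence(prop)$chi2, 0)
  # 2x2 diagonal: all expected 5, chi2 = 4 * 25/5 = 20
  res <- chi_square_independence(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  expect_error(chi_square_independence(matrix(c(1, 0, 2, 0), 2, 2)),
               "marginal")
  expect_error(chi_square_independence(matrix(c(-1, 1, 1, 1), 2, 2)))
})

test_that("chi-square equals the textbook oracle on random tables", {
  set.seed(62)
  for (rep in 1:200) {
    m <- random_contingency(sample(2:4, 1), sample(2:4, 1))
    res <- chi_square_independence(m)
    expect_equal(res$chi2, oracle_chi2(m), tolerance = 1e-9)
    expect_equal(res$df, (nrow(m) - 1) * (ncol(m) - 1))
    expect_equal(rowSums(res$expected), rowSums(m))
  }
})

test_that("taxonomy_breakdown row totals equal the class sums", {
  fa <- fa_record(list("a", 3, 7, TRUE), list("b", 3, 3, TRUE),
                  list("c", Inf, 3, TRUE), list("d", 0, 0, FALSE))
  calls <- classify_transplant(fa)
  tax <- c(a = "d__B; f__Lachnospiraceae", b = "d__B; f__Lachnospiraceae",
           c = "d__B; f__Ruminococcaceae", d = "d__B; f__Lachnospiraceae")
  out <- taxonomy_breakdown(calls, tax)
  expect_equal(out$total, out$successfully + out$possibly + out$environmental)
  lachno <- out[out$family == "Lachnospiraceae", ]
  expect_equal(lachno$total, 3)
  expect_equal(lachno[, c("successfully", "possibly", "environmental")],
               data.frame(successfully = 1, possibly = 1, environmental = 1),
               ignore_attr = TRUE)
  expect_error(taxonomy_breakdown(calls, tax[1:2]), "missing")
})

test_that("donor-surviving families dominate the successful column", {
  sim <- simulate_study(tiny_config(seed = 15))
  f <- quartile_filter(sim$table)
  fa <- first_appearances(f$table, sim$frame, "repeat",
                          transplant_table = sim$table)
  calls <- classify_transplant(fa)
  out <- taxonomy_breakdown(calls, sim$taxonomy)
  surv_fams <- unique(sim$truth$family[sim$truth$origin == "donor_surviving"])
  n_succ <- sum(out$successfully)
  expect_gt(n_succ, 0)
  expect_equal(sum(out$successfully[out$family %in% surv_fams]), n_succ)
})

test_that("transplant_da_contingency assembles the observed 3x3", {
  fa <- fa_record(list("a", 3, 7, TRUE), list("b", 3, 3, TRUE),
                  list("c", Inf, 3, TRUE), list("d", 0, 0, FALSE),
                  list("e", 0, 3, TRUE), list("f", 7, 7, TRUE))
  calls <- classify_transplant(fa)
  da <- c(a = "higher_in_treated", b = "not_differentially_abundant",
          c = "higher_in_control", d = "not_differentially_abundant",
          e = "higher_in_treated", f = "higher_in_control")
  res <- transplant_da_contingency(calls, da)
  expect_equal(sum(res$observed), 6)
  expect_equal(res$df, 4)
  expect_equal(res$observed["successfully_transplanted", "higher_in_treated"], 2)
  expect_error(transplant_da_contingency(calls, da[1:3]), "no DA class")
})

test_that("call and contingency exports round-trip the key numbers", {
  fa <- fa_record(list("a", 3, 7, TRUE), list("b", 3, 3, TRUE),
                  list("c", 0, 0, FALSE))
  calls <- classify_transplant(fa)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_calls_tsv(calls, path)
  back <- read.delim(path)
  expect_equal(back$class, calls$class)
  res <- chi_square_independence(matrix(c(10, 2, 3, 11), 2, 2))
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_contingency_tsv(res, path2)
  lines <- readLines(path2)
  expect_true(any(grepl(sprintf("chi2\t%.10g", res$chi2), lines, fixed = TRUE)))
})
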
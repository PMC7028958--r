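#' Scenario configuration for the synthetic engraftment study
#'
#' Describes the world the generator emulates: a pooled adult cecal-content
#' donor community ("transplant", TRPL) of which only a spore-forming subset
#' survives on the eggshell, chick cecal communities sampled over days
#' posthatching in a treated and a control arm, and multinomial sequencing
#' noise. Surviving donor ASVs are scheduled to appear in treated chicks
#' `engraftment_lead` timepoints before they appear in controls; environmental
#' ASVs colonize both arms on the same schedule; non-surviving donor ASVs
#' never appear in any chick.
#'
#' Defaults mirror the study's descriptive numbers where it states them
#' (445 donor ASVs; timepoints 0, 3, 7, 14 dph; about 7 chicks per group;
#' mean sequencing depth 82,544 reads) and field-typical values where it does
#' not (log-normal rank-abundance with `sigma_log = 1.5`; 40% of donor ASVs
#' eggshell-surviving; 80 environmental ASVs).
#'
#' @param n_donor_asvs number of ASVs in the donor community.
#' @param spore_fraction proportion of donor ASVs that survive on the
#'   eggshell and can engraft.
#' @param n_environmental_asvs number of environment-derived ASVs.
#' @param timepoints strictly increasing ages in days posthatching.
#' @param n_per_group chick samples per arm per timepoint.
#' @param n_trpl donor (TRPL) samples.
#' @param depth_mean expected reads per sample (Poisson); must be at least
#'   5,000 so rarefaction at the study depth is feasible.
#' @param engraftment_lead number of timepoints by which surviving donor ASVs
#'   precede their appearance in controls.
#' @param sigma_log log-normal shape of the rank-abundance distributions.
#' @param experiment experiment label for the chick samples.
#' @param seed integer RNG seed; the entire simulation is a deterministic
#'   function of the configuration including this seed.
#' @param succession_profile families-by-timepoints matrix of relative-
#'   abundance multipliers encoding community succession (environmental
#'   Enterobacteriaceae dominant at hatch, replaced by Lachnospiraceae and
#'   then Ruminococcaceae). Row names are families, one column per timepoint.
#' @return a list of class `scenario_config`.
#' @seealso [simulate_study()], [simulate_qpcr()]
#' @export
scenario_config <- function(n_donor_asvs = 445L,
                            spore_fraction = 0.4,
                            n_environmental_asvs = 80L,
                            timepoints = c(0L, 3L, 7L, 14L),
                            n_per_group = 7L,
                            n_trpl = 3L,
                            depth_mean = 82544,
                            engraftment_lead = 1L,
                            sigma_log = 1.5,
                            experiment = "repeat",
                            seed = 1L,
                            succession_profile = default_succession(timepoints)) {
  stopifnot(n_donor_asvs >= 1, n_environmental_asvs >= 1,
            spore_fraction >= 0, spore_fraction <= 1,
            length(timepoints) >= 1, all(diff(timepoints) > 0),
            n_per_group >= 1, n_trpl >= 1,
            depth_mean >= 5000,
            engraftment_lead >= 0, sigma_log > 0,
            is.matrix(succession_profile),
            ncol(succession_profile) == length(timepoints),
            all(succession_profile > 0))
  structure(list(n_donor_asvs = as.integer(n_donor_asvs),
                 spore_fraction = spore_fraction,
                 n_environmental_asvs = as.integer(n_environmental_asvs),
                 timepoints = as.integer(timepoints),
                 n_per_group = as.integer(n_per_group),
                 n_trpl = as.integer(n_trpl),
                 depth_mean = depth_mean,
                 engraftment_lead = as.integer(engraftment_lead),
                 sigma_log = sigma_log,
                 experiment = experiment,
                 seed = as.integer(seed),
                 succession_profile = succession_profile),
            class = "scenario_config")
}

# family vocabulary of the study's taxonomy summaries, with sampling weights
# for donor vs environmental origin
.donor_families <- c("Lachnospiraceae" = 0.43, "Ruminococcaceae" = 0.35,
                     "Clostridiales vadin BB60 group" = 0.07,
                     "Christensenellaceae" = 0.04, "Erysipelotrichaceae" = 0.04,
                     "Peptococcaceae" = 0.03, "Bacteroidaceae" = 0.02,
                     "Lactobacillaceae" = 0.02)
.env_families <- c("Enterobacteriaceae" = 0.30, "Clostridiaceae 1" = 0.25,
                   "Bacillaceae" = 0.12, "Enterococcaceae" = 0.10,
                   "Peptostreptococcaceae" = 0.10, "Paenibacillaceae" = 0.07,
                   "Staphylococcaceae" = 0.04, "Microbacteriaceae" = 0.02)

#' Default successional trajectory
#'
#' Relative-abundance multipliers per family over the sampled ages:
#' Enterobacteriaceae start high and decay, Lachnospiraceae rise first,
#' Ruminococcaceae rise later; families not listed hold a constant weight.
#'
#' @param timepoints ages in days posthatching.
#' @return families-by-timepoints numeric matrix.
#' @export
default_succession <- function(timepoints) {
  k <- length(timepoints)
  ramp <- function(from, to) exp(seq(log(from), log(to), length.out = k))
  families <- union(names(.donor_families), names(.env_families))
  prof <- matrix(1, length(families), k,
                 dimnames = list(families, as.character(timepoints)))
  prof["Enterobacteriaceae", ] <- ramp(8, 0.25)
  prof["Clostridiaceae 1", ] <- ramp(3, 0.5)
  prof["Lachnospiraceae", ] <- c(ramp(0.5, 3)[-1], 3)[seq_len(k)]
  prof["Ruminococcaceae", ] <- ramp(0.2, 3)
  prof
}

#' Simulate an egg-surface transplant study
#'
#' Generates the full input set of the analysis chain: an ASV count table
#' over TRPL (donor) and chick samples, per-sample metadata, a taxonomy, a
#' random rooted bifurcating phylogeny covering all ASVs, and the ground
#' truth the classifier-recovery tests score against.
#'
#' The generative model: donor and environmental ASVs receive log-normal
#' base abundances; each surviving donor ASV is scheduled a first-appearance
#' timepoint in the treated arm (weighted towards early ages) and appears in
#' the control arm `engraftment_lead` timepoints later (possibly never);
#' environmental ASVs share one schedule across arms. A chick sample at age t
#' has expected composition proportional to base abundance times the family's
#' succession multiplier at t, restricted to ASVs scheduled to be present;
#' observed counts are multinomial at a Poisson(`depth_mean`) depth. TRPL
#' samples are multinomial draws from the donor community itself.
#'
#' @param config a [scenario_config()].
#' @return a list with elements `table` ([asv_table()]), `frame`
#'   ([sample_frame()]), `taxonomy` (named lineage vector), `tree`
#'   (ape `phylo`), and `truth` (see Details).
#' @details `truth` is a list: `origin` (named vector in
#'   `donor_surviving` / `donor_nonsurviving` / `environmental`),
#'   `treated_first` / `control_first` (named vectors of scheduled
#'   first-appearance ages, `Inf` for never), and `expected_proportions`
#'   (samples-by-ASVs matrix of pre-noise compositions, bookkeeping used by
#'   [simulate_qpcr()] and the rank-correlation tests).
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cf <- config
  nt <- length(cf$timepoints)
  if (cf$n_per_group < 1 || cf$n_trpl < 1) stop("empty group in design")
  withr_seed(cf$seed, {
    n_d <- cf$n_donor_asvs
    n_e <- cf$n_environmental_asvs
    donor_ids <- sprintf("asv_d%03d", seq_len(n_d))
    env_ids <- sprintf("asv_e%03d", seq_len(n_e))
    asv_ids <- c(donor_ids, env_ids)

    fam_d <- sample(names(.donor_families), n_d, TRUE, .donor_families)
    fam_e <- sample(names(.env_families), n_e, TRUE, .env_families)
    family <- stats::setNames(c(fam_d, fam_e), asv_ids)

    base <- stats::setNames(stats::rlnorm(n_d + n_e, 0, cf$sigma_log), asv_ids)
    donor_prop <- base[donor_ids] / sum(base[donor_ids])

    n_surv <- round(cf$spore_fraction * n_d)
    surviving <- sample(donor_ids, n_surv)
    origin <- stats::setNames(rep("environmental", n_d + n_e), asv_ids)
    origin[donor_ids] <- "donor_nonsurviving"
    origin[surviving] <- "donor_surviving"

    # scheduled first-appearance timepoint INDEX per arm (Inf age = never)
    idx_weights <- rev(seq_len(nt)) / sum(seq_len(nt))  # early-weighted
    t_idx <- stats::setNames(rep(NA_integer_, n_d + n_e), asv_ids)
    t_idx[surviving] <- sample(seq_len(nt), n_surv, TRUE, idx_weights)
    t_idx[env_ids] <- sample(seq_len(nt), n_e, TRUE, idx_weights)
    c_idx <- t_idx
    c_idx[surviving] <- t_idx[surviving] + cf$engraftment_lead
    age_of <- function(i) ifelse(is.na(i) | i > nt, Inf, cf$timepoints[pmax(i, 1)])
    treated_first <- stats::setNames(age_of(t_idx), asv_ids)
    control_first <- stats::setNames(age_of(c_idx), asv_ids)

    # design: TRPL samples then arm x timepoint blocks
    sid <- character(0); exper <- character(0); treat <- character(0)
    age <- integer(0)
    sid <- sprintf("TRPL_%d", seq_len(cf$n_trpl))
    exper <- rep("donor", cf$n_trpl)
    treat <- rep("transplant", cf$n_trpl)
    age <- rep(NA_integer_, cf$n_trpl)
    for (arm in c("control", "treated")) for (k in seq_len(nt)) {
      lab <- group_label(cf$experiment, arm, cf$timepoints[k])
      sid <- c(sid, sprintf("%s_%d", lab, seq_len(cf$n_per_group)))
      exper <- c(exper, rep(cf$experiment, cf$n_per_group))
      treat <- c(treat, rep(arm, cf$n_per_group))
      age <- c(age, rep(cf$timepoints[k], cf$n_per_group))
    }
    frame <- sample_frame(sid, exper, treat, age)

    # expected compositions
    expected <- matrix(0, length(sid), length(asv_ids),
                       dimnames = list(sid, asv_ids))
    expected[frame$treatment == "transplant", ] <-
      matrix(c(donor_prop, numeric(n_e)), cf$n_trpl, length(asv_ids),
             byrow = TRUE)
    prof <- cf$succession_profile
    for (i in which(frame$treatment != "transplant")) {
      k <- match(frame$age_dph[i], cf$timepoints)
      first <- if (frame$treatment[i] == "treated") treated_first else control_first
      present <- first <= frame$age_dph[i]
      if (!any(present)) stop("no ASV present in sample ", sid[i],
                              "; adjust the scenario schedule")
      w <- base * prof[family, k] * present
      expected[i, ] <- w / sum(w)
    }

    depths <- stats::rpois(length(sid), cf$depth_mean)
    counts <- matrix(0L, length(sid), length(asv_ids),
                     dimnames = list(sid, asv_ids))
    for (i in seq_along(sid))
      counts[i, ] <- as.integer(stats::rmultinom(1, depths[i], expected[i, ]))

    tree <- ape::rcoal(length(asv_ids), tip.label = sample(asv_ids))

    lineage <- sprintf("d__Bacteria; p__Firmicutes; c__Clostridia; o__Clostridiales; f__%s; g__unassigned",
                       family)
    taxonomy <- stats::setNames(lineage, asv_ids)
    taxonomy[family == "Enterobacteriaceae"] <-
      sub("p__Firmicutes; c__Clostridia; o__Clostridiales",
          "p__Proteobacteria; c__Gammaproteobacteria; o__Enterobacteriales",
          taxonomy[family == "Enterobacteriaceae"])

    list(table = asv_table(counts), frame = frame, taxonomy = taxonomy,
         tree = tree,
         truth = list(origin = origin, treated_first = treated_first,
                      control_first = control_first,
                      family = family,
                      expected_proportions = expected))
  })
}

#' Simulate triplicate qPCR cycle-threshold values
#'
#' Emulates the study's relative-quantification assay: for every sample and
#' every target family, three cycle-threshold (CT) replicates plus triplicate
#' reference-gene (whole-community V4) CTs. Under ideal amplification
#' efficiency a target at true proportion p crosses threshold
#' `-log2(p)` cycles after the reference, so CT_target =
#' CT_ref - log2(p) + noise; replicates that would cross after cycle 40 are
#' reported as non-detected (`NA`), never imputed.
#'
#' @param config the [scenario_config()] the truth came from.
#' @param truth the `truth` element of [simulate_study()].
#' @param targets families to assay (default: the two succession markers and
#'   Enterobacteriaceae).
#' @param samples sample ids to assay (default: all rows of the recorded
#'   composition matrix).
#' @param ct_ref mean reference-gene CT.
#' @param noise_sd replicate-to-replicate CT standard deviation.
#' @return a [ct_table()].
#' @export
simulate_qpcr <- function(config, truth,
                          targets = c("Lachnospiraceae", "Ruminococcaceae",
                                      "Enterobacteriaceae"),
                          samples = rownames(truth$expected_proportions),
                          ct_ref = 16, noise_sd = 0.1) {
  stopifnot(inherits(config, "scenario_config"),
            is.matrix(truth$expected_proportions))
  prop <- truth$expected_proportions[samples, , drop = FALSE]
  withr_seed(config$seed + 1L, {
    rows <- list()
    for (s in samples) {
      ref_ct <- ct_ref + stats::rnorm(3, 0, noise_sd)
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, target = "V4", replicate = 1:3, ct = ref_ct)
      for (tg in targets) {
        p <- sum(prop[s, truth$family == tg])
        ct <- if (p > 0) mean(ref_ct) - log2(p) + stats::rnorm(3, 0, noise_sd)
              else rep(Inf, 3)
        ct[ct > 40] <- NA  # crossed after the last cycle: non-detected
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = s, target = tg, replicate = 1:3, ct = ct)
      }
    }
    df <- do.call(rbind, rows)
    ct_table(df$sample_id, df$target, df$replicate, df$ct, reference = "V4")
  })
}
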
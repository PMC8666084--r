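#' Human chromosome lengths (GRCh38)
#'
#' Base-pair lengths of chromosomes 1-22, X and Y in the GRCh38 assembly,
#' used as the default genomic coordinate space of the simulator.
#'
#' @return named numeric vector (bare chromosome labels).
#' @export
default_chromosome_lengths <- function() {
  c("1" = 248956422, "2" = 242193529, "3" = 198295559, "4" = 190214555,
    "5" = 181538259, "6" = 170805979, "7" = 159345973, "8" = 145138636,
    "9" = 138394717, "10" = 133797422, "11" = 135086622, "12" = 133275309,
    "13" = 114364328, "14" = 107043718, "15" = 101991189, "16" = 90338345,
    "17" = 83257441, "18" = 80373285, "19" = 58617616, "20" = 64444167,
    "21" = 46709983, "22" = 50818468, "X" = 156040895, "Y" = 57227415)
}

#' Cohort specification for the CNV simulator
#'
#' CNVs recur at polymorphic loci: the generator first draws a pool of
#' candidate CNV loci (position and length per locus, log-uniform lengths
#' within `len_range`), then gives each subject CNVs at loci sampled
#' without replacement, with per-carrier breakpoint jitter of
#' `jitter` x locus length on each side. This mirrors real call sets, in
#' which the same copy number polymorphism is observed across many
#' subjects with slightly different breakpoints — the source of
#' between-subject profile similarity.
#'
#' The rare scenario confines the cohort to one randomly chosen chromosome
#' with 1..`max_cnvs_rare` CNVs per subject (uniform), emulating rare CNV
#' profiles capped at five CNVs. The common scenario draws Poisson CNV
#' counts per subject from a genome-wide pool (loci allocated to
#' chromosomes proportional to length). Types are deletions with
#' probability `p_deletion` (default 0.35, the observed
#' deletion:amplification ratio of roughly 0.35:0.65).
#'
#' @param n_subjects positive integer cohort size.
#' @param scenario `"rare"` or `"common"`.
#' @param max_cnvs_rare per-subject CNV cap in the rare scenario (default 5).
#' @param mean_cnvs_common Poisson mean CNVs/subject in the common scenario
#'   (default 3, matching real call sets averaging about 3 CNVs/subject).
#' @param loci_per_chrom average number of recurrent CNV loci per
#'   chromosome (default 20).
#' @param jitter per-carrier breakpoint jitter as a fraction of locus
#'   length (default 0.1).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param len_range CNV length bounds in bp, log-uniform (default 1e4-1e6).
#' @param p_deletion probability a CNV is a deletion, in (0, 1).
#' @return object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects, scenario = c("rare", "common"),
                        max_cnvs_rare = 5L, mean_cnvs_common = 3,
                        loci_per_chrom = 20L, jitter = 0.1,
                        chrom_lengths = default_chromosome_lengths(),
                        len_range = c(1e4, 1e6), p_deletion = 0.35) {
  scenario <- match.arg(scenario)
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 1)
    stop("n_subjects must be a positive integer", call. = FALSE)
  stopifnot(max_cnvs_rare >= 1, mean_cnvs_common >= 0,
            loci_per_chrom >= 1, jitter >= 0, jitter < 0.5,
            length(len_range) == 2L, len_range[1] >= 1,
            len_range[2] >= len_range[1],
            p_deletion > 0, p_deletion < 1,
            length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)))
  if (len_range[2] * (1 + 2 * jitter) > min(chrom_lengths))
    stop("CNV length bound exceeds the shortest chromosome", call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), scenario = scenario,
                 max_cnvs_rare = as.integer(max_cnvs_rare),
                 mean_cnvs_common = mean_cnvs_common,
                 loci_per_chrom = as.integer(loci_per_chrom), jitter = jitter,
                 chrom_lengths = chrom_lengths, len_range = len_range,
                 p_deletion = p_deletion),
            class = "cohort_spec")
}

#' Dosage randomization specification
#'
#' Deletions draw dosage 0 or 1 (default equal probability 0.5); ampli-
#' fications draw 3..7 (default equal probability 0.2 each).
#'
#' @param deletion_values named numeric vector of probabilities over
#'   deletion dosages.
#' @param amplification_values named numeric vector of probabilities over
#'   amplification dosages (> 2).
#' @return object of class `"dosage_spec"`.
#' @export
dosage_spec <- function(deletion_values = c("0" = 0.5, "1" = 0.5),
                        amplification_values = c("3" = 0.2, "4" = 0.2,
                                                 "5" = 0.2, "6" = 0.2,
                                                 "7" = 0.2)) {
  chk <- function(v, nm) {
    if (abs(sum(v) - 1) > 1e-9) stop(nm, " probabilities must sum to 1", call. = FALSE)
    if (is.null(names(v))) stop(nm, " must be named by dosage value", call. = FALSE)
    v
  }
  del <- chk(deletion_values, "deletion")
  amp <- chk(amplification_values, "amplification")
  if (!all(as.numeric(names(del)) %in% c(0, 1)))
    stop("deletion dosages must lie in {0, 1}", call. = FALSE)
  if (!all(as.numeric(names(amp)) > 2))
    stop("amplification dosages must exceed 2", call. = FALSE)
  structure(list(deletion_values = del, amplification_values = amp),
            class = "dosage_spec")
}

#' Effect specification for the label-generating logistic model
#'
#' Coefficients of the per-CNV terms in the case-control label model: for
#' subject i with CNVs j = 1..m_i,
#' `logit P(Y_i = 1) = beta0 + sum_j [ beta_len * len_j / ls
#'   + beta_del * I(del_j) + beta_amp * I(amp_j) + beta_dsg * |d_j - 2|
#'   + beta_len_del_dsg * (len_j / ls) * I(del_j) * d_j
#'   + beta_len_amp_dsg * (len_j / ls) * I(amp_j) * d_j ]`
#' with `len_j = end_j - start_j` and `ls = length_scale`. All-zero
#' non-intercept coefficients define the null scenario.
#'
#' @param beta0 baseline logit (disease prevalence on the logit scale). The
#'   default `qlogis(877/1214)` (about 0.956, prevalence 0.72) matches the
#'   affected:control composition of the neurological-deficit cohorts the
#'   simulation design emulates (877 individuals with dyslexia or
#'   intellectual disability vs 337 controls).
#' @param beta_len,beta_del,beta_amp,beta_dsg main-effect coefficients.
#' @param beta_len_del_dsg,beta_len_amp_dsg interaction coefficients.
#' @param length_scale bp divisor applied to length terms to keep logits
#'   finite (default 1e6).
#' @return object of class `"effect_spec"`.
#' @export
effect_spec <- function(beta0 = stats::qlogis(877 / 1214), beta_len = 0,
                        beta_del = 0, beta_amp = 0,
                        beta_dsg = 0, beta_len_del_dsg = 0,
                        beta_len_amp_dsg = 0, length_scale = 1e6) {
  stopifnot(length_scale > 0)
  structure(list(beta0 = beta0, beta_len = beta_len, beta_del = beta_del,
                 beta_amp = beta_amp, beta_dsg = beta_dsg,
                 beta_len_del_dsg = beta_len_del_dsg,
                 beta_len_amp_dsg = beta_len_amp_dsg,
                 length_scale = length_scale),
            class = "effect_spec")
}

# pool of candidate recurrent CNV loci: one chromosome (rare) or the whole
# genome with loci allocated proportional to chromosome length (common)
draw_locus_pool <- function(spec) {
  if (spec$scenario == "rare") {
    ch <- sample(names(spec$chrom_lengths), 1L)
    n_loci <- rep(spec$loci_per_chrom, 1L)
    names(n_loci) <- ch
  } else {
    tot <- spec$loci_per_chrom * length(spec$chrom_lengths)
    n_loci <- round(tot * spec$chrom_lengths / sum(spec$chrom_lengths))
    n_loci[n_loci < 1] <- 1
  }
  chrom <- rep(names(n_loci), n_loci)
  m <- length(chrom)
  len <- round(exp(stats::runif(m, log(spec$len_range[1]),
                                log(spec$len_range[2]))))
  L <- unname(spec$chrom_lengths[chrom])
  margin <- ceiling(len * spec$jitter) + 1
  start <- floor(stats::runif(m, 1 + margin, L - len - margin + 1))
  data.frame(chrom = chrom, start = start, end = start + len - 1,
             stringsAsFactors = FALSE)
}

#' Prevalence-preserving effect specification for power studies
#'
#' A nonzero per-CNV effect shifts every subject's linear predictor by
#' roughly `beta * E[per-subject burden]`, which drives the prevalence to
#' 0 or 1 and destroys the case-control contrast. This helper centers the
#' intercept so the cohort-average linear predictor stays at
#' `qlogis(prevalence)`: `beta0 = qlogis(prevalence) - beta_dsg * E[m] *
#' E[DR]`, with `E[m]` the mean CNV count implied by the cohort spec and
#' `E[DR]` the mean dosage distance from the diploid reference implied by
#' the dosage spec and deletion probability.
#'
#' @param beta_dsg dosage effect size.
#' @param spec a [cohort_spec()].
#' @param dosage a [dosage_spec()].
#' @param prevalence target baseline disease rate (default 877/1214).
#' @return an [effect_spec()] with the compensated intercept.
#' @export
power_effects <- function(beta_dsg, spec, dosage = dosage_spec(),
                          prevalence = 877 / 1214) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(dosage, "dosage_spec"))
  e_m <- if (spec$scenario == "rare") (1 + spec$max_cnvs_rare) / 2 else
    spec$mean_cnvs_common
  e_dr_del <- sum(dosage$deletion_values *
                    abs(as.numeric(names(dosage$deletion_values)) - 2))
  e_dr_amp <- sum(dosage$amplification_values *
                    abs(as.numeric(names(dosage$amplification_values)) - 2))
  e_dr <- spec$p_deletion * e_dr_del + (1 - spec$p_deletion) * e_dr_amp
  effect_spec(beta0 = stats::qlogis(prevalence) - beta_dsg * e_m * e_dr,
              beta_dsg = beta_dsg)
}

#' Simulate a CNV cohort
#'
#' Reproducible given `seed`. Draws the locus pool, per-subject CNV counts
#' (uniform 1..max on one random chromosome in the rare scenario; Poisson
#' genome-wide in the common scenario), assigns each subject's CNVs to loci
#' sampled without replacement, jitters breakpoints per carrier, and draws
#' types independently per CNV with `p_deletion`. CNV intervals always lie
#' within chromosome bounds. Initial dosages are 1 (deletions) and 3
#' (amplifications); randomize with [assign_dosages()].
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [cnv_profile_set()] whose subjects are "s1".."sN".
#' @export
simulate_profiles <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_subjects
  subjects <- paste0("s", seq_len(n))
  pool <- draw_locus_pool(spec)
  counts <- if (spec$scenario == "rare") {
    sample.int(min(spec$max_cnvs_rare, nrow(pool)), n, replace = TRUE)
  } else {
    pmin(stats::rpois(n, spec$mean_cnvs_common), nrow(pool))
  }
  m <- sum(counts)
  if (m == 0L)
    return(cnv_profile_set(
      data.frame(subject = character(), chrom = character(), start = numeric(),
                 end = numeric(), type_code = integer(), dosage = numeric()),
      subjects = subjects))
  loci <- unlist(lapply(counts, function(k)
    if (k > 0L) sample.int(nrow(pool), k) else integer(0)))
  base <- pool[loci, , drop = FALSE]
  llen <- base$end - base$start + 1
  jit <- llen * spec$jitter
  start <- round(base$start + stats::runif(m, -jit, jit))
  end <- round(base$end + stats::runif(m, -jit, jit))
  start <- pmax(1, start)
  end <- pmax(start, pmin(end, unname(spec$chrom_lengths[base$chrom])))
  type_code <- ifelse(stats::runif(m) < spec$p_deletion, 1L, 3L)
  tab <- data.frame(subject = rep(subjects, counts), chrom = base$chrom,
                    start = start, end = end,
                    type_code = type_code,
                    dosage = ifelse(type_code == 1L, 1, 3),
                    stringsAsFactors = FALSE)
  cnv_profile_set(tab, subjects = subjects)
}

#' Randomize CNV dosages
#'
#' Draws each deletion's dosage from the deletion distribution and each
#' amplification's from the amplification distribution, preserving the
#' type/dosage consistency rule.
#'
#' @param profiles a [cnv_profile_set()].
#' @param spec a [dosage_spec()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [cnv_profile_set()] with new dosages.
#' @export
assign_dosages <- function(profiles, spec = dosage_spec(), seed = NULL) {
  stopifnot(inherits(profiles, "cnv_profile_set"), inherits(spec, "dosage_spec"))
  if (!is.null(seed)) set.seed(seed)
  tab <- profiles$cnv
  if (nrow(tab) == 0L) return(profiles)
  del <- tab$type_code == 1L
  if (any(del))
    tab$dosage[del] <- as.numeric(sample(names(spec$deletion_values),
                                         sum(del), replace = TRUE,
                                         prob = spec$deletion_values))
  if (any(!del))
    tab$dosage[!del] <- as.numeric(sample(names(spec$amplification_values),
                                          sum(!del), replace = TRUE,
                                          prob = spec$amplification_values))
  cnv_profile_set(tab, subjects = profiles$subjects)
}

# per-subject linear predictor of the label model
label_linear_predictor <- function(profiles, eff) {
  tab <- profiles$cnv
  n <- length(profiles$subjects)
  eta <- rep(eff$beta0, n)
  if (nrow(tab) == 0L) return(eta)
  len <- (tab$end - tab$start) / eff$length_scale
  is_del <- as.numeric(tab$type_code == 1L)
  is_amp <- 1 - is_del
  term <- eff$beta_len * len +
    eff$beta_del * is_del + eff$beta_amp * is_amp +
    eff$beta_dsg * abs(tab$dosage - 2) +
    eff$beta_len_del_dsg * len * is_del * tab$dosage +
    eff$beta_len_amp_dsg * len * is_amp * tab$dosage
  idx <- match(tab$subject, profiles$subjects)
  eta + as.numeric(tapply(term, factor(idx, levels = seq_len(n)), sum,
                          default = 0))
}

#' Draw case-control labels from the CNV-dependent logistic model
#'
#' Each subject's success probability is `plogis` of the [effect_spec()]
#' linear predictor summed over that subject's CNVs; subjects with no CNVs
#' get logit `beta0`.
#'
#' @param profiles a [cnv_profile_set()].
#' @param eff an [effect_spec()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer 0/1 vector aligned with `profiles$subjects`.
#' @export
simulate_labels <- function(profiles, eff = effect_spec(), seed = NULL) {
  stopifnot(inherits(profiles, "cnv_profile_set"), inherits(eff, "effect_spec"))
  if (!is.null(seed)) set.seed(seed)
  eta <- label_linear_predictor(profiles, eff)
  if (any(!is.finite(eta)))
    stop("non-finite linear predictor; increase length_scale", call. = FALSE)
  stats::rbinom(length(eta), 1L, stats::plogis(eta))
}

#' Type-I error / power simulation study
#'
#' For each replicate: simulate a cohort, randomize dosages, draw labels,
#' and test. Rare scenario: the single simulated chromosome is tested.
#' Common scenario: every chromosome is tested and the minimum p-value is
#' Bonferroni-adjusted by the number of chromosomes tested. Replicates with
#' degenerate labels (all 0 or all 1) are redrawn and counted.
#'
#' @param spec a [cohort_spec()].
#' @param dosage a [dosage_spec()].
#' @param eff an [effect_spec()] (all-zero coefficients = null scenario).
#' @param n_reps number of replicates (>= 1).
#' @param alpha rejection level (default 0.05).
#' @param seed integer seed driving the whole study.
#' @param kcfg a [kernel_config()].
#' @return list with `rejection_rate` (fraction of p <= alpha), `p_values`,
#'   and `n_redrawn` (degenerate label redraws).
#' @export
run_simulation_study <- function(spec, dosage = dosage_spec(),
                                 eff = effect_spec(), n_reps, alpha = 0.05,
                                 seed = 1L, kcfg = kernel_config()) {
  stopifnot(inherits(spec, "cohort_spec"), n_reps >= 1)
  set.seed(seed)
  pvals <- numeric(n_reps)
  n_redrawn <- 0L
  for (r in seq_len(n_reps)) {
    prof <- simulate_profiles(spec, seed = NULL)
    prof <- assign_dosages(prof, dosage, seed = NULL)
    y <- simulate_labels(prof, eff, seed = NULL)
    tries <- 0L
    while (length(unique(y)) < 2L && tries < 1000L) {
      y <- simulate_labels(prof, eff, seed = NULL)
      n_redrawn <- n_redrawn + 1L
      tries <- tries + 1L
    }
    if (length(unique(y)) < 2L)
      stop("labels degenerate in 1000 consecutive redraws; check beta0",
           call. = FALSE)
    ph <- phenotype_table(prof$subjects, y)
    if (spec$scenario == "rare") {
      ch <- prof$chromosomes
      pvals[r] <- if (length(ch) == 0L) 1 else
        test_region(prof, ph, ch[1], kcfg)$p_value
    } else {
      rep_ <- scan_genome(prof, ph, scan_config(alpha = alpha), kcfg)
      pvals[r] <- min(1, rep_$m_tests * min(rep_$results$p_value))
    }
  }
  list(rejection_rate = mean(pvals <= alpha), p_values = pvals,
       n_redrawn = n_redrawn)
}

#' QQ-plot data for a vector of p-values
#'
#' Sorted observed p-values against uniform order statistics
#' `(i - 0.5) / n`, on both the raw and -log10 scales.
#'
#' @param p_values numeric vector in \[0, 1\].
#' @return data frame with columns `expected`, `observed`,
#'   `neg_log10_expected`, `neg_log10_observed`.
#' @export
qq_data <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("no p-values", call. = FALSE)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  obs <- sort(p)
  expd <- (seq_along(obs) - 0.5) / length(obs)
  data.frame(expected = expd, observed = obs,
             neg_log10_expected = -log10(expd),
             neg_log10_observed = -log10(pmax(obs, 1e-300)))
}
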
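test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 23), 0.05 / 23)
  expect_equal(round(bonferroni_threshold(0.05, 23), 4), 0.0022)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 4), 0.0025)
  expect_error(bonferroni_threshold(0.05, 0), "positive")
})

test_that("genome scan tests each chromosome with the right divisor", {
  set.seed(20)
  ps <- random_profile_set(40, chroms = c("1", "2"))
  y <- rep(c(0, 1), 20)
  ph <- phenotype_table(ps$subjects, y)
  rep_ <- scan_genome(ps, ph)
  expect_equal(nrow(rep_$results), 2)
  expect_equal(rep_$m_tests, 2)
  expect_equal(rep_$threshold, 0.05 / 2)
  # fixed divisor override: threshold from 23 regardless of region count
  rep23 <- scan_genome(ps, ph, scan_config(m_tests = 23))
  expect_equal(rep23$threshold, 0.05 / 23)
  expect_equal(nrow(rep23$results), 2)
  # significance flags are exactly p < threshold
  expect_identical(rep23$results$significant,
                   rep23$results$p_value < rep23$threshold)
})

test_that("subject order does not affect scan p-values", {
  set.seed(21)
  ps <- random_profile_set(30)
  y <- rbinom(30, 1, 0.5); y[1:2] <- 0:1
  ph <- phenotype_table(ps$subjects, y)
  p1 <- scan_genome(ps, ph)$results$p_value
  perm <- sample(30)
  ps2 <- cnv_profile_set(ps$cnv, subjects = ps$subjects[perm])
  ph2 <- phenotype_table(ps$subjects[perm], y[perm])
  p2 <- scan_genome(ps2, ph2)$results$p_value
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("band scan honors any-overlap counting and omits empty bands", {
  cb <- read_cytobands(toy_path("toy_cytoband.txt"))
  # one CNV spanning the p36/p35 boundary on chr1 counts in both bands
  tab <- data.frame(subject = c("a", "b", "c", "d"), chrom = "1",
                    start = c(9.5e6, 2e6, 2.1e6, 1.9e6),
                    end = c(10.5e6, 2.2e6, 2.3e6, 2.05e6),
                    type_code = 1L, dosage = 1)
  ps <- cnv_profile_set(tab)
  ph <- phenotype_table(c("a", "b", "c", "d"), c(0, 1, 0, 1))
  rep_ <- scan_bands(ps, ph, scan_config(level = "band", cytobands = cb))
  expect_identical(rep_$results$band, c("p36", "p35"))   # q11, chr2 omitted
  expect_equal(rep_$results$n_cnvs[rep_$results$band == "p36"], 4)
  expect_equal(rep_$results$n_cnvs[rep_$results$band == "p35"], 1)
  # default band threshold reuses the per-chromosome divisor
  expect_equal(rep_$m_tests, length(ps$chromosomes))
  # band-level Bonferroni switch divides by bands tested
  repb <- scan_bands(ps, ph, scan_config(level = "band", cytobands = cb,
                                         band_threshold = "band"))
  expect_equal(repb$m_tests, 2)
  expect_error(scan_bands(ps, ph, scan_config(alpha = 0.05)), "cytoband")
})

test_that("a band concentrating case CNVs attains the scan minimum p", {
  set.seed(22)
  n <- 60
  subjects <- paste0("s", 1:n)
  y <- rep(0:1, each = 30)
  # background CNVs everywhere; cases share one recurrent CNV in band p35
  rows <- data.frame(subject = subjects, chrom = "1",
                     start = 3.1e7 + seq_len(n) * 1000,
                     end = 3.1e7 + seq_len(n) * 1000 + 5e4,
                     type_code = 3L, dosage = 4)
  case_rows <- data.frame(subject = subjects[y == 1], chrom = "1",
                          start = 1.5e7, end = 1.52e7,
                          type_code = 1L, dosage = 0)
  ps <- cnv_profile_set(rbind(rows, case_rows), subjects = subjects)
  ph <- phenotype_table(subjects, y)
  cb <- read_cytobands(toy_path("toy_cytoband.txt"))
  rep_ <- scan_bands(ps, ph, scan_config(level = "band", cytobands = cb))
  best <- rep_$results$band[which.min(rep_$results$p_value)]
  expect_identical(best, "p35")
})

test_that("per-band kernels over a disjoint partition sum to the chromosome kernel", {
  set.seed(23)
  ps <- random_profile_set(20, chroms = "1")
  whole <- kernel_matrix(ps, "1")$K
  cuts <- c(1, 3e5, 7e5, Inf)
  # partition membership by CNV start position so each CNV lands in exactly
  # one piece: restrict the profile set, not the kernel region
  parts <- lapply(1:3, function(i) {
    keep <- ps$cnv$start >= cuts[i] & ps$cnv$start < cuts[i + 1]
    tab <- ps$cnv[keep, , drop = FALSE]
    if (nrow(tab) == 0) matrix(0, 20, 20) else
      kernel_matrix(cnv_profile_set(tab, subjects = ps$subjects), "1")$K
  })
  expect_equal(whole, Reduce(`+`, parts), tolerance = 1e-10)
})

test_that("combined band profiles keep whole CNVs and add across chromosomes", {
  set.seed(24)
  ps <- random_profile_set(15, chroms = c("1", "2"))
  all_bands <- data.frame(chrom = c("1", "2"), start = 1, end = 1e9)
  expect_equal(combined_band_profile(ps, all_bands)$cnv, ps$cnv)
  none <- data.frame(chrom = "5", start = 1, end = 1e9)
  ps0 <- combined_band_profile(ps, none)
  expect_equal(nrow(ps0$cnv), 0)
  y <- rbinom(15, 1, 0.5); y[1:2] <- 0:1
  ph <- phenotype_table(ps$subjects, y)
  expect_equal(test_region(ps0, ph, NULL)$p_value, 1)
  # two bands on different chromosomes: kernel = sum of per-band kernels
  bands <- data.frame(chrom = c("1", "2"), start = 1, end = 1e9)
  comb <- combined_band_profile(ps, bands)
  Ksum <- kernel_matrix(ps, "1")$K + kernel_matrix(ps, "2")$K
  expect_equal(kernel_matrix(comb, NULL)$K, Ksum, tolerance = 1e-10)
})

test_that("Manhattan data caps floored p-values and uses strict inequality", {
  df <- data.frame(region = c("chr1p1", "chr1p2", "chr1p3"), chrom = "1",
                   start = c(1, 100, 200), end = c(99, 199, 299),
                   band = c("p1", "p2", "p3"), n_cnvs = 5L,
                   Q = 1, p_value = c(0.0025, 1e-310, 0.5),
                   method = "davies", note = "")
  df$p_value <- pmax(df$p_value, 1e-300)
  rep_ <- mckat:::new_scan_report(df, threshold = 0.0025, m_tests = 20,
                                  level = "band", alpha = 0.05)
  md <- manhattan_data(rep_)
  expect_false(md$significant[md$band == "p1"])   # p == threshold: on the line
  expect_true(md$capped[md$band == "p2"])
  expect_equal(md$neg_log10_p[md$band == "p2"], 300)
  expect_equal(md$threshold_line, rep(-log10(0.0025), 3))
  chrom_rep <- rep_; chrom_rep$level <- "chromosome"
  expect_error(manhattan_data(chrom_rep), "band-level")
})
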
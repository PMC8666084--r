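#' Bonferroni-adjusted significance threshold
#'
#' `alpha / m`, controlling the family-wise error rate over m tests; with
#' alpha = 0.05 and the 23 human chromosome pairs, 0.05/23 = 2.2e-3.
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param m positive integer number of tests.
#' @return per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("m must be a positive integer", call. = FALSE)
  alpha / m
}

#' Scan configuration
#'
#' @param level `"chromosome"`, `"band"` or `"custom"`.
#' @param alpha family-wise error rate (default 0.05).
#' @param m_tests optional override of the Bonferroni divisor (e.g. a fixed
#'   23 for the human chromosome pairs regardless of how many regions carry
#'   CNVs).
#' @param cytobands a [read_cytobands()] map; required for `level = "band"`.
#' @param band_threshold for band scans: `"chromosome"` (default) reuses the
#'   per-chromosome threshold alpha / (number of chromosomes), `"band"`
#'   divides alpha by the number of bands actually tested (honest band-level
#'   FWER).
#' @return object of class `"scan_config"`.
#' @export
scan_config <- function(level = c("chromosome", "band", "custom"),
                        alpha = 0.05, m_tests = NULL, cytobands = NULL,
                        band_threshold = c("chromosome", "band")) {
  level <- match.arg(level)
  band_threshold <- match.arg(band_threshold)
  stopifnot(alpha > 0, alpha < 1)
  if (level == "band" && (is.null(cytobands) || nrow(cytobands) == 0L))
    stop("band-level scan requires a non-empty cytoband map", call. = FALSE)
  if (!is.null(m_tests) && (m_tests < 1 || m_tests != round(m_tests)))
    stop("m_tests must be a positive integer", call. = FALSE)
  structure(list(level = level, alpha = alpha, m_tests = m_tests,
                 cytobands = cytobands, band_threshold = band_threshold),
            class = "scan_config")
}

new_scan_report <- function(results, threshold, m_tests, level, alpha) {
  results$significant <- results$p_value < threshold
  ord <- order(chrom_rank(results$chrom), results$start)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, threshold = threshold,
                 m_tests = m_tests, level = level, alpha = alpha),
            class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("<scan_report> %s level: %d region(s), threshold %.3g (alpha %.3g / m %d), %d significant\n",
              x$level, nrow(x$results), x$threshold, x$alpha, x$m_tests,
              sum(x$results$significant)))
  invisible(x)
}

result_row <- function(res, chrom, start, end, band = NA_character_) {
  data.frame(region = res$region, chrom = chrom, start = start, end = end,
             band = band, n_cnvs = res$n_cnvs, Q = res$Q,
             p_value = res$p_value, method = res$method,
             note = res$note, stringsAsFactors = FALSE)
}

#' Chromosome-wide association scan
#'
#' Runs the kernel association test once per chromosome present in the CNV
#' profile set, in genomic order, with Bonferroni FWER control. The divisor
#' m defaults to the number of chromosomes tested; set `m_tests` in the
#' config to reproduce a fixed divisor (e.g. 23).
#'
#' @param profiles a [cnv_profile_set()] aligned with `pheno`.
#' @param pheno a [phenotype_table()].
#' @param cfg a [scan_config()].
#' @param kcfg a [kernel_config()].
#' @return a `"scan_report"`: results data frame (genomic order), threshold,
#'   m_tests, level, alpha.
#' @export
scan_genome <- function(profiles, pheno, cfg = scan_config(),
                        kcfg = kernel_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  chroms <- profiles$chromosomes
  if (length(chroms) == 0L) stop("profile set has no CNVs", call. = FALSE)
  rows <- lapply(chroms, function(ch) {
    res <- test_region(profiles, pheno, ch, kcfg)
    result_row(res, chrom = ch, start = 1,
               end = max(profiles$cnv$end[profiles$cnv$chrom == ch]))
  })
  results <- do.call(rbind, rows)
  m <- if (!is.null(cfg$m_tests)) cfg$m_tests else length(chroms)
  new_scan_report(results, bonferroni_threshold(cfg$alpha, m), m,
                  "chromosome", cfg$alpha)
}

#' Cytogenetic-band association scan
#'
#' Runs the kernel association test once per cytogenetic band containing at
#' least one cohort CNV (any base-pair overlap; a boundary-spanning CNV
#' counts in every band it touches and contributes in full, no clipping).
#' By default the significance threshold is the per-chromosome threshold
#' alpha / (number of chromosomes present), not alpha / (number of bands);
#' see [scan_config()] `band_threshold = "band"` for band-level Bonferroni.
#'
#' @inheritParams scan_genome
#' @return a `"scan_report"` with one row per tested band.
#' @export
scan_bands <- function(profiles, pheno, cfg, kcfg = kernel_config()) {
  stopifnot(inherits(cfg, "scan_config"))
  cb <- cfg$cytobands
  if (is.null(cb) || nrow(cb) == 0L)
    stop("band-level scan requires a non-empty cytoband map", call. = FALSE)
  tab <- profiles$cnv
  rows <- list()
  for (i in seq_len(nrow(cb))) {
    reg <- list(chrom = cb$chrom[i], start = cb$start[i], end = cb$end[i],
                label = paste0("chr", cb$chrom[i], cb$band[i]))
    if (!any(region_rows(tab, resolve_region(reg)))) next
    res <- test_region(profiles, pheno, reg, kcfg)
    rows[[length(rows) + 1L]] <- result_row(res, chrom = cb$chrom[i],
                                            start = cb$start[i],
                                            end = cb$end[i],
                                            band = cb$band[i])
  }
  if (length(rows) == 0L)
    stop("no cytoband contains any cohort CNV", call. = FALSE)
  results <- do.call(rbind, rows)
  m <- if (!is.null(cfg$m_tests)) {
    cfg$m_tests
  } else if (cfg$band_threshold == "band") {
    nrow(results)
  } else {
    length(profiles$chromosomes)
  }
  new_scan_report(results, bonferroni_threshold(cfg$alpha, m), m,
                  "band", cfg$alpha)
}

#' Restrict a profile set to CNVs overlapping selected bands
#'
#' Builds the combined profile used to test a set of bands jointly: only
#' CNVs with any overlap with at least one listed band are retained (whole
#' CNVs, no clipping); all subjects are kept. Testing the result with
#' `region = NULL` sums within-chromosome pair contributions across the
#' selected bands (cross-chromosome pairs contribute 0).
#'
#' @param profiles a [cnv_profile_set()].
#' @param bands data frame with columns `chrom`, `start`, `end` (e.g. rows
#'   of a cytoband map).
#' @return a [cnv_profile_set()] with the same subjects.
#' @export
combined_band_profile <- function(profiles, bands) {
  stopifnot(inherits(profiles, "cnv_profile_set"))
  bands <- as.data.frame(bands)
  if (nrow(bands) == 0L) stop("bands must be non-empty", call. = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(bands)))
  tab <- profiles$cnv
  keep <- rep(FALSE, nrow(tab))
  for (i in seq_len(nrow(bands))) {
    keep <- keep | (tab$chrom == norm_chrom(bands$chrom[i]) &
                      tab$end >= bands$start[i] & tab$start <= bands$end[i])
  }
  cnv_profile_set(tab[keep, , drop = FALSE], subjects = profiles$subjects,
                  strict = FALSE)
}

#' Plot-ready Manhattan data from a band scan
#'
#' One row per tested band: chromosome, band, interval midpoint, -log10 p
#' (capped at 300 for floored p-values, with a flag), the threshold line
#' -log10(alpha / m) and the significance flag (strict inequality).
#'
#' @param report a band-level `"scan_report"`.
#' @return data frame in genomic order.
#' @export
manhattan_data <- function(report) {
  stopifnot(inherits(report, "scan_report"))
  if (report$level != "band")
    stop("manhattan_data expects a band-level scan report", call. = FALSE)
  df <- report$results
  if (nrow(df) == 0L) stop("empty scan report", call. = FALSE)
  data.frame(chrom = paste0("chr", df$chrom),
             band = df$band,
             midpoint = (df$start + df$end) / 2,
             neg_log10_p = pmin(-log10(df$p_value), 300),
             capped = df$p_value <= 1e-300,
             threshold_line = -log10(report$threshold),
             significant = df$significant,
             stringsAsFactors = FALSE)
}
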
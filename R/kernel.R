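#' Kernel configuration
#'
#' @param type_mismatch similarity assigned to a deletion/amplification pair.
#'   The default 0.5 follows the type sub-kernel `((t1 == t2) + 1) / 2`;
#'   setting 0 makes mismatched types annihilate the pair's contribution.
#'   Values outside `{0, 0.5}` are allowed but flagged with a warning.
#' @param dosage_base base of the dosage decay term
#'   `base^-|DR(d1) - DR(d2)|`, where `DR(d) = |d - 2|` is the distance of a
#'   copy number from the diploid reference. Must be > 1; default 2.
#' @param region optional genomic interval restricting which CNVs contribute:
#'   `list(chrom =, start =, end =)` or just a chromosome label.
#' @return object of class `"kernel_config"`.
#' @export
kernel_config <- function(type_mismatch = 0.5, dosage_base = 2, region = NULL) {
  stopifnot(is.numeric(type_mismatch), length(type_mismatch) == 1L,
            type_mismatch >= 0, type_mismatch <= 1)
  if (!type_mismatch %in% c(0, 0.5))
    warning("type_mismatch outside the validated presets {0, 0.5}", call. = FALSE)
  stopifnot(is.numeric(dosage_base), length(dosage_base) == 1L)
  if (dosage_base <= 1) stop("dosage_base must be > 1", call. = FALSE)
  structure(list(type_mismatch = type_mismatch, dosage_base = dosage_base,
                 region = region),
            class = "kernel_config")
}

#' Positional similarity of two CNVs: interval Jaccard index
#'
#' Intervals are 1-based inclusive, so length = end - start + 1 and a
#' single-base CNV has length 1. Returns 1 iff the intervals are identical
#' and 0 iff they are disjoint.
#'
#' @param a,b `"cnv"` objects on the same chromosome.
#' @return Jaccard index in \[0, 1\].
#' @export
position_similarity <- function(a, b) {
  inter <- max(0, min(a$end, b$end) - max(a$start, b$start) + 1)
  uni <- (a$end - a$start + 1) + (b$end - b$start + 1) - inter
  inter / uni
}

#' Type similarity of two CNVs
#'
#' 1 when both are deletions or both amplifications; `cfg$type_mismatch`
#' (default 0.5) otherwise.
#'
#' @param a,b `"cnv"` objects.
#' @param cfg a [kernel_config()].
#' @return value in \[0, 1\].
#' @export
type_similarity <- function(a, b, cfg = kernel_config()) {
  if (a$type_code == b$type_code) 1 else cfg$type_mismatch
}

#' Distance of a copy number from the diploid reference
#'
#' `DR(dosage) = |dosage - 2|`.
#'
#' @param dosage non-negative numeric copy number(s).
#' @return non-negative numeric.
#' @export
dosage_dr <- function(dosage) abs(dosage - 2)

#' Dosage similarity of two CNVs
#'
#' `base^-|DR(d_a) - DR(d_b)|`: 1 when the two copy numbers are equally far
#' from the diploid reference, halving (for base 2) per unit of difference.
#'
#' @inheritParams type_similarity
#' @return value in (0, 1\].
#' @export
dosage_similarity <- function(a, b, cfg = kernel_config()) {
  cfg$dosage_base^(-abs(dosage_dr(a$dosage) - dosage_dr(b$dosage)))
}

#' Single-pair CNV kernel
#'
#' Product of the positional (Jaccard), type and dosage sub-kernels.
#' Equals 1 iff the two CNVs have identical intervals, identical type and
#' equal DR values; 0 iff the intervals are disjoint. Symmetric.
#'
#' @inheritParams type_similarity
#' @return value in \[0, 1\].
#' @examples
#' a <- cnv("chr1", 1, 100, "del", 1)
#' b <- cnv("chr1", 51, 150, "amp", 3)
#' single_pair_kernel(a, b)  # (50/150) * 0.5 * 2^0 = 1/6
#' @export
single_pair_kernel <- function(a, b, cfg = kernel_config()) {
  position_similarity(a, b) * type_similarity(a, b, cfg) *
    dosage_similarity(a, b, cfg)
}

# vectorized m x m single-pair kernel over CNV table rows (one chromosome)
pair_kernel_block <- function(d, cfg) {
  m <- nrow(d)
  if (m == 0L) return(matrix(0, 0, 0))
  s <- d$start; e <- d$end
  inter <- pmax(0, outer(e, e, pmin) - outer(s, s, pmax) + 1)
  len <- e - s + 1
  S <- inter / (outer(len, len, "+") - inter)
  tt <- outer(d$type_code, d$type_code, "==")
  S <- S * ifelse(tt, 1, cfg$type_mismatch)
  dr <- dosage_dr(d$dosage)
  S * cfg$dosage_base^(-abs(outer(dr, dr, "-")))
}

#' Whole-region CNV kernel between two profiles
#'
#' Aggregate similarity of two CNV profiles within one chromosome/region:
#' 0 when either profile is empty, otherwise the sum of the single-pair
#' kernel over all cross pairs. Unbounded above; symmetric.
#'
#' @param Ri,Rj lists of `"cnv"` objects, all on one chromosome.
#' @param cfg a [kernel_config()].
#' @return non-negative real.
#' @export
whole_region_kernel <- function(Ri, Rj, cfg = kernel_config()) {
  if (length(Ri) == 0L || length(Rj) == 0L) return(0)
  ch <- unique(c(vapply(Ri, `[[`, "", "chrom"), vapply(Rj, `[[`, "", "chrom")))
  if (length(ch) > 1L)
    stop("whole_region_kernel: CNVs span multiple chromosomes (",
         paste(ch, collapse = ", "), ")", call. = FALSE)
  tot <- 0
  for (a in Ri) for (b in Rj) tot <- tot + single_pair_kernel(a, b, cfg)
  tot
}

# resolve a region spec into list(chrom = <bare label or NA>, start, end, label)
resolve_region <- function(region) {
  if (is.null(region))
    return(list(chrom = NA_character_, start = -Inf, end = Inf, label = "genome"))
  if (is.character(region) && length(region) == 1L)
    return(list(chrom = norm_chrom(region), start = -Inf, end = Inf,
                label = paste0("chr", norm_chrom(region))))
  if (is.list(region)) {
    stopifnot(!is.null(region$chrom))
    s <- if (is.null(region$start)) -Inf else as.numeric(region$start)
    e <- if (is.null(region$end)) Inf else as.numeric(region$end)
    lab <- if (!is.null(region$label)) region$label else
      paste0("chr", norm_chrom(region$chrom), ":",
             format(s, scientific = FALSE, trim = TRUE), "-",
             format(e, scientific = FALSE, trim = TRUE))
    return(list(chrom = norm_chrom(region$chrom), start = s, end = e, label = lab))
  }
  stop("unrecognized region specification", call. = FALSE)
}

# rows of a CNV table overlapping a resolved region (any base-pair overlap,
# whole-CNV contribution, no clipping)
region_rows <- function(tab, rr) {
  if (is.na(rr$chrom)) return(rep(TRUE, nrow(tab)))
  tab$chrom == rr$chrom & tab$end >= rr$start & tab$start <= rr$end
}

#' Subject-by-subject kernel matrix for a genomic region
#'
#' Builds the n x n similarity matrix whose (i, j) entry is the
#' whole-region kernel between subjects i and j, using every CNV with any
#' base-pair overlap with the region (no clipping). With `region = NULL`
#' the per-chromosome matrices are summed over all chromosomes present
#' (cross-chromosome CNV pairs contribute 0).
#'
#' @param profiles a [cnv_profile_set()].
#' @param region chromosome label, `list(chrom =, start =, end =)`, or NULL
#'   for genome-wide.
#' @param cfg a [kernel_config()].
#' @return object of class `"kernel_matrix"`: list with `subjects`, `K`
#'   (symmetric n x n matrix) and `region` label.
#' @export
kernel_matrix <- function(profiles, region = NULL, cfg = kernel_config()) {
  stopifnot(inherits(profiles, "cnv_profile_set"))
  n <- length(profiles$subjects)
  if (n == 0L) stop("kernel_matrix: zero subjects", call. = FALSE)
  if (!is.null(cfg$region) && is.null(region)) region <- cfg$region
  rr <- resolve_region(region)
  tab <- profiles$cnv
  K <- matrix(0, n, n, dimnames = list(profiles$subjects, profiles$subjects))
  chroms <- if (is.na(rr$chrom)) unique(tab$chrom) else rr$chrom
  for (ch in chroms) {
    d <- tab[tab$chrom == ch & tab$end >= rr$start & tab$start <= rr$end, ,
             drop = FALSE]
    m <- nrow(d)
    if (m == 0L) next
    S <- pair_kernel_block(d, cfg)
    M <- matrix(0, n, m)
    M[cbind(match(d$subject, profiles$subjects), seq_len(m))] <- 1
    K <- K + M %*% S %*% t(M)
  }
  K <- (K + t(K)) / 2  # exact symmetry against float round-off
  structure(list(subjects = profiles$subjects, K = K, region = rr$label),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix> %d x %d, region %s\n",
              nrow(x$K), ncol(x$K), x$region))
  invisible(x)
}
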
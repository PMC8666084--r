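# deterministic builders shared across test files

# one random CNV with consistent type/dosage, uniform position
random_cnv <- function(chrom = "1", max_pos = 1e6, max_len = 5e4) {
  s <- sample.int(max_pos, 1)
  len <- sample.int(max_len, 1)
  type <- sample(c("del", "amp"), 1)
  d <- if (type == "del") sample(0:1, 1) else sample(3:7, 1)
  cnv(chrom, s, s + len - 1, type, d)
}

# random CNV table for n subjects (independent of the simulate module, for
# kernel property tests); clustered = TRUE reuses a small set of intervals
# so that profiles overlap
random_profile_set <- function(n, mean_cnvs = 3, chroms = c("1", "2"),
                               clustered = TRUE, n_loci = 8) {
  rows <- list()
  loci <- data.frame(chrom = sample(chroms, n_loci, replace = TRUE),
                     start = sample.int(9e5, n_loci),
                     len = sample.int(1e5, n_loci))
  for (i in seq_len(n)) {
    k <- stats::rpois(1, mean_cnvs)
    if (k == 0) next
    for (j in seq_len(k)) {
      if (clustered) {
        l <- sample.int(n_loci, 1)
        ch <- loci$chrom[l]
        s <- loci$start[l] + sample.int(2000, 1) - 1000
        e <- s + loci$len[l] + sample.int(2000, 1) - 1000
        if (e < s) e <- s
      } else {
        ch <- sample(chroms, 1)
        s <- sample.int(9e5, 1)
        e <- s + sample.int(1e5, 1)
      }
      type <- sample(c(1L, 3L), 1)
      d <- if (type == 1L) sample(0:1, 1) else sample(3:7, 1)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = paste0("s", i), chrom = ch, start = s, end = e,
                   type_code = type, dosage = d, stringsAsFactors = FALSE)
    }
  }
  cnv_profile_set(do.call(rbind, rows), subjects = paste0("s", seq_len(n)))
}

# brute-force oracle: all-pairs double loop through the scalar kernel API
naive_kernel_matrix <- function(ps, chrom, cfg = kernel_config(),
                                start = -Inf, end = Inf) {
  n <- length(ps$subjects)
  K <- matrix(0, n, n)
  prof <- lapply(ps$subjects, function(su) {
    cl <- profile_of(ps, su, chrom)
    Filter(function(x) x$end >= start && x$start <= end, cl)
  })
  for (i in seq_len(n)) for (j in seq_len(n))
    K[i, j] <- whole_region_kernel(prof[[i]], prof[[j]], cfg)
  K
}

toy_path <- function(f) system.file("extdata", f, package = "mckat")
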
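# accepted spellings for the CNV type column
.TYPE_TOKENS <- c("1" = 1L, "3" = 3L,
                  "del" = 1L, "deletion" = 1L,
                  "amp" = 3L, "amplification" = 3L)

#' Normalize chromosome labels
#'
#' Strips an optional "chr" prefix so that "chr8" and "8" refer to the same
#' chromosome. The prefix is re-attached by output routines.
#'
#' @param x character vector of chromosome labels.
#' @return character vector of bare labels ("1".."22", "X", "Y", ...).
#' @export
norm_chrom <- function(x) {
  x <- as.character(x)
  sub("^[Cc][Hh][Rr]", "", x)
}

# genomic sort order for bare chromosome labels: 1..22, X, Y, then others
chrom_rank <- function(x) {
  x <- norm_chrom(x)
  n <- suppressWarnings(as.numeric(x))
  r <- ifelse(!is.na(n), n,
              ifelse(toupper(x) == "X", 23,
                     ifelse(toupper(x) == "Y", 24, 25)))
  r + (match(x, sort(unique(x))) * 1e-6)  # stable tie-break for exotic labels
}

parse_type <- function(tok) {
  key <- tolower(trimws(as.character(tok)))
  out <- .TYPE_TOKENS[key]
  if (anyNA(out)) {
    bad <- unique(key[is.na(out)])
    stop("unknown CNV type token(s): ", paste(bad, collapse = ", "),
         "; accepted: 1, 3, del, amp, deletion, amplification (case-insensitive)",
         call. = FALSE)
  }
  unname(out)
}

#' Construct a single CNV
#'
#' A CNV is an interval on one chromosome plus a type code (1 = deletion,
#' 3 = amplification) and an integer dosage (total copy number; 2 is the
#' diploid reference).
#'
#' @param chrom chromosome label ("8" or "chr8").
#' @param start,end 1-based inclusive base-pair positions, `end >= start`.
#' @param type type token: 1, 3, "del", "amp", "deletion", "amplification".
#' @param dosage non-negative integer copy number; if `NA`, imputed as 1 for
#'   deletions and 3 for amplifications.
#' @return object of class `"cnv"`.
#' @examples
#' cnv("chr1", 100, 5000, "del", 1)
#' @export
cnv <- function(chrom, start, end, type, dosage = NA) {
  type_code <- parse_type(type)
  if (is.na(dosage)) dosage <- if (type_code == 1L) 1L else 3L
  start <- as.numeric(start); end <- as.numeric(end); dosage <- as.numeric(dosage)
  if (!is.finite(start) || !is.finite(end) || start < 1 || end < start)
    stop("invalid CNV interval [", start, ", ", end, "]", call. = FALSE)
  if (dosage < 0 || dosage != round(dosage))
    stop("dosage must be a non-negative integer", call. = FALSE)
  structure(list(chrom = norm_chrom(chrom), start = start, end = end,
                 type_code = type_code, dosage = dosage),
            class = "cnv")
}

#' @export
print.cnv <- function(x, ...) {
  cat(sprintf("<cnv> chr%s:%g-%g %s dosage=%g\n", x$chrom, x$start, x$end,
              if (x$type_code == 1L) "del" else "amp", x$dosage))
  invisible(x)
}

# type/dosage consistency rule: del => dosage in {0,1}; amp => dosage > 2
check_type_dosage <- function(df, strict = TRUE, lines = NULL) {
  bad <- (df$type_code == 1L & !(df$dosage %in% c(0, 1))) |
         (df$type_code == 3L & df$dosage <= 2)
  if (any(bad)) {
    where <- if (is.null(lines)) which(bad) else lines[bad]
    msg <- paste0("type/dosage inconsistency (deletion needs dosage 0 or 1, ",
                  "amplification dosage > 2) at line(s) ",
                  paste(utils::head(where, 5), collapse = ", "),
                  if (sum(bad) > 5) " ..." else "")
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(df)
}

#' Construct a CNV profile set
#'
#' Per-subject, per-chromosome ordered collections of CNVs for a cohort,
#' stored as one data frame. Subjects with zero CNVs are legal and retained
#' (they contribute zero rows to every kernel).
#'
#' @param cnv_table data frame with columns `subject`, `chrom`, `start`,
#'   `end`, `type_code`, `dosage`.
#' @param subjects ordered character vector of cohort subject ids; defaults
#'   to the subjects appearing in `cnv_table`.
#' @param strict reject type/dosage inconsistencies (default) instead of
#'   downgrading them to warnings.
#' @return object of class `"cnv_profile_set"` with elements `subjects`,
#'   `cnv` (the sorted table) and `chromosomes`.
#' @export
cnv_profile_set <- function(cnv_table, subjects = NULL, strict = TRUE) {
  need <- c("subject", "chrom", "start", "end", "type_code", "dosage")
  if (!all(need %in% names(cnv_table)))
    stop("cnv_table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  df <- cnv_table[need]
  df$subject <- as.character(df$subject)
  df$chrom <- norm_chrom(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$type_code <- as.integer(df$type_code); df$dosage <- as.numeric(df$dosage)
  if (any(!is.finite(df$start) | !is.finite(df$end)))
    stop("non-numeric start/end position", call. = FALSE)
  if (any(df$end < df$start))
    stop("CNV with end < start at row(s) ",
         paste(utils::head(which(df$end < df$start), 5), collapse = ", "),
         call. = FALSE)
  if (!all(df$type_code %in% c(1L, 3L)))
    stop("type_code must be 1 (deletion) or 3 (amplification)", call. = FALSE)
  check_type_dosage(df, strict = strict)
  if (is.null(subjects)) subjects <- unique(df$subject)
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("duplicate subject ids", call. = FALSE)
  if (!all(df$subject %in% subjects))
    stop("cnv_table contains subjects absent from `subjects`", call. = FALSE)
  ord <- order(match(df$subject, subjects), chrom_rank(df$chrom), df$start, df$end)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  chroms <- unique(df$chrom)[order(chrom_rank(unique(df$chrom)))]
  structure(list(subjects = subjects, cnv = df, chromosomes = chroms),
            class = "cnv_profile_set")
}

#' @export
print.cnv_profile_set <- function(x, ...) {
  cat(sprintf("<cnv_profile_set> %d subjects, %d CNVs on %d chromosome(s)\n",
              length(x$subjects), nrow(x$cnv), length(x$chromosomes)))
  invisible(x)
}

#' CNVs of one subject on one chromosome
#'
#' @param ps a [cnv_profile_set()].
#' @param subject subject id.
#' @param chrom chromosome label.
#' @return list of `"cnv"` objects sorted by start position (possibly empty).
#' @export
profile_of <- function(ps, subject, chrom) {
  stopifnot(inherits(ps, "cnv_profile_set"))
  d <- ps$cnv[ps$cnv$subject == subject & ps$cnv$chrom == norm_chrom(chrom), ]
  lapply(seq_len(nrow(d)), function(i)
    structure(list(chrom = d$chrom[i], start = d$start[i], end = d$end[i],
                   type_code = d$type_code[i], dosage = d$dosage[i]),
              class = "cnv"))
}

#' Read a tab-delimited CNV call table
#'
#' Expected header: `subject chrom start end type [dosage]`. When the dosage
#' column is absent, dosage is imputed as 1 for deletions and 3 for
#' amplifications (the convention for call sets that lack copy-number
#' estimates).
#'
#' @param path file path.
#' @param strict reject type/dosage inconsistencies (default TRUE).
#' @return a [cnv_profile_set()].
#' @export
read_cnv_table <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject", "chrom", "start", "end", "type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("CNV table missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(df)
  if (n == 0L) stop("CNV table has no data rows", call. = FALSE)
  lines <- seq_len(n) + 1L  # header is line 1
  start <- suppressWarnings(as.numeric(df$start))
  end <- suppressWarnings(as.numeric(df$end))
  bad <- !is.finite(start) | !is.finite(end)
  if (any(bad))
    stop("malformed start/end at line(s) ",
         paste(utils::head(lines[bad], 5), collapse = ", "), call. = FALSE)
  if (any(start > end))
    stop("start > end at line(s) ",
         paste(utils::head(lines[start > end], 5), collapse = ", "), call. = FALSE)
  type_code <- parse_type(df$type)
  if ("dosage" %in% names(df)) {
    dosage <- suppressWarnings(as.numeric(df$dosage))
    if (anyNA(dosage))
      stop("malformed dosage at line(s) ",
           paste(utils::head(lines[is.na(dosage)], 5), collapse = ", "), call. = FALSE)
  } else {
    dosage <- ifelse(type_code == 1L, 1, 3)
  }
  tab <- data.frame(subject = df$subject, chrom = df$chrom, start = start,
                    end = end, type_code = type_code, dosage = dosage,
                    stringsAsFactors = FALSE)
  check_type_dosage(tab, strict = strict, lines = lines)
  # all validation already done above (with file line numbers)
  suppressWarnings(cnv_profile_set(tab, strict = FALSE))
}

#' Write a CNV profile set as a tab-delimited table
#'
#' Inverse of [read_cnv_table()]: `read_cnv_table(write_cnv_table(ps, f))`
#' reproduces `ps` (chromosome labels are written with a "chr" prefix).
#'
#' @param ps a [cnv_profile_set()].
#' @param path output file path.
#' @export
write_cnv_table <- function(ps, path) {
  stopifnot(inherits(ps, "cnv_profile_set"))
  d <- ps$cnv
  out <- data.frame(subject = d$subject, chrom = paste0("chr", d$chrom),
                    start = format(d$start, scientific = FALSE, trim = TRUE),
                    end = format(d$end, scientific = FALSE, trim = TRUE),
                    type = ifelse(d$type_code == 1L, "del", "amp"),
                    dosage = d$dosage)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expected header: `subject phenotype [covariate...]`. The phenotype must be
#' binary 0/1 and non-constant; all remaining columns become the numeric
#' covariate matrix Z (no intercept column).
#'
#' @param path file path.
#' @return object of class `"phenotype_table"`: list with `subjects`, `y`
#'   (0/1 vector) and `Z` (n x c numeric matrix, c >= 0).
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject", "phenotype") %in% names(df)))
    stop("phenotype table needs columns 'subject' and 'phenotype'", call. = FALSE)
  if (anyNA(df)) stop("phenotype table contains missing values", call. = FALSE)
  subjects <- as.character(df$subject)
  if (anyDuplicated(subjects)) stop("duplicate subject ids", call. = FALSE)
  y <- df$phenotype
  if (!all(y %in% c(0, 1)))
    stop("phenotype must be binary 0/1; found: ",
         paste(utils::head(unique(y[!y %in% c(0, 1)]), 3), collapse = ", "),
         call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("constant phenotype: degenerate null model", call. = FALSE)
  covnames <- setdiff(names(df), c("subject", "phenotype"))
  Z <- if (length(covnames)) {
    m <- as.matrix(df[covnames])
    storage.mode(m) <- "numeric"
    if (anyNA(m)) stop("non-numeric covariate values", call. = FALSE)
    m
  } else {
    matrix(numeric(0), nrow = length(y), ncol = 0)
  }
  phenotype_table(subjects, y, Z)
}

#' Construct a phenotype table in code
#'
#' @param subjects character vector of subject ids.
#' @param y binary 0/1 vector aligned with `subjects`.
#' @param Z numeric covariate matrix with `length(subjects)` rows (may have
#'   zero columns).
#' @return object of class `"phenotype_table"`.
#' @export
phenotype_table <- function(subjects, y, Z = NULL) {
  subjects <- as.character(subjects)
  y <- as.integer(y)
  if (is.null(Z)) Z <- matrix(numeric(0), nrow = length(y), ncol = 0)
  Z <- as.matrix(Z)
  stopifnot(length(subjects) == length(y), nrow(Z) == length(y),
            all(y %in% c(0L, 1L)))
  if (length(unique(y)) < 2L)
    stop("constant phenotype: degenerate null model", call. = FALSE)
  structure(list(subjects = subjects, y = y, Z = Z), class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> n=%d (cases=%d), %d covariate(s)\n",
              length(x$y), sum(x$y), ncol(x$Z)))
  invisible(x)
}

#' Read a UCSC cytoBand file
#'
#' UCSC cytoBand.txt layout: chrom, chromStart, chromEnd, name, gieStain;
#' tab-delimited, no header, chromStart 0-based half-open. Coordinates are
#' converted to the internal 1-based inclusive convention
#' (start = chromStart + 1, end = chromEnd).
#'
#' @param path file path.
#' @return object of class `"cytoband_map"`: data frame with columns
#'   `chrom`, `start`, `end`, `band`, `stain`, sorted within chromosome.
#' @export
read_cytobands <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) data.frame())
  if (nrow(raw) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      band = character(), stain = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cytoband_map", "data.frame")
    return(out)
  }
  if (ncol(raw) < 4L)
    stop("cytoband file needs >= 4 tab-delimited columns (UCSC cytoBand.txt)",
         call. = FALSE)
  out <- data.frame(chrom = norm_chrom(raw[[1]]),
                    start = as.numeric(raw[[2]]) + 1,
                    end = as.numeric(raw[[3]]),
                    band = as.character(raw[[4]]),
                    stain = if (ncol(raw) >= 5) as.character(raw[[5]]) else "",
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$start) | !is.finite(out$end)))
    stop("malformed cytoband coordinates", call. = FALSE)
  out <- out[order(chrom_rank(out$chrom), out$start), , drop = FALSE]
  rownames(out) <- NULL
  for (ch in unique(out$chrom)) {
    d <- out[out$chrom == ch, ]
    if (nrow(d) > 1L && any(d$start[-1] <= d$end[-nrow(d)]))
      stop("overlapping cytobands on chromosome ", ch, call. = FALSE)
  }
  class(out) <- c("cytoband_map", "data.frame")
  out
}

#' Align a CNV profile set with a phenotype table
#'
#' Restricts both to the intersection of subject ids, in one canonical order
#' (the phenotype table's order). Subjects present in only one input are
#' reported via `message()`. Subjects without CNVs are retained: they carry
#' all-zero kernel rows.
#'
#' @param profiles a [cnv_profile_set()].
#' @param pheno a [phenotype_table()].
#' @return list with elements `profiles`, `pheno` and `dropped` (character
#'   vector of ids present in only one input).
#' @export
align_cohort <- function(profiles, pheno) {
  stopifnot(inherits(profiles, "cnv_profile_set"),
            inherits(pheno, "phenotype_table"))
  common <- intersect(pheno$subjects, profiles$subjects)
  if (length(common) == 0L)
    stop("no subjects in common between CNV and phenotype tables", call. = FALSE)
  dropped <- c(setdiff(profiles$subjects, common), setdiff(pheno$subjects, common))
  if (length(dropped))
    message("align_cohort: dropping ", length(dropped),
            " subject(s) present in only one input: ",
            paste(utils::head(dropped, 10), collapse = ", "),
            if (length(dropped) > 10) " ..." else "")
  keep <- pheno$subjects %in% common
  ph <- phenotype_table(pheno$subjects[keep], pheno$y[keep],
                        pheno$Z[keep, , drop = FALSE])
  tab <- profiles$cnv[profiles$cnv$subject %in% common, , drop = FALSE]
  pr <- cnv_profile_set(tab, subjects = ph$subjects, strict = FALSE)
  list(profiles = pr, pheno = ph, dropped = dropped)
}

#' Write scan results as a tab-delimited table
#'
#' Columns: `region`, `n_cnvs`, `Q`, `p_value`, `p_adjusted_threshold`,
#' `significant`; rows in genomic order.
#'
#' @param results a `scan_report` (from [scan_genome()] / [scan_bands()]) or
#'   a data frame of results with a `threshold` attribute.
#' @param path output file path.
#' @param header_lines optional character vector written as leading `#`
#'   comment lines (provenance).
#' @export
write_results <- function(results, path, header_lines = NULL) {
  if (inherits(results, "scan_report")) {
    df <- results$results
    thr <- results$threshold
  } else {
    df <- as.data.frame(results)
    thr <- attr(results, "threshold")
    if (is.null(thr)) thr <- NA_real_
  }
  if (is.null(df) || nrow(df) == 0L)
    stop("no results to write", call. = FALSE)
  ord <- order(chrom_rank(df$chrom), df$start)
  df <- df[ord, , drop = FALSE]
  out <- data.frame(region = df$region, n_cnvs = df$n_cnvs, Q = df$Q,
                    p_value = df$p_value, p_adjusted_threshold = thr,
                    significant = df$significant)
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  if (!is.null(header_lines)) writeLines(paste0("# ", header_lines), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
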
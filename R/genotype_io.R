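# Genotype / phenotype input, validation and quality control.
#
# A GenotypeMatrix is an integer matrix of allele dosages (0/1/2, NA for
# missing) with individuals in rows, plus a marker metadata data.frame.

#' Construct a GenotypeMatrix
#'
#' The central container of the package: an `n_individuals x m_snps` integer
#' dosage matrix (values 0, 1, 2; `NA` marks a missing genotype) together
#' with individual ids and per-marker metadata.
#'
#' @param values integer matrix of dosages, individuals in rows.
#' @param individual_ids character vector of unique individual ids; defaults
#'   to rownames of `values` or `ind1..indN`.
#' @param markers data.frame of marker metadata with at least an `id`
#'   column; optional columns `chrom`, `pos`, `ref`, `alt`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(values, individual_ids = NULL, markers = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  bad <- !is.na(values) & !(values %in% 0:2)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("dosage out of range {0,1,2} at row %d, column %d",
                 idx[1L], idx[2L]), call. = FALSE)
  }
  if (is.null(individual_ids)) {
    individual_ids <- rownames(values)
    if (is.null(individual_ids))
      individual_ids <- paste0("ind", seq_len(nrow(values)))
  }
  individual_ids <- as.character(individual_ids)
  if (length(individual_ids) != nrow(values))
    stop("number of individual ids does not match row count", call. = FALSE)
  if (anyDuplicated(individual_ids))
    stop("individual ids must be unique", call. = FALSE)
  if (is.null(markers)) {
    ids <- colnames(values)
    if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(values)))
    markers <- data.frame(id = ids, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(markers) || is.null(markers$id))
    stop("markers must be a data.frame with an 'id' column", call. = FALSE)
  if (nrow(markers) != ncol(values))
    stop("marker metadata rows must match column count", call. = FALSE)
  dimnames(values) <- list(individual_ids, markers$id)
  structure(list(values = values,
                 individual_ids = individual_ids,
                 markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d individuals x %d SNPs (%d missing entries)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' Number of individuals / markers
#' @param g a `genotype_matrix`.
#' @return integer count.
#' @export
n_individuals <- function(g) nrow(g$values)

#' @rdname n_individuals
#' @export
n_markers <- function(g) ncol(g$values)

#' Read genotypes from a VCF file
#'
#' Converts hard-called GT fields of biallelic records to alt-allele dosages
#' (0/0 -> 0, 0/1 -> 1, 1/1 -> 2, ./. -> `NA`).  Multi-allelic records are
#' skipped with a warning; phased separators (`|`) are accepted.
#'
#' @param path path to a VCF (v4.x) file, plain or bgzipped.
#' @return a [genotype_matrix()] with marker metadata (id, chrom, pos, ref,
#'   alt) from the VCF.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read VCF: '%s' does not exist", path), call. = FALSE)
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf() requires the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  alt <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt)
  multi <- n_alt != 1L
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    vcf <- vcf[!multi]
  }
  if (nrow(vcf) == 0L)
    stop("no biallelic sites found in VCF", call. = FALSE)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt))
    stop("VCF has no GT genotype field", call. = FALSE)
  dos <- gt_to_dosage(gt)           # sites x samples
  rr <- SummarizedExperiment::rowRanges(vcf)
  markers <- data.frame(
    id = rownames(vcf),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))),
    stringsAsFactors = FALSE)
  genotype_matrix(t(dos), individual_ids = colnames(gt), markers = markers)
}

# "0/0" -> 0, "0|1" -> 1, "1/1" -> 2, "./." or "." -> NA; any other call
# (e.g. haploid "1") counted by its alt alleles.
gt_to_dosage <- function(gt) {
  alleles <- gsub("\\|", "/", gt)
  map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  out <- map[alleles]
  unknown <- is.na(out) & !(alleles %in% c("./.", ".", ".|."))
  if (any(unknown)) {
    # fall back: count '1' alleles in the call
    out[unknown] <- vapply(strsplit(alleles[unknown], "/"), function(a) {
      if (any(a == ".")) NA_integer_ else sum(a == "1")
    }, integer(1))
  }
  matrix(out, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Read a genotype matrix from delimited text
#'
#' The file must carry an id header row and id header column.  Values are
#' integers in `{0,1,2}` or the missing code.
#'
#' @param path path to a tab- or comma-delimited file (delimiter sniffed
#'   from the header line).
#' @param orientation `"individuals-in-rows"` (default) or
#'   `"snps-in-rows"`; the returned matrix is always individuals x SNPs.
#' @param missing_code token representing a missing genotype (default
#'   `"NA"`).
#' @return a [genotype_matrix()].
#' @export
read_matrix <- function(path,
                        orientation = c("individuals-in-rows", "snps-in-rows"),
                        missing_code = "NA") {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    stop(sprintf("cannot read matrix: '%s' does not exist", path),
         call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, row.names = 1L,
                    na.strings = missing_code, check.names = FALSE,
                    colClasses = "character")
  m <- as.matrix(tab)
  suppressWarnings(num <- matrix(as.integer(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  bad <- (!is.na(m)) & (is.na(num) | !(num %in% 0:2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("invalid genotype token '%s' at row '%s', column '%s'",
                 m[idx[1L], idx[2L]], rownames(m)[idx[1L]],
                 colnames(m)[idx[2L]]), call. = FALSE)
  }
  if (orientation == "snps-in-rows") num <- t(num)
  genotype_matrix(num)
}

#' Write a genotype matrix as delimited text
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(g, path, sep = "\t") {
  tab <- as.data.frame(g$values)
  write.table(tab, path, sep = sep, quote = FALSE, na = "NA",
              row.names = TRUE, col.names = NA)
  invisible(path)
}

#' Read a phenotype table
#'
#' Delimited text with an `id` column (first column) and one numeric column
#' per trait; missing values allowed.
#'
#' @param path path to the file.
#' @return a data.frame with character `id` and numeric trait columns.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read phenotypes: '%s' does not exist", path),
         call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab)[1L] <- "id"
  tab$id <- as.character(tab$id)
  for (j in seq_along(tab)[-1L]) tab[[j]] <- as.numeric(tab[[j]])
  tab
}

#' Per-marker call rate
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector (one value per marker) of the fraction of
#'   non-missing genotypes, in `[0, 1]`.
#' @export
compute_call_rate <- function(g) {
  colMeans(!is.na(g$values))
}

#' Per-marker minor allele frequency
#'
#' The alt-allele frequency is `mean(dosage)/2` over non-missing entries;
#' MAF is its fold-over at 0.5.  Markers with no called genotypes get `NA`.
#'
#' @param g a [genotype_matrix()].
#' @return numeric vector of MAF values in `[0, 0.5]` (or `NA`).
#' @export
compute_maf <- function(g) {
  p <- colMeans(g$values, na.rm = TRUE) / 2
  p[is.nan(p)] <- NA_real_
  pmin(p, 1 - p)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit chi-square of observed genotype
#' counts against expected counts at the sample allele frequency.
#' Monomorphic input is defined to have statistic 0 and p-value 1.
#'
#' @param n0,n1,n2 counts of dosage-0, dosage-1 and dosage-2 genotypes.
#' @return list with `chisq` and `p`.
#' @export
hwe_test <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n <= 0) stop("hwe_test needs at least one genotype", call. = FALSE)
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(list(chisq = 0, p = 1))
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chisq <- sum((c(n0, n1, n2) - expected)^2 / expected)
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# Vectorized HWE p-values over markers (same statistic as hwe_test()).
hwe_p_values <- function(g) {
  v <- g$values
  n0 <- colSums(v == 0L, na.rm = TRUE)
  n1 <- colSums(v == 1L, na.rm = TRUE)
  n2 <- colSums(v == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p <- ifelse(n > 0, (2 * n2 + n1) / (2 * n), NA_real_)
  poly <- !is.na(p) & p > 0 & p < 1
  chisq <- numeric(length(n))
  q <- 1 - p
  e0 <- n * q^2; e1 <- 2 * n * p * q; e2 <- n * p^2
  chisq[poly] <- ((n0 - e0)^2 / e0 + (n1 - e1)^2 / e1 +
                    (n2 - e2)^2 / e2)[poly]
  pv <- rep(1, length(n))
  pv[poly] <- pchisq(chisq[poly], df = 1, lower.tail = FALSE)
  pv[n == 0] <- NA_real_
  pv
}

#' Apply marker quality control
#'
#' Removes markers with call rate strictly below `min_call_rate`, minor
#' allele frequency strictly below `min_maf`, or a Hardy-Weinberg
#' chi-square p-value strictly below `hwe_p` (defaults are the conventional
#' whole-genome-sequencing thresholds: 90% call rate, 5% MAF, p < 1e-7).
#' A marker failing several filters is attributed to the first failing one
#' in the order call rate, MAF, HWE.  Markers with zero called genotypes
#' are removed under the call-rate filter.
#'
#' @param g a [genotype_matrix()].
#' @param min_call_rate minimum call rate retained (default 0.90).
#' @param min_maf minimum minor allele frequency retained (default 0.05).
#' @param hwe_p HWE p-value threshold (default 1e-7).
#' @return list with the filtered `genotype` and a `report` (class
#'   `qc_report`) itemizing removals.
#' @export
apply_qc <- function(g, min_call_rate = 0.90, min_maf = 0.05,
                     hwe_p = 1e-7) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 0.5, hwe_p >= 0, hwe_p <= 1)
  m <- n_markers(g)
  cr <- compute_call_rate(g)
  maf <- compute_maf(g)
  hp <- hwe_p_values(g)
  fail_cr <- cr < min_call_rate
  fail_maf <- !fail_cr & (is.na(maf) | maf < min_maf)
  fail_hwe <- !fail_cr & !fail_maf & !is.na(hp) & hp < hwe_p
  keep <- !(fail_cr | fail_maf | fail_hwe)
  if (!any(keep))
    stop("quality control removed every marker", call. = FALSE)
  out <- genotype_matrix(g$values[, keep, drop = FALSE],
                         individual_ids = g$individual_ids,
                         markers = g$markers[keep, , drop = FALSE])
  report <- structure(list(
    input_markers = m,
    removed_call_rate = sum(fail_cr),
    removed_maf = sum(fail_maf),
    removed_hwe = sum(fail_hwe),
    retained = sum(keep),
    thresholds = list(min_call_rate = min_call_rate, min_maf = min_maf,
                      hwe_p = hwe_p)),
    class = "qc_report")
  list(genotype = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  labels <- c(sprintf("removed, call rate < %.2f", x$thresholds$min_call_rate),
              sprintf("removed, MAF < %.3f", x$thresholds$min_maf),
              sprintf("removed, HWE p < %g", x$thresholds$hwe_p),
              "retained")
  counts <- c(x$removed_call_rate, x$removed_maf, x$removed_hwe,
              x$retained)
  cat(sprintf("QC report: %d markers in\n", x$input_markers))
  cat(sprintf("  %-26s : %d\n", labels, counts), sep = "")
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param x a `qc_report`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string or `path` invisibly.
#' @export
qc_report_json <- function(x, path = NULL) {
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Mean-dosage imputation of missing genotypes
#'
#' Replaces each missing entry with the rounded marker-mean dosage.  The
#' compression stages require a complete matrix; real pipelines impute
#' upstream (e.g. Beagle), so this convenience is off by default everywhere.
#'
#' @param g a [genotype_matrix()].
#' @return a complete [genotype_matrix()].
#' @export
impute_mean <- function(g) {
  v <- g$values
  if (!anyNA(v)) return(g)
  means <- round(colMeans(v, na.rm = TRUE))
  means[is.nan(means)] <- 0
  idx <- which(is.na(v), arr.ind = TRUE)
  v[idx] <- as.integer(means[idx[, 2L]])
  genotype_matrix(v, g$individual_ids, g$markers)
}
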
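# The genotype_matrix container: samples x SNPs additive-coded genotypes
# with variant metadata, optional per-call quality fields and phenotype labels.

#' Construct a genotype matrix
#'
#' The universal input container of the package: an `n_samples x n_variants`
#' matrix of additive-coded genotypes (count of alternate alleles, 0/1/2,
#' `NA` = missing call), plus per-variant metadata, optional per-call genotype
#' quality (GQ) and read depth (DP) matrices, and an optional binary phenotype
#' per sample (1 = case).
#'
#' Variants are stored sorted by (chrom, pos); (chrom, pos, ref, alt) must be
#' unique. Duplicate (chrom, pos) pairs are allowed but marked multiallelic,
#' matching how split multiallelic VCF records are handled.
#'
#' @param calls numeric matrix, samples in rows, variants in columns; values
#'   in {0, 1, 2, NA}. Row names are sample ids, column names variant ids.
#' @param variants data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   and optionally `multiallelic` (logical, default `FALSE`).
#' @param gq,dp optional numeric matrices with the same shape as `calls`.
#' @param labels optional 0/1 vector, one per sample (1 = case).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, variants, gq = NULL, dp = NULL, labels = NULL) {
  calls <- as.matrix(calls)
  if (!is.data.frame(variants)) stop("`variants` must be a data.frame")
  need <- c("id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  if (ncol(calls) != nrow(variants))
    stop("calls has ", ncol(calls), " columns but variants has ", nrow(variants), " rows")
  if (is.null(variants$multiallelic)) variants$multiallelic <- FALSE
  if (any(variants$pos < 1)) stop("variant positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles must differ")
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  if (anyDuplicated(key)) stop("duplicate (chrom, pos, ref, alt) variant(s)")

  bad <- calls[!is.na(calls) & !(calls %in% c(0, 1, 2))]
  if (length(bad)) stop("genotype calls must be 0, 1, 2 or NA; found ", bad[1])

  # sort by (chrom, pos); duplicated positions imply split multiallelics
  ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt, method = "radix")
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (!is.null(gq)) gq <- as.matrix(gq)[, ord, drop = FALSE]
  if (!is.null(dp)) dp <- as.matrix(dp)[, ord, drop = FALSE]
  dup_pos <- paste(variants$chrom, variants$pos)
  variants$multiallelic <- variants$multiallelic | duplicated(dup_pos) |
    duplicated(dup_pos, fromLast = TRUE)
  rownames(variants) <- NULL

  if (is.null(rownames(calls))) rownames(calls) <- paste0("sample", seq_len(nrow(calls)))
  colnames(calls) <- variants$id
  if (!is.null(gq)) dimnames(gq) <- dimnames(calls)
  if (!is.null(dp)) dimnames(dp) <- dimnames(calls)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(calls)) stop("labels length must equal sample count")
    if (any(!labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
    names(labels) <- rownames(calls)
  }
  structure(
    list(calls = calls, variants = variants, gq = gq, dp = dp, labels = labels),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "genotype_matrix: %d samples x %d variants (%s), %.1f%% missing%s\n",
    n_samples(x), n_snps(x),
    paste(unique(x$variants$chrom), collapse = ","),
    100 * mean(is.na(x$calls)),
    if (is.null(x$labels)) "" else sprintf(", %d cases / %d controls",
                                           sum(x$labels == 1), sum(x$labels == 0))
  ))
  invisible(x)
}

#' Number of samples / variants in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) nrow(gm$calls)

#' @rdname n_samples
#' @export
n_snps <- function(gm) ncol(gm$calls)

#' Variant identifiers of a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector of variant ids in genomic order.
#' @export
variant_ids <- function(gm) gm$variants$id

#' Subset a genotype matrix by samples and/or variants
#'
#' @param gm a `genotype_matrix`.
#' @param samples sample ids or indices (default all).
#' @param snps variant ids or column indices (default all).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_gm <- function(gm, samples = NULL, snps = NULL) {
  si <- if (is.null(samples)) seq_len(n_samples(gm)) else {
    if (is.character(samples)) match(samples, rownames(gm$calls)) else samples
  }
  vi <- if (is.null(snps)) seq_len(n_snps(gm)) else {
    if (is.character(snps)) match(snps, gm$variants$id) else snps
  }
  if (anyNA(si)) stop("unknown sample id(s)")
  if (anyNA(vi)) stop("unknown variant id(s)")
  structure(
    list(
      calls = gm$calls[si, vi, drop = FALSE],
      variants = gm$variants[vi, , drop = FALSE],
      gq = if (!is.null(gm$gq)) gm$gq[si, vi, drop = FALSE],
      dp = if (!is.null(gm$dp)) gm$dp[si, vi, drop = FALSE],
      labels = if (!is.null(gm$labels)) gm$labels[si]
    ),
    class = "genotype_matrix"
  )
}

#' Extract a genomic region from a genotype matrix
#'
#' Returns the variants whose position lies in the 1-based closed interval
#' `[start, end]` on chromosome `chrom`; the sample set is unchanged. An empty
#' result is returned with a warning, not an error.
#'
#' @param gm a `genotype_matrix`.
#' @param chrom chromosome label.
#' @param start,end interval bounds in bp, `start <= end`.
#' @return a `genotype_matrix`.
#' @export
extract_region <- function(gm, chrom, start, end) {
  stopifnot(start <= end)
  keep <- which(gm$variants$chrom == chrom &
                  gm$variants$pos >= start & gm$variants$pos <= end)
  if (!length(keep))
    warning("no variants in ", chrom, ":", start, "-", end)
  subset_gm(gm, snps = keep)
}

# positional key used for cross-cohort matching
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
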
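# Reading and writing genotype data: VCF (via vcfR) and plain TSV matrices.

#' Read a VCF file into a genotype matrix
#'
#' Diploid GT fields are converted to additive dosages (count of non-reference
#' alleles): `0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./.` -> missing. Records with
#' more than one ALT allele are retained as a single column (dosage = count of
#' non-reference alleles) but flagged `multiallelic` so downstream QC removes
#' them. Per-call GQ and DP are captured when the FORMAT declares them.
#'
#' @param path VCF file (v4.x, plain or bgzipped).
#' @param region optional `list(chrom =, start =, end =)` restricting the
#'   result to a 1-based closed genomic interval.
#' @param labels optional 0/1 phenotype vector named by sample id.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, region = NULL, labels = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("VCF has no records: ", path)

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt_raw)) stop("VCF has no GT field: ", path)

  alleles <- strsplit(gsub("\\|", "/", as.vector(gt_raw)), "/", fixed = TRUE)
  n_al <- lengths(alleles)
  non_missing <- !is.na(as.vector(gt_raw))
  if (any(non_missing & n_al != 2)) {
    bad <- which(non_missing & n_al != 2)[1]
    rec <- (bad - 1) %% nrow(gt_raw) + 1
    stop("non-diploid GT at record ", fix$CHROM[rec], ":", fix$POS[rec])
  }
  dose <- vapply(alleles, function(a) {
    if (length(a) != 2 || any(a == ".")) return(NA_real_)
    sum(a != "0")
  }, numeric(1))
  dose[!non_missing] <- NA_real_
  calls <- t(matrix(dose, nrow = nrow(gt_raw), dimnames = dimnames(gt_raw)))

  grab_num <- function(el) {
    m <- tryCatch(vcfR::extract.gt(vcf, element = el, as.numeric = TRUE),
                  error = function(e) NULL)
    if (is.null(m) || all(is.na(m))) NULL else t(m)
  }
  gq <- grab_num("GQ")
  dp <- grab_num("DP")

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  alt1 <- sub(",.*$", "", fix$ALT)
  id <- fix$ID
  synth <- is.na(id) | id == "." | id == ""
  id[synth] <- paste(fix$CHROM[synth], fix$POS[synth], fix$REF[synth], alt1[synth], sep = ":")

  variants <- data.frame(
    id = id, chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = alt1, multiallelic = multi,
    stringsAsFactors = FALSE
  )
  gm <- genotype_matrix(calls, variants, gq = gq, dp = dp)
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[rownames(gm$calls)]
    gm$labels <- stats::setNames(as.integer(labels), rownames(gm$calls))
  }
  if (!is.null(region)) gm <- extract_region(gm, region$chrom, region$start, region$end)
  gm
}

#' Write a genotype matrix as a VCF v4.2 text file
#'
#' Emits one biallelic record per variant with GT (and GQ/DP when present).
#' Dosages map back to unphased genotypes `0/0`, `0/1`, `1/1`; missing calls
#' become `./.`.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  has_q <- !is.null(gm$gq) && !is.null(gm$dp)
  fmt <- if (has_q) "GT:GQ:DP" else "GT"
  gt_map <- c("0/0", "0/1", "1/1")
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=dualnet",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_q) '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    if (has_q) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$calls)), collapse = "\t")
  )
  v <- gm$variants
  lines <- vapply(seq_len(n_snps(gm)), function(j) {
    g <- gm$calls[, j]
    cells <- ifelse(is.na(g), "./.", gt_map[g + 1])
    if (has_q) {
      cells <- paste(cells,
                     ifelse(is.na(gm$gq[, j]), ".", gm$gq[, j]),
                     ifelse(is.na(gm$dp[, j]), ".", gm$dp[, j]), sep = ":")
    }
    paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".", "PASS",
            ".", fmt, cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Read / write a genotype matrix as TSV
#'
#' Plain-text exchange format: samples as rows, first column `sample_id`,
#' remaining columns one per variant (header = variant id), cells 0/1/2/NA.
#' Variant ids of the form `chrom:pos:ref:alt` are parsed back into metadata;
#' other ids get a placeholder chromosome and sequential positions.
#'
#' @param path TSV file path.
#' @param gm a [genotype_matrix()] (for writing).
#' @return [read_genotype_tsv()] returns a `genotype_matrix`;
#'   [write_genotype_tsv()] returns `path` invisibly.
#' @export
read_genotype_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") stop("first column must be sample_id: ", path)
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$sample_id
  ids <- colnames(calls)
  parts <- strsplit(ids, ":", fixed = TRUE)
  parseable <- lengths(parts) == 4 & !is.na(suppressWarnings(
    vapply(parts, function(p) as.numeric(p[2]), numeric(1))))
  variants <- data.frame(
    id = ids,
    chrom = ifelse(parseable, vapply(parts, `[`, "", 1), "un"),
    pos = ifelse(parseable,
                 vapply(parts, function(p) suppressWarnings(as.numeric(p[2])), 0),
                 seq_along(ids)),
    ref = ifelse(parseable, vapply(parts, `[`, "", 3), "A"),
    alt = ifelse(parseable, vapply(parts, `[`, "", 4), "G"),
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, variants)
}

#' @rdname read_genotype_tsv
#' @export
write_genotype_tsv <- function(gm, path) {
  df <- data.frame(sample_id = rownames(gm$calls), gm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write phenotype labels as TSV (columns sample_id, label)
#' @param path TSV file path.
#' @param labels named 0/1 vector (for writing).
#' @return named integer vector of labels; or `path` invisibly.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("labels TSV needs columns sample_id, label: ", path)
  stats::setNames(as.integer(df$label), df$sample_id)
}

#' @rdname read_labels_tsv
#' @export
write_labels_tsv <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), label = as.integer(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Mask low-quality genotype calls
#'
#' Sets to missing every call whose genotype quality is below `gq_min` or
#' whose read depth is below `dp_min` (strict inequalities: GQ 20 / DP 10 are
#' kept under the defaults). A matrix without GQ/DP is returned unchanged with
#' a warning.
#'
#' @param gm a [genotype_matrix()] with `gq` and `dp` fields.
#' @param thresholds a [qc_thresholds()] object (fields `gq_min`, `dp_min`).
#' @return a `genotype_matrix` with failing calls set to `NA`.
#' @export
mask_low_quality <- function(gm, thresholds = qc_thresholds()) {
  if (is.null(gm$gq) || is.null(gm$dp)) {
    warning("genotype matrix has no GQ/DP fields; nothing masked")
    return(gm)
  }
  bad <- (!is.na(gm$gq) & gm$gq < thresholds$gq_min) |
    (!is.na(gm$dp) & gm$dp < thresholds$dp_min)
  gm$calls[bad] <- NA
  gm
}
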
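# Per-SNP functional annotations: four closed category families, binary
# indicator encoding, and annotation-defined SNP groups.

#' Annotation category families and their closed vocabularies
#'
#' Four families describe each SNP: genomic context (with "region none" for
#' SNPs outside exonic/intronic/UTR sequence), Ensembl gene biotype, most
#' severe predicted consequence, and ClinVar-style clinical significance.
#' Every family additionally admits "unknown". Blank or missing cells are
#' mapped to "unknown" on load; values outside the vocabulary are rejected.
#'
#' @return `annotation_families()`: character vector of the four family
#'   (column) names, in canonical order. `annotation_vocabulary()`: named
#'   list of allowed values per family.
#' @export
annotation_families <- function() {
  c("genomic_context", "gene_biotype", "most_severe_consequence",
    "clinical_significance")
}

#' @rdname annotation_families
#' @export
annotation_vocabulary <- function() {
  list(
    genomic_context = c("exonic", "intronic", "UTR", "region none", "unknown"),
    gene_biotype = c("TEC", "long noncoding RNA", "protein coding",
                     "transcribed unprocessed pseudogene", "unknown"),
    most_severe_consequence = c(
      "3 prime UTR variant", "5 prime UTR variant",
      "TF binding site variant", "intergenic variant", "intron variant",
      "missense variant", "regulatory region variant",
      "splice donor region variant", "splice polypyrimidine tract variant",
      "splice region variant", "stop gained", "synonymous variant", "unknown"),
    clinical_significance = c(
      "pathogenic", "likely pathogenic", "uncertain significance",
      "drug response", "other", "risk factor", "association", "protective",
      "established risk allele", "unknown")
  )
}

#' Load a per-SNP annotation table from TSV
#'
#' Expects columns `snp_id` plus the four family columns of
#' [annotation_families()]. Blank/NA cells become "unknown"; any value outside
#' the family's closed vocabulary is rejected with the offending value named.
#'
#' @param path TSV file path.
#' @return an `annotation_table` (data.frame with validated columns).
#' @export
load_annotations <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  as_annotation_table(df)
}

#' Validate a data.frame as an annotation table
#' @param df data.frame with `snp_id` and the four family columns.
#' @return an `annotation_table`.
#' @export
as_annotation_table <- function(df) {
  fams <- annotation_families()
  miss <- setdiff(c("snp_id", fams), names(df))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$snp_id))
    stop("duplicate snp_id in annotation table: ",
         df$snp_id[duplicated(df$snp_id)][1])
  vocab <- annotation_vocabulary()
  for (f in fams) {
    v <- df[[f]]
    v[is.na(v) | trimws(v) == ""] <- "unknown"
    bad <- setdiff(unique(v), vocab[[f]])
    if (length(bad))
      stop("value not in ", f, " vocabulary: \"", bad[1], "\"")
    df[[f]] <- v
  }
  df <- df[, c("snp_id", fams)]
  structure(df, class = c("annotation_table", "data.frame"))
}

#' One-hot indicator encoding of an annotation table
#'
#' One binary column per observed family=value combination; within each row,
#' exactly one 1 per family. Column order is deterministic: families in
#' canonical order, values byte-lexicographic within a family.
#'
#' @param tbl an `annotation_table`.
#' @return binary matrix, SNPs in rows (named by snp_id), groups in columns
#'   (named `family=value`).
#' @export
encode_indicators <- function(tbl) {
  cols <- list()
  for (f in annotation_families()) {
    for (v in lex_sort(unique(tbl[[f]]))) {
      cols[[paste0(f, "=", v)]] <- as.integer(tbl[[f]] == v)
    }
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- tbl$snp_id
  mat
}

#' Build annotation-defined SNP groups against a genotype matrix
#'
#' For every observed family=value, collects the genotype-matrix column
#' indices of the SNPs carrying that annotation. Ids are resolved first by
#' exact variant id, then positionally by `chrom:pos:ref:alt`. Groups smaller
#' than `min_size` are dropped with a warning (they cannot support stratified
#' 5-fold model fitting).
#'
#' @param tbl an `annotation_table`.
#' @param gm a [genotype_matrix()].
#' @param min_size minimum members per retained group (default 10).
#' @return list of `annotation_group` objects (fields `label`, `family`,
#'   `value`, `members` = column indices, `snp_ids`), with attributes
#'   `n_unresolved` and `dropped` (labels of undersized groups).
#' @export
build_groups <- function(tbl, gm, min_size = 10) {
  idx <- match(tbl$snp_id, gm$variants$id)
  pos_key <- variant_key(gm$variants)
  idx[is.na(idx)] <- match(tbl$snp_id[is.na(idx)], pos_key)
  n_unresolved <- sum(is.na(idx))
  if (all(is.na(idx)))
    stop("no annotation snp_id resolves to the genotype matrix")

  groups <- list()
  dropped <- character(0)
  for (f in annotation_families()) {
    for (v in lex_sort(unique(tbl[[f]]))) {
      members <- idx[tbl[[f]] == v]
      members <- sort(members[!is.na(members)])
      label <- paste0(f, "=", v)
      if (length(members) < min_size) {
        dropped <- c(dropped, label)
        next
      }
      groups[[label]] <- structure(
        list(label = label, family = f, value = v, members = members,
             snp_ids = gm$variants$id[members]),
        class = "annotation_group"
      )
    }
  }
  if (length(dropped))
    warning("dropped ", length(dropped), " group(s) below min_size ",
            min_size, ": ", paste(dropped, collapse = ", "))
  structure(groups, n_unresolved = n_unresolved, dropped = dropped)
}
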
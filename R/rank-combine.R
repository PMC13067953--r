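# Combining local and global scores: the alpha-weighted blend, the nested-CV
# alpha grid search, SNP ranking and top/bottom panel construction.

#' Alpha-weighted combination of local and global scores
#'
#' `alpha * local + (1 - alpha) * global`. `alpha = 1` uses only the local
#' (window) score, `alpha = 0` only the global (annotation) score. SNPs with
#' a missing local score (dropped window tail) fall back to their global
#' score alone.
#'
#' @param local,global score vectors in \[0, 1\] (local may contain NA).
#' @param alpha weight in \[0, 1\].
#' @return numeric vector of combined scores.
#' @export
combined_score <- function(local, global, alpha) {
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  out <- alpha * local + (1 - alpha) * global
  out[is.na(local)] <- global[is.na(local)]
  out
}

#' Build a per-SNP combined score table
#'
#' @param local,global named per-SNP score vectors (from
#'   [score_windows()] / [assign_global_scores()]).
#' @param alpha blend weight.
#' @param variants variant metadata data.frame (id, chrom, pos).
#' @return a ranked data.frame (class `combined_score_table`) with columns
#'   rank, snp_id, chrom, pos, local_score, global_score, combined_score,
#'   alpha, no_local (flag for tail SNPs scored by global only).
#' @export
combined_score_table <- function(local, global, alpha, variants) {
  stopifnot(length(local) == nrow(variants), length(global) == nrow(variants))
  tbl <- data.frame(
    snp_id = variants$id, chrom = variants$chrom, pos = variants$pos,
    ref = variants$ref, alt = variants$alt,
    local_score = as.numeric(local), global_score = as.numeric(global),
    combined_score = combined_score(as.numeric(local), as.numeric(global), alpha),
    alpha = alpha, no_local = is.na(local),
    stringsAsFactors = FALSE
  )
  rank_snps(tbl)
}

#' Rank SNPs by combined score
#'
#' Descending combined score; ties broken by ascending genomic position,
#' then by SNP id — fully deterministic.
#'
#' @param tbl data.frame with columns snp_id, chrom, pos, combined_score.
#' @return the table sorted by rank, with a `rank` column (1 = best)
#'   prepended; class `combined_score_table`.
#' @export
rank_snps <- function(tbl) {
  ord <- order(-tbl$combined_score, tbl$chrom, tbl$pos, tbl$snp_id,
               method = "radix")
  out <- tbl[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  class(out) <- c("combined_score_table", "data.frame")
  out
}

#' Optimize the local/global blend weight by inner cross-validation
#'
#' For each alpha on the grid, all SNPs are re-ranked by their combined
#' score, the top `top_k` SNPs are taken as a panel, and the stacking
#' ensemble is evaluated on that panel's features over the training samples
#' by `inner_folds`-fold out-of-fold cross-validation (every sample's
#' prediction is out-of-fold at both the base and metamodel level). The
#' alpha with the highest mean inner accuracy wins; exact ties break toward
#' the smallest alpha. Identical panels arising for different alpha values
#' are evaluated once and cached.
#'
#' @param local,global per-SNP score vectors computed on the training
#'   samples only.
#' @param gm_train [genotype_matrix()] restricted to the (outer-)training
#'   samples, with labels.
#' @param grid candidate alpha values (default 0.0 to 1.0 by 0.1).
#' @param inner_folds folds of the inner CV (default 5).
#' @param top_k panel size used for evaluation (default 100).
#' @param cfg base-learner pair.
#' @param seed integer seed.
#' @return object of class `alpha_search`: `results` data.frame (alpha,
#'   inner_accuracy), `chosen_alpha`, `note` on tie-breaking.
#' @export
optimize_alpha <- function(local, global, gm_train,
                           grid = seq(0, 1, by = 0.1), inner_folds = 5,
                           top_k = 100, cfg = default_stack_config(),
                           seed = 42) {
  if (!length(grid)) stop("alpha grid is empty")
  if (top_k > n_snps(gm_train))
    stop("top_k (", top_k, ") exceeds SNP count (", n_snps(gm_train), ")")
  grid <- sort(grid)
  cache <- new.env(parent = emptyenv())
  acc <- vapply(grid, function(a) {
    tbl <- combined_score_table(local, global, a, gm_train$variants)
    panel <- tbl$snp_id[seq_len(top_k)]
    key <- paste(sort(panel), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    m <- fit_oof_stack(gm_train$calls[, panel, drop = FALSE], gm_train$labels,
                       cfg = cfg, n_folds = inner_folds, seed = seed,
                       refit = FALSE)
    cache[[key]] <- oof_cv_accuracy(m)
    cache[[key]]
  }, numeric(1))
  best <- which.max(acc)  # first max -> smallest alpha on ties
  tie <- sum(abs(acc - acc[best]) < 1e-15) > 1
  structure(
    list(results = data.frame(alpha = grid, inner_accuracy = acc),
         chosen_alpha = grid[best],
         note = if (tie) "tie broken toward smallest alpha" else "unique maximum"),
    class = "alpha_search"
  )
}

#' Aggregate per-fold score tables into a final ranking
#'
#' Averages each SNP's combined score over the outer folds (each fold having
#' used its own chosen alpha) and re-ranks with the standard tie-break.
#'
#' @param fold_tables list of `combined_score_table`s over the same SNP
#'   universe.
#' @return a `combined_score_table` with the cross-fold mean scores.
#' @export
aggregate_fold_scores <- function(fold_tables) {
  if (!length(fold_tables)) stop("no fold tables to aggregate")
  ref <- fold_tables[[1]]
  ref <- ref[order(ref$snp_id, method = "radix"), ]
  acc <- matrix(NA_real_, nrow(ref), length(fold_tables))
  for (i in seq_along(fold_tables)) {
    t_i <- fold_tables[[i]]
    if (!setequal(t_i$snp_id, ref$snp_id) || nrow(t_i) != nrow(ref))
      stop("fold tables cover different SNP sets")
    acc[, i] <- t_i$combined_score[match(ref$snp_id, t_i$snp_id)]
  }
  out <- data.frame(
    snp_id = ref$snp_id, chrom = ref$chrom, pos = ref$pos,
    ref = ref$ref, alt = ref$alt,
    local_score = NA_real_, global_score = NA_real_,
    combined_score = rowMeans(acc),
    alpha = NA_real_, no_local = ref$no_local,
    stringsAsFactors = FALSE
  )
  rank_snps(out)
}

#' Build top and bottom SNP panels from a ranking
#'
#' For each requested size `s`, the top panel holds ranks 1..s and the
#' bottom panel the last s ranks (the negative control).
#'
#' @param ranking a `combined_score_table`.
#' @param sizes panel sizes (default 100, 500, 1000).
#' @return named list (`top_100`, `bottom_100`, ...) of snp_id vectors.
#' @export
build_panels <- function(ranking, sizes = c(100, 500, 1000)) {
  n <- nrow(ranking)
  if (any(sizes > n))
    stop("panel size ", max(sizes), " exceeds number of ranked SNPs (", n, ")")
  out <- list()
  for (s in sizes) {
    out[[paste0("top_", s)]] <- ranking$snp_id[seq_len(s)]
    out[[paste0("bottom_", s)]] <- ranking$snp_id[seq(n - s + 1, n)]
  }
  out
}

#' Write a ranking table as TSV
#' @param ranking a `combined_score_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ranking_tsv <- function(ranking, path) {
  df <- as.data.frame(ranking)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.10g", x)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
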
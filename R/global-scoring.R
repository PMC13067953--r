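# Global scoring: stacking-ensemble accuracy per annotation group, averaged
# into a per-SNP global score over all groups containing the SNP.

#' Score annotation groups with the stacking ensemble
#'
#' For each annotation-defined SNP group, fits [fit_oof_stack()] on the
#' group's SNP columns over the training samples and records the holdout
#' accuracy. Groups too small for the stratified OOF split (or whose fit
#' fails) are skipped with a warning.
#'
#' @param gm a [genotype_matrix()] with labels and no missing calls.
#' @param groups list of annotation groups from [build_groups()].
#' @param split list with disjoint sample-id/index vectors `train`, `holdout`.
#' @param cfg base-learner pair.
#' @param seed integer seed.
#' @return data.frame (label, family, size, accuracy) with one row per
#'   scored group.
#' @export
score_annotation_groups <- function(gm, groups, split,
                                    cfg = default_stack_config(), seed = 42) {
  if (is.null(gm$labels)) stop("genotype matrix has no phenotype labels")
  if (!length(groups)) stop("no annotation groups to score")
  tr <- resolve_ids(gm, split$train)
  ho <- resolve_ids(gm, split$holdout)
  if (length(intersect(tr, ho))) stop("train and holdout overlap")

  rows <- lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    a <- tryCatch({
      # shared seed across groups: one OOF sample split for the whole stage
      m <- fit_oof_stack(gm$calls[tr, sort(g$members), drop = FALSE],
                         gm$labels[tr],
                         cfg = cfg, seed = seed)
      holdout_score(m, gm$calls[ho, g$members, drop = FALSE],
                    gm$labels[ho])$accuracy
    }, error = function(e) {
      warning("group \"", g$label, "\" skipped (", conditionMessage(e), ")",
              call. = FALSE)
      NA_real_
    })
    data.frame(label = g$label, family = g$family, size = length(g$members),
               accuracy = a, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!is.na(out$accuracy), , drop = FALSE]
}

#' Assign per-SNP global scores from group accuracies
#'
#' Each SNP's global score is the unweighted mean of the accuracies of all
#' annotation groups containing it, across families. SNPs that ended up in
#' no surviving group receive the mean of all group accuracies and are
#' flagged as fallback.
#'
#' @param group_acc data.frame from [score_annotation_groups()].
#' @param groups the group list the accuracies were computed for.
#' @param n_snps total number of SNPs in the genotype matrix.
#' @param snp_ids optional variant ids used to name the score vector.
#' @return object of class `global_score_table`: `groups` (the accuracy
#'   table), `snp_scores` (numeric length `n_snps`), `group_count` (groups
#'   per SNP), `fallback` (logical flags).
#' @export
assign_global_scores <- function(group_acc, groups, n_snps, snp_ids = NULL) {
  if (!nrow(group_acc)) stop("empty group accuracy table")
  total <- numeric(n_snps)
  count <- integer(n_snps)
  for (i in seq_len(nrow(group_acc))) {
    g <- groups[[group_acc$label[i]]]
    total[g$members] <- total[g$members] + group_acc$accuracy[i]
    count[g$members] <- count[g$members] + 1L
  }
  fallback <- count == 0
  scores <- ifelse(fallback, mean(group_acc$accuracy), total / pmax(count, 1))
  if (!is.null(snp_ids)) names(scores) <- snp_ids
  structure(
    list(groups = group_acc, snp_scores = scores, group_count = count,
         fallback = fallback),
    class = "global_score_table"
  )
}
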
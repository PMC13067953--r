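# Nested-CV orchestration, panel evaluation, baselines with paired tests,
# LD proxies and ablation, cross-cohort rank transfer, cohort summaries.

#' Run the full nested cross-validation prioritization pipeline
#'
#' Outer loop: stratified `outer_folds`-fold CV over samples. Within each
#' outer training set, a stratified `score_split_frac` train/holdout split
#' drives window scoring ([score_windows()]) and annotation-group scoring
#' ([score_annotation_groups()]); the blend weight alpha is then tuned by
#' the inner CV grid search ([optimize_alpha()]), SNPs are ranked, and
#' top/bottom panels of each requested size are evaluated by training the
#' stacking ensemble on the outer-training samples (panel features only) and
#' scoring the untouched outer test fold. Every quantity used to rank a
#' fold's panels derives solely from that fold's outer-training samples.
#'
#' The cross-fold final ranking averages each SNP's combined score over the
#' outer folds via [aggregate_fold_scores()].
#'
#' @param gm a QC'd, imputed [genotype_matrix()] with labels.
#' @param annotations an `annotation_table` covering the matrix's SNPs.
#' @param outer_folds,inner_folds fold counts (default 5/5).
#' @param window_size SNPs per local window (default 100).
#' @param keep_partial keep the trailing partial window.
#' @param alpha_grid candidate blend weights (default 0.0-1.0 by 0.1).
#' @param top_k panel size used inside the alpha search (default 100).
#' @param panel_sizes evaluated panel sizes (default 100, 500, 1000).
#' @param score_split_frac training fraction of the within-fold score split.
#' @param min_group_size minimum annotation-group size (default 10).
#' @param cfg base-learner pair (see [default_stack_config()]).
#' @param seed integer seed governing every split and fit.
#' @return object of class `nested_cv_result`: per-fold details (chosen
#'   alpha, score tables, panels, sample-id bookkeeping), `panel_evaluations`
#'   (per-panel fold metrics with 95% CIs), `final_ranking`, `alphas`.
#' @export
run_nested_cv <- function(gm, annotations, outer_folds = 5, inner_folds = 5,
                          window_size = 100, keep_partial = FALSE,
                          alpha_grid = seq(0, 1, by = 0.1), top_k = 100,
                          panel_sizes = c(100, 500, 1000),
                          score_split_frac = 0.8, min_group_size = 10,
                          cfg = default_stack_config(), seed = 42) {
  if (is.null(gm$labels)) stop("genotype matrix has no phenotype labels")
  if (anyNA(gm$calls)) stop("genotype matrix has missing calls; impute first")
  ws <- make_windows(n_snps(gm), window_size, keep_partial)
  groups <- suppressWarnings(build_groups(annotations, gm, min_group_size))
  fold_of <- stratified_folds(gm$labels, outer_folds, seed)

  folds <- vector("list", outer_folds)
  for (f in seq_len(outer_folds)) {
    folds[[f]] <- tryCatch(
      nested_cv_fold(gm, ws, groups, fold_of, f, inner_folds, alpha_grid,
                     top_k, panel_sizes, score_split_frac, cfg,
                     mix_seed(seed, f)),
      error = function(e) structure(list(failed = TRUE,
                                         message = conditionMessage(e)),
                                    class = "nested_cv_fold_failure")
    )
  }
  ok <- !vapply(folds, inherits, logical(1), "nested_cv_fold_failure")
  if (sum(ok) < 3)
    stop("fewer than 3 outer folds succeeded; cannot form confidence intervals")

  panel_ids <- unlist(lapply(panel_sizes, function(s) paste0(c("top_", "bottom_"), s)))
  pe <- lapply(panel_ids, function(pid) {
    aucs <- vapply(folds[ok], function(fd) fd$panel_metrics[[pid]]$auc, numeric(1))
    accs <- vapply(folds[ok], function(fd) fd$panel_metrics[[pid]]$accuracy, numeric(1))
    list(panel = pid, auc = aucs, accuracy = accs,
         auc_ci = ci95(aucs), accuracy_ci = ci95(accs))
  })
  names(pe) <- panel_ids

  structure(
    list(folds = folds, panel_evaluations = pe,
         final_ranking = aggregate_fold_scores(
           lapply(folds[ok], `[[`, "score_table")),
         alphas = vapply(folds[ok], `[[`, numeric(1), "alpha"),
         window_set = ws, groups = groups, outer_fold_of = fold_of,
         panel_sizes = panel_sizes, seed = seed),
    class = "nested_cv_result"
  )
}

# one outer fold of the nested CV
nested_cv_fold <- function(gm, ws, groups, fold_of, f, inner_folds, alpha_grid,
                           top_k, panel_sizes, score_split_frac, cfg, seed) {
  train_idx <- which(fold_of != f)
  test_idx <- which(fold_of == f)
  gm_tr <- subset_gm(gm, samples = train_idx)

  split <- stratified_split(gm_tr$labels, score_split_frac, mix_seed(seed, 101))
  local <- score_windows(gm_tr, ws, split, cfg, mix_seed(seed, 202))
  grp_acc <- score_annotation_groups(gm_tr, groups, split, cfg, mix_seed(seed, 303))
  globals <- assign_global_scores(grp_acc, groups, n_snps(gm_tr),
                                  gm_tr$variants$id)
  search <- optimize_alpha(local$snp_scores, globals$snp_scores, gm_tr,
                           grid = alpha_grid, inner_folds = inner_folds,
                           top_k = top_k, cfg = cfg, seed = mix_seed(seed, 404))
  tbl <- combined_score_table(local$snp_scores, globals$snp_scores,
                              search$chosen_alpha, gm_tr$variants)
  panels <- build_panels(tbl, panel_sizes)

  metrics <- lapply(panels, function(panel) {
    m <- fit_oof_stack(gm_tr$calls[, panel, drop = FALSE], gm_tr$labels,
                       cfg = cfg, seed = mix_seed(seed, 505))
    hs <- holdout_score(m, gm$calls[test_idx, panel, drop = FALSE],
                        gm$labels[test_idx])
    list(auc = hs$auc, accuracy = hs$accuracy)
  })
  list(
    alpha = search$chosen_alpha, alpha_search = search,
    local = local, globals = globals, score_table = tbl, panels = panels,
    panel_metrics = metrics,
    train_ids = rownames(gm_tr$calls),
    test_ids = rownames(gm$calls)[test_idx],
    score_split = list(train = rownames(gm_tr$calls)[split$train],
                       holdout = rownames(gm_tr$calls)[split$holdout])
  )
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf("nested_cv_result: %d outer folds, alphas = %s\n",
              length(x$folds), paste(x$alphas, collapse = ", ")))
  for (pid in names(x$panel_evaluations)) {
    pe <- x$panel_evaluations[[pid]]
    cat(sprintf("  %-12s AUC %.3f (%.3f-%.3f)  acc %.3f\n", pid,
                pe$auc_ci$mean, pe$auc_ci$lower, pe$auc_ci$upper,
                pe$accuracy_ci$mean))
  }
  invisible(x)
}

#' Evaluate a SNP panel by stratified cross-validation
#'
#' Per fold, the stacking ensemble is trained on the training portion
#' restricted to the panel's features and scored (AUC, accuracy) on the
#' test fold; fold metrics are aggregated with [ci95()].
#'
#' @param gm a [genotype_matrix()] with labels and no missing calls.
#' @param panel vector of snp_ids present in `gm`.
#' @param folds number of CV folds (default 5).
#' @param cfg base-learner pair.
#' @param seed integer seed.
#' @return object of class `panel_evaluation`: per-fold `auc` and
#'   `accuracy`, plus `auc_ci` / `accuracy_ci`.
#' @export
evaluate_panel <- function(gm, panel, folds = 5, cfg = default_stack_config(),
                           seed = 42) {
  if (is.null(gm$labels)) stop("genotype matrix has no phenotype labels")
  panel <- intersect(panel, gm$variants$id)
  if (!length(panel)) stop("panel is empty after matching to the matrix")
  fold_of <- stratified_folds(gm$labels, folds, seed)
  aucs <- accs <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    m <- fit_oof_stack(gm$calls[tr, panel, drop = FALSE], gm$labels[tr],
                       cfg = cfg, seed = mix_seed(seed, f))
    hs <- holdout_score(m, gm$calls[te, panel, drop = FALSE], gm$labels[te])
    aucs[f] <- hs$auc; accs[f] <- hs$accuracy
  }
  structure(
    list(panel_size = length(panel), auc = aucs, accuracy = accs,
         auc_ci = ci95(aucs), accuracy_ci = ci95(accs), seed = seed),
    class = "panel_evaluation"
  )
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat(sprintf("panel_evaluation (%d SNPs): AUC %.3f (%.3f-%.3f), acc %.3f (%.3f-%.3f)\n",
              x$panel_size, x$auc_ci$mean, x$auc_ci$lower, x$auc_ci$upper,
              x$accuracy_ci$mean, x$accuracy_ci$lower, x$accuracy_ci$upper))
  invisible(x)
}

#' Baseline: ridge-penalized logistic regression on all SNPs
#'
#' Per stratified fold, features constant in the training portion are
#' dropped, the remaining features are standardized on the training portion
#' only, and an L2-penalized logistic model (lambda = 1/n_train, up to 1,000
#' IRLS iterations) is fitted and scored on the test fold.
#'
#' @param gm a [genotype_matrix()] with labels and no missing calls.
#' @param folds number of CV folds (default 5).
#' @param seed integer seed (fold split shared with other baselines /
#'   pipelines given the same seed, so paired tests are valid).
#' @return list with per-fold `auc` and the number of dropped constant
#'   features per fold.
#' @export
baseline_logreg_all_snps <- function(gm, folds = 5, seed = 42) {
  if (is.null(gm$labels)) stop("genotype matrix has no phenotype labels")
  if (anyNA(gm$calls)) stop("genotype matrix has missing calls; impute first")
  fold_of <- stratified_folds(gm$labels, folds, seed)
  aucs <- numeric(folds)
  dropped <- integer(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    Xtr <- gm$calls[tr, , drop = FALSE]
    keep <- apply(Xtr, 2, function(x) stats::var(x) > 0)
    dropped[f] <- sum(!keep)
    if (any(!keep))
      warning(sum(!keep), " constant feature(s) dropped in fold ", f)
    fit <- glmnet::glmnet(Xtr[, keep, drop = FALSE], gm$labels[tr],
                          family = "binomial", alpha = 0,
                          lambda = 1 / length(tr), standardize = TRUE,
                          maxit = 1000)
    pr <- stats::predict(fit, gm$calls[te, keep, drop = FALSE],
                         type = "response")[, 1]
    aucs[f] <- auc(gm$labels[te], pr)
  }
  list(auc = aucs, dropped_constant = dropped)
}

# one-way two-group ANOVA F statistic per feature column (vectorized)
anova_f_stats <- function(X, y) {
  i1 <- y == 1; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0); n <- n1 + n0
  m1 <- colMeans(X[i1, , drop = FALSE])
  m0 <- colMeans(X[i0, , drop = FALSE])
  m <- (n1 * m1 + n0 * m0) / n
  ssb <- n1 * (m1 - m)^2 + n0 * (m0 - m)^2
  ssw <- colSums((t(t(X[i1, , drop = FALSE]) - m1))^2) +
    colSums((t(t(X[i0, , drop = FALSE]) - m0))^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  f[ssb == 0] <- 0  # identical class means (incl. constant features)
  f
}

#' Baseline: univariate ANOVA-F selection + random forest
#'
#' Per stratified fold, the ANOVA F statistic of every SNP is computed on
#' the training portion only, the top `k` SNPs are selected, and a random
#' forest (100 trees) on those features is scored on the test fold.
#'
#' @param gm a [genotype_matrix()] with labels and no missing calls.
#' @param k SNPs selected per fold (default 100).
#' @param folds number of CV folds (default 5).
#' @param seed integer seed.
#' @return list with per-fold `auc` and `selected` (list of snp_id vectors,
#'   recomputed per fold).
#' @export
baseline_anova_rf <- function(gm, k = 100, folds = 5, seed = 42) {
  if (is.null(gm$labels)) stop("genotype matrix has no phenotype labels")
  if (anyNA(gm$calls)) stop("genotype matrix has missing calls; impute first")
  if (k > n_snps(gm)) stop("k exceeds the number of SNPs")
  fold_of <- stratified_folds(gm$labels, folds, seed)
  aucs <- numeric(folds)
  selected <- vector("list", folds)
  rf <- rf_learner()
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    fstat <- anova_f_stats(gm$calls[tr, , drop = FALSE], gm$labels[tr])
    top <- order(-fstat, seq_along(fstat))[seq_len(k)]
    selected[[f]] <- gm$variants$id[top]
    bl <- .fit_base(rf, gm$calls[tr, top, drop = FALSE], gm$labels[tr],
                    mix_seed(seed, f))
    pr <- .predict_base(bl, gm$calls[te, top, drop = FALSE])
    aucs[f] <- auc(gm$labels[te], pr)
  }
  list(auc = aucs, selected = selected)
}

#' Two-sided paired t test on fold-wise metrics
#'
#' Degenerate cases are handled rather than erroring the pipeline: if the
#' paired differences have zero variance, p is reported as 1.0 when the mean
#' difference is 0, otherwise the result is flagged degenerate with `p = NA`.
#'
#' @param a,b equal-length (>= 2) fold-wise metric vectors, paired by fold.
#' @return list with `t`, `p`, `mean_diff`, `degenerate`.
#' @export
paired_ttest <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 paired values")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1.0, mean_diff = 0, degenerate = TRUE))
    return(list(t = NA_real_, p = NA_real_, mean_diff = mean(d), degenerate = TRUE))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
  list(t = t, p = 2 * stats::pt(-abs(t), df = length(d) - 1),
       mean_diff = mean(d), degenerate = FALSE)
}

#' Pairwise linkage disequilibrium r-squared of two genotype vectors
#'
#' Squared Pearson correlation of unphased additive genotypes (composite
#' LD) over mutually non-missing samples. If fewer than 2 mutual samples
#' remain or either vector is constant on that subset, `NA` is returned
#' with a warning.
#'
#' @param g1,g2 additive genotype vectors ({0,1,2}, NA allowed).
#' @return r-squared in \[0, 1\], or NA.
#' @export
ld_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2) {
    warning("fewer than 2 mutually non-missing samples; r2 undefined")
    return(NA_real_)
  }
  if (stats::var(g1[ok]) == 0 || stats::var(g2[ok]) == 0) {
    warning("constant genotype vector; r2 undefined")
    return(NA_real_)
  }
  stats::cor(g1[ok], g2[ok])^2
}

#' LD proxies of a target SNP
#'
#' All other SNPs whose r-squared with the target reaches `threshold`
#' (default 0.2, the conventional moderate-LD cutoff).
#'
#' @param gm a [genotype_matrix()].
#' @param target_snp snp_id of the target variant.
#' @param threshold minimum r-squared (default 0.2).
#' @return object of class `ld_result`: `target`, named `r2` vector over all
#'   SNPs (target = 1), `proxies` data.frame (snp_id, r2), `threshold`.
#' @export
ld_proxies <- function(gm, target_snp, threshold = 0.2) {
  j <- match(target_snp, gm$variants$id)
  if (is.na(j)) stop("target SNP not in matrix: ", target_snp)
  r2 <- suppressWarnings(
    stats::cor(gm$calls, gm$calls[, j], use = "pairwise.complete.obs")[, 1]^2
  )
  names(r2) <- gm$variants$id
  r2[j] <- 1
  prox <- which(!is.na(r2) & r2 >= threshold)
  prox <- setdiff(prox, j)
  structure(
    list(target = target_snp, r2 = r2,
         proxies = data.frame(snp_id = gm$variants$id[prox],
                              r2 = unname(r2[prox]),
                              stringsAsFactors = FALSE)[
                                order(-r2[prox], gm$variants$id[prox]), ],
         threshold = threshold),
    class = "ld_result"
  )
}

#' Ablate a target SNP and its LD proxies from the top panel, then evaluate
#'
#' Removes the target and every proxy (r-squared >= `threshold`) from the
#' top `panel_size` ranked SNPs, optionally backfills from the next-ranked
#' SNPs to restore the panel size, and evaluates the ablated panel with
#' [evaluate_panel()].
#'
#' @param gm a [genotype_matrix()] with labels and no missing calls.
#' @param ranking a `combined_score_table` over the matrix's SNPs.
#' @param target_snp snp_id of the target variant.
#' @param threshold proxy r-squared threshold (default 0.2).
#' @param panel_size top-panel size (default 100).
#' @param backfill restore the panel to `panel_size` from the next ranks
#'   (default TRUE; FALSE evaluates the shortened panel).
#' @param folds,cfg,seed passed to [evaluate_panel()].
#' @return list with `panel_before`, `panel_after`, `removed`, `ld`, and
#'   `evaluation` (a `panel_evaluation`).
#' @export
ablate_and_evaluate <- function(gm, ranking, target_snp, threshold = 0.2,
                                panel_size = 100, backfill = TRUE, folds = 5,
                                cfg = default_stack_config(), seed = 42) {
  ld <- ld_proxies(gm, target_snp, threshold)
  excluded <- c(target_snp, ld$proxies$snp_id)
  before <- ranking$snp_id[seq_len(min(panel_size, nrow(ranking)))]
  after <- setdiff(before, excluded)
  if (backfill) {
    pool <- setdiff(ranking$snp_id, c(before, excluded))
    need <- panel_size - length(after)
    after <- c(after, utils::head(pool, need))
  }
  if (length(after) < panel_size)
    warning("ablated panel has only ", length(after), " SNPs")
  list(panel_before = before, panel_after = after,
       removed = intersect(before, excluded), ld = ld,
       evaluation = evaluate_panel(gm, after, folds = folds, cfg = cfg,
                                   seed = seed))
}

#' Transfer a SNP ranking to an external cohort
#'
#' Matches ranked SNPs into the external genotype matrix by
#' (chrom, pos, ref, alt), tolerating a ref/alt swap (logged via the `flip`
#' column); `position_only = TRUE` relaxes matching to (chrom, pos).
#' Unmatched SNPs are dropped and the surviving rows re-ranked, so panels
#' built from the result backfill naturally from the next matched ranks.
#'
#' @param ranking a `combined_score_table` carrying ref/alt columns.
#' @param gm_external the external cohort's [genotype_matrix()] (same genome
#'   build — caller asserts).
#' @param position_only match by position alone.
#' @return the matched ranking (re-ranked), with columns `external_id` and
#'   `flip`.
#' @export
transfer_rankings <- function(ranking, gm_external, position_only = FALSE) {
  ev <- gm_external$variants
  if (position_only) {
    ext_key <- paste(ev$chrom, ev$pos, sep = ":")
    hit <- match(paste(ranking$chrom, ranking$pos, sep = ":"), ext_key)
    flip <- rep(FALSE, nrow(ranking))
  } else {
    if (!all(c("ref", "alt") %in% names(ranking)))
      stop("ranking lacks ref/alt columns needed for allele-aware matching")
    ext_key <- paste(ev$chrom, ev$pos, ev$ref, ev$alt, sep = ":")
    hit <- match(paste(ranking$chrom, ranking$pos, ranking$ref, ranking$alt,
                       sep = ":"), ext_key)
    swap <- match(paste(ranking$chrom, ranking$pos, ranking$alt, ranking$ref,
                        sep = ":"), ext_key)
    flip <- is.na(hit) & !is.na(swap)
    hit[flip] <- swap[flip]
  }
  if (all(is.na(hit))) stop("no ranked SNP matches the external cohort")
  top100 <- utils::head(order(ranking$rank), 100)
  if (mean(!is.na(hit[top100])) < 0.5)
    warning("fewer than 50% of the top-100 SNPs matched the external cohort")
  out <- ranking[!is.na(hit), , drop = FALSE]
  out$external_id <- ev$id[hit[!is.na(hit)]]
  out$flip <- flip[!is.na(hit)]
  out$rank <- NULL
  rank_snps(out)
}

#' APOE epsilon-4 carrier count from a genotype-category summary
#'
#' Carriers are the individuals whose APOE genotype contains at least one
#' epsilon-4 allele: e2/e4 + e3/e4 + e4/e4.
#'
#' @param counts named vector/list of the six APOE genotype counts, names
#'   `e2/e2`, `e2/e3`, `e2/e4`, `e3/e3`, `e3/e4`, `e4/e4`.
#' @param cohort_size total cohort size (> 0, >= sum of counts).
#' @return list with `count` and `percent` (of `cohort_size`).
#' @export
epsilon4_carrier_count <- function(counts, cohort_size) {
  need <- c("e2/e2", "e2/e3", "e2/e4", "e3/e3", "e3/e4", "e4/e4")
  counts <- unlist(counts)
  miss <- setdiff(need, names(counts))
  if (length(miss)) stop("missing genotype categories: ", paste(miss, collapse = ", "))
  if (any(counts < 0)) stop("genotype counts must be >= 0")
  if (cohort_size <= 0) stop("cohort size must be positive")
  if (sum(counts[need]) > cohort_size)
    stop("genotype counts exceed the cohort size")
  cnt <- unname(counts["e2/e4"] + counts["e3/e4"] + counts["e4/e4"])
  list(count = cnt, percent = 100 * cnt / cohort_size)
}
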
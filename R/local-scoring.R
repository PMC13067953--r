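# Local scoring: nonoverlapping 100-SNP genomic windows, each scored by the
# holdout accuracy of a stacking ensemble trained on its member SNPs.

#' Partition SNPs into nonoverlapping fixed-size windows
#'
#' Windows are contiguous half-open index intervals `[start, end)` of length
#' `window_size` in genomic order. By default the trailing partial window is
#' dropped and counted (14,094 SNPs -> 140 windows of 100 with 94 dropped);
#' `keep_partial = TRUE` retains it as a short final window instead.
#'
#' @param n_snps number of SNPs (must be >= `window_size`).
#' @param window_size SNPs per window (default 100).
#' @param keep_partial keep the trailing partial window.
#' @return object of class `window_set`: data.frame `windows` (window, start,
#'   end, size), `window_size`, `n_dropped_tail`, `n_snps`.
#' @export
make_windows <- function(n_snps, window_size = 100, keep_partial = FALSE) {
  stopifnot(window_size >= 1)
  if (n_snps < window_size)
    stop("n_snps (", n_snps, ") is smaller than window_size (", window_size, ")")
  k <- n_snps %/% window_size
  start <- (seq_len(k) - 1) * window_size + 1
  end <- start + window_size
  tail_len <- n_snps - k * window_size
  if (keep_partial && tail_len > 0) {
    start <- c(start, k * window_size + 1)
    end <- c(end, n_snps + 1)
    tail_len <- 0L
  }
  structure(
    list(windows = data.frame(window = seq_along(start), start = start,
                              end = end, size = end - start),
         window_size = window_size, n_dropped_tail = tail_len,
         n_snps = n_snps),
    class = "window_set"
  )
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d windows of %d SNPs (%d trailing SNPs dropped)\n",
              nrow(x$windows), x$window_size, x$n_dropped_tail))
  invisible(x)
}

#' Score genomic windows with the stacking ensemble
#'
#' For each window, fits [fit_oof_stack()] on the window's SNP columns over
#' the training samples and records the ensemble's holdout accuracy; that
#' accuracy becomes the local score of every SNP in the window. SNPs in the
#' dropped tail get a missing local score. A window whose fit fails (e.g.
#' degenerate columns) receives the uninformative score 0.5 and is logged,
#' so one bad window does not abort the run.
#'
#' @param gm a [genotype_matrix()] with labels and no missing calls.
#' @param ws a [make_windows()] result for `n_snps(gm)`.
#' @param split list with sample-id (or index) vectors `train` and `holdout`,
#'   disjoint and stratified by the caller.
#' @param cfg base-learner pair (see [default_stack_config()]).
#' @param seed integer seed.
#' @return object of class `local_score_table`: data.frame `windows`
#'   (window, start, end, accuracy, failed) and `snp_scores` (named numeric,
#'   NA for dropped-tail SNPs).
#' @export
score_windows <- function(gm, ws, split, cfg = default_stack_config(),
                          seed = 42) {
  if (is.null(gm$labels)) stop("genotype matrix has no phenotype labels")
  if (ws$n_snps != n_snps(gm))
    stop("window set was built for ", ws$n_snps, " SNPs, matrix has ", n_snps(gm))
  tr <- resolve_ids(gm, split$train)
  ho <- resolve_ids(gm, split$holdout)
  if (length(intersect(tr, ho))) stop("train and holdout overlap")

  w <- ws$windows
  acc <- numeric(nrow(w))
  failed <- logical(nrow(w))
  for (i in seq_len(nrow(w))) {
    cols <- seq(w$start[i], w$end[i] - 1)
    # canonical within-window column order: scores do not depend on how the
    # caller permuted SNPs inside a window
    cols <- cols[order(gm$variants$pos[cols], gm$variants$id[cols])]
    res <- tryCatch({
      # one shared seed: every window sees the same OOF sample split, and
      # identical windows get identical scores
      m <- fit_oof_stack(gm$calls[tr, cols, drop = FALSE], gm$labels[tr],
                         cfg = cfg, seed = seed)
      holdout_score(m, gm$calls[ho, cols, drop = FALSE], gm$labels[ho])$accuracy
    }, error = function(e) {
      warning("window ", i, " failed (", conditionMessage(e),
              "); scored 0.5", call. = FALSE)
      NA_real_
    })
    failed[i] <- is.na(res)
    acc[i] <- if (is.na(res)) 0.5 else res
  }
  snp_scores <- rep(NA_real_, n_snps(gm))
  for (i in seq_len(nrow(w))) snp_scores[seq(w$start[i], w$end[i] - 1)] <- acc[i]
  names(snp_scores) <- gm$variants$id
  structure(
    list(windows = cbind(w, accuracy = acc, failed = failed),
         snp_scores = snp_scores),
    class = "local_score_table"
  )
}

# sample ids or integer indices -> integer indices
resolve_ids <- function(gm, ids) {
  if (is.character(ids)) {
    idx <- match(ids, rownames(gm$calls))
    if (anyNA(idx)) stop("unknown sample id(s) in split")
    idx
  } else as.integer(ids)
}
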
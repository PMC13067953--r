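# Shared internal helpers: seeded randomness, stratified resampling, misc.

#' Derive a child seed from a parent seed and an integer key
#'
#' All randomness in the package flows from user-supplied seeds through this
#' mixing function, so that independent stages (folds, learners, replicates)
#' get distinct but reproducible streams. Stays below 2^31 - 1.
#' @keywords internal
#' @noRd
mix_seed <- function(seed, key) {
  s <- (as.numeric(seed) %% 2147483563) + 1
  k <- (as.numeric(key) %% 2147483563) + 1
  as.integer((s * 48271 + k * 104729) %% 2147483563)
}

#' Evaluate code under a temporary RNG seed
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds, balancing the two phenotype
#' classes across folds (round-robin within a seeded shuffle of each class).
#'
#' @param y binary labels (0/1), length n.
#' @param k number of folds.
#' @param seed integer seed.
#' @return integer vector of fold ids in 1..k, one per sample.
#' @keywords internal
#' @noRd
stratified_folds <- function(y, k, seed) {
  stopifnot(k >= 2, length(y) >= k)
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified train/holdout split
#'
#' @param y binary labels.
#' @param train_frac fraction of each class assigned to the training part.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `holdout`.
#' @keywords internal
#' @noRd
stratified_split <- function(y, train_frac, seed) {
  stopifnot(train_frac > 0, train_frac < 1)
  train <- integer(0)
  with_seed(seed, {
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      n_tr <- max(1L, floor(train_frac * length(idx)))
      train <- c(train, idx[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  list(train = train, holdout = setdiff(seq_along(y), train))
}

# Sort order for values within an annotation family / variant ids:
# byte-wise (C locale) so results do not depend on the session locale.
lex_sort <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
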
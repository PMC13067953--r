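# k-nearest-neighbour genotype imputation.

#' Impute missing genotypes by k nearest neighbours
#'
#' Each missing call is replaced by the mean genotype of the `k` samples
#' nearest to its sample, among those with an observed call at that variant.
#' Distances are Euclidean over mutually non-missing variants, rescaled by
#' the fraction of coordinates observed (so sparsely overlapping pairs are
#' not artificially close). The imputed mean is rounded to the nearest of
#' {0, 1, 2}, with exact half-way ties rounded down, keeping genotypes
#' integral for downstream Hardy-Weinberg and LD computations. Non-missing
#' calls are never altered.
#'
#' If fewer than `k` samples have an observed call at a variant, the column
#' mean is used instead (logged as a warning). An all-missing column is an
#' error.
#'
#' @param gm a [genotype_matrix()].
#' @param k neighbour count (default 5).
#' @return a `genotype_matrix` with no missing calls.
#' @export
impute_knn <- function(gm, k = 5) {
  M <- gm$calls
  if (!anyNA(M)) return(gm)
  n <- nrow(M); p <- ncol(M)
  all_missing <- colSums(!is.na(M)) == 0
  if (any(all_missing))
    stop("variant(s) with no observed calls cannot be imputed: ",
         paste(gm$variants$id[all_missing], collapse = ", "))

  W <- !is.na(M)
  M0 <- M; M0[!W] <- 0
  S <- M0^2
  # squared distances restricted to mutually observed coordinates
  D2 <- S %*% t(W) + W %*% t(S) - 2 * (M0 %*% t(M0))
  n_mut <- W %*% t(W)
  D2 <- D2 * p / pmax(n_mut, 1)
  D2[n_mut == 0] <- Inf
  diag(D2) <- Inf

  round_half_down <- function(x) ceiling(x - 0.5)
  fallback <- character(0)
  out <- M
  for (j in which(colSums(!W) > 0)) {
    donors <- which(W[, j])
    for (i in which(!W[, j])) {
      d <- D2[i, donors]
      usable <- donors[is.finite(d)]
      d <- d[is.finite(d)]
      if (length(usable) < k) {
        out[i, j] <- as.integer(round_half_down(mean(M[donors, j])))
        fallback <- c(fallback, gm$variants$id[j])
      } else {
        nb <- usable[order(d, usable)[seq_len(k)]]
        out[i, j] <- as.integer(round_half_down(mean(M[nb, j])))
      }
    }
  }
  if (length(fallback))
    warning("fewer than k donors; column-mean fallback used for: ",
            paste(unique(fallback), collapse = ", "))
  out[out < 0] <- 0L
  out[out > 2] <- 2L
  gm$calls <- out
  gm
}
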
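# Shared fixtures and independent oracles used across test files.

# minimal genotype matrix from a calls matrix; variants on one chromosome
# at positions 10, 20, 30, ...
make_gm <- function(calls, labels = NULL, chrom = "chr1", gq = NULL, dp = NULL) {
  calls <- as.matrix(calls)
  p <- ncol(calls)
  variants <- data.frame(
    id = paste0("rs", seq_len(p)), chrom = chrom, pos = 10 * seq_len(p),
    ref = "A", alt = "G", stringsAsFactors = FALSE
  )
  if (is.null(rownames(calls))) rownames(calls) <- paste0("s", seq_len(nrow(calls)))
  genotype_matrix(calls, variants, gq = gq, dp = dp, labels = labels)
}

# random genotypes with labels independent of genotype (null data)
null_gm <- function(n, p, seed, freq = 0.3) {
  withr::with_seed(seed, {
    calls <- matrix(rbinom(n * p, 2, freq), n, p)
    make_gm(calls, labels = sample(rep_len(c(0, 1), n)))
  })
}

# write a small VCF text fixture; gts is a variants x samples character matrix
write_vcf_fixture <- function(path, chrom, pos, id, ref, alt, gts,
                              format = "GT") {
  n_smp <- ncol(gts)
  hdr <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype Quality">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("smp", seq_len(n_smp))), collapse = "\t")
  )
  rows <- vapply(seq_along(pos), function(i) {
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", format,
            gts[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  path
}

# --- independent oracles --------------------------------------------------

# exact HWE p-value by explicit enumeration of heterozygote counts, using
# unnormalized multinomial weights and renormalization (no closed-form
# normalizer shared with the implementation)
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_r <- 2 * min(n_AA, n_aa) + n_Aa
  if (n_r == 0) return(1.0)
  hets <- seq(n_r %% 2, min(n_r, 2 * n - n_r), by = 2)
  w <- vapply(hets, function(h) {
    hom_r <- (n_r - h) / 2
    hom_c <- n - h - hom_r
    exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) - lfactorial(hom_c) +
          h * log(2))
  }, numeric(1))
  pr <- w / sum(w)
  sum(pr[pr <= pr[match(n_Aa, hets)] * (1 + 1e-12)])
}

# AUC by explicit enumeration of all positive-negative pairs
auc_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force kNN imputation of a single missing cell (i, j)
knn_oracle_cell <- function(M, i, j, k) {
  p <- ncol(M)
  d <- sapply(seq_len(nrow(M)), function(r) {
    if (r == i) return(Inf)
    ok <- !is.na(M[i, ]) & !is.na(M[r, ])
    if (!any(ok)) return(Inf)
    sqrt(sum((M[i, ok] - M[r, ok])^2) * p / sum(ok))
  })
  donors <- which(!is.na(M[, j]) & is.finite(d))
  nb <- donors[order(d[donors], donors)][seq_len(k)]
  ceiling(mean(M[nb, j]) - 0.5)
}
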
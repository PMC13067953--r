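# Variant-level quality control: call rate, exact Hardy-Weinberg test,
# minor allele frequency, monomorphic/multiallelic exclusion.

#' Quality-control thresholds
#'
#' Defaults follow standard WGS case-control practice: variants with call
#' rate < 95%, missing rate > 20%, exact Hardy-Weinberg P < 1e-6 or minor
#' allele frequency < 1% are removed; calls with GQ < 20 or DP < 10 are
#' masked to missing.
#'
#' @param min_variant_call_rate minimum fraction of non-missing calls.
#' @param hwe_p_min minimum exact HWE p-value.
#' @param maf_min minimum minor allele frequency.
#' @param gq_min,dp_min per-call genotype quality / read depth lower bounds
#'   (calls strictly below are masked).
#' @param max_missing_rate maximum fraction of missing calls.
#' @param remove_monomorphic remove variants with zero minor allele
#'   frequency (`FALSE` disables the rule, e.g. when all other thresholds
#'   are also set to their permissive extremes).
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_variant_call_rate = 0.95, hwe_p_min = 1e-6,
                          maf_min = 0.01, gq_min = 20, dp_min = 10,
                          max_missing_rate = 0.20, remove_monomorphic = TRUE) {
  fr <- c(min_variant_call_rate = min_variant_call_rate,
          hwe_p_min = hwe_p_min, maf_min = maf_min,
          max_missing_rate = max_missing_rate)
  if (any(fr < 0 | fr > 1))
    stop("fractional thresholds must lie in [0, 1]")
  structure(list(min_variant_call_rate = min_variant_call_rate,
                 hwe_p_min = hwe_p_min, maf_min = maf_min,
                 gq_min = gq_min, dp_min = dp_min,
                 max_missing_rate = max_missing_rate,
                 remove_monomorphic = remove_monomorphic),
            class = "qc_thresholds")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test on biallelic genotype counts: conditional on the
#' observed allele counts, the probability of every attainable heterozygote
#' count is computed, and the p-value is the sum of probabilities no greater
#' than that of the observed configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote).
#' @return p-value in (0, 1]. Monomorphic counts give exactly 1.
#' @export
hwe_exact_pvalue <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("at least one genotype call required")
  n_r <- 2 * min(n_AA, n_aa) + n_Aa  # rare-allele count
  if (n_r == 0) return(1.0)          # monomorphic: single attainable config

  # heterozygote counts attainable with n_r rare alleles among n diploids
  hets <- seq(n_r %% 2, min(n_r, 2 * n - n_r), by = 2)
  # log P(het = h | n, n_r) up to the shared normalizer
  lp <- vapply(hets, function(h) {
    hom_r <- (n_r - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  p_obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= p_obs * (1 + 1e-12)]))
}

#' Minor allele frequency of an additive genotype vector
#'
#' `min(f, 1 - f)` where `f` is the alternate-allele frequency over
#' non-missing calls.
#'
#' @param calls genotypes in {0, 1, 2, NA}; at least one non-missing.
#' @return frequency in \[0, 0.5\].
#' @export
maf <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop("maf undefined: all calls missing")
  f <- sum(calls) / (2 * length(calls))
  min(f, 1 - f)
}

#' Variant-level quality control
#'
#' Removes variants failing any rule, applying the rules in a fixed order so
#' each removed variant is reported under exactly one reason:
#' `multiallelic`, then `low_call_rate` (call rate below
#' `min_variant_call_rate`), `excess_missing` (missing fraction above
#' `max_missing_rate`), `hwe` (exact test p below `hwe_p_min`), `maf` (minor
#' allele frequency below `maf_min`), and finally `monomorphic`.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `matrix` (the surviving `genotype_matrix`) and `report`
#'   (class `qc_report`: per-variant call_rate, maf, hwe_p, removal_reason,
#'   plus per-reason counts).
#' @export
variant_qc <- function(gm, thresholds = qc_thresholds()) {
  t <- thresholds
  p <- n_snps(gm)
  call_rate <- colMeans(!is.na(gm$calls))
  mafs <- rep(NA_real_, p)
  hwe_p <- rep(NA_real_, p)
  for (j in seq_len(p)) {
    g <- gm$calls[!is.na(gm$calls[, j]), j]
    if (length(g)) {
      mafs[j] <- min(sum(g), 2 * length(g) - sum(g)) / (2 * length(g))
      hwe_p[j] <- hwe_exact_pvalue(sum(g == 0), sum(g == 1), sum(g == 2))
    }
  }
  reason <- rep("none", p)
  mark <- function(cond, why) {
    hit <- reason == "none" & !is.na(cond) & cond
    reason[hit] <<- why
  }
  mark(gm$variants$multiallelic, "multiallelic")
  mark(call_rate < t$min_variant_call_rate, "low_call_rate")
  mark(1 - call_rate > t$max_missing_rate, "excess_missing")
  mark(hwe_p < t$hwe_p_min, "hwe")
  mark(mafs < t$maf_min, "maf")
  if (isTRUE(t$remove_monomorphic)) {
    mark(mafs == 0, "monomorphic")
    mark(call_rate == 0, "monomorphic")  # no informative calls at all
  }

  keep <- reason == "none"
  if (!any(keep))
    stop("variant QC removed every variant; review the thresholds")
  report <- structure(
    list(
      variants = data.frame(id = gm$variants$id, call_rate = call_rate,
                            maf = mafs, hwe_p = hwe_p, removal_reason = reason,
                            stringsAsFactors = FALSE),
      counts = table(factor(reason, levels = c("none", "multiallelic",
                                               "low_call_rate", "excess_missing",
                                               "hwe", "maf", "monomorphic"))),
      n_input = p, n_survivors = sum(keep), thresholds = t
    ),
    class = "qc_report"
  )
  list(matrix = subset_gm(gm, snps = which(keep)), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("variant QC: %d -> %d variants\n", x$n_input, x$n_survivors))
  removed <- x$counts[names(x$counts) != "none" & x$counts > 0]
  for (r in names(removed)) cat(sprintf("  removed %-14s %d\n", r, removed[[r]]))
  invisible(x)
}

#' Write a QC report as TSV
#' @param report a `qc_report` from [variant_qc()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
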
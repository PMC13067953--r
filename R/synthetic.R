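# Seeded synthetic case-control genotype data with LD-block structure,
# planted causal variants, causal-enriched annotations, and data artifacts
# (missing and low-quality calls) for exercising QC and imputation.

#' Simulation configuration
#'
#' Genotypes are generated from a latent-Gaussian threshold model: within
#' each LD block, samples draw a latent multivariate normal vector with
#' exchangeable correlation `within_block_rho`, and each coordinate is
#' thresholded at the Hardy-Weinberg quantiles of its (uniformly drawn)
#' allele frequency to give genotypes {0, 1, 2}. Blocks are independent, so
#' `within_block_rho` directly controls LD strength inside blocks and
#' marginal genotype frequencies are Hardy-Weinberg exact. The phenotype is
#' a logistic model on the planted causal genotypes; annotations enrich
#' causal SNPs with "informative" category values at rate
#' `annotation_enrichment`.
#'
#' @param n_samples,n_snps cohort dimensions.
#' @param block_size SNPs per LD block (default 50).
#' @param within_block_rho latent exchangeable correlation in \[0, 1)
#'   (default 0.7, moderate regional LD).
#' @param allele_freq_range alternate-allele frequency range (default
#'   0.05-0.5).
#' @param causal_snp_indices indices of the planted causal SNPs.
#' @param effect_sizes per-causal-SNP log-odds per alternate allele
#'   (recycled). Default: +0.5 for the first half of the causal set and
#'   -0.5 for the second half — causal SNPs are typically planted as
#'   genomically contiguous clusters, so each cluster carries a coherent
#'   signal while overall prevalence stays near 1/2. (Per-SNP sign
#'   alternation would make effects of LD-correlated neighbours cancel.)
#' @param intercept log-odds intercept (default 0).
#' @param annotation_enrichment probability that a causal SNP receives the
#'   informative value in each annotation family (default 0.9).
#' @param missing_rate,low_quality_rate per-call artifact rates.
#' @param chrom,pos_start,pos_step genomic coordinates of the simulated
#'   region (defaults emulate a dense ~100-kb regional panel on chr19).
#' @param seed master seed; all generator randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_samples, n_snps, block_size = 50,
                       within_block_rho = 0.7,
                       allele_freq_range = c(0.05, 0.5),
                       causal_snp_indices = integer(0),
                       effect_sizes = NULL, intercept = 0,
                       annotation_enrichment = 0.9,
                       missing_rate = 0, low_quality_rate = 0,
                       chrom = "chr19", pos_start = 44905791, pos_step = 7,
                       seed = 42) {
  if (within_block_rho < 0 || within_block_rho >= 1)
    stop("within_block_rho must lie in [0, 1)")
  probs <- c(annotation_enrichment, missing_rate, low_quality_rate)
  if (any(probs < 0 | probs > 1)) stop("rates must lie in [0, 1]")
  if (length(causal_snp_indices) > n_snps)
    stop("more causal SNPs than SNPs")
  if (length(causal_snp_indices) &&
      (min(causal_snp_indices) < 1 || max(causal_snp_indices) > n_snps))
    stop("causal_snp_indices out of range")
  if (is.null(effect_sizes) && length(causal_snp_indices)) {
    k <- length(causal_snp_indices)
    effect_sizes <- rep(0.5, k)
    if (k > 1) effect_sizes[seq(floor(k / 2) + 1, k)] <- -0.5
  }
  structure(
    list(n_samples = n_samples, n_snps = n_snps, block_size = block_size,
         within_block_rho = within_block_rho,
         allele_freq_range = allele_freq_range,
         causal_snp_indices = as.integer(causal_snp_indices),
         effect_sizes = effect_sizes %||% numeric(0), intercept = intercept,
         annotation_enrichment = annotation_enrichment,
         missing_rate = missing_rate, low_quality_rate = low_quality_rate,
         chrom = chrom, pos_start = pos_start, pos_step = pos_step,
         seed = seed),
    class = "sim_config"
  )
}

#' Simulate LD-block genotypes
#'
#' @param cfg a [sim_config()].
#' @return a [genotype_matrix()] (no labels yet; see
#'   [simulate_phenotype()]). Attribute `allele_freqs` records the target
#'   alternate-allele frequency of each SNP.
#' @export
simulate_genotypes <- function(cfg) {
  n <- cfg$n_samples; p <- cfg$n_snps
  rho <- cfg$within_block_rho
  with_seed(mix_seed(cfg$seed, 1), {
    freqs <- stats::runif(p, cfg$allele_freq_range[1], cfg$allele_freq_range[2])
    calls <- matrix(0L, n, p)
    starts <- seq(1, p, by = cfg$block_size)
    for (s in starts) {
      cols <- s:min(s + cfg$block_size - 1, p)
      shared <- stats::rnorm(n)
      z <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(n * length(cols)), n)
      # HWE thresholds for each SNP's alt frequency f:
      # P(0) = (1-f)^2, P(1) = 2f(1-f), P(2) = f^2
      for (ci in seq_along(cols)) {
        f <- freqs[cols[ci]]
        q0 <- stats::qnorm((1 - f)^2)
        q1 <- stats::qnorm((1 - f)^2 + 2 * f * (1 - f))
        calls[, cols[ci]] <- (z[, ci] >= q0) + (z[, ci] >= q1)
      }
    }
    bases <- c("A", "C", "G", "T")
    refs <- sample(bases, p, replace = TRUE)
    alts <- vapply(refs, function(r) sample(setdiff(bases, r), 1), "")
    variants <- data.frame(
      id = sprintf("snp%05d", seq_len(p)),
      chrom = cfg$chrom,
      pos = cfg$pos_start + (seq_len(p) - 1) * cfg$pos_step,
      ref = refs, alt = unname(alts), stringsAsFactors = FALSE
    )
    rownames(calls) <- sprintf("ind%04d", seq_len(n))
    gm <- genotype_matrix(calls, variants)
    attr(gm, "allele_freqs") <- freqs
    gm
  })
}

#' Simulate a binary phenotype from planted causal SNPs
#'
#' `P(case) = logistic(intercept + sum_j beta_j * g_j)` over the causal
#' SNPs; labels drawn independently per sample.
#'
#' @param gm a [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg the same [sim_config()].
#' @return named 0/1 label vector (1 = case).
#' @export
simulate_phenotype <- function(gm, cfg) {
  eta <- rep(cfg$intercept, n_samples(gm))
  if (length(cfg$causal_snp_indices)) {
    beta <- rep_len(cfg$effect_sizes, length(cfg$causal_snp_indices))
    G <- gm$calls[, cfg$causal_snp_indices, drop = FALSE]
    G[is.na(G)] <- 0
    eta <- eta + drop(G %*% beta)
  }
  with_seed(mix_seed(cfg$seed, 2), {
    stats::setNames(stats::rbinom(length(eta), 1, stats::plogis(eta)),
                    rownames(gm$calls))
  })
}

# background category frequencies per family; informative values (the ones
# causal SNPs are enriched for) listed first in each family
sim_annotation_background <- function() {
  list(
    genomic_context = c("exonic" = 0.08, "intronic" = 0.55, "UTR" = 0.07,
                        "region none" = 0.25, "unknown" = 0.05),
    gene_biotype = c("protein coding" = 0.45, "long noncoding RNA" = 0.20,
                     "TEC" = 0.05, "transcribed unprocessed pseudogene" = 0.05,
                     "unknown" = 0.25),
    most_severe_consequence = c(
      "missense variant" = 0.02, "intron variant" = 0.50,
      "intergenic variant" = 0.15, "regulatory region variant" = 0.08,
      "3 prime UTR variant" = 0.05, "5 prime UTR variant" = 0.03,
      "synonymous variant" = 0.05, "splice region variant" = 0.02,
      "splice polypyrimidine tract variant" = 0.02,
      "splice donor region variant" = 0.01,
      "TF binding site variant" = 0.01, "stop gained" = 0.005,
      "unknown" = 0.055),
    clinical_significance = c(
      "pathogenic" = 0.005, "likely pathogenic" = 0.003,
      "uncertain significance" = 0.08, "drug response" = 0.002,
      "risk factor" = 0.02, "association" = 0.01, "other" = 0.03,
      "protective" = 0.0005, "established risk allele" = 0.0005,
      "unknown" = 0.849)
  )
}

#' Simulate per-SNP annotations with causal enrichment
#'
#' Non-causal SNPs draw category values from realistic background
#' frequencies; causal SNPs receive the informative value of each family
#' (exonic / protein coding / missense variant / pathogenic) with
#' probability `annotation_enrichment`, otherwise a background draw.
#'
#' @param cfg a [sim_config()].
#' @param snp_ids optional ids (default the generator's id scheme).
#' @return an `annotation_table`.
#' @export
simulate_annotations <- function(cfg, snp_ids = NULL) {
  p <- cfg$n_snps
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%05d", seq_len(p))
  bg <- sim_annotation_background()
  informative <- vapply(bg, function(x) names(x)[1], "")
  causal <- logical(p)
  causal[cfg$causal_snp_indices] <- TRUE
  with_seed(mix_seed(cfg$seed, 3), {
    df <- data.frame(snp_id = snp_ids, stringsAsFactors = FALSE)
    for (f in annotation_families()) {
      v <- sample(names(bg[[f]]), p, replace = TRUE, prob = bg[[f]])
      enrich <- causal & stats::runif(p) < cfg$annotation_enrichment
      v[enrich] <- informative[[f]]
      df[[f]] <- v
    }
    as_annotation_table(df)
  })
}

#' Inject missingness and low-quality calls into a genotype matrix
#'
#' Attaches per-call GQ and DP matrices (baseline draws of high-quality
#' values), then sets a `missing_rate` fraction of calls to missing and
#' degrades a `low_quality_rate` fraction to GQ < 20 or DP < 10 (half
#' each), so that [mask_low_quality()] and [impute_knn()] have realistic
#' work to do.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [sim_config()] (fields `missing_rate`, `low_quality_rate`,
#'   `seed`).
#' @return the modified `genotype_matrix`.
#' @export
inject_artifacts <- function(gm, cfg) {
  n <- n_samples(gm); p <- n_snps(gm)
  with_seed(mix_seed(cfg$seed, 4), {
    gq <- matrix(sample(40:99, n * p, replace = TRUE), n, p)
    dp <- matrix(sample(20:60, n * p, replace = TRUE), n, p)
    if (cfg$low_quality_rate > 0) {
      lq <- which(stats::runif(n * p) < cfg$low_quality_rate)
      half <- seq_along(lq) %% 2 == 0
      gq[lq[half]] <- sample(0:19, sum(half), replace = TRUE)
      dp[lq[!half]] <- sample(0:9, sum(!half), replace = TRUE)
    }
    if (cfg$missing_rate > 0) {
      miss <- stats::runif(n * p) < cfg$missing_rate
      gm$calls[miss] <- NA
    }
    dimnames(gq) <- dimnames(gm$calls)
    dimnames(dp) <- dimnames(gm$calls)
    gm$gq <- gq
    gm$dp <- dp
  })
  gm
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Emits `genotypes.vcf` (with GQ/DP), `genotypes.tsv`, `labels.tsv` and
#' `annotations.tsv` into `dir`; [read_vcf()] / [load_annotations()]
#' round-trip to equal objects.
#'
#' @param gm a [genotype_matrix()] with labels.
#' @param annotations an `annotation_table`.
#' @param dir output directory (created if needed).
#' @return named list of file paths, invisibly.
#' @export
write_fixture <- function(gm, annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    genotypes = file.path(dir, "genotypes.tsv"),
    labels = file.path(dir, "labels.tsv"),
    annotations = file.path(dir, "annotations.tsv")
  )
  write_vcf(gm, paths$vcf)
  write_genotype_tsv(gm, paths$genotypes)
  if (!is.null(gm$labels)) write_labels_tsv(gm$labels, paths$labels)
  utils::write.table(as.data.frame(annotations), paths$annotations,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Simulate a complete planted-signal cohort
#'
#' Convenience wrapper: genotypes + phenotype + annotations (+ artifacts
#' when the config requests them) in one call.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (labelled [genotype_matrix()]) and `annotations`.
#' @export
simulate_cohort <- function(cfg) {
  gm <- simulate_genotypes(cfg)
  gm$labels <- simulate_phenotype(gm, cfg)
  if (cfg$missing_rate > 0 || cfg$low_quality_rate > 0)
    gm <- inject_artifacts(gm, cfg)
  list(gm = gm, annotations = simulate_annotations(cfg, gm$variants$id))
}
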
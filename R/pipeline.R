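# Run configuration, validation, and the end-to-end pipeline with a
# reproducible run manifest.

#' Build a run configuration
#'
#' Bundles paths and every tunable of the pipeline. Defaults follow the
#' method's standard operating point: 100-SNP windows, alpha grid 0.0-1.0 in
#' steps of 0.1, 5 outer / 5 inner folds, panels of 100/500/1000, seed 42,
#' and the QC thresholds of [qc_thresholds()].
#'
#' @param genotypes path to a VCF or genotype TSV.
#' @param labels path to a labels TSV (sample_id, label); optional for VCFs
#'   if labels are embedded downstream.
#' @param annotations path to the annotation TSV.
#' @param outdir output directory.
#' @param qc a [qc_thresholds()] object.
#' @param window_size,alpha_grid,outer_folds,inner_folds,top_k,panel_sizes,seed
#'   pipeline tunables (see [run_nested_cv()]). `alpha_grid` may be a numeric
#'   vector or a `"start:stop:step"` string.
#' @param knn_k neighbour count for imputation.
#' @param min_group_size minimum annotation-group size.
#' @param keep_partial_window keep the trailing short window.
#' @param learners base-learner pair.
#' @param region optional `list(chrom=, start=, end=)` to extract first.
#' @return a `run_config` list.
#' @export
run_config <- function(genotypes = NULL, labels = NULL, annotations = NULL,
                       outdir = "dualnet_out", qc = qc_thresholds(),
                       window_size = 100, alpha_grid = seq(0, 1, by = 0.1),
                       outer_folds = 5, inner_folds = 5, top_k = 100,
                       panel_sizes = c(100, 500, 1000), knn_k = 5,
                       min_group_size = 10, keep_partial_window = FALSE,
                       learners = default_stack_config(), region = NULL,
                       seed = 42) {
  validate_config(list(
    genotypes = genotypes, labels = labels, annotations = annotations,
    outdir = outdir, qc = qc, window_size = window_size,
    alpha_grid = alpha_grid, outer_folds = outer_folds,
    inner_folds = inner_folds, top_k = top_k, panel_sizes = panel_sizes,
    knn_k = knn_k, min_group_size = min_group_size,
    keep_partial_window = keep_partial_window, learners = learners,
    region = region, seed = seed
  ))
}

#' Parse an alpha-grid specification
#'
#' Accepts a numeric vector or a `"start:stop:step"` string; endpoints are
#' included within a 1e-9 floating tolerance.
#'
#' @param spec grid specification.
#' @return sorted numeric vector of alpha values in \[0, 1\].
#' @export
parse_alpha_grid <- function(spec) {
  if (is.character(spec)) {
    parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
    if (length(parts) != 3 || anyNA(parts) || parts[3] <= 0)
      stop("alpha grid spec must be \"start:stop:step\": ", spec)
    n_steps <- floor((parts[2] - parts[1]) / parts[3] + 1e-9)
    spec <- parts[1] + (0:n_steps) * parts[3]
  }
  spec <- sort(unique(round(as.numeric(spec), 12)))
  if (!length(spec) || any(spec < 0 | spec > 1))
    stop("alpha values must lie in [0, 1]")
  spec
}

#' Validate and normalize a run configuration
#'
#' Fills defaults, parses the alpha grid, coerces learner entries given as
#' plain lists (config files) via [base_learner_config()], and reports every
#' violated range in a single error.
#'
#' @param config a named list, or a path to a YAML/JSON config file.
#' @return a normalized `run_config` object.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- list(
    genotypes = NULL, labels = NULL, annotations = NULL,
    outdir = "dualnet_out", qc = qc_thresholds(), window_size = 100,
    alpha_grid = seq(0, 1, by = 0.1), outer_folds = 5, inner_folds = 5,
    top_k = 100, panel_sizes = c(100, 500, 1000), knn_k = 5,
    min_group_size = 10, keep_partial_window = FALSE,
    learners = default_stack_config(), region = NULL, seed = 42
  )
  cfg <- utils::modifyList(defaults, config[!vapply(config, is.null, TRUE)])
  if (is.list(cfg$qc) && !inherits(cfg$qc, "qc_thresholds"))
    cfg$qc <- do.call(qc_thresholds, cfg$qc)
  cfg$alpha_grid <- parse_alpha_grid(cfg$alpha_grid)
  cfg$learners <- lapply(cfg$learners, function(l) {
    if (inherits(l, "base_learner_config")) l
    else do.call(base_learner_config, l)
  })
  problems <- character(0)
  chk <- function(cond, msg) if (!cond) problems <<- c(problems, msg)
  chk(cfg$window_size >= 1, "window_size must be positive")
  chk(cfg$outer_folds >= 2, "outer_folds must be >= 2")
  chk(cfg$inner_folds >= 2, "inner_folds must be >= 2")
  chk(all(cfg$panel_sizes >= 1), "panel sizes must be positive")
  chk(cfg$top_k >= 1, "top_k must be positive")
  chk(cfg$knn_k >= 1, "knn_k must be positive")
  chk(cfg$min_group_size >= 1, "min_group_size must be positive")
  chk(length(cfg$learners) == 2, "exactly two base learners required")
  if (length(problems))
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  structure(cfg, class = "run_config")
}

#' Run the full pipeline from files to ranked outputs
#'
#' Executes: read genotypes (VCF or TSV) -> optional region extraction ->
#' low-quality call masking -> variant QC -> kNN imputation -> nested-CV
#' prioritization (windows, annotation groups, alpha search, ranking,
#' panels, panel evaluation) -> baselines -> output files. A JSON manifest
#' records the seed, package version, input digests, per-fold alphas and
#' every output path, so any artifact is reproducible from manifest + seed.
#'
#' @param config a `run_config` (or anything [validate_config()] accepts).
#' @return the manifest list, invisibly; outputs are written to
#'   `config$outdir` (ranking.tsv, panel files, qc_report.tsv,
#'   metrics.json, manifest.json).
#' @export
run_full <- function(config) {
  cfg <- validate_config(config)
  for (p in c("genotypes", "annotations")) {
    if (is.null(cfg[[p]])) stop("config lacks required path: ", p)
    if (!file.exists(cfg[[p]])) stop(p, " file not found: ", cfg[[p]])
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  is_vcf <- grepl("\\.vcf(\\.gz)?$", cfg$genotypes)
  gm <- if (is_vcf) read_vcf(cfg$genotypes) else read_genotype_tsv(cfg$genotypes)
  if (!is.null(cfg$labels)) {
    lab <- read_labels_tsv(cfg$labels)
    gm$labels <- stats::setNames(as.integer(lab[rownames(gm$calls)]),
                                 rownames(gm$calls))
  }
  if (is.null(gm$labels) || anyNA(gm$labels))
    stop("phenotype labels missing for some samples")
  annotations <- load_annotations(cfg$annotations)
  if (!is.null(cfg$region))
    gm <- extract_region(gm, cfg$region$chrom, cfg$region$start, cfg$region$end)

  if (!is.null(gm$gq)) gm <- mask_low_quality(gm, cfg$qc)
  qc <- variant_qc(gm, cfg$qc)
  gm <- impute_knn(qc$matrix, k = cfg$knn_k)

  res <- run_nested_cv(
    gm, annotations, outer_folds = cfg$outer_folds,
    inner_folds = cfg$inner_folds, window_size = cfg$window_size,
    keep_partial = cfg$keep_partial_window, alpha_grid = cfg$alpha_grid,
    top_k = cfg$top_k, panel_sizes = cfg$panel_sizes,
    min_group_size = cfg$min_group_size, cfg = cfg$learners, seed = cfg$seed
  )
  base_lr <- baseline_logreg_all_snps(gm, folds = cfg$outer_folds, seed = cfg$seed)
  base_rf <- baseline_anova_rf(gm, k = min(cfg$top_k, n_snps(gm)),
                               folds = cfg$outer_folds, seed = cfg$seed)

  out <- function(f) file.path(cfg$outdir, f)
  write_qc_report(qc$report, out("qc_report.tsv"))
  write_ranking_tsv(res$final_ranking, out("ranking.tsv"))
  panel_files <- list()
  for (pid in names(build_panels(res$final_ranking, cfg$panel_sizes))) {
    pf <- out(paste0("panel_", pid, ".txt"))
    writeLines(build_panels(res$final_ranking, cfg$panel_sizes)[[pid]], pf)
    panel_files[[pid]] <- pf
  }
  dualnet_auc <- res$panel_evaluations[[paste0("top_", max(cfg$panel_sizes))]]$auc
  metrics <- list(
    alphas = res$alphas,
    panels = lapply(res$panel_evaluations, function(pe)
      list(auc = pe$auc, auc_mean = pe$auc_ci$mean,
           auc_ci = c(pe$auc_ci$lower, pe$auc_ci$upper),
           accuracy = pe$accuracy, accuracy_mean = pe$accuracy_ci$mean)),
    baseline_logreg_auc = base_lr$auc,
    baseline_anova_rf_auc = base_rf$auc,
    dualnet_vs_logreg = paired_ttest(dualnet_auc, base_lr$auc),
    dualnet_vs_anova_rf = paired_ttest(dualnet_auc, base_rf$auc)
  )
  jsonlite::write_json(metrics, out("metrics.json"), auto_unbox = TRUE,
                       digits = NA)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dualnet")),
    seed = cfg$seed,
    alphas = res$alphas,
    inputs = list(
      genotypes = unname(tools::md5sum(cfg$genotypes)),
      labels = if (!is.null(cfg$labels)) unname(tools::md5sum(cfg$labels)),
      annotations = unname(tools::md5sum(cfg$annotations))
    ),
    config = list(
      window_size = cfg$window_size, alpha_grid = cfg$alpha_grid,
      outer_folds = cfg$outer_folds, inner_folds = cfg$inner_folds,
      top_k = cfg$top_k, panel_sizes = cfg$panel_sizes, knn_k = cfg$knn_k,
      min_group_size = cfg$min_group_size,
      learners = vapply(cfg$learners, `[[`, "", "kind")
    ),
    n_samples = n_samples(gm), n_snps_post_qc = n_snps(gm),
    outputs = c(list(qc_report = out("qc_report.tsv"),
                     ranking = out("ranking.tsv"),
                     metrics = out("metrics.json")), panel_files)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(c(manifest, list(result = res)))
}
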
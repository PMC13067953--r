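# Panel evaluation, baselines, LD utilities, transfer, cohort arithmetic.

test_that("evaluate_panel scores a separable SNP perfectly and reproduces", {
  withr::with_seed(110, {
    y <- sample(0:1, 120, replace = TRUE)
    calls <- matrix(rbinom(120 * 6, 2, 0.3), 120, 6)
    calls[, 2] <- 2 * y
    gm <- make_gm(calls, labels = y)
  })
  pe <- evaluate_panel(gm, "rs2", seed = 4)
  expect_equal(pe$auc_ci$mean, 1.0)
  pe2 <- evaluate_panel(gm, "rs2", seed = 4)
  expect_identical(pe$auc, pe2$auc)
  expect_error(evaluate_panel(gm, "rs_nothere"), "empty")
})

test_that("baseline logistic regression: separability, leakage-free scaling", {
  withr::with_seed(111, {
    y <- sample(0:1, 100, replace = TRUE)
    calls <- matrix(rbinom(100 * 5, 2, 0.3), 100, 5)
    calls[, 1] <- 2 * y
    gm <- make_gm(calls, labels = y)
  })
  res <- baseline_logreg_all_snps(gm, seed = 2)
  expect_equal(mean(res$auc), 1.0)
  # constant features are dropped (warned once per affected fold)
  gm$calls[, 3] <- 1
  ws <- testthat::capture_warnings(res2 <- baseline_logreg_all_snps(gm, seed = 2))
  expect_match(ws, "constant", all = TRUE)
  expect_equal(res2$dropped_constant, rep(1L, 5))
  # altering a test-fold sample leaves that fold's training predictions
  # untouched (standardization and fit use the training portion only)
  gm3 <- gm
  fold1_test <- which(dualnet:::stratified_folds(gm$labels, 5, 2) == 1)
  gm3$calls[fold1_test[1], 2] <- 2 - gm3$calls[fold1_test[1], 2]
  r3 <- suppressWarnings(baseline_logreg_all_snps(gm3, seed = 2))
  r2 <- suppressWarnings(baseline_logreg_all_snps(gm, seed = 2))
  expect_equal(r3$auc[-1], r2$auc[-1])
})

test_that("ANOVA-F selection is per-fold and finds planted effects", {
  withr::with_seed(112, {
    y <- sample(0:1, 150, replace = TRUE)
    calls <- matrix(rbinom(150 * 30, 2, 0.3), 150, 30)
    calls[, 5] <- pmin(2, calls[, 5] + y)  # strong planted effect
    gm <- make_gm(calls, labels = y)
  })
  res <- baseline_anova_rf(gm, k = 3, seed = 6)
  expect_true(all(vapply(res$selected, function(s) "rs5" %in% s, TRUE)))
  expect_length(res$auc, 5)
  # F statistic is 0 for a feature with identical class means
  yy <- rep(0:1, 30)
  f <- dualnet:::anova_f_stats(cbind(same_mean = rep(c(0, 2, 2, 0), 15)), yy)
  expect_equal(unname(f), 0)
  expect_error(baseline_anova_rf(gm, k = 100), "exceeds")
})

test_that("null-label baselines sit near chance", {
  la <- ra <- numeric(3)
  for (i in 1:3) {
    gm <- null_gm(200, 60, seed = 300 + i)
    la[i] <- mean(baseline_logreg_all_snps(gm, seed = i)$auc)
    ra[i] <- mean(baseline_anova_rf(gm, k = 20, seed = i)$auc)
  }
  expect_gt(mean(la), 0.40); expect_lt(mean(la), 0.60)
  expect_gt(mean(ra), 0.40); expect_lt(mean(ra), 0.60)
})

test_that("ld_r2 matches direct Pearson computation and is symmetric", {
  g1 <- c(0, 1, 2, 0, 1, 2)
  g2 <- c(0, 1, 1, 0, 2, 2)
  expect_equal(ld_r2(g1, g2), cor(g1, g2)^2)
  expect_equal(ld_r2(g1, g1), 1.0)
  expect_equal(ld_r2(g1, 2 - g1), 1.0)  # allele flip
  expect_equal(ld_r2(g1, g2), ld_r2(g2, g1))
  # mutual non-missing restriction
  g3 <- c(0, 1, 2, NA, 1, 2); g4 <- c(NA, 1, 1, 0, 2, 2)
  ok <- !is.na(g3) & !is.na(g4)
  expect_equal(ld_r2(g3, g4), cor(g3[ok], g4[ok])^2)
  expect_warning(r <- ld_r2(g1, rep(1, 6)), "constant")
  expect_true(is.na(r))
})

test_that("ld_proxies finds duplicates, excludes independents, boundary at 1.0", {
  withr::with_seed(120, {
    calls <- matrix(rbinom(400 * 5, 2, 0.4), 400, 5)
    calls[, 2] <- calls[, 1]                       # exact duplicate
    flip_few <- sample(400, 60)
    calls[, 3] <- calls[, 1]
    calls[flip_few, 3] <- rbinom(60, 2, 0.4)       # strong but imperfect LD
    gm <- make_gm(calls)
  })
  res <- ld_proxies(gm, "rs1", threshold = 0.2)
  expect_equal(unname(res$r2["rs1"]), 1)
  expect_true(all(c("rs2", "rs3") %in% res$proxies$snp_id))
  expect_false("rs4" %in% res$proxies$snp_id)      # independent SNP
  # threshold 1.0 keeps only exact correlates
  hard <- ld_proxies(gm, "rs1", threshold = 1.0)
  expect_equal(hard$proxies$snp_id, "rs2")
  expect_error(ld_proxies(gm, "rs99"), "not in matrix")
})

test_that("ablation removes the target and proxies and backfills", {
  withr::with_seed(121, {
    y <- sample(0:1, 150, replace = TRUE)
    calls <- matrix(rbinom(150 * 30, 2, 0.3), 150, 30)
    calls[, 1] <- pmin(2, calls[, 1] + y)   # dominant causal SNP
    calls[, 2] <- calls[, 1]                # its proxy
    gm <- make_gm(calls, labels = y)
    s <- runif(30, 0.4, 0.6); s[1:2] <- c(0.99, 0.98)
  })
  ranking <- combined_score_table(s, s, 1, gm$variants)
  ab <- ablate_and_evaluate(gm, ranking, "rs1", panel_size = 10, seed = 5)
  expect_setequal(ab$removed, c("rs1", "rs2"))
  expect_length(ab$panel_after, 10)                 # backfilled
  expect_false(any(c("rs1", "rs2") %in% ab$panel_after))
  expect_equal(ab$panel_after[9:10],
               setdiff(ranking$snp_id, c(ab$panel_before, "rs2"))[1:2])
  # no target in panel, no proxies -> panel unchanged
  lone <- combined_score_table(seq(0.1, 0.9, length.out = 30),
                               rep(0.5, 30), 1, gm$variants)
  top10 <- lone$snp_id[1:10]
  stopifnot(!"rs1" %in% top10, !"rs2" %in% top10)
  ab2 <- ablate_and_evaluate(gm, lone, "rs1", panel_size = 10, seed = 5)
  expect_equal(ab2$panel_after, top10)
})

test_that("rankings transfer by position with allele-swap tolerance", {
  gm <- null_gm(10, 8, seed = 122)
  withr::with_seed(123, s <- runif(8))
  ranking <- combined_score_table(s, s, 1, gm$variants)
  # external = copy -> identity matching
  tr <- transfer_rankings(ranking, gm)
  expect_equal(tr$snp_id, ranking$snp_id)
  expect_false(any(tr$flip))

  # drop one variant, swap ref/alt of another
  ext <- subset_gm(gm, snps = setdiff(1:8, 3))
  swap_at <- which(ext$variants$id == "rs5")
  ext$variants$ref[swap_at] <- gm$variants$alt[5]
  ext$variants$alt[swap_at] <- gm$variants$ref[5]
  tr2 <- transfer_rankings(ranking, ext)
  expect_equal(nrow(tr2), 7)
  expect_false("rs3" %in% tr2$snp_id)
  expect_true(tr2$flip[tr2$snp_id == "rs5"])
  expect_equal(tr2$rank, 1:7)  # re-ranked, panels backfill naturally

  # position-only matching tolerates allele changes
  ext2 <- ext
  ext2$variants$ref <- "T"; ext2$variants$alt <- "C"
  tr3 <- transfer_rankings(ranking, ext2, position_only = TRUE)
  expect_equal(nrow(tr3), 7)
  # zero overlap errors
  far <- ext
  far$variants$pos <- far$variants$pos + 10000
  expect_error(transfer_rankings(ranking, far), "no ranked SNP")
})

test_that("epsilon4 carrier arithmetic matches the genotype-category sums", {
  counts <- c("e2/e2" = 2, "e2/e3" = 57, "e2/e4" = 7, "e3/e3" = 257,
              "e3/e4" = 110, "e4/e4" = 10)
  res <- epsilon4_carrier_count(counts, 443)
  expect_equal(res$count, 127)
  expect_equal(round(res$percent, 1), 28.7)
  zero <- epsilon4_carrier_count(
    c("e2/e2" = 5, "e2/e3" = 5, "e2/e4" = 0, "e3/e3" = 5, "e3/e4" = 0,
      "e4/e4" = 0), 15)
  expect_equal(zero$count, 0)
  expect_error(epsilon4_carrier_count(counts, 0), "positive")
  expect_error(epsilon4_carrier_count(counts[-1], 443), "missing genotype")
  expect_error(epsilon4_carrier_count(counts, 100), "exceed")
})
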
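# Annotation-group scoring and per-SNP global score assignment.

make_groups <- function(gm, assignment) {
  # assignment: list(label = member indices); builds bare group objects
  tbl <- data.frame(
    snp_id = variant_ids(gm), genomic_context = "intronic",
    gene_biotype = "unknown", most_severe_consequence = "intron variant",
    clinical_significance = "unknown", stringsAsFactors = FALSE
  )
  for (lbl in names(assignment)) tbl$gene_biotype[assignment[[lbl]]] <- lbl
  suppressWarnings(build_groups(as_annotation_table(tbl), gm, min_size = 1))
}

test_that("a separable group scores 1.0 and scoring is deterministic", {
  withr::with_seed(70, {
    y <- sample(0:1, 150, replace = TRUE)
    calls <- matrix(rbinom(150 * 12, 2, 0.3), 150, 12)
    calls[, 3] <- 2 * y
    gm <- make_gm(calls, labels = y)
  })
  groups <- make_groups(gm, list("protein coding" = 1:6, "TEC" = 7:12))
  split <- list(train = 1:110, holdout = 111:150)
  acc <- score_annotation_groups(gm, groups, split, seed = 4)
  expect_equal(acc$accuracy[acc$label == "gene_biotype=protein coding"], 1.0)
  acc2 <- score_annotation_groups(gm, groups, split, seed = 4)
  expect_identical(acc$accuracy, acc2$accuracy)
})

test_that("group accuracy is invariant to member-order permutation", {
  gm <- null_gm(100, 10, seed = 71)
  split <- list(train = 1:75, holdout = 76:100)
  g1 <- make_groups(gm, list("protein coding" = 1:6))
  a1 <- score_annotation_groups(gm, g1, split, seed = 3)
  g2 <- g1
  g2[["gene_biotype=protein coding"]]$members <- rev(6:1)
  a2 <- score_annotation_groups(gm, g2, split, seed = 3)
  expect_equal(
    a1$accuracy[a1$label == "gene_biotype=protein coding"],
    a2$accuracy[a2$label == "gene_biotype=protein coding"])
})

test_that("global scores average group accuracies and bound by min/max", {
  gm <- null_gm(10, 6, seed = 72)
  # overlapping groups come from different families: biotype covers SNPs 1-4,
  # clinical significance covers SNPs 3-6
  tbl <- data.frame(
    snp_id = variant_ids(gm), genomic_context = "intronic",
    gene_biotype = c(rep("protein coding", 4), "unknown", "unknown"),
    most_severe_consequence = "intron variant",
    clinical_significance = c("unknown", "unknown", rep("pathogenic", 4)),
    stringsAsFactors = FALSE
  )
  groups <- suppressWarnings(build_groups(as_annotation_table(tbl), gm,
                                          min_size = 1))
  # accuracies at the published magnitudes serve as inputs here
  acc <- data.frame(
    label = c("gene_biotype=protein coding", "clinical_significance=pathogenic"),
    family = c("gene_biotype", "clinical_significance"), size = c(4, 4),
    accuracy = c(0.630, 0.695), stringsAsFactors = FALSE
  )
  gt <- assign_global_scores(acc, groups, n_snps(gm), variant_ids(gm))
  expect_equal(unname(gt$snp_scores[1]), 0.630)    # one group
  expect_equal(unname(gt$snp_scores[3]), 0.6625)   # mean of 0.630, 0.695
  expect_equal(unname(gt$snp_scores[6]), 0.695)
  expect_false(any(gt$fallback[1:6]))
  for (j in 1:6) {
    accs_j <- acc$accuracy[c(j %in% 1:4, j %in% 3:6)]
    expect_gte(gt$snp_scores[j], min(accs_j))
    expect_lte(gt$snp_scores[j], max(accs_j))
  }
})

test_that("ungrouped SNPs get the overall-mean fallback, flagged", {
  gm <- null_gm(10, 5, seed = 73)
  groups <- make_groups(gm, list("protein coding" = 1:3))
  acc <- data.frame(label = "gene_biotype=protein coding",
                    family = "gene_biotype", size = 3, accuracy = 0.61,
                    stringsAsFactors = FALSE)
  # drop the complement groups so SNPs 4-5 are uncovered
  groups <- groups["gene_biotype=protein coding"]
  gt <- assign_global_scores(acc, groups, n_snps(gm), variant_ids(gm))
  expect_equal(unname(gt$snp_scores[4]), 0.61)
  expect_true(all(gt$fallback[4:5]))
  expect_error(assign_global_scores(acc[0, ], groups, 5), "empty")
})

test_that("adding a group at a SNP's current score leaves the score unchanged", {
  gm <- null_gm(10, 6, seed = 74)
  g1 <- make_groups(gm, list("protein coding" = 1:3))["gene_biotype=protein coding"]
  acc1 <- data.frame(label = "gene_biotype=protein coding",
                     family = "gene_biotype", size = 3, accuracy = 0.7,
                     stringsAsFactors = FALSE)
  before <- assign_global_scores(acc1, g1, 6)$snp_scores[2]
  g2 <- c(g1, make_groups(gm, list("TEC" = 1:4))["gene_biotype=TEC"])
  acc2 <- rbind(acc1, data.frame(label = "gene_biotype=TEC",
                                 family = "gene_biotype", size = 4,
                                 accuracy = before, stringsAsFactors = FALSE))
  after <- assign_global_scores(acc2, g2, 6)$snp_scores[2]
  expect_equal(after, before)
})

test_that("null-label groups score near chance", {
  accs <- numeric(6)
  k <- 0
  for (i in 1:3) {
    gm <- null_gm(200, 16, seed = 80 + i)
    groups <- make_groups(gm, list("protein coding" = 1:8, "TEC" = 9:16))
    split <- list(train = 1:150, holdout = 151:200)
    a <- score_annotation_groups(gm, groups, split, seed = i)
    accs[k + seq_len(nrow(a))] <- a$accuracy
    k <- k + nrow(a)
  }
  expect_gt(mean(accs), 0.40); expect_lt(mean(accs), 0.60)
})
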
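# The OOF stacking ensemble and its metric utilities.

test_that("auc matches pairwise Mann-Whitney enumeration and handles ties", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1.0)
  expect_equal(auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0.0)
  # one win, one loss-free tie among the 4 pos-neg pairs -> 2.5/4
  expect_equal(auc(c(1, 0, 1, 0), c(0.6, 0.6, 0.4, 0.2)), 0.625)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)  # all tied -> midrank 0.5
  withr::with_seed(8, {
    for (i in 1:15) {
      n <- sample(10:50, 1)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
      expect_equal(auc(y, s), auc_oracle(y, s))
    }
  })
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "one class")
})

test_that("auc is invariant under strictly monotone score transforms", {
  withr::with_seed(12, {
    y <- sample(0:1, 40, replace = TRUE)
    y[1:2] <- 0:1
    s <- runif(40)
    a <- auc(y, s)
    expect_equal(auc(y, exp(3 * s)), a)
    expect_equal(auc(y, rank(s)), a)
  })
})

test_that("ci95 is the normal approximation over folds", {
  ci <- ci95(c(0.6, 0.7))
  expect_equal(ci$mean, 0.65)
  expect_equal(ci$upper - ci$mean, 1.96 * sd(c(0.6, 0.7)) / sqrt(2))
  expect_equal(ci$mean - ci$lower, ci$upper - ci$mean)  # symmetric
  cc <- ci95(rep(0.8, 5))
  expect_equal(c(cc$lower, cc$upper), c(0.8, 0.8))  # zero width
  expect_error(ci95(0.5), "at least 2")
})

test_that("a separable feature yields perfect holdout performance", {
  withr::with_seed(1, {
    y <- sample(0:1, 200, replace = TRUE)
    X <- cbind(sep = 2 * y, noise = matrix(runif(200 * 3), 200))
    rownames(X) <- paste0("s", 1:200)
  })
  m <- fit_oof_stack(X[1:150, ], y[1:150], seed = 3)
  hs <- holdout_score(m, X[151:200, ], y[151:200])
  expect_equal(hs$accuracy, 1.0)
  expect_equal(hs$auc, 1.0)
})

test_that("OOF bookkeeping fills each sample exactly once and stacks reproduce", {
  gm <- null_gm(60, 8, seed = 31)
  m <- fit_oof_stack(gm$calls, gm$labels, seed = 5)
  expect_equal(dim(m$oof_probs), c(60, 2))
  expect_false(anyNA(m$oof_probs))
  expect_setequal(m$train_ids, rownames(gm$calls))
  # every fold appears and each sample has one fold
  expect_equal(sort(unique(m$fold)), 1:5)
  # bit-reproducible with the same seed
  m2 <- fit_oof_stack(gm$calls, gm$labels, seed = 5)
  expect_identical(m$oof_probs, m2$oof_probs)
  expect_identical(predict(m, gm$calls), predict(m2, gm$calls))
})

test_that("degenerate and invalid stacking inputs error clearly", {
  gm <- null_gm(20, 4, seed = 7)
  expect_error(fit_oof_stack(gm$calls, rep(1, 20)), "both classes")
  expect_error(fit_oof_stack(gm$calls[, 0], gm$labels), "no features")
  bad <- gm$calls; bad[1, 1] <- NA
  expect_error(fit_oof_stack(bad, gm$labels), "missing")
})

test_that("holdout_score detects train/holdout leakage via sample ids", {
  gm <- null_gm(50, 5, seed = 13)
  m <- fit_oof_stack(gm$calls[1:40, ], gm$labels[1:40], seed = 1)
  expect_error(holdout_score(m, gm$calls[35:50, ], gm$labels[35:50]),
               "leakage")
  expect_s3_class(holdout_score(m, gm$calls[41:50, ], gm$labels[41:50]),
                  "holdout_score")
})

test_that("null labels give chance-level holdout performance", {
  aucs <- accs <- numeric(10)
  for (i in 1:10) {
    withr::with_seed(100 + i, {
      n <- 300
      X <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
                  dimnames = list(paste0("s", 1:n), NULL))
      y <- sample(rep_len(0:1, n))
    })
    tr <- 1:240; ho <- 241:300
    m <- fit_oof_stack(X[tr, ], y[tr], seed = i)
    hs <- holdout_score(m, X[ho, ], y[ho])
    aucs[i] <- hs$auc; accs[i] <- hs$accuracy
  }
  expect_gt(mean(aucs), 0.40); expect_lt(mean(aucs), 0.60)
  expect_gt(mean(accs), 0.40); expect_lt(mean(accs), 0.60)
})

test_that("base learner configs validate and the neural slot is pluggable", {
  expect_equal(rf_learner()$n_estimators, 100)
  expect_equal(rf_learner()$random_state, 42)
  expect_error(base_learner_config("boosted_stumps"), "unknown")
  expect_warning(cfg <- base_learner_config("attentive_tabular_net", n_d = 8,
                                            max_epochs = 10, patience = 5),
                 "mlp_learner")
  expect_equal(cfg$kind, "mlp")
  expect_equal(cfg$hidden, 8)
  expect_error(
    suppressWarnings(base_learner_config("attentive_tabular_net",
                                         max_epochs = 5, patience = 9)),
    "patience")
  # an mlp-backed stack runs end to end
  gm <- null_gm(40, 5, seed = 77)
  m <- fit_oof_stack(gm$calls, gm$labels,
                     cfg = list(rf_learner(), mlp_learner(hidden = 2)),
                     seed = 2)
  expect_length(predict(m, gm$calls), 40)
})

test_that("paired_ttest matches the closed-form computation and handles degeneracy", {
  a <- c(0.70, 0.68, 0.72, 0.69, 0.71)
  b <- c(0.65, 0.66, 0.64, 0.67, 0.66)
  res <- paired_ttest(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_false(res$degenerate)

  same <- paired_ttest(a, a)
  expect_equal(same$p, 1.0)
  expect_true(same$degenerate)

  shift <- paired_ttest(a, a + 0.1)
  expect_true(shift$degenerate)
  expect_true(is.na(shift$p))
})
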
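# Out-of-fold (OOF) stacking ensemble: two base classifiers whose
# cross-validated probabilities feed a logistic metamodel, plus the metric
# utilities (AUC, fold-wise 95% CI) used throughout the package.

#' Base-learner configurations
#'
#' The stacking ensemble combines two base classifiers behind a common
#' contract (fit + probability prediction). Three learners are built in:
#'
#' * `rf_learner()`: random forest via \pkg{ranger}; `n_estimators` trees,
#'   `max_features = "sqrt"` (mtry = floor(sqrt(p))), seeded by
#'   `random_state`, single-threaded for reproducibility.
#' * `logistic_learner()`: logistic regression fitted by IRLS
#'   ([stats::glm.fit()]); aliased coefficients are treated as zero. The
#'   default partner of the random forest.
#' * `mlp_learner()`: single-hidden-layer feed-forward network via
#'   \pkg{nnet}, with `hidden` units, weight decay and an iteration cap; the
#'   neural option for the second slot.
#'
#' `base_learner_config()` builds any of these from a `kind` string and is
#' what config-file parsing uses. A `kind` of `"attentive_tabular_net"` is
#' accepted for config compatibility and mapped, with a warning, to
#' `mlp_learner(hidden = n_d)`.
#'
#' @param n_estimators number of trees.
#' @param max_features only `"sqrt"` is supported (mtry = floor(sqrt(p))).
#' @param random_state,seed learner-level seed, mixed with the fit-level seed.
#' @param hidden hidden-layer size.
#' @param decay L2 weight decay.
#' @param max_iter optimizer iteration cap.
#' @param kind one of `"random_forest"`, `"logistic"`, `"mlp"`.
#' @param ... fields passed through to the kind's constructor.
#' @return an object of class `base_learner_config`.
#' @export
rf_learner <- function(n_estimators = 100, max_features = "sqrt",
                       random_state = 42) {
  stopifnot(n_estimators > 0)
  structure(list(kind = "random_forest", n_estimators = n_estimators,
                 max_features = max_features, random_state = random_state),
            class = "base_learner_config")
}

#' @rdname rf_learner
#' @export
logistic_learner <- function(seed = 42) {
  structure(list(kind = "logistic", seed = seed),
            class = "base_learner_config")
}

#' @rdname rf_learner
#' @export
mlp_learner <- function(hidden = 8, decay = 0.1, max_iter = 100, seed = 42) {
  stopifnot(hidden > 0, max_iter > 0)
  structure(list(kind = "mlp", hidden = hidden, decay = decay,
                 max_iter = max_iter, seed = seed),
            class = "base_learner_config")
}

#' @rdname rf_learner
#' @export
base_learner_config <- function(kind, ...) {
  args <- list(...)
  switch(
    kind,
    random_forest = do.call(rf_learner, args[intersect(names(args),
      c("n_estimators", "max_features", "random_state"))]),
    logistic = do.call(logistic_learner, args[intersect(names(args), "seed")]),
    mlp = do.call(mlp_learner, args[intersect(names(args),
      c("hidden", "decay", "max_iter", "seed"))]),
    attentive_tabular_net = {
      if (!is.null(args$patience) && !is.null(args$max_epochs) &&
          args$patience > args$max_epochs)
        stop("patience must not exceed max_epochs")
      warning("attentive_tabular_net is not available; ",
              "using mlp_learner(hidden = n_d) in its slot")
      mlp_learner(hidden = args$n_d %||% 8, seed = args$seed %||% 42)
    },
    stop("unknown base learner kind: ", kind)
  )
}

#' Default base-learner pair for the stacking ensemble
#' @return list of two `base_learner_config` objects (random forest +
#'   logistic regression).
#' @export
default_stack_config <- function() list(rf_learner(), logistic_learner())

# --- base-learner contract ------------------------------------------------

.fit_base <- function(cfg, X, y, seed) {
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  fit <- switch(
    cfg$kind,
    random_forest = {
      mtry <- max(1L, floor(sqrt(ncol(X))))
      ranger::ranger(
        x = X, y = factor(y, levels = c(0, 1)),
        num.trees = cfg$n_estimators, mtry = mtry, probability = TRUE,
        seed = mix_seed(cfg$random_state, seed), num.threads = 1
      )
    },
    logistic = {
      if (ncol(X) >= 2) {
        # lightly ridge-penalized (lambda = 1/n): well-defined for p > n and
        # under separation, fast on wide annotation groups
        list(net = glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                  lambda = 1 / nrow(X), standardize = FALSE))
      } else {
        g <- tryCatch(
          suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                          family = stats::binomial())),
          error = function(e) NULL
        )
        coef <- if (is.null(g))
          c(stats::qlogis(max(min(mean(y), 1 - 1e-6), 1e-6)), rep(0, ncol(X)))
        else g$coefficients
        coef[is.na(coef)] <- 0
        list(coef = coef)
      }
    },
    mlp = {
      with_seed(mix_seed(cfg$seed, seed), {
        nnet::nnet(x = X, y = y, size = cfg$hidden, decay = cfg$decay,
                   maxit = cfg$max_iter, entropy = TRUE, trace = FALSE)
      })
    },
    stop("unknown base learner kind: ", cfg$kind)
  )
  structure(list(cfg = cfg, fit = fit, features = colnames(X)),
            class = "base_learner_fit")
}

.predict_base <- function(bl, X) {
  if (is.null(colnames(X))) colnames(X) <- bl$features
  switch(
    bl$cfg$kind,
    random_forest = {
      pr <- stats::predict(bl$fit, data = X, num.threads = 1)$predictions
      unname(pr[, "1"])
    },
    logistic = {
      if (!is.null(bl$fit$net))
        unname(stats::predict(bl$fit$net, X, type = "response")[, 1])
      else
        unname(stats::plogis(drop(cbind(1, X) %*% bl$fit$coef)))
    },
    mlp = unname(drop(stats::predict(bl$fit, X)))
  )
}

# --- OOF stacking ---------------------------------------------------------

#' Fit an out-of-fold stacking ensemble
#'
#' Splits the training samples into `n_folds` stratified folds; for each
#' fold, both base learners are trained on the remaining folds and predict
#' the held-out fold, so every sample receives exactly one out-of-fold (OOF)
#' probability per base learner. A logistic metamodel is then fitted on the
#' assembled OOF probability pairs — it never sees a base model's in-sample
#' fit. Finally (unless `refit = FALSE`) both base learners are refitted on
#' the full training set for downstream holdout prediction.
#'
#' @param X numeric matrix (samples x features) with row names = sample ids;
#'   no missing values.
#' @param y binary labels (0/1), both classes present.
#' @param cfg list of two [base_learner_config][rf_learner] objects.
#' @param n_folds folds for the OOF split (default 5).
#' @param seed integer seed for the stratified split and the learner fits.
#' @param refit refit base learners on all of (X, y) after OOF assembly.
#' @return an object of class `stacked_model`: refit base learners,
#'   metamodel, `oof_probs` (n x 2), fold assignment, recorded training
#'   sample ids.
#' @export
fit_oof_stack <- function(X, y, cfg = default_stack_config(), n_folds = 5,
                          seed = 42, refit = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (ncol(X) == 0) stop("no features to fit on")
  if (anyNA(X)) stop("X contains missing values; impute first")
  if (length(unique(y)) < 2) stop("both classes must be present in y")
  if (nrow(X) < n_folds) stop("need at least n_folds samples")
  if (length(cfg) != 2) stop("cfg must list exactly two base learners")
  if (is.null(rownames(X))) rownames(X) <- paste0("s", seq_len(nrow(X)))

  fold <- stratified_folds(y, n_folds, seed)
  oof <- matrix(NA_real_, nrow(X), 2,
                dimnames = list(rownames(X),
                                vapply(cfg, `[[`, "", "kind")))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    for (l in 1:2) {
      bl <- .fit_base(cfg[[l]], X[tr, , drop = FALSE], y[tr],
                      mix_seed(seed, f * 2 + l))
      oof[!tr, l] <- .predict_base(bl, X[!tr, , drop = FALSE])
    }
  }
  meta_df <- data.frame(p1 = oof[, 1], p2 = oof[, 2], y = y)
  meta <- suppressWarnings(
    stats::glm(y ~ p1 + p2, data = meta_df, family = stats::binomial())
  )
  learners <- if (refit) {
    lapply(1:2, function(l) .fit_base(cfg[[l]], X, y, mix_seed(seed, l)))
  }
  structure(
    list(learners = learners, meta = meta, oof_probs = oof, fold = fold,
         y = y, cfg = cfg, seed = seed, n_folds = n_folds,
         train_ids = rownames(X)),
    class = "stacked_model"
  )
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("stacked_model: %s + %s -> logistic metamodel (%d samples, %d folds)\n",
              x$cfg[[1]]$kind, x$cfg[[2]]$kind, length(x$y), x$n_folds))
  invisible(x)
}

#' Predict case probabilities from a stacked model
#' @param object a `stacked_model` fitted with `refit = TRUE`.
#' @param newdata numeric feature matrix with the training columns.
#' @param ... unused.
#' @return vector of metamodel probabilities.
#' @export
predict.stacked_model <- function(object, newdata, ...) {
  if (is.null(object$learners))
    stop("model was fitted with refit = FALSE; no full-data base learners")
  newdata <- as.matrix(newdata)
  p1 <- .predict_base(object$learners[[1]], newdata)
  p2 <- .predict_base(object$learners[[2]], newdata)
  unname(stats::predict(object$meta, data.frame(p1 = p1, p2 = p2),
                        type = "response"))
}

#' Evaluate a stacked model on a holdout set
#'
#' Asserts, via the sample ids recorded at fit time, that no holdout sample
#' took part in training (leakage guard), then scores the metamodel
#' probabilities: accuracy at the 0.5 threshold and rank-based AUC.
#'
#' @param model a `stacked_model`.
#' @param X_holdout feature matrix with row names = sample ids, disjoint from
#'   the training ids.
#' @param y_holdout binary labels.
#' @return object of class `holdout_score` with fields `accuracy` and `auc`.
#' @export
holdout_score <- function(model, X_holdout, y_holdout) {
  X_holdout <- as.matrix(X_holdout)
  ids <- rownames(X_holdout)
  if (!is.null(ids)) {
    overlap <- intersect(ids, model$train_ids)
    if (length(overlap))
      stop("leakage: holdout sample(s) were used in training: ",
           paste(utils::head(overlap, 3), collapse = ", "))
  }
  probs <- predict(model, X_holdout)
  y_holdout <- as.integer(y_holdout)
  structure(
    list(accuracy = mean((probs > 0.5) == (y_holdout == 1)),
         auc = auc(y_holdout, probs), probs = probs),
    class = "holdout_score"
  )
}

# Cross-validated accuracy of the stack measured entirely out-of-fold:
# for each OOF fold, the metamodel is refitted on the other folds' OOF
# probability rows and predicts this fold, so no sample's own data enters
# either modelling level of its prediction. Used by the inner-loop alpha
# search.
oof_cv_accuracy <- function(model) {
  acc <- vapply(seq_len(model$n_folds), function(f) {
    tr <- model$fold != f
    df <- data.frame(p1 = model$oof_probs[, 1], p2 = model$oof_probs[, 2],
                     y = model$y)
    m <- suppressWarnings(stats::glm(y ~ p1 + p2, data = df[tr, ],
                                     family = stats::binomial()))
    pr <- stats::predict(m, df[!tr, ], type = "response")
    mean((pr > 0.5) == (model$y[!tr] == 1))
  }, numeric(1))
  mean(acc)
}

# --- metrics --------------------------------------------------------------

#' Area under the ROC curve (rank statistic)
#'
#' Mann-Whitney U normalized by `n_pos * n_neg`, with midrank handling of
#' tied scores; invariant under strictly monotone score transforms.
#'
#' @param y binary labels (both classes present).
#' @param s numeric scores (higher = more case-like).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(y, s) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: only one class present")
  r <- rank(s)  # midranks for ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Normal-approximation 95% confidence interval across folds
#'
#' `mean +/- 1.96 * sd / sqrt(k)` with the k-1 sample standard deviation.
#'
#' @param values per-fold metric values (length >= 2).
#' @return list with `mean`, `lower`, `upper`.
#' @export
ci95 <- function(values) {
  if (length(values) < 2) stop("need at least 2 fold values for a CI")
  m <- mean(values)
  half <- 1.96 * stats::sd(values) / sqrt(length(values))
  list(mean = m, lower = m - half, upper = m + half)
}
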
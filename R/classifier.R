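MODEL_NAMES <- c("logistic", "svm_rbf", "random_forest",
                 "gradient_boosted_trees", "adaptive_boosting")

#' Area under the ROC curve
#'
#' Trapezoidal area under the receiver operating characteristic curve of a
#' continuous score against binary labels, with tied scores handled by the
#' midrank convention. Equivalent to the Mann-Whitney U statistic divided
#' by n1*n0: the probability that a random positive outscores a random
#' negative (ties counting one half).
#'
#' @param scores Numeric decision values or probabilities (higher = more
#'   positive).
#' @param labels Binary labels: logical, 0/1, or a 2-level factor whose
#'   second level is positive.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary01(labels)
  if (length(scores) != length(y))
    stop("scores and labels must have equal length", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  f <- droplevels(as.factor(labels))
  if (nlevels(f) > 2L) stop("labels must be binary", call. = FALSE)
  # convention: "incompetent" (the detection target) is positive when named
  if ("incompetent" %in% levels(f)) return(as.integer(f == "incompetent"))
  as.integer(f == levels(f)[nlevels(f)])
}

#' Surgeon-grouped, approximately stratified k folds
#'
#' All videos of one surgeon share a fold (no same-surgeon leakage between
#' training and test); folds are balanced greedily on positive-class count
#' and size. Deterministic given the seed.
#'
#' @param surgeon_ids Character vector, one per video.
#' @param labels Binary labels, one per video.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer fold assignment in `1..k`, one per video.
#' @export
grouped_stratified_folds <- function(surgeon_ids, labels, k = 5L,
                                     seed = 1L) {
  y <- as_binary01(labels)
  surgeons <- unique(surgeon_ids)
  if (length(surgeons) < k)
    stop("need at least k = ", k, " surgeons for k folds", call. = FALSE)
  per <- data.frame(
    surgeon = surgeons,
    n = as.integer(table(surgeon_ids)[surgeons]),
    pos = vapply(surgeons, function(s) sum(y[surgeon_ids == s]),
                 integer(1)))
  per <- with_seed(seed, per[sample(nrow(per)), , drop = FALSE])
  per <- per[order(-per$n, -per$pos), , drop = FALSE]
  fold_n <- integer(k); fold_pos <- integer(k); fold_neg <- integer(k)
  fold_of <- stats::setNames(integer(length(surgeons)), per$surgeon)
  for (i in seq_len(nrow(per))) {
    # balance each class count across folds, then fold size; index order
    # breaks remaining ties deterministically
    pos_i <- per$pos[i]; neg_i <- per$n[i] - per$pos[i]
    j <- order(fold_pos * pos_i + fold_neg * neg_i, fold_n)[1L]
    fold_of[per$surgeon[i]] <- j
    fold_n[j] <- fold_n[j] + per$n[i]
    fold_pos[j] <- fold_pos[j] + pos_i
    fold_neg[j] <- fold_neg[j] + neg_i
  }
  unname(fold_of[surgeon_ids])
}

standardize_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl < 1e-12] <- 1  # constant columns pass through centered
  list(center = ctr, scale = scl)
}

standardize_apply <- function(X, std) {
  scale(X, center = std$center, scale = std$scale)
}

#' Fit one skill-classification model
#'
#' The five model families, with fixed documented hyperparameters:
#' `logistic` (ridge-penalized logistic regression, C = 1), `svm_rbf`
#' (RBF-kernel SVM, cost 1, gamma 1/p on standardized features),
#' `random_forest` (500 trees), `gradient_boosted_trees` (100 trees, depth
#' 3, learning rate 0.1), and `adaptive_boosting` (discrete AdaBoost/SAMME
#' with 100 depth-1 stumps). Feature standardization is fit on the
#' training data supplied here and stored with the model, so no statistics
#' leak from later test data.
#'
#' @param model One of `r paste0('"', MODEL_NAMES, '"', collapse = ", ")`.
#' @param X Numeric feature matrix (rows = videos).
#' @param labels Binary labels (positive = incompetent).
#' @param seed Integer seed for the stochastic fitters.
#' @return A `surgesture_model` with a [predict_scores()] method.
#' @export
fit_skill_model <- function(model = MODEL_NAMES, X, labels, seed = 1L) {
  model <- match.arg(model)
  X <- as.matrix(X)
  y <- as_binary01(labels)
  if (length(unique(y)) < 2L)
    stop("training labels must contain both classes", call. = FALSE)
  std <- standardize_fit(X)
  Z <- standardize_apply(X, std)
  fit <- with_seed(seed, switch(model,
    logistic = glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                              lambda = 1 / nrow(Z), standardize = FALSE),
    svm_rbf = e1071::svm(Z, factor(y, levels = c(0, 1)),
                         kernel = "radial", cost = 1, gamma = 1 / ncol(Z),
                         scale = FALSE),
    random_forest = randomForest::randomForest(
      Z, factor(y, levels = c(0, 1)), ntree = 500L),
    gradient_boosted_trees = xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3L,
                    eta = 0.1, nthread = 1L),
      data = xgboost::xgb.DMatrix(Z, label = y, nthread = 1L),
      nrounds = 100L, verbose = 0),
    adaptive_boosting = fit_adaboost(Z, y, n_stumps = 100L)
  ))
  structure(list(model_name = model, fit = fit, std = std,
                 feature_names = colnames(X)),
            class = "surgesture_model")
}

#' Continuous decision scores of a fitted model
#'
#' Probabilities or margins (never hard labels), oriented so that larger
#' values indicate the positive (incompetent) class.
#'
#' @param object A `surgesture_model`.
#' @param X Feature matrix with the training columns.
#' @return Numeric score per row.
#' @export
predict_scores <- function(object, X) {
  stopifnot(inherits(object, "surgesture_model"))
  Z <- standardize_apply(as.matrix(X)[, object$feature_names, drop = FALSE],
                         object$std)
  fit <- object$fit
  switch(object$model_name,
    logistic = as.numeric(stats::predict(fit, newx = Z,
                                         type = "response")),
    svm_rbf = {
      pr <- stats::predict(fit, Z, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # column name "a/b": positive values favor class a
      if (startsWith(colnames(dv)[1L], "1")) as.numeric(dv[, 1L])
      else -as.numeric(dv[, 1L])
    },
    random_forest = as.numeric(stats::predict(fit, Z,
                                              type = "prob")[, "1"]),
    gradient_boosted_trees = as.numeric(stats::predict(
      fit, xgboost::xgb.DMatrix(Z, nthread = 1L))),
    adaptive_boosting = predict_adaboost(fit, Z))
}

# ---- discrete AdaBoost (SAMME) over depth-1 rpart stumps ------------------

fit_adaboost <- function(Z, y, n_stumps = 100L) {
  n <- nrow(Z)
  df <- as.data.frame(Z)
  names(df) <- paste0("f", seq_len(ncol(Z)))
  df$.y <- factor(y, levels = c(0, 1))
  w <- rep(1 / n, n)
  stumps <- list(); alphas <- numeric()
  ctl <- rpart::rpart.control(maxdepth = 1L, cp = -1, minsplit = 2L,
                              xval = 0L, maxcompete = 0L,
                              maxsurrogate = 0L)
  fml <- .y ~ .
  environment(fml) <- environment()  # rpart resolves `w` here
  for (m in seq_len(n_stumps)) {
    stump <- rpart::rpart(fml, data = df, weights = w,
                          method = "class", control = ctl)
    pred <- stats::predict(stump, df, type = "class")
    miss <- pred != df$.y
    err <- sum(w[miss])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1L]] <- stump
    alphas <- c(alphas, alpha)
    if (sum(miss) == 0L) break
    w <- w * exp(2 * alpha * miss)
    w <- w / sum(w)
  }
  list(stumps = stumps, alphas = alphas, p = ncol(Z))
}

predict_adaboost <- function(fit, Z) {
  df <- as.data.frame(Z)
  names(df) <- paste0("f", seq_len(ncol(Z)))
  if (length(fit$stumps) == 0L) return(rep(0, nrow(Z)))
  score <- rep(0, nrow(Z))
  for (m in seq_along(fit$stumps)) {
    h <- as.integer(as.character(
      stats::predict(fit$stumps[[m]], df, type = "class")))
    score <- score + fit$alphas[m] * (2 * h - 1)
  }
  score
}

# ---- cross-validation -----------------------------------------------------

#' Cross-validated skill classification
#'
#' Five-fold (by default), surgeon-grouped cross-validation of the five
#' classical model families over one or more binary targets (overall
#' competence and the four mGOALS items). Per fold, feature
#' standardization is fit on the training rows only; optional
#' class-balancing timeline augmentation is likewise applied to training
#' folds only. Fold AUCs use the self-contained [roc_auc()]; both the
#' fold-mean and the pooled-prediction AUC are reported.
#'
#' @param features Numeric feature matrix or data.frame (feature columns
#'   only), one row per video.
#' @param targets Named list of binary label vectors, one per target.
#' @param surgeon_ids Character vector, one per video.
#' @param k Folds (default 5).
#' @param seed Integer seed (folds, model fits, augmentation).
#' @param models Subset of the five model names (default all).
#' @param cases Optional list of `surgesture_case` aligned with rows;
#'   required when `augment` is given.
#' @param augment Optional `augment_params`: balance classes inside each
#'   training fold by timeline augmentation before fitting.
#' @param taxonomy Taxonomy used to extract features of augmented cases.
#' @return A `classification_report`: list with `folds` (per model x
#'   target x fold AUC), `summary` (mean AUC and fold count), `pooled`
#'   (pooled-prediction AUC), `k`, `seed`.
#' @export
run_cv <- function(features, targets, surgeon_ids, k = 5L, seed = 1L,
                   models = MODEL_NAMES, cases = NULL, augment = NULL,
                   taxonomy = default_taxonomy()) {
  X <- as.matrix(as.data.frame(features))
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  if (!is.list(targets) || is.null(names(targets)))
    stop("targets must be a named list of label vectors", call. = FALSE)
  if (!is.null(augment) && is.null(cases))
    stop("training-fold augmentation needs the raw `cases` timelines",
         call. = FALSE)
  models <- match.arg(models, MODEL_NAMES, several.ok = TRUE)
  fold_rows <- list(); pooled_rows <- list(); notes <- character()
  for (tg in names(targets)) {
    y <- as_binary01(targets[[tg]])
    if (length(y) != nrow(X))
      stop("target '", tg, "' length does not match feature rows",
           call. = FALSE)
    folds <- grouped_stratified_folds(surgeon_ids, y, k = k, seed = seed)
    pooled <- stats::setNames(
      rep(list(list(scores = numeric(), y = integer())), length(models)),
      models)
    for (f in seq_len(k)) {
      tr <- folds != f; te <- !tr
      y_tr <- y[tr]; y_te <- y[te]
      if (length(unique(y_te)) < 2L || length(unique(y_tr)) < 2L) {
        notes <- c(notes, sprintf(
          "target %s fold %d skipped: single-class fold", tg, f))
        next
      }
      X_tr <- X[tr, , drop = FALSE]
      if (!is.null(augment)) {
        bal <- balance_classes(cases[tr], y_tr, local_params(augment, f),
                               taxonomy)
        n_new <- length(bal$cases) - sum(tr)
        if (n_new > 0L) {
          X_aug <- as.matrix(extract_feature_matrix(
            bal$cases[(sum(tr) + 1L):length(bal$cases)], taxonomy,
            quiet = TRUE)[, colnames(X), drop = FALSE])
          X_tr <- rbind(X_tr, X_aug)
          y_tr <- as_binary01(bal$labels)
        }
      }
      for (mdl in models) {
        fitted <- fit_skill_model(mdl, X_tr, y_tr,
                                  seed = seed + 1000L * f)
        sc <- predict_scores(fitted, X[te, , drop = FALSE])
        fold_rows[[length(fold_rows) + 1L]] <- data.frame(
          model = mdl, target = tg, fold = f, n_test = sum(te),
          auc = roc_auc(sc, y_te), stringsAsFactors = FALSE)
        pooled[[mdl]]$scores <- c(pooled[[mdl]]$scores, sc)
        pooled[[mdl]]$y <- c(pooled[[mdl]]$y, y_te)
      }
    }
    for (mdl in models) {
      if (length(pooled[[mdl]]$y) > 0L)
        pooled_rows[[length(pooled_rows) + 1L]] <- data.frame(
          model = mdl, target = tg,
          pooled_auc = roc_auc(pooled[[mdl]]$scores, pooled[[mdl]]$y),
          stringsAsFactors = FALSE)
    }
  }
  folds_df <- do.call(rbind, fold_rows)
  summary_df <- stats::aggregate(auc ~ model + target, data = folds_df,
                                 FUN = mean)
  names(summary_df)[names(summary_df) == "auc"] <- "mean_auc"
  nf <- stats::aggregate(fold ~ model + target, data = folds_df,
                         FUN = length)
  names(nf)[names(nf) == "fold"] <- "n_folds"
  summary_df <- merge(summary_df, nf, by = c("model", "target"))
  structure(list(folds = folds_df, summary = summary_df,
                 pooled = do.call(rbind, pooled_rows),
                 k = k, seed = seed, notes = notes),
            class = "classification_report")
}

local_params <- function(params, fold) {
  params$seed <- as.integer((params$seed + 104729L * fold) %%
                              .Machine$integer.max)
  params
}

#' @export
print.classification_report <- function(x, ...) {
  cat("<classification_report> mean fold AUC:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# ---- feature importance ---------------------------------------------------

#' Feature-importance mining
#'
#' `method = "permutation"` (the cross-model default): mean AUC drop over
#' `n_repeats` shuffles of each feature column, floored at 0.
#' `method = "native"`: absolute coefficients for the linear model,
#' impurity-based importances for the tree ensembles, stump-weight sums
#' for AdaBoost (the SVM has no native importance and falls back to
#' permutation). Scores are normalized to sum to 1 and the top 10 are
#' extracted, ties broken by feature name.
#'
#' @param fitted A `surgesture_model` from [fit_skill_model()].
#' @param X Feature matrix on which importance is measured.
#' @param labels Binary labels aligned with `X`.
#' @param method `"permutation"` or `"native"`.
#' @param n_repeats Shuffles per feature for the permutation method.
#' @param seed Integer seed for the shuffles.
#' @return An `importance_report`: list with `scores` (named, sums to 1)
#'   and `top10` (`data.frame` feature, score).
#' @export
feature_importance <- function(fitted, X, labels,
                               method = c("permutation", "native"),
                               n_repeats = 5L, seed = 1L) {
  stopifnot(inherits(fitted, "surgesture_model"))
  method <- match.arg(method)
  X <- as.matrix(as.data.frame(X))[, fitted$feature_names, drop = FALSE]
  y <- as_binary01(labels)
  if (method == "permutation" && length(unique(y)) < 2L)
    stop("permutation importance needs both classes present",
         call. = FALSE)
  raw <- if (method == "native") native_importance(fitted)
         else permutation_importance(fitted, X, y, n_repeats, seed)
  raw <- pmax(raw, 0)
  scores <- if (sum(raw) > 0) raw / sum(raw)
            else stats::setNames(rep(1 / length(raw), length(raw)),
                                 names(raw))
  o <- order(-scores, names(scores))
  top10 <- data.frame(feature = names(scores)[o][1:min(10, length(scores))],
                      score = unname(scores[o][1:min(10, length(scores))]),
                      stringsAsFactors = FALSE)
  structure(list(model = fitted$model_name, method = method,
                 scores = scores, top10 = top10),
            class = "importance_report")
}

native_importance <- function(fitted) {
  nm <- fitted$feature_names
  fit <- fitted$fit
  raw <- switch(fitted$model_name,
    logistic = abs(as.numeric(stats::coef(fit))[-1L]),
    random_forest = as.numeric(
      randomForest::importance(fit)[, "MeanDecreaseGini"]),
    gradient_boosted_trees = {
      imp <- xgboost::xgb.importance(model = fit)
      v <- stats::setNames(rep(0, length(nm)), nm)
      v[imp$Feature] <- imp$Gain
      unname(v)
    },
    adaptive_boosting = {
      v <- stats::setNames(rep(0, length(nm)), paste0("f", seq_along(nm)))
      for (m in seq_along(fit$stumps)) {
        var <- as.character(fit$stumps[[m]]$frame$var[1L])
        if (var %in% names(v)) v[var] <- v[var] + fit$alphas[m]
      }
      unname(v)
    },
    svm_rbf = stop("the RBF SVM has no native importance; use ",
                   "method = 'permutation'", call. = FALSE))
  stats::setNames(raw, nm)
}

permutation_importance <- function(fitted, X, y, n_repeats, seed) {
  base <- roc_auc(predict_scores(fitted, X), y)
  with_seed(seed, {
    drops <- vapply(seq_len(ncol(X)), function(j) {
      mean(vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- X[sample(nrow(X)), j]
        base - roc_auc(predict_scores(fitted, Xp), y)
      }, numeric(1)))
    }, numeric(1))
    stats::setNames(drops, colnames(X))
  })
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("<importance_report> %s (%s), top 10:\n", x$model, x$method))
  print(x$top10, row.names = FALSE)
  invisible(x)
}
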
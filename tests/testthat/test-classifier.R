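# small separable toy: two shifted Gaussian clusters over a few features
toy_data <- function(n = 40, p = 6, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * p), n, p)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + sep
  colnames(X) <- paste0("x", 1:p)
  list(X = X, y = y)
}

test_that("roc_auc handles the canonical cases", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("roc_auc equals the pairwise Mann-Whitney oracle, and inverts", {
  set.seed(10)
  for (i in 1:50) {
    n <- sample(6:25, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))  # induce ties
    expect_equal(roc_auc(s, y), oracle_auc(s, y), tolerance = 1e-12)
    expect_equal(roc_auc(s, 1 - y), 1 - roc_auc(s, y), tolerance = 1e-12)
  }
})

test_that("folds group surgeons, stratify classes, and are deterministic", {
  sid <- paste0("S", 1:10)
  y <- rep(0:1, 5)
  f <- grouped_stratified_folds(sid, y, k = 5, seed = 2)
  expect_equal(as.integer(table(f)), rep(2L, 5))

  sid2 <- c(rep("A", 3), paste0("B", 1:7))
  y2 <- c(1, 1, 1, rep(0:1, length.out = 7))
  f2 <- grouped_stratified_folds(sid2, y2, k = 5, seed = 3)
  expect_length(unique(f2[sid2 == "A"]), 1L)
  expect_identical(f2, grouped_stratified_folds(sid2, y2, k = 5, seed = 3))
  expect_error(grouped_stratified_folds(paste0("S", 1:4), rep(0:1, 2),
                                        k = 5), "at least k")
})

test_that("all five models separate a linearly separable toy perfectly", {
  d <- toy_data()
  for (mdl in c("logistic", "svm_rbf", "random_forest",
                "gradient_boosted_trees", "adaptive_boosting")) {
    fit <- fit_skill_model(mdl, d$X, d$y, seed = 4)
    expect_equal(roc_auc(predict_scores(fit, d$X), d$y), 1,
                 info = mdl)
  }
})

test_that("run_cv reports per-fold and pooled AUC and is reproducible", {
  d <- toy_data(n = 60, seed = 5)
  sid <- rep(paste0("S", 1:20), each = 3)
  rep1 <- run_cv(d$X, list(overall = d$y), sid, k = 5, seed = 7,
                 models = c("logistic", "adaptive_boosting"))
  expect_equal(sort(unique(rep1$folds$fold)), 1:5)
  expect_true(all(rep1$summary$mean_auc > 0.9))
  expect_equal(nrow(rep1$pooled), 2L)
  rep2 <- run_cv(d$X, list(overall = d$y), sid, k = 5, seed = 7,
                 models = c("logistic", "adaptive_boosting"))
  expect_identical(rep1$folds, rep2$folds)
})

test_that("a test-fold-only marker feature cannot inflate AUC (no leakage)", {
  set.seed(11)
  n <- 100
  X <- matrix(rnorm(n * 10), n, 10)
  colnames(X) <- paste0("x", 1:10)
  y <- rbinom(n, 1, 0.5)
  sid <- rep(paste0("S", 1:25), each = 4)
  folds <- grouped_stratified_folds(sid, y, k = 5, seed = 1)
  # marker equals the label on fold-1 rows only; a leaky pipeline that saw
  # test rows during standardization/training could exploit it
  X2 <- cbind(X, marker = ifelse(folds == 1, y * 10, 0))
  rep <- run_cv(X2, list(overall = y), sid, k = 5, seed = 1,
                models = "logistic")
  expect_lt(rep$summary$mean_auc, 0.72)
})

test_that("importance normalizes, ranks an informative feature first", {
  set.seed(12)
  n <- 120
  X <- matrix(rnorm(n * 20), n, 20)
  colnames(X) <- paste0("x", 1:20)
  y <- rbinom(n, 1, plogis(3 * X[, 7]))
  fit <- fit_skill_model("logistic", X, y, seed = 1)
  for (meth in c("permutation", "native")) {
    imp <- feature_importance(fit, X, y, method = meth, seed = 2)
    expect_equal(sum(imp$scores), 1, tolerance = 1e-9)
    expect_equal(imp$top10$feature[1], "x7")
    expect_equal(nrow(imp$top10), 10L)
  }
  rf <- fit_skill_model("random_forest", X, y, seed = 1)
  impn <- feature_importance(rf, X, y, method = "native")
  expect_equal(impn$top10$feature[1], "x7")
  expect_error(feature_importance(fit, X, rep(1, n),
                                  method = "permutation"), "both classes")
})

test_that("all-noise features yield no dominant importance score", {
  set.seed(13)
  n <- 150
  X <- matrix(rnorm(n * 30), n, 30)
  colnames(X) <- paste0("x", 1:30)
  y <- rbinom(n, 1, 0.5)
  fit <- fit_skill_model("logistic", X, y, seed = 1)
  imp <- feature_importance(fit, X, y, method = "native")
  expect_lt(max(imp$scores), 0.2)
})
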
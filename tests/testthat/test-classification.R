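test_that("a separable toy problem is fit perfectly at large C", {
  X <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  y <- c("A", "A", "B", "B")
  fit <- fit_linear_classifier(X, y, C = 1e6)
  expect_equal(predict(fit, X), y)
  cm <- confusion(y, predict(fit, X), c("A", "B"))
  expect_equal(balanced_accuracy(cm), 1)
})

test_that("the heavy-regularisation limit collapses to class priors", {
  set.seed(5)
  X <- matrix(rnorm(300), ncol = 3)
  y <- rep(c("A", "B", "B", "B"), 25)  # priors 0.25 / 0.75
  fit <- fit_linear_classifier(X, y, C = 1e-10)
  expect_lt(max(abs(fit$weights)), 1e-3)
  P <- predict_proba(fit, X)
  expect_equal(unname(colMeans(P)), c(0.25, 0.75), tolerance = 1e-3)
  expect_equal(unname(rowSums(P)), rep(1, 100), tolerance = 1e-9)
})

test_that("predict is the argmax of predict_proba with canonical tie-break", {
  set.seed(6)
  X <- matrix(rnorm(60), ncol = 2)
  y <- sample(c("A", "B", "C"), 30, replace = TRUE)
  fit <- fit_linear_classifier(X, y, C = 1)
  P <- predict_proba(fit, X)
  expect_equal(predict(fit, X), fit$classes[apply(P, 1, which.max)])
  # hand-built exact tie goes to the earlier class in canonical order
  tied <- structure(list(weights = matrix(0, 2, 1), biases = c(0, 0),
                         classes = c("A", "B"), C = 1, converged = TRUE),
                    class = "linear_classifier")
  expect_equal(predict(tied, matrix(1, 1, 1)), "A")
})

test_that("degenerate fits and width mismatches raise errors", {
  X <- matrix(rnorm(20), ncol = 2)
  expect_error(fit_linear_classifier(X, rep("A", 10), C = 1), "two distinct")
  Xbad <- X; Xbad[1] <- Inf
  expect_error(fit_linear_classifier(Xbad, rep(c("A", "B"), 5), C = 1),
               "non-finite")
  fit <- fit_linear_classifier(X, rep(c("A", "B"), 5), C = 1)
  expect_error(predict(fit, matrix(0, 1, 5)), "width")
})

test_that("group k-fold keeps groups whole and balances fold sizes", {
  groups <- rep(sprintf("g%02d", 1:12), times = c(8, 7, 6, 5, 4, 4, 3, 3,
                                                  2, 2, 1, 1))
  folds <- group_kfold(groups, 4)
  expect_equal(sort(unique(folds)), 1:4)
  for (g in unique(groups)) {
    expect_equal(length(unique(folds[groups == g])), 1)
  }
  expect_lte(diff(range(table(folds))), 3)
  expect_error(group_kfold(c("a", "b"), 3), "at least 3 distinct groups")
})

test_that("grid search agrees with an exhaustive independent evaluation", {
  set.seed(7)
  n <- 120
  X <- matrix(rnorm(n * 4), ncol = 4)
  beta <- c(2, -2, 0, 0)
  y <- ifelse(stats::runif(n) < stats::plogis(X %*% beta), "A", "B")
  groups <- rep(sprintf("g%d", 1:12), each = 10)
  cfg <- cv_config(k_inner = 4, C_grid = c(0.01, 1, 100))
  gs <- grid_search_C(X, y, groups, cfg)
  # independent oracle: evaluate every C with the same deterministic splits
  folds <- group_kfold(groups, 4)
  oracle <- vapply(cfg$C_grid, function(C) {
    mean(vapply(1:4, function(f) {
      fit <- fit_linear_classifier(X[folds != f, ], y[folds != f], C = C,
                                   classes = sort(unique(y)))
      smsengage:::fold_balanced_accuracy(
        y[folds == f], predict(fit, X[folds == f, ]), sort(unique(y)))
    }, numeric(1)))
  }, numeric(1))
  expect_equal(gs$mean_scores, oracle)
  expect_equal(gs$best_C, cfg$C_grid[which.max(oracle)])
})

test_that("grid search tie-breaks to the smallest C and handles single grids", {
  X <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  y <- rep(c("A", "B"), each = 10)
  groups <- rep(sprintf("g%d", 1:10), times = 2)
  one <- grid_search_C(X, y, groups, cv_config(k_inner = 5, C_grid = 42))
  expect_equal(one$best_C, 42)
  # widely separated classes: every C scores 1.0, so the smallest wins
  gs <- grid_search_C(X, y, groups,
                      cv_config(k_inner = 5, C_grid = c(0.5, 5, 50)))
  expect_equal(gs$mean_scores, rep(1, 3))
  expect_equal(gs$best_C, 0.5)
})

test_that("nested CV partitions records by whole groups with zero leakage", {
  set.seed(8)
  n <- 20
  X <- matrix(rnorm(n * 2), ncol = 2)
  y <- rep(c("A", "B"), 10)
  groups <- rep(sprintf("g%d", 1:10), each = 2)
  cfg <- cv_config(k_outer = 10, k_inner = 5, C_grid = c(0.1, 10))
  res <- nested_cv(X, y, groups, cfg)
  test_idx <- lapply(res$folds, `[[`, "test_idx")
  expect_equal(sort(unlist(test_idx)), 1:n)          # union = everything
  expect_equal(anyDuplicated(unlist(test_idx)), 0)   # pairwise disjoint
  for (f in res$folds) {
    expect_equal(length(intersect(f$train_groups, f$test_groups)), 0)
    # whole groups: each test group's records are all in this fold
    for (g in f$test_groups) {
      expect_true(all(which(groups == g) %in% f$test_idx))
    }
  }
  expect_equal(leakage_violations(res), 0)
  expect_error(nested_cv(X, y, rep("g1", n), cfg), "distinct groups")
})

test_that("nested CV is deterministic for identical inputs", {
  set.seed(9)
  X <- matrix(rnorm(80), ncol = 2)
  y <- rep(c("A", "B"), 20)
  groups <- rep(sprintf("g%d", 1:8), each = 5)
  cfg <- cv_config(k_outer = 4, k_inner = 3, C_grid = c(0.1, 1))
  r1 <- nested_cv(X, y, groups, cfg)
  r2 <- nested_cv(X, y, groups, cfg)
  expect_identical(r1$outer_fold, r2$outer_fold)
  expect_identical(vapply(r1$folds, `[[`, numeric(1), "best_C"),
                   vapply(r2$folds, `[[`, numeric(1), "best_C"))
  expect_identical(lapply(r1$folds, `[[`, "proba"),
                   lapply(r2$folds, `[[`, "proba"))
})
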
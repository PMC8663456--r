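#' Cross-validation configuration
#'
#' @param k_outer Outer folds (performance estimation); default 10.
#' @param k_inner Inner folds (hyperparameter selection); default 10.
#' @param C_grid Inverse regularisation strengths searched, ascending.
#'   The default spans under- to over-regularised regimes for unit-norm
#'   features.
#' @param seed Integer seed recorded with results (fold construction is
#'   deterministic; the seed feeds anything stochastic layered on top).
#' @return A `cv_config` list.
#' @export
cv_config <- function(k_outer = 10, k_inner = 10,
                      C_grid = c(0.01, 0.1, 1, 10, 100), seed = 1L) {
  stopifnot(k_outer >= 2, k_inner >= 2, length(C_grid) >= 1, all(C_grid > 0))
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 C_grid = sort(as.numeric(C_grid)), seed = as.integer(seed)),
            class = "cv_config")
}

#' Fit an L2-regularised multinomial logistic model
#'
#' Maximises the multinomial log-likelihood minus `1/(2C)` times the
#' squared L2 norm of the weights (intercepts unpenalised), by L-BFGS with
#' analytic gradients from a zero start. The objective is strictly convex
#' in the weights, so the fit is deterministic.
#'
#' @param X Numeric feature matrix (rows = records), all entries finite.
#' @param y Character/factor labels; at least two distinct values.
#' @param C Inverse regularisation strength (> 0).
#' @param classes Canonical class order; defaults to sorted unique labels.
#'   Classes absent from `y` get weights pushed to the penalty optimum.
#' @param maxit,gtol Optimiser budget and gradient-norm tolerance.
#' @return A `linear_classifier` with `weights` (classes x features),
#'   `biases`, `classes`, `C` and a `converged` flag.
#' @export
fit_linear_classifier <- function(X, y, C = 1, classes = NULL,
                                  maxit = 1000, gtol = 1e-8) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- as.character(y)
  stopifnot(nrow(X) == length(y), C > 0)
  if (any(!is.finite(X))) stop("non-finite feature values", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("need at least two distinct labels to fit", call. = FALSE)
  }
  if (is.null(classes)) classes <- sort(unique(y))
  if (!all(y %in% classes)) stop("labels outside the class set", call. = FALSE)

  n <- nrow(X); d <- ncol(X); K <- length(classes)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), match(y, classes))] <- 1

  unpack <- function(theta) {
    W <- matrix(theta[seq_len(d * K)], d, K)
    b <- theta[d * K + seq_len(K)]
    list(W = W, b = b)
  }
  softmax_rows <- function(S) {
    S <- S - apply(S, 1, max)
    E <- exp(S)
    E / rowSums(E)
  }
  fn <- function(theta) {
    p <- unpack(theta)
    S <- X %*% p$W + rep(p$b, each = n)
    S <- S - apply(S, 1, max)
    ll <- sum(S[Y == 1]) - sum(log(rowSums(exp(S))))
    -ll + sum(p$W^2) / (2 * C)
  }
  gr <- function(theta) {
    p <- unpack(theta)
    P <- softmax_rows(X %*% p$W + rep(p$b, each = n))
    R <- P - Y
    c(as.vector(crossprod(X, R) + p$W / C), colSums(R))
  }

  theta0 <- numeric(d * K + K)
  opt <- stats::optim(theta0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  gnorm <- sqrt(sum(gr(opt$par)^2))
  converged <- gnorm <= max(gtol, 1e-5 * (1 + abs(opt$value)))
  p <- unpack(opt$par)
  structure(list(weights = t(p$W), biases = p$b, classes = classes, C = C,
                 converged = converged, gradient_norm = gnorm),
            class = "linear_classifier")
}

#' Class probabilities and labels from a fitted linear classifier
#'
#' `predict_proba()` returns the softmax probability matrix (rows sum to
#' 1); `predict()` returns the argmax label, ties broken toward the
#' earlier class in canonical order.
#'
#' @param object A `linear_classifier`.
#' @param X Feature matrix with the width the model was fitted on.
#' @param ... Unused.
#' @return A probability matrix, or a character vector of labels.
#' @export
predict_proba <- function(object, X) {
  stopifnot(inherits(object, "linear_classifier"))
  X <- as.matrix(X)
  if (ncol(X) != ncol(object$weights)) {
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(X), ncol(object$weights)), call. = FALSE)
  }
  S <- X %*% t(object$weights) + rep(object$biases, each = nrow(X))
  S <- S - apply(S, 1, max)
  E <- exp(S)
  P <- E / rowSums(E)
  colnames(P) <- object$classes
  P
}

#' @rdname predict_proba
#' @export
predict.linear_classifier <- function(object, X, ...) {
  P <- predict_proba(object, X)
  object$classes[apply(P, 1, which.max)]
}

#' Group-constrained k-fold assignment
#'
#' Assigns whole groups to folds so no group spans train and test: groups
#' are sorted by descending size (ties by first appearance) and each is
#' placed greedily into the currently smallest fold. Deterministic.
#'
#' @param groups Vector of group ids, one per record.
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1..k`, one per record.
#' @export
group_kfold <- function(groups, k) {
  groups <- as.character(groups)
  ug <- unique(groups)
  if (length(ug) < k) {
    stop(sprintf("need at least %d distinct groups for %d folds; have %d",
                 k, k, length(ug)), call. = FALSE)
  }
  sizes <- table(factor(groups, levels = ug))
  ord <- order(-as.integer(sizes), match(ug, ug))
  fold_of_group <- integer(length(ug))
  fold_sizes <- integer(k)
  for (gi in ord) {
    f <- which.min(fold_sizes)
    fold_of_group[gi] <- f
    fold_sizes[f] <- fold_sizes[f] + as.integer(sizes[gi])
  }
  fold_of_group[match(groups, ug)]
}

# mean of the defined per-class sensitivities of predictions vs truth;
# classes absent from the truth are excluded rather than scored 0
fold_balanced_accuracy <- function(y_true, y_pred, classes) {
  sens <- vapply(classes, function(cl) {
    pos <- y_true == cl
    if (!any(pos)) return(NA_real_)
    mean(y_pred[pos] == cl)
  }, numeric(1))
  mean(sens, na.rm = TRUE)
}

#' Inner-loop grid search for the regularisation strength
#'
#' Evaluates each `C` in `config$C_grid` by group-constrained
#' `config$k_inner`-fold cross-validation and returns the `C` with the
#' highest mean balanced accuracy; exact ties go to the smallest `C`.
#'
#' @param X,y Training data.
#' @param groups Group ids (anti-leakage unit), one per record.
#' @param config A [cv_config()].
#' @param classes Canonical class order.
#' @return A list with `best_C` and the per-C mean scores.
#' @export
grid_search_C <- function(X, y, groups, config = cv_config(), classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (is.null(classes)) classes <- sort(unique(y))
  folds <- group_kfold(groups, config$k_inner)
  scores <- vapply(config$C_grid, function(C) {
    accs <- vapply(seq_len(config$k_inner), function(f) {
      tr <- folds != f; te <- !tr
      if (!any(te) || length(unique(y[tr])) < 2) return(NA_real_)
      fit <- fit_linear_classifier(X[tr, , drop = FALSE], y[tr], C = C,
                                   classes = classes)
      fold_balanced_accuracy(y[te], predict(fit, X[te, , drop = FALSE]),
                             classes)
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- config$C_grid[which.max(scores)]  # grid ascending: ties -> smallest
  list(best_C = best, C_grid = config$C_grid, mean_scores = scores)
}

#' Group-constrained nested cross-validation
#'
#' Outer folds partition the groups (never the records), so no group spans
#' an outer train/test boundary. Within each outer training set an inner
#' group-constrained grid search selects `C`; the model is refit on the
#' whole outer training set and scored on the held-out fold. Every record
#' is tested exactly once.
#'
#' @param X,y Full data set.
#' @param groups Group ids: message cluster ids for the intent model,
#'   participant ids for the reply model.
#' @param config A [cv_config()].
#' @param classes Canonical class order (defaults to sorted unique labels).
#' @return A `nested_cv_result`: list of per-fold results (`fold`,
#'   `best_C`, `test_idx`, `y_true`, `y_pred`, `proba`, `train_groups`,
#'   `test_groups`, `converged`) plus `classes` and the fold assignment.
#' @export
nested_cv <- function(X, y, groups, config = cv_config(), classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  groups <- as.character(groups)
  stopifnot(nrow(X) == length(y), length(groups) == length(y))
  if (is.null(classes)) classes <- sort(unique(y))
  outer <- group_kfold(groups, config$k_outer)
  folds <- lapply(seq_len(config$k_outer), function(f) {
    te <- which(outer == f)
    tr <- which(outer != f)
    gs <- grid_search_C(X[tr, , drop = FALSE], y[tr], groups[tr],
                        config = config, classes = classes)
    fit <- fit_linear_classifier(X[tr, , drop = FALSE], y[tr],
                                 C = gs$best_C, classes = classes)
    proba <- predict_proba(fit, X[te, , drop = FALSE])
    list(fold = f, best_C = gs$best_C, test_idx = te,
         y_true = y[te], y_pred = classes[apply(proba, 1, which.max)],
         proba = proba,
         train_groups = unique(groups[tr]), test_groups = unique(groups[te]),
         converged = fit$converged)
  })
  structure(list(folds = folds, classes = classes, outer_fold = outer,
                 groups = groups, config = config),
            class = "nested_cv_result")
}

#' Audit a nested-CV result for group leakage
#'
#' @param result A `nested_cv_result`.
#' @return Number of group ids appearing on both sides of any outer
#'   train/test boundary (0 when the constraint holds).
#' @export
leakage_violations <- function(result) {
  sum(vapply(result$folds, function(f) {
    length(intersect(f$train_groups, f$test_groups))
  }, integer(1)))
}
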
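#' Confusion matrix
#'
#' @param y_true,y_pred Label vectors of equal length.
#' @param classes Canonical class order; every label must belong to it.
#' @return A K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion <- function(y_true, y_pred, classes) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  stopifnot(length(y_true) == length(y_pred))
  unknown <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(unknown) > 0) {
    stop("labels outside the class set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class, TP/FP/FN/TN are derived one-vs-rest and the standard
#' ratios computed. A zero denominator yields `NA` (undefined), never 0:
#' undefined cells are excluded from macroaverages.
#'
#' @param cm A confusion matrix from [confusion()].
#' @return A tibble with one row per class and columns `class`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `fpr`, `fnr`, `f1`.
#' @export
per_class_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  classes <- rownames(cm)
  rows <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    sens <- ratio(tp, tp + fn)
    spec <- ratio(tn, tn + fp)
    ppv <- ratio(tp, tp + fp)
    npv <- ratio(tn, tn + fn)
    f1 <- if (is.na(sens) || is.na(ppv) || (ppv + sens) == 0) NA_real_ else
      2 * ppv * sens / (ppv + sens)
    tibble::tibble(class = classes[i], sensitivity = sens, specificity = spec,
                   ppv = ppv, npv = npv,
                   fpr = if (is.na(spec)) NA_real_ else 1 - spec,
                   fnr = if (is.na(sens)) NA_real_ else 1 - sens,
                   f1 = f1)
  })
  do.call(rbind, rows)
}

#' Balanced accuracy
#'
#' The unweighted mean of per-class sensitivities. Requires every class to
#' have at least one true instance; an empty class makes the mean
#' undefined and is an error here (fold-level scoring that tolerates
#' absent classes excludes them instead).
#'
#' @param cm A confusion matrix from [confusion()].
#' @return A number in `[0, 1]`.
#' @export
balanced_accuracy <- function(cm) {
  cm <- as.matrix(cm)
  if (any(rowSums(cm) == 0)) {
    stop("balanced accuracy undefined: class(es) with no true instances: ",
         paste(rownames(cm)[rowSums(cm) == 0], collapse = ", "),
         call. = FALSE)
  }
  mean(diag(cm) / rowSums(cm))
}

#' Macroaverage of per-class values
#'
#' Unweighted mean over the classes whose value is defined; `NA` entries
#' (undefined metrics) are excluded.
#'
#' @param values Numeric vector of per-class values.
#' @return Their mean.
#' @export
macroaverage <- function(values) {
  if (all(is.na(values))) stop("all per-class values undefined", call. = FALSE)
  mean(values, na.rm = TRUE)
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores for the chosen class (that
#' class positive, all others negative) and returns the (FPR, TPR) points,
#' including the (0,0) and (1,1) anchors. `auc_trapezoid()` integrates a
#' point set by the trapezoidal rule; on a ROC curve this equals the
#' probability a random positive outscores a random negative, ties
#' counting one half.
#'
#' @param y_true Label vector.
#' @param scores Numeric score (probability) for the positive class.
#' @param positive The class treated as positive; must occur in `y_true`.
#' @return `roc_curve_ovr()`: a tibble of `fpr`, `tpr`, sorted;
#'   `auc_trapezoid()`: a number in `[0, 1]`.
#' @export
roc_curve_ovr <- function(y_true, scores, positive) {
  stopifnot(length(y_true) == length(scores), all(is.finite(scores)))
  pos <- y_true == positive
  if (!any(pos)) stop("class '", positive, "' absent from y_true",
                      call. = FALSE)
  if (all(pos)) stop("no negative instances for class '", positive, "'",
                     call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]; s <- scores[ord]
  # step once per distinct score (ties move diagonally in one step)
  last_of_run <- c(s[-1] != s[-length(s)], TRUE)
  tp <- cumsum(pos)[last_of_run]
  fp <- cumsum(!pos)[last_of_run]
  tibble::tibble(fpr = c(0, fp / sum(!pos), 1), tpr = c(0, tp / sum(pos), 1))
}

#' @rdname roc_curve_ovr
#' @param points A tibble/data frame with `fpr` and `tpr` columns.
#' @export
auc_trapezoid <- function(points) {
  x <- points$fpr; y <- points$tpr
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Aggregate a metric across cross-validation folds
#'
#' @param fold_values Numeric vector, one value per fold (`NA` allowed and
#'   dropped).
#' @param conf Confidence level for the t-interval.
#' @return A list with `mean`, `sd` (n-1 denominator), `ci_low`, `ci_high`
#'   (two-sided Student-t interval), and `n`. With fewer than 2 defined
#'   values, `sd` and the CI are `NA`.
#' @export
aggregate_folds <- function(fold_values, conf = 0.95) {
  v <- fold_values[!is.na(fold_values)]
  n <- length(v)
  if (n == 0) return(list(mean = NA_real_, sd = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, n = 0L))
  m <- mean(v)
  if (n < 2) return(list(mean = m, sd = NA_real_, ci_low = NA_real_,
                         ci_high = NA_real_, n = 1L))
  s <- stats::sd(v)
  half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, sd = s, ci_low = m - half, ci_high = m + half, n = n)
}

#' Evaluation report across nested-CV folds
#'
#' Builds the per-class mean (SD) metric panel, macroaverages, the
#' balanced-accuracy t-interval across outer folds, and pooled one-vs-rest
#' ROC curves with per-class and macro AUC.
#'
#' @param result A `nested_cv_result` from [nested_cv()].
#' @return An `evaluation_report` list: `per_class` (tibble of fold means
#'   and SDs per metric), `macro` (tibble), `balanced_accuracy` (from
#'   [aggregate_folds()]), `roc` (tibble of class/fpr/tpr), `auc` (named
#'   per-class vector), `auc_macro`, `confusion` (pooled).
#' @export
evaluation_report <- function(result) {
  stopifnot(inherits(result, "nested_cv_result"))
  classes <- result$classes
  metric_names <- c("sensitivity", "specificity", "ppv", "npv", "fpr",
                    "fnr", "f1")

  fold_metrics <- lapply(result$folds, function(f) {
    per_class_metrics(confusion(f$y_true, f$y_pred, classes))
  })
  per_class <- do.call(rbind, lapply(seq_along(classes), function(i) {
    row <- tibble::tibble(class = classes[i])
    for (mn in metric_names) {
      vals <- vapply(fold_metrics, function(pm) pm[[mn]][i], numeric(1))
      row[[paste0(mn, "_mean")]] <- if (all(is.na(vals))) NA_real_ else
        mean(vals, na.rm = TRUE)
      row[[paste0(mn, "_sd")]] <- if (sum(!is.na(vals)) < 2) NA_real_ else
        stats::sd(vals, na.rm = TRUE)
    }
    row
  }))
  macro <- tibble::tibble(metric = metric_names)
  macro$mean <- vapply(metric_names, function(mn) {
    macroaverage(per_class[[paste0(mn, "_mean")]])
  }, numeric(1))

  fold_ba <- vapply(result$folds, function(f) {
    fold_balanced_accuracy(f$y_true, f$y_pred, classes)
  }, numeric(1))
  ba <- aggregate_folds(fold_ba)

  y_true_all <- unlist(lapply(result$folds, `[[`, "y_true"))
  proba_all <- do.call(rbind, lapply(result$folds, `[[`, "proba"))
  roc <- list(); auc <- stats::setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    if (any(y_true_all == cl) && !all(y_true_all == cl)) {
      pts <- roc_curve_ovr(y_true_all, proba_all[, cl], cl)
      roc[[cl]] <- tibble::tibble(class = cl, fpr = pts$fpr, tpr = pts$tpr)
      auc[cl] <- auc_trapezoid(pts)
    }
  }
  structure(list(
    per_class = per_class, macro = macro, balanced_accuracy = ba,
    fold_balanced_accuracy = fold_ba,
    roc = if (length(roc)) do.call(rbind, roc) else NULL,
    auc = auc, auc_macro = macroaverage(auc),
    confusion = confusion(y_true_all,
                          unlist(lapply(result$folds, `[[`, "y_pred")),
                          classes),
    classes = classes
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  ba <- x$balanced_accuracy
  cat(sprintf("<evaluation_report> balanced accuracy %.3f (95%% CI %.3f-%.3f), macro AUC %.3f\n",
              ba$mean, ba$ci_low, ba$ci_high, x$auc_macro))
  invisible(x)
}
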
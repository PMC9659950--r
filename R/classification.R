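#' Build a subject-by-feature table from cluster means
#'
#' Feature (s, j) = mean of subject s's map over cluster j's voxels;
#' the features mirror how per-cluster mean szReHo and z-FC values are
#' extracted for classification.
#'
#' @param subject_maps List of [stat_map]s (one per subject).
#' @param clusters Named list of logical ROI masks (or `grf_result`
#'   cluster entries via [define_roi_from_cluster()]).
#' @param labels Optional factor/vector of class labels, length =
#'   subjects.
#' @return Data frame of features with optional `label` column.
#' @export
assemble_features <- function(subject_maps, clusters, labels = NULL) {
  if (length(clusters) == 0) stop("no clusters supplied")
  if (is.null(names(clusters)) || any(names(clusters) == ""))
    names(clusters) <- paste0("cluster", seq_along(clusters))
  feat <- vapply(clusters, function(roi) {
    vapply(subject_maps, function(m) {
      if (!identical(dim(roi), dim(m$values)))
        stop("cluster grid does not match subject map grid")
      mean(m$values[roi])
    }, 1)
  }, numeric(length(subject_maps)))
  feat <- as.data.frame(matrix(feat, nrow = length(subject_maps),
                               dimnames = list(NULL, names(clusters))))
  if (!is.null(labels)) feat$label <- labels
  feat
}

#' Iteratively prune collinear features
#'
#' While any feature pair has |Pearson r| above the threshold, take the
#' most correlated pair and drop the member with the larger mean
#' absolute correlation to all remaining features (ties: drop the later
#' column, keeping the output deterministic).
#'
#' @param features Numeric data frame / matrix (no label column).
#' @param threshold Absolute-correlation cutoff (default 0.75).
#' @return Feature table restricted to the surviving columns (original
#'   order preserved); dropped names in attribute `"dropped"`.
#' @export
prune_collinear <- function(features, threshold = 0.75) {
  x <- as.data.frame(features)
  dropped <- character(0)
  repeat {
    if (ncol(x) < 2L) break
    cm <- abs(stats::cor(as.matrix(x)))
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    ij <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(abs(stats::cor(as.matrix(x))) -
                           diag(ncol(x))) * ncol(x) / (ncol(x) - 1)
    i <- ij[1]; j <- ij[2]
    drop_idx <- if (mean_abs[i] > mean_abs[j]) i
                else if (mean_abs[j] > mean_abs[i]) j
                else max(i, j)
    dropped <- c(dropped, colnames(x)[drop_idx])
    x <- x[, -drop_idx, drop = FALSE]
  }
  attr(x, "dropped") <- dropped
  x
}

# fit an (optionally L2-regularised) logistic model; returns predict fn
fit_logistic <- function(x, y, lambda = 0) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("training labels contain a single class")
  if (lambda > 0) {
    # glmnet needs >= 2 columns; pad single-feature designs with an
    # all-zero column that cannot influence the fit
    pad <- ncol(x) == 1L
    xg <- if (pad) cbind(x, 0) else x
    fit <- suppressWarnings(
      glmnet::glmnet(xg, y, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = TRUE,
                     exclude = if (pad) 2L))
    function(newx) {
      newx <- as.matrix(newx)
      if (pad) newx <- cbind(newx, 0)
      as.numeric(stats::predict(fit, newx, type = "response"))
    }
  } else {
    xd <- cbind(1, x)
    fit <- suppressWarnings(
      stats::glm.fit(xd, y, family = stats::binomial()))
    cf <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    function(newx) {
      eta <- cbind(1, as.matrix(newx)) %*% cf
      as.numeric(1 / (1 + exp(-eta)))
    }
  }
}

#' Leave-one-out cross-validated logistic regression
#'
#' Each subject is predicted by a model trained on the other N - 1;
#' predictions are by construction independent of subject order.
#'
#' @param features Numeric feature table (no label column).
#' @param labels Binary labels (factor or 0/1); the second factor level
#'   is treated as the positive class.
#' @param lambda L2 (ridge) penalty; 0 = plain maximum likelihood.
#' @return List: `scores` (held-out positive-class probabilities),
#'   `predictions` (0/1 at the 0.5 threshold), `labels01`,
#'   `degenerate_folds` (folds whose training labels were single-class).
#' @export
loocv_evaluate <- function(features, labels, lambda = 0) {
  x <- as.matrix(features)
  y <- label01(labels)
  n <- length(y)
  if (n < 3L) stop("need N >= 3 subjects for LOOCV")
  scores <- numeric(n)
  degen <- integer(0)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      degen <- c(degen, i)
      scores[i] <- mean(ytr)
      next
    }
    pred <- fit_logistic(x[-i, , drop = FALSE], ytr, lambda)
    scores[i] <- pred(x[i, , drop = FALSE])
  }
  list(scores = scores, predictions = as.integer(scores >= 0.5),
       labels01 = y, degenerate_folds = degen)
}

label01 <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  f <- factor(labels)
  if (nlevels(f) != 2L) stop("labels must be binary")
  as.integer(f) - 1L
}

#' Grid-search hyperparameters by LOOCV accuracy
#'
#' Evaluates every candidate ridge penalty by leave-one-out accuracy and
#' returns the best; ties are broken toward the strongest
#' regularisation.
#'
#' @param features Numeric feature table.
#' @param labels Binary labels.
#' @param grid Numeric vector of candidate lambda values (default a
#'   7-point log grid including 0).
#' @return List: `lambda`, `accuracy`, `grid_accuracy`.
#' @export
grid_search_logistic <- function(features, labels,
                                 grid = c(0, 10^seq(-3, 1, length.out = 6))) {
  if (length(grid) == 0) stop("hyperparameter grid is empty")
  y <- label01(labels)
  if (length(unique(y)) < 2L) stop("labels contain a single class")
  acc <- vapply(grid, function(l) {
    cv <- loocv_evaluate(features, y, lambda = l)
    mean(cv$predictions == y)
  }, 1)
  best <- max(acc)
  lam <- max(grid[acc == best])   # strongest regularisation among ties
  list(lambda = lam, accuracy = best,
       grid_accuracy = data.frame(lambda = grid, accuracy = acc))
}

#' Classification metrics from held-out predictions
#'
#' Confusion-matrix metrics at the 0.5 probability threshold, Cohen's
#' kappa, and the trapezoidal ROC AUC over all unique score thresholds
#' (equal to the Mann-Whitney U statistic divided by `n1 * n0`).
#'
#' @param predictions 0/1 predicted classes.
#' @param scores Positive-class probabilities or scores.
#' @param labels True binary labels.
#' @return List of class `classifier_report`: `auc`, `accuracy`,
#'   `sensitivity`, `specificity`, `kappa`, `confusion`, `roc`
#'   (data frame of FPR/TPR points).
#' @export
compute_metrics <- function(predictions, scores, labels) {
  y <- label01(labels)
  pred <- as.integer(predictions)
  if (length(unique(y)) < 2L) stop("AUC undefined for single-class labels")
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  n <- length(y)
  acc <- (tp + tn) / n
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe < 1) (po - pe) / (1 - pe) else 0
  # ROC by sweeping unique thresholds from high to low
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(u) sum(scores >= u & y == 1) / sum(y == 1), 1)
  fpr <- vapply(thr, function(u) sum(scores >= u & y == 0) / sum(y == 0), 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(auc = auc, accuracy = acc, sensitivity = sens,
                 specificity = spec, kappa = kappa,
                 confusion = c(tp = tp, fn = fn, tn = tn, fp = fp),
                 roc = data.frame(fpr = fpr, tpr = tpr)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> AUC %.3f | accuracy %.3f | ",
                     "sensitivity %.3f | specificity %.3f | kappa %.3f\n"),
              x$auc, x$accuracy, x$sensitivity, x$specificity, x$kappa))
  if (!is.null(x$permutation_p))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$permutation_p, x$n_perm))
  invisible(x)
}

#' Classification pipeline: prune, grid-search, LOOCV, metrics
#'
#' @param features Numeric feature table (no label column).
#' @param labels Binary labels.
#' @param prune_threshold Collinearity cutoff (default 0.75).
#' @param grid Ridge-penalty grid (see [grid_search_logistic()]).
#' @return `classifier_report` with extra fields `lambda`,
#'   `kept_features`, `scores`, `predictions`.
#' @export
classify_subjects <- function(features, labels, prune_threshold = 0.75,
                              grid = c(0, 10^seq(-3, 1, length.out = 6))) {
  pruned <- prune_collinear(features, prune_threshold)
  gs <- grid_search_logistic(pruned, labels, grid)
  cv <- loocv_evaluate(pruned, labels, gs$lambda)
  rep <- compute_metrics(cv$predictions, cv$scores, labels)
  rep$lambda <- gs$lambda
  rep$kept_features <- colnames(pruned)
  rep$scores <- cv$scores
  rep$predictions <- cv$predictions
  rep
}

#' Permutation test of classifier performance
#'
#' Re-runs the full pipeline (collinearity pruning, hyperparameter grid
#' search, LOOCV) under `n_perm` random label permutations and reports
#' `p = (1 + #{perm statistic >= observed}) / (n_perm + 1)`. The test
#' statistic is LOOCV accuracy by default (`statistic = "auc"`
#' available). A reduced grid may be passed to keep the permutation loop
#' affordable; the grid used is recorded in the result.
#'
#' @param features Numeric feature table.
#' @param labels Binary labels.
#' @param n_perm Number of permutations (default 5000).
#' @param seed RNG seed for the permutations.
#' @param statistic `"accuracy"` (default) or `"auc"`.
#' @param prune_threshold,grid Passed to [classify_subjects()].
#' @return List: `p`, `observed`, `perm_stats`, `n_perm`, `grid`.
#' @export
permutation_test <- function(features, labels, n_perm = 5000, seed = 1,
                             statistic = c("accuracy", "auc"),
                             prune_threshold = 0.75, grid = c(0, 1)) {
  statistic <- match.arg(statistic)
  y <- label01(labels)
  stat_of <- function(lab) {
    rep <- classify_subjects(features, lab, prune_threshold, grid)
    if (statistic == "accuracy") rep$accuracy else rep$auc
  }
  observed <- stat_of(y)
  set.seed(seed)
  perm_stats <- vapply(seq_len(n_perm), function(i) stat_of(sample(y)), 1)
  p <- (1 + sum(perm_stats >= observed)) / (n_perm + 1)
  list(p = p, observed = observed, perm_stats = perm_stats,
       n_perm = n_perm, grid = grid, statistic = statistic)
}
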
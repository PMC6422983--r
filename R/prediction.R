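# Feature ranking with RReliefF and coverage depth/uniformity class
# prediction with an RBF-kernel SVM under stratified cross-validation.

#' RReliefF feature ranking for a continuous target
#'
#' Regression variant of the Relief family: features are scored by how well
#' their value differences track target differences among near neighbours.
#' For each sampled instance the `k_neighbors` nearest instances (Manhattan
#' distance on min-max scaled features) contribute the accumulators
#' `N_dC` (target differs), `N_dA[f]` (feature differs) and
#' `N_dC&dA[f]` (both differ), and the weight of feature `f` is
#' `N_dC&dA[f] / N_dC - (N_dA[f] - N_dC&dA[f]) / (m - N_dC)`,
#' i.e. the difference between the probability that the feature separates
#' instances with different predictions and the probability that it
#' separates instances with similar predictions.
#'
#' @param features Numeric matrix or data.frame (instances x features).
#' @param target Numeric target vector.
#' @param k_neighbors Number of nearest neighbours (default 10).
#' @param n_iterations Number of sampled instances (default: all, in
#'   deterministic order).
#' @param seed Integer seed (used only when `n_iterations < n`).
#' @return A data.frame with `feature`, `weight` and `rank` (1 = best),
#'   ordered as the input columns.
#' @export
rrelieff_rank <- function(features, target, k_neighbors = 10L,
                          n_iterations = NULL, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(p))
  if (n < k_neighbors + 1L) {
    stop("need at least k_neighbors + 1 instances", call. = FALSE)
  }
  rng <- apply(x, 2L, function(v) diff(range(v)))
  const <- rng == 0
  if (any(const)) {
    warning(sprintf("constant feature(s) receive weight 0: %s",
                    paste(colnames(x)[const], collapse = ", ")))
    rng[const] <- 1
  }
  xs <- sweep(sweep(x, 2L, apply(x, 2L, min)), 2L, rng, "/")
  t_rng <- diff(range(target))
  if (t_rng == 0) {
    stop("`target` is constant; nothing to rank against", call. = FALSE)
  }
  td <- (target - min(target)) / t_rng
  if (is.null(n_iterations)) n_iterations <- n
  picks <- if (n_iterations >= n) {
    seq_len(n)
  } else {
    local_seed(seed, sample.int(n, n_iterations))
  }
  m <- length(picks)
  n_dc <- 0
  n_da <- numeric(p)
  n_dcda <- numeric(p)
  w_nb <- 1 / k_neighbors
  for (i in picks) {
    d <- rowSums(abs(xs - rep(xs[i, ], each = n)))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k_neighbors)]
    dc <- abs(td[i] - td[nb])
    da <- abs(xs[nb, , drop = FALSE] -
                matrix(xs[i, ], k_neighbors, p, byrow = TRUE))
    n_dc <- n_dc + sum(dc) * w_nb
    n_da <- n_da + colSums(da) * w_nb
    n_dcda <- n_dcda + colSums(da * dc) * w_nb
  }
  if (n_dc == 0 || n_dc >= m) {
    stop("degenerate target differences among neighbours", call. = FALSE)
  }
  w <- n_dcda / n_dc - (n_da - n_dcda) / (m - n_dc)
  w[const] <- 0
  data.frame(feature = colnames(x), weight = w,
             rank = rank(-w, ties.method = "min"),
             stringsAsFactors = FALSE)
}

#' Define binary target classes from a continuous target
#'
#' Tertile-based class definitions: after an equal-frequency 3-group
#' split, depth mode labels the lowest tertile positive (poorly covered
#' amplicons) and uniformity mode labels the highest tertile positive
#' (amplicons with high inter-sample coverage variation).
#'
#' @param values Continuous target (mean coverage or uniformity CV).
#' @param mode `"depth"` or `"uniformity"`.
#' @return Integer 0/1 labels.
#' @export
define_target_classes <- function(values, mode = c("depth", "uniformity")) {
  mode <- match.arg(mode)
  g <- equal_frequency_discretize(values, 3L)
  as.integer(if (mode == "depth") g == 1L else g == 3L)
}

# Rank-statistic AUROC of scores for binary labels (1 = positive).
auroc_score <- function(scores, labels) {
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

stratified_folds <- function(labels, folds, seed) {
  local_seed(seed, {
    assignment <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      assignment[idx] <- rep_len(seq_len(folds), length(idx))
    }
    assignment
  })
}

#' Train and evaluate an RBF-kernel SVM under stratified cross-validation
#'
#' Features are standardized with training-fold statistics only; decision
#' scores of the held-out folds are pooled, AUROC is computed by the rank
#' statistic, its 95% CI by percentile bootstrap over amplicons of the
#' pooled out-of-fold scores, and precision is evaluated at decision
#' threshold 0.
#'
#' @param features Numeric matrix or data.frame (instances x features).
#' @param labels Binary 0/1 labels.
#' @param folds Number of stratified folds (default 3).
#' @param cost SVM cost parameter `C` (default 1).
#' @param gamma RBF kernel width; default `1 / n_features` on the
#'   standardized features.
#' @param n_bootstrap Bootstrap resamples for the AUROC CI (default 1000;
#'   0 skips the CI).
#' @param seed Integer seed controlling folding and bootstrap.
#' @return An object of class `classifier_report`: list with `auroc`,
#'   `auroc_ci`, `precision`, `n_folds`, `seed`, and the pooled
#'   out-of-fold `scores`, `labels`, `fold`.
#' @export
train_eval_svm_rbf <- function(features, labels, folds = 3L, cost = 1,
                               gamma = NULL, n_bootstrap = 1000L, seed = 1L) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) {
    stop("`labels` must be binary 0/1", call. = FALSE)
  }
  if (min(table(labels)) < folds) {
    stop("each class needs at least `folds` members for stratification",
         call. = FALSE)
  }
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  fold <- stratified_folds(labels, folds, seed)
  scores <- numeric(length(labels))
  y <- factor(ifelse(labels == 1L, "pos", "neg"), levels = c("neg", "pos"))
  for (f in seq_len(folds)) {
    tr <- fold != f
    te <- !tr
    if (length(unique(labels[tr])) < 2L || length(unique(labels[te])) < 2L) {
      stop("a fold contains a single class", call. = FALSE)
    }
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2L, stats::sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2L, mu), 2L, sg, "/")
    xte <- sweep(sweep(x[te, , drop = FALSE], 2L, mu), 2L, sg, "/")
    fit <- e1071::svm(xtr, y[tr], kernel = "radial", cost = cost,
                      gamma = gamma, scale = FALSE)
    dv <- attr(stats::predict(fit, xte, decision.values = TRUE),
               "decision.values")
    # libsvm's decision value is positive for the first training label;
    # orient so that higher score means "pos"
    flip <- if (fit$labels[1] == which(levels(y) == "pos")) 1 else -1
    scores[te] <- flip * dv[, 1]
  }
  auc <- auroc_score(scores, labels)
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0L) {
    boot <- local_seed(seed + 1L, {
      vapply(seq_len(n_bootstrap), function(b) {
        repeat {
          idx <- sample.int(length(labels), replace = TRUE)
          if (length(unique(labels[idx])) == 2L) break
        }
        auroc_score(scores[idx], labels[idx])
      }, numeric(1))
    })
    ci <- unname(stats::quantile(boot, c(0.025, 0.975), type = 7))
  }
  pred_pos <- scores > 0
  precision <- if (any(pred_pos)) {
    sum(labels[pred_pos] == 1L) / sum(pred_pos)
  } else {
    NA_real_
  }
  structure(
    list(auroc = auc, auroc_ci = ci, precision = precision,
         n_folds = folds, seed = seed, scores = scores, labels = labels,
         fold = fold),
    class = "classifier_report"
  )
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> AUROC %.3f (95%% CI %.3f-%.3f), precision %.3f, %d folds\n",
              x$auroc, x$auroc_ci[1], x$auroc_ci[2], x$precision, x$n_folds))
  invisible(x)
}

#' Compare two feature sets with a shared cross-validation design
#'
#' Runs [train_eval_svm_rbf()] on both feature sets with identical fold
#' assignments per replicate and reports the mean AUROC difference
#' (combined minus baseline) and the fraction of replicates favouring the
#' combined set.
#'
#' @param features_baseline,features_combined Feature matrices over the
#'   same amplicons.
#' @param labels Shared binary labels.
#' @param replicates Number of replicates with distinct fold seeds.
#' @param seed Integer base seed.
#' @param ... Passed to [train_eval_svm_rbf()].
#' @return A list with `mean_delta`, `frac_positive`, and the per-replicate
#'   `deltas`, `auroc_baseline`, `auroc_combined`.
#' @export
compare_feature_sets <- function(features_baseline, features_combined,
                                 labels, replicates = 20L, seed = 1L, ...) {
  if (nrow(as.matrix(features_baseline)) !=
      nrow(as.matrix(features_combined))) {
    stop("feature sets must cover the same amplicons", call. = FALSE)
  }
  a1 <- numeric(replicates)
  a2 <- numeric(replicates)
  for (r in seq_len(replicates)) {
    s <- seed + r * 1000L
    a1[r] <- train_eval_svm_rbf(features_baseline, labels, seed = s,
                                n_bootstrap = 0L, ...)$auroc
    a2[r] <- train_eval_svm_rbf(features_combined, labels, seed = s,
                                n_bootstrap = 0L, ...)$auroc
  }
  deltas <- a2 - a1
  list(mean_delta = mean(deltas), frac_positive = mean(deltas > 0),
       deltas = deltas, auroc_baseline = a1, auroc_combined = a2)
}
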
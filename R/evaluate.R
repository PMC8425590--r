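#' Degree-normalised length-3 path score (L3 baseline)
#'
#' For a pair `(i, j)`, sums over all intermediate pairs `(x, y)` with edges
#' `i-x`, `x-y`, `y-j` the term `1 / sqrt(deg(x) * deg(y))`. This is the
#' path-of-length-3 link-prediction heuristic used to constrain the negative
#' sampling protocol.
#'
#' @param net an [annotated_network()].
#' @param i,j protein identifiers or indices, `i != j`.
#' @return Non-negative scalar; 0 when no length-3 path exists.
#' @export
l3_score <- function(net, i, j) {
  ii <- as_index(net, i); jj <- as_index(net, j)
  if (ii == jj) stop("i and j must differ")
  l3_matrix(net)[ii, jj]
}

# Full L3 score matrix: A W A with W = A / sqrt(d d^T) (0 where deg = 0).
l3_matrix <- function(net) {
  A <- net$adjacency
  d <- rowSums(A)
  s <- ifelse(d > 0, 1 / sqrt(d), 0)
  W <- A * outer(s, s)
  A %*% W %*% A
}

#' Sample non-interacting protein pairs for evaluation
#'
#' Draws `n_total` distinct non-adjacent pairs of which exactly
#' `n_constrained` contain at least one protein occurring in the `top_n`
#' L3-ranked non-adjacent candidate pairs; the remaining
#' `n_total - n_constrained` pairs avoid those proteins.
#'
#' @param net an [annotated_network()].
#' @param rng_seed integer seed.
#' @param n_total total negatives (default 244).
#' @param n_constrained negatives touching the L3 top list (default 100).
#' @param top_n size of the L3 candidate ranking (default 500).
#' @return Two-column character matrix of protein identifiers.
#' @export
sample_negatives <- function(net, rng_seed = 1L, n_total = 244L,
                             n_constrained = 100L, top_n = 500L) {
  A <- net$adjacency
  n <- nrow(A)
  up <- which(upper.tri(A) & A == 0L, arr.ind = TRUE)
  if (nrow(up) == 0L) stop("network has no non-adjacent pairs")

  L3 <- l3_matrix(net)
  sc <- L3[cbind(up[, 1], up[, 2])]
  pid <- canonical_pair_id(net$proteins[up[, 1]], net$proteins[up[, 2]])
  ord <- order(-sc, pid)
  top <- up[ord[seq_len(min(top_n, nrow(up)))], , drop = FALSE]
  top_proteins <- unique(as.vector(top))

  touches <- up[, 1] %in% top_proteins | up[, 2] %in% top_proteins
  pool_con <- which(touches)
  pool_unc <- which(!touches)
  if (length(pool_con) < n_constrained ||
      length(pool_unc) < n_total - n_constrained)
    stop("infeasible negative sampling: ", length(pool_con),
         " constrained and ", length(pool_unc),
         " unconstrained non-adjacent pairs available, need ",
         n_constrained, " + ", n_total - n_constrained)

  set.seed(rng_seed)
  pick <- c(sample(pool_con, n_constrained),
            sample(pool_unc, n_total - n_constrained))
  cbind(net$proteins[up[pick, 1]], net$proteins[up[pick, 2]])
}

#' Precision, recall and F-measure at a threshold
#'
#' Predicted positive when `probability >= threshold`; degenerate
#' denominators yield 0.
#'
#' @param probabilities numeric vector.
#' @param labels 0/1 vector of the same length.
#' @param threshold decision threshold (default 0.5).
#' @return Named list `precision`, `recall`, `f_measure`.
#' @export
classification_metrics <- function(probabilities, labels, threshold = 0.5) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  pred <- probabilities >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f_measure = f)
}

#' ROC-AUC and PR-AUC of a ranking
#'
#' ROC-AUC uses the Mann-Whitney formulation with mid-rank tie correction.
#' PR-AUC uses the average-precision (step interpolation) convention over
#' distinct score thresholds.
#'
#' @param probabilities numeric scores.
#' @param labels 0/1 vector; both classes must be present.
#' @return Named list `roc_auc`, `pr_auc`.
#' @export
ranking_metrics <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(probabilities, ties.method = "average")
  roc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  ord <- order(-probabilities)
  lab <- labels[ord]
  sc <- probabilities[ord]
  grp_end <- cumsum(rle(sc)$lengths)  # last index of each distinct score
  tp <- cumsum(lab == 1)[grp_end]
  fp <- cumsum(lab == 0)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  drec <- diff(c(0, rec))
  pr <- sum(drec * prec)
  list(roc_auc = roc, pr_auc = pr)
}

#' Five-fold cross-validated evaluation of the full pipeline
#'
#' Positive edges are partitioned into five folds. For each fold the test
#' edges are removed from the training adjacency, the model is refitted,
#' candidate pairs (test positives, negatives and training edges — the
#' latter populate the sliding window with known interactions) are scored
#' and calibrated, and metrics are computed on the test positives versus
#' the negatives. Negatives are drawn once per network and reused across
#' folds.
#'
#' @param net an [annotated_network()].
#' @param K number of modules.
#' @param hyper a [hyperparams()].
#' @param phi decay coefficient.
#' @param rng_seed integer seed (folds, negatives and fits).
#' @param n_folds number of folds (default 5).
#' @param max_interior,half_width scoring/calibration options.
#' @param negatives optional pre-drawn negative pairs (two-column matrix);
#'   drawn with [sample_negatives()] when `NULL`.
#' @param n_negatives,n_constrained,l3_top negative-sampling protocol.
#' @param threshold decision threshold for precision/recall/F.
#' @param folds optional precomputed integer fold assignment per edge.
#' @param max_iter,tol,n_restarts passed to [fit_modules()].
#' @return An object of class `ngpm_eval`: data frame `per_fold`, list
#'   `mean` of the five metrics, `folds`, `negatives`, `threshold`.
#' @export
five_fold_cv <- function(net, K, hyper = hyperparams(K), phi = 1,
                         rng_seed = 1L, n_folds = 5L, max_interior = 3L,
                         half_width = 50L, negatives = NULL,
                         n_negatives = 244L, n_constrained = 100L,
                         l3_top = 500L, threshold = 0.5, folds = NULL,
                         max_iter = 200L, tol = 1e-6, n_restarts = 2L) {
  A <- net$adjacency
  idx <- which(upper.tri(A) & A == 1L, arr.ind = TRUE)
  n_edges <- nrow(idx)
  if (n_edges < n_folds) stop("need at least ", n_folds, " edges")
  seeds <- child_seeds(rng_seed, 3L + n_folds)

  if (is.null(negatives))
    negatives <- sample_negatives(net, seeds[1], n_negatives, n_constrained,
                                  l3_top)
  if (is.null(folds)) {
    set.seed(seeds[2])
    folds <- sample(rep(seq_len(n_folds), length.out = n_edges))
  }

  per_fold <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- idx[folds == f, , drop = FALSE]
    if (nrow(test) == 0L) stop("fold ", f, " has an empty test set")
    Atr <- A
    Atr[test] <- 0L
    Atr[test[, c(2, 1), drop = FALSE]] <- 0L
    train_net <- annotated_network(net$proteins, Atr, net$annotations,
                                   net$catalog)
    fit <- fit_modules(train_net, K, hyper, max_iter = max_iter, tol = tol,
                       n_restarts = n_restarts, rng_seed = seeds[3 + f])
    test_pairs <- cbind(net$proteins[test[, 1]], net$proteins[test[, 2]])
    queries <- rbind(test_pairs, negatives)
    board <- build_scoreboard(train_net, fit$membership, queries, phi,
                              max_interior, half_width)
    pred <- predict_probabilities(board, queries)
    labels <- c(rep(1L, nrow(test_pairs)), rep(0L, nrow(negatives)))
    cls <- classification_metrics(pred$probability, labels, threshold)
    rnk <- ranking_metrics(pred$probability, labels)
    per_fold[[f]] <- data.frame(fold = f, n_test = nrow(test_pairs),
                                precision = cls$precision,
                                recall = cls$recall,
                                f_measure = cls$f_measure,
                                roc_auc = rnk$roc_auc, pr_auc = rnk$pr_auc)
  }
  per_fold <- do.call(rbind, per_fold)
  metric_cols <- c("precision", "recall", "f_measure", "roc_auc", "pr_auc")
  structure(list(per_fold = per_fold,
                 mean = as.list(colMeans(per_fold[metric_cols])),
                 folds = folds, negatives = negatives,
                 threshold = threshold),
            class = "ngpm_eval")
}

#' @export
print.ngpm_eval <- function(x, ...) {
  m <- x$mean
  cat(sprintf(paste0("ngpm_eval (%d folds): precision %.3f  recall %.3f  ",
                     "F %.3f  ROC-AUC %.3f  PR-AUC %.3f\n"),
              nrow(x$per_fold), m$precision, m$recall, m$f_measure,
              m$roc_auc, m$pr_auc))
  invisible(x)
}

#' Sweep the number of modules K
#'
#' Runs [five_fold_cv()] for each value of `K_values` with shared folds and
#' shared negatives, so rows differ only in K.
#'
#' @param net an [annotated_network()].
#' @param K_values integer vector of module counts to try.
#' @param phi,rng_seed,... passed to [five_fold_cv()] (`hyper` is rebuilt per
#'   K with default priors unless supplied through `...` as `zeta` etc.).
#' @return data frame with one row per K: mean metrics plus `K`; attribute
#'   `best` names the best K per metric.
#' @export
k_sweep <- function(net, K_values, phi = 1, rng_seed = 1L, ...) {
  if (length(K_values) == 0L) stop("K_values must be non-empty")
  seeds <- child_seeds(rng_seed, 2L)
  A <- net$adjacency
  n_edges <- sum(A) / 2
  set.seed(seeds[1])
  folds <- sample(rep(seq_len(5L), length.out = n_edges))
  negatives <- NULL
  rows <- lapply(K_values, function(K) {
    ev <- five_fold_cv(net, K, hyperparams(K), phi, rng_seed = seeds[2],
                       folds = folds, negatives = negatives, ...)
    negatives <<- ev$negatives
    data.frame(K = K, precision = ev$mean$precision, recall = ev$mean$recall,
               f_measure = ev$mean$f_measure, roc_auc = ev$mean$roc_auc,
               pr_auc = ev$mean$pr_auc)
  })
  out <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "f_measure", "roc_auc", "pr_auc")
  attr(out, "best") <- vapply(metric_cols,
                              function(m) out$K[which.max(out[[m]])],
                              numeric(1))
  out
}
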
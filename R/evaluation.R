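#' K-nearest-neighbour label transfer accuracy
#'
#' Classifies each test point by majority vote over its k Euclidean nearest
#' training neighbours; vote ties are broken by the candidate class with the
#' smallest mean neighbour distance, then lexicographically. Returns the
#' fraction of test points whose predicted label matches the held-out label.
#'
#' @param E_train,E_test embedding matrices (same number of columns).
#' @param labels_train,labels_test label vectors.
#' @param k neighbour count (default 5).
#' @return Fraction correct in `[0, 1]`.
#' @export
knn_transfer_accuracy <- function(E_train, labels_train, E_test, labels_test,
                                  k = 5L) {
  pred <- knn_predict(E_train, labels_train, E_test, k)
  mean(pred == as.character(labels_test))
}

#' @rdname knn_transfer_accuracy
#' @return `knn_predict` returns the predicted label vector.
#' @export
knn_predict <- function(E_train, labels_train, E_test, k = 5L) {
  E_train <- as.matrix(E_train); E_test <- as.matrix(E_test)
  labels_train <- as.character(labels_train)
  n_tr <- nrow(E_train)
  if (n_tr == 0 || nrow(E_test) == 0) stop("empty inputs")
  if (k > n_tr) stop("k exceeds training size")
  d2 <- sq_dist_cross(E_test, E_train)
  pred <- character(nrow(E_test))
  for (i in seq_len(nrow(E_test))) {
    ord <- order(d2[i, ])[seq_len(k)]
    nb_lab <- labels_train[ord]
    tab <- table(nb_lab)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      mean_d <- vapply(top, function(cl) mean(d2[i, ord[nb_lab == cl]]),
                       numeric(1))
      top <- top[mean_d == min(mean_d)]
      top <- sort(top)[1]
    }
    pred[i] <- top
  }
  pred
}

# internal: squared Euclidean cross-distance matrix (rows of A vs rows of B)
sq_dist_cross <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

#' Alignment (mixing) score
#'
#' Measures how well conditions are mixed in an embedding. Every condition
#' is downsampled to the smallest condition's size; for each cell, x_i
#' counts how many of its k nearest neighbours (self excluded) come from its
#' own condition. The score is `1 - (mean(x) - k/N_c) / (k - k/N_c)` with
#' `N_c` the number of conditions, clipped to `[0, 1]`: 1 when neighbourhoods
#' are as mixed as random labelling, 0 when every neighbourhood is purely
#' same-condition.
#'
#' @param E embedding matrix.
#' @param condition_of per-cell condition labels.
#' @param k neighbour count; default `max(10, round(0.01 * n))` on the
#'   downsampled total n.
#' @param seed seed for the downsampling.
#' @return Score in `[0, 1]`.
#' @export
alignment_score <- function(E, condition_of, k = NULL, seed = 1L) {
  E <- as.matrix(E)
  condition_of <- as.character(condition_of)
  conds <- sort(unique(condition_of))
  if (length(conds) < 2) stop("need at least 2 conditions")
  n_min <- min(table(condition_of))
  keep <- withr::with_seed(seed, {
    unlist(lapply(conds, function(cn) {
      i <- which(condition_of == cn)
      if (length(i) > n_min) sample(i, n_min) else i
    }))
  })
  Es <- E[keep, , drop = FALSE]
  cs <- condition_of[keep]
  n <- nrow(Es)
  if (is.null(k)) k <- max(10L, round(0.01 * n))
  if (k >= n) stop("k must be smaller than the downsampled total")
  d2 <- sq_dist_cross(Es, Es)
  diag(d2) <- Inf
  same <- numeric(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]
    same[i] <- sum(cs[nb] == cs[i])
  }
  n_c <- length(conds)
  expected <- k / n_c
  score <- 1 - (mean(same) - expected) / (k - expected)
  min(max(score, 0), 1)
}

#' Composite alignment accuracy
#'
#' Cross-condition label-transfer accuracy multiplied by the alignment
#' score. In pairwise mode, a KNN classifier trained on the control
#' condition's embeddings labels all other cells. In multiway mode, each
#' condition in turn serves as the representative that labels all remaining
#' conditions, and the mean of those accuracies is used.
#'
#' @param E embedding matrix for all cells.
#' @param condition_of per-cell condition labels.
#' @param type_of per-cell type labels (must be complete for the training
#'   role; `"unlabeled"` test cells are dropped from accuracy).
#' @param mode `"pairwise"` or `"multiway"`.
#' @param control control / reference condition name for pairwise mode
#'   (default: first condition in sorted order).
#' @param k KNN neighbour count.
#' @param align_k,seed passed to [alignment_score()].
#' @return List of class `evaluation_report`: `label_accuracy`,
#'   `alignment_score`, `composite` (their product), `per_class_accuracy`,
#'   and `params`.
#' @export
composite_accuracy <- function(E, condition_of, type_of,
                               mode = c("pairwise", "multiway"),
                               control = NULL, k = 5L, align_k = NULL,
                               seed = 1L) {
  mode <- match.arg(mode)
  E <- as.matrix(E)
  condition_of <- as.character(condition_of)
  type_of <- as.character(type_of)
  conds <- sort(unique(condition_of))
  one_sweep <- function(rep_cond) {
    tr <- which(condition_of == rep_cond)
    te <- which(condition_of != rep_cond & type_of != UNLABELED)
    if (any(type_of[tr] == UNLABELED))
      stop("training condition '", rep_cond, "' has unlabeled cells")
    pred <- knn_predict(E[tr, , drop = FALSE], type_of[tr],
                        E[te, , drop = FALSE], k)
    list(acc = mean(pred == type_of[te]), pred = pred, truth = type_of[te])
  }
  if (mode == "pairwise") {
    if (is.null(control)) control <- conds[1]
    sw <- one_sweep(control)
    acc <- sw$acc
    per_class <- vapply(sort(unique(sw$truth)), function(cl)
      mean(sw$pred[sw$truth == cl] == cl), numeric(1))
  } else {
    sweeps <- lapply(conds, one_sweep)
    acc <- mean(vapply(sweeps, `[[`, numeric(1), "acc"))
    truth <- unlist(lapply(sweeps, `[[`, "truth"))
    pred <- unlist(lapply(sweeps, `[[`, "pred"))
    per_class <- vapply(sort(unique(truth)), function(cl)
      mean(pred[truth == cl] == cl), numeric(1))
  }
  asc <- alignment_score(E, condition_of, k = align_k, seed = seed)
  structure(list(label_accuracy = acc, alignment_score = asc,
                 composite = acc * asc, per_class_accuracy = per_class,
                 params = list(k_neighbors = k, align_k = align_k,
                               seed = seed, mode = mode, control = control)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("label accuracy:  %.4f\nalignment score: %.4f\ncomposite:       %.4f\n",
              x$label_accuracy, x$alignment_score, x$composite))
  invisible(x)
}

#' Interpolation accuracy (10-fold cross-validation)
#'
#' Per fold, a KNN classifier is trained on 90% of the real expression
#' matrix; it is scored (a) on the held-out 10% of real cells and (b) on all
#' interpolated cells. Both accuracies are averaged over the folds. An
#' interpolation that preserves cell identity scores close to the
#' expression cross-validation accuracy.
#'
#' @param expression cells x genes matrix of real expression.
#' @param labels labels for the real cells.
#' @param interpolated cells x genes matrix of interpolated expression in
#'   the same gene space.
#' @param interpolated_labels labels of the interpolated cells.
#' @param k KNN neighbour count.
#' @param folds number of folds (default 10).
#' @param seed fold-assignment seed.
#' @return List with `expression_accuracy` and `interpolation_accuracy`.
#' @export
interpolation_accuracy <- function(expression, labels, interpolated,
                                   interpolated_labels, k = 5L,
                                   folds = 10L, seed = 1L) {
  expression <- as.matrix(expression)
  interpolated <- as.matrix(interpolated)
  if (ncol(expression) != ncol(interpolated))
    stop("expression and interpolated matrices must share the gene space")
  n <- nrow(expression)
  if (n < folds) stop("fewer cells than folds")
  fold_of <- withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
  acc_expr <- acc_interp <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    acc_expr[f] <- knn_transfer_accuracy(
      expression[tr, , drop = FALSE], labels[tr],
      expression[te, , drop = FALSE], labels[te], k)
    acc_interp[f] <- knn_transfer_accuracy(
      expression[tr, , drop = FALSE], labels[tr],
      interpolated, interpolated_labels, k)
  }
  list(expression_accuracy = mean(acc_expr),
       interpolation_accuracy = mean(acc_interp))
}

#' Area under the ROC curve for a score-based ranking
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a randomly chosen
#' positive outranks a randomly chosen negative, with ties counted 1/2.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector marking the positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("need both positives and negatives")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean silhouette coefficient
#'
#' Standard mean silhouette width with Euclidean distance. A cell in a
#' singleton class has silhouette 0 (with a warning).
#'
#' @param E embedding matrix.
#' @param labels class labels (at least 2 classes).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_coefficient <- function(E, labels) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 classes")
  if (any(table(labels) < 2))
    warning("singleton class(es); their silhouette is defined as 0")
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dist(as.matrix(E)))
  mean(sil[, "sil_width"])
}
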
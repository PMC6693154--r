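#' TP10K library-size normalisation
#'
#' Scales every cell's counts so they sum to 10,000, removing library-size
#' differences between cells.
#'
#' @param ds an `expression_dataset` in the `counts` layer.
#' @return The dataset in the `tp10k` layer.
#' @export
tp10k_normalize <- function(ds) {
  check_layer(ds, "counts")
  totals <- rowSums(ds$values)
  if (any(totals <= 0))
    stop("all-zero cell(s): ", paste(ds$cell_ids[totals <= 0], collapse = ", "))
  out <- ds
  out$values <- ds$values * (10000 / totals)
  out$layer <- "tp10k"
  out
}

#' Natural-log transform, log(1 + x)
#'
#' @param ds an `expression_dataset` in the `tp10k` layer.
#' @return The dataset in the `log` layer.
#' @export
log1p_transform <- function(ds) {
  check_layer(ds, "tp10k")
  if (any(ds$values < 0)) stop("negative values cannot be log-transformed")
  out <- ds
  out$values <- log1p(ds$values)
  out$layer <- "log"
  out
}

#' Per-gene scaling and centring
#'
#' Z-scores every feature using the population (divide-by-n) standard
#' deviation. Zero-variance features become all-zero columns rather than
#' NaN.
#'
#' @param ds an `expression_dataset` in the `log` layer.
#' @return The dataset in the `scaled` layer.
#' @export
scale_center <- function(ds) {
  check_layer(ds, c("log", "scaled"))
  x <- ds$values
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  sd_pop <- sqrt(colMeans(xc^2))
  keep <- sd_pop > 0
  xc[, keep] <- sweep(xc[, keep, drop = FALSE], 2, sd_pop[keep], "/")
  xc[, !keep] <- 0
  out <- ds
  out$values <- xc
  out$layer <- "scaled"
  out
}

#' Select highly variable genes per condition
#'
#' Within each condition, features are ranked by their variance on the log
#' layer; the union of the per-condition top-k sets is kept (the conventional
#' union-of-top-3000 selection). Feature order is preserved.
#'
#' @param ds an `expression_dataset` in the `log` or `scaled` layer. When the
#'   layer is `scaled`, variances are still computed on `log_values` if
#'   supplied, otherwise on the scaled values with a warning-free fallback is
#'   not attempted: pass the log-layer dataset via `log_ds`.
#' @param per_condition_top_k number of top-variance features per condition.
#' @param log_ds optional log-layer dataset to rank variances on when `ds`
#'   is already scaled (same features, same cells).
#' @return The dataset restricted to the selected features.
#' @export
select_variable_genes <- function(ds, per_condition_top_k, log_ds = NULL) {
  check_layer(ds, c("log", "scaled"))
  stopifnot(per_condition_top_k >= 1)
  rank_on <- if (ds$layer == "log") ds else {
    if (is.null(log_ds)) ds else {
      check_layer(log_ds, "log")
      stopifnot(identical(log_ds$feature_ids, ds$feature_ids))
      log_ds
    }
  }
  k <- per_condition_top_k
  nf <- length(ds$feature_ids)
  if (k > nf) {
    warning("per_condition_top_k (", k, ") exceeds feature count (", nf,
            "); keeping all features")
    k <- nf
  }
  keep <- logical(nf)
  for (cond in conditions_of(ds)) {
    sub <- rank_on$values[rank_on$condition_of == cond, , drop = FALSE]
    v <- apply(sub, 2, stats::var)
    keep[order(v, decreasing = TRUE)[seq_len(k)]] <- TRUE
  }
  subset_cells(ds, features = which(keep))
}

#' PCA reduction of the pooled scaled matrix
#'
#' Computes an exact SVD of the pooled (all conditions) scaled matrix and
#' returns the component scores in place of gene expression. Component sign
#' is fixed so the largest-magnitude loading of each component is positive,
#' making results reproducible across platforms.
#'
#' @param ds an `expression_dataset` in the `scaled` layer.
#' @param n_components number of components to keep.
#' @param seed unused by the exact solver; kept for interface stability.
#' @return A list with `dataset` (layer `pca`, cells x n_components scores)
#'   and `basis` (a list with `rotation` features x components, `center`,
#'   and `feature_ids`) for projecting new or perturbed expression.
#' @export
pca_reduce <- function(ds, n_components, seed = 1L) {
  check_layer(ds, "scaled")
  if (n_components <= 0) stop("n_components must be positive")
  n_components <- as.integer(n_components)
  if (n_components > min(dim(ds$values)))
    stop("n_components exceeds min(cells, features)")
  x <- ds$values
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  sv <- svd(xc, nu = n_components, nv = n_components)
  rot <- sv$v
  # sign convention: largest |loading| per component positive
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) {
      rot[, j] <- -rot[, j]
      sv$u[, j] <- -sv$u[, j]
    }
  }
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  dimnames(scores) <- list(ds$cell_ids, paste0("PC", seq_len(n_components)))
  dimnames(rot) <- list(ds$feature_ids, colnames(scores))
  out <- expression_dataset(scores, condition_of = ds$condition_of,
                            type_of = ds$type_of, layer = "pca")
  basis <- list(rotation = rot, center = center, feature_ids = ds$feature_ids)
  list(dataset = out, basis = basis)
}

#' Project an expression matrix onto a stored PCA basis
#'
#' @param values cells x features matrix in the same feature space and
#'   processing layer the basis was computed on.
#' @param basis the `basis` element returned by [pca_reduce()].
#' @return cells x components score matrix.
#' @export
pca_project <- function(values, basis) {
  stopifnot(ncol(values) == length(basis$center))
  sweep(values, 2, basis$center) %*% basis$rotation
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: counts -> TP10K -> log1p -> (HVG selection) ->
#' scale/centre -> (PCA).
#'
#' @param ds counts-layer dataset.
#' @param hvg_k per-condition top-k for variable-gene selection
#'   (`NULL` keeps all genes).
#' @param pca_dims number of principal components (`NULL` skips PCA).
#' @return A list with `dataset` (the encoder input), `expression` (the
#'   scaled gene-space dataset, identical to `dataset` when PCA is skipped)
#'   and `basis` (PCA basis or `NULL`).
#' @export
preprocess_chain <- function(ds, hvg_k = NULL, pca_dims = NULL) {
  lg <- log1p_transform(tp10k_normalize(ds))
  if (!is.null(hvg_k)) lg <- select_variable_genes(lg, hvg_k)
  sc <- scale_center(lg)
  if (is.null(pca_dims))
    return(list(dataset = sc, expression = sc, basis = NULL))
  pc <- pca_reduce(sc, pca_dims)
  list(dataset = pc$dataset, expression = sc, basis = pc$basis)
}
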
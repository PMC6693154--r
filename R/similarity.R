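#' Pairwise squared Euclidean distances
#'
#' @param X numeric matrix, n x d (rows are cells).
#' @return Symmetric n x n matrix with zero diagonal; entry (i, k) is
#'   `||x_i - x_k||^2`.
#' @export
squared_distances <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 rows")
  sq <- rowSums(X^2)
  d2 <- add_cols(-2 * tcrossprod(X), sq) + sq
  d2[d2 < 0] <- 0          # numerical negatives
  diag(d2) <- 0
  0.5 * (d2 + t(d2))       # enforce exact symmetry
}

#' Calibrate a Gaussian kernel bandwidth to a target perplexity
#'
#' Binary search on the per-cell bandwidth sigma^2 so that the entropy of the
#' normalised Gaussian kernel over the cell's neighbours (self excluded)
#' satisfies 2^H = perplexity. This is the same calibration tSNE uses to set
#' each cell's effective neighbourhood size.
#'
#' @param d2_row squared distances from one cell to the other n-1 cells.
#' @param perplexity target perplexity (effective neighbour count); clamped
#'   to n-1 with a warning when unreachable.
#' @param tol convergence tolerance on log2 perplexity.
#' @param max_iter maximum bisection steps.
#' @return List with `sigma_sq` and `q_row` (probability vector over the
#'   n-1 neighbours).
#' @export
calibrate_bandwidth <- function(d2_row, perplexity = 30, tol = 1e-3,
                                max_iter = 50L) {
  stopifnot(all(is.finite(d2_row)), length(d2_row) >= 1)
  n1 <- length(d2_row)
  if (perplexity > n1) {
    warning("perplexity ", perplexity, " unreachable with ", n1,
            " neighbours; clamped to ", n1)
    perplexity <- n1
  }
  res <- calibrate_rows(matrix(d2_row, nrow = 1), perplexity, tol, max_iter)
  list(sigma_sq = res$sigma_sq[1], q_row = res$probs[1, ])
}

# internal: vectorised row-wise bandwidth calibration.
# d2 is an n x m matrix of squared distances (self column already removed or
# handled by the caller via `exclude` diagonal masking). Returns row-wise
# sigma^2 and row-stochastic probabilities.
calibrate_rows <- function(d2, perplexity, tol = 1e-3, max_iter = 50L,
                           exclude_diag = FALSE) {
  n <- nrow(d2)
  target <- log2(perplexity)
  lo <- rep(1e-12, n); hi <- rep(1e12, n)
  sig <- rep(1, n)
  probs <- matrix(0, n, ncol(d2))
  diag_col <- if (exclude_diag) seq_len(n) else rep(0L, n)
  active <- seq_len(n)
  # subtract each row's smallest non-self distance before exponentiating;
  # the normalised kernel and its entropy are invariant to the shift and
  # the weights cannot all underflow at small sigma^2
  d2s <- d2
  if (exclude_diag) diag(d2s) <- Inf
  row_min <- d2s[cbind(seq_len(n), max.col(-d2s, ties.method = "first"))]
  d2s <- d2 - row_min
  for (it in seq_len(max_iter)) {
    da <- d2s[active, , drop = FALSE]
    w <- exp(-0.5 * da / sig[active])
    if (exclude_diag)
      w[cbind(seq_along(active), diag_col[active])] <- 0
    rs <- rowSums(w)
    degenerate <- rs <= 0 | !is.finite(rs)
    if (any(degenerate)) {
      nn <- ncol(d2) - exclude_diag
      w[degenerate, ] <- 1 / nn
      if (exclude_diag)
        w[cbind(seq_along(active), diag_col[active])] <- 0
      rs[degenerate] <- rowSums(w[degenerate, , drop = FALSE])
    }
    p <- w / rs
    # entropy via H = 0.5/sigma^2 * E[d2] + log(normaliser); avoids
    # elementwise logs (diagonal contributes nothing since p there is 0)
    H <- (0.5 / sig[active] * rowSums(p * da) + log(rs)) / log(2)
    H[degenerate] <- log2(ncol(d2) - exclude_diag)
    err <- H - target
    probs[active, ] <- p
    done <- abs(err) <= tol
    if (all(done)) break
    rem <- active[!done]
    err <- err[!done]
    # entropy increases with sigma^2: too high -> shrink, too low -> grow
    hi[rem[err > 0]] <- sig[rem[err > 0]]
    lo[rem[err < 0]] <- sig[rem[err < 0]]
    sig[rem] <- sqrt(lo[rem] * hi[rem])   # geometric bisection
    active <- rem
  }
  list(sigma_sq = sig, probs = probs)
}

#' Within-condition expression-space transition matrix
#'
#' Builds the row-stochastic cell-cell similarity matrix Q for one condition
#' (or one mini-batch of one condition): a Gaussian kernel on squared
#' Euclidean distances with a per-cell bandwidth calibrated to the target
#' perplexity, zero diagonal (a cell never transitions to itself), each row
#' normalised to sum to one. Rows whose neighbours are all at identical
#' distance fall back to the uniform distribution over non-self cells.
#'
#' @param X cells x features matrix for one condition / mini-batch.
#' @param perplexity target perplexity (default 30).
#' @param tol,max_iter calibration controls, see [calibrate_bandwidth()].
#' @param cell_index optional ids for the rows.
#' @return An object of class `condition_kernel` with elements `probs`
#'   (n x n, zero diagonal, row-stochastic), `sigma_sq`, `perplexity_target`
#'   and `cell_index`.
#' @export
expression_transition_matrix <- function(X, perplexity = 30, tol = 1e-3,
                                         max_iter = 50L, cell_index = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop("need at least 3 cells")
  if (perplexity > n - 1) {
    warning("perplexity ", perplexity, " unreachable with ", n,
            " cells; clamped to ", n - 1)
    perplexity <- n - 1
  }
  d2 <- squared_distances(X)
  res <- calibrate_rows(d2, perplexity, tol, max_iter, exclude_diag = TRUE)
  probs <- res$probs
  diag(probs) <- 0
  probs <- probs / rowSums(probs)
  if (is.null(cell_index)) cell_index <- rownames(X)
  structure(list(probs = probs, sigma_sq = res$sigma_sq,
                 perplexity_target = perplexity, cell_index = cell_index),
            class = "condition_kernel")
}

#' Achieved perplexity of each kernel row
#'
#' @param kernel a `condition_kernel`.
#' @return Numeric vector, 2^H of each row (H in bits).
#' @export
row_perplexity <- function(kernel) {
  p <- kernel$probs
  lp <- p
  lp[p > 0] <- log2(p[p > 0])
  2^(-rowSums(p * lp))
}
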
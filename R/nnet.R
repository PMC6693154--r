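# Internal multilayer-perceptron engine used by the encoder, the decoders
# and the shared-autoencoder baseline. Hidden layers are
# affine -> batch-norm -> ReLU -> (inverted) dropout; the output layer is a
# plain affine map. Gradients are exact analytic backprop; optimisation is
# Adam. Everything is plain base-R matrix algebra (BLAS does the heavy
# lifting at the batch sizes involved).

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9   # running = m*running + (1-m)*batch

# Xavier/Glorot uniform init for a fan_in x fan_out weight matrix
xavier_init <- function(fan_in, fan_out) {
  a <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -a, a), fan_in, fan_out)
}

# Build an MLP: input_dim -> hidden_sizes -> output_dim.
# Draws weights from the current RNG state (callers seed).
mlp_new <- function(input_dim, hidden_sizes, output_dim,
                    batch_norm = TRUE, dropout_rate = 0.3) {
  sizes <- c(input_dim, hidden_sizes, output_dim)
  n_layer <- length(sizes) - 1L
  layers <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    d_in <- sizes[l]; d_out <- sizes[l + 1]
    hidden <- l < n_layer
    layers[[l]] <- list(
      W = xavier_init(d_in, d_out),
      b = numeric(d_out),
      hidden = hidden,
      bn = if (hidden && batch_norm)
        list(gamma = rep(1, d_out), beta = numeric(d_out),
             running_mean = numeric(d_out), running_var = rep(1, d_out))
      else NULL)
  }
  structure(list(layers = layers, input_dim = input_dim,
                 hidden_sizes = hidden_sizes, output_dim = output_dim,
                 batch_norm = batch_norm, dropout_rate = dropout_rate),
            class = "walkalign_mlp")
}

# Forward pass. training=TRUE uses batch statistics for batch-norm, updates
# running averages in the returned net, and applies dropout (masks drawn
# from the current RNG unless supplied). Returns list(out, cache, net).
mlp_forward <- function(net, X, training = FALSE, dropout_masks = NULL) {
  n <- nrow(X)
  caches <- vector("list", length(net$layers))
  A <- X
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    Z <- add_cols(A %*% ly$W, ly$b)
    cache <- list(A_in = A)
    if (ly$hidden) {
      if (!is.null(ly$bn)) {
        if (training) {
          mu <- colMeans(Z)
          Zc <- add_cols(Z, -mu)
          v <- colMeans(Zc^2)
          inv_sd <- 1 / sqrt(v + BN_EPS)
          Xhat <- mul_cols(Zc, inv_sd)
          ly$bn$running_mean <- BN_MOMENTUM * ly$bn$running_mean +
            (1 - BN_MOMENTUM) * mu
          ly$bn$running_var <- BN_MOMENTUM * ly$bn$running_var +
            (1 - BN_MOMENTUM) * v
          net$layers[[l]]$bn <- ly$bn
        } else {
          inv_sd <- 1 / sqrt(ly$bn$running_var + BN_EPS)
          Xhat <- mul_cols(add_cols(Z, -ly$bn$running_mean), inv_sd)
        }
        H <- add_cols(mul_cols(Xhat, ly$bn$gamma), ly$bn$beta)
        cache$Xhat <- Xhat; cache$inv_sd <- inv_sd
      } else H <- Z
      R <- pmax(H, 0)
      cache$relu_mask <- H > 0
      if (training && net$dropout_rate > 0) {
        keep <- 1 - net$dropout_rate
        mask <- if (!is.null(dropout_masks)) dropout_masks[[l]] else
          matrix(stats::rbinom(length(R), 1, keep), nrow(R), ncol(R)) / keep
        A <- R * mask
        cache$drop_mask <- mask
      } else A <- R
    } else A <- Z
    caches[[l]] <- cache
  }
  list(out = A, cache = caches, net = net)
}

# Backward pass: dOut is dLoss/d(output). Returns list(grads, dX); grads[[l]]
# has dW, db and (for batch-norm layers) dgamma, dbeta. `training` must match
# the forward call that produced `cache`.
mlp_backward <- function(net, cache, dOut, training = TRUE) {
  grads <- vector("list", length(net$layers))
  dA <- dOut
  for (l in rev(seq_along(net$layers))) {
    ly <- net$layers[[l]]
    cc <- cache[[l]]
    if (ly$hidden) {
      if (!is.null(cc$drop_mask)) dA <- dA * cc$drop_mask
      dH <- dA * cc$relu_mask
      if (!is.null(ly$bn)) {
        n <- nrow(dH)
        dgamma <- colSums(dH * cc$Xhat)
        dbeta <- colSums(dH)
        dXhat <- mul_cols(dH, ly$bn$gamma)
        if (training) {
          # full batch-norm backward through batch statistics
          s1 <- colSums(dXhat)
          s2 <- colSums(dXhat * cc$Xhat)
          dZ <- add_cols(dXhat, -s1 / n) - mul_cols(cc$Xhat, s2 / n)
          dZ <- mul_cols(dZ, cc$inv_sd)
        } else {
          dZ <- mul_cols(dXhat, cc$inv_sd)
        }
        grads[[l]] <- list(dgamma = dgamma, dbeta = dbeta)
      } else dZ <- dH
    } else dZ <- dA
    gl <- grads[[l]]
    gl$dW <- crossprod(cc$A_in, dZ)
    gl$db <- colSums(dZ)
    grads[[l]] <- gl
    dA <- tcrossprod(dZ, ly$W)
  }
  list(grads = grads, dX = dA)
}

# Sum of squared Frobenius norms of the weight matrices (biases and
# batch-norm parameters excluded)
mlp_ridge <- function(net) sum(vapply(net$layers,
                                      function(l) sum(l$W^2), numeric(1)))

# Add the ridge gradient 2*lambda*W to existing grads
add_ridge_grad <- function(grads, net, lambda) {
  if (lambda == 0) return(grads)
  for (l in seq_along(net$layers))
    grads[[l]]$dW <- grads[[l]]$dW + 2 * lambda * net$layers[[l]]$W
  grads
}

## ---- Adam optimiser ---------------------------------------------------

ADAM_B1 <- 0.9
ADAM_B2 <- 0.999
ADAM_EPS <- 1e-8

adam_init_like <- function(params) {
  lapply(params, function(p) {
    z <- p; z[] <- 0
    list(m = z, v = z)
  })
}

# One Adam update for a flat named list of arrays; state mirrors params.
adam_update <- function(params, grads, state, lr, t) {
  for (k in seq_along(params)) {
    g <- grads[[k]]
    st <- state[[k]]
    st$m <- ADAM_B1 * st$m + (1 - ADAM_B1) * g
    st$v <- ADAM_B2 * st$v + (1 - ADAM_B2) * g^2
    mhat <- st$m / (1 - ADAM_B1^t)
    vhat <- st$v / (1 - ADAM_B2^t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + ADAM_EPS)
    state[[k]] <- st
  }
  list(params = params, state = state)
}

# Flatten a net's trainable parameters into a named list (order stable),
# and write them back. Used by the optimiser and by gradient checks.
mlp_params <- function(net) {
  out <- list()
  for (l in seq_along(net$layers)) {
    ly <- net$layers[[l]]
    out[[paste0("L", l, ".W")]] <- ly$W
    out[[paste0("L", l, ".b")]] <- ly$b
    if (!is.null(ly$bn)) {
      out[[paste0("L", l, ".gamma")]] <- ly$bn$gamma
      out[[paste0("L", l, ".beta")]] <- ly$bn$beta
    }
  }
  out
}

mlp_set_params <- function(net, params) {
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W <- params[[paste0("L", l, ".W")]]
    net$layers[[l]]$b <- params[[paste0("L", l, ".b")]]
    if (!is.null(net$layers[[l]]$bn)) {
      net$layers[[l]]$bn$gamma <- params[[paste0("L", l, ".gamma")]]
      net$layers[[l]]$bn$beta <- params[[paste0("L", l, ".beta")]]
    }
  }
  net
}

mlp_grads_flat <- function(net, grads) {
  out <- list()
  for (l in seq_along(net$layers)) {
    out[[paste0("L", l, ".W")]] <- grads[[l]]$dW
    out[[paste0("L", l, ".b")]] <- grads[[l]]$db
    if (!is.null(net$layers[[l]]$bn)) {
      out[[paste0("L", l, ".gamma")]] <- grads[[l]]$dgamma
      out[[paste0("L", l, ".beta")]] <- grads[[l]]$dbeta
    }
  }
  out
}

# Row-wise softmax with max-subtraction overflow guard
softmax_rows <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  E / rowSums(E)
}

# fast column-vector broadcast helpers (avoid sweep's overhead)
add_cols <- function(M, v) M + rep(v, each = nrow(M))
mul_cols <- function(M, v) M * rep(v, each = nrow(M))
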
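#' Encoder / training configuration
#'
#' Collects every tunable of the alignment procedure. Defaults follow the
#' method's standard settings: a three-hidden-layer encoder (512, 256, 128),
#' a 32-dimensional embedding (64 once three or more conditions are aligned),
#' batch normalisation and 30% dropout on hidden layers, ridge penalty
#' 1e-4 on the weight matrices, Adam with learning rate 1e-4 for 15,000
#' steps, per-condition mini-batches of 150 cells, and kernel perplexity 30.
#'
#' @param hidden_sizes integer vector of hidden-layer widths.
#' @param embedding_dim embedding dimension K; if `NULL`, 32 for two
#'   conditions and 64 for three or more (resolved at training time).
#' @param dropout_rate hidden-layer dropout rate in `[0, 1)`.
#' @param batch_norm use batch normalisation on hidden layers.
#' @param lambda ridge penalty on weight matrices (biases excluded).
#' @param learning_rate Adam learning rate.
#' @param max_steps number of Adam updates.
#' @param batch_size per-condition mini-batch size.
#' @param perplexity target perplexity of the expression-space kernel.
#' @param alpha weight of the walker (alignment) loss.
#' @param beta weight of the classifier loss when labels are supplied.
#' @param mode `"pairwise"`, `"all_pairs"` or `"reference"`; `NULL` selects
#'   pairwise for two conditions and all_pairs otherwise.
#' @param reference_condition reference condition name (mode `"reference"`).
#' @param classifier_backprop_encoder whether classifier gradients flow into
#'   the encoder (joint training) or stop at the head.
#' @param seed integer seed controlling initialisation, batching and dropout.
#' @return An object of class `encoder_config`.
#' @export
encoder_config <- function(hidden_sizes = c(512L, 256L, 128L),
                           embedding_dim = NULL,
                           dropout_rate = 0.3,
                           batch_norm = TRUE,
                           lambda = 1e-4,
                           learning_rate = 1e-4,
                           max_steps = 15000L,
                           batch_size = 150L,
                           perplexity = 30,
                           alpha = 1.0,
                           beta = 1.0,
                           mode = NULL,
                           reference_condition = NULL,
                           classifier_backprop_encoder = TRUE,
                           seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1,
            lambda >= 0, learning_rate > 0, max_steps >= 0,
            batch_size >= 1, perplexity > 0, alpha >= 0, beta >= 0)
  if (!is.null(mode))
    mode <- match.arg(mode, c("pairwise", "all_pairs", "reference"))
  if (!is.null(mode) && mode == "reference" && is.null(reference_condition))
    stop("mode 'reference' needs reference_condition")
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 embedding_dim = if (is.null(embedding_dim)) NULL
                 else as.integer(embedding_dim),
                 dropout_rate = dropout_rate, batch_norm = batch_norm,
                 lambda = lambda, learning_rate = learning_rate,
                 max_steps = as.integer(max_steps),
                 batch_size = as.integer(batch_size),
                 perplexity = perplexity, alpha = alpha, beta = beta,
                 mode = mode, reference_condition = reference_condition,
                 classifier_backprop_encoder = classifier_backprop_encoder,
                 seed = as.integer(seed)),
            class = "encoder_config")
}

#' Build a fresh (untrained) alignment model
#'
#' Hidden layers are affine -> batch-norm -> ReLU -> dropout; the embedding
#' layer is a plain affine map (linear activation). Weights are
#' Xavier-initialised from `config$seed`.
#'
#' @param input_dim number of input features the encoder consumes.
#' @param config an [encoder_config()].
#' @param class_names optional class names; when given, a linear classifier
#'   head from the embedding to the classes is attached.
#' @param n_conditions used to resolve the default embedding dimension.
#' @return An object of class `alignment_model`.
#' @export
build_encoder <- function(input_dim, config = encoder_config(),
                          class_names = NULL, n_conditions = 2L) {
  stopifnot(input_dim >= 1)
  K <- if (!is.null(config$embedding_dim)) config$embedding_dim
  else if (n_conditions >= 3) 64L else 32L
  model <- withr::with_seed(config$seed, {
    net <- mlp_new(input_dim, config$hidden_sizes, K,
                   batch_norm = config$batch_norm,
                   dropout_rate = config$dropout_rate)
    classifier <- if (!is.null(class_names))
      list(W = xavier_init(K, length(class_names)),
           b = numeric(length(class_names)),
           class_names = class_names)
    list(net = net, classifier = classifier)
  })
  structure(list(net = model$net, classifier = model$classifier,
                 config = config, input_dim = as.integer(input_dim),
                 embedding_dim = K, loss_trace = NULL, projection = NULL,
                 feature_ids = NULL),
            class = "alignment_model")
}

#' @export
print.alignment_model <- function(x, ...) {
  cat("alignment_model: ", x$input_dim, " -> ",
      paste(x$config$hidden_sizes, collapse = " -> "), " -> ",
      x$embedding_dim, "\n", sep = "")
  if (!is.null(x$classifier))
    cat("classifier head over: ",
        paste(x$classifier$class_names, collapse = ", "), "\n", sep = "")
  if (!is.null(x$loss_trace))
    cat("trained ", nrow(x$loss_trace), " steps; final loss ",
        signif(utils::tail(x$loss_trace$total, 1), 5), "\n", sep = "")
  invisible(x)
}

#' Embedding-space random-walk transition matrices
#'
#' Forward and backward one-step transition probabilities between two sets of
#' embeddings, obtained by row-wise softmax over embedding dot products, plus
#' the two round-trip (two-step) transition matrices.
#'
#' @param E_s m x K embeddings of the walk-originating condition.
#' @param E_t n x K embeddings of the other condition.
#' @return A list of class `transition_set` with `P_fwd` (m x n), `P_bwd`
#'   (n x m), `P_round_s` (`P_fwd %*% P_bwd`, m x m) and `P_round_t`
#'   (`P_bwd %*% P_fwd`, n x n); every row of every matrix sums to one.
#' @export
embedding_transitions <- function(E_s, E_t) {
  E_s <- as.matrix(E_s); E_t <- as.matrix(E_t)
  if (ncol(E_s) != ncol(E_t)) stop("embedding dimensions differ")
  Z <- tcrossprod(E_s, E_t)          # m x n dot products
  P_fwd <- softmax_rows(Z)
  P_bwd <- softmax_rows(t(Z))
  structure(list(P_fwd = P_fwd, P_bwd = P_bwd,
                 P_round_s = P_fwd %*% P_bwd,
                 P_round_t = P_bwd %*% P_fwd),
            class = "transition_set")
}

LOG_CLAMP <- 1e-30

# cross-entropy of target rows q against model rows p, -sum q log p, with
# log clamped at LOG_CLAMP; returns per-row vector
ce_rows <- function(Q, P) {
  -rowSums(Q * log(pmax(P, LOG_CLAMP)))
}

#' Round-trip random-walk objective
#'
#' The alignment loss for one condition pair: the mean cross-entropy between
#' each condition's expression-space kernel rows (zero diagonal) and the
#' corresponding round-trip walk landing distributions. Because the kernel
#' assigns no mass to the starting cell, the round trip's self-return
#' probability receives no target mass but still competes for row mass,
#' implicitly penalising walks that return to their origin.
#'
#' @param kernel_s,kernel_t `condition_kernel` objects for the two
#'   mini-batches.
#' @param trans a `transition_set` from [embedding_transitions()].
#' @return List with `loss` and the per-condition terms `term_s`, `term_t`.
#' @export
walker_objective <- function(kernel_s, kernel_t, trans) {
  Qs <- kernel_s$probs; Qt <- kernel_t$probs
  if (nrow(Qs) != nrow(trans$P_round_s) || nrow(Qt) != nrow(trans$P_round_t))
    stop("kernel and transition dimensions disagree")
  term_s <- mean(ce_rows(Qs, trans$P_round_s))
  term_t <- mean(ce_rows(Qt, trans$P_round_t))
  list(loss = term_s + term_t, term_s = term_s, term_t = term_t)
}

#' Build a cell-type indicator matrix
#'
#' @param type_of per-cell labels; the `"unlabeled"` sentinel (or `NA`)
#'   yields an all-zero row.
#' @param class_names class universe (defaults to the sorted labels present).
#' @return n x C 0/1 matrix with `class_names` as columns.
#' @export
label_matrix <- function(type_of, class_names = NULL) {
  type_of <- as.character(type_of)
  type_of[is.na(type_of)] <- UNLABELED
  if (is.null(class_names))
    class_names <- sort(setdiff(unique(type_of), UNLABELED))
  A <- matrix(0, length(type_of), length(class_names),
              dimnames = list(NULL, class_names))
  hit <- match(type_of, class_names)
  ok <- !is.na(hit)
  A[cbind(which(ok), hit[ok])] <- 1
  A
}

#' Classifier (supervised) objective
#'
#' Mean softmax cross-entropy between predicted and true cell-type labels
#' over labeled cells only; unlabeled cells (all-zero indicator rows)
#' contribute nothing. Returns 0 when no cell is labeled.
#'
#' @param A n x C indicator matrix ([label_matrix()]).
#' @param logits n x C classifier scores.
#' @return Scalar loss.
#' @export
supervised_objective <- function(A, logits) {
  stopifnot(all(dim(A) == dim(logits)))
  labeled <- rowSums(A) > 0
  if (!any(labeled)) return(0)
  P <- softmax_rows(logits[labeled, , drop = FALSE])
  mean(ce_rows(A[labeled, , drop = FALSE], P))
}

## ---- internal: loss + gradients for one training step -----------------

# ordered condition pairs dictated by the alignment mode
mode_pairs <- function(conds, mode, k_ref = NULL) {
  if (mode == "pairwise") {
    if (length(conds) != 2)
      stop("mode 'pairwise' requires exactly 2 conditions, got ",
           length(conds))
    list(c(conds[1], conds[2]), c(conds[2], conds[1]))
  } else if (mode == "all_pairs") {
    out <- list()
    for (a in conds) for (b in conds) if (a != b)
      out[[length(out) + 1]] <- c(a, b)
    out
  } else {  # reference: walks originate at the reference only
    if (!k_ref %in% conds) stop("unknown reference condition: ", k_ref)
    lapply(setdiff(conds, k_ref), function(l) c(k_ref, l))
  }
}

# Loss and analytic gradients for one step. X_by_cond: named list of
# per-condition input batches. kernels: named list of condition_kernel for
# walk-originating conditions. A_by_cond: named list of indicator matrices
# (or NULL). Forward pass stacks all batches so batch-norm sees the full
# mini-batch. Returns loss components, flat encoder grads, classifier grads
# and the updated net (running batch-norm statistics).
alignment_step <- function(model, X_by_cond, kernels, A_by_cond = NULL,
                           training = TRUE, dropout_masks = NULL) {
  cfg <- model$config
  conds <- names(X_by_cond)
  sizes <- vapply(X_by_cond, nrow, integer(1))
  offsets <- cumsum(c(0, sizes))[seq_along(sizes)]
  names(offsets) <- conds
  X <- do.call(rbind, X_by_cond)
  fw <- mlp_forward(model$net, X, training = training,
                    dropout_masks = dropout_masks)
  E <- fw$out
  idx <- lapply(conds, function(cn)
    offsets[[cn]] + seq_len(sizes[[cn]]))
  names(idx) <- conds
  E_by <- lapply(idx, function(i) E[i, , drop = FALSE])

  pairs <- mode_pairs(conds, cfg$mode, cfg$reference_condition)
  dE <- matrix(0, nrow(E), ncol(E))
  walker <- 0
  for (pr in pairs) {
    a <- pr[1]; b <- pr[2]
    Ea <- E_by[[a]]; Eb <- E_by[[b]]
    Z <- tcrossprod(Ea, Eb)
    A_f <- softmax_rows(Z)        # a -> b
    B_f <- softmax_rows(t(Z))     # b -> a
    P <- A_f %*% B_f              # round trip for rows of a
    Q <- kernels[[a]]$probs
    m <- nrow(Q)
    Pc <- pmax(P, LOG_CLAMP)
    walker <- walker + mean(ce_rows(Q, P))
    # dL/dP, zero where target mass is zero or log is clamped
    G <- -(Q / Pc) / m
    G[P < LOG_CLAMP] <- 0
    dA <- G %*% t(B_f)
    dB <- crossprod(A_f, G)
    # softmax backward, rows
    dZa <- A_f * (dA - rowSums(dA * A_f))
    dZb <- B_f * (dB - rowSums(dB * B_f))
    dE[idx[[a]], ] <- dE[idx[[a]], ] + dZa %*% Eb + t(dZb) %*% Eb
    dE[idx[[b]], ] <- dE[idx[[b]], ] + t(dZa) %*% Ea + dZb %*% Ea
  }
  dE <- cfg$alpha * dE
  walker_w <- cfg$alpha * walker

  # classifier term: each condition contributes (1/batch size) * sum of
  # labeled-cell cross-entropies, so unlabeled cells dilute the term rather
  # than being renormalised away
  sup <- 0
  cls_grads <- NULL
  if (!is.null(model$classifier) && !is.null(A_by_cond)) {
    A_full <- do.call(rbind, A_by_cond[conds])
    labeled <- rowSums(A_full) > 0
    if (any(labeled)) {
      logits <- add_cols(E %*% model$classifier$W, model$classifier$b)
      row_w <- unlist(lapply(conds, function(cn)
        rep(1 / sizes[[cn]], sizes[[cn]])), use.names = FALSE)
      Pcls <- softmax_rows(logits[labeled, , drop = FALSE])
      ce <- ce_rows(A_full[labeled, , drop = FALSE], Pcls)
      sup <- sum(row_w[labeled] * ce)
      dlog <- matrix(0, nrow(E), ncol(logits))
      dlog[labeled, ] <- cfg$beta * row_w[labeled] *
        (Pcls - A_full[labeled, , drop = FALSE])
      cls_grads <- list(
        dW = crossprod(E, dlog) + 2 * cfg$lambda * model$classifier$W,
        db = colSums(dlog))
      if (cfg$classifier_backprop_encoder)
        dE <- dE + tcrossprod(dlog, model$classifier$W)
    } else if (!is.null(model$classifier)) {
      cls_grads <- list(dW = 2 * cfg$lambda * model$classifier$W,
                        db = numeric(length(model$classifier$b)))
    }
  }

  bw <- mlp_backward(fw$net, fw$cache, dE, training = training)
  grads <- add_ridge_grad(bw$grads, fw$net, cfg$lambda)
  ridge <- cfg$lambda * (mlp_ridge(fw$net) +
    if (!is.null(model$classifier)) sum(model$classifier$W^2) else 0)
  total <- walker_w + cfg$beta * sup + ridge
  list(total = total, walker = walker, supervised = sup, ridge = ridge,
       grads = mlp_grads_flat(fw$net, grads), cls_grads = cls_grads,
       net = fw$net, E = E)
}

#' Full training objective for one mini-batch
#'
#' `alpha * walker + beta * supervised + lambda * ridge`, where the ridge
#' term covers all weight matrices (encoder and classifier head) but no
#' biases or normalisation parameters. Mainly useful for inspection and for
#' gradient checking; [train_alignment()] computes the same quantity
#' internally.
#'
#' @param model an `alignment_model`.
#' @param X_by_cond named list of per-condition input batches.
#' @param kernels named list of `condition_kernel` objects for every
#'   walk-originating condition.
#' @param A_by_cond optional named list of indicator matrices.
#' @param training use batch statistics (as during training).
#' @return List with `total`, `walker`, `supervised`, `ridge`.
#' @export
total_objective <- function(model, X_by_cond, kernels, A_by_cond = NULL,
                            training = TRUE) {
  st <- alignment_step(model, X_by_cond, kernels, A_by_cond,
                       training = training)
  st[c("total", "walker", "supervised", "ridge")]
}

## ---- training loop ----------------------------------------------------

# epoch-wise without-replacement batch sampler for one condition
make_sampler <- function(n, batch_size) {
  queue <- sample.int(n)
  function() {
    if (length(queue) < batch_size) queue <<- sample.int(n)
    take <- queue[seq_len(batch_size)]
    queue <<- queue[-seq_len(batch_size)]
    take
  }
}

#' Train an alignment model
#'
#' Runs `max_steps` Adam updates. Each step draws an independent
#' mini-batch per condition (uniform without replacement within an epoch),
#' rebuilds each walk-originating condition's perplexity-calibrated kernel Q
#' on the batch, computes round-trip walk transition matrices for every
#' condition pair dictated by the mode, and descends the total objective.
#' The run is deterministic given `config$seed`.
#'
#' @param ds an `expression_dataset` (any non-counts layer; typically
#'   `scaled` or `pca`).
#' @param labels optional per-cell type labels (defaults to `ds$type_of`
#'   when any cell is typed; pass `NULL` explicitly stored labels are used,
#'   `NA`/`"unlabeled"` entries are treated as unlabeled). When any label is
#'   present a classifier head is attached and the supervised term is active.
#' @param config an [encoder_config()].
#' @param basis optional PCA basis (from [pca_reduce()]) recorded on the
#'   model so gene-space perturbations can be projected into the encoder's
#'   input space.
#' @param use_labels set `FALSE` to ignore all labels (pure unsupervised).
#' @return A trained `alignment_model` with a `loss_trace` data frame
#'   (columns `step`, `total`, `walker`, `supervised`, `ridge`).
#' @export
train_alignment <- function(ds, labels = NULL, config = encoder_config(),
                            basis = NULL, use_labels = TRUE) {
  stopifnot(inherits(ds, "expression_dataset"))
  conds <- conditions_of(ds)
  if (length(conds) < 2) stop("alignment needs at least 2 conditions")
  if (is.null(config$mode))
    config$mode <- if (length(conds) == 2) "pairwise" else "all_pairs"
  if (config$mode == "pairwise" && length(conds) > 2)
    stop("mode 'pairwise' requires exactly 2 conditions, got ", length(conds))
  if (config$mode == "reference" &&
      !config$reference_condition %in% conds)
    stop("unknown reference condition: ", config$reference_condition)

  if (is.null(labels)) labels <- ds$type_of
  if (!use_labels) labels <- rep(UNLABELED, nrow(ds$values))
  labels[is.na(labels)] <- UNLABELED
  class_names <- sort(setdiff(unique(labels), UNLABELED))
  has_labels <- length(class_names) > 0

  model <- build_encoder(ncol(ds$values), config,
                         class_names = if (has_labels) class_names,
                         n_conditions = length(conds))
  config <- model$config
  model$projection <- basis
  model$feature_ids <- ds$feature_ids

  cond_idx <- lapply(conds, function(cn) which(ds$condition_of == cn))
  names(cond_idx) <- conds
  sizes <- vapply(cond_idx, length, integer(1))
  eff_bs <- stats::setNames(pmin(sizes, config$batch_size), conds)
  if (any(eff_bs < config$batch_size))
    warning("condition(s) smaller than batch_size; using full condition: ",
            paste(conds[eff_bs < config$batch_size], collapse = ", "))
  # per-condition perplexity, clamped once if a batch is too small
  eff_perp <- stats::setNames(pmin(config$perplexity, eff_bs - 1), conds)
  if (any(eff_perp < config$perplexity))
    warning("perplexity clamped to batch size - 1 for: ",
            paste(conds[eff_perp < config$perplexity], collapse = ", "))
  origin_conds <- unique(vapply(
    mode_pairs(conds, config$mode, config$reference_condition),
    `[`, character(1), 1))

  A_full <- if (has_labels) label_matrix(labels, class_names)

  withr::with_seed(config$seed, {
    samplers <- lapply(conds, function(cn)
      make_sampler(sizes[[cn]], eff_bs[[cn]]))
    names(samplers) <- conds
    params <- mlp_params(model$net)
    state <- adam_init_like(params)
    if (has_labels) {
      cls_state <- adam_init_like(model$classifier[c("W", "b")])
    }
    trace <- matrix(NA_real_, config$max_steps, 4)
    for (step in seq_len(config$max_steps)) {
      batch <- lapply(conds, function(cn) cond_idx[[cn]][samplers[[cn]]()])
      names(batch) <- conds
      X_by <- lapply(batch, function(i) ds$values[i, , drop = FALSE])
      kernels <- list()
      for (cn in origin_conds)
        kernels[[cn]] <- suppressWarnings(
          expression_transition_matrix(X_by[[cn]], eff_perp[[cn]]))
      A_by <- if (has_labels)
        lapply(batch, function(i) A_full[i, , drop = FALSE])
      st <- alignment_step(model, X_by, kernels, A_by, training = TRUE)
      model$net <- st$net   # running batch-norm statistics
      up <- adam_update(params, st$grads, state, config$learning_rate, step)
      params <- up$params; state <- up$state
      model$net <- mlp_set_params(model$net, params)
      if (has_labels && !is.null(st$cls_grads)) {
        upc <- adam_update(model$classifier[c("W", "b")],
                           list(W = st$cls_grads$dW, b = st$cls_grads$db),
                           cls_state, config$learning_rate, step)
        model$classifier$W <- upc$params$W
        model$classifier$b <- upc$params$b
        cls_state <- upc$state
      }
      trace[step, ] <- c(st$total, st$walker, st$supervised, st$ridge)
    }
  })
  model$config <- config
  model$loss_trace <- data.frame(step = seq_len(config$max_steps),
                                 total = trace[, 1], walker = trace[, 2],
                                 supervised = trace[, 3], ridge = trace[, 4])
  model
}

#' Embed cells into the alignment space
#'
#' Inference-mode forward pass: dropout off, batch normalisation using the
#' stored running statistics.
#'
#' @param model a trained `alignment_model`.
#' @param ds an `expression_dataset` (or bare matrix) in the encoder's input
#'   space.
#' @return cells x K embedding matrix.
#' @export
embed_cells <- function(model, ds) {
  X <- if (inherits(ds, "expression_dataset")) ds$values else as.matrix(ds)
  if (ncol(X) != model$input_dim)
    stop("input has ", ncol(X), " features; encoder expects ",
         model$input_dim)
  E <- mlp_forward(model$net, X, training = FALSE)$out
  rownames(E) <- rownames(X)
  colnames(E) <- paste0("dim_", seq_len(ncol(E)))
  E
}

#' Predicted cell-type probabilities from the classifier head
#'
#' @param model a trained `alignment_model` with a classifier head.
#' @param ds dataset or matrix in the encoder's input space.
#' @return cells x classes matrix of softmax probabilities.
#' @export
predict_types <- function(model, ds) {
  if (is.null(model$classifier)) stop("model has no classifier head")
  E <- embed_cells(model, ds)
  P <- softmax_rows(sweep(E %*% model$classifier$W, 2,
                          model$classifier$b, "+"))
  colnames(P) <- model$classifier$class_names
  rownames(P) <- rownames(E)
  P
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the weight arrays, the full
#' configuration and the loss trace; `load -> embed` reproduces embeddings
#' exactly.
#'
#' @param model an `alignment_model` or `decoder_model`.
#' @param path file path.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Train the shared-autoencoder baseline
#'
#' Same encoder architecture and optimiser settings as the alignment model,
#' but the embedding is learned by minimising the mean squared error of
#' reconstructing each condition's expression profiles through
#' condition-specific decoders trained simultaneously; no random-walk term.
#' Serves as the comparison baseline for the walker objective.
#'
#' @param ds an `expression_dataset` (the encoder input; possibly PCA
#'   scores).
#' @param config an [encoder_config()] (`mode` is ignored).
#' @param target dataset holding the reconstruction target (defaults to
#'   `ds`); the decoders always reconstruct expression profiles, so when the
#'   encoder consumes PCA scores pass the gene-space dataset here.
#' @return List with `model` (an `alignment_model` without classifier) and
#'   `decoders` (named list of `decoder_model`).
#' @export
train_shared_autoencoder <- function(ds, config = encoder_config(),
                                     target = ds) {
  stopifnot(inherits(ds, "expression_dataset"))
  stopifnot(identical(ds$cell_ids, target$cell_ids))
  conds <- conditions_of(ds)
  if (length(conds) < 2) stop("need at least 2 conditions")
  model <- build_encoder(ncol(ds$values), config,
                         n_conditions = length(conds))
  config <- model$config
  model$feature_ids <- ds$feature_ids
  G <- ncol(target$values)
  K <- model$embedding_dim

  cond_idx <- lapply(conds, function(cn) which(ds$condition_of == cn))
  names(cond_idx) <- conds
  sizes <- vapply(cond_idx, length, integer(1))
  eff_bs <- pmin(sizes, config$batch_size)
  if (any(eff_bs < config$batch_size))
    warning("condition(s) smaller than batch_size; using full condition: ",
            paste(conds[eff_bs < config$batch_size], collapse = ", "))

  withr::with_seed(config$seed + 1L, {
    dec_nets <- lapply(conds, function(cn)
      mlp_new(K, rev(config$hidden_sizes), G,
              batch_norm = config$batch_norm,
              dropout_rate = config$dropout_rate))
    names(dec_nets) <- conds
  })

  withr::with_seed(config$seed, {
    samplers <- lapply(conds, function(cn)
      make_sampler(sizes[[cn]], eff_bs[[cn]]))
    names(samplers) <- conds
    enc_params <- mlp_params(model$net)
    enc_state <- adam_init_like(enc_params)
    dec_params <- lapply(dec_nets, mlp_params)
    dec_state <- lapply(dec_params, adam_init_like)
    trace <- matrix(NA_real_, config$max_steps, 4)
    n_cond <- length(conds)
    for (step in seq_len(config$max_steps)) {
      batch <- lapply(conds, function(cn) cond_idx[[cn]][samplers[[cn]]()])
      names(batch) <- conds
      X_by <- lapply(batch, function(i) ds$values[i, , drop = FALSE])
      Y_by <- lapply(batch, function(i) target$values[i, , drop = FALSE])
      X <- do.call(rbind, X_by)
      fw <- mlp_forward(model$net, X, training = TRUE)
      model$net <- fw$net
      E <- fw$out
      offsets <- cumsum(c(0, vapply(X_by, nrow, integer(1))))
      dE <- matrix(0, nrow(E), ncol(E))
      mse <- 0
      ridge <- config$lambda * mlp_ridge(model$net)
      for (ci in seq_along(conds)) {
        cn <- conds[ci]
        rows <- (offsets[ci] + 1):offsets[ci + 1]
        Ec <- E[rows, , drop = FALSE]
        dfw <- mlp_forward(dec_nets[[cn]], Ec, training = TRUE)
        dec_nets[[cn]] <- dfw$net
        resid <- dfw$out - Y_by[[cn]]
        mse_c <- mean(resid^2)
        mse <- mse + mse_c / n_cond
        dOut <- 2 * resid / (length(resid) * n_cond)
        dbw <- mlp_backward(dec_nets[[cn]], dfw$cache, dOut)
        dgr <- add_ridge_grad(dbw$grads, dec_nets[[cn]], config$lambda)
        ridge <- ridge + config$lambda * mlp_ridge(dec_nets[[cn]])
        upd <- adam_update(dec_params[[cn]],
                           mlp_grads_flat(dec_nets[[cn]], dgr),
                           dec_state[[cn]], config$learning_rate, step)
        dec_params[[cn]] <- upd$params; dec_state[[cn]] <- upd$state
        dec_nets[[cn]] <- mlp_set_params(dec_nets[[cn]], upd$params)
        dE[rows, ] <- dbw$dX
      }
      bw <- mlp_backward(model$net, fw$cache, dE)
      egr <- add_ridge_grad(bw$grads, model$net, config$lambda)
      upe <- adam_update(enc_params, mlp_grads_flat(model$net, egr),
                         enc_state, config$learning_rate, step)
      enc_params <- upe$params; enc_state <- upe$state
      model$net <- mlp_set_params(model$net, upe$params)
      trace[step, ] <- c(mse + ridge, mse, 0, ridge)
    }
  })
  model$config <- config
  model$loss_trace <- data.frame(step = seq_len(config$max_steps),
                                 total = trace[, 1], walker = trace[, 2],
                                 supervised = trace[, 3], ridge = trace[, 4])
  decoders <- lapply(conds, function(cn)
    structure(list(net = dec_nets[[cn]], condition = cn,
                   feature_ids = target$feature_ids),
              class = "decoder_model"))
  names(decoders) <- conds
  list(model = model, decoders = decoders)
}
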
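#' Decoder training configuration defaults
#'
#' @param learning_rate Adam learning rate.
#' @param max_steps maximum Adam updates (the conventional cap is 30,000).
#' @param batch_size mini-batch size (defaults to the encoder's).
#' @param seed RNG seed for initialisation, batching and dropout.
#' @return A list of class `decoder_config`.
#' @export
decoder_config <- function(learning_rate = 1e-4, max_steps = 30000L,
                           batch_size = 150L, seed = 1L) {
  structure(list(learning_rate = learning_rate,
                 max_steps = as.integer(max_steps),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "decoder_config")
}

#' Train a condition-specific decoder
#'
#' Learns a map from alignment-space coordinates back to one condition's
#' expression space. The decoder architecture mirrors the encoder in reverse
#' (K -> reversed hidden sizes -> features), with the same hidden-layer
#' regularisation (batch-norm + dropout) and a linear output layer. It
#' minimises the MSE of reconstructing that condition's expression from the
#' frozen encoder's embeddings; the encoder itself is not updated.
#'
#' The reconstruction target is always an expression-space matrix: when the
#' encoder consumed PCA scores, pass the gene-space dataset as `target`.
#'
#' @param model a trained `alignment_model` (frozen).
#' @param ds dataset in the encoder's input space.
#' @param condition which condition's cells to train on.
#' @param target dataset holding the reconstruction target values (defaults
#'   to `ds`); must share cells with `ds`.
#' @param config a [decoder_config()].
#' @return A `decoder_model`.
#' @export
train_decoder <- function(model, ds, condition, target = ds,
                          config = decoder_config()) {
  stopifnot(inherits(model, "alignment_model"),
            inherits(ds, "expression_dataset"))
  if (!condition %in% ds$condition_of)
    stop("condition not present: ", condition)
  stopifnot(identical(ds$cell_ids, target$cell_ids))
  rows <- which(ds$condition_of == condition)
  E <- embed_cells(model, subset_cells(ds, cells = rows))
  Y <- target$values[rows, , drop = FALSE]
  n <- nrow(E); G <- ncol(Y)
  bs <- min(config$batch_size, n)
  enc_cfg <- model$config
  net <- withr::with_seed(config$seed, {
    mlp_new(ncol(E), rev(enc_cfg$hidden_sizes), G,
            batch_norm = enc_cfg$batch_norm,
            dropout_rate = enc_cfg$dropout_rate)
  })
  withr::with_seed(config$seed + 1L, {
    sampler <- make_sampler(n, bs)
    params <- mlp_params(net)
    state <- adam_init_like(params)
    trace <- numeric(config$max_steps)
    for (step in seq_len(config$max_steps)) {
      b <- sampler()
      fw <- mlp_forward(net, E[b, , drop = FALSE], training = TRUE)
      net <- fw$net
      resid <- fw$out - Y[b, , drop = FALSE]
      trace[step] <- mean(resid^2)
      dOut <- 2 * resid / length(resid)
      bw <- mlp_backward(net, fw$cache, dOut)
      up <- adam_update(params, mlp_grads_flat(net, bw$grads), state,
                        config$learning_rate, step)
      params <- up$params; state <- up$state
      net <- mlp_set_params(net, params)
    }
  })
  structure(list(net = net, condition = condition,
                 feature_ids = target$feature_ids, config = config,
                 loss_trace = if (config$max_steps > 0)
                   data.frame(step = seq_len(config$max_steps),
                              mse = trace) else NULL),
            class = "decoder_model")
}

#' Decode alignment coordinates into a condition's expression space
#'
#' @param decoder a `decoder_model`.
#' @param E cells x K embedding matrix.
#' @return cells x features matrix of decoded expression.
#' @export
decode_cells <- function(decoder, E) {
  out <- mlp_forward(decoder$net, as.matrix(E), training = FALSE)$out
  rownames(out) <- rownames(E)
  colnames(out) <- decoder$feature_ids
  out
}

#' Interpolate every cell into every condition
#'
#' Embeds all cells (whatever condition they were sequenced in) and decodes
#' the embeddings through each condition-specific decoder, simulating how
#' each cell would look had it been measured under every condition.
#'
#' @param decoders named list of `decoder_model`, one per condition.
#' @param model the trained `alignment_model`.
#' @param ds dataset in the encoder's input space (all cells).
#' @return Named list (one element per condition) of cells x genes matrices.
#' @export
interpolate_expression <- function(decoders, model, ds) {
  conds <- conditions_of(ds)
  missing <- setdiff(conds, names(decoders))
  if (length(missing))
    stop("missing decoder for condition: ", paste(missing, collapse = ", "))
  E <- embed_cells(model, ds)
  out <- lapply(conds, function(cn) decode_cells(decoders[[cn]], E))
  names(out) <- conds
  out
}

#' State-variance map
#'
#' For each cell and gene, the sample variance (n - 1 denominator) of the
#' cell's interpolated expression across conditions. High-variance entries
#' flag genes whose predicted expression for that cell depends strongly on
#' condition. With exactly two conditions the paired difference
#' (second minus first, in the list's order) is also returned, and
#' `variance == paired_diff^2 / 2` entrywise.
#'
#' @param interpolations named list of equal-shape cells x genes matrices,
#'   one per condition (see [interpolate_expression()]).
#' @return An object of class `state_variance_map`: list with `variance`
#'   (cells x genes), `paired_diff` (present iff exactly 2 conditions;
#'   attribute `"order"` records the sign convention), `per_cell_score`
#'   (row means of `variance`) and `conditions`.
#' @export
state_variance_map <- function(interpolations) {
  n_cond <- length(interpolations)
  if (n_cond < 2) stop("need at least 2 conditions")
  dims <- lapply(interpolations, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("interpolated matrices must share a shape")
  mean_mat <- Reduce(`+`, interpolations) / n_cond
  ss <- Reduce(`+`, lapply(interpolations, function(m) (m - mean_mat)^2))
  variance <- ss / (n_cond - 1)
  paired_diff <- NULL
  if (n_cond == 2) {
    paired_diff <- interpolations[[2]] - interpolations[[1]]
    attr(paired_diff, "order") <- paste(names(interpolations)[2], "-",
                                        names(interpolations)[1])
  }
  structure(list(variance = variance, paired_diff = paired_diff,
                 per_cell_score = rowMeans(variance),
                 conditions = names(interpolations)),
            class = "state_variance_map")
}
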
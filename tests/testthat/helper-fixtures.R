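# Shared fixtures. The heavy ones (trained models on the standard synthetic
# instance) are built lazily and cached so several test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# desk-scale training configuration: reduced architecture and step count
# with the learning rate raised so the loss trace plateaus within the
# shorter run; PCA-30 inputs (see the methods vignette)
desk_config <- function(seed = 11L, max_steps = 2000L, ...) {
  encoder_config(hidden_sizes = c(128L, 64L), embedding_dim = 32L,
                 learning_rate = 2e-3, max_steps = max_steps,
                 seed = seed, ...)
}

# the standard synthetic instance: 3 types x 150 cells x 2 conditions,
# global + mild type-specific condition effects (generator defaults)
main_instance <- function() {
  fixture("main_instance", function() {
    sim <- simulate_dataset(synthetic_spec())
    pp <- preprocess_chain(sim$dataset, pca_dims = 30)
    list(sim = sim, pp = pp)
  })
}

# unsupervised alignment model trained on the standard instance
main_model <- function() {
  fixture("main_model", function() {
    mi <- main_instance()
    train_alignment(mi$pp$dataset, config = desk_config(),
                    basis = mi$pp$basis, use_labels = FALSE)
  })
}

main_report <- function() {
  fixture("main_report", function() {
    mi <- main_instance()
    E <- embed_cells(main_model(), mi$pp$dataset)
    composite_accuracy(E, mi$pp$dataset$condition_of,
                       mi$pp$dataset$type_of, mode = "pairwise",
                       control = "condition_1")
  })
}

# decoders for both conditions of the standard instance (gene-space targets)
main_decoders <- function() {
  fixture("main_decoders", function() {
    mi <- main_instance()
    model <- main_model()
    conds <- conditions_of(mi$pp$dataset)
    dec <- lapply(conds, function(cn)
      train_decoder(model, mi$pp$dataset, cn, target = mi$pp$expression,
                    config = decoder_config(learning_rate = 1e-3,
                                            max_steps = 5000L, seed = 3L)))
    names(dec) <- conds
    dec
  })
}

# small deterministic dataset for unit tests (no training involved)
tiny_dataset <- function(n_per = 20L, n_genes = 40L, seed = 7L) {
  withr::with_seed(seed, {
    n <- 2L * n_per
    counts <- matrix(rpois(n * n_genes, lambda = 5), n, n_genes)
    expression_dataset(counts,
                       cell_ids = sprintf("c%02d", seq_len(n)),
                       feature_ids = sprintf("g%02d", seq_len(n_genes)),
                       condition_of = rep(c("a", "b"), each = n_per),
                       type_of = rep(c("t1", "t2"), length.out = n),
                       layer = "counts")
  })
}
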
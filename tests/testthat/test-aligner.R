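test_that("encoder construction chains shapes and is seed-deterministic", {
  cfg <- encoder_config(hidden_sizes = c(8L, 4L), embedding_dim = 2L,
                        seed = 5L)
  m <- build_encoder(10L, cfg)
  shapes <- lapply(m$net$layers, function(l) dim(l$W))
  expect_equal(shapes, list(c(10L, 8L), c(8L, 4L), c(4L, 2L)))
  m2 <- build_encoder(10L, cfg)
  expect_identical(m$net, m2$net)
  # empty hidden sizes: a single linear layer is still a valid encoder
  m0 <- build_encoder(6L, encoder_config(hidden_sizes = integer(0),
                                         embedding_dim = 3L))
  expect_equal(length(m0$net$layers), 1L)
  expect_equal(dim(m0$net$layers[[1]]$W), c(6L, 3L))
})

test_that("embedding transitions match brute-force walk enumeration", {
  # all-zero embeddings: uniform transitions
  ts <- embedding_transitions(matrix(0, 2, 3), matrix(0, 3, 3))
  expect_equal(ts$P_fwd, matrix(1 / 3, 2, 3))
  expect_equal(ts$P_round_s, matrix(1 / 2, 2, 2))
  # single cells: everything is [[1]]
  t1 <- embedding_transitions(matrix(1.5, 1, 2), matrix(-2, 1, 2))
  for (M in t1) expect_equal(M, matrix(1, 1, 1), ignore_attr = TRUE)
  # random instance vs explicit two-step sums
  withr::with_seed(2, {
    Es <- matrix(rnorm(8), 4, 2)
    Et <- matrix(rnorm(6), 3, 2)
  })
  ts2 <- embedding_transitions(Es, Et)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (k in 1:4) for (j in 1:3)
    oracle[i, k] <- oracle[i, k] + ts2$P_fwd[i, j] * ts2$P_bwd[j, k]
  expect_equal(ts2$P_round_s, oracle, tolerance = 1e-12)
  for (M in ts2)
    expect_equal(rowSums(M), rep(1, nrow(M)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  # softmax overflow guard
  big <- embedding_transitions(matrix(500, 2, 1), matrix(c(500, -500), 2, 1))
  expect_true(all(is.finite(big$P_round_s)))
})

test_that("walker objective reduces to entropy at its optimum", {
  withr::with_seed(3, {
    Xs <- matrix(rnorm(20), 5, 4)
    Xt <- matrix(rnorm(24), 6, 4)
  })
  ks <- expression_transition_matrix(Xs, 3)
  kt <- expression_transition_matrix(Xt, 3)
  H <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  # P matching Q off-diagonal exactly: loss equals summed mean row entropies
  trans <- list(P_round_s = ks$probs, P_round_t = kt$probs)
  w <- walker_objective(ks, kt, trans)
  expect_equal(w$loss, mean(apply(ks$probs, 1, H)) +
                 mean(apply(kt$probs, 1, H)), tolerance = 1e-10)
  # uniform P including the diagonal: per-row CE is log(m), not log(m-1)
  ks_u <- ks
  ks_u$probs <- matrix(1 / 4, 5, 5); diag(ks_u$probs) <- 0
  ks_u$probs <- ks_u$probs / rowSums(ks_u$probs)
  trans_u <- list(P_round_s = matrix(1 / 5, 5, 5),
                  P_round_t = matrix(1 / 6, 6, 6))
  w_u <- walker_objective(ks_u, kt, trans_u)
  expect_equal(w_u$term_s, log(5), tolerance = 1e-12)
  expect_equal(w_u$term_t, log(6), tolerance = 1e-12)
  # random instance vs scalar double loop
  withr::with_seed(8, {
    Es <- matrix(rnorm(10), 5, 2)
    Et <- matrix(rnorm(12), 6, 2)
  })
  tr <- embedding_transitions(Es, Et)
  w2 <- walker_objective(ks, kt, tr)
  loop <- 0
  for (i in 1:5) for (k in 1:5)
    if (ks$probs[i, k] > 0)
      loop <- loop - ks$probs[i, k] * log(tr$P_round_s[i, k]) / 5
  for (j in 1:6) for (k in 1:6)
    if (kt$probs[j, k] > 0)
      loop <- loop - kt$probs[j, k] * log(tr$P_round_t[j, k]) / 6
  expect_equal(w2$loss, loop, tolerance = 1e-10)
})

test_that("walker loss is invariant to joint rotation of the embeddings", {
  withr::with_seed(21, {
    Xs <- matrix(rnorm(40), 10, 4); Xt <- matrix(rnorm(40), 10, 4)
    Es <- matrix(rnorm(30), 10, 3); Et <- matrix(rnorm(30), 10, 3)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  ks <- expression_transition_matrix(Xs, 4)
  kt <- expression_transition_matrix(Xt, 4)
  w1 <- walker_objective(ks, kt, embedding_transitions(Es, Et))
  w2 <- walker_objective(ks, kt, embedding_transitions(Es %*% R, Et %*% R))
  expect_equal(w1$loss, w2$loss, tolerance = 1e-9)
})

test_that("supervised objective averages over labeled cells only", {
  A0 <- label_matrix(rep(UNLABELED, 4), c("x", "y"))
  expect_equal(supervised_objective(A0, matrix(rnorm(8), 4, 2)), 0)
  # strongly favourable logits drive the loss to 0
  A1 <- label_matrix(c("x", UNLABELED), c("x", "y"))
  logits <- rbind(c(50, -50), c(0, 0))
  expect_lt(supervised_objective(A1, logits), 1e-20)
  # hand-computed softmax cross-entropy for 3 labeled cells
  withr::with_seed(5, L <- matrix(rnorm(8), 4, 2))
  A <- label_matrix(c("x", "y", UNLABELED, "x"), c("x", "y"))
  hand <- 0
  for (i in c(1, 2, 4)) {
    p <- exp(L[i, ]) / sum(exp(L[i, ]))
    cls <- if (i == 2) 2 else 1
    hand <- hand - log(p[cls]) / 3
  }
  expect_equal(supervised_objective(A, L), hand, tolerance = 1e-12)
})

test_that("total objective reduces to the walker term without labels/ridge", {
  withr::with_seed(6, {
    Xs <- matrix(rnorm(30), 6, 5)
    Xt <- matrix(rnorm(30), 6, 5)
  })
  cfg <- encoder_config(hidden_sizes = c(4L), embedding_dim = 2L,
                        dropout_rate = 0, lambda = 0, mode = "pairwise",
                        seed = 2L)
  model <- build_encoder(5L, cfg)
  kers <- list(a = expression_transition_matrix(Xs, 3),
               b = expression_transition_matrix(Xt, 3))
  tot <- total_objective(model, list(a = Xs, b = Xt), kers)
  expect_equal(tot$total, tot$walker)
  expect_equal(tot$ridge, 0)
  expect_equal(tot$supervised, 0)
})

test_that("analytic gradients agree with central differences", {
  withr::with_seed(42, {
    Xs <- matrix(rnorm(30), 6, 5)
    Xt <- matrix(rnorm(30), 6, 5)
  })
  cfg <- encoder_config(hidden_sizes = c(4L, 3L), embedding_dim = 2L,
                        dropout_rate = 0, batch_norm = TRUE, lambda = 1e-3,
                        mode = "pairwise", seed = 7L)
  model <- build_encoder(5L, cfg, class_names = c("A", "B"))
  kers <- list(a = expression_transition_matrix(Xs, 3),
               b = expression_transition_matrix(Xt, 3))
  Xb <- list(a = Xs, b = Xt)
  Ab <- list(a = label_matrix(c("A", "B", "A", UNLABELED, UNLABELED, "B"),
                              c("A", "B")),
             b = label_matrix(c("B", UNLABELED, "A", "A", "B", UNLABELED),
                              c("A", "B")))
  st <- walkalign:::alignment_step(model, Xb, kers, Ab, training = TRUE)
  params <- walkalign:::mlp_params(model$net)
  eps <- 1e-5
  loss_at <- function(m) walkalign:::alignment_step(m, Xb, kers, Ab,
                                                    training = TRUE)$total
  for (k in names(params)) {
    g_num <- params[[k]]; g_num[] <- 0
    for (i in seq_along(params[[k]])) {
      p2 <- params; m2 <- model
      p2[[k]][i] <- p2[[k]][i] + eps
      m2$net <- walkalign:::mlp_set_params(m2$net, p2)
      lp <- loss_at(m2)
      p2[[k]][i] <- p2[[k]][i] - 2 * eps
      m2$net <- walkalign:::mlp_set_params(m2$net, p2)
      lm <- loss_at(m2)
      g_num[i] <- (lp - lm) / (2 * eps)
    }
    denom <- max(1e-8, max(abs(g_num)))
    expect_lt(max(abs(st$grads[[k]] - g_num)) / denom, 1e-4)
  }
})

test_that("training is deterministic and concentrates twin conditions", {
  # two identical conditions: after training, forward transitions should
  # concentrate on each cell's twin far beyond the uniform baseline
  withr::with_seed(30, X <- matrix(rnorm(60 * 10), 60, 10))
  ds <- expression_dataset(rbind(X, X),
                           cell_ids = sprintf("c%03d", 1:120),
                           condition_of = rep(c("a", "b"), each = 60),
                           layer = "scaled")
  cfg <- encoder_config(hidden_sizes = c(32L), embedding_dim = 8L,
                        learning_rate = 3e-3, max_steps = 1500L,
                        batch_size = 60L, perplexity = 10, seed = 4L)
  m1 <- suppressWarnings(train_alignment(ds, config = cfg))
  cfg_short <- cfg; cfg_short$max_steps <- 60L
  m2a <- suppressWarnings(train_alignment(ds, config = cfg_short))
  m2b <- suppressWarnings(train_alignment(ds, config = cfg_short))
  expect_identical(m2a$loss_trace, m2b$loss_trace)
  expect_lt(tail(m1$loss_trace$total, 1), m1$loss_trace$total[1])
  E <- embed_cells(m1, ds)
  P <- embedding_transitions(E[1:60, ], E[61:120, ])$P_fwd
  expect_gt(mean(diag(P)), 10 / 60)
})

test_that("pairwise mode refuses more than two conditions", {
  ds <- tiny_dataset()
  ds$condition_of[1:10] <- "c"
  expect_error(train_alignment(ds, config = encoder_config(
    mode = "pairwise", max_steps = 1L)), "exactly 2 conditions")
  expect_error(train_alignment(ds, config = encoder_config(
    mode = "reference", reference_condition = "nope", max_steps = 1L)),
    "unknown reference")
})

test_that("multi-way modes run and keep transition contracts", {
  withr::with_seed(77, {
    base <- matrix(rnorm(45 * 6), 45, 6)
    ds <- expression_dataset(
      base + rep(c(0, 0.5, 1), each = 15),
      condition_of = rep(c("a", "b", "c"), each = 15),
      type_of = rep(rep(c("t1", "t2", "t3"), each = 5), 3),
      layer = "scaled")
  })
  for (mode in c("all_pairs", "reference")) {
    cfg <- encoder_config(hidden_sizes = c(16L), embedding_dim = NULL,
                          learning_rate = 2e-3, max_steps = 50L,
                          batch_size = 15L, perplexity = 5,
                          mode = mode,
                          reference_condition = if (mode == "reference") "a",
                          seed = 1L)
    m <- suppressWarnings(train_alignment(ds, config = cfg,
                                          use_labels = FALSE))
    expect_equal(m$embedding_dim, 64L)   # >= 3 conditions widens K
    expect_true(all(is.finite(m$loss_trace$total)))
    E <- embed_cells(m, ds)
    ts <- embedding_transitions(E[1:15, ], E[16:30, ])
    expect_equal(rowSums(ts$P_round_s), rep(1, 15), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("inference embedding is deterministic and matches linear oracle", {
  ds <- tiny_dataset()
  sc <- scale_center(log1p_transform(tp10k_normalize(ds)))
  cfg <- encoder_config(hidden_sizes = integer(0), embedding_dim = 3L,
                        dropout_rate = 0.5, seed = 9L)
  m <- build_encoder(40L, cfg)
  E1 <- embed_cells(m, sc)
  E2 <- embed_cells(m, sc)
  expect_identical(E1, E2)           # no stochastic layers at inference
  W <- m$net$layers[[1]]$W
  b <- m$net$layers[[1]]$b
  expect_equal(E1, sweep(sc$values %*% W, 2, b, "+"), tolerance = 1e-12,
               ignore_attr = TRUE)
  # duplicated input rows embed identically
  dup <- rbind(sc$values[1, , drop = FALSE], sc$values[1, , drop = FALSE])
  Ed <- embed_cells(m, dup)
  expect_equal(Ed[1, ], Ed[2, ])
  expect_error(embed_cells(m, sc$values[, 1:10]), "expects")
})

test_that("checkpoints round-trip exactly", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset()
  sc <- scale_center(log1p_transform(tp10k_normalize(ds)))
  cfg <- encoder_config(hidden_sizes = c(8L), embedding_dim = 2L,
                        learning_rate = 2e-3, max_steps = 20L,
                        batch_size = 20L, perplexity = 5, seed = 3L)
  m <- train_alignment(sc, config = cfg, use_labels = FALSE)
  f <- file.path(dir, "ckpt.rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(embed_cells(m2, sc), embed_cells(m, sc))
})

test_that("shared autoencoder learns reconstruction and is deterministic", {
  # rank-2 data, linear encoder/decoder with K = 2: MSE must approach 0
  withr::with_seed(15, {
    U <- matrix(rnorm(80), 40, 2)
    V <- matrix(rnorm(12), 2, 6)
  })
  ds <- expression_dataset(U %*% V, condition_of = rep(c("a", "b"), 20),
                           layer = "scaled")
  cfg <- encoder_config(hidden_sizes = integer(0), embedding_dim = 2L,
                        dropout_rate = 0, batch_norm = FALSE, lambda = 0,
                        learning_rate = 5e-3, max_steps = 2000L,
                        batch_size = 20L, seed = 8L)
  ae <- train_shared_autoencoder(ds, cfg)
  expect_lt(tail(ae$model$loss_trace$total, 1), 1e-3)
  # untrained model MSE is on the variance scale of the data
  cfg0 <- cfg; cfg0$max_steps <- 0L
  ae0 <- train_shared_autoencoder(ds, cfg0)
  E0 <- embed_cells(ae0$model, ds)
  rec0 <- decode_cells(ae0$decoders[["a"]], E0[ds$condition_of == "a", ])
  mse0 <- mean((rec0 - ds$values[ds$condition_of == "a", ])^2)
  expect_gt(mse0, 0.1 * mean(ds$values^2))
  ae2 <- train_shared_autoencoder(ds, cfg)
  expect_identical(ae$model$loss_trace, ae2$model$loss_trace)
})
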
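test_that("knn label transfer matches a brute-force oracle", {
  # duplicated training point with k = 1 returns its label
  tr <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  expect_equal(knn_predict(tr, c("p", "q"), tr[2, , drop = FALSE], k = 1L),
               "q")
  # all labels identical: accuracy is that label's frequency in the test set
  expect_equal(knn_transfer_accuracy(tr, c("p", "p"),
                                     matrix(rnorm(10), 5, 2),
                                     c("p", "p", "q", "q", "q"), k = 2L),
               0.4)
  # random instance vs exhaustive search with the documented tie rules
  withr::with_seed(14, {
    E_tr <- matrix(rnorm(20), 10, 2)
    lab <- sample(c("u", "v", "w"), 10, replace = TRUE)
    E_te <- matrix(rnorm(12), 6, 2)
  })
  pred <- knn_predict(E_tr, lab, E_te, k = 3L)
  for (i in 1:6) {
    d <- sqrt(colSums((t(E_tr) - E_te[i, ])^2))
    nb <- order(d)[1:3]
    tab <- table(lab[nb])
    cand <- names(tab)[tab == max(tab)]
    if (length(cand) > 1) {
      md <- sapply(cand, function(cl) mean(d[nb][lab[nb] == cl]))
      cand <- sort(cand[md == min(md)])[1]
    }
    expect_equal(pred[i], cand)
  }
  expect_error(knn_predict(E_tr, lab, E_te, k = 20L), "exceeds")
})

test_that("knn transfer agrees with the class package on clean data", {
  skip_if_not_installed("class")
  withr::with_seed(31, {
    E_tr <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2))
    lab <- rep(c("m", "n"), each = 20)
    E_te <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 6), 10, 2))
  })
  ours <- knn_predict(E_tr, lab, E_te, k = 5L)
  ref <- as.character(class::knn(E_tr, E_te, factor(lab), k = 5))
  expect_equal(ours, ref)
})

test_that("knn accuracy is invariant to joint rigid rotation", {
  withr::with_seed(55, {
    E_tr <- matrix(rnorm(60), 20, 3)
    lab_tr <- sample(c("a", "b"), 20, replace = TRUE)
    E_te <- matrix(rnorm(30), 10, 3)
    lab_te <- sample(c("a", "b"), 10, replace = TRUE)
    R <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  })
  a1 <- knn_transfer_accuracy(E_tr, lab_tr, E_te, lab_te, 3L)
  a2 <- knn_transfer_accuracy(E_tr %*% R, lab_tr, E_te %*% R, lab_te, 3L)
  expect_equal(a1, a2)
})

test_that("alignment score hits its endpoints", {
  withr::with_seed(40, {
    blob1 <- matrix(rnorm(300), 150, 2)
    blob2 <- matrix(rnorm(300, mean = 100), 150, 2)
  })
  E_sep <- rbind(blob1, blob2)
  cond <- rep(c("a", "b"), each = 150)
  expect_lt(alignment_score(E_sep, cond, k = 10), 0.02)
  # random labels on one cloud: score ~ 1
  scores <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      E <- matrix(rnorm(1000), 500, 2)
      cl <- sample(rep(c("a", "b"), each = 250))
    })
    alignment_score(E, cl, k = 30, seed = s)
  }, numeric(1))
  expect_equal(mean(scores), 1, tolerance = 0.1)
  # clipping keeps interleaved duplicates inside [0, 1]
  dup <- rbind(blob1, blob1)
  s_dup <- alignment_score(dup, cond, k = 10)
  expect_gte(s_dup, 0); expect_lte(s_dup, 1)
  expect_error(alignment_score(E_sep, cond, k = 400), "smaller")
})

test_that("alignment score decreases as conditions separate", {
  withr::with_seed(63, E <- matrix(rnorm(400), 200, 2))
  cond <- rep(c("a", "b"), each = 100)
  sc <- vapply(c(0, 1, 2, 4, 8), function(d) {
    Es <- E; Es[101:200, 1] <- Es[101:200, 1] + d
    alignment_score(Es, cond, k = 10)
  }, numeric(1))
  expect_true(all(diff(sc) <= 1e-9))
})

test_that("composite accuracy is the product of its two factors", {
  withr::with_seed(26, {
    E <- rbind(matrix(rnorm(100), 50, 2),
               matrix(rnorm(100), 50, 2))
  })
  cond <- rep(c("ctrl", "stim"), each = 50)
  type <- rep(rep(c("t1", "t2"), each = 25), 2)
  E[type == "t2", 1] <- E[type == "t2", 1] + 10
  rep_ <- composite_accuracy(E, cond, type, mode = "pairwise",
                             control = "ctrl", k = 3L)
  expect_equal(rep_$composite,
               rep_$label_accuracy * rep_$alignment_score,
               tolerance = 1e-12)
  expect_gte(rep_$composite, 0); expect_lte(rep_$composite, 1)
  expect_equal(sort(names(rep_$per_class_accuracy)), c("t1", "t2"))
  # multiway mean equals manual representative sweeps
  cond3 <- rep(c("a", "b", "c"), length.out = 100)
  rep3 <- composite_accuracy(E, cond3, type, mode = "multiway", k = 3L)
  accs <- vapply(c("a", "b", "c"), function(cn) {
    tr <- cond3 == cn
    mean(knn_predict(E[tr, ], type[tr], E[!tr, ], k = 3L) == type[!tr])
  }, numeric(1))
  expect_equal(rep3$label_accuracy, mean(accs), tolerance = 1e-12)
  # unlabeled training cells are an error
  type_bad <- type; type_bad[cond == "ctrl"][1] <- UNLABELED
  expect_error(composite_accuracy(E, cond, type_bad, control = "ctrl"),
               "unlabeled")
})

test_that("interpolation accuracy treats identical inputs identically", {
  withr::with_seed(70, {
    X <- rbind(matrix(rnorm(200), 50, 4),
               matrix(rnorm(200, 3), 50, 4))
    lab <- rep(c("p", "q"), each = 50)
  })
  r <- interpolation_accuracy(X, lab, X, lab, k = 3L, seed = 5L)
  expect_equal(r$expression_accuracy, r$interpolation_accuracy,
               tolerance = 0.06)
  r2 <- interpolation_accuracy(X, lab, X, lab, k = 3L, seed = 5L)
  expect_identical(r, r2)
  # pure-noise interpolation falls to roughly the majority-class rate
  withr::with_seed(71, noise <- matrix(rnorm(400, 0, 20), 100, 4))
  rn <- interpolation_accuracy(X, lab, noise, lab, k = 3L, seed = 5L)
  expect_lt(rn$interpolation_accuracy, 0.7)
  expect_error(interpolation_accuracy(X[1:5, ], lab[1:5], X, lab,
                                      folds = 10L), "fewer cells")
})

test_that("silhouette coefficient matches a hand computation", {
  # two tight far-apart clusters: ~ 1
  withr::with_seed(80, {
    E <- rbind(matrix(rnorm(40, 0, 0.01), 20, 2),
               matrix(rnorm(40, 50, 0.01), 20, 2))
  })
  lab <- rep(c("a", "b"), each = 20)
  expect_gt(silhouette_coefficient(E, lab), 0.99)
  # random labels on one cloud: ~ 0
  withr::with_seed(81, {
    E1 <- matrix(rnorm(400), 200, 2)
    l1 <- sample(c("a", "b"), 200, replace = TRUE)
  })
  expect_lt(abs(silhouette_coefficient(E1, l1)), 0.05)
  # 6-point manual oracle
  pts <- matrix(c(0, 0, 1, 0, 0, 1, 4, 0, 5, 0, 4, 1), 6, 2, byrow = TRUE)
  lab6 <- c("x", "x", "x", "y", "y", "y")
  d <- as.matrix(dist(pts))
  sil <- numeric(6)
  for (i in 1:6) {
    own <- lab6 == lab6[i]
    a_i <- mean(d[i, own & seq_len(6) != i])
    b_i <- mean(d[i, !own])
    sil[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  expect_equal(silhouette_coefficient(pts, lab6), mean(sil),
               tolerance = 1e-12)
  expect_error(silhouette_coefficient(pts, rep("x", 6)), "2 classes")
})

test_that("auroc matches the Mann-Whitney construction", {
  expect_equal(auroc(c(3, 2, 1, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(c(0, 1, 2, 3), c(TRUE, TRUE, FALSE, FALSE)), 0)
  withr::with_seed(90, {
    s <- rnorm(50)
    pos <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  })
  w <- wilcox.test(s[pos], s[!pos], exact = FALSE, correct = FALSE)
  expect_equal(auroc(s, pos),
               unname(w$statistic) / (sum(pos) * sum(!pos)),
               tolerance = 1e-12)
})
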
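test_that("attention_forward satisfies its normalization contracts", {
  withr_seed(3)
  X <- matrix(rnorm(50), 10, 5)
  out <- attention_forward(X)           # zero-initialized map
  expect_equal(rowSums(out$A), rep(1, 10), tolerance = 1e-6)
  expect_equal(out$A, matrix(1 / 5, 10, 5), tolerance = 1e-12)
  expect_equal(out$Z, X / 5, tolerance = 1e-12)

  # direct one-node evaluation
  tiny <- attention_forward(matrix(c(1, 1), 1, 2))
  expect_equal(tiny$Z, matrix(0.5, 1, 2), tolerance = 1e-15)

  # nonzero map still row-normalizes and weights elementwise
  att <- list(W = matrix(rnorm(50), 10, 5) * 0.01, b = rnorm(5) * 0.01)
  out2 <- attention_forward(X, att)
  expect_equal(rowSums(out2$A), rep(1, 10), tolerance = 1e-6)
  expect_true(all(out2$A > 0))
  expect_equal(out2$Z, X * out2$A, tolerance = 1e-12)
  expect_error(attention_forward(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("gcn_layer matches the explicit triple loop", {
  withr_seed(6)
  S <- renormalized_propagation(build_adjacency(random_phenotypes(10, seed = 6)))
  H <- matrix(rnorm(40), 10, 4)
  Theta <- matrix(rnorm(12), 4, 3)
  expect_equal(unname(gcn_layer(S, H, Theta, "relu")),
               naive_gcn_layer(S, H, Theta, relu = TRUE), tolerance = 1e-10)
  expect_equal(unname(gcn_layer(S, H, Theta, "none")),
               naive_gcn_layer(S, H, Theta, relu = FALSE), tolerance = 1e-10)
  # identity and clamp cases
  expect_equal(gcn_layer(diag(10), H, diag(4), "none"), H, tolerance = 1e-15)
  expect_identical(gcn_layer(diag(10), -abs(H), diag(4), "relu"),
                   matrix(0, 10, 4))
  expect_error(gcn_layer(S, H, matrix(0, 5, 2)), "mismatch")
})

test_that("masked cross entropy counts labeled nodes only", {
  probs <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  labs <- factor(c("a", "b", "a"))
  expect_equal(masked_cross_entropy(probs, labs, c(TRUE, TRUE, FALSE)), 0,
               tolerance = 1e-12)
  expect_equal(masked_cross_entropy(probs, labs, c(FALSE, FALSE, TRUE)),
               log(2), tolerance = 1e-12)
  # random case against an explicit sum
  withr_seed(9)
  p <- softmax <- exp(matrix(rnorm(20), 10, 2)); p <- p / rowSums(p)
  y <- factor(sample(c("a", "b"), 10, TRUE))
  m <- c(rep(TRUE, 6), rep(FALSE, 4))
  manual <- -mean(sapply(1:6, function(i) log(p[i, as.integer(y)[i]])))
  expect_equal(masked_cross_entropy(p, y, m), manual, tolerance = 1e-12)
  expect_error(masked_cross_entropy(p, y, rep(FALSE, 10)), "no nodes")
})

test_that("forward produces distributions and matches hand computation", {
  g <- planted_feature_graph(10, 2, seed = 41)
  m <- train_gcn(g, model_config(epochs = 3, seed = 1))
  probs <- forward(g, m)
  expect_equal(unname(rowSums(probs)), rep(1, nrow(g$X)), tolerance = 1e-10)

  # hand-computed forward pass from the stored weights (attention disabled)
  m2 <- train_gcn(g, model_config(epochs = 3, seed = 1,
                                  attention_enabled = FALSE))
  S <- renormalized_propagation(g$W)
  H <- g$X
  K <- m2$config$hidden_layers
  for (k in seq_len(K)) H <- pmax(S %*% H %*% m2$params$theta[[k]], 0)
  O <- S %*% H %*% m2$params$theta[[K + 1]]
  P <- exp(O - apply(O, 1, max)); P <- P / rowSums(P)
  expect_identical(unname(forward(g, m2)), unname(P))
})

test_that("training is deterministic and recovers planted structure", {
  g <- planted_feature_graph(30, 5, seed = 12)
  m1 <- train_gcn(g, model_config(seed = 4))
  m2 <- train_gcn(g, model_config(seed = 4))
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  expect_length(m1$history, 200L)

  pred <- predict_gcn(g, m1)
  expect_gte(mean(pred$labels == g$labels[g$test_mask]), 0.9)

  # loss trends down early on separable data
  expect_lt(mean(m1$history[6:10]), mean(m1$history[1:5]) + 1e-8)

  expect_error(train_gcn(population_graph(g$X, g$W, g$labels,
                                          rep(FALSE, nrow(g$X)),
                                          rep(FALSE, nrow(g$X))),
                         model_config()), "empty")
})

test_that("test labels never influence training (transductive contract)", {
  g <- planted_feature_graph(20, 3, seed = 30)
  m1 <- train_gcn(g, model_config(epochs = 30, seed = 2))
  g_pert <- g
  # flip every test-node label
  flipped <- factor(ifelse(as.character(g$labels) == "AD", "CU", "AD"),
                    levels = levels(g$labels))
  g_pert$labels[g_pert$test_mask] <- flipped[g_pert$test_mask]
  m2 <- train_gcn(g_pert, model_config(epochs = 30, seed = 2))
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("disabling attention reproduces the plain GCN path bit for bit", {
  g <- planted_feature_graph(15, 4, seed = 8)
  cfg <- model_config(epochs = 10, seed = 3, attention_enabled = FALSE)
  m <- train_gcn(g, cfg)
  expect_null(m$params$attention)
  expect_null(m$attention_map)

  # independent plain-GCN trainer: same math coded separately
  S <- renormalized_propagation(g$W)
  X <- g$X; n <- nrow(X); mm <- ncol(X)
  classes <- levels(droplevels(g$labels[g$train_mask]))
  yi <- match(as.character(g$labels), classes)
  midx <- which(g$train_mask); nl <- length(midx)
  K <- cfg$hidden_layers
  dims <- c(mm, rep(cfg$hidden_width, K), length(classes))
  set.seed(cfg$seed)
  th <- lapply(seq_len(K + 1), function(k) {
    lim <- sqrt(6 / (dims[k] + dims[k + 1]))
    matrix(runif(dims[k] * dims[k + 1], -lim, lim), dims[k], dims[k + 1])
  })
  ms <- lapply(th, function(x) x * 0); vs <- ms
  for (ep in seq_len(cfg$epochs)) {
    dm <- lapply(seq_len(K), function(k) {
      matrix(rbinom(n * dims[k], 1, 1 - cfg$dropout), n, dims[k]) /
        (1 - cfg$dropout)
    })
    Hs <- list(X); U <- vector("list", K); D <- vector("list", K)
    for (k in seq_len(K)) {
      D[[k]] <- Hs[[k]] * dm[[k]]
      U[[k]] <- S %*% D[[k]] %*% th[[k]]
      Hs[[k + 1]] <- pmax(U[[k]], 0)
    }
    O <- S %*% Hs[[K + 1]] %*% th[[K + 1]]
    P <- exp(O - apply(O, 1, max)); P <- P / rowSums(P)
    dO <- matrix(0, n, length(classes)); dO[midx, ] <- P[midx, ]
    dO[cbind(midx, yi[midx])] <- dO[cbind(midx, yi[midx])] - 1
    dO <- dO / nl
    gth <- vector("list", K + 1)
    gth[[K + 1]] <- crossprod(S %*% Hs[[K + 1]], dO)
    dH <- S %*% dO %*% t(th[[K + 1]])
    for (k in rev(seq_len(K))) {
      dU <- dH * (U[[k]] > 0)
      gth[[k]] <- crossprod(S %*% D[[k]], dU)
      dH <- (S %*% dU %*% t(th[[k]])) * dm[[k]]
    }
    b1 <- 0.9; b2 <- 0.999
    for (j in seq_len(K + 1)) {
      gg <- gth[[j]] + cfg$weight_decay * th[[j]]
      ms[[j]] <- b1 * ms[[j]] + (1 - b1) * gg
      vs[[j]] <- b2 * vs[[j]] + (1 - b2) * gg^2
      th[[j]] <- th[[j]] - cfg$learning_rate * (ms[[j]] / (1 - b1^ep)) /
        (sqrt(vs[[j]] / (1 - b2^ep)) + 1e-8)
    }
  }
  for (k in seq_len(K + 1)) expect_identical(m$params$theta[[k]], th[[k]])
})

test_that("prediction ties break to the lowest class index", {
  # craft a two-node graph and a model whose output is exactly uniform
  g <- planted_feature_graph(3, 1, seed = 2)
  m <- train_gcn(g, model_config(epochs = 2, seed = 1))
  m$params$theta[[m$config$hidden_layers + 1]][] <- 0   # logits all zero
  if (!is.null(m$params$attention)) {
    m$params$attention$W[] <- 0; m$params$attention$b[] <- 0
  }
  pred <- predict_gcn(g, m, mask = rep(TRUE, nrow(g$X)))
  expect_true(all(pred$probs == 0.5))
  expect_true(all(pred$labels == m$classes[1]))
})

test_that("node permutation permutes predictions identically", {
  g <- planted_feature_graph(12, 4, seed = 19)
  cfg <- model_config(epochs = 15, seed = 5, dropout = 0,
                      attention_enabled = FALSE)
  m <- train_gcn(g, cfg)
  probs <- forward(g, m)
  withr_seed(20)
  perm <- sample(nrow(g$X))
  gp <- population_graph(g$X[perm, ], g$W[perm, perm], g$labels[perm],
                         g$train_mask[perm], g$test_mask[perm])
  # same weights applied to the permuted graph
  probs_p <- forward(gp, m)
  expect_equal(unname(probs_p), unname(probs[perm, ]), tolerance = 1e-10)
})

test_that("cross-validation recovers separable fixtures and stays at chance on noise", {
  g <- planted_feature_graph(30, 5, seed = 77)
  cv <- cross_validate(g$X, g$phenotypes, g$labels,
                       config = model_config(epochs = 120),
                       n_repeats = 4, seed = 7)
  expect_gte(cv$mean[["ACC"]], 0.95)
  expect_identical(nrow(cv$splits), 4L)

  # determinism of split assignments and metrics
  cv2 <- cross_validate(g$X, g$phenotypes, g$labels,
                        config = model_config(epochs = 120),
                        n_repeats = 4, seed = 7)
  expect_identical(cv$splits, cv2$splits)

  # shuffled labels: chance level
  withr_seed(88)
  labs_shuf <- sample(g$labels)
  cv0 <- cross_validate(g$X, g$phenotypes, labs_shuf,
                        config = model_config(epochs = 60),
                        n_repeats = 4, seed = 9)
  n_test <- 4 * 6   # 10% of 60 labeled per split
  expect_lt(abs(cv0$mean[["ACC"]] - 0.5), 3 * sqrt(0.25 / n_test))
})

test_that("grid search scores every combination and picks the best", {
  g <- planted_feature_graph(25, 5, seed = 55)
  gs <- grid_search(g$X, g$phenotypes, g$labels,
                    grid = list(epochs = c(1L, 150L)),
                    base_config = model_config(seed = 2),
                    n_repeats = 3, seed = 3)
  expect_identical(nrow(gs$table), 2L)
  expect_identical(gs$best_config$epochs, 150L)

  gs1 <- grid_search(g$X, g$phenotypes, g$labels,
                     grid = list(hidden_width = 16L),
                     base_config = model_config(epochs = 5, seed = 2),
                     n_repeats = 2, seed = 3)
  expect_identical(gs1$best_config$hidden_width, 16L)
  expect_identical(nrow(gs1$table), 1L)
})

test_that("attention ranking normalizes, flags, and finds signal features", {
  g <- planted_feature_graph(20, 4, seed = 14)
  m <- train_gcn(g, model_config(epochs = 20, seed = 1))
  rk <- rank_roi_attention(m, roi_names = colnames(g$X))
  expect_equal(sum(rk$normalized_weight), 1, tolerance = 1e-10)
  expect_true(all(diff(rk$normalized_weight) <= 0))
  expect_identical(rk$displayed, rk$normalized_weight >= 0.05)

  m_plain <- train_gcn(g, model_config(epochs = 5, attention_enabled = FALSE))
  expect_error(rank_roi_attention(m_plain), "attention")

  # single-feature signal: that column ranks top-3 in most seeds
  hits <- 0L
  for (s in 1:12) {
    withr_seed(200 + s)
    n <- 60; M <- 8
    X <- matrix(rnorm(n * M, 0, 0.3), n, M)
    cls <- factor(rep(c("AD", "CU"), each = 30), levels = c("AD", "CU"))
    X[, 4] <- X[, 4] + ifelse(cls == "AD", 2, -2)   # all signal in feature 4
    rownames(X) <- sprintf("n%03d", 1:n)
    phen <- data.frame(subject = rownames(X),
                       age = runif(n, 60, 64) + ifelse(cls == "AD", 16, 0),
                       gender = factor(sample(c("F", "M"), n, TRUE)),
                       apoe4_count = ifelse(cls == "AD", 2L, 0L))
    gr <- population_graph(X, build_adjacency(phen), cls,
                           rep(TRUE, n), rep(FALSE, n), phen)
    mm <- train_gcn(gr, model_config(seed = s))
    rk <- rank_roi_attention(mm, roi_names = sprintf("f%d", 1:M))
    hits <- hits + ("f4" %in% rk$roi[1:3])
  }
  expect_gte(hits, 9L)  # >= 15/20 rate
})
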
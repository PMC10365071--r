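#' Model configuration for the graph convolutional classifier
#'
#' Defaults follow the study settings: dropout 0.3, learning rate 0.01,
#' 200 epochs, 3 hidden layers; hidden width 16 and weight decay 5e-4
#' are the conventional choices for whole-graph GCNs and are exposed to
#' the grid search.
#'
#' @param hidden_layers number of hidden graph-convolution layers K
#' @param hidden_width units per hidden layer
#' @param dropout dropout rate in `[0, 1)`, applied to the input of each
#'   hidden layer during training only
#' @param learning_rate Adam step size
#' @param epochs full-graph gradient steps
#' @param weight_decay L2 penalty added to gradients
#' @param seed integer seed controlling initialization and dropout
#' @param attention_enabled embed the dot-product attention module?
#' @return an object of class `model_config`
#' @export
model_config <- function(hidden_layers = 3L, hidden_width = 16L,
                         dropout = 0.3, learning_rate = 0.01,
                         epochs = 200L, weight_decay = 5e-4,
                         seed = 1L, attention_enabled = TRUE) {
  if (!is_count(hidden_layers)) abort_fmt("hidden_layers must be >= 1")
  if (!is_count(hidden_width)) abort_fmt("hidden_width must be >= 1")
  if (!is_count(epochs)) abort_fmt("epochs must be >= 1")
  if (dropout < 0 || dropout >= 1) abort_fmt("dropout must lie in [0, 1)")
  structure(
    list(hidden_layers = as.integer(hidden_layers),
         hidden_width = as.integer(hidden_width),
         dropout = dropout, learning_rate = learning_rate,
         epochs = as.integer(epochs), weight_decay = weight_decay,
         seed = as.integer(seed),
         attention_enabled = isTRUE(attention_enabled)),
    class = "model_config"
  )
}

# Glorot/Xavier symmetric-uniform initialization
glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Dot-product attention over node features
#'
#' Computes the pairwise node similarity `Y = X X^T` (N x N), passes
#' each row of `Y` through a learnable linear map to M logits, applies a
#' row-wise softmax to obtain the attention map `A` (N x M, rows summing
#' to 1), and refines the features elementwise: `Z = X * A`. With a
#' zero-initialized linear map every row of `A` is uniform `1/M` and
#' `Z = X / M`.
#'
#' @param X numeric node-feature matrix N x M
#' @param attention list with `W` (N x M) and `b` (length M), or NULL
#'   for a zero-initialized map
#' @return list with `Z` (refined features) and `A` (attention map)
#' @export
attention_forward <- function(X, attention = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) abort_fmt("node features must be finite")
  n <- nrow(X); m <- ncol(X)
  if (is.null(attention)) {
    attention <- list(W = matrix(0, n, m), b = numeric(m))
  }
  Y <- tcrossprod(X)                       # N x N node similarities
  G <- Y %*% attention$W +
    matrix(attention$b, n, m, byrow = TRUE)
  A <- softmax_rows(G)
  list(Z = X * A, A = A)
}

#' One graph-convolution layer
#'
#' `H' = activation(S H Theta)`: propagate node representations through
#' the graph operator `S`, mix channels with the weight matrix `Theta`,
#' then apply the nonlinearity.
#'
#' @param S propagation matrix N x N (see [renormalized_propagation()])
#' @param H node representations N x d
#' @param Theta weight matrix d x d'
#' @param activation `"relu"` or `"none"`
#' @return matrix N x d'
#' @export
gcn_layer <- function(S, H, Theta, activation = c("relu", "none")) {
  activation <- match.arg(activation)
  S <- as.matrix(S); H <- as.matrix(H); Theta <- as.matrix(Theta)
  if (ncol(S) != nrow(H)) abort_fmt("S (%d cols) and H (%d rows) mismatch",
                                    ncol(S), nrow(H))
  if (ncol(H) != nrow(Theta)) abort_fmt("H (%d cols) and Theta (%d rows) mismatch",
                                        ncol(H), nrow(Theta))
  out <- S %*% H %*% Theta
  if (activation == "relu") out <- pmax(out, 0)
  out
}

#' Cross-entropy over labeled nodes only
#'
#' The transductive loss: mean of `-log p(true class)` over the masked
#' (labeled) nodes; unlabeled nodes contribute nothing.
#'
#' @param probs N x C matrix of class probabilities (rows sum to 1)
#' @param labels factor of length N (may be NA off-mask)
#' @param mask logical mask of the labeled nodes
#' @return scalar loss
#' @export
masked_cross_entropy <- function(probs, labels, mask) {
  mask <- as.logical(mask)
  if (!any(mask)) abort_fmt("mask selects no nodes")
  labels <- as.factor(labels)
  yi <- as.integer(labels)[mask]
  if (anyNA(yi)) abort_fmt("labels missing on masked nodes")
  p <- probs[cbind(which(mask), yi)]
  -mean(log(pmax(p, 1e-300)))
}

# forward pass through attention + GCN stack; returns all intermediates
# needed for backprop. drop_masks: NULL (inference) or list of per-layer
# inverted-dropout multiplier matrices.
gcn_forward_full <- function(X, S, params, drop_masks = NULL) {
  K <- length(params$theta) - 1L
  att <- NULL
  if (!is.null(params$attention)) {
    att <- attention_forward(X, params$attention)
    H0 <- att$Z
  } else {
    H0 <- X
  }
  H <- vector("list", K + 1L); H[[1L]] <- H0
  D <- vector("list", K)       # post-dropout hidden inputs
  U <- vector("list", K)       # pre-activation hidden outputs
  for (k in seq_len(K)) {
    Dk <- H[[k]]
    if (!is.null(drop_masks)) Dk <- Dk * drop_masks[[k]]
    D[[k]] <- Dk
    U[[k]] <- S %*% Dk %*% params$theta[[k]]
    H[[k + 1L]] <- pmax(U[[k]], 0)
  }
  O <- S %*% H[[K + 1L]] %*% params$theta[[K + 1L]]
  probs <- softmax_rows(O)
  list(probs = probs, O = O, H = H, D = D, U = U, att = att)
}

#' Class probabilities for every node
#'
#' Deterministic forward pass (no dropout) of a trained model on a
#' population graph: attention refinement when enabled, K ReLU graph
#' convolutions, a linear graph-convolution output layer and a row-wise
#' softmax.
#'
#' @param graph a [population_graph()]
#' @param model a trained model from [train_gcn()]
#' @return N x C matrix of probabilities; rows sum to 1
#' @export
forward <- function(graph, model) {
  stopifnot(inherits(graph, "population_graph"),
            inherits(model, "unb_gcn_model"))
  if (ncol(graph$X) != nrow(model$params$theta[[1L]])) {
    abort_fmt("graph has %d features but model expects %d",
              ncol(graph$X), nrow(model$params$theta[[1L]]))
  }
  S <- renormalized_propagation(graph$W)
  out <- gcn_forward_full(graph$X, S, model$params, drop_masks = NULL)
  colnames(out$probs) <- model$classes
  rownames(out$probs) <- rownames(graph$X)
  out$probs
}

#' Train the semi-supervised graph convolutional classifier
#'
#' Whole-graph transductive training: every node (labeled or not) takes
#' part in propagation, but the cross-entropy loss -- minimized with
#' Adam -- is computed on the train-mask nodes only, so test labels
#' never influence gradients. Inverted dropout is applied to the input
#' of each hidden layer during training. With a fixed `config$seed` the
#' loss history and final weights are reproducible bit for bit.
#'
#' @param graph a [population_graph()] with a nonempty train mask
#'   covering at least two classes
#' @param config a [model_config()]
#' @return an object of class `unb_gcn_model`: layer weights, attention
#'   parameters (if enabled), attention map on the training graph,
#'   per-epoch loss history, class levels and the config snapshot
#' @export
train_gcn <- function(graph, config = model_config()) {
  stopifnot(inherits(graph, "population_graph"),
            inherits(config, "model_config"))
  mask <- graph$train_mask
  if (!any(mask)) abort_fmt("train mask is empty")
  labels <- droplevels(as.factor(graph$labels[mask]))
  if (nlevels(labels) < 2L) abort_fmt("train mask covers a single class")
  classes <- levels(droplevels(as.factor(graph$labels[mask])))
  n <- nrow(graph$X); m <- ncol(graph$X)
  n_class <- length(classes)
  K <- config$hidden_layers
  yi <- match(as.character(graph$labels), classes)
  midx <- which(mask)
  n_lab <- length(midx)

  S <- renormalized_propagation(graph$W)

  with_seed(config$seed, {
    params <- list(theta = vector("list", K + 1L), attention = NULL)
    if (config$attention_enabled) {
      # zero init: attention starts uniform (A = 1/M), i.e. at the plain-GCN
      # operating point, and moves away only as the loss demands; a scaled
      # random init saturates the softmax because X X^T entries are O(M)
      params$attention <- list(W = matrix(0, n, m), b = numeric(m))
    }
    dims <- c(m, rep(config$hidden_width, K), n_class)
    for (k in seq_len(K + 1L)) {
      params$theta[[k]] <- glorot_uniform(dims[k], dims[k + 1L])
    }

    # Adam state mirrors the parameter list
    flat <- function(p) c(if (!is.null(p$attention)) list(p$attention$W, p$attention$b),
                          p$theta)
    zeros_like <- lapply(flat(params), function(x) x * 0)
    mstate <- zeros_like; vstate <- zeros_like
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    history <- numeric(config$epochs)
    X <- graph$X

    for (epoch in seq_len(config$epochs)) {
      drop_masks <- NULL
      if (config$dropout > 0) {
        drop_masks <- lapply(seq_len(K), function(k) {
          d <- dims[if (k == 1L) 1L else k]
          keep <- matrix(stats::rbinom(n * d, 1L, 1 - config$dropout), n, d)
          keep / (1 - config$dropout)
        })
      }
      fw <- gcn_forward_full(X, S, params, drop_masks)
      p_true <- fw$probs[cbind(midx, yi[midx])]
      history[epoch] <- -mean(log(pmax(p_true, 1e-300)))

      # ---- backward pass ----
      dO <- matrix(0, n, n_class)
      dO[midx, ] <- fw$probs[midx, , drop = FALSE]
      dO[cbind(midx, yi[midx])] <- dO[cbind(midx, yi[midx])] - 1
      dO <- dO / n_lab

      grads <- list(theta = vector("list", K + 1L), attention = NULL)
      SH <- S %*% fw$H[[K + 1L]]
      grads$theta[[K + 1L]] <- crossprod(SH, dO)
      dH <- S %*% dO %*% t(params$theta[[K + 1L]])   # S symmetric
      for (k in rev(seq_len(K))) {
        dU <- dH * (fw$U[[k]] > 0)
        SD <- S %*% fw$D[[k]]
        grads$theta[[k]] <- crossprod(SD, dU)
        dD <- S %*% dU %*% t(params$theta[[k]])
        if (!is.null(drop_masks)) dD <- dD * drop_masks[[k]]
        dH <- dD
      }
      if (!is.null(params$attention)) {
        dZ <- dH
        A <- fw$att$A
        dA <- dZ * X
        # softmax backward, row-wise
        dG <- A * (dA - rowSums(dA * A))
        Y <- tcrossprod(X)
        grads$attention <- list(W = crossprod(Y, dG), b = colSums(dG))
      }

      # ---- Adam update with decoupled-from-loss L2 on the gradient ----
      gflat <- flat(grads)
      pflat <- flat(params)
      for (j in seq_along(pflat)) {
        g <- gflat[[j]] + config$weight_decay * pflat[[j]]
        mstate[[j]] <- b1 * mstate[[j]] + (1 - b1) * g
        vstate[[j]] <- b2 * vstate[[j]] + (1 - b2) * g^2
        mhat <- mstate[[j]] / (1 - b1^epoch)
        vhat <- vstate[[j]] / (1 - b2^epoch)
        pflat[[j]] <- pflat[[j]] - config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
      j <- 1L
      if (!is.null(params$attention)) {
        params$attention$W <- pflat[[1L]]
        params$attention$b <- as.numeric(pflat[[2L]])
        j <- 3L
      }
      for (k in seq_len(K + 1L)) params$theta[[k]] <- pflat[[j + k - 1L]]
    }

    attention_map <- if (config$attention_enabled) {
      attention_forward(X, params$attention)$A
    } else {
      NULL
    }
    structure(
      list(params = params, classes = classes, history = history,
           attention_map = attention_map, config = config,
           n_nodes = n, n_features = m),
      class = "unb_gcn_model"
    )
  })
}

#' @export
print.unb_gcn_model <- function(x, ...) {
  cat(sprintf("<unb_gcn_model> %d nodes, %d features -> %s; %d hidden layers%s\n",
              x$n_nodes, x$n_features, paste(x$classes, collapse = "/"),
              x$config$hidden_layers,
              if (x$config$attention_enabled) " + attention" else ""))
  cat(sprintf("  final training loss: %.4f\n", utils::tail(x$history, 1)))
  invisible(x)
}

#' Predict node labels
#'
#' Argmax of the deterministic forward probabilities on the masked
#' nodes; exact ties resolve to the lowest class index.
#'
#' @param graph a [population_graph()]
#' @param model a trained model
#' @param mask logical mask of nodes to predict (default: test mask)
#' @return list with `labels` (factor on masked nodes), `probs` (their
#'   probability rows) and `mask`
#' @export
predict_gcn <- function(graph, model, mask = graph$test_mask) {
  probs <- forward(graph, model)
  mask <- as.logical(mask)
  pm <- probs[mask, , drop = FALSE]
  idx <- max.col(pm, ties.method = "first")
  list(labels = factor(model$classes[idx], levels = model$classes),
       probs = pm, mask = mask)
}

# split metrics for one trained split (binary AUC on the positive class)
split_metrics <- function(pred, truth, positive, probs = NULL) {
  rep_ <- classification_report(pred, truth, positive)
  auc <- NA_real_
  if (!is.null(probs) && nlevels(as.factor(truth)) == 2L &&
      positive %in% colnames(probs)) {
    auc <- tryCatch(
      roc_auc(probs[, positive], truth, positive_class = positive, ci = FALSE)$auc,
      error = function(e) NA_real_)
  }
  c(ACC = rep_$ACC, SEN = rep_$SEN, SPE = rep_$SPE, AUC = auc)
}

#' Repeated stratified-split cross-validation
#'
#' Repeatedly holds out a stratified fraction of the labeled subjects as
#' test nodes, trains transductively (test nodes stay in the graph,
#' unlabeled) and reports accuracy, sensitivity, specificity and AUC per
#' split plus their mean and SD. The defaults mirror the study protocol:
#' 90/10 random splits repeated 10 times.
#'
#' @param features numeric matrix, subjects x features (e.g. a
#'   biomarker matrix)
#' @param phenotypes phenotype data.frame for [build_adjacency()]
#' @param labels factor of diagnoses, same subject order
#' @param config a [model_config()]
#' @param n_repeats number of random splits
#' @param test_fraction held-out fraction per class
#' @param spec an [edge_spec()]
#' @param positive_class class treated as positive for SEN/SPE/AUC
#'   (default: first level)
#' @param seed master seed for the split sequence
#' @return list with `splits` (data.frame of per-split metrics),
#'   `mean` and `sd` (named vectors)
#' @export
cross_validate <- function(features, phenotypes, labels,
                           config = model_config(), n_repeats = 10L,
                           test_fraction = 0.1, spec = default_edge_spec(),
                           positive_class = NULL, seed = 1L) {
  features <- as.matrix(features)
  labels <- as.factor(labels)
  n <- nrow(features)
  stopifnot(length(labels) == n, nrow(phenotypes) == n)
  if (is.null(positive_class)) positive_class <- levels(labels)[1L]
  W <- build_adjacency(phenotypes, spec)
  labeled <- which(!is.na(labels))

  res <- with_seed(seed, {
    out <- vector("list", n_repeats)
    for (r in seq_len(n_repeats)) {
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        test_idx <- unlist(lapply(split(labeled, labels[labeled]), function(ix) {
          if (length(ix) == 0L) return(integer(0))
          sample(ix, max(1L, round(test_fraction * length(ix))))
        }), use.names = FALSE)
        train_idx <- setdiff(labeled, test_idx)
        if (nlevels(droplevels(labels[train_idx])) == nlevels(droplevels(labels[labeled])) &&
            length(test_idx) > 0L) { ok <- TRUE; break }
        warning("resampling split: a class was absent", call. = FALSE)
      }
      if (!ok) abort_fmt("could not draw a split covering every class")
      g <- population_graph(
        X = features, W = W, labels = replace(labels, test_idx, NA),
        train_mask = seq_len(n) %in% train_idx,
        test_mask = seq_len(n) %in% test_idx,
        phenotypes = phenotypes)
      cfg <- config; cfg$seed <- config$seed + r
      model <- train_gcn(g, cfg)
      pred <- predict_gcn(g, model)
      out[[r]] <- split_metrics(pred$labels, labels[test_idx],
                                positive_class, pred$probs)
    }
    out
  })
  splits <- as.data.frame(do.call(rbind, res))
  splits$split <- seq_len(n_repeats)
  list(splits = splits,
       mean = colMeans(splits[, c("ACC", "SEN", "SPE", "AUC")], na.rm = TRUE),
       sd = apply(splits[, c("ACC", "SEN", "SPE", "AUC")], 2L, stats::sd, na.rm = TRUE))
}

#' Exhaustive grid search over model configurations
#'
#' Evaluates every combination of the supplied parameter values with
#' [cross_validate()] and returns the full score table plus the best
#' configuration: highest mean accuracy, ties broken by smaller model
#' size (total parameter count) and then by earlier grid order.
#'
#' @param features,phenotypes,labels as in [cross_validate()]
#' @param grid named list of parameter value vectors; names must be
#'   [model_config()] arguments (e.g. `hidden_width`, `epochs`)
#' @param base_config config supplying the non-gridded parameters
#' @param ... passed on to [cross_validate()]
#' @return list with `best_config`, `best_row` and `table` (one row per
#'   combination, with mean metrics)
#' @export
grid_search <- function(features, phenotypes, labels, grid,
                        base_config = model_config(), ...) {
  if (!is.list(grid) || length(grid) == 0L || is.null(names(grid))) {
    abort_fmt("grid must be a nonempty named list of parameter vectors")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  scores <- vector("list", nrow(combos))
  sizes <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    cfg <- base_config
    for (nm in names(combos)) cfg[[nm]] <- combos[[nm]][i]
    cfg <- do.call(model_config, cfg[names(formals(model_config))])
    cv <- cross_validate(features, phenotypes, labels, config = cfg, ...)
    m <- ncol(as.matrix(features))
    n_class <- nlevels(droplevels(as.factor(labels)))
    dims <- c(m, rep(cfg$hidden_width, cfg$hidden_layers), n_class)
    sizes[i] <- sum(dims[-length(dims)] * dims[-1L])
    scores[[i]] <- cv$mean
  }
  tab <- cbind(combos, do.call(rbind, scores), model_size = sizes)
  ord <- order(-tab$ACC, tab$model_size, seq_len(nrow(tab)))
  best <- ord[1L]
  best_cfg <- base_config
  for (nm in names(combos)) best_cfg[[nm]] <- combos[[nm]][best]
  best_cfg <- do.call(model_config, best_cfg[names(formals(model_config))])
  list(best_config = best_cfg, best_row = tab[best, , drop = FALSE], table = tab)
}

#' Rank ROIs by attention weight
#'
#' Averages the trained attention map over nodes, normalizes the
#' per-ROI means to sum to 1, and returns them sorted descending. ROIs
#' with normalized weight below the 0.05 display threshold are flagged
#' (`displayed = FALSE`) rather than removed.
#'
#' @param model a trained model with attention enabled
#' @param roi_names optional feature/ROI names (default: from the map)
#' @param display_threshold weights below it are flagged, default 0.05
#' @return data.frame with columns `roi`, `raw_weight`,
#'   `normalized_weight`, `displayed`, sorted by weight
#' @export
rank_roi_attention <- function(model, roi_names = NULL,
                               display_threshold = 0.05) {
  stopifnot(inherits(model, "unb_gcn_model"))
  if (!model$config$attention_enabled || is.null(model$attention_map)) {
    abort_fmt("model was trained without the attention module")
  }
  raw <- colMeans(model$attention_map)
  if (is.null(roi_names)) {
    roi_names <- if (!is.null(names(raw))) names(raw) else
      sprintf("feature%02d", seq_along(raw))
  }
  w <- raw / sum(raw)
  ord <- order(-w)
  data.frame(roi = roi_names[ord], raw_weight = raw[ord],
             normalized_weight = w[ord],
             displayed = w[ord] >= display_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
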
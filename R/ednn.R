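#' Configuration of the encoder-decoder neural network
#'
#' The EDNN is a shallow network: K inputs (a node's direct-neighbor
#' vector), one hidden layer of rectifier (ReLU) units whose activations are
#' the node embedding, and K logistic (sigmoid) outputs predicting the
#' node's random-walk reach profile. It is trained by mean squared error.
#' The 10-unit default hidden layer is the dimension at which the
#' reconstruction MSE bottoms out among {2, 5, 10, 15, 20} on data of this
#' kind; see [hidden_dim_sweep()] to re-run that comparison.
#'
#' @param hidden_dim embedding dimension (default 10, minimum 2).
#' @param epochs training epochs (default 500; reconstruction must be fit
#'   tightly for embedding distances to track neighborhood change, and the
#'   training sets here are small).
#' @param batch_size minibatch size (default 32).
#' @param learning_rate Adam step size (default 1e-2).
#' @param seed RNG seed controlling initialization and batch shuffling.
#' @return object of class `ednn_config`.
#' @export
ednn_config <- function(hidden_dim = 10, epochs = 500, batch_size = 32,
                        learning_rate = 1e-2, seed = 1) {
  stopifnot(hidden_dim >= 2, epochs >= 1, batch_size >= 1, learning_rate > 0)
  structure(list(hidden_dim = as.integer(hidden_dim),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = seed,
                 hidden_activation = "relu", output_activation = "logistic",
                 loss = "mse"),
            class = "ednn_config")
}

#' Assemble the joint EDNN training set from multiplexes and walk profiles
#'
#' One training row per (multiplex, layer, node): the input is the node's
#' direct-neighbor vector in that layer, the target its walk-reach profile.
#' All multiplexes are pooled so that every node of every layer of every
#' individual is embedded into one joint space.
#'
#' @param multiplexes list of [build_multiplex()] objects sharing one node
#'   set.
#' @param profiles list of [walk_profiles()] results, parallel to
#'   `multiplexes`.
#' @param weighted use weighted (`TRUE`) or binary neighbor vectors.
#' @return list with `inputs` (n x K), `targets` (n x K) and `index`
#'   (data.frame `owner`, `layer`, `node`).
#' @export
assemble_training_set <- function(multiplexes, profiles, weighted = TRUE) {
  if (length(multiplexes) == 0L) stop("empty multiplex list")
  if (length(profiles) != length(multiplexes)) {
    stop("profiles must parallel multiplexes")
  }
  ids <- multiplexes[[1L]]$node_ids
  xs <- vector("list", length(multiplexes))
  ys <- vector("list", length(multiplexes))
  idxs <- vector("list", length(multiplexes))
  for (i in seq_along(multiplexes)) {
    mpx <- multiplexes[[i]]
    if (!identical(mpx$node_ids, ids)) stop("multiplexes must share one node set")
    ps <- profiles[[i]]
    if (nrow(ps$index) != length(mpx$layers) * length(ids)) {
      stop("profile set ", i, " does not cover every (layer, node)")
    }
    x <- matrix(0, nrow(ps$index), length(ids), dimnames = list(NULL, ids))
    for (r in seq_len(nrow(ps$index))) {
      x[r, ] <- neighbor_vector(mpx, ps$index$layer[r], ps$index$node[r],
                                weighted = weighted)
    }
    xs[[i]] <- x
    ys[[i]] <- ps$profiles[, ids, drop = FALSE]
    idxs[[i]] <- data.frame(owner = mpx$owner, ps$index,
                            stringsAsFactors = FALSE)
  }
  list(inputs = do.call(rbind, xs), targets = do.call(rbind, ys),
       index = do.call(rbind, idxs))
}

relu <- function(z) pmax(z, 0)
sigmoid <- function(z) 1 / (1 + exp(-z))

ednn_forward <- function(model, x) {
  h <- relu(sweep(x %*% model$W1, 2L, model$b1, `+`))
  yhat <- sigmoid(sweep(h %*% model$W2, 2L, model$b2, `+`))
  list(h = h, yhat = yhat)
}

#' Train the encoder-decoder network and extract node embeddings
#'
#' Glorot-uniform initialization, minibatch Adam on the mean squared error
#' between logistic outputs and reach-profile targets. The hidden-layer
#' activations of the trained network are the node embeddings. Training is
#' deterministic given `config$seed` (single-threaded base-R matrix ops).
#'
#' @param rows training set from [assemble_training_set()].
#' @param config an [ednn_config()].
#' @return list with `model` (class `ednn_model`: weights, config, loss
#'   history) and `embedding` (class `embedding_set`: `index` data.frame and
#'   `vectors` matrix with `hidden_dim` columns).
#' @export
train_ednn <- function(rows, config = ednn_config()) {
  stopifnot(inherits(config, "ednn_config"))
  x <- rows$inputs; y <- rows$targets
  if (is.null(x) || nrow(x) == 0L) stop("empty training set")
  n <- nrow(x); K <- ncol(x); d <- config$hidden_dim
  if (d >= K) warning("hidden_dim >= input dimension: no compression")
  set.seed(as.integer(config$seed))
  lim1 <- sqrt(6 / (K + d)); lim2 <- sqrt(6 / (d + K))
  model <- list(
    W1 = matrix(stats::runif(K * d, -lim1, lim1), K, d),
    b1 = numeric(d),
    W2 = matrix(stats::runif(d * K, -lim2, lim2), d, K),
    b2 = numeric(K),
    config = config, node_ids = colnames(x)
  )
  # Adam state
  mom <- lapply(model[1:4], function(p) p * 0)
  vel <- lapply(model[1:4], function(p) p * 0)
  b1m <- 0.9; b2m <- 0.999; eps <- 1e-8; lr <- config$learning_rate
  step <- 0L
  loss_history <- numeric(config$epochs + 1L)
  full <- ednn_forward(model, x)
  loss_history[1L] <- mean((full$yhat - y)^2)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    for (s0 in starts) {
      bi <- ord[s0:min(s0 + config$batch_size - 1L, n)]
      xb <- x[bi, , drop = FALSE]; yb <- y[bi, , drop = FALSE]
      z1 <- sweep(xb %*% model$W1, 2L, model$b1, `+`)
      h <- relu(z1)
      yhat <- sigmoid(sweep(h %*% model$W2, 2L, model$b2, `+`))
      m <- nrow(xb)
      # dL/dyhat for MSE over all n*K output entries
      dy <- 2 * (yhat - yb) / (m * K)
      dz2 <- dy * yhat * (1 - yhat)
      gW2 <- crossprod(h, dz2); gb2 <- colSums(dz2)
      dh <- dz2 %*% t(model$W2)
      dz1 <- dh * (z1 > 0)
      gW1 <- crossprod(xb, dz1); gb1 <- colSums(dz1)
      grads <- list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
      step <- step + 1L
      for (p in names(grads)) {
        mom[[p]] <- b1m * mom[[p]] + (1 - b1m) * grads[[p]]
        vel[[p]] <- b2m * vel[[p]] + (1 - b2m) * grads[[p]]^2
        mhat <- mom[[p]] / (1 - b1m^step)
        vhat <- vel[[p]] / (1 - b2m^step)
        model[[p]] <- model[[p]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    full <- ednn_forward(model, x)
    loss_history[epoch + 1L] <- mean((full$yhat - y)^2)
    if (!is.finite(loss_history[epoch + 1L])) {
      stop("non-finite training loss at epoch ", epoch,
           " (learning rate ", lr, ", batch size ", config$batch_size, ")")
    }
  }
  class(model) <- "ednn_model"
  model$loss_history <- loss_history
  emb <- ednn_forward(model, x)$h
  colnames(emb) <- paste0("v", seq_len(d))
  embedding <- structure(
    list(index = rows$index, vectors = emb, config = config,
         final_loss = loss_history[length(loss_history)]),
    class = "embedding_set")
  list(model = model, embedding = embedding)
}

#' @export
print.ednn_model <- function(x, ...) {
  cat("ednn_model:", nrow(x$W1), "inputs ->", ncol(x$W1),
      "hidden (relu) ->", ncol(x$W2), "outputs (logistic)\n")
  lh <- x$loss_history
  cat(sprintf("  MSE %.3g -> %.3g over %d epochs\n",
              lh[1L], lh[length(lh)], length(lh) - 1L))
  invisible(x)
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("embedding_set:", nrow(x$vectors), "points in",
      ncol(x$vectors), "dimensions; final training MSE",
      signif(x$final_loss, 4), "\n")
  invisible(x)
}

#' Embed a (possibly unseen) node through the trained encoder
#'
#' The encoder parameters are shared across nodes, so any direct-neighbor
#' vector over the training node set — including one for a node never seen
#' during training — maps deterministically to an embedding.
#'
#' @param model a trained `ednn_model`.
#' @param neighbor_vec numeric vector of length K (the input dimension).
#' @return embedding vector of length `hidden_dim`.
#' @export
embed_node <- function(model, neighbor_vec) {
  stopifnot(inherits(model, "ednn_model"))
  if (length(neighbor_vec) != nrow(model$W1)) {
    stop("neighbor vector length ", length(neighbor_vec),
         " does not match input dimension ", nrow(model$W1))
  }
  drop(relu(matrix(neighbor_vec, 1L) %*% model$W1 + model$b1))
}

#' Reconstruction error across embedding dimensions
#'
#' Retrains the EDNN for each candidate hidden dimension and reports the
#' final training MSE (optionally on a held-out 10% validation split), the
#' quantity by which the default dimension of 10 was chosen.
#'
#' @param rows training set from [assemble_training_set()].
#' @param dims candidate hidden dimensions (default `c(2, 5, 10, 15, 20)`).
#' @param config base [ednn_config()]; `hidden_dim` is overridden per run.
#' @param validation_split fraction held out for validation MSE (0 disables).
#' @return data.frame with `hidden_dim`, `train_mse`, `val_mse`.
#' @export
hidden_dim_sweep <- function(rows, dims = c(2, 5, 10, 15, 20),
                             config = ednn_config(), validation_split = 0) {
  n <- nrow(rows$inputs)
  val <- integer(0)
  if (validation_split > 0) {
    set.seed(derive_seed(config$seed, 99L))
    val <- sample.int(n, max(1L, floor(validation_split * n)))
  }
  tr <- setdiff(seq_len(n), val)
  res <- data.frame(hidden_dim = dims, train_mse = NA_real_, val_mse = NA_real_)
  for (i in seq_along(dims)) {
    cfg <- config; cfg$hidden_dim <- as.integer(dims[i])
    sub <- list(inputs = rows$inputs[tr, , drop = FALSE],
                targets = rows$targets[tr, , drop = FALSE],
                index = rows$index[tr, , drop = FALSE])
    fit <- suppressWarnings(train_ednn(sub, cfg))
    res$train_mse[i] <- fit$embedding$final_loss
    if (length(val)) {
      pred <- ednn_forward(fit$model, rows$inputs[val, , drop = FALSE])$yhat
      res$val_mse[i] <- mean((pred - rows$targets[val, , drop = FALSE])^2)
    }
  }
  res
}

#' Run the full embedding pipeline on a set of multiplexes
#'
#' Convenience wrapper: compute walk-reach profiles for every multiplex,
#' assemble the joint training set, and train the EDNN once.
#'
#' @param multiplexes list of [build_multiplex()] objects (or a single one).
#' @param config an [ednn_config()].
#' @param walk_length,n_repeats,walk_mode,weighted walk parameters, see
#'   [walk_profiles()].
#' @param walk_seed master seed for the walk simulations (defaults to
#'   `config$seed`).
#' @param profiles optional precomputed list of [walk_profiles()] results;
#'   when supplied the walk parameters are ignored.
#' @return an `embedding_set` (with the trained model attached as attribute
#'   `model`).
#' @export
mnda_embed <- function(multiplexes, config = ednn_config(), walk_length = 5,
                       n_repeats = 100, walk_mode = "monte_carlo",
                       weighted = TRUE, walk_seed = NULL, profiles = NULL) {
  if (inherits(multiplexes, "multiplex_network")) multiplexes <- list(multiplexes)
  if (is.null(profiles)) {
    walk_seed <- walk_seed %||% config$seed
    profiles <- lapply(seq_along(multiplexes), function(i) {
      walk_profiles(multiplexes[[i]], walk_length = walk_length,
                    n_repeats = n_repeats, seed = derive_seed(walk_seed, i),
                    mode = walk_mode, weighted = weighted)
    })
  }
  rows <- assemble_training_set(multiplexes, profiles, weighted = weighted)
  fit <- train_ednn(rows, config)
  emb <- fit$embedding
  attr(emb, "model") <- fit$model
  emb
}
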
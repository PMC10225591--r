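# Small fixtures built in code, shared across test files.

# toy abundance table: n samples x K taxa of Poisson counts, two time points
toy_table <- function(n_ind = 5, K = 4, seed = 1, two_timepoints = FALSE) {
  set.seed(seed)
  n <- if (two_timepoints) 2L * n_ind else n_ind
  counts <- matrix(rpois(n * K, lambda = 20), n, K)
  ids <- sprintf("ind%d", seq_len(n_ind))
  if (two_timepoints) {
    sample_id <- c(paste0(ids, "_t1"), paste0(ids, "_t2"))
    meta <- data.frame(sample_id = sample_id,
                       individual_id = rep(ids, 2L),
                       time_point = rep(c("t1", "t2"), each = n_ind))
  } else {
    meta <- data.frame(sample_id = paste0(ids, "_t1"),
                       individual_id = ids, time_point = "t1")
  }
  dimnames(counts) <- list(meta$sample_id, paste0("tax", seq_len(K)))
  abundance_table(counts, meta)
}

# path graph a - b - c as a two-layer multiplex (identical layers)
path_multiplex <- function(w_ab = 1, w_bc = 1) {
  ids <- c("a", "b", "c")
  m <- matrix(0, 3, 3, dimnames = list(ids, ids))
  m["a", "b"] <- m["b", "a"] <- w_ab
  m["b", "c"] <- m["c", "b"] <- w_bc
  build_multiplex(list(layer1 = m, layer2 = m))
}

# random connected-ish weighted graph as symmetric adjacency
random_adjacency <- function(K = 8, p = 0.4, seed = 1) {
  set.seed(seed)
  m <- matrix(0, K, K, dimnames = list(paste0("n", 1:K), paste0("n", 1:K)))
  for (i in 1:(K - 1)) for (j in (i + 1):K) {
    if (runif(1) < p) m[i, j] <- m[j, i] <- runif(1, 0.1, 1)
  }
  # ensure no isolated nodes: chain fallback
  for (i in which(rowSums(m) == 0)) {
    j <- if (i == 1) 2 else i - 1
    m[i, j] <- m[j, i] <- 0.5
  }
  m
}

# independent brute-force enumeration of "visited within T steps" reach
# probabilities: depth-first expansion over all length-T weighted paths.
enumerate_reach <- function(w, start, walk_length) {
  K <- nrow(w)
  reach <- numeric(K)
  recurse <- function(pos, visited, prob, steps_left) {
    if (steps_left == 0L) {
      reach[visited] <<- reach[visited] + prob
      return(invisible())
    }
    nb <- which(w[pos, ] > 0)
    if (length(nb) == 0L) {          # dead end: walk terminates
      reach[visited] <<- reach[visited] + prob
      return(invisible())
    }
    pr <- w[pos, nb] / sum(w[pos, nb])
    for (k in seq_along(nb)) {
      recurse(nb[k], union(visited, nb[k]), prob * pr[k], steps_left - 1L)
    }
  }
  recurse(start, integer(0), 1, walk_length)
  reach
}

# quick EDNN config for tests
quick_config <- function(seed = 1, epochs = 60, hidden_dim = 4) {
  ednn_config(hidden_dim = hidden_dim, epochs = epochs, seed = seed,
              learning_rate = 1e-2)
}
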
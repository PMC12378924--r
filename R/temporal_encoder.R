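#' Temporal graph encoder configuration
#'
#' Defaults follow the reference configuration: a 4-layer ontology-aware
#' graph encoder with 256-dimensional hidden representations and 8 attention
#' heads, a disentangled latent made of 6 factors of 64 dimensions each
#' (pooled latent dimension 384), Adam with learning rate 1e-4 and weight
#' decay 1e-5, regularization coefficients 0.01 and dropout 0.3.
#'
#' @param layers number of propagation layers.
#' @param hidden_dim hidden width of each layer.
#' @param n_factors number of latent clinical factors `K`.
#' @param factor_dim dimension of each factor block; the pooled latent
#'   dimension is `n_factors * factor_dim`.
#' @param attention_heads heads used by attention pooling.
#' @param dropout dropout rate on MLP projections (training mode only; all
#'   evaluation paths are deterministic).
#' @param learning_rate,weight_decay Adam settings for the trainable heads.
#' @param reg_coefficient default weight of the covariance/temporal
#'   regularizers.
#' @param pooling `"mean"` (exactly permutation invariant, default) or
#'   `"attention"`.
#' @param seed seed for the encoder's parameter initialization.
#' @return object of class `encoder_config`.
#' @export
encoder_config <- function(layers = 4L, hidden_dim = 256L, n_factors = 6L,
                           factor_dim = 64L, attention_heads = 8L,
                           dropout = 0.3, learning_rate = 1e-4,
                           weight_decay = 1e-5, reg_coefficient = 0.01,
                           pooling = c("mean", "attention"), seed = 1L) {
  pooling <- match.arg(pooling)
  cfg <- list(layers = as.integer(layers), hidden_dim = as.integer(hidden_dim),
              n_factors = as.integer(n_factors),
              factor_dim = as.integer(factor_dim),
              latent_dim = as.integer(n_factors) * as.integer(factor_dim),
              attention_heads = as.integer(attention_heads),
              dropout = dropout, learning_rate = learning_rate,
              weight_decay = weight_decay,
              reg_coefficient = reg_coefficient,
              pooling = pooling, seed = as.integer(seed))
  stop_if(any(unlist(cfg[c("layers", "hidden_dim", "n_factors", "factor_dim",
                           "attention_heads")]) <= 0),
          "encoder dimensions must be positive")
  structure(cfg, class = "encoder_config")
}

# Deterministic (seeded) encoder parameters for a given input dimension.
# Message transforms are per edge label; `zero_messages` freezes propagation
# to the residual identity (useful for exact expected values).
encoder_params <- function(d_in, config, labels = c("intra", "inter",
                                                    "ontology"),
                           zero_messages = FALSE) {
  with_seed(substream_seed(config$seed, "encoder"), {
    W_in <- xavier_matrix(d_in, config$hidden_dim)
    W_msg <- stats::setNames(lapply(labels, function(l) {
      if (zero_messages) matrix(0, config$hidden_dim, config$hidden_dim)
      else xavier_matrix(config$hidden_dim, config$hidden_dim) * 0.1
    }), labels)
    W_out <- xavier_matrix(config$hidden_dim, config$latent_dim)
    queries <- xavier_matrix(config$attention_heads, config$hidden_dim)
    list(W_in = W_in, W_msg = W_msg, W_out = W_out, queries = queries)
  })
}

#' Relation-tensor feature propagation
#'
#' Mixes a clinical state through a stack of relation slices:
#' `x~ = sum_r t(W_r) (G_r x)`, where each slice `G_r` encodes one semantic
#' relation over the vocabulary and `W_r` maps its propagated activation.
#'
#' @param state numeric length-`|E|` vector.
#' @param relation_tensor list with `slices` (list of `|E| x |E|` matrices)
#'   and `transforms` (list of `|E| x m` matrices, same length; identity if
#'   omitted).
#' @return propagated feature vector of length `m`.
#' @export
relation_tensor_mix <- function(state, relation_tensor) {
  slices <- relation_tensor$slices
  stop_if(length(slices) < 1, "relation tensor needs at least one slice")
  transforms <- relation_tensor$transforms %||%
    lapply(slices, function(s) diag(nrow(s)))
  n <- length(state)
  out <- NULL
  for (r in seq_along(slices)) {
    G <- slices[[r]]
    stop_if(nrow(G) != n || ncol(G) != n,
            "slice ", r, " has shape ", nrow(G), "x", ncol(G),
            " but |E| = ", n)
    W <- transforms[[r]]
    stop_if(nrow(W) != n, "transform ", r, " row count must be |E|")
    term <- as.numeric(t(W) %*% (G %*% state))
    out <- if (is.null(out)) term else out + term
  }
  out
}

#' Encode a patient event graph into a latent trajectory
#'
#' Runs `config$layers` rounds of relation-aware residual message passing on
#' the patient's temporal event graph (edge labels `intra`, `inter`,
#' `ontology`), pools same-timestamp node embeddings with a permutation
#' invariant pooling function, and projects to the pooled latent dimension.
#' Visits with no events yield a zero latent. Deterministic given seed and
#' config.
#'
#' @param event_graph a `temporal_event_graph` from [build_event_graph()].
#' @param table an `embedding_table` covering all concepts.
#' @param config an [encoder_config].
#' @param params optional explicit parameter list (from `encoder_params`);
#'   `zero_messages = TRUE` builds parameters whose message transforms are
#'   zero, making propagation the identity.
#' @param zero_messages see above.
#' @return object of class `latent_trajectory`: `z` (`T x latent_dim`
#'   matrix), `n_factors`, `factor_dim`.
#' @export
encode_trajectory <- function(event_graph, table, config,
                              params = NULL, zero_messages = FALSE) {
  stop_if(nrow(event_graph$nodes) == 0, "event graph has no nodes")
  E <- table$matrix
  if (is.null(params)) {
    params <- encoder_params(ncol(E), config, zero_messages = zero_messages)
  }
  nodes <- event_graph$nodes
  edges <- event_graph$edges
  H <- E[nodes$concept, , drop = FALSE] %*% params$W_in
  # undirected neighbor lists with edge labels
  if (nrow(edges) > 0) {
    nb_from <- c(edges$from, edges$to)
    nb_to <- c(edges$to, edges$from)
    nb_lab <- c(edges$label, edges$label)
  } else {
    nb_from <- integer(0); nb_to <- integer(0); nb_lab <- character(0)
  }
  hd <- config$hidden_dim
  for (layer in seq_len(config$layers)) {
    M <- matrix(0, nrow(H), hd)
    if (length(nb_from) > 0) {
      for (i in unique(nb_from)) {
        sel <- which(nb_from == i)
        keys <- t(vapply(sel, function(k) {
          as.numeric(crossprod(params$W_msg[[nb_lab[k]]], H[nb_to[k], ]))
        }, numeric(hd)))
        scores <- as.numeric(keys %*% H[i, ]) / sqrt(hd)
        a <- softmax(scores)
        M[i, ] <- as.numeric(a %*% keys)
      }
    }
    H <- H + pmax(M, 0)
  }
  Tn <- event_graph$n_timestamps
  Z <- matrix(0, Tn, config$latent_dim)
  for (t in seq_len(Tn)) {
    here <- which(nodes$t == t)
    if (length(here) == 0) next   # empty encounter: zero latent
    pooled <- pool_nodes(H[here, , drop = FALSE], config, params)
    Z[t, ] <- as.numeric(pooled %*% params$W_out)
  }
  structure(list(z = Z, n_factors = config$n_factors,
                 factor_dim = config$factor_dim),
            class = "latent_trajectory")
}

pool_nodes <- function(Hsub, config, params) {
  if (config$pooling == "mean" || nrow(Hsub) == 1) {
    return(colMeans(Hsub))
  }
  # multi-head attention pooling: each head weights nodes by a learned query;
  # head outputs are averaged (keeps the hidden dimension)
  heads <- lapply(seq_len(config$attention_heads), function(h) {
    a <- softmax(as.numeric(Hsub %*% params$queries[h, ]) /
                   sqrt(ncol(Hsub)))
    as.numeric(a %*% Hsub)
  })
  Reduce(`+`, heads) / length(heads)
}

#' Partition a latent vector into ordered factor blocks
#'
#' Splits `z` into `K` contiguous blocks of equal size whose concatenation
#' reproduces `z` exactly.
#'
#' @param z numeric vector (or a `latent_trajectory`, partitioned per row).
#' @param K number of factors; must divide `length(z)`.
#' @return list of `K` numeric vectors (or, for a trajectory, a list of `K`
#'   `T x (d/K)` matrices).
#' @export
factor_partition <- function(z, K) {
  if (inherits(z, "latent_trajectory")) {
    d <- ncol(z$z)
    stop_if(d %% K != 0, "latent dim ", d, " not divisible by K = ", K)
    w <- d / K
    return(lapply(seq_len(K), function(k) {
      z$z[, ((k - 1) * w + 1):(k * w), drop = FALSE]
    }))
  }
  d <- length(z)
  stop_if(d %% K != 0, "length(z) = ", d, " not divisible by K = ", K)
  w <- d / K
  lapply(seq_len(K), function(k) z[((k - 1) * w + 1):(k * w)])
}

#' Pairwise squared-cosine covariance penalty between factors
#'
#' `sum_{i != j} (cos(z_i, z_j))^2` over ordered factor pairs; zero for
#' mutually orthogonal factors, and a zero-norm factor contributes 0 to its
#' pairs. Invariant to positive rescaling of any factor.
#'
#' @param blocks list of numeric factor vectors (>= 2).
#' @return scalar penalty.
#' @export
covariance_loss <- function(blocks) {
  K <- length(blocks)
  stop_if(K < 2, "need at least two factors")
  norms <- vapply(blocks, function(b) sqrt(sum(b^2)), 0)
  total <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    if (norms[i] == 0 || norms[j] == 0) next
    cs <- sum(blocks[[i]] * blocks[[j]]) / (norms[i] * norms[j])
    total <- total + cs^2
  }
  total
}

#' Temporal smoothness penalty
#'
#' Penalizes abrupt latent shifts between consecutive timesteps. With
#' `per_factor = TRUE` the penalty is summed over factor blocks
#' (`sum_t sum_k ||dz_k(t)||^2`); with `FALSE` it is the whole-vector form
#' (`sum_t ||dz(t)||^2`). The two coincide for any complete partition.
#'
#' @param traj a `latent_trajectory` (or plain `T x d` matrix).
#' @param per_factor sum per factor block (requires factor metadata).
#' @param K factors used when `traj` is a plain matrix and
#'   `per_factor = TRUE`.
#' @return scalar penalty (0 when `T < 2`).
#' @export
temporal_smoothness_loss <- function(traj, per_factor = TRUE, K = NULL) {
  Z <- if (inherits(traj, "latent_trajectory")) traj$z else as.matrix(traj)
  if (nrow(Z) < 2) return(0)
  D <- diff(Z)
  if (!per_factor) return(sum(D^2))
  K <- K %||% if (inherits(traj, "latent_trajectory")) traj$n_factors else 1
  stop_if(ncol(Z) %% K != 0, "latent dim not divisible by K")
  w <- ncol(Z) / K
  total <- 0
  for (k in seq_len(K)) {
    total <- total + sum(D[, ((k - 1) * w + 1):(k * w), drop = FALSE]^2)
  }
  total
}

#' Gaussian-surrogate mutual-information penalty between factor blocks
#'
#' Estimates the redundancy between factor subspaces over a batch with a
#' Gaussian canonical-correlation surrogate: for each ordered pair of blocks
#' the penalty adds `-1/2 * sum log(1 - rho^2)` over canonical correlations
#' `rho`, with `rho^2` clipped at `1 - 1e-6`. Zero iff all blocks are
#' (Gaussian-)uncorrelated; always nonnegative.
#'
#' @param blocks list of `n x d_k` matrices, one per factor, sharing `n`.
#' @param min_batch minimum rows required for estimation.
#' @return scalar penalty.
#' @export
mi_disentanglement_loss <- function(blocks, min_batch = 8L) {
  K <- length(blocks)
  stop_if(K < 2, "need at least two factor blocks")
  n <- nrow(blocks[[1]])
  stop_if(n < min_batch, "batch size ", n, " below minimum ", min_batch)
  total <- 0
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    rho <- tryCatch(stats::cancor(blocks[[i]], blocks[[j]])$cor,
                    error = function(e) numeric(0))
    if (length(rho) == 0) next   # degenerate (constant) block: uncorrelated
    r2 <- pmin(rho^2, 1 - 1e-6)
    total <- total - 0.5 * sum(log(1 - r2))
  }
  total
}
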
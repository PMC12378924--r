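#' Initialize a concept embedding table
#'
#' Xavier-uniform initialization of one `d`-dimensional vector per concept,
#' seeded for reproducibility. Alternative initializations: the Laplacian
#' eigenmap of the ontology (`init = "eigenmap"`) or an externally adapted
#' matrix passed via `adapted`.
#'
#' @param kb a [knowledge_base].
#' @param d embedding dimension.
#' @param init one of `"xavier"`, `"eigenmap"`, `"adapted"`.
#' @param adapted `|E| x d` matrix used when `init = "adapted"`.
#' @param seed RNG seed for `"xavier"`.
#' @return object of class `embedding_table`: `matrix` (`|E| x d`, rows in
#'   vocabulary order) and `layer` index 0.
#' @export
init_embeddings <- function(kb, d, init = c("xavier", "eigenmap", "adapted"),
                            adapted = NULL, seed = 1L) {
  init <- match.arg(init)
  n <- length(kb$vocab)
  M <- switch(init,
    xavier = with_seed(seed, xavier_matrix(n, d)),
    eigenmap = {
      A <- hierarchy_adjacency(kb)
      laplacian_eigenmap(A, d)$vectors
    },
    adapted = {
      stop_if(is.null(adapted), "init='adapted' requires the adapted matrix")
      stop_if(nrow(adapted) != n || ncol(adapted) != d,
              "adapted matrix must be |E| x d")
      adapted
    })
  rownames(M) <- kb$vocab$concept_ids
  structure(list(matrix = M, layer = 0L), class = "embedding_table")
}

# undirected adjacency of the is-a hierarchy plus lateral edges
hierarchy_adjacency <- function(kb) {
  n <- length(kb$vocab)
  A <- matrix(0, n, n)
  he <- kb$ontology$hierarchy_edges
  if (nrow(he) > 0) {
    i <- concept_index(kb$vocab, he$child)
    j <- concept_index(kb$vocab, he$parent)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  le <- kb$ontology$lateral_edges
  if (nrow(le) > 0) {
    i <- concept_index(kb$vocab, le$child)
    j <- concept_index(kb$vocab, le$parent)
    A[cbind(i, j)] <- 1; A[cbind(j, i)] <- 1
  }
  diag(A) <- 0
  A
}

#' Attention-weighted neighborhood context vectors
#'
#' For every concept, an attention-weighted sum of its ontology neighbors'
#' embeddings. Similarity is scaled dot product (`e_i . e_j / sqrt(d)`) by
#' default or cosine. Isolated concepts keep their own embedding as context
#' (loss-neutral).
#'
#' @param table an `embedding_table`.
#' @param ontology an [ontology_graph].
#' @param similarity `"scaled_dot"` or `"cosine"`.
#' @return list: `context` (`|E| x d` matrix of context vectors) and
#'   `weights` (list of per-concept attention weight vectors, each summing
#'   to 1).
#' @export
neighborhood_attention <- function(table, ontology,
                                   similarity = c("scaled_dot", "cosine")) {
  similarity <- match.arg(similarity)
  E <- table$matrix
  d <- ncol(E)
  nb <- ontology_neighbors(ontology)
  ctx <- E
  weights <- vector("list", nrow(E))
  for (i in seq_len(nrow(E))) {
    js <- unique(nb[[i]]$neighbor)
    if (length(js) == 0) next
    scores <- vapply(js, function(j) {
      phi_similarity(E[i, ], E[j, ], similarity, d,
                     ids = rownames(E)[c(i, j)])
    }, 0)
    a <- softmax(scores)
    weights[[i]] <- stats::setNames(a, rownames(E)[js])
    ctx[i, ] <- as.numeric(a %*% E[js, , drop = FALSE])
  }
  list(context = ctx, weights = weights)
}

phi_similarity <- function(u, v, similarity, d, ids = NULL) {
  if (similarity == "scaled_dot") return(sum(u * v) / sqrt(d))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("zero-norm embedding under cosine similarity",
         if (!is.null(ids)) paste0(" (concepts ",
                                   paste(ids, collapse = ", "), ")"),
         call. = FALSE)
  }
  sum(u * v) / (nu * nv)
}

#' Relation-specific residual propagation over the ontology
#'
#' Applies `L` layers of the residual update
#' `e_i <- e_i + ReLU(sum_r sum_{j in N_r(i)} alpha_ij^(r) W_r e_j)`,
#' where the relation-specific attention uses keys `W_r e_j` and the softmax
#' is taken jointly over all (relation, neighbor) pairs of a concept, so the
#' weights form one distribution per node.
#'
#' @param table an `embedding_table`.
#' @param ontology an [ontology_graph].
#' @param transforms named list of `d x d` matrices, one per relation label
#'   occurring in the neighbor structure (including `"is_a"`/`"has_child"`).
#' @param L number of propagation layers, `>= 1`.
#' @param similarity passed to the attention scores.
#' @return refined `embedding_table` with `layer = L`.
#' @export
relation_propagate <- function(table, ontology, transforms, L = 1L,
                               similarity = c("scaled_dot", "cosine")) {
  similarity <- match.arg(similarity)
  stop_if(L < 1, "L must be >= 1")
  nb <- ontology_neighbors(ontology)
  labels <- unique(unlist(lapply(nb, function(x) x$relation)))
  missing <- setdiff(labels, names(transforms))
  stop_if(length(missing) > 0, "missing relation transform(s): ",
          paste(missing, collapse = ", "))
  E <- table$matrix
  d <- ncol(E)
  for (layer in seq_len(L)) {
    msg <- matrix(0, nrow(E), d)
    for (i in seq_len(nrow(E))) {
      nbi <- nb[[i]]
      if (nrow(nbi) == 0) next
      keys <- t(vapply(seq_len(nrow(nbi)), function(k) {
        as.numeric(transforms[[nbi$relation[k]]] %*% E[nbi$neighbor[k], ])
      }, numeric(d)))
      scores <- vapply(seq_len(nrow(nbi)), function(k) {
        phi_similarity(E[i, ], keys[k, ], similarity, d)
      }, 0)
      a <- softmax(scores)
      msg[i, ] <- as.numeric(a %*% keys)
    }
    E <- E + pmax(msg, 0)
  }
  structure(list(matrix = E, layer = table$layer + L),
            class = "embedding_table")
}

#' Structural reconstruction penalty for refined embeddings
#'
#' `sum_i || e_i^(L) - e~_i ||^2`: deviation of the refined table from the
#' ontology-informed context vectors. Nonnegative, zero iff equal.
#'
#' @param refined `embedding_table` (or matrix) after propagation.
#' @param context `|E| x d` matrix of context vectors from
#'   [neighborhood_attention()].
#' @return scalar loss.
#' @export
embedding_struct_loss <- function(refined, context) {
  E <- if (inherits(refined, "embedding_table")) refined$matrix else refined
  stop_if(!all(dim(E) == dim(context)),
          "refined table and context vectors differ in shape")
  sum((E - context)^2)
}
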
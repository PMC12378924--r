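#' Concept vocabulary
#'
#' An ordered vocabulary of coded clinical concepts. Each concept has exactly
#' one semantic type (by default one of `diagnosis`, `medication`, `lab`,
#' `procedure`) and a flag saying whether it carries a numeric value (labs do).
#'
#' @param concept_ids character vector of unique concept identifiers; the
#'   order fixes the 1..|E| index map used by every matrix in the package.
#' @param semantic_type character vector, one type per concept.
#' @param value_bearing logical vector, `TRUE` where the concept carries a
#'   numeric value. Defaults to `semantic_type == "lab"`.
#' @param names optional human-readable concept names.
#' @return An object of class `concept_vocabulary`.
#' @export
concept_vocabulary <- function(concept_ids, semantic_type,
                               value_bearing = semantic_type == "lab",
                               names = concept_ids) {
  concept_ids <- as.character(concept_ids)
  stop_if(anyDuplicated(concept_ids) > 0, "concept ids must be unique")
  stop_if(length(semantic_type) != length(concept_ids),
          "semantic_type must match concept_ids in length")
  stop_if(length(value_bearing) != length(concept_ids),
          "value_bearing must match concept_ids in length")
  structure(list(
    concept_ids = concept_ids,
    names = as.character(names),
    semantic_type = as.character(semantic_type),
    value_bearing = as.logical(value_bearing),
    index = stats::setNames(seq_along(concept_ids), concept_ids)
  ), class = "concept_vocabulary")
}

#' @export
length.concept_vocabulary <- function(x) length(x$concept_ids)

#' @export
print.concept_vocabulary <- function(x, ...) {
  cat("<concept_vocabulary> ", length(x), " concepts; types: ",
      paste(sprintf("%s=%d", names(table(x$semantic_type)),
                    table(x$semantic_type)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

concept_index <- function(vocab, ids) {
  idx <- vocab$index[as.character(ids)]
  if (anyNA(idx)) {
    bad <- as.character(ids)[is.na(idx)]
    stop("unknown concept id(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(idx)
}

#' Medical ontology graph
#'
#' Typed directed edges over the vocabulary: `is_a` child-to-parent edges form
#' the hierarchy (required to be acyclic); all other relation labels are
#' lateral relations.
#'
#' @param vocab a [concept_vocabulary].
#' @param edges data.frame with columns `child`, `parent`, `relation`
#'   (relation label `"is_a"` feeds the hierarchy; anything else is lateral).
#' @return An object of class `ontology_graph` with components
#'   `hierarchy_edges`, `lateral_edges`, `relation_types`.
#' @export
ontology_graph <- function(vocab, edges) {
  stopifnot(is.data.frame(edges))
  stop_if(!all(c("child", "parent", "relation") %in% names(edges)),
          "edges needs columns child, parent, relation")
  concept_index(vocab, edges$child)   # validates endpoints
  concept_index(vocab, edges$parent)
  hier <- edges[edges$relation == "is_a", c("child", "parent")]
  lat <- edges[edges$relation != "is_a", ]
  # acyclicity of the hierarchy is checked by the closure computation
  g <- structure(list(
    vocab = vocab,
    hierarchy_edges = hier,
    lateral_edges = lat,
    relation_types = sort(unique(as.character(edges$relation)))
  ), class = "ontology_graph")
  invisible(transitive_closure(vocab, hier))  # reject cycles on construction
  g
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$hierarchy_edges), " is_a edges, ",
      nrow(x$lateral_edges), " lateral edges, relations: ",
      paste(x$relation_types, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# neighbor list of an ontology graph: for each concept index, a data.frame of
# (neighbor index, relation label). Hierarchy edges contribute both ways
# (child sees parent under "is_a", parent sees child under "has_child") so
# information can flow down as well as up; lateral edges follow their stated
# direction.
ontology_neighbors <- function(ontology) {
  vocab <- ontology$vocab
  n <- length(vocab)
  src <- integer(0); dst <- integer(0); rel <- character(0)
  if (nrow(ontology$hierarchy_edges) > 0) {
    ci <- concept_index(vocab, ontology$hierarchy_edges$child)
    pi <- concept_index(vocab, ontology$hierarchy_edges$parent)
    src <- c(src, ci, pi)
    dst <- c(dst, pi, ci)
    rel <- c(rel, rep("is_a", length(ci)), rep("has_child", length(pi)))
  }
  if (nrow(ontology$lateral_edges) > 0) {
    si <- concept_index(vocab, ontology$lateral_edges$child)
    ti <- concept_index(vocab, ontology$lateral_edges$parent)
    src <- c(src, si)
    dst <- c(dst, ti)
    rel <- c(rel, as.character(ontology$lateral_edges$relation))
  }
  split(data.frame(neighbor = dst, relation = rel,
                   stringsAsFactors = FALSE),
        factor(src, levels = seq_len(n)))
}

#' Strict-ancestry transitive closure of an is-a hierarchy
#'
#' Computes the binary ancestry matrix `T` with `T[i, j] = 1` iff concept `i`
#' is a strict ancestor of concept `j` under the transitive closure of
#' child-to-parent edges. The diagonal is zero: a concept is not its own
#' ancestor. Cyclic input is rejected with one offending cycle listed.
#'
#' @param vocab a [concept_vocabulary].
#' @param hierarchy_edges data.frame with columns `child`, `parent`.
#' @return binary `|E| x |E|` ancestry matrix (dense, 0/1).
#' @export
transitive_closure <- function(vocab, hierarchy_edges) {
  n <- length(vocab)
  A <- matrix(0, n, n)  # A[p, c] = 1 for direct parent -> child
  if (nrow(hierarchy_edges) > 0) {
    ci <- concept_index(vocab, hierarchy_edges$child)
    pi <- concept_index(vocab, hierarchy_edges$parent)
    A[cbind(pi, ci)] <- 1
  }
  # Kahn toposort on parent->child arcs; leftover nodes expose a cycle.
  indeg <- colSums(A)
  queue <- which(indeg == 0)
  order <- integer(0)
  indeg_w <- indeg
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    kids <- which(A[v, ] > 0)
    for (k in kids) {
      indeg_w[k] <- indeg_w[k] - 1
      if (indeg_w[k] == 0) queue <- c(queue, k)
    }
  }
  if (length(order) < n && any(indeg_w[setdiff(seq_len(n), order)] > 0)) {
    cyc <- find_cycle(A)
    if (!is.null(cyc)) {
      stop("hierarchy contains a cycle: ",
           paste(vocab$concept_ids[cyc], collapse = " -> "), call. = FALSE)
    }
  }
  # closure by reverse-topological accumulation: descendants(v) =
  # union over children c of {c} + descendants(c)
  Tm <- A
  for (v in rev(order)) {
    kids <- which(A[v, ] > 0)
    if (length(kids) > 0) {
      acc <- A[v, ]
      for (k in kids) acc <- pmax(acc, Tm[k, ])
      Tm[v, ] <- acc
    }
  }
  diag(Tm) <- 0
  dimnames(Tm) <- list(vocab$concept_ids, vocab$concept_ids)
  Tm
}

# locate one directed cycle in adjacency matrix A (for the error message)
find_cycle <- function(A) {
  n <- nrow(A)
  color <- integer(n)  # 0 white, 1 grey, 2 black
  parent <- integer(n)
  dfs <- function(v) {
    color[v] <<- 1L
    for (w in which(A[v, ] > 0)) {
      if (color[w] == 0L) {
        parent[w] <<- v
        res <- dfs(w)
        if (!is.null(res)) return(res)
      } else if (color[w] == 1L) {
        path <- v
        while (path[1] != w) path <- c(parent[path[1]], path)
        return(c(path, w))
      }
    }
    color[v] <<- 2L
    NULL
  }
  for (s in seq_len(n)) {
    if (color[s] == 0L) {
      res <- dfs(s)
      if (!is.null(res)) return(res)
    }
  }
  NULL
}

#' Unnormalized graph Laplacian L = D - A
#'
#' @param adjacency symmetric nonnegative matrix with zero diagonal.
#' @return the Laplacian matrix; its row sums are exactly zero and it is
#'   symmetric positive semidefinite.
#' @export
graph_laplacian <- function(adjacency) {
  adjacency <- as_dense(adjacency)
  check_square(adjacency, what = "adjacency")
  stop_if(max(abs(adjacency - t(adjacency))) > 1e-12,
          "adjacency must be symmetric")
  stop_if(any(adjacency < 0), "adjacency must be nonnegative")
  A <- adjacency
  diag(A) <- 0
  diag(rowSums(A), nrow(A)) - A
}

#' Laplacian eigenmap embedding
#'
#' Embeds graph nodes with the eigenvectors of the unnormalized Laplacian
#' belonging to the `d` smallest eigenvalues, the minimizer of
#' `Tr(E' L E)` over orthonormal `E`. By default the trivial near-constant
#' eigenvector is kept (the literal optimum); `drop_trivial = TRUE` skips
#' eigenvalues below `tol` first, the classical eigenmap usage.
#'
#' @param adjacency symmetric nonnegative adjacency matrix (or a Laplacian
#'   via `is_laplacian = TRUE`).
#' @param d target dimension, `d <= n`.
#' @param drop_trivial skip near-zero eigenvalues (connected components).
#' @param tol eigenvalue threshold used when `drop_trivial` is set.
#' @param is_laplacian interpret `adjacency` as an already-built Laplacian.
#' @return list with `vectors` (`n x d`, orthonormal columns), `values`
#'   (the `d` selected eigenvalues, ascending) and `objective`
#'   (`Tr(E' L E)` = sum of selected eigenvalues).
#' @export
laplacian_eigenmap <- function(adjacency, d, drop_trivial = FALSE,
                               tol = 1e-9, is_laplacian = FALSE) {
  L <- if (is_laplacian) as_dense(adjacency) else graph_laplacian(adjacency)
  n <- nrow(L)
  stop_if(d > n, "d = ", d, " exceeds number of nodes n = ", n)
  stop_if(d < 1, "d must be >= 1")
  eig <- eigen(L, symmetric = TRUE)
  # eigen() returns descending order; flip to ascending (ties keep LAPACK's
  # deterministic ordering, reversed)
  vals <- rev(eig$values)
  vecs <- eig$vectors[, rev(seq_len(n)), drop = FALSE]
  keep <- seq_len(n)
  if (drop_trivial) {
    keep <- which(vals > tol)
    stop_if(length(keep) < d,
            "not enough non-trivial eigenvalues: have ", length(keep),
            ", need ", d)
  }
  sel <- keep[seq_len(d)]
  E <- vecs[, sel, drop = FALSE]
  list(vectors = E,
       values = vals[sel],
       objective = sum(diag(t(E) %*% L %*% E)))
}

#' Relation (valid co-occurrence) matrix from lateral + structural edges
#'
#' Builds the binary matrix of semantically valid co-occurrences used by the
#' masking rules. The matrix is symmetrized on load (an edge in either
#' direction sets both entries) and its diagonal is forced to zero so an
#' event can never support itself.
#'
#' @param vocab a [concept_vocabulary].
#' @param pairs data.frame with columns `from`, `to` (concept ids).
#' @return symmetric binary `|E| x |E|` matrix with zero diagonal.
#' @export
relation_matrix <- function(vocab, pairs) {
  n <- length(vocab)
  R <- matrix(0, n, n)
  if (nrow(pairs) > 0) {
    i <- concept_index(vocab, pairs$from)
    j <- concept_index(vocab, pairs$to)
    R[cbind(i, j)] <- 1
    R[cbind(j, i)] <- 1
  }
  diag(R) <- 0
  dimnames(R) <- list(vocab$concept_ids, vocab$concept_ids)
  R
}

#' One-hot semantic type matrix
#'
#' @param vocab a [concept_vocabulary].
#' @param types optional ordered type levels; defaults to the sorted unique
#'   types present.
#' @return binary `|E| x c` matrix with exactly one 1 per row.
#' @export
type_matrix <- function(vocab, types = sort(unique(vocab$semantic_type))) {
  Tm <- matrix(0, length(vocab), length(types),
               dimnames = list(vocab$concept_ids, types))
  Tm[cbind(seq_len(length(vocab)),
           match(vocab$semantic_type, types))] <- 1
  stop_if(anyNA(match(vocab$semantic_type, types)),
          "types does not cover all semantic types present")
  Tm
}

#' Curated causal-precedence matrix
#'
#' `C[i, j] = 1` means concept `i` causally precedes concept `j`. The edge
#' set must be acyclic as a directed graph; the diagonal is zero.
#'
#' @param vocab a [concept_vocabulary].
#' @param pairs data.frame with columns `cause`, `effect`.
#' @return binary `|E| x |E|` matrix.
#' @export
causal_matrix <- function(vocab, pairs) {
  n <- length(vocab)
  C <- matrix(0, n, n)
  if (nrow(pairs) > 0) {
    i <- concept_index(vocab, pairs$cause)
    j <- concept_index(vocab, pairs$effect)
    stop_if(any(i == j), "causal self-loop rejected")
    C[cbind(i, j)] <- 1
  }
  cyc <- find_cycle(C)
  if (!is.null(cyc)) {
    stop("causal edges contain a cycle: ",
         paste(vocab$concept_ids[cyc], collapse = " -> "), call. = FALSE)
  }
  dimnames(C) <- list(vocab$concept_ids, vocab$concept_ids)
  C
}

#' Assemble a knowledge base
#'
#' Bundles the vocabulary, ontology and all derived constraint matrices used
#' downstream: ancestry closure, relation matrix, type matrix and causal
#' matrix.
#'
#' @param vocab a [concept_vocabulary].
#' @param ontology an [ontology_graph] over `vocab`.
#' @param relation_pairs data.frame (`from`, `to`) of valid co-occurrence
#'   pairs; defaults to sibling pairs (shared parent) plus all
#'   ancestor-descendant pairs plus the ontology's lateral edges.
#' @param causal_pairs data.frame (`cause`, `effect`); may be empty.
#' @return An object of class `knowledge_base`.
#' @export
knowledge_base <- function(vocab, ontology,
                           relation_pairs = NULL,
                           causal_pairs = data.frame(cause = character(0),
                                                     effect = character(0))) {
  ancestry <- transitive_closure(vocab, ontology$hierarchy_edges)
  if (is.null(relation_pairs)) {
    relation_pairs <- structural_relation_pairs(vocab, ontology, ancestry)
  }
  structure(list(
    vocab = vocab,
    ontology = ontology,
    ancestry = ancestry,
    relation = relation_matrix(vocab, relation_pairs),
    types = type_matrix(vocab),
    causal = causal_matrix(vocab, causal_pairs)
  ), class = "knowledge_base")
}

# default co-occurrence support: siblings (shared direct parent), all
# ancestor-descendant pairs, and lateral ontology edges
structural_relation_pairs <- function(vocab, ontology, ancestry) {
  from <- character(0); to <- character(0)
  he <- ontology$hierarchy_edges
  if (nrow(he) > 0) {
    for (p in unique(he$parent)) {
      kids <- he$child[he$parent == p]
      if (length(kids) >= 2) {
        cmb <- utils::combn(kids, 2)
        from <- c(from, cmb[1, ]); to <- c(to, cmb[2, ])
      }
    }
  }
  anc <- which(ancestry == 1, arr.ind = TRUE)
  if (nrow(anc) > 0) {
    from <- c(from, vocab$concept_ids[anc[, 1]])
    to <- c(to, vocab$concept_ids[anc[, 2]])
  }
  if (nrow(ontology$lateral_edges) > 0) {
    from <- c(from, as.character(ontology$lateral_edges$child))
    to <- c(to, as.character(ontology$lateral_edges$parent))
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' @export
print.knowledge_base <- function(x, ...) {
  cat("<knowledge_base> ", length(x$vocab), " concepts, ",
      sum(x$ancestry), " ancestry pairs, ", sum(x$relation) / 2,
      " relation pairs, ", sum(x$causal), " causal edges\n", sep = "")
  invisible(x)
}

#' Undirected shortest-path distance in the hierarchy
#'
#' Hop distance between concepts through the undirected is-a graph; used as
#' the ontology distance for planted "jump" anomalies. Unreachable pairs get
#' `Inf`.
#'
#' @param vocab a [concept_vocabulary].
#' @param hierarchy_edges data.frame (`child`, `parent`).
#' @return `|E| x |E|` distance matrix.
#' @export
hierarchy_distance <- function(vocab, hierarchy_edges) {
  n <- length(vocab)
  A <- matrix(FALSE, n, n)
  if (nrow(hierarchy_edges) > 0) {
    i <- concept_index(vocab, hierarchy_edges$child)
    j <- concept_index(vocab, hierarchy_edges$parent)
    A[cbind(i, j)] <- TRUE; A[cbind(j, i)] <- TRUE
  }
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {           # BFS per source; n is small here
    frontier <- s; depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- which(colSums(A[frontier, , drop = FALSE]) > 0)
      nxt <- nxt[D[s, nxt] > depth]
      D[s, nxt] <- depth
      frontier <- nxt
    }
  }
  dimnames(D) <- list(vocab$concept_ids, vocab$concept_ids)
  D
}
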
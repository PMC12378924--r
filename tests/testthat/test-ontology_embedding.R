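make_table <- function(M, ids) {
  rownames(M) <- ids
  structure(list(matrix = M, layer = 0L), class = "embedding_table")
}

test_that("neighborhood attention weights are a softmax over neighbors", {
  v <- chain_vocab()
  ont <- ontology_graph(v, chain_edges())
  # a <- b <- c chain; b has neighbors a (parent) and c (child)
  E <- make_table(rbind(c(1, 0), c(0, 1), c(1, 1)), v$concept_ids)
  att <- neighborhood_attention(E, ont)
  for (w in att$weights) {
    if (!is.null(w)) {
      expect_true(all(w >= 0))
      expect_equal(sum(w), 1, tolerance = 1e-10)
    }
  }
  # single-neighbor nodes copy their neighbor exactly
  expect_equal(att$context["a", ], unname(E$matrix["b", ]))
  expect_equal(att$context["c", ], unname(E$matrix["b", ]))
})

test_that("attention matches a hand-computed softmax", {
  v <- concept_vocabulary(c("i", "j", "k"), rep("diagnosis", 3))
  ont <- ontology_graph(v, data.frame(child = c("i", "i"),
                                      parent = c("j", "k"),
                                      relation = "is_a"))
  E <- make_table(rbind(c(1, 0), c(1, 0), c(0, 1)), v$concept_ids)
  att <- neighborhood_attention(E, ont)
  # scores: e_i.e_j/sqrt(2) = 1/sqrt(2); e_i.e_k/sqrt(2) = 0
  a1 <- exp(2^(-1 / 2)) / (exp(2^(-1 / 2)) + 1)
  expect_equal(unname(att$weights[[1]]["j"]), a1, tolerance = 1e-12)
  expect_equal(att$context["i", ],
               a1 * c(1, 0) + (1 - a1) * c(0, 1), tolerance = 1e-12)
})

test_that("identical neighbor embeddings split attention evenly", {
  v <- concept_vocabulary(c("i", "j", "k"), rep("diagnosis", 3))
  ont <- ontology_graph(v, data.frame(child = c("i", "i"),
                                      parent = c("j", "k"),
                                      relation = "is_a"))
  E <- make_table(rbind(c(2, 1), c(1, 3), c(1, 3)), v$concept_ids)
  att <- neighborhood_attention(E, ont)
  expect_equal(unname(att$weights[[1]]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(att$context["i", ], c(1, 3))
})

test_that("cosine similarity rejects zero-norm embeddings", {
  v <- concept_vocabulary(c("i", "j"), rep("diagnosis", 2))
  ont <- ontology_graph(v, data.frame(child = "i", parent = "j",
                                      relation = "is_a"))
  E <- make_table(rbind(c(0, 0), c(1, 0)), v$concept_ids)
  expect_error(neighborhood_attention(E, ont, similarity = "cosine"),
               "zero-norm")
})

test_that("relation propagation is residual: zero transforms are identity", {
  v <- chain_vocab()
  ont <- ontology_graph(v, chain_edges())
  set.seed(3)
  E <- make_table(matrix(stats::rnorm(6), 3, 2), v$concept_ids)
  Z <- list(is_a = matrix(0, 2, 2), has_child = matrix(0, 2, 2))
  for (L in c(1, 3)) {
    out <- relation_propagate(E, ont, Z, L = L)
    expect_equal(out$matrix, E$matrix)
    expect_equal(out$layer, L)
  }
  expect_error(relation_propagate(E, ont, Z["is_a"], L = 1), "missing relation")
})

test_that("one layer with identity transform adds the single neighbor", {
  v <- concept_vocabulary(c("i", "j"), rep("diagnosis", 2))
  ont <- ontology_graph(v, data.frame(child = "i", parent = "j",
                                      relation = "is_a"))
  E <- make_table(rbind(c(0.5, 0.2), c(0.3, 0.7)), v$concept_ids)
  out <- relation_propagate(E, ont, list(is_a = diag(2), has_child = diag(2)),
                            L = 1)
  # i gains its (nonnegative) neighbor j; j gains i
  expect_equal(out$matrix["i", ], c(0.5 + 0.3, 0.2 + 0.7))
  expect_equal(out$matrix["j", ], c(0.3 + 0.5, 0.7 + 0.2))
})

test_that("ReLU clamps negative pre-activations to the identity", {
  v <- concept_vocabulary(c("i", "j"), rep("diagnosis", 2))
  ont <- ontology_graph(v, data.frame(child = "i", parent = "j",
                                      relation = "is_a"))
  E <- make_table(rbind(c(1, 1), c(1, 1)), v$concept_ids)
  neg <- list(is_a = -diag(2), has_child = -diag(2))
  out <- relation_propagate(E, ont, neg, L = 2)
  expect_equal(out$matrix, E$matrix)
})

test_that("structural embedding loss is a nonnegative squared deviation", {
  expect_equal(embedding_struct_loss(rbind(c(1, 0)), rbind(c(0, 0))), 1)
  M <- matrix(stats::rnorm(10), 5, 2)
  expect_equal(embedding_struct_loss(M, M), 0)
  set.seed(4)
  for (rep in 1:100) {
    A <- matrix(stats::rnorm(8), 4, 2)
    B <- matrix(stats::rnorm(8), 4, 2)
    l <- embedding_struct_loss(A, B)
    expect_gte(l, 0)
    if (l == 0) expect_equal(A, B)
    # invariant under joint row permutation
    p <- sample(4)
    expect_equal(embedding_struct_loss(A[p, ], B[p, ]), l)
  }
  expect_error(embedding_struct_loss(matrix(0, 2, 2), matrix(0, 3, 2)),
               "shape")
})

test_that("xavier initialization is seeded and within bounds", {
  kb <- small_world()$kb
  e1 <- init_embeddings(kb, 8, seed = 5)
  e2 <- init_embeddings(kb, 8, seed = 5)
  expect_identical(e1$matrix, e2$matrix)
  lim <- sqrt(6 / (length(kb$vocab) + 8))
  expect_true(all(abs(e1$matrix) <= lim))
  e3 <- init_embeddings(kb, 4, init = "eigenmap")
  expect_equal(dim(e3$matrix), c(length(kb$vocab), 4L))
})
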
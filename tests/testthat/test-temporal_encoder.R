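small_cfg <- function(...) {
  encoder_config(layers = 2L, hidden_dim = 8L, n_factors = 2L,
                 factor_dim = 4L, attention_heads = 2L, seed = 1L, ...)
}

test_that("encoder config enforces d = K x factor_dim", {
  cfg <- encoder_config()
  expect_equal(cfg$latent_dim, cfg$n_factors * cfg$factor_dim)
  expect_equal(encoder_config()$latent_dim, 384L)
  expect_error(encoder_config(hidden_dim = 0), "positive")
})

test_that("relation tensor mixing reduces to known special cases", {
  x <- c(1, 0, 2)
  rt <- list(slices = list(diag(3)), transforms = list(diag(3)))
  expect_equal(relation_tensor_mix(x, rt), x)
  rt2 <- list(slices = list(diag(3), matrix(0, 3, 3)),
              transforms = list(diag(3), diag(3)))
  expect_equal(relation_tensor_mix(x, rt2), x)
  # random instance vs explicit triple loop
  set.seed(21)
  k <- 3; n <- 4; m <- 2
  slices <- replicate(k, matrix(stats::rnorm(n * n), n, n), simplify = FALSE)
  tr <- replicate(k, matrix(stats::rnorm(n * m), n, m), simplify = FALSE)
  x <- stats::rnorm(n)
  out <- relation_tensor_mix(x, list(slices = slices, transforms = tr))
  expected <- numeric(m)
  for (r in 1:k) for (a in 1:m) for (i in 1:n) for (j in 1:n) {
    expected[a] <- expected[a] + tr[[r]][i, a] * slices[[r]][i, j] * x[j]
  }
  expect_equal(out, expected, tolerance = 1e-12)
  expect_error(relation_tensor_mix(c(1, 2), rt), "shape")
})

test_that("encoding with zero messages projects each visit's mean embedding", {
  v <- tiny_vocab()
  cfg <- small_cfg()
  set.seed(2)
  E <- structure(list(matrix = `rownames<-`(matrix(stats::rnorm(4 * 6), 4, 6),
                                            v$concept_ids), layer = 0L),
                 class = "embedding_table")
  traj <- patient_trajectory("p", 1:2,
    list(encode_state("dx1", v), encode_state("rx1", v)))
  g <- build_event_graph(traj)
  lat <- encode_trajectory(g, E, cfg, zero_messages = TRUE)
  params <- kganomaly:::encoder_params(6, cfg, zero_messages = TRUE)
  proj <- function(i) as.numeric((E$matrix[i, ] %*% params$W_in) %*% params$W_out)
  expect_equal(lat$z[1, ], proj(1), tolerance = 1e-12)
  expect_equal(lat$z[2, ], proj(3), tolerance = 1e-12)
})

test_that("pooling is permutation invariant and deterministic", {
  w <- small_world()
  kb <- w$kb
  cfg <- small_cfg()
  E <- init_embeddings(kb, 6, seed = 3)
  p <- w$cohort[[1]]
  g <- build_event_graph(p, kb)
  z1 <- encode_trajectory(g, E, cfg)$z
  z2 <- encode_trajectory(g, E, cfg)$z
  expect_identical(z1, z2)   # bit-identical reruns
  # permute the event order within each visit
  perm <- p
  for (t in seq_along(perm$states)) {
    dec <- decode_state(perm$states[[t]], kb$vocab)
    ids <- rev(dec$events)
    perm$states[[t]] <- encode_state(lapply(ids, function(id) {
      if (id %in% names(dec$values)) list(concept = id, value = dec$values[[id]])
      else list(concept = id)
    }), kb$vocab)
  }
  g2 <- build_event_graph(perm, kb)
  z3 <- encode_trajectory(g2, E, cfg)$z
  expect_equal(z1, z3, tolerance = 1e-10)
})

test_that("empty visits produce a zero latent", {
  v <- tiny_vocab()
  cfg <- small_cfg()
  E <- init_embeddings(structure(list(vocab = v,
    ontology = ontology_graph(v, data.frame(child = character(0),
                                            parent = character(0),
                                            relation = character(0))),
    ancestry = matrix(0, 4, 4), relation = matrix(0, 4, 4),
    types = type_matrix(v), causal = matrix(0, 4, 4)),
    class = "knowledge_base"), 6, seed = 1)
  traj <- patient_trajectory("p", 1:2,
    list(encode_state("dx1", v), encode_state(list(), v)))
  lat <- encode_trajectory(build_event_graph(traj), E, cfg)
  expect_false(all(lat$z[1, ] == 0))
  expect_true(all(lat$z[2, ] == 0))
})

test_that("factor partition splits and reassembles exactly", {
  z <- 1:6
  b <- factor_partition(z, 3)
  expect_equal(b, list(1:2, 3:4, 5:6))
  expect_equal(factor_partition(z, 1), list(z))
  expect_error(factor_partition(z, 4), "not divisible")
  set.seed(22)
  for (rep in 1:100) {
    K <- sample(c(1, 2, 3, 6), 1)
    z <- stats::rnorm(12)
    expect_equal(unlist(factor_partition(z, K)), z)
  }
})

test_that("covariance loss matches hand-computed cosine cases", {
  expect_equal(covariance_loss(list(c(1, 0), c(0, 1))), 0)
  expect_equal(covariance_loss(list(c(1, 2), c(1, 2))), 2)
  expect_equal(covariance_loss(list(c(1, 0), c(1, 1))), 1, tolerance = 1e-12)
  # zero-norm factor contributes nothing
  expect_equal(covariance_loss(list(c(0, 0), c(1, 1))), 0)
  # invariant to positive rescaling
  set.seed(23)
  b <- list(stats::rnorm(4), stats::rnorm(4), stats::rnorm(4))
  l <- covariance_loss(b)
  b2 <- b; b2[[2]] <- 7.3 * b2[[2]]
  expect_equal(covariance_loss(b2), l, tolerance = 1e-12)
  expect_error(covariance_loss(list(c(1, 2))), "two factors")
})

test_that("temporal smoothness is the summed squared step, per factor or not", {
  Z <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(temporal_smoothness_loss(Z, per_factor = FALSE), 0)
  Z2 <- rbind(c(0, 0), c(1, 0))
  expect_equal(temporal_smoothness_loss(Z2, per_factor = FALSE), 1)
  set.seed(24)
  for (rep in 1:100) {
    Z <- matrix(stats::rnorm(5 * 12), 5, 12)
    expect_equal(temporal_smoothness_loss(Z, per_factor = TRUE, K = 4),
                 temporal_smoothness_loss(Z, per_factor = FALSE),
                 tolerance = 1e-12)
  }
  expect_equal(temporal_smoothness_loss(matrix(1, 1, 3)), 0)
})

test_that("Gaussian-surrogate MI penalty tracks the closed form", {
  set.seed(25)
  n <- 1e4
  blocks <- list(matrix(stats::rnorm(n * 2), n, 2),
                 matrix(stats::rnorm(n * 2), n, 2))
  expect_lte(mi_disentanglement_loss(blocks), 0.05)
  # exact copy hits the clipping ceiling
  b <- matrix(stats::rnorm(100 * 2), 100, 2)
  l <- mi_disentanglement_loss(list(b, b))
  expect_true(is.finite(l))
  expect_equal(l, 2 * (-0.5) * sum(log(1 - rep(1 - 1e-6, 2))),
               tolerance = 1e-6)
  # bivariate Gaussian with rho = 0.9: per-ordered-pair -0.5 log(0.19)
  n <- 1e5
  x <- stats::rnorm(n)
  y <- 0.9 * x + sqrt(1 - 0.81) * stats::rnorm(n)
  l <- mi_disentanglement_loss(list(cbind(x), cbind(y)))
  expect_equal(l / 2, -0.5 * log(1 - 0.81), tolerance = 0.05)
  expect_error(mi_disentanglement_loss(list(cbind(1:4), cbind(1:4))),
               "batch size")
})
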
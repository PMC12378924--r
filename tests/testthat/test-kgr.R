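softmax_vec <- function(x) { e <- exp(x - max(x)); e / sum(e) }

test_that("soft assignment is a shift-invariant softmax of P'z", {
  P <- diag(3)
  expect_equal(soft_assign(c(0, 0, 0), P), rep(1 / 3, 3))
  expect_equal(soft_assign(c(log(2), 0, -1e9), P)[1:2], c(2 / 3, 1 / 3),
               tolerance = 1e-9)
  z <- stats::rnorm(3)
  expect_equal(soft_assign(z, P), soft_assign(z + 5, P + 0),
               tolerance = 1e-12)
  expect_error(soft_assign(c(Inf, 0, 0), P), "non-finite")
  expect_error(soft_assign(c(1, 2), P), "does not match")
})

test_that("hierarchy hinge penalizes children scored above ancestors", {
  anc <- matrix(0, 2, 2); anc[1, 2] <- 1   # concept 1 ancestor of 2
  expect_equal(hierarchy_violation_loss(c(0.5, 0.5), anc), 0)
  expect_equal(hierarchy_violation_loss(c(0.3, 0.7), anc), 0.4)
  # decreasing along a topological order is always consistent
  v <- dag_vocab(6)
  set.seed(31)
  edges <- random_dag_edges(6, 0.4)
  Tm <- transitive_closure(v, edges[, c("child", "parent")])
  # score ancestors above descendants: s decreasing in descendant count
  s <- softmax_vec(rowSums(Tm))
  expect_equal(hierarchy_violation_loss(s, Tm), 0)
})

test_that("causal and multistep hinges match hand and oracle values", {
  C <- matrix(0, 2, 2); C[1, 2] <- 1
  expect_equal(causal_violation_loss(c(0.6, 0.4), C), 0)
  expect_equal(causal_violation_loss(c(0.2, 0.5), C), 0.3)
  expect_equal(causal_violation_loss(c(0.5, 0.5), matrix(0, 2, 2)), 0)

  expect_equal(multistep_causal_loss(matrix(c(0.2, 0.8), 1), C), 0)
  S <- rbind(c(0.2, 0.8), c(0.5, 0.5))
  # only cross-step pair: s_2(2) - s_1(1) = 0.5 - 0.2
  expect_equal(multistep_causal_loss(S, C), 0.3)
  # brute-force triple loop on random instances
  set.seed(32)
  for (rep in 1:100) {
    n <- sample(2:10, 1); Tn <- sample(1:5, 1)
    C <- matrix(stats::rbinom(n * n, 1, 0.3), n, n); diag(C) <- 0
    S <- matrix(stats::runif(Tn * n), Tn, n)
    expected <- 0
    if (Tn > 1) for (t in 1:(Tn - 1)) for (i in 1:n) for (j in 1:n) {
      if (C[i, j] > 0) expected <- expected + max(0, S[t + 1, j] - S[t, i])
    }
    expect_equal(multistep_causal_loss(S, C), expected, tolerance = 1e-12)
  }
})

test_that("order-consistent assignments give zero hinge, inversions positive", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(3:10, 1)
    edges <- random_dag_edges(n, 0.35)
    Tm <- transitive_closure(dag_vocab(n), edges[, c("child", "parent")])
    if (sum(Tm) == 0) next
    # monotone assignment along the partial order: ancestors get higher mass
    depth <- rowSums(Tm)   # more descendants -> earlier in topological order
    s <- softmax_vec(depth + 0.01 * stats::runif(n))
    # small noise can break ties only between incomparable concepts: make
    # comparable pairs strictly ordered by depth before asserting zero
    comparable <- which(Tm == 1, arr.ind = TRUE)
    if (all(depth[comparable[, 1]] > depth[comparable[, 2]])) {
      expect_equal(hierarchy_violation_loss(s, Tm), 0)
      # planted single inversion turns the loss strictly positive
      k <- comparable[sample(nrow(comparable), 1), ]
      s2 <- s
      s2[c(k[1], k[2])] <- s2[c(k[2], k[1])] + c(0, 1e-3)
      s2 <- s2 / sum(s2)
      expect_gt(hierarchy_violation_loss(s2, Tm), 0)
    }
  }
})

test_that("KL alignment handles support, epsilon and hand values", {
  expect_equal(kl_alignment_loss(c(0.3, 0.7), c(0.3, 0.7), eps = 0), 0)
  expect_equal(kl_alignment_loss(c(0.5, 0.5), c(1, 0), eps = 0), log(2))
  expect_error(kl_alignment_loss(c(0, 1), c(1, 0), eps = 0), "support")
  # epsilon bias is bounded below by -log(1 + eps |E|)
  set.seed(34)
  for (rep in 1:20) {
    n <- sample(2:10, 1)
    q <- softmax_vec(stats::rnorm(n))
    eps <- 10^stats::runif(1, -8, -1)
    l <- kl_alignment_loss(q, q, eps = eps)
    expect_lte(l, 0)
    expect_gte(l, -log(1 + eps * n))
  }
})

test_that("priors are proper distributions in both modes", {
  v <- tiny_vocab()
  u <- derive_prior(list(), v, "uniform")
  expect_equal(u$q, rep(0.25, 4))
  # cohort: dx1 three times, dx2 once -> add-one (4/6, 2/6, 1/6...) over 4
  traj <- patient_trajectory("p", 1:3,
    list(encode_state(c("dx1", "dx2"), v), encode_state("dx1", v),
         encode_state("dx1", v)))
  f <- derive_prior(list(traj), v, "frequency")
  expect_equal(f$q[1:2], c(4, 2) / sum(c(4, 2, 1, 1)))
  expect_equal(sum(f$q), 1, tolerance = 1e-12)
})

test_that("refinement gradient matches central finite differences", {
  set.seed(35)
  for (rep in 1:50) {
    n <- sample(4:8, 1); d <- sample(3:6, 1); Tn <- sample(1:3, 1)
    P <- matrix(stats::rnorm(d * n), d, n)
    edges <- random_dag_edges(n, 0.3)
    anc <- transitive_closure(dag_vocab(n), edges[, c("child", "parent")])
    C <- matrix(stats::rbinom(n * n, 1, 0.2), n, n); diag(C) <- 0
    Z <- matrix(stats::rnorm(Tn * d), Tn, d)
    cfg <- refinement_config()
    gamma <- rep(1, Tn)
    obj <- function(Zm) kganomaly:::refine_objective(Zm, P, anc, C, gamma,
                                                     cfg)$value
    S <- t(apply(Z, 1, soft_assign, P = P))
    if (Tn == 1) S <- matrix(S, 1)
    G <- kganomaly:::refine_gradient(Z, P, anc, C, gamma, cfg, S)
    h <- 1e-6
    num <- G * 0
    for (t in seq_len(Tn)) for (k in seq_len(d)) {
      Zp <- Z; Zp[t, k] <- Zp[t, k] + h
      Zm <- Z; Zm[t, k] <- Zm[t, k] - h
      num[t, k] <- (obj(Zp) - obj(Zm)) / (2 * h)
    }
    denom <- max(1e-8, max(abs(num)))
    expect_lt(max(abs(G - num)) / denom, 1e-5)
  }
})

test_that("safeguarded refinement never increases the objective", {
  set.seed(36)
  for (rep in 1:100) {
    n <- 6; d <- 4; Tn <- 3
    P <- matrix(stats::rnorm(d * n), d, n)
    edges <- random_dag_edges(n, 0.3)
    anc <- transitive_closure(dag_vocab(n), edges[, c("child", "parent")])
    C <- matrix(stats::rbinom(n * n, 1, 0.2), n, n); diag(C) <- 0
    Z <- matrix(stats::rnorm(Tn * d), Tn, d)
    res <- refine_trajectory(Z, P, anc, C,
                             refinement_config(eta = 0.5, max_steps = 10))
    expect_true(all(diff(res$trace) <= 1e-12))
    expect_lte(res$objective, res$trace[1])
    # assignment rows stay distributions
    expect_equal(unname(rowSums(res$assignments)), rep(1, Tn),
                 tolerance = 1e-8)
  }
})

test_that("refinement leaves consistent assignments unchanged and descends on violations", {
  # no constraints: zero objective, Z returned bit-exactly
  Z <- matrix(stats::rnorm(8), 2, 4)
  P <- matrix(stats::rnorm(12), 4, 3)
  res <- refine_trajectory(Z, P, matrix(0, 3, 3), matrix(0, 3, 3))
  expect_identical(res$Z, Z)
  # planted hierarchy violation decreases under descent
  anc <- matrix(0, 2, 2); anc[1, 2] <- 1
  P2 <- diag(2)
  Z2 <- matrix(c(0, 1), 1, 2)   # child scored above ancestor
  res2 <- refine_trajectory(Z2, P2, anc, matrix(0, 2, 2),
                            refinement_config(eta = 1e-2, max_steps = 50))
  l0 <- hierarchy_violation_loss(soft_assign(Z2[1, ], P2), anc)
  l1 <- hierarchy_violation_loss(soft_assign(res2$Z[1, ], P2), anc)
  expect_lt(l1, l0)
})
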
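test_that("risk score is the sigmoid readout of summed latents", {
  Z <- matrix(stats::rnorm(12), 3, 4)
  expect_equal(risk_score(Z, list(w = numeric(4), b = 0)), 0.5)
  # arrange w'Z sum + b = ln 3 -> 0.75
  w <- c(1, 0, 0, 0)
  b <- log(3) - sum(Z %*% w)
  expect_equal(risk_score(Z, list(w = w, b = b)), 0.75, tolerance = 1e-12)
  # strictly increasing in b
  rs <- vapply(seq(-2, 2, by = 0.5), function(b) {
    risk_score(Z, list(w = w, b = b))
  }, 0)
  expect_true(all(diff(rs) > 0))
})

test_that("logit-scale hierarchy penalty flags the same violations as the softmax scale", {
  anc <- matrix(0, 2, 2); anc[1, 2] <- 1
  P <- diag(2)
  expect_equal(latent_hierarchy_loss(c(0, 0), anc, P), 0)
  expect_equal(latent_hierarchy_loss(c(0.3, 0.7), anc, P), 0.4,
               tolerance = 1e-12)
  set.seed(61)
  for (rep in 1:100) {
    n <- 5; d <- 4
    P <- matrix(stats::rnorm(d * n), d, n)
    edges <- random_dag_edges(n, 0.4)
    Tm <- transitive_closure(dag_vocab(n), edges[, c("child", "parent")])
    z <- stats::rnorm(d)
    logit_l <- latent_hierarchy_loss(z, Tm, P)
    softmax_l <- hierarchy_violation_loss(soft_assign(z, P), Tm)
    # softmax is order-preserving, so the two penalties vanish together
    expect_equal(logit_l > 1e-12, softmax_l > 1e-15)
  }
})

test_that("composite objective breakdown always sums to the total", {
  w <- small_world()
  model <- small_model()
  zero <- objective_weights(task = 0, embed_struct = 0, covariance = 0,
                            temporal = 0, mi = 0, smooth = 0,
                            latent_cons = 0, hierarchy = 0, kl = 0,
                            causal = 0, multistep = 0, laplacian = 0)
  out <- composite_objective(w$cohort[1:4], model, zero)
  expect_equal(out$total, 0)
  set.seed(62)
  for (rep in 1:5) {
    ww <- do.call(objective_weights, as.list(stats::runif(12, 0, 0.5)))
    batch <- sample(w$cohort, 6)
    labels <- stats::rbinom(6, 1, 0.5)
    out <- composite_objective(batch, model, ww, labels = labels)
    expect_equal(sum(out$breakdown), out$total, tolerance = 1e-8)
    expect_true(all(is.finite(out$breakdown)))
  }
  # task-only weights with near-perfect predictions give a near-zero loss
  m2 <- model
  m2$predictor <- list(w = numeric(model$config$encoder$latent_dim), b = 30)
  out <- composite_objective(w$cohort[1:4], m2,
                             objective_weights(task = 1, embed_struct = 0,
                                               covariance = 0, temporal = 0,
                                               mi = 0, smooth = 0,
                                               latent_cons = 0, hierarchy = 0,
                                               kl = 0, causal = 0,
                                               multistep = 0, laplacian = 0),
                             labels = rep(1, 4))
  expect_lt(out$total, 1e-8)
})

test_that("training is deterministic and its loss decreases", {
  w <- small_world()
  pcfg <- desk_pipeline_config(seed = 11L)
  pcfg$epochs <- 30L
  m1 <- kg_train(w$cohort, w$kb, pcfg, seed = 11L)
  m2 <- kg_train(w$cohort, w$kb, pcfg, seed = 11L)
  expect_identical(m1$decoder, m2$decoder)
  expect_identical(m1$embeddings$matrix, m2$embeddings$matrix)
  expect_lt(m1$loss_curve[10], m1$loss_curve[1])
  expect_true(all(diff(m1$loss_curve[1:10]) < 0))
})

test_that("the emitted config snapshot carries the default coefficients", {
  model <- small_model()
  snap <- model$snapshot
  expect_equal(snap$weights$covariance, 0.01)
  expect_equal(snap$weights$temporal, 0.01)
  expect_equal(snap$encoder$dropout, 0.3)
  expect_equal(snap$encoder$learning_rate, 1e-4)
  expect_equal(snap$encoder$weight_decay, 1e-5)
  # reference defaults: 6 x 64 factors -> 384-dimensional latent
  expect_equal(encoder_config()$latent_dim, 384L)
})

test_that("anomaly scores respect single-component weighting and bounds", {
  w <- small_world()
  model <- small_model()
  rep_ <- anomaly_score(model, w$cohort[1:12])
  expect_true(all(rep_$score >= 0 & rep_$score <= 1))
  m_only <- anomaly_score(model, w$cohort[1:12], weights = c(1, 0, 0, 0))
  expect_equal(order(m_only$score), order(rank(m_only$mask,
                                               ties.method = "average")))
  unfit <- structure(list(trained = FALSE), class = "kg_model")
  expect_error(anomaly_score(unfit, w$cohort[1:2]), "not fitted")
})

test_that("detection metrics match pair-counting oracles", {
  expect_equal(evaluate_detection(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))$auroc, 1)
  expect_equal(evaluate_detection(c(0.1, 0.4, 0.35, 0.8),
                                  c(0, 0, 1, 1))$auroc, 0.75)
  set.seed(63)
  null_auc <- replicate(1000, {
    s <- stats::runif(30)
    evaluate_detection(s, sample(c(rep(1, 10), rep(0, 20))))$auroc
  })
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
  expect_error(evaluate_detection(1:4, c(1, 1, 1, 1)), "both positive")
})

test_that("type-preserving relabeling leaves risk and anomaly scores unchanged", {
  cfg <- generator_config(n_patients = 25L, seed = 17L)
  kb <- generate_knowledge_base(cfg)
  gen <- generate_cohort(kb, cfg)
  cohort <- gen$cohort
  v <- kb$vocab
  # permute vocabulary positions within semantic types
  set.seed(64)
  perm <- seq_along(v$concept_ids)
  for (ty in unique(v$semantic_type)) {
    sel <- which(v$semantic_type == ty)
    perm[sel] <- sample(sel)
  }
  vocab_p <- concept_vocabulary(v$concept_ids[perm], v$semantic_type[perm],
                                v$value_bearing[perm], v$names[perm])
  ont <- kb$ontology
  edges <- rbind(
    data.frame(child = ont$hierarchy_edges$child,
               parent = ont$hierarchy_edges$parent, relation = "is_a"),
    if (nrow(ont$lateral_edges) > 0)
      data.frame(child = ont$lateral_edges$child,
                 parent = ont$lateral_edges$parent,
                 relation = ont$lateral_edges$relation) else NULL)
  idxR <- which(kb$relation > 0 & upper.tri(kb$relation), arr.ind = TRUE)
  idxC <- which(kb$causal > 0, arr.ind = TRUE)
  kb_p <- knowledge_base(
    vocab_p, ontology_graph(vocab_p, edges),
    relation_pairs = data.frame(from = v$concept_ids[idxR[, 1]],
                                to = v$concept_ids[idxR[, 2]]),
    causal_pairs = data.frame(cause = v$concept_ids[idxC[, 1]],
                              effect = v$concept_ids[idxC[, 2]]))
  expect_equal(kb_p$relation[v$concept_ids, v$concept_ids], kb$relation)
  # re-encode the same clinical record against the permuted vocabulary
  cohort_p <- lapply(cohort, function(p) {
    states <- lapply(p$states, function(s) {
      dec <- decode_state(s, v)
      encode_state(lapply(dec$events, function(id) {
        if (id %in% names(dec$values)) list(concept = id,
                                            value = dec$values[[id]])
        else list(concept = id)
      }), vocab_p)
    })
    patient_trajectory(p$patient_id, p$timestamps, states, p$context)
  })
  pcfg <- desk_pipeline_config(seed = 17L)
  pcfg$epochs <- 40L
  E <- kganomaly:::pipeline_embeddings(kb, pcfg, 17L)
  E_p <- structure(list(matrix = E$matrix[perm, , drop = FALSE], layer = 0L),
                   class = "embedding_table")
  labels <- rep(c(0, 1), length.out = length(cohort))
  m1 <- kg_train(cohort, kb, pcfg, labels = labels, seed = 17L,
                 embeddings = E)
  m2 <- kg_train(cohort_p, kb_p, pcfg, labels = labels, seed = 17L,
                 embeddings = E_p)
  r1 <- vapply(cohort, function(p) {
    risk_score(kganomaly:::encode_patient(m1, p), m1$predictor)
  }, 0)
  r2 <- vapply(cohort_p, function(p) {
    risk_score(kganomaly:::encode_patient(m2, p), m2$predictor)
  }, 0)
  expect_equal(r1, r2, tolerance = 1e-10)
  s1 <- anomaly_score(m1, cohort)
  s2 <- anomaly_score(m2, cohort_p)
  expect_equal(s1$score, s2$score, tolerance = 1e-10)
})
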
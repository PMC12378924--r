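#' Composite objective weights
#'
#' Coefficients of the components of the composite training objective. The
#' regularization components default to 0.01; the supervised task term to 1.
#' `latent_cons` (the hinge on pre-softmax concept logits) defaults to 0 so
#' the hierarchy penalty is not applied twice — the softmax-scale hierarchy
#' hinge is the active one.
#'
#' @param task supervised risk BCE weight.
#' @param embed_struct ontology reconstruction penalty on embeddings.
#' @param covariance pairwise factor cosine penalty.
#' @param temporal per-factor temporal smoothness.
#' @param mi Gaussian-surrogate mutual-information penalty.
#' @param smooth whole-vector temporal smoothness.
#' @param latent_cons hierarchy hinge on concept logits.
#' @param hierarchy hierarchy hinge on softmax assignments.
#' @param kl KL alignment to the prior.
#' @param causal same-timestep causal hinge.
#' @param multistep consecutive-timestep causal hinge.
#' @param laplacian co-occurrence Laplacian smoothness of adapted factors.
#' @return named numeric vector of class `objective_weights`.
#' @export
objective_weights <- function(task = 1, embed_struct = 0.01,
                              covariance = 0.01, temporal = 0.01,
                              mi = 0.01, smooth = 0.01, latent_cons = 0,
                              hierarchy = 0.01, kl = 0.01, causal = 0.01,
                              multistep = 0.01, laplacian = 0.01) {
  w <- c(task = task, embed_struct = embed_struct, covariance = covariance,
         temporal = temporal, mi = mi, smooth = smooth,
         latent_cons = latent_cons, hierarchy = hierarchy, kl = kl,
         causal = causal, multistep = multistep, laplacian = laplacian)
  stop_if(any(w < 0), "objective weights must be >= 0")
  structure(w, class = "objective_weights")
}

#' Pipeline configuration
#'
#' Bundles the encoder, refinement and objective settings with the
#' embedding initialization used by the fitted pipeline. Embeddings
#' concatenate a spectral block (Laplacian eigenmap of the ontology, scaled
#' by `spectral_scale`, grounding latent distances in ontology geometry)
#' with a random block (near-orthogonal Xavier vectors keeping individual
#' concepts distinguishable in the soft assignments).
#'
#' @param encoder an [encoder_config] (its seed also seeds the heads).
#' @param refine a [refinement_config] used at scoring time. Few steps by
#'   default: the post-refinement residual is the anomaly signal, and full
#'   convergence would erase it.
#' @param weights an [objective_weights].
#' @param spectral_dim,spectral_scale size and scale of the spectral
#'   embedding block.
#' @param random_dim size of the random identity block.
#' @param assign_scale temperature applied to the concept projection so the
#'   soft assignments are peaked on the visit's events rather than
#'   near-uniform.
#' @param epochs,patience,val_frac forecast-head training controls (early
#'   stopping on a validation split).
#' @param score_weights weights of the four anomaly components
#'   (mask, violation, jump, forecast); uniform by default.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(encoder = encoder_config(),
                            refine = refinement_config(max_steps = 5L),
                            weights = objective_weights(),
                            spectral_dim = 8L, spectral_scale = 1.5,
                            random_dim = 32L, assign_scale = 20,
                            epochs = 400L, patience = 40L, val_frac = 0.1,
                            score_weights = c(mask = 1, violation = 1,
                                              jump = 1, forecast = 1)) {
  structure(list(encoder = encoder, refine = refine, weights = weights,
                 spectral_dim = as.integer(spectral_dim),
                 spectral_scale = spectral_scale,
                 random_dim = as.integer(random_dim),
                 assign_scale = assign_scale,
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_frac = val_frac,
                 score_weights = score_weights / sum(score_weights)),
            class = "pipeline_config")
}

# hybrid embedding table: [scaled eigenmap block | Xavier block]
pipeline_embeddings <- function(kb, config, seed) {
  n <- length(kb$vocab)
  d_spec <- min(config$spectral_dim, n)
  A <- hierarchy_adjacency(kb)
  spec <- laplacian_eigenmap(A, d_spec)$vectors * config$spectral_scale
  rnd <- with_seed(substream_seed(seed, "embed"),
                   xavier_matrix(n, config$random_dim))
  M <- cbind(spec, rnd)
  rownames(M) <- kb$vocab$concept_ids
  structure(list(matrix = M, layer = 0L), class = "embedding_table")
}

#' Predicted risk of a latent trajectory
#'
#' `sigma(sum_t w' z(t) + b)`: a sigmoid readout of the summed latent
#' states.
#'
#' @param traj a `latent_trajectory` (or `T x d` matrix).
#' @param predictor list with `w` (length `d`) and `b`.
#' @return probability in (0, 1).
#' @export
risk_score <- function(traj, predictor) {
  Z <- if (inherits(traj, "latent_trajectory")) traj$z else as.matrix(traj)
  stop_if(length(predictor$w) != ncol(Z), "predictor dimension mismatch")
  sigmoid(sum(Z %*% predictor$w) + predictor$b)
}

#' Hierarchy hinge on pre-softmax concept logits
#'
#' The latent-state consistency penalty applied to the raw concept logits
#' `P' z` rather than to the softmax assignment, keeping it distinct from
#' the assignment-scale hierarchy penalty.
#'
#' @param z latent vector.
#' @param ancestry strict-ancestry matrix.
#' @param P projection matrix `d x |E|`.
#' @return scalar penalty.
#' @export
latent_hierarchy_loss <- function(z, ancestry, P) {
  order_hinge(as.numeric(crossprod(P, z)), ancestry)
}

# ---------------------------------------------------------------------------
# model fitting

encode_patient <- function(model, traj) {
  g <- build_event_graph(traj, model$kb)
  encode_trajectory(g, model$embeddings, model$config$encoder,
                    params = model$enc_params)
}

# columns of P are the encoder images of each concept as a singleton visit,
# scaled so that assignment logits are on a discriminative scale
projection_from_embeddings <- function(embeddings, enc_params, scale = 1) {
  C <- (embeddings$matrix %*% enc_params$W_in) %*% enc_params$W_out
  nrm <- mean(sqrt(rowSums(C^2)))
  t(C) * scale / max(nrm^2, 1e-12)   # d x |E|
}

#' Fit the anomaly-detection pipeline on a cohort
#'
#' Builds the hybrid concept embeddings, the deterministic graph encoder and
#' the concept projection, derives the frequency prior, and trains the
#' one-step forecast decoder (a per-concept logistic readout of the latent
#' state) with Adam, early-stopping on a validation split. If patient
#' labels are supplied, a logistic risk head is fitted on the summed
#' latents. Deterministic given `seed`.
#'
#' @param cohort list of [patient_trajectory].
#' @param kb a [knowledge_base].
#' @param config a [pipeline_config]; the reference defaults (latent
#'   dimension 384 etc.) are scaled down by callers for desk-size cohorts.
#' @param labels optional 0/1 outcome per patient (for the risk head).
#' @param seed master seed.
#' @param embeddings optional precomputed `embedding_table` (rows in
#'   vocabulary order); defaults to the hybrid spectral+random table.
#' @return object of class `kg_model`.
#' @export
kg_train <- function(cohort, kb, config = pipeline_config(), labels = NULL,
                     seed = 1L, embeddings = NULL) {
  stop_if(length(cohort) == 0, "empty cohort")
  enc <- config$encoder
  embeddings <- embeddings %||% pipeline_embeddings(kb, config, seed)
  enc_params <- encoder_params(ncol(embeddings$matrix), enc)
  model <- structure(list(kb = kb, config = config, embeddings = embeddings,
                          enc_params = enc_params, trained = FALSE),
                     class = "kg_model")
  model$P <- projection_from_embeddings(embeddings, enc_params,
                                        scale = config$assign_scale)
  model$prior <- derive_prior(cohort, kb$vocab, "frequency")

  # latents for the whole cohort (fixed features for the heads)
  lat <- lapply(cohort, function(p) encode_patient(model, p))
  d <- enc$latent_dim
  # one-step forecast training pairs: (z(t), indicator(t+1))
  Zs <- list(); Ys <- list()
  for (k in seq_along(cohort)) {
    Tn <- nrow(lat[[k]]$z)
    if (Tn < 2) next
    Zs[[length(Zs) + 1]] <- lat[[k]]$z[seq_len(Tn - 1), , drop = FALSE]
    Ys[[length(Ys) + 1]] <- t(vapply(2:Tn, function(t) {
      cohort[[k]]$states[[t]]$indicator
    }, numeric(length(kb$vocab))))
  }
  Z <- do.call(rbind, Zs); Y <- do.call(rbind, Ys)
  stop_if(is.null(Z) || nrow(Z) < 2, "cohort has too few transitions to fit")
  fit <- fit_forecast_head(Z, Y, lr = enc$learning_rate * 100,
                           weight_decay = enc$weight_decay,
                           epochs = config$epochs, patience = config$patience,
                           val_frac = config$val_frac,
                           seed = substream_seed(seed, "train"))
  model$decoder <- fit$decoder
  model$loss_curve <- fit$loss_curve

  if (!is.null(labels)) {
    feats <- t(vapply(lat, function(l) colSums(l$z), numeric(d)))
    suppressWarnings(
      gl <- stats::glm.fit(cbind(1, feats), labels,
                           family = stats::binomial()))
    model$predictor <- list(w = gl$coefficients[-1], b = gl$coefficients[1])
    model$predictor$w[is.na(model$predictor$w)] <- 0
  } else {
    model$predictor <- list(w = numeric(d), b = 0)
  }
  model$trained <- TRUE
  model$snapshot <- config_snapshot(model)
  model
}

# full-batch Adam on the multi-label logistic forecast head
fit_forecast_head <- function(Z, Y, lr, weight_decay, epochs, patience,
                              val_frac, seed) {
  n <- nrow(Z); ne <- ncol(Y); d <- ncol(Z)
  idx <- with_seed(seed, sample(n))
  n_val <- max(1, round(val_frac * n))
  val <- idx[seq_len(n_val)]; trn <- idx[-seq_len(n_val)]
  A <- matrix(0, ne, d); b <- numeric(ne)
  mA <- A; vA <- A; mb <- b; vb <- b
  beta1 <- 0.9; beta2 <- 0.999; epsA <- 1e-8
  bce <- function(rows) {
    L <- Z[rows, , drop = FALSE] %*% t(A) +
      matrix(b, length(rows), ne, byrow = TRUE)
    p <- sigmoid(L)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -mean(Y[rows, ] * log(p) + (1 - Y[rows, ]) * log(1 - p))
  }
  best <- Inf; best_A <- A; best_b <- b; wait <- 0
  loss_curve <- numeric(0)
  for (ep in seq_len(epochs)) {
    L <- Z[trn, , drop = FALSE] %*% t(A) +
      matrix(b, length(trn), ne, byrow = TRUE)
    G <- (sigmoid(L) - Y[trn, , drop = FALSE]) / (length(trn) * ne)
    gA <- t(G) %*% Z[trn, , drop = FALSE] + weight_decay * A
    gb <- colSums(G)
    mA <- beta1 * mA + (1 - beta1) * gA; vA <- beta2 * vA + (1 - beta2) * gA^2
    mb <- beta1 * mb + (1 - beta1) * gb; vb <- beta2 * vb + (1 - beta2) * gb^2
    c1 <- 1 - beta1^ep; c2 <- 1 - beta2^ep
    A <- A - lr * (mA / c1) / (sqrt(vA / c2) + epsA)
    b <- b - lr * (mb / c1) / (sqrt(vb / c2) + epsA)
    tr_loss <- bce(trn); va_loss <- bce(val)
    if (!is.finite(tr_loss)) {
      A <- best_A; b <- best_b
      warning("forecast head diverged; reverting to best checkpoint")
      break
    }
    loss_curve <- c(loss_curve, tr_loss)
    if (va_loss < best - 1e-9) {
      best <- va_loss; best_A <- A; best_b <- b; wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= patience) break
    }
  }
  list(decoder = list(A = best_A, b = best_b), loss_curve = loss_curve)
}

config_snapshot <- function(model) {
  enc <- model$config$encoder
  list(encoder = unclass(enc),
       refine = unclass(model$config$refine),
       weights = as.list(unclass(model$config$weights)),
       score_weights = as.list(model$config$score_weights))
}

#' @export
print.kg_model <- function(x, ...) {
  cat("<kg_model> ", if (x$trained) "fitted" else "unfitted",
      "; |E| = ", length(x$kb$vocab),
      ", latent dim ", x$config$encoder$latent_dim, "\n", sep = "")
  invisible(x)
}

# ---------------------------------------------------------------------------
# anomaly scoring

patient_components <- function(model, traj) {
  kb <- model$kb
  lat <- encode_patient(model, traj)
  Tn <- nrow(lat$z)
  # mask component: overall fraction of active events without related partner
  n_active <- 0; n_rej <- 0
  rej_t <- numeric(Tn)
  for (t in seq_len(Tn)) {
    st <- traj$states[[t]]
    na_t <- sum(st$indicator)
    if (na_t == 0) next
    mr <- suppressWarnings(hard_mask(st, kb$relation))
    n_active <- n_active + na_t
    n_rej <- n_rej + mr$rejection_fraction * na_t
    rej_t[t] <- mr$rejection_fraction
  }
  mask_c <- if (n_active == 0) 0 else n_rej / n_active
  # knowledge-violation component: refinement residual (hierarchy + causal)
  ref <- refine_trajectory(lat$z, model$P, kb$ancestry, kb$causal,
                           model$config$refine)
  viol_c <- ref$objective
  # factor-jump component: largest per-step latent shift
  jump_t <- if (Tn < 2) 0 else rowSums(diff(lat$z)^2)
  jump_c <- max(jump_t, 0)
  # forecast component: one-step forecast error of the next visit's
  # indicator (per-visit BCE over the vocabulary, covering both missed
  # events and predicted-but-absent ones), averaged over transitions
  fc_t <- numeric(max(0, Tn - 1))
  if (Tn >= 2) {
    for (t in seq_len(Tn - 1)) {
      logit <- as.numeric(model$decoder$A %*% lat$z[t, ]) + model$decoder$b
      p <- pmin(pmax(sigmoid(logit), 1e-12), 1 - 1e-12)
      y <- traj$states[[t + 1]]$indicator
      fc_t[t] <- -mean(y * log(p) + (1 - y) * log(1 - p))
    }
  }
  fc_c <- if (length(fc_t) == 0) 0 else mean(fc_t)
  list(components = c(mask = mask_c, violation = viol_c,
                      jump = jump_c, forecast = fc_c),
       per_timestep = list(mask_rejection = rej_t,
                           jump = c(0, jump_t),
                           forecast = c(fc_t, NA)),
       latent = lat)
}

rank_normalize <- function(x) (rank(x, ties.method = "average") - 0.5) / length(x)

#' Score a cohort for anomalies
#'
#' For every patient, four nonnegative components are computed: the
#' hard-mask rejection fraction, the post-refinement hierarchy+causal
#' violation magnitude, the largest per-step factor shift
#' `max_t sum_k ||dz_k(t)||^2`, and the mean one-step forecast error of the
#' next visit's events. Each component is rank-normalized to `[0, 1]`
#' across the cohort (midranks, so ties land mid-interval) and combined
#' with configurable weights (uniform by default), giving a score in
#' `[0, 1]` that is invariant to monotone rescaling of any single
#' component.
#'
#' @param model a fitted `kg_model`.
#' @param cohort list of [patient_trajectory] to score jointly (the cohort
#'   defines the rank normalization).
#' @param weights optional component weights (length 4, renormalized).
#' @return object of class `kg_anomaly_report`: data.frame with
#'   `patient_id`, `score`, raw components, rank-normalized components;
#'   per-timestep breakdowns in `attr(, "per_timestep")`.
#' @export
anomaly_score <- function(model, cohort, weights = NULL) {
  stop_if(!inherits(model, "kg_model") || !isTRUE(model$trained),
          "model not fitted")
  w <- weights %||% model$config$score_weights
  stop_if(length(w) != 4, "need four component weights")
  w <- w / sum(w)
  comp <- lapply(cohort, function(p) patient_components(model, p))
  raw <- t(vapply(comp, function(c) c$components, numeric(4)))
  rn <- apply(raw, 2, rank_normalize)
  score <- as.numeric(rn %*% w)
  rep <- data.frame(patient_id = vapply(cohort, function(p) p$patient_id, ""),
                    score = score,
                    mask = raw[, "mask"], violation = raw[, "violation"],
                    jump = raw[, "jump"], forecast = raw[, "forecast"],
                    mask_rank = rn[, "mask"], violation_rank = rn[, "violation"],
                    jump_rank = rn[, "jump"], forecast_rank = rn[, "forecast"],
                    stringsAsFactors = FALSE)
  attr(rep, "per_timestep") <- lapply(comp, function(c) c$per_timestep)
  attr(rep, "weights") <- w
  class(rep) <- c("kg_anomaly_report", "data.frame")
  rep
}

# ---------------------------------------------------------------------------
# composite objective

#' Composite training objective with named breakdown
#'
#' Weighted sum of the supervised task BCE and all knowledge/temporal
#' regularizers over a batch of patients. The breakdown always sums to the
#' total (within numerical precision); a non-finite component aborts with
#' its name.
#'
#' @param cohort list of [patient_trajectory].
#' @param model a `kg_model` (fitted or not; only its features are used).
#' @param weights an [objective_weights].
#' @param labels optional 0/1 outcomes (enables the task term).
#' @return list: `total`, `breakdown` (named numeric of weighted
#'   components), `raw` (unweighted component values).
#' @export
composite_objective <- function(cohort, model, weights = objective_weights(),
                                labels = NULL) {
  kb <- model$kb
  lat <- lapply(cohort, function(p) encode_patient(model, p))
  K <- model$config$encoder$n_factors
  raw <- c(task = 0, embed_struct = 0, covariance = 0, temporal = 0,
           mi = 0, smooth = 0, latent_cons = 0, hierarchy = 0, kl = 0,
           causal = 0, multistep = 0, laplacian = 0)
  if (!is.null(labels)) {
    p <- vapply(lat, risk_score, 0, predictor = model$predictor)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    raw["task"] <- -mean(labels * log(p) + (1 - labels) * log(1 - p))
  }
  att <- neighborhood_attention(model$embeddings, kb$ontology)
  raw["embed_struct"] <- embedding_struct_loss(model$embeddings, att$context)
  cov_v <- 0; n_steps <- 0
  for (l in lat) {
    for (t in seq_len(nrow(l$z))) {
      cov_v <- cov_v + covariance_loss(factor_partition(l$z[t, ], K))
      n_steps <- n_steps + 1
    }
  }
  raw["covariance"] <- cov_v / max(1, n_steps)
  raw["temporal"] <- mean(vapply(lat, temporal_smoothness_loss, 0,
                                 per_factor = TRUE))
  raw["smooth"] <- mean(vapply(lat, temporal_smoothness_loss, 0,
                               per_factor = FALSE))
  Zall <- do.call(rbind, lapply(lat, function(l) l$z))
  if (nrow(Zall) >= 8) {
    raw["mi"] <- mi_disentanglement_loss(
      lapply(seq_len(K), function(k) {
        w <- ncol(Zall) / K
        Zall[, ((k - 1) * w + 1):(k * w), drop = FALSE]
      }))
  }
  hier_v <- 0; kl_v <- 0; caus_v <- 0; multi_v <- 0; cons_v <- 0
  for (l in lat) {
    S <- t(apply(l$z, 1, soft_assign, P = model$P))
    for (t in seq_len(nrow(S))) {
      hier_v <- hier_v + hierarchy_violation_loss(S[t, ], kb$ancestry)
      kl_v <- kl_v + kl_alignment_loss(S[t, ], model$prior)
      caus_v <- caus_v + causal_violation_loss(S[t, ], kb$causal)
      cons_v <- cons_v + latent_hierarchy_loss(l$z[t, ], kb$ancestry, model$P)
    }
    multi_v <- multi_v + multistep_causal_loss(S, kb$causal)
  }
  raw["hierarchy"] <- hier_v / length(lat)
  raw["kl"] <- kl_v / length(lat)
  raw["causal"] <- caus_v / length(lat)
  raw["multistep"] <- multi_v / length(lat)
  raw["latent_cons"] <- cons_v / length(lat)
  if (!is.null(model$adapted)) {
    raw["laplacian"] <- laplacian_smoothness(model$adapted$V,
                                             model$adapted$laplacian)
  }
  bad <- names(raw)[!is.finite(raw)]
  stop_if(length(bad) > 0, "non-finite objective component: ",
          paste(bad, collapse = ", "))
  breakdown <- unclass(weights)[names(raw)] * raw
  list(total = sum(breakdown), breakdown = breakdown, raw = raw)
}

# ---------------------------------------------------------------------------
# detection metrics

#' Detection metrics for anomaly scores
#'
#' AUROC by the rank statistic with midrank ties, plus precision, recall
#' and F1 at a threshold. Needs at least one positive and one negative
#' label.
#'
#' @param scores numeric anomaly scores (higher = more anomalous).
#' @param labels 0/1 ground-truth labels.
#' @param threshold decision threshold for the binary metrics.
#' @return list: `auroc`, `precision`, `recall`, `f1`, `n_pos`, `n_neg`.
#' @export
evaluate_detection <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stop_if(n1 == 0 || n0 == 0, "need both positive and negative labels")
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_ else
    2 * precision * recall / (precision + recall)
  list(auroc = auroc, precision = precision, recall = recall, f1 = f1,
       n_pos = n1, n_neg = n0)
}
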
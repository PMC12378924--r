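#' Soft concept assignment from a latent state
#'
#' Projects a latent vector into the event space and normalizes with a
#' softmax: `s = softmax(P' z)`. Each component is the soft relevance of one
#' concept at that timestep.
#'
#' @param z latent vector of length `d`.
#' @param P projection matrix `d x |E|` (columns in vocabulary order).
#' @return probability vector over concepts (sums to 1).
#' @export
soft_assign <- function(z, P) {
  stop_if(length(z) != nrow(P), "dim(z) = ", length(z),
          " does not match nrow(P) = ", nrow(P))
  softmax(as.numeric(crossprod(P, z)))
}

# generic partial-order hinge: sum_ij M_ij * max(0, s_j - s_i)
order_hinge <- function(s, M) {
  check_square(M, length(s), "constraint matrix")
  idx <- which(M > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  sum(M[idx] * pmax(0, s[idx[, 2]] - s[idx[, 1]]))
}

# gradient of order_hinge wrt s (a subgradient at ties)
order_hinge_grad <- function(s, M) {
  g <- numeric(length(s))
  idx <- which(M > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(g)
  act <- s[idx[, 2]] > s[idx[, 1]]
  if (any(act)) {
    w <- M[idx][act]
    g_j <- tapply(w, idx[act, 2], sum)
    g_i <- tapply(w, idx[act, 1], sum)
    g[as.integer(names(g_j))] <- g[as.integer(names(g_j))] + g_j
    g[as.integer(names(g_i))] <- g[as.integer(names(g_i))] - g_i
  }
  g
}

#' Hierarchy-consistency hinge penalty
#'
#' `sum_ij T_ij max(0, s_j - s_i)` over the strict-ancestry matrix: positive
#' whenever a descendant is scored above one of its ancestors, zero iff the
#' assignment respects the hierarchy's partial order.
#'
#' @param s probability (or score) vector over concepts.
#' @param ancestry binary strict-ancestry matrix from
#'   [transitive_closure()].
#' @return scalar penalty.
#' @export
hierarchy_violation_loss <- function(s, ancestry) order_hinge(s, ancestry)

#' Causal-precedence hinge penalty
#'
#' `sum_ij C_ij max(0, s_j - s_i)`: positive whenever a causally subsequent
#' event is scored higher than its cause at the same timestep.
#'
#' @param s score vector over concepts.
#' @param causal binary causal matrix from [causal_matrix()].
#' @return scalar penalty.
#' @export
causal_violation_loss <- function(s, causal) order_hinge(s, causal)

#' Multi-step (cascaded) causal penalty
#'
#' Couples consecutive timesteps:
#' `sum_{t=1}^{T-1} sum_ij C_ij max(0, s_j(t+1) - s_i(t))`. Zero for a
#' single timestep.
#'
#' @param S assignment matrix `T x |E|` (rows are per-timestep scores).
#' @param causal binary causal matrix.
#' @return scalar penalty.
#' @export
multistep_causal_loss <- function(S, causal) {
  S <- as.matrix(S)
  Tn <- nrow(S)
  if (Tn < 2) return(0)
  idx <- which(causal > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(0)
  total <- 0
  for (t in seq_len(Tn - 1)) {
    total <- total + sum(causal[idx] *
                           pmax(0, S[t + 1, idx[, 2]] - S[t, idx[, 1]]))
  }
  total
}

#' KL alignment penalty against a prior event distribution
#'
#' `sum_i q_i log(q_i / (s_i + eps))` with the convention `0 log 0 = 0`.
#' With `eps = 0` this is the KL divergence (nonnegative, zero iff `s = q`
#' on the support of `q`); a positive `eps` introduces a small negative bias
#' bounded below by `-log(1 + eps |E|)`.
#'
#' @param s predicted event distribution.
#' @param q prior distribution (a `prior_distribution` or plain vector).
#' @param eps smoothing added to `s` inside the logarithm.
#' @return scalar penalty.
#' @export
kl_alignment_loss <- function(s, q, eps = 1e-8) {
  if (inherits(q, "prior_distribution")) {
    eps <- q$eps
    q <- q$q
  }
  stop_if(length(s) != length(q), "s and q differ in length")
  sup <- q > 0
  stop_if(any(s[sup] + eps == 0),
          "s + eps vanishes on the support of q; use eps > 0")
  sum(q[sup] * log(q[sup] / (s[sup] + eps)))
}

#' Derive a prior event distribution
#'
#' `mode = "frequency"`: add-one-smoothed event frequencies over a cohort;
#' `mode = "uniform"`: `1/|E|` everywhere.
#'
#' @param source a cohort (list of [patient_trajectory]) for frequency mode,
#'   or anything with a vocabulary for uniform mode.
#' @param vocab the [concept_vocabulary].
#' @param mode `"frequency"` or `"uniform"`.
#' @param eps smoothing constant stored with the prior (used by
#'   [kl_alignment_loss()]).
#' @return object of class `prior_distribution`: `q`, `eps`.
#' @export
derive_prior <- function(source, vocab, mode = c("frequency", "uniform"),
                         eps = 1e-8) {
  mode <- match.arg(mode)
  n <- length(vocab)
  q <- if (mode == "uniform") {
    rep(1 / n, n)
  } else {
    counts <- numeric(n)
    stop_if(length(source) == 0, "empty cohort")
    for (p in source) for (s in p$states) counts <- counts + s$indicator
    (counts + 1) / sum(counts + 1)
  }
  structure(list(q = q, eps = eps), class = "prior_distribution")
}

#' Refinement configuration
#'
#' @param eta gradient step size.
#' @param lambda1,lambda2 weights of the hierarchy and causal penalties.
#' @param max_steps maximum descent steps.
#' @param safeguard halve the step (up to `max_halvings`) whenever a step
#'   would increase the combined objective, guaranteeing monotone descent.
#' @param max_halvings halvings allowed per step.
#' @param learn_gamma co-optimize the per-timestep causal scale
#'   `gamma_t = exp(g_t)` (initialized at `g_t = 0`).
#' @param use_multistep include the consecutive-timestep causal penalty.
#' @return object of class `refinement_config`.
#' @export
refinement_config <- function(eta = 1e-2, lambda1 = 1, lambda2 = 1,
                              max_steps = 50L, safeguard = TRUE,
                              max_halvings = 20L, learn_gamma = FALSE,
                              use_multistep = TRUE) {
  stop_if(eta <= 0, "eta must be > 0")
  stop_if(lambda1 < 0 || lambda2 < 0, "lambda weights must be >= 0")
  structure(list(eta = eta, lambda1 = lambda1, lambda2 = lambda2,
                 max_steps = as.integer(max_steps), safeguard = safeguard,
                 max_halvings = as.integer(max_halvings),
                 learn_gamma = learn_gamma, use_multistep = use_multistep),
            class = "refinement_config")
}

# combined refinement objective over a whole trajectory:
#   sum_t [ lambda1 * L_hier(s_t) + gamma_t * lambda2 * L_causal(s_t) ]
#   + lambda2 * L_multistep(S)   (if enabled)
refine_objective <- function(Z, P, ancestry, causal, gamma, cfg) {
  S <- t(apply(Z, 1, soft_assign, P = P))
  if (ncol(Z) == 0) stop("empty latent")
  total <- 0
  for (t in seq_len(nrow(Z))) {
    total <- total + cfg$lambda1 * order_hinge(S[t, ], ancestry) +
      gamma[t] * cfg$lambda2 * order_hinge(S[t, ], causal)
  }
  if (cfg$use_multistep) {
    total <- total + cfg$lambda2 * multistep_causal_loss(S, causal)
  }
  list(value = total, S = S)
}

# gradient of the combined objective wrt every z(t) (T x d matrix).
# chain rule through the softmax: dL/dz_t = P (s_t * g_t - s_t <s_t, g_t>)
refine_gradient <- function(Z, P, ancestry, causal, gamma, cfg, S) {
  Tn <- nrow(Z)
  Gs <- matrix(0, Tn, ncol(S))     # dL/ds(t)
  for (t in seq_len(Tn)) {
    g <- cfg$lambda1 * order_hinge_grad(S[t, ], ancestry) +
      gamma[t] * cfg$lambda2 * order_hinge_grad(S[t, ], causal)
    Gs[t, ] <- g
  }
  if (cfg$use_multistep && Tn >= 2) {
    idx <- which(causal > 0, arr.ind = TRUE)
    if (nrow(idx) > 0) {
      for (t in seq_len(Tn - 1)) {
        act <- S[t + 1, idx[, 2]] > S[t, idx[, 1]]
        if (any(act)) {
          w <- causal[idx][act]
          add <- tapply(w, idx[act, 2], sum)
          sub <- tapply(w, idx[act, 1], sum)
          jj <- as.integer(names(add)); ii <- as.integer(names(sub))
          Gs[t + 1, jj] <- Gs[t + 1, jj] + cfg$lambda2 * add
          Gs[t, ii] <- Gs[t, ii] - cfg$lambda2 * sub
        }
      }
    }
  }
  GZ <- matrix(0, Tn, ncol(Z))
  for (t in seq_len(Tn)) {
    s <- S[t, ]; g <- Gs[t, ]
    GZ[t, ] <- as.numeric(P %*% (s * g - s * sum(s * g)))
  }
  GZ
}

#' Knowledge-guided refinement of a latent trajectory
#'
#' Gradient descent on the latent states against the weighted hierarchy and
#' causal hinge penalties evaluated through the softmax assignment
#' (`s(t) = softmax(P' z(t))`), with an optional consecutive-timestep causal
#' term coupling the steps. The simplex constraint on `s` is enforced
#' structurally by the softmax. With the halving safeguard on, the combined
#' objective at return never exceeds its initial value; if the initial
#' objective is zero the input is returned unchanged.
#'
#' @param Z `T x d` latent matrix (or a `latent_trajectory`).
#' @param P projection matrix `d x |E|`.
#' @param ancestry,causal binary constraint matrices.
#' @param config a [refinement_config].
#' @return list: `Z` (refined matrix), `objective` (value at return),
#'   `trace` (objective per accepted step), `gamma` (per-timestep causal
#'   scales), `assignments` (final `T x |E|` matrix).
#' @export
refine_trajectory <- function(Z, P, ancestry, causal,
                              config = refinement_config()) {
  was_traj <- inherits(Z, "latent_trajectory")
  Zm <- if (was_traj) Z$z else as.matrix(Z)
  Tn <- nrow(Zm)
  g_t <- numeric(Tn)                        # gamma_t = exp(g_t), start at 1
  gamma <- exp(g_t)
  cur <- refine_objective(Zm, P, ancestry, causal, gamma, config)
  trace <- cur$value
  if (cur$value <= 0) {
    return(list(Z = Zm, objective = cur$value, trace = trace,
                gamma = gamma, assignments = cur$S))
  }
  eta <- config$eta
  for (step in seq_len(config$max_steps)) {
    GZ <- refine_gradient(Zm, P, ancestry, causal, gamma, config, cur$S)
    if (any(!is.finite(GZ))) {
      stop("non-finite gradient at refinement step ", step, call. = FALSE)
    }
    if (config$learn_gamma) {
      # d obj / d g_t = gamma_t * lambda2 * L_causal(s_t); descend jointly
      gg <- vapply(seq_len(Tn), function(t) {
        gamma[t] * config$lambda2 * order_hinge(cur$S[t, ], causal)
      }, 0)
    }
    step_eta <- eta
    accepted <- FALSE
    for (h in 0:config$max_halvings) {
      cand <- Zm - step_eta * GZ
      g_cand <- if (config$learn_gamma) g_t - step_eta * gg else g_t
      gam_cand <- exp(g_cand)
      obj <- refine_objective(cand, P, ancestry, causal, gam_cand, config)
      if (!config$safeguard || obj$value <= cur$value) {
        Zm <- cand; g_t <- g_cand; gamma <- gam_cand; cur <- obj
        accepted <- TRUE
        break
      }
      step_eta <- step_eta / 2
    }
    if (!accepted) break                    # cannot descend further
    trace <- c(trace, cur$value)
    if (cur$value <= 0) break
  }
  list(Z = Zm, objective = cur$value, trace = trace, gamma = gamma,
       assignments = cur$S)
}
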
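#' Patient-event occurrence matrix
#'
#' Binary `|P| x |E|` matrix with a 1 where a patient ever experienced an
#' event over their whole trajectory.
#'
#' @param cohort list of [patient_trajectory].
#' @param vocab the [concept_vocabulary].
#' @return binary matrix, rows named by patient id.
#' @export
occurrence_matrix <- function(cohort, vocab) {
  B <- matrix(0, length(cohort), length(vocab),
              dimnames = list(vapply(cohort, function(p) p$patient_id, ""),
                              vocab$concept_ids))
  for (k in seq_along(cohort)) {
    for (s in cohort[[k]]$states) B[k, ] <- pmax(B[k, ], s$indicator)
  }
  B
}

# plug-in entropy of a binary vector (natural log)
binary_entropy <- function(x) {
  p <- mean(x)
  if (p == 0 || p == 1) return(0)
  -p * log(p) - (1 - p) * log(1 - p)
}

#' Event co-occurrence graph via normalized mutual information
#'
#' Edge weight between events i and j is
#' `MI(B[,i], B[,j]) / sqrt(H(B[,i]) H(B[,j]))` with plug-in (maximum
#' likelihood) entropies over patients. Constant columns (zero entropy) give
#' weight 0 by convention; the diagonal is 0. Returns the graph together
#' with its unnormalized Laplacian.
#'
#' @param B binary occurrence matrix from [occurrence_matrix()].
#' @return list: `G` (symmetric `|E| x |E|`, entries in `[0,1]`),
#'   `laplacian`.
#' @export
cooccurrence_nmi <- function(B) {
  stop_if(nrow(B) < 2, "need at least two patients")
  n <- ncol(B)
  H <- apply(B, 2, binary_entropy)
  G <- matrix(0, n, n, dimnames = dimnames(B)[c(2, 2)])
  for (i in seq_len(n - 1)) {
    if (H[i] == 0) next
    for (j in (i + 1):n) {
      if (H[j] == 0) next
      # MI from the 2x2 contingency table
      mi <- 0
      for (a in 0:1) for (b in 0:1) {
        p_ab <- mean(B[, i] == a & B[, j] == b)
        if (p_ab > 0) {
          p_a <- mean(B[, i] == a); p_b <- mean(B[, j] == b)
          mi <- mi + p_ab * log(p_ab / (p_a * p_b))
        }
      }
      w <- max(0, min(1, mi / sqrt(H[i] * H[j])))
      G[i, j] <- w; G[j, i] <- w
    }
  }
  list(G = G, laplacian = graph_laplacian(G))
}

#' Laplacian smoothness of an embedding matrix
#'
#' `Tr(V' L V)`, equal to `1/2 sum_ij G_ij ||v_i - v_j||^2`: small when
#' co-occurring events have similar embeddings.
#'
#' @param V `|E| x d` embedding matrix.
#' @param L graph Laplacian.
#' @return scalar.
#' @export
laplacian_smoothness <- function(V, L) {
  stop_if(nrow(V) != nrow(L), "V and L disagree on |E|")
  sum(diag(t(V) %*% L %*% V))
}

#' Graph-regularized matrix factorization of the occurrence matrix
#'
#' Alternating least squares on
#' `||B - U V'||_F^2 + gamma (||U||_F^2 + ||V||_F^2) + lambda Tr(V' L V)`.
#' The U-step is ridge regression; the V-step solves the Sylvester-type
#' system `V (U'U + gamma I) + lambda L V = B' U` exactly through the
#' eigendecomposition of `L`, so the objective is non-increasing at every
#' half-iteration.
#'
#' @param B binary occurrence matrix.
#' @param d factor dimension.
#' @param gamma ridge weight (must be > 0 unless B has full-rank factors).
#' @param lambda Laplacian weight.
#' @param L event Laplacian (defaults to zero: plain ridge factorization).
#' @param max_iter,tol convergence controls (relative objective change).
#' @param seed initialization seed.
#' @return object of class `factor_pair`: `U`, `V`, `objective` (final),
#'   `trace` (objective after every half-iteration), `converged`.
#' @export
factorize <- function(B, d, gamma = 0.1, lambda = 0, L = NULL,
                      max_iter = 500L, tol = 1e-8, seed = 1L) {
  stop_if(d < 1, "d must be >= 1")
  B <- as_dense(B)
  np <- nrow(B); ne <- ncol(B)
  if (is.null(L)) L <- matrix(0, ne, ne)
  stop_if(gamma == 0 && lambda == 0 && d > 1,
          "gamma = 0 risks singular normal equations; use gamma > 0")
  eig <- eigen(L, symmetric = TRUE)
  with_seed(substream_seed(seed, "factorize"), {
    U <- matrix(stats::runif(np * d, -0.1, 0.1), np, d)
    V <- matrix(stats::runif(ne * d, -0.1, 0.1), ne, d)
  })
  obj <- function(U, V) {
    sum((B - U %*% t(V))^2) + gamma * (sum(U^2) + sum(V^2)) +
      lambda * sum(diag(t(V) %*% L %*% V))
  }
  trace <- obj(U, V)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # U-step: ridge regression rows
    M <- crossprod(V) + gamma * diag(d)
    Mi <- tryCatch(solve(M), error = function(e) {
      stop("singular normal equations in U-step; use gamma > 0",
           call. = FALSE)
    })
    U <- B %*% V %*% Mi
    trace <- c(trace, obj(U, V))
    # V-step: solve V (U'U + gamma I) + lambda L V = B'U via eigenbasis of L
    A <- crossprod(U) + gamma * diag(d)
    RHS <- t(eig$vectors) %*% (t(B) %*% U)
    Vt <- matrix(0, ne, d)
    for (r in seq_len(ne)) {
      Ar <- A + lambda * eig$values[r] * diag(d)
      Vt[r, ] <- tryCatch(solve(Ar, RHS[r, ]), error = function(e) {
        stop("singular normal equations in V-step; use gamma > 0",
             call. = FALSE)
      })
    }
    V <- eig$vectors %*% Vt
    o <- obj(U, V)
    trace <- c(trace, o)
    prev <- trace[length(trace) - 2]
    if (abs(prev - o) <= tol * max(1, abs(prev))) {
      converged <- TRUE
      break
    }
  }
  structure(list(U = U, V = V, objective = trace[length(trace)],
                 trace = trace, converged = converged,
                 gamma = gamma, lambda = lambda),
            class = "factor_pair")
}

#' Ridge alignment of adapted embeddings to pre-trained vectors
#'
#' The unique minimizer of `||V W - V_pre||_F^2 + alpha ||W||_F^2`:
#' `W = (V'V + alpha I)^-1 V' V_pre`. With `alpha = 0` the system must be
#' full rank.
#'
#' @param V `|E| x d` adapted embedding matrix.
#' @param V_pre `|E| x d'` pre-trained vectors (same row order).
#' @param alpha ridge weight, `>= 0`.
#' @return `d x d'` projection matrix `W`.
#' @export
align_projection <- function(V, V_pre, alpha = 0.1) {
  stop_if(nrow(V) != nrow(V_pre), "V and V_pre must have equal row counts")
  stop_if(alpha < 0, "alpha must be >= 0")
  M <- crossprod(V) + alpha * diag(ncol(V))
  tryCatch(solve(M, crossprod(V, V_pre)), error = function(e) {
    stop("V'V is rank-deficient with alpha = 0; use alpha > 0",
         call. = FALSE)
  })
}
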
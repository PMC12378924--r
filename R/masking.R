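#' Hard knowledge-guided mask
#'
#' Keeps an active event iff at least one co-active event is related to it
#' under the relation matrix: `m_i = 1[ sum_{j active} R_ij > 0 ]` applied to
#' active entries only. Events with no support are zeroed; their attached
#' values are dropped and recorded for audit.
#'
#' @param state a `clinical_state` (or plain 0/1 indicator vector).
#' @param relation binary symmetric relation matrix with zero diagonal.
#' @param vocab optional [concept_vocabulary] for the audit of dropped
#'   values.
#' @return object of class `mask_result`: `mask`, `masked` (indicator),
#'   `confidence`, `rejection_fraction`, `dropped_values`.
#' @export
hard_mask <- function(state, relation, vocab = NULL) {
  x <- state_indicator(state)
  check_mask_dims(x, relation)
  support <- as.numeric(relation %*% x)
  m <- as.numeric(x > 0 & support > 0)
  finish_mask(state, x, m, relational_confidence(state, relation))
}

#' Normalized relational confidence scores
#'
#' `s_i = (1/||x||_1) * sum_j R_ij x_j`: the share of co-occurring events
#' related to event `i`. An all-zero state returns all-zero confidence (and
#' a warning), since the normalization is undefined there.
#'
#' @inheritParams hard_mask
#' @return numeric vector `s` of length `|E|`, entries in `[0, 1]`.
#' @export
relational_confidence <- function(state, relation) {
  x <- state_indicator(state)
  check_mask_dims(x, relation)
  n_active <- sum(x)
  if (n_active == 0) {
    warning("empty state: relational confidence undefined, returning zeros")
    return(stats::setNames(numeric(length(x)), rownames(relation)))
  }
  stats::setNames(as.numeric(relation %*% x) / n_active, rownames(relation))
}

#' Soft (differentiable) mask
#'
#' `x~_i = x_i * sigmoid(alpha * s_i)` — a temperature-controlled gate that
#' approaches the hard mask's support as `alpha` grows wherever `s_i > 0`.
#' Default `alpha = 4` gates a half-supported event at about 0.88.
#'
#' @param state indicator vector or `clinical_state`.
#' @param confidence confidence vector from [relational_confidence()].
#' @param alpha nonnegative temperature.
#' @return gated numeric state vector.
#' @export
soft_mask <- function(state, confidence, alpha = 4) {
  stop_if(alpha < 0, "alpha must be >= 0")
  x <- state_indicator(state)
  stop_if(length(x) != length(confidence),
          "state and confidence differ in length")
  x * sigmoid(alpha * confidence)
}

#' Type-consistent mask
#'
#' Stricter rule: an active event is kept only if some co-active event is
#' related to it AND shares its semantic type:
#' `m_i = 1[ exists active j with R_ij = 1 and type(i) = type(j) ]`.
#' Always at most as permissive as [hard_mask()].
#'
#' @inheritParams hard_mask
#' @param types binary `|E| x c` one-hot type matrix.
#' @return `mask_result` as in [hard_mask()].
#' @export
typed_mask <- function(state, relation, types, vocab = NULL) {
  x <- state_indicator(state)
  check_mask_dims(x, relation)
  stop_if(nrow(types) != length(x), "type matrix row count mismatch")
  stop_if(any(rowSums(types) != 1), "type matrix rows must be one-hot")
  same_type <- types %*% t(types)          # 1 iff type(i) == type(j)
  support <- as.numeric((relation * same_type) %*% x)
  m <- as.numeric(x > 0 & support > 0)
  finish_mask(state, x, m, relational_confidence(state, relation))
}

state_indicator <- function(state) {
  if (inherits(state, "clinical_state")) state$indicator else as.numeric(state)
}

check_mask_dims <- function(x, relation) {
  stop_if(nrow(relation) != length(x) || ncol(relation) != length(x),
          "relation matrix dimension (", nrow(relation), "x", ncol(relation),
          ") does not match state length ", length(x))
}

finish_mask <- function(state, x, m, confidence) {
  n_active <- sum(x)
  rejected <- if (n_active == 0) 0 else (n_active - sum(m)) / n_active
  dropped <- character(0)
  if (inherits(state, "clinical_state") && length(state$values) > 0 &&
      !is.null(names(confidence))) {
    # values attached to masked-out labs travel with the event; keep an audit
    dropped <- intersect(names(state$values), names(confidence)[m == 0])
  }
  structure(list(mask = m,
                 masked = x * m,
                 confidence = confidence,
                 rejection_fraction = rejected,
                 dropped_values = dropped),
            class = "mask_result")
}

#' @export
print.mask_result <- function(x, ...) {
  cat("<mask_result> kept ", sum(x$masked), " active events; rejection ",
      signif(x$rejection_fraction, 3), "\n", sep = "")
  invisible(x)
}
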
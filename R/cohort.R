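#' Static patient context
#'
#' @param age nonnegative age in years.
#' @param sex categorical sex label.
#' @param comorbidities binary flag vector (0/1).
#' @return object of class `patient_context`.
#' @export
patient_context <- function(age, sex = "unknown", comorbidities = integer(0)) {
  stop_if(age < 0, "age must be >= 0")
  structure(list(age = as.numeric(age), sex = as.character(sex),
                 comorbidities = as.integer(comorbidities)),
            class = "patient_context")
}

#' Encode a visit's events as a multi-hot clinical state
#'
#' Produces the length-`|E|` 0/1 indicator of which events occur, with an
#' attached sparse value map for value-bearing concepts (labs). Listing an
#' event twice is idempotent; supplying a value for a concept that does not
#' carry values is an error.
#'
#' @param events character vector of concept ids, or a list of
#'   `list(concept =, value =)` entries for valued events.
#' @param vocab a [concept_vocabulary].
#' @return object of class `clinical_state`: `indicator` (0/1 vector) and
#'   `values` (named numeric, names are concept ids).
#' @export
encode_state <- function(events, vocab) {
  ind <- numeric(length(vocab))
  vals <- stats::setNames(numeric(0), character(0))
  if (is.character(events)) {
    events <- lapply(events, function(e) list(concept = e))
  }
  for (ev in events) {
    id <- ev$concept
    i <- concept_index(vocab, id)
    ind[i] <- 1
    if (!is.null(ev$value) && !is.na(ev$value)) {
      stop_if(!vocab$value_bearing[i],
              "value supplied for non-value-bearing concept: ", id)
      vals[as.character(id)] <- as.numeric(ev$value)
    }
  }
  # canonical order: values sorted by concept index, so states encoded from
  # any event ordering compare (and serialize) identically
  if (length(vals) > 0) vals <- vals[order(concept_index(vocab, names(vals)))]
  structure(list(indicator = ind, values = vals), class = "clinical_state")
}

#' Decode a clinical state back to its event list
#'
#' Inverse of [encode_state()]: returns the active concept ids and the value
#' map, exactly as encoded.
#'
#' @param state a `clinical_state`.
#' @param vocab the matching [concept_vocabulary].
#' @return list with `events` (character) and `values` (named numeric).
#' @export
decode_state <- function(state, vocab) {
  list(events = vocab$concept_ids[state$indicator > 0],
       values = state$values)
}

#' Patient trajectory
#'
#' An ordered sequence of clinical states at strictly increasing timestamps
#' plus static context.
#'
#' @param patient_id identifier.
#' @param timestamps strictly increasing numeric vector (or dates, coerced).
#' @param states list of `clinical_state`, one per timestamp.
#' @param context a [patient_context].
#' @return object of class `patient_trajectory`.
#' @export
patient_trajectory <- function(patient_id, timestamps, states,
                               context = patient_context(0)) {
  timestamps <- as.numeric(timestamps)
  stop_if(length(timestamps) < 1, "trajectory needs at least one timestamp")
  stop_if(length(timestamps) != length(states),
          "timestamps and states differ in length for patient ", patient_id)
  stop_if(any(diff(timestamps) <= 0),
          "timestamps not strictly increasing for patient ", patient_id)
  structure(list(patient_id = as.character(patient_id),
                 timestamps = timestamps, states = states, context = context),
            class = "patient_trajectory")
}

#' @export
print.patient_trajectory <- function(x, ...) {
  cat("<patient_trajectory> ", x$patient_id, ": ", length(x$timestamps),
      " visits, ", sum(vapply(x$states, function(s) sum(s$indicator), 0)),
      " events\n", sep = "")
  invisible(x)
}

#' Temporal event graph of one patient
#'
#' One node per (timestamp, active event). Edges: an intra-visit clique among
#' co-occurring events; a complete bipartite set of inter-visit edges between
#' consecutive visits; and ontology-labelled edges wherever the knowledge
#' base relates two co-present concepts.
#'
#' @param trajectory a [patient_trajectory].
#' @param kb a [knowledge_base] (optional; `NULL` skips ontology edges).
#' @return object of class `temporal_event_graph` with `nodes`
#'   (data.frame `t`, `concept`) and `edges` (data.frame `from`, `to`,
#'   `label`), node indices referring to rows of `nodes`.
#' @export
build_event_graph <- function(trajectory, kb = NULL) {
  Tn <- length(trajectory$timestamps)
  t_idx <- integer(0); cpt <- integer(0)
  for (t in seq_len(Tn)) {
    act <- which(trajectory$states[[t]]$indicator > 0)
    t_idx <- c(t_idx, rep(t, length(act)))
    cpt <- c(cpt, act)
  }
  nodes <- data.frame(t = t_idx, concept = cpt)
  from <- integer(0); to <- integer(0); label <- character(0)
  for (t in seq_len(Tn)) {
    here <- which(nodes$t == t)
    if (length(here) >= 2) {
      cmb <- utils::combn(here, 2)
      from <- c(from, cmb[1, ]); to <- c(to, cmb[2, ])
      label <- c(label, rep("intra", ncol(cmb)))
    }
    if (t < Tn) {
      nxt <- which(nodes$t == t + 1)
      if (length(here) > 0 && length(nxt) > 0) {
        grid <- expand.grid(a = here, b = nxt)
        from <- c(from, grid$a); to <- c(to, grid$b)
        label <- c(label, rep("inter", nrow(grid)))
      }
    }
    if (!is.null(kb) && length(here) >= 2) {
      cmb <- utils::combn(here, 2)
      for (k in seq_len(ncol(cmb))) {
        ci <- nodes$concept[cmb[1, k]]; cj <- nodes$concept[cmb[2, k]]
        if (kb$relation[ci, cj] > 0) {
          from <- c(from, cmb[1, k]); to <- c(to, cmb[2, k])
          label <- c(label, "ontology")
        }
      }
    }
  }
  structure(list(nodes = nodes,
                 edges = data.frame(from = from, to = to, label = label,
                                    stringsAsFactors = FALSE),
                 n_timestamps = Tn),
            class = "temporal_event_graph")
}

#' Event transition tensor
#'
#' Sparse binary tensor `A[t, i, j] = 1` iff event `i` is active at timestamp
#' `t` and event `j` is active at timestamp `t + 1` (the temporal reading of
#' an observed transition). The slice at the final timestamp is all zero.
#' `within_time = TRUE` records within-timestamp ordered pairs instead.
#'
#' @param trajectory a [patient_trajectory].
#' @param n_concepts vocabulary size `|E|`.
#' @param within_time record same-timestamp pairs instead of consecutive-time
#'   pairs.
#' @return object of class `transition_tensor`: triplet data.frame
#'   (`t`, `i`, `j`) plus `dims = c(T, |E|, |E|)`.
#' @export
transition_tensor <- function(trajectory, n_concepts,
                              within_time = FALSE) {
  Tn <- length(trajectory$timestamps)
  t_out <- integer(0); i_out <- integer(0); j_out <- integer(0)
  for (t in seq_len(Tn)) {
    a <- which(trajectory$states[[t]]$indicator > 0)
    if (within_time) {
      if (length(a) > 0) {
        grid <- expand.grid(i = a, j = a)
        grid <- grid[grid$i != grid$j, ]
        t_out <- c(t_out, rep(t, nrow(grid)))
        i_out <- c(i_out, grid$i); j_out <- c(j_out, grid$j)
      }
    } else if (t < Tn) {
      b <- which(trajectory$states[[t + 1]]$indicator > 0)
      if (length(a) > 0 && length(b) > 0) {
        grid <- expand.grid(i = a, j = b)
        t_out <- c(t_out, rep(t, nrow(grid)))
        i_out <- c(i_out, grid$i); j_out <- c(j_out, grid$j)
      }
    }
  }
  structure(list(entries = data.frame(t = t_out, i = i_out, j = j_out),
                 dims = c(Tn, n_concepts, n_concepts)),
            class = "transition_tensor")
}

#' Z-score lab values per concept across a cohort
#'
#' Centers and scales each value-bearing concept's values over all visits of
#' all patients; raw values stay in the `values` maps, the standardized ones
#' are returned as an attribute-friendly list for downstream encoders.
#'
#' @param cohort list of [patient_trajectory].
#' @param vocab the [concept_vocabulary].
#' @return list with per-concept `center`/`scale` and a function
#'   `standardize(concept_id, value)`.
#' @export
lab_standardizer <- function(cohort, vocab) {
  acc <- list()
  for (p in cohort) for (s in p$states) {
    for (id in names(s$values)) acc[[id]] <- c(acc[[id]], s$values[[id]])
  }
  center <- vapply(acc, mean, 0)
  scale <- vapply(acc, function(v) {
    s <- stats::sd(v); if (is.na(s) || s == 0) 1 else s
  }, 0)
  list(center = center, scale = scale,
       standardize = function(concept_id, value) {
         if (!concept_id %in% names(center)) return(value)
         (value - center[[concept_id]]) / scale[[concept_id]]
       })
}
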
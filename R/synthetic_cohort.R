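#' Synthetic generator configuration
#'
#' Conditions for the synthetic knowledge base and cohort: a four-level
#' is-a hierarchy (root, branches, cluster parents, leaf concepts), lateral
#' relations at a fixed density, a causal DAG consistent with concept order,
#' and a latent Markov health-state process emitting visit event sets from
#' per-state concept clusters. Planted anomalies come in three classes that
#' align one-to-one with detector components: `cooccurrence` (an event with
#' no related partner in its visit), `causal` (a cause/effect pair swapped
#' across visits) and `jump` (one visit replaced by a cluster at maximal
#' ontology distance).
#'
#' @param n_concepts vocabulary size.
#' @param n_types number of semantic types (cycled over
#'   diagnosis/medication/lab/procedure).
#' @param n_branches second-level branches under the root.
#' @param n_parents cluster parents (split round-robin over branches).
#' @param second_parent_prob probability a leaf gets a second parent.
#' @param lateral_density density of random lateral relation edges.
#' @param causal_per_cluster causal edges drawn inside each health cluster.
#' @param n_patients cohort size.
#' @param visits_range inclusive range of visits per patient.
#' @param events_range inclusive range of events sampled per visit.
#' @param k_health number of latent health states (clusters used for
#'   emission; must not exceed the parents of the first branch).
#' @param self_transition probability of staying in the same health state.
#' @param anomaly_rate fraction of patients receiving one planted anomaly.
#' @param anomaly_mix named proportions over
#'   `c("cooccurrence", "causal", "jump")`.
#' @param seed master seed; all generator randomness flows from it through
#'   named substreams.
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n_concepts = 60L, n_types = 4L,
                             n_branches = 2L, n_parents = 10L,
                             second_parent_prob = 0.15,
                             lateral_density = 0.01,
                             causal_per_cluster = 2L,
                             n_patients = 200L,
                             visits_range = c(8L, 12L),
                             events_range = c(3L, 5L),
                             k_health = 5L,
                             self_transition = 0.7,
                             anomaly_rate = 0.1,
                             anomaly_mix = c(cooccurrence = 1 / 3,
                                             causal = 1 / 3, jump = 1 / 3),
                             seed = 1L) {
  cfg <- list(n_concepts = as.integer(n_concepts),
              n_types = as.integer(n_types),
              n_branches = as.integer(n_branches),
              n_parents = as.integer(n_parents),
              second_parent_prob = second_parent_prob,
              lateral_density = lateral_density,
              causal_per_cluster = as.integer(causal_per_cluster),
              n_patients = as.integer(n_patients),
              visits_range = as.integer(visits_range),
              events_range = as.integer(events_range),
              k_health = as.integer(k_health),
              self_transition = self_transition,
              anomaly_rate = anomaly_rate,
              anomaly_mix = anomaly_mix / sum(anomaly_mix),
              seed = as.integer(seed))
  stop_if(anomaly_rate < 0 || anomaly_rate > 1, "anomaly_rate must be in [0,1]")
  stop_if(self_transition <= 0 || self_transition >= 1,
          "self_transition must be in (0,1)")
  n_layers <- 1L + 1L + 1L + 1L
  stop_if(cfg$n_concepts < 1 + cfg$n_branches + cfg$n_parents + cfg$k_health,
          "infeasible config: hierarchy layers need more concepts than given")
  stop_if(cfg$k_health > ceiling(cfg$n_parents / cfg$n_branches),
          "k_health exceeds the cluster parents available in branch 1")
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic knowledge base
#'
#' Builds the layered is-a DAG (root, branches, parents, leaves; leaves get
#' 1-2 parents), semantic types, lateral relations at the configured
#' density, the structural relation matrix (siblings + ancestry + laterals)
#' and a causal DAG whose edges connect leaves inside each health cluster,
#' oriented by concept index (hence acyclic). The returned knowledge base
#' additionally carries `$clusters` (per health state: parent + leaf
#' members) used by the cohort generator.
#'
#' @param config a [generator_config].
#' @return a [knowledge_base] with the extra `clusters` field.
#' @export
generate_knowledge_base <- function(config) {
  with_seed(substream_seed(config$seed, "kb"), {
    n <- config$n_concepts
    ids <- sprintf("C%03d", seq_len(n))
    root <- ids[1]
    branches <- ids[1 + seq_len(config$n_branches)]
    parents <- ids[1 + config$n_branches + seq_len(config$n_parents)]
    leaves <- ids[(1 + config$n_branches + config$n_parents + 1):n]
    # types: internal nodes are diagnoses (chronic concepts); leaves cycle
    # through all types so every cluster mixes types
    type_levels <- c("diagnosis", "medication", "lab",
                     "procedure")[seq_len(config$n_types)]
    types <- character(n)
    types[match(c(root, branches, parents), ids)] <- type_levels[1]
    types[match(leaves, ids)] <-
      rep(type_levels, length.out = length(leaves))
    vocab <- concept_vocabulary(ids, types)

    child <- character(0); parent <- character(0)
    child <- c(child, branches); parent <- c(parent, rep(root, length(branches)))
    pb <- rep(branches, length.out = length(parents))  # round-robin branches
    child <- c(child, parents); parent <- c(parent, pb)
    lp <- rep(parents, length.out = length(leaves))    # balanced leaf split
    child <- c(child, leaves); parent <- c(parent, lp)
    # optional second parent for a leaf, same branch to keep clusters local
    for (k in seq_along(leaves)) {
      if (stats::runif(1) < config$second_parent_prob) {
        same_branch <- parents[pb == pb[match(lp[k], parents)]]
        alt <- setdiff(same_branch, lp[k])
        if (length(alt) > 0) {
          child <- c(child, leaves[k])
          parent <- c(parent, sample(alt, 1))
        }
      }
    }
    edges <- data.frame(child = child, parent = parent, relation = "is_a",
                        stringsAsFactors = FALSE)
    # lateral relations: random ordered pairs at the configured density
    n_lat <- round(config$lateral_density * n * (n - 1) / 2)
    if (n_lat > 0) {
      pick <- function() sort(sample(n, 2))
      lat <- unique(t(replicate(n_lat, pick())))
      edges <- rbind(edges,
                     data.frame(child = ids[lat[, 1]], parent = ids[lat[, 2]],
                                relation = "associated_with",
                                stringsAsFactors = FALSE))
    }
    ontology <- ontology_graph(vocab, edges)

    # health clusters: the parents of branch 1, each with its leaf children
    branch1_parents <- parents[pb == branches[1]][seq_len(config$k_health)]
    clusters <- lapply(branch1_parents, function(p) {
      list(parent = p, members = leaves[lp == p])
    })
    # spare clusters (other branches) are jump targets
    spare_parents <- setdiff(parents, branch1_parents)
    spare <- lapply(spare_parents, function(p) {
      list(parent = p, members = leaves[lp == p])
    })

    # causal edges inside each health cluster, oriented by concept index;
    # cause and effect children kept disjoint so emission stays feasible
    cause <- character(0); effect <- character(0)
    for (cl in clusters) {
      mem <- cl$members
      if (length(mem) < 4) next
      n_edges <- min(config$causal_per_cluster, floor(length(mem) / 2))
      if (n_edges < 1) next
      picked <- sample(mem, 2 * n_edges)
      for (e in seq_len(n_edges)) {
        pair <- sort(match(picked[c(2 * e - 1, 2 * e)], ids))
        cause <- c(cause, ids[pair[1]]); effect <- c(effect, ids[pair[2]])
      }
    }
    # relation matrix: clinical compatibility is branch-level — all concepts
    # under one branch are pairwise related (so chronic conditions stay
    # plausible anywhere in their service line) — plus ancestry and laterals
    rel_from <- character(0); rel_to <- character(0)
    for (b in branches) {
      sub <- c(b, parents[pb == b], leaves[pb[match(lp, parents)] == b])
      if (length(sub) >= 2) {
        cmb <- utils::combn(sub, 2)
        rel_from <- c(rel_from, cmb[1, ]); rel_to <- c(rel_to, cmb[2, ])
      }
    }
    lat_edges <- edges[edges$relation != "is_a", , drop = FALSE]
    rel_pairs <- data.frame(
      from = c(rel_from, root, lat_edges$child),
      to = c(rel_to, root, lat_edges$parent),
      stringsAsFactors = FALSE)
    rel_pairs <- rel_pairs[rel_pairs$from != rel_pairs$to, ]
    anc <- transitive_closure(vocab, edges[edges$relation == "is_a",
                                           c("child", "parent")])
    anc_idx <- which(anc == 1, arr.ind = TRUE)
    rel_pairs <- rbind(rel_pairs,
                       data.frame(from = ids[anc_idx[, 1]],
                                  to = ids[anc_idx[, 2]],
                                  stringsAsFactors = FALSE))
    kb <- knowledge_base(vocab, ontology,
                         relation_pairs = rel_pairs,
                         causal_pairs = data.frame(cause = cause,
                                                   effect = effect,
                                                   stringsAsFactors = FALSE))
    kb$clusters <- clusters
    kb$spare_clusters <- spare
    kb
  })
}

# Markov transition matrix over health states: diagonally dominant,
# remainder spread uniformly (all clusters sit in one ontology branch, so
# every ordinary switch is a short ontology move).
health_transition_matrix <- function(K, self) {
  P <- matrix((1 - self) / (K - 1), K, K)
  diag(P) <- self
  P
}

#' Generate a clean synthetic cohort
#'
#' Each patient follows a first-order Markov chain over `k_health` hidden
#' states; a state emits a visit's events from its cluster (parent concept
#' plus leaf children, all pairwise related, so the clean cohort has
#' hard-mask rejection fraction 0 by construction). Causal effects are only
#' emitted after their cause has appeared, and causes persist for the rest
#' of the trajectory once emitted (chronic-condition semantics), so causes
#' always precede their effects. Lab concepts get Gaussian values with a
#' state-dependent mean and unit variance.
#'
#' @param kb knowledge base from [generate_knowledge_base()].
#' @param config the same [generator_config].
#' @return list: `cohort` (list of [patient_trajectory]), `hidden_states`
#'   (list of per-patient state paths).
#' @export
generate_cohort <- function(kb, config) {
  with_seed(substream_seed(config$seed, "cohort"), {
    vocab <- kb$vocab
    K <- length(kb$clusters)
    P_trans <- health_transition_matrix(K, config$self_transition)
    C <- kb$causal
    causes_of <- lapply(seq_len(length(vocab)), function(j) which(C[, j] > 0))
    # state-dependent lab means, fixed for the whole cohort
    lab_mu <- matrix(stats::rnorm(K * length(vocab), 0, 2), K, length(vocab))
    cohort <- vector("list", config$n_patients)
    paths <- vector("list", config$n_patients)
    for (pnum in seq_len(config$n_patients)) {
      Tn <- sample(seq(config$visits_range[1], config$visits_range[2]), 1)
      h <- integer(Tn)
      h[1] <- sample(K, 1)
      for (t in 2:Tn) h[t] <- sample(K, 1, prob = P_trans[h[t - 1], ])
      seen <- character(0)          # concepts emitted so far (any visit)
      chronic <- character(0)       # causes that persist once emitted
      states <- vector("list", Tn)
      for (t in seq_len(Tn)) {
        cl <- kb$clusters[[h[t]]]
        n_ev <- sample(seq(config$events_range[1], config$events_range[2]), 1)
        picked <- cl$parent            # the cluster parent anchors every visit
        # an effect may only be emitted once its cause has appeared at a
        # strictly earlier visit
        allowed <- Filter(function(cid) {
          cs <- causes_of[[concept_index(vocab, cid)]]
          length(cs) == 0 || any(vocab$concept_ids[cs] %in% seen)
        }, sample(cl$members))
        picked <- c(picked, utils::head(allowed, n_ev - 1))
        # chronic causes persist
        picked <- unique(c(picked, chronic))
        new_causes <- picked[vapply(picked, function(cid) {
          any(C[concept_index(vocab, cid), ] > 0)
        }, TRUE)]
        chronic <- union(chronic, new_causes)
        seen <- union(seen, picked)
        events <- lapply(picked, function(cid) {
          ci <- concept_index(vocab, cid)
          if (vocab$value_bearing[ci]) {
            list(concept = cid, value = stats::rnorm(1, lab_mu[h[t], ci], 1))
          } else list(concept = cid)
        })
        states[[t]] <- encode_state(events, vocab)
      }
      ctx <- patient_context(age = round(stats::runif(1, 20, 90)),
                             sex = sample(c("F", "M"), 1),
                             comorbidities = stats::rbinom(3, 1, 0.2))
      cohort[[pnum]] <- patient_trajectory(sprintf("P%04d", pnum),
                                           seq_len(Tn), states, ctx)
      paths[[pnum]] <- h
    }
    list(cohort = cohort, hidden_states = paths)
  })
}

#' Plant labelled anomalies into a clean cohort
#'
#' Selects exactly `round(anomaly_rate * n_patients)` patients and gives
#' each exactly one anomaly:
#' `cooccurrence` injects an event with no relation-matrix partner in its
#' visit; `causal` swaps a realized cause/effect pair across visits (the
#' cause is removed from early visits and reappears, supported by a
#' sibling, after its effect); `jump` replaces one visit's events with a
#' cluster at maximal ontology distance from the previous visit's cluster.
#'
#' @param cohort clean cohort list from [generate_cohort()].
#' @param kb the knowledge base (with `clusters`).
#' @param config the [generator_config].
#' @return list: `cohort` (modified), `truth` (data.frame `patient_id`,
#'   `label`, `type`, `t`).
#' @export
plant_anomalies <- function(cohort, kb, config) {
  n_pos <- round(config$anomaly_rate * length(cohort))
  truth <- data.frame(patient_id = vapply(cohort, function(p) p$patient_id, ""),
                      label = 0L, type = NA_character_, t = NA_integer_,
                      stringsAsFactors = FALSE)
  if (n_pos == 0) return(list(cohort = cohort, truth = truth))
  with_seed(substream_seed(config$seed, "anomalies"), {
    mix <- config$anomaly_mix
    counts <- floor(mix * n_pos)
    while (sum(counts) < n_pos) {
      k <- which.max(mix * n_pos - counts)
      counts[k] <- counts[k] + 1
    }
    types <- rep(names(counts), counts)
    victims <- sample(seq_along(cohort), n_pos)
    dist <- hierarchy_distance(kb$vocab, kb$ontology$hierarchy_edges)
    for (k in seq_along(victims)) {
      idx <- victims[k]
      res <- NULL
      for (attempt in 1:100) {
        res <- switch(types[k],
          cooccurrence = plant_cooccurrence(cohort[[idx]], kb),
          causal = plant_causal(cohort[[idx]], kb),
          jump = plant_jump(cohort[[idx]], kb, dist))
        if (!is.null(res)) break
        # resample a victim if this patient offers no injection site
        pool <- setdiff(seq_along(cohort),
                        c(victims[seq_len(k)], which(truth$label == 1)))
        if (length(pool) == 0) break
        idx <- sample(pool, 1)
        victims[k] <- idx
      }
      stop_if(is.null(res), "no valid injection site for anomaly type ",
              types[k], " after 100 attempts")
      cohort[[idx]] <- res$trajectory
      truth$label[idx] <- 1L
      truth$type[idx] <- types[k]
      truth$t[idx] <- res$t
    }
    list(cohort = cohort, truth = truth)
  })
}

plant_cooccurrence <- function(traj, kb) {
  vocab <- kb$vocab
  Tn <- length(traj$timestamps)
  for (t in sample(Tn)) {
    active <- which(traj$states[[t]]$indicator > 0)
    if (length(active) == 0) next
    unrelated <- which(rowSums(kb$relation[, active, drop = FALSE]) == 0)
    unrelated <- setdiff(unrelated, active)
    if (length(unrelated) == 0) next
    inj <- sample(unrelated, 1)
    dec <- decode_state(traj$states[[t]], vocab)
    events <- c(lapply(dec$events, function(e) {
      if (e %in% names(dec$values)) list(concept = e, value = dec$values[[e]])
      else list(concept = e)
    }), list(if (vocab$value_bearing[inj]) {
      list(concept = vocab$concept_ids[inj], value = stats::rnorm(1))
    } else list(concept = vocab$concept_ids[inj])))
    traj$states[[t]] <- encode_state(events, vocab)
    return(list(trajectory = traj, t = t))
  }
  NULL
}

plant_causal <- function(traj, kb) {
  vocab <- kb$vocab
  Tn <- length(traj$timestamps)
  if (Tn < 3) return(NULL)
  C <- kb$causal
  edges <- which(C > 0, arr.ind = TRUE)
  if (nrow(edges) == 0) return(NULL)
  for (e in sample(nrow(edges))) {
    ci <- edges[e, 1]; cj <- edges[e, 2]
    first_j <- first_active_visit(traj, cj)
    if (is.na(first_j) || first_j >= Tn) next
    cause_visits <- which(vapply(traj$states,
                                 function(s) s$indicator[ci] > 0, TRUE))
    if (length(cause_visits) == 0) next
    # removing the cause must not leave any visit with fewer than 2 events
    if (any(vapply(cause_visits, function(t) {
      sum(traj$states[[t]]$indicator) < 3
    }, TRUE))) next
    for (t in cause_visits) {
      traj$states[[t]]$indicator[ci] <- 0
      traj$states[[t]]$values <-
        traj$states[[t]]$values[names(traj$states[[t]]$values) !=
                                  vocab$concept_ids[ci]]
    }
    # reinject the cause after the effect, supported by a related partner
    t_late <- sample(seq(first_j + 1, Tn), 1)
    partners <- which(kb$relation[ci, ] > 0)
    partner <- if (length(partners) > 0) sample(partners, 1) else NULL
    add <- c(ci, partner)
    dec <- decode_state(traj$states[[t_late]], vocab)
    ids <- union(dec$events, vocab$concept_ids[add])
    events <- lapply(ids, function(id) {
      if (id %in% names(dec$values)) list(concept = id, value = dec$values[[id]])
      else if (vocab$value_bearing[concept_index(vocab, id)] &&
               !id %in% dec$events) list(concept = id, value = stats::rnorm(1))
      else list(concept = id)
    })
    traj$states[[t_late]] <- encode_state(events, vocab)
    return(list(trajectory = traj, t = t_late))
  }
  NULL
}

first_active_visit <- function(traj, ci) {
  hits <- which(vapply(traj$states, function(s) s$indicator[ci] > 0, TRUE))
  if (length(hits) == 0) NA_integer_ else hits[1]
}

plant_jump <- function(traj, kb, dist) {
  vocab <- kb$vocab
  Tn <- length(traj$timestamps)
  if (Tn < 3) return(NULL)
  t <- sample(2:(Tn - 1), 1)
  prev_active <- which(traj$states[[t - 1]]$indicator > 0)
  if (length(prev_active) == 0) return(NULL)
  targets <- c(kb$clusters, kb$spare_clusters)
  dvals <- vapply(targets, function(cl) {
    p <- concept_index(vocab, cl$parent)
    mean(dist[p, prev_active])
  }, 0)
  cl <- targets[[which.max(dvals)]]
  n_ev <- min(length(cl$members) + 1, 4)
  picked <- c(cl$parent, sample(cl$members, n_ev - 1))
  events <- lapply(picked, function(id) {
    ci <- concept_index(vocab, id)
    if (vocab$value_bearing[ci]) list(concept = id, value = stats::rnorm(1))
    else list(concept = id)
  })
  traj$states[[t]] <- encode_state(events, vocab)
  list(trajectory = traj, t = t)
}
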
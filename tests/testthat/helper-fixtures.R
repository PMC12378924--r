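# Shared fixtures, built in code.

# tiny 4-concept vocabulary: two diagnoses, one medication, one lab
tiny_vocab <- function() {
  concept_vocabulary(c("dx1", "dx2", "rx1", "lab1"),
                     c("diagnosis", "diagnosis", "medication", "lab"))
}

# chain hierarchy a -> b -> c (c is_a b, b is_a a) over three diagnoses
chain_vocab <- function() {
  concept_vocabulary(c("a", "b", "c"), rep("diagnosis", 3))
}

chain_edges <- function() {
  data.frame(child = c("c", "b"), parent = c("b", "a"),
             relation = "is_a", stringsAsFactors = FALSE)
}

# random DAG adjacency over n nodes (edges respect a random topological
# order), returned as a child->parent edge list over concepts V1..Vn
random_dag_edges <- function(n, p = 0.25) {
  ord <- sample(n)
  from <- integer(0); to <- integer(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) {
      # ord[i] is the ancestor side: edge child ord[j] -> parent ord[i]
      from <- c(from, ord[j]); to <- c(to, ord[i])
    }
  }
  if (length(from) == 0) {
    return(data.frame(child = character(0), parent = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  data.frame(child = paste0("V", from), parent = paste0("V", to),
             relation = "is_a", stringsAsFactors = FALSE)
}

dag_vocab <- function(n) {
  concept_vocabulary(paste0("V", seq_len(n)), rep("diagnosis", n))
}

# exhaustive DFS reachability oracle over child->parent edges:
# anc[i, j] = 1 iff i reachable from j following child->parent upward
reachability_oracle <- function(n, edges) {
  A <- matrix(0, n, n)   # parent row -> child col direct
  if (nrow(edges) > 0) {
    ci <- as.integer(sub("V", "", edges$child))
    pi <- as.integer(sub("V", "", edges$parent))
    A[cbind(pi, ci)] <- 1
  }
  R <- matrix(0, n, n)
  for (s in seq_len(n)) {
    stack <- which(A[s, ] > 0)
    seen <- logical(n)
    while (length(stack) > 0) {
      v <- stack[1]; stack <- stack[-1]
      if (seen[v]) next
      seen[v] <- TRUE
      R[s, v] <- 1
      stack <- c(stack, which(A[v, ] > 0))
    }
  }
  R
}

# symmetric random adjacency with zero diagonal
random_adjacency <- function(n, p = 0.3) {
  A <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p) { A[i, j] <- 1; A[j, i] <- 1 }
  }
  A
}

# small generated knowledge base + clean cohort, shared by pipeline tests
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- generator_config(n_patients = 40L, seed = 11L)
      kb <- generate_knowledge_base(cfg)
      gen <- generate_cohort(kb, cfg)
      cache <<- list(cfg = cfg, kb = kb, cohort = gen$cohort)
    }
    cache
  }
})

# a tiny fitted model on the small world (cached across tests)
small_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world()
      pcfg <- desk_pipeline_config(seed = 11L)
      pcfg$epochs <- 60L
      cache <<- kg_train(w$cohort, w$kb, pcfg, seed = 11L)
    }
    cache
  }
})
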
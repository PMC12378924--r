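# Readers and writers for the on-disk formats: concept/ontology/causal TSVs,
# cohort JSONL, embedding TSVs, MatrixMarket matrices, config snapshots.

#' Write a knowledge base to a directory
#'
#' Emits `concepts.tsv` (`concept_id  name  semantic_type  value_bearing`),
#' `ontology.tsv` (`child  parent  relation`), `causal.tsv`
#' (`cause  effect`) and the relation matrix as MatrixMarket
#' (`relation.mtx`).
#'
#' @param kb a [knowledge_base].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_knowledge_base <- function(kb, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- kb$vocab
  utils::write.table(
    data.frame(concept_id = v$concept_ids, name = v$names,
               semantic_type = v$semantic_type,
               value_bearing = as.integer(v$value_bearing)),
    file.path(dir, "concepts.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  he <- kb$ontology$hierarchy_edges
  le <- kb$ontology$lateral_edges
  ont <- rbind(
    if (nrow(he) > 0) data.frame(child = he$child, parent = he$parent,
                                 relation = "is_a") else NULL,
    if (nrow(le) > 0) data.frame(child = le$child, parent = le$parent,
                                 relation = le$relation) else NULL)
  if (is.null(ont)) ont <- data.frame(child = character(0),
                                      parent = character(0),
                                      relation = character(0))
  utils::write.table(ont, file.path(dir, "ontology.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ce <- which(kb$causal > 0, arr.ind = TRUE)
  utils::write.table(
    data.frame(cause = v$concept_ids[ce[, 1]],
               effect = v$concept_ids[ce[, 2]]),
    file.path(dir, "causal.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(kb$relation, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "relation.mtx"))
  invisible(dir)
}

#' Read a knowledge base from a directory
#'
#' Inverse of [write_knowledge_base()]. Unknown relation labels load as
#' lateral relations; a dangling concept id or malformed line is rejected
#' with its location.
#'
#' @param dir directory holding the TSV/MatrixMarket files.
#' @return a [knowledge_base].
#' @export
read_knowledge_base <- function(dir) {
  cf <- file.path(dir, "concepts.tsv")
  stop_if(!file.exists(cf), "missing concepts.tsv under ", dir)
  cv <- utils::read.table(cf, sep = "\t", header = TRUE,
                          colClasses = "character")
  stop_if(!all(c("concept_id", "semantic_type",
                 "value_bearing") %in% names(cv)),
          "concepts.tsv lacks required columns")
  vocab <- concept_vocabulary(cv$concept_id, cv$semantic_type,
                              as.integer(cv$value_bearing) == 1,
                              names = cv$name %||% cv$concept_id)
  ont <- utils::read.table(file.path(dir, "ontology.tsv"), sep = "\t",
                           header = TRUE, colClasses = "character")
  ontology <- ontology_graph(vocab, ont)
  caus <- utils::read.table(file.path(dir, "causal.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
  rel_path <- file.path(dir, "relation.mtx")
  rel_pairs <- NULL
  if (file.exists(rel_path)) {
    R <- as.matrix(Matrix::readMM(rel_path))
    idx <- which(R > 0 & upper.tri(R), arr.ind = TRUE)
    rel_pairs <- data.frame(from = vocab$concept_ids[idx[, 1]],
                            to = vocab$concept_ids[idx[, 2]],
                            stringsAsFactors = FALSE)
  }
  knowledge_base(vocab, ontology, relation_pairs = rel_pairs,
                 causal_pairs = caus)
}

#' Write a cohort as JSONL
#'
#' One patient per line:
#' `{"patient_id", "context": {"age","sex","comorbidities"},
#'   "visits": [{"time", "events": [{"concept", "value"?}]}]}`.
#'
#' @param cohort list of [patient_trajectory].
#' @param path output file.
#' @param vocab the [concept_vocabulary].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, vocab) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in cohort) {
    visits <- lapply(seq_along(p$timestamps), function(t) {
      dec <- decode_state(p$states[[t]], vocab)
      events <- lapply(dec$events, function(id) {
        if (id %in% names(dec$values)) {
          list(concept = id, value = dec$values[[id]])
        } else list(concept = id)
      })
      list(time = p$timestamps[t], events = events)
    })
    rec <- list(patient_id = p$patient_id,
                context = list(age = p$context$age, sex = p$context$sex,
                               comorbidities = p$context$comorbidities),
                visits = visits)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read a cohort from JSONL
#'
#' Inverse of [write_cohort()]. Non-increasing timestamps or a value on a
#' non-value-bearing concept are rejected naming the patient.
#'
#' @param path JSONL file.
#' @param vocab the [concept_vocabulary].
#' @return list of [patient_trajectory].
#' @export
read_cohort <- function(path, vocab) {
  lines <- readLines(path)
  lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    states <- lapply(rec$visits, function(v) {
      encode_state(v$events, vocab)
    })
    times <- vapply(rec$visits, function(v) as.numeric(v$time), 0)
    ctx <- patient_context(rec$context$age %||% 0,
                           rec$context$sex %||% "unknown",
                           unlist(rec$context$comorbidities) %||% integer(0))
    patient_trajectory(rec$patient_id, times, states, ctx)
  })
}

#' Write/read an embedding table as TSV
#'
#' `concept_id` followed by the embedding coordinates, one concept per row.
#'
#' @param table an `embedding_table` (or plain matrix with rownames).
#' @param path file path.
#' @return `path` invisibly / an `embedding_table`.
#' @export
write_embeddings <- function(table, path) {
  M <- if (inherits(table, "embedding_table")) table$matrix else table
  df <- data.frame(concept_id = rownames(M), M, check.names = FALSE)
  names(df) <- c("concept_id", paste0("d", seq_len(ncol(M))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  M <- as.matrix(df[, -1, drop = FALSE])
  dimnames(M) <- list(df$concept_id, NULL)
  structure(list(matrix = M, layer = 0L), class = "embedding_table")
}

#' Write ground-truth labels / anomaly scores as TSV
#'
#' @param x data.frame (`truth` from [plant_anomalies()] or a
#'   `kg_anomaly_report`).
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a configuration snapshot as JSON
#'
#' @param config any nested configuration list.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config_snapshot <- function(config, path) {
  jsonlite::write_json(drop_closures(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  invisible(path)
}

drop_closures <- function(x) {
  if (is.function(x)) return(NULL)
  if (is.list(x)) {
    x <- lapply(x, drop_closures)
    x[!vapply(x, is.null, TRUE)]
  } else x
}
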
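# Internal numerical helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax <- function(x) {
  if (any(!is.finite(x))) stop("softmax: non-finite logits")
  e <- exp(x - max(x))
  e / sum(e)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

# Named RNG substream: deterministic per (seed, label) so components are
# independently reproducible from one master seed.
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 1000003L + as.integer(h %% 1000003L)) %% 2147483647L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Xavier-uniform initializer: U(-sqrt(6/(fan_in+fan_out)), +).
xavier_matrix <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

as_dense <- function(m) {
  if (inherits(m, "Matrix")) as.matrix(m) else m
}

check_square <- function(m, n = NULL, what = "matrix") {
  stop_if(nrow(m) != ncol(m), what, " must be square")
  if (!is.null(n)) stop_if(nrow(m) != n, what, " has wrong dimension: ",
                           nrow(m), " vs expected ", n)
  invisible(m)
}
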
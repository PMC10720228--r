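#' @keywords internal
"_PACKAGE"

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so seeded helpers do not perturb the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage substreams derived from one base seed.
# Offsets keep the derived seed inside the 32-bit integer range.
substream_seed <- function(seed, stream) {
  offsets <- c(simulation = 1e5L, null_calibration = 2e5L, kmeans = 3e5L,
               covariates = 4e5L, states = 5e5L)
  if (!stream %in% names(offsets)) stop("unknown RNG substream: ", stream)
  (as.integer(seed) + offsets[[stream]]) %% .Machine$integer.max
}

#' Canonical edge ordering for a symmetric matrix
#'
#' Enumerates the upper triangle of a `p` x `p` symmetric matrix in row-major
#' order: (1,2), (1,3), ..., (1,p), (2,3), ... This ordering is used for every
#' edge vector in the package so that matrices, edge tables and clustering
#' inputs all agree.
#'
#' @param p Number of nodes (parcels or networks).
#' @return A data frame with integer columns `i` and `j` (`i < j`),
#'   one row per edge, `p*(p-1)/2` rows in total.
#' @export
edge_index_table <- function(p) {
  stopifnot(p >= 2)
  i <- rep.int(seq_len(p - 1L), times = (p - 1L):1L)
  j <- unlist(lapply(seq_len(p - 1L), function(k) (k + 1L):p), use.names = FALSE)
  data.frame(i = i, j = j)
}

# Vectorize the upper triangle of `m` in canonical edge order.
vectorize_edges <- function(m, idx = edge_index_table(nrow(m))) {
  m[cbind(idx$i, idx$j)]
}

# Rebuild a symmetric matrix (diagonal `diag_value`) from a canonical
# edge vector.
edges_to_matrix <- function(values, p, diag_value = NA_real_) {
  idx <- edge_index_table(p)
  stopifnot(length(values) == nrow(idx))
  m <- matrix(diag_value, p, p)
  m[cbind(idx$i, idx$j)] <- values
  m[cbind(idx$j, idx$i)] <- values
  m
}

# Clip correlations away from +/-1 so atanh stays finite.
clip_correlation <- function(r, eps = 1e-7) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}
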
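# Static functional connectivity: network partitions, Fisher-z Pearson
# correlation matrices, network-concatenated series, and deterministic edge
# vectorization.

#' Network partition from an atlas lookup table
#'
#' Validates and freezes an atlas lookup mapping parcels to network labels.
#' Parcel order and network order are fixed at construction and carried
#' through every downstream edge ordering.
#'
#' @param lookup Data frame with columns `parcel_id`, `parcel_name`,
#'   `network_label` and optionally `size` (e.g. voxels per parcel, used for
#'   size-weighted network series).
#' @return Object of class `network_partition`: the lookup plus `networks`
#'   (unique labels in first-appearance order) and `membership` (integer
#'   network index per parcel).
#' @export
network_partition <- function(lookup) {
  need <- c("parcel_id", "parcel_name", "network_label")
  missing_cols <- setdiff(need, names(lookup))
  if (length(missing_cols))
    stop("atlas lookup lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(lookup$parcel_id))
    stop("duplicated parcel_id in atlas lookup")
  networks <- unique(as.character(lookup$network_label))
  structure(list(lookup = lookup, networks = networks,
                 membership = match(as.character(lookup$network_label),
                                    networks)),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat(sprintf("Network partition: %d parcels in %d networks\n",
              nrow(x$lookup), length(x$networks)))
  print(table(factor(x$lookup$network_label, levels = x$networks)))
  invisible(x)
}

#' Fisher z-transformed Pearson connectivity matrix
#'
#' Pairwise Pearson correlation of parcel time series, mapped through the
#' inverse hyperbolic tangent (Fisher z). Correlations are clipped to
#' `+/-(1 - 1e-7)` before the transform so that duplicated or perfectly
#' anti-correlated parcels stay finite.
#'
#' @param timeseries T x P matrix (T >= 3).
#' @return P x P symmetric matrix of z values, diagonal `NA` (self-
#'   connectivity is undefined).
#' @export
static_fc <- function(timeseries) {
  x <- as.matrix(timeseries)
  if (nrow(x) < 3) stop("need at least 3 time points for correlation")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(x)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance parcel(s): ", paste(bad, collapse = ", "))
  }
  z <- atanh(clip_correlation(stats::cor(x)))
  diag(z) <- NA_real_
  z
}

#' Network-concatenated time series
#'
#' One series per network, the (optionally size-weighted) mean of its
#' constituent parcel series — the parcel-level analogue of extracting a
#' single concatenated mask per network before correlation.
#'
#' @param timeseries T x P matrix in the partition's parcel order.
#' @param partition A [network_partition()].
#' @param weights Optional per-parcel weights (e.g. parcel sizes); default
#'   unweighted mean.
#' @return T x N matrix (N networks), columns named by network label.
#' @export
network_timeseries <- function(timeseries, partition, weights = NULL) {
  x <- as.matrix(timeseries)
  stopifnot(inherits(partition, "network_partition"),
            ncol(x) == nrow(partition$lookup))
  if (is.null(weights)) weights <- rep(1, ncol(x))
  stopifnot(length(weights) == ncol(x), all(weights > 0))
  out <- sapply(seq_along(partition$networks), function(k) {
    cols <- which(partition$membership == k)
    if (!length(cols)) stop("empty network: ", partition$networks[k])
    w <- weights[cols] / sum(weights[cols])
    x[, cols, drop = FALSE] %*% w
  })
  colnames(out) <- partition$networks
  out
}

#' Vectorize a connectivity matrix at a given scope
#'
#' Deterministic row-major upper-triangle ordering in atlas order. Scopes:
#' `"global"` (all parcel pairs), `"within:<network>"` (pairs inside one
#' network), and `"between_networks"` (for a network-by-network matrix, all
#' network pairs — 45 for 10 networks).
#'
#' @param matrix Symmetric connectivity matrix (parcel- or network-level).
#' @param partition A [network_partition()]; not needed for
#'   `"between_networks"` on a network-level matrix.
#' @param scope Scope string.
#' @return Data frame `i`, `j`, `scope`, `z` in canonical order.
#' @export
edge_vector <- function(matrix, partition = NULL, scope = "global") {
  p <- nrow(matrix)
  if (scope == "global" || scope == "between_networks") {
    idx <- edge_index_table(p)
  } else if (startsWith(scope, "within:")) {
    stopifnot(inherits(partition, "network_partition"))
    net <- sub("^within:", "", scope)
    k <- match(net, partition$networks)
    if (is.na(k)) stop("unknown network in scope: ", net)
    parcels <- which(partition$membership == k)
    if (length(parcels) < 2) stop("network ", net, " has fewer than 2 parcels")
    idx <- edge_index_table(length(parcels))
    idx <- data.frame(i = parcels[idx$i], j = parcels[idx$j])
  } else {
    stop("unknown scope: ", scope)
  }
  data.frame(i = idx$i, j = idx$j, scope = scope,
             z = matrix[cbind(idx$i, idx$j)])
}

# Edge -> network pair bookkeeping for a parcel-level edge set: returns, for
# each canonical global edge, the network index of each endpoint.
edge_networks <- function(partition) {
  p <- nrow(partition$lookup)
  idx <- edge_index_table(p)
  data.frame(i = idx$i, j = idx$j,
             net_i = partition$membership[idx$i],
             net_j = partition$membership[idx$j])
}
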
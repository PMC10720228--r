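# Three-level inference: (1) global HC over all parcel-pair p-values,
# (2) HC within each network and over the between-network connections,
# (3) BH-FDR on individual connections at global, between-network and
# within-network scopes.

#' Benjamini-Hochberg FDR adjustment with discovery flags
#'
#' Step-up adjusted p-values (monotone, capped at 1) via
#' `stats::p.adjust(method = "BH")`; an edge is a discovery when its
#' adjusted value is at most `q`.
#'
#' @param pvalues P-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Data frame `p`, `p_adjusted`, `discovered`.
#' @export
fdr_adjust <- function(pvalues, q = 0.05) {
  stopifnot(q > 0, q < 1)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adjusted = adj, discovered = adj <= q)
}

#' Run the full three-level hierarchical analysis
#'
#' Level 1: Higher Criticism omnibus test on the group p-values of all
#' parcel-pair connections. Level 2: one HC test per network on its
#' within-network connections, plus one HC test on the network-level
#' (concatenated-series) connections. Level 3: BH-FDR on individual
#' connections, run unconditionally across all connections, across the
#' between-network connections, and within each network separately.
#'
#' @param edge_table Parcel-level [fit_all_edges()] output in canonical
#'   global edge order (needs `i`, `j`, `p_group`, `partial_eta2`,
#'   `group_mean_diff_z`).
#' @param network_edge_table Network-level edge table for the
#'   concatenated-series analysis (45 edges for 10 networks).
#' @param partition The [network_partition()] the edges were built under.
#' @param alpha HC test level (default 0.05).
#' @param q FDR level (default 0.05).
#' @param variant,alpha0 HC variant parameters (see [hc_statistic()]).
#' @param n_null_replicates Monte-Carlo null size per distinct p-value count
#'   (default 2000).
#' @param seed Seed for the null calibration substream.
#' @param null_cache Optional environment reusing null distributions across
#'   cohorts (keyed by p-value count); useful in replicate studies.
#' @return Object of class `hierarchy_report`.
#' @export
run_hierarchy <- function(edge_table, network_edge_table, partition,
                          alpha = 0.05, q = 0.05,
                          variant = c("hc_plus", "hc2004"), alpha0 = 0.5,
                          n_null_replicates = 2000, seed = 1L,
                          null_cache = NULL) {
  variant <- match.arg(variant)
  stopifnot(inherits(partition, "network_partition"))
  p <- nrow(partition$lookup)
  n_net <- length(partition$networks)
  if (nrow(edge_table) != p * (p - 1) / 2)
    stop("edge table does not cover all global parcel-pair edges")
  if (nrow(network_edge_table) != n_net * (n_net - 1) / 2)
    stop("network edge table does not cover all network-pair edges")
  if (is.null(null_cache)) null_cache <- new.env(parent = emptyenv())
  get_null <- function(n) {
    key <- sprintf("%s_%g_%d", variant, alpha0, n)
    if (is.null(null_cache[[key]]))
      null_cache[[key]] <- hc_null_distribution(
        n, variant = variant, alpha0 = alpha0,
        n_replicates = n_null_replicates,
        seed = substream_seed(seed, "null_calibration"))
    null_cache[[key]]
  }

  nets <- edge_networks(partition)
  within_idx <- lapply(seq_len(n_net), function(k)
    which(nets$net_i == k & nets$net_j == k))
  names(within_idx) <- partition$networks

  global_hc <- hc_test(edge_table$p_group, get_null(nrow(edge_table)),
                       alpha = alpha)
  within_hc <- lapply(within_idx, function(rows)
    hc_test(edge_table$p_group[rows], get_null(length(rows)), alpha = alpha))
  between_hc <- hc_test(network_edge_table$p_group,
                        get_null(nrow(network_edge_table)), alpha = alpha)

  fdr_global <- cbind(edge_table[c("i", "j")],
                      fdr_adjust(edge_table$p_group, q))
  fdr_between <- cbind(network_edge_table[c("i", "j")],
                       fdr_adjust(network_edge_table$p_group, q))
  fdr_within <- lapply(within_idx, function(rows)
    cbind(edge_table[rows, c("i", "j")],
          fdr_adjust(edge_table$p_group[rows], q)))

  structure(list(global = global_hc, within_network = within_hc,
                 between_network = between_hc,
                 fdr_global = fdr_global, fdr_between = fdr_between,
                 fdr_within = fdr_within,
                 edge_table = edge_table,
                 network_edge_table = network_edge_table,
                 partition = partition,
                 params = list(alpha = alpha, q = q, variant = variant,
                               alpha0 = alpha0,
                               n_null_replicates = n_null_replicates,
                               seed = seed)),
            class = "hierarchy_report")
}

#' @export
print.hierarchy_report <- function(x, ...) {
  cat("Hierarchical connectome group-difference analysis\n")
  cat(sprintf("  Level 1  global HC = %.2f (empirical p = %.4g)%s\n",
              x$global$hc_value, x$global$empirical_p,
              if (x$global$reject) " *" else ""))
  cat("  Level 2  within-network HC:\n")
  for (nm in names(x$within_network)) {
    h <- x$within_network[[nm]]
    cat(sprintf("    %-14s HC = %6.2f (p = %.4g)%s\n", nm, h$hc_value,
                h$empirical_p, if (h$reject) " *" else ""))
  }
  cat(sprintf("  Level 2  between-network HC = %.2f (p = %.4g)%s\n",
              x$between_network$hc_value, x$between_network$empirical_p,
              if (x$between_network$reject) " *" else ""))
  n_within <- sum(vapply(x$fdr_within, function(d) sum(d$discovered), 0))
  cat(sprintf(paste0("  Level 3  FDR discoveries: %d global, %d ",
                     "between-network, %d within-network\n"),
              sum(x$fdr_global$discovered), sum(x$fdr_between$discovered),
              n_within))
  invisible(x)
}

#' Write a hierarchy report to disk
#'
#' Emits a machine-readable JSON summary (HC values, empirical p-values,
#' histogram counts, discovery counts) and CSV tables: the full edge table,
#' the unthresholded group-difference and partial eta^2 matrices in canonical
#' atlas order, and the FDR tables per scope.
#'
#' @param report A [run_hierarchy()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
report_hierarchy <- function(report, dir) {
  stopifnot(inherits(report, "hierarchy_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- nrow(report$partition$lookup)
  hc_summary <- function(h)
    list(hc_value = h$hc_value, empirical_p = h$empirical_p,
         reject = h$reject, n_pvalues = h$n_pvalues,
         histogram_counts = h$histogram$counts)
  summary <- list(
    params = report$params,
    global = hc_summary(report$global),
    within_network = lapply(report$within_network, hc_summary),
    between_network = hc_summary(report$between_network),
    fdr_discoveries = list(
      global = sum(report$fdr_global$discovered),
      between_network = sum(report$fdr_between$discovered),
      within_network = lapply(report$fdr_within,
                              function(d) sum(d$discovered))))
  paths <- c(summary = file.path(dir, "hierarchy_summary.json"))
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_matrix_csv <- function(values, file) {
    m <- edges_to_matrix(values, p)
    df <- as.data.frame(m)
    names(df) <- report$partition$lookup$parcel_name
    utils::write.csv(cbind(parcel = report$partition$lookup$parcel_name, df),
                     file, row.names = FALSE)
    file
  }
  paths["edge_table"] <- file.path(dir, "edge_table.csv")
  utils::write.csv(report$edge_table, paths["edge_table"], row.names = FALSE)
  paths["diff_matrix"] <- write_matrix_csv(
    report$edge_table$group_mean_diff_z, file.path(dir, "group_diff_z.csv"))
  paths["eta2_matrix"] <- write_matrix_csv(
    report$edge_table$partial_eta2, file.path(dir, "partial_eta2.csv"))
  paths["fdr_global"] <- file.path(dir, "fdr_global.csv")
  utils::write.csv(report$fdr_global, paths["fdr_global"], row.names = FALSE)
  paths["fdr_between"] <- file.path(dir, "fdr_between.csv")
  utils::write.csv(report$fdr_between, paths["fdr_between"], row.names = FALSE)
  invisible(paths)
}
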
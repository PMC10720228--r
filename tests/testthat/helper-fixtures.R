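# Small in-code fixtures shared across test files.

tiny_cohort <- function(seed = 7, n1 = 6, n2 = 6, sizes = c(4, 4, 4),
                        n_t = 120, ...) {
  simulate_cohort(sim_config(n_group1 = n1, n_group2 = n2,
                             network_sizes = sizes, n_timepoints = n_t,
                             seed = seed, ...))
}

# Manifest where each case subject mirrors a control subject's covariates.
paired_manifest <- function(n_per_group = 8) {
  covs <- data.frame(sex = rep(c("F", "M"), length.out = n_per_group),
                     age = seq(18, 30, length.out = n_per_group),
                     mean_fd = rep(c(0.08, 0.25, 0.12, 0.3, 0.05),
                                   length.out = n_per_group))
  data.frame(subject_id = sprintf("s%02d", seq_len(2 * n_per_group)),
             group = rep(c("control", "case"), each = n_per_group),
             rbind(covs, covs))
}

# Hand-built edge table (only the columns run_hierarchy() consumes).
crafted_edge_table <- function(pvalues, p) {
  idx <- edge_index_table(p)
  stopifnot(length(pvalues) == nrow(idx))
  data.frame(i = idx$i, j = idx$j, p_group = pvalues,
             partial_eta2 = 0.01, group_mean_diff_z = 0,
             t_group = 0, beta_group = 0, df = 10, flagged = FALSE)
}

equal_partition <- function(n_networks, parcels_each) {
  network_partition(data.frame(
    parcel_id = seq_len(n_networks * parcels_each),
    parcel_name = sprintf("p%03d", seq_len(n_networks * parcels_each)),
    network_label = rep(paste0("net", seq_len(n_networks)),
                        each = parcels_each)))
}
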
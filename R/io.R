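# Cohort I/O and end-to-end pipelines tying simulation -> denoising ->
# connectome -> hierarchical testing -> dynamic states. Formats are plain
# text: CSV manifest/atlas, per-subject tab-separated time-series and
# confound tables, JSON config echo.

#' Write a cohort to disk
#'
#' Layout: `manifest.csv`, `atlas.csv`, `config.json` (full parameter echo
#' for bit-for-bit reproduction), `timeseries/<subject>.tsv` and
#' `confounds/<subject>.tsv` (tab-separated, one row per volume, named
#' columns).
#'
#' @param cohort An `fc_cohort` from [simulate_cohort()] (or the same
#'   structure loaded from disk).
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "confounds"), showWarnings = FALSE)
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$partition$lookup, file.path(dir, "atlas.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$config))
    jsonlite::write_json(unclass(cohort$config),
                         file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (id in cohort$manifest$subject_id) {
    utils::write.table(cohort$timeseries[[id]],
                       file.path(dir, "timeseries", paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cohort$confounds[[id]],
                       file.path(dir, "confounds", paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a cohort from disk
#'
#' Reads the manifest, atlas lookup, per-subject time series and confounds
#' written by [write_cohort()] (or prepared externally in the same layout).
#' Parcel order and count are validated against the atlas for every subject;
#' subjects with missing files are dropped with a warning (or raise an error
#' with `drop_missing = FALSE`).
#'
#' @param dir Cohort directory.
#' @param drop_missing Drop subjects whose files are absent? Default TRUE.
#' @return An `fc_cohort`.
#' @export
load_cohort <- function(dir, drop_missing = TRUE) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  need <- c("subject_id", "group", "sex", "age", "mean_fd")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) stop("manifest lacks column(s): ",
                         paste(miss, collapse = ", "))
  manifest$group <- factor(manifest$group)
  if (nlevels(manifest$group) != 2)
    stop("manifest group column must have exactly 2 levels, got: ",
         paste(levels(manifest$group), collapse = ", "))
  partition <- network_partition(utils::read.csv(file.path(dir, "atlas.csv")))
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path))
    jsonlite::read_json(cfg_path, simplifyVector = TRUE) else NULL

  present <- vapply(manifest$subject_id, function(id)
    file.exists(file.path(dir, "timeseries", paste0(id, ".tsv"))) &&
      file.exists(file.path(dir, "confounds", paste0(id, ".tsv"))),
    logical(1))
  if (any(!present)) {
    msg <- paste("missing files for subject(s):",
                 paste(manifest$subject_id[!present], collapse = ", "))
    if (!drop_missing) stop(msg)
    warning(msg, "; dropped")
    manifest <- manifest[present, , drop = FALSE]
  }
  read_tsv <- function(path) as.matrix(utils::read.delim(path, check.names = FALSE))
  timeseries <- list(); confounds <- list()
  for (id in manifest$subject_id) {
    ts <- read_tsv(file.path(dir, "timeseries", paste0(id, ".tsv")))
    if (ncol(ts) != nrow(partition$lookup))
      stop("subject ", id, " has ", ncol(ts), " parcels; atlas defines ",
           nrow(partition$lookup))
    if (!identical(colnames(ts), as.character(partition$lookup$parcel_name)))
      stop("subject ", id, ": time-series columns do not match atlas ",
           "parcel_name order")
    cf <- read_tsv(file.path(dir, "confounds", paste0(id, ".tsv")))
    cf_need <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z",
                 "wm", "csf")
    cf_miss <- setdiff(cf_need, colnames(cf))
    if (length(cf_miss))
      stop("subject ", id, " confounds lack column(s): ",
           paste(cf_miss, collapse = ", "))
    timeseries[[id]] <- ts
    confounds[[id]] <- cf[, cf_need, drop = FALSE]
  }
  structure(list(manifest = manifest, timeseries = timeseries,
                 confounds = confounds, partition = partition,
                 config = config),
            class = "fc_cohort")
}

# Denoise every subject and apply motion exclusion; returns the reduced
# cohort plus the decisions.
preprocess_cohort <- function(cohort, tr_seconds = NULL, ...) {
  if (is.null(tr_seconds)) tr_seconds <- cohort$config$tr_seconds
  if (is.null(tr_seconds)) stop("tr_seconds not given and absent from config")
  # exclusion first: high-motion subjects never enter the regression stage
  decisions <- lapply(cohort$manifest$subject_id, function(id)
    motion_exclusion(
      framewise_displacement(cohort$confounds[[id]][, 1:6, drop = FALSE]),
      subject_id = id))
  names(decisions) <- cohort$manifest$subject_id
  excluded <- vapply(decisions, `[[`, logical(1), "excluded")
  keep <- cohort$manifest$subject_id[!excluded]
  cohort$manifest <- cohort$manifest[!excluded, , drop = FALSE]
  cohort$timeseries <- cohort$timeseries[keep]
  cohort$confounds <- cohort$confounds[keep]
  for (id in keep) {
    cf <- cohort$confounds[[id]]
    den <- denoise_subject(cohort$timeseries[[id]],
                           motion = cf[, 1:6, drop = FALSE],
                           tissue_signals = cf[, 7:8, drop = FALSE],
                           tr_seconds = tr_seconds, ...)
    cohort$timeseries[[id]] <- den$series
  }
  cohort$exclusions <- decisions
  cohort
}

#' Static hierarchical analysis of a cohort
#'
#' Optionally denoises each subject's series (confound + spike regression,
#' band-pass) and applies motion exclusion, computes Fisher-z connectivity
#' at parcel and network-concatenated level, fits the per-edge group models
#' with sex/age/mean-FD covariates, and runs the three-level HC/FDR
#' hierarchy.
#'
#' @param cohort An `fc_cohort`.
#' @param denoise Run the denoising/exclusion stage first? Default TRUE
#'   (use FALSE for series that are already clean).
#' @param covariates Include sex/age/FD covariates in the edge models?
#' @param ... Passed to [run_hierarchy()] (alpha, q, variant,
#'   n_null_replicates, seed, null_cache, ...).
#' @return A `hierarchy_report` (see [run_hierarchy()]); the analyzed
#'   cohort is attached as attribute `cohort`.
#' @export
run_static_pipeline <- function(cohort, denoise = TRUE, covariates = TRUE,
                                ...) {
  if (denoise) cohort <- preprocess_cohort(cohort)
  design <- build_design(cohort$manifest, covariates = covariates)
  p <- nrow(cohort$partition$lookup)
  fc <- lapply(cohort$timeseries, static_fc)
  edge_table <- fit_all_edges(stack_edges(fc), design,
                              edge_index = edge_index_table(p))
  net_fc <- lapply(cohort$timeseries, function(ts)
    static_fc(network_timeseries(ts, cohort$partition)))
  n_net <- length(cohort$partition$networks)
  net_table <- fit_all_edges(stack_edges(net_fc), design,
                             edge_index = edge_index_table(n_net))
  report <- run_hierarchy(edge_table, net_table, cohort$partition, ...)
  attr(report, "cohort") <- cohort
  report
}

#' Dynamic FC state analysis of a cohort
#'
#' Computes sliding-window FC for every subject, pools all windows, estimates
#' recurring states by k-means with correlation distance (cluster count
#' selected over `k_range`), derives per-subject NT/MDT/FRC metrics, and
#' compares them between groups.
#'
#' @param cohort An `fc_cohort`.
#' @param spec A [window_spec()]; the TR defaults to the cohort config's.
#' @param k_range Candidate state counts (default 2:10).
#' @param denoise Denoise first? Default FALSE (the static pipeline usually
#'   ran already; set TRUE for raw input).
#' @param seed Seed for the clustering substream.
#' @param ... Passed to [cluster_states()].
#' @return List of class `dynamic_report`: `model` (a `state_model`),
#'   `windows`, `metrics` (per subject), `comparison` (group tests).
#' @export
run_dynamic_pipeline <- function(cohort, spec = NULL, k_range = 2:10,
                                 denoise = FALSE, seed = 1L, ...) {
  if (denoise) cohort <- preprocess_cohort(cohort)
  if (is.null(spec)) {
    tr <- cohort$config$tr_seconds
    spec <- if (is.null(tr)) window_spec() else window_spec(tr_seconds = tr)
  }
  n_t <- nrow(cohort$timeseries[[1]])
  windows <- make_windows(n_t, spec)
  wfc <- lapply(cohort$timeseries, windowed_fc, windows = windows)
  pooled <- do.call(rbind, wfc)
  subject <- rep(cohort$manifest$subject_id,
                 each = nrow(windows))
  model <- cluster_states(pooled, subject, k_range = k_range, seed = seed, ...)
  metrics <- subject_state_metrics(model)
  metrics <- metrics[match(cohort$manifest$subject_id, metrics$subject_id), ]
  comparison <- compare_state_dynamics(
    metrics, cohort$manifest$group[match(metrics$subject_id,
                                         cohort$manifest$subject_id)])
  structure(list(model = model, windows = windows, spec = spec,
                 metrics = metrics, comparison = comparison),
            class = "dynamic_report")
}

#' @export
print.dynamic_report <- function(x, ...) {
  print(x$model)
  cat(sprintf("  windows per subject: %d (length %d volumes, step %d)\n",
              nrow(x$windows), x$spec$length_volumes, x$spec$step_volumes))
  cat("  group comparison:\n")
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

#' Full pipeline: static hierarchy plus dynamic states
#'
#' @param cohort An `fc_cohort`.
#' @param denoise Denoise (once) before both analyses? Default TRUE.
#' @param seed Base seed for null calibration and clustering substreams.
#' @param static_args,dynamic_args Extra arguments for
#'   [run_static_pipeline()] / [run_dynamic_pipeline()].
#' @return List with `static` (a `hierarchy_report`) and `dynamic`
#'   (a `dynamic_report`).
#' @export
run_full_pipeline <- function(cohort, denoise = TRUE, seed = 1L,
                              static_args = list(), dynamic_args = list()) {
  if (denoise) cohort <- preprocess_cohort(cohort)
  static <- do.call(run_static_pipeline,
                    c(list(cohort = cohort, denoise = FALSE, seed = seed),
                      static_args))
  dynamic <- do.call(run_dynamic_pipeline,
                     c(list(cohort = cohort, denoise = FALSE, seed = seed),
                       dynamic_args))
  list(static = static, dynamic = dynamic)
}
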
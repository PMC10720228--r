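# Synthetic cohort generator: parcel time series with block-structured
# network covariance, planted rare-weak group effects on the correlation
# scale, covariate effects on Fisher-z edges, and an optional hidden
# Markov-switching covariance process for the dynamic-state analysis.

#' Simulation configuration for a synthetic rs-fMRI cohort
#'
#' Captures every parameter of the synthetic-cohort generator. Defaults
#' mirror the study design the package targets: two groups of 39 and 44
#' subjects, 234 volumes at a repetition time of 2.5 s, and 243 cortical
#' parcels assigned to 10 cognition-related networks.
#'
#' @param n_group1,n_group2 Subjects per group (group 1 = control,
#'   group 2 = case; the case group carries the planted effect).
#' @param network_sizes Integer vector of parcels per network (all >= 2);
#'   its sum defines the number of parcels.
#' @param n_timepoints Number of volumes per subject.
#' @param tr_seconds Repetition time in seconds.
#' @param within_network_corr,between_network_corr Baseline correlation for
#'   parcel pairs inside the same network resp. across networks;
#'   `0 <= between < within < 1`.
#' @param effect_sparsity_eps Fraction of edges perturbed in the case group
#'   (the "rare" part of the rare-weak alternative).
#' @param effect_size_delta Absolute correlation shift applied to each
#'   perturbed edge (the "weak" part); sign drawn per edge.
#' @param covariate_effects Named numeric vector of per-edge Fisher-z slopes
#'   applied additively for covariates `age`, `sex` and `mean_fd`
#'   (units: z per year, z per sex level, z per mm).
#' @param n_states Number of hidden covariance states (1 = static cohort).
#' @param state_transition_prob Per-volume probability of switching state in
#'   the first-order Markov chain (used when `n_states > 1`).
#' @param state_coupling Between-network correlation of the network pairs
#'   that each non-baseline state couples (default 0.45). State 1 is the
#'   baseline block covariance; state `s > 1` additionally couples network
#'   pairs `(1,2), (3,4), ...` (pairing rotated by one network per further
#'   state), so states differ in coupling *pattern* — the feature a
#'   correlation-distance clustering can recover — rather than overall FC
#'   level.
#' @param age_range Two-element range of the uniform age distribution, years.
#' @param mean_fd_mean,mean_fd_sd Location/scale of the truncated-normal
#'   (>= 0.01 mm) mean framewise-displacement distribution.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_group1 = 39, n_group2 = 44,
                       network_sizes = c(25, 24, 24, 24, 25, 24, 24, 25, 24, 24),
                       n_timepoints = 234, tr_seconds = 2.5,
                       within_network_corr = 0.3, between_network_corr = 0.05,
                       effect_sparsity_eps = 0, effect_size_delta = 0,
                       covariate_effects = c(age = 0, sex = 0, mean_fd = 0),
                       n_states = 1, state_transition_prob = 0.05,
                       state_coupling = 0.45,
                       age_range = c(18, 30),
                       mean_fd_mean = 0.15, mean_fd_sd = 0.05,
                       seed = 1L) {
  stopifnot(n_group1 >= 2, n_group2 >= 2,
            all(network_sizes >= 2), n_timepoints >= 3,
            tr_seconds > 0,
            within_network_corr > 0, within_network_corr < 1,
            between_network_corr >= 0,
            between_network_corr < within_network_corr,
            effect_sparsity_eps >= 0, effect_sparsity_eps <= 1,
            n_states >= 1,
            state_transition_prob > 0, state_transition_prob < 1,
            length(age_range) == 2, diff(age_range) > 0,
            mean_fd_mean > 0, mean_fd_sd > 0)
  covs <- c(age = 0, sex = 0, mean_fd = 0)
  if (length(covariate_effects)) {
    unknown <- setdiff(names(covariate_effects), names(covs))
    if (length(unknown)) stop("unknown covariate effect: ", paste(unknown, collapse = ", "))
    covs[names(covariate_effects)] <- covariate_effects
  }
  stopifnot(state_coupling > between_network_corr, state_coupling < 1)
  if (n_states > 1 && length(network_sizes) < 2)
    stop("switching states need at least 2 networks to differ in coupling")
  structure(list(
    n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
    n_parcels = as.integer(sum(network_sizes)),
    network_sizes = as.integer(network_sizes),
    n_timepoints = as.integer(n_timepoints), tr_seconds = tr_seconds,
    within_network_corr = within_network_corr,
    between_network_corr = between_network_corr,
    effect_sparsity_eps = effect_sparsity_eps,
    effect_size_delta = effect_size_delta,
    covariate_effects = covs,
    n_states = as.integer(n_states),
    state_transition_prob = state_transition_prob,
    state_coupling = state_coupling,
    age_range = age_range, mean_fd_mean = mean_fd_mean,
    mean_fd_sd = mean_fd_sd, seed = as.integer(seed)
  ), class = "sim_config")
}

#' Block-structured correlation matrix for a set of networks
#'
#' Unit-diagonal matrix with `within_network_corr` for parcel pairs in the
#' same network and `between_network_corr` otherwise, emulating the block
#' appearance of network-ordered connectivity matrices.
#'
#' @inheritParams sim_config
#' @return A symmetric positive-definite correlation matrix of dimension
#'   `sum(network_sizes)`.
#' @export
build_block_covariance <- function(network_sizes, within_network_corr,
                                   between_network_corr = 0) {
  stopifnot(all(network_sizes >= 1),
            within_network_corr >= 0, within_network_corr < 1,
            between_network_corr >= 0,
            between_network_corr <= within_network_corr)
  labels <- rep(seq_along(network_sizes), times = network_sizes)
  p <- length(labels)
  m <- matrix(between_network_corr, p, p)
  same <- outer(labels, labels, "==")
  m[same] <- within_network_corr
  diag(m) <- 1
  ev_min <- min(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-12)
    stop("requested block correlations do not yield a positive-definite ",
         "matrix (smallest eigenvalue ", format(ev_min), ")")
  m
}

# Project a symmetric matrix to the nearest positive-definite correlation
# matrix (Higham alternating projections, via Matrix::nearPD).
nearest_pd_correlation <- function(m, tol = 1e-8) {
  if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) > tol) {
    diag(m) <- 1
    return(m)
  }
  res <- try(Matrix::nearPD(m, corr = TRUE, eig.tol = tol, conv.tol = tol,
                            maxit = 200), silent = TRUE)
  if (inherits(res, "try-error") || !res$converged)
    stop("projection to the nearest positive-definite correlation matrix failed")
  as.matrix(res$mat)
}

#' Plant a rare-weak group effect on a correlation matrix
#'
#' Shifts `round(eps * E)` randomly chosen off-diagonal pairs (E = number of
#' upper-triangle edges) by `+/- delta` on the correlation scale, the sign
#' drawn independently per edge, then repairs the result to the nearest
#' positive-definite correlation matrix. This constructs the sparse-weak
#' alternative that the Higher Criticism test is designed to detect.
#'
#' @param base_covariance Correlation matrix to perturb.
#' @param eps Fraction of edges to perturb, in `[0, 1]`.
#' @param delta Absolute correlation shift per perturbed edge.
#' @param seed Integer seed for edge and sign selection.
#' @return A list with `covariance` (the repaired perturbed matrix) and
#'   `edges` (data frame `i`, `j`, `delta` of actually perturbed pairs;
#'   zero rows when `eps = 0`).
#' @export
plant_group_effect <- function(base_covariance, eps, delta, seed = 1L) {
  p <- nrow(base_covariance)
  stopifnot(p >= 2, isSymmetric(unname(base_covariance)),
            eps >= 0, eps <= 1)
  idx <- edge_index_table(p)
  n_edges <- nrow(idx)
  n_hit <- round(eps * n_edges)
  if (n_hit == 0)
    return(list(covariance = base_covariance,
                edges = cbind(idx[0, ], delta = numeric(0))))
  with_seed(seed, {
    hit <- sort(sample.int(n_edges, n_hit))
    signs <- sample(c(-1, 1), n_hit, replace = TRUE)
  })
  shift <- signs * delta
  m <- base_covariance
  ii <- idx$i[hit]; jj <- idx$j[hit]
  new_r <- m[cbind(ii, jj)] + shift
  if (any(abs(new_r) >= 1))
    stop("delta pushes a correlation outside (-1, 1); reduce |delta|")
  m[cbind(ii, jj)] <- new_r
  m[cbind(jj, ii)] <- new_r
  m <- nearest_pd_correlation(m)
  list(covariance = m, edges = data.frame(i = ii, j = jj, delta = shift))
}

#' Simulate one subject's parcel time series
#'
#' Draws zero-mean multivariate normal samples whose covariance at each
#' volume is selected by a first-order Markov chain over hidden states
#' (uniform initial state). With a single state the chain is constant and
#' the series is stationary.
#'
#' @param covariances A single covariance matrix or a list of one per state.
#' @param n_timepoints Number of volumes to draw.
#' @param state_transition_prob Per-volume switching probability.
#' @param seed Integer seed.
#' @return List with `series` (T x P matrix) and `states` (length-T integer
#'   vector of the true state at each volume).
#' @export
simulate_subject_timeseries <- function(covariances, n_timepoints,
                                        state_transition_prob = 0.05,
                                        seed = 1L) {
  if (is.matrix(covariances)) covariances <- list(covariances)
  n_states <- length(covariances)
  p <- nrow(covariances[[1]])
  chols <- lapply(covariances, function(s) {
    ch <- try(chol(s), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("state covariance is not positive definite")
    ch
  })
  with_seed(seed, {
    states <- integer(n_timepoints)
    states[1] <- sample.int(n_states, 1)
    if (n_states > 1 && n_timepoints > 1) {
      flips <- stats::runif(n_timepoints - 1) < state_transition_prob
      for (t in 2:n_timepoints) {
        states[t] <- if (flips[t - 1]) {
          sample(setdiff(seq_len(n_states), states[t - 1]), 1)
        } else states[t - 1]
      }
    } else states[] <- states[1]
    z <- matrix(stats::rnorm(n_timepoints * p), n_timepoints, p)
    series <- matrix(0, n_timepoints, p)
    for (s in seq_len(n_states)) {
      rows <- states == s
      if (any(rows)) series[rows, ] <- z[rows, , drop = FALSE] %*% chols[[s]]
    }
  })
  list(series = series, states = states)
}

# State covariances: state 1 is the baseline block structure; each further
# state couples disjoint network pairs (pairing rotated per state) at
# `state_coupling`, so states differ in coupling pattern.
build_state_covariances <- function(config) {
  base <- build_block_covariance(config$network_sizes,
                                 config$within_network_corr,
                                 config$between_network_corr)
  if (config$n_states == 1) return(list(base))
  n_net <- length(config$network_sizes)
  labels <- rep(seq_len(n_net), times = config$network_sizes)
  c(list(base), lapply(seq_len(config$n_states - 1), function(s) {
    # rotate network order by s - 1, then pair consecutive networks
    order_s <- ((seq_len(n_net) + (s - 1) - 1) %% n_net) + 1
    pair_of <- integer(n_net)
    pair_of[order_s] <- (seq_len(n_net) + 1) %/% 2
    coupled <- outer(pair_of[labels], pair_of[labels], "==") &
      outer(labels, labels, "!=")
    m <- base
    m[coupled] <- config$state_coupling
    nearest_pd_correlation(m)
  }))
}

# Random-walk motion parameters whose expected framewise displacement
# matches `target_mean_fd` (rotation step sd tied to translation sd so
# translations and scaled rotations contribute equally).
simulate_motion <- function(n_timepoints, target_mean_fd, head_radius = 50) {
  sigma <- target_mean_fd / (6 * sqrt(2 / pi))
  d_trans <- matrix(stats::rnorm(3 * (n_timepoints - 1), sd = sigma),
                    n_timepoints - 1, 3)
  d_rot <- matrix(stats::rnorm(3 * (n_timepoints - 1), sd = sigma / head_radius),
                  n_timepoints - 1, 3)
  motion <- apply(rbind(0, cbind(d_trans, d_rot)), 2, cumsum)
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  motion
}

# Default atlas lookup for a simulated cohort: 10 generic cognition-related
# network labels recycled over however many networks the config requests.
default_network_labels <- function(n) {
  base <- c("DorsAttnA", "DorsAttnB", "SalVentAttnA", "SalVentAttnB",
            "ContA", "ContB", "ContC", "DefaultA", "DefaultB", "DefaultC")
  if (n <= length(base)) base[seq_len(n)] else
    paste0("Net", seq_len(n))
}

sim_partition <- function(config) {
  labels <- default_network_labels(length(config$network_sizes))
  network <- rep(labels, times = config$network_sizes)
  parcel_id <- seq_len(config$n_parcels)
  network_partition(data.frame(
    parcel_id = parcel_id,
    parcel_name = sprintf("%s_parcel%02d", network,
                          unlist(lapply(config$network_sizes, seq_len))),
    network_label = network))
}

#' Simulate a full synthetic cohort
#'
#' Generates a subject manifest (group, sex, age, mean framewise
#' displacement), per-subject parcel time series drawn under the
#' group-specific (and, when `n_states > 1`, state-switching) covariance,
#' and per-subject confound tables with motion traces consistent with each
#' subject's mean FD. Case-group subjects are drawn under the perturbed
#' covariance carrying the planted rare-weak effect; configured covariate
#' effects are added on the Fisher-z scale of each subject's target
#' correlation matrix.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `fc_cohort`: list with `manifest`,
#'   `timeseries` (named list of T x P matrices), `confounds` (named list of
#'   T x 8 matrices), `partition`, `true_states` (named list), `planted_edges`
#'   and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$n_parcels
  base_states <- build_state_covariances(config)
  planted <- plant_group_effect(base_states[[1]], config$effect_sparsity_eps,
                                config$effect_size_delta,
                                seed = substream_seed(config$seed, "states"))
  # apply the same edge perturbation to every state covariance of the case group
  case_states <- lapply(base_states, function(s) {
    if (nrow(planted$edges) == 0) return(s)
    m <- s
    ij <- cbind(planted$edges$i, planted$edges$j)
    m[ij] <- m[ij] + planted$edges$delta
    m[cbind(planted$edges$j, planted$edges$i)] <- m[ij]
    nearest_pd_correlation(m)
  })

  n <- config$n_group1 + config$n_group2
  group <- factor(rep(c("control", "case"), c(config$n_group1, config$n_group2)),
                  levels = c("control", "case"))
  manifest <- with_seed(substream_seed(config$seed, "covariates"), {
    sex <- factor(sample(c("F", "M"), n, replace = TRUE), levels = c("F", "M"))
    # guard the two-level invariant at small n
    if (nlevels(droplevels(sex)) < 2) sex[1:2] <- c("F", "M")
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    fd <- config$mean_fd_mean + config$mean_fd_sd * stats::rnorm(n)
    fd <- pmax(fd, 0.01)
    data.frame(subject_id = sprintf("sub-%03d", seq_len(n)),
               group = group, sex = sex, age = round(age, 1),
               mean_fd = round(fd, 4))
  })

  partition <- sim_partition(config)
  idx <- edge_index_table(p)
  ce <- config$covariate_effects
  has_cov_fx <- any(ce != 0)

  timeseries <- vector("list", n); names(timeseries) <- manifest$subject_id
  confounds <- vector("list", n); names(confounds) <- manifest$subject_id
  true_states <- vector("list", n); names(true_states) <- manifest$subject_id

  for (s in seq_len(n)) {
    covs <- if (group[s] == "case") case_states else base_states
    if (has_cov_fx) {
      x <- c(age = manifest$age[s],
             sex = as.numeric(manifest$sex[s] == "M"),
             mean_fd = manifest$mean_fd[s])
      shift_z <- sum(ce * x)
      covs <- lapply(covs, function(m) {
        z <- atanh(clip_correlation(vectorize_edges(m, idx)))
        nearest_pd_correlation(edges_to_matrix(tanh(z + shift_z), p, 1))
      })
    }
    sub_seed <- (substream_seed(config$seed, "simulation") + s) %% .Machine$integer.max
    sim <- simulate_subject_timeseries(covs, config$n_timepoints,
                                       config$state_transition_prob,
                                       seed = sub_seed)
    ts <- sim$series
    colnames(ts) <- partition$lookup$parcel_name
    timeseries[[s]] <- ts
    true_states[[s]] <- sim$states
    with_seed((sub_seed + 7e5L) %% .Machine$integer.max, {
      motion <- simulate_motion(config$n_timepoints, manifest$mean_fd[s])
      wm <- as.numeric(stats::filter(stats::rnorm(config$n_timepoints),
                                     0.5, method = "recursive"))
      csf <- as.numeric(stats::filter(stats::rnorm(config$n_timepoints),
                                      0.5, method = "recursive"))
    })
    confounds[[s]] <- cbind(motion, wm = wm, csf = csf)
  }

  structure(list(manifest = manifest, timeseries = timeseries,
                 confounds = confounds, partition = partition,
                 true_states = true_states, planted_edges = planted$edges,
                 config = config),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic functional-connectivity cohort\n")
  cat(sprintf("  subjects: %d control + %d case\n", cfg$n_group1, cfg$n_group2))
  cat(sprintf("  parcels:  %d in %d networks\n", cfg$n_parcels,
              length(cfg$network_sizes)))
  cat(sprintf("  volumes:  %d at TR %.2f s\n", cfg$n_timepoints, cfg$tr_seconds))
  cat(sprintf("  planted effect: eps = %g, delta = %g (%d edges)\n",
              cfg$effect_sparsity_eps, cfg$effect_size_delta,
              nrow(x$planted_edges)))
  if (cfg$n_states > 1)
    cat(sprintf("  hidden states: %d (switch prob %.3f)\n",
                cfg$n_states, cfg$state_transition_prob))
  invisible(x)
}
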
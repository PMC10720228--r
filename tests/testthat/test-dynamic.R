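test_that("window construction matches the 18-volume / 60%-overlap scheme", {
  spec <- window_spec()
  expect_equal(spec$step_volumes, 7L)          # round(18 * 0.4)
  expect_equal(spec$duration_seconds, 45)      # 18 volumes at TR 2.5 s

  w <- make_windows(234, spec)
  expect_equal(nrow(w), 31)                    # floor((234 - 18) / 7) + 1
  expect_equal(w$start[1], 1L)
  expect_equal(diff(w$start), rep(7L, 30))
  expect_true(all(w$end <= 234))

  expect_equal(nrow(make_windows(18, spec)), 1)
  w0 <- make_windows(36, window_spec(overlap_fraction = 0))
  expect_equal(w0$start, c(1L, 19L))           # contiguous, non-overlapping
  expect_error(make_windows(10, spec), "shorter")
})

test_that("windowed FC reflects the underlying stationarity", {
  set.seed(40)
  sigma <- build_block_covariance(c(3, 3), 0.4, 0.1)
  x <- simulate_subject_timeseries(sigma, 234, seed = 1)$series
  w18 <- windowed_fc(x, make_windows(234, window_spec()))
  expect_equal(dim(w18), c(31, 15))
  expect_false(any(attr(w18, "flagged")))

  # identical windows give identical rows
  xr <- x[rep(1:18, 3), ]
  wr <- windowed_fc(xr, make_windows(54, window_spec(overlap_fraction = 0,
                                                     step_volumes = 18)))
  expect_equal(wr[1, ], wr[2, ], tolerance = 1e-12)

  # longer windows shrink window-to-window variance under stationarity
  w54 <- windowed_fc(x, make_windows(234, window_spec(length_volumes = 54)))
  expect_lt(mean(apply(w54, 2, var)), mean(apply(w18, 2, var)))

  # planted switching states inflate between-window variance
  covs <- hcfc:::build_state_covariances(
    sim_config(network_sizes = rep(3, 4), n_states = 2, seed = 1))
  x2 <- simulate_subject_timeseries(covs, 234, 0.05, seed = 2)$series
  x1 <- simulate_subject_timeseries(covs[[1]], 234, seed = 2)$series
  v2 <- mean(apply(windowed_fc(x2, make_windows(234, window_spec())), 2, var))
  v1 <- mean(apply(windowed_fc(x1, make_windows(234, window_spec())), 2, var))
  expect_gt(v2, v1)

  # zero-variance parcel flags the window
  xf <- x
  xf[1:18, 2] <- 5
  wf <- windowed_fc(xf, make_windows(234, window_spec()))
  expect_true(attr(wf, "flagged")[1])
  expect_true(all(is.na(wf[1, ])))
})

test_that("k-means recovers planted states and is seed-deterministic", {
  cfg <- sim_config(n_group1 = 6, n_group2 = 6, network_sizes = rep(4, 6),
                    n_timepoints = 234, n_states = 2,
                    state_transition_prob = 0.05, seed = 50)
  co <- simulate_cohort(cfg)
  w <- make_windows(234, window_spec())
  pooled <- do.call(rbind, lapply(co$timeseries, windowed_fc, windows = w))
  subj <- rep(co$manifest$subject_id, each = nrow(w))
  m <- cluster_states(pooled, subj, k_range = 2:6, seed = 9)
  expect_equal(m$k, 2)

  truth <- unlist(lapply(co$manifest$subject_id, function(id) {
    st <- co$true_states[[id]]
    vapply(seq_len(nrow(w)), function(i)
      round(mean(st[w$start[i]:w$end[i]] == 2)), numeric(1))
  }))
  acc <- max(mean((m$assignments$state - 1) == truth),
             mean((2 - m$assignments$state) == truth))
  expect_gt(acc, 0.9)

  m2 <- cluster_states(pooled, subj, k_range = 2:6, seed = 9)
  expect_identical(m$assignments, m2$assignments)
  expect_identical(m$centroids, m2$centroids)

  # duplicating every window changes neither centroids nor selection
  md <- cluster_states(rbind(pooled, pooled), c(subj, subj),
                       k_range = 2:6, seed = 9)
  expect_equal(md$k, m$k)
  expect_equal(md$centroids[order(md$centroids[, 1]), ],
               m$centroids[order(m$centroids[, 1]), ], tolerance = 1e-6)
})

test_that("single-state data yields weakly separable forced clusters", {
  cfg <- sim_config(n_group1 = 5, n_group2 = 5, network_sizes = rep(4, 4),
                    n_timepoints = 234, seed = 51)
  co <- simulate_cohort(cfg)
  w <- make_windows(234, window_spec())
  pooled <- do.call(rbind, lapply(co$timeseries, windowed_fc, windows = w))
  subj <- rep(co$manifest$subject_id, each = nrow(w))
  m <- cluster_states(pooled, subj, k_range = 2, seed = 3)
  expect_lt(m$mean_silhouette, 0.3)
})

test_that("state metrics match hand computation and the scanning oracle", {
  m <- state_metrics(c(1, 1, 2, 2, 1))
  expect_equal(m$nt, 2)
  expect_equal(m$mdt, c(1.5, 2))
  expect_equal(m$frc, c(0.6, 0.4))

  const <- state_metrics(rep(1, 7), n_states = 2)
  expect_equal(const$nt, 0)
  expect_equal(const$frc, c(1, 0))
  expect_true(is.na(const$mdt[2]))

  alt <- state_metrics(c(1, 2, 1, 2))
  expect_equal(alt$nt, 3)
  expect_equal(alt$mdt, c(1, 1))

  # exhaustive agreement with the scanning oracle, sequences of length <= 8
  for (len in 1:8) {
    grid <- as.matrix(expand.grid(rep(list(1:2), len)))
    for (r in seq_len(nrow(grid))) {
      s <- grid[r, ]
      expect_equal(state_metrics(s, 2), state_metrics_brute(s, 2))
    }
  }
})

test_that("frequency sums to one and transitions are bounded", {
  set.seed(41)
  for (r in 1:50) {
    s <- sample(1:3, sample(1:30, 1), replace = TRUE)
    m <- state_metrics(s, 3)
    expect_equal(sum(m$frc), 1)
    expect_lte(m$nt, length(s) - 1)
    expect_true(all(m$mdt >= 1, na.rm = TRUE))
  }
})

test_that("group comparisons of state dynamics behave at the extremes", {
  met <- data.frame(subject_id = sprintf("s%d", 1:12),
                    nt = rep(c(3, 5, 7), 4),
                    mdt_state1 = rep(c(2, 3, 4), 4),
                    frc_state1 = rep(0.6, 12),
                    mdt_state2 = rep(c(1, 2, 3), 4),
                    frc_state2 = rep(0.4, 12))
  grp <- rep(c("control", "case"), each = 6)
  same <- compare_state_dynamics(met, grp)   # identical groups
  expect_equal(same$p[same$metric == "NT"], 1, tolerance = 1e-10)
  expect_true(all(same$p[same$metric == "MDT"] > 0.99))

  met2 <- met
  met2$nt <- c(2:7, 20:25)                   # disjoint NT distributions
  sep <- compare_state_dynamics(met2, grp)
  expect_lt(sep$p[sep$metric == "NT"], 1e-3)

  met3 <- met
  met3$mdt_state2[1:6] <- NA                 # state unvisited by one group
  flg <- compare_state_dynamics(met3, grp)
  expect_true(flg$flagged[flg$metric == "MDT" & flg$state == 2])
})
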
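test_that("block covariance has the requested structure and is PD", {
  m <- build_block_covariance(2, 0.5)
  expect_equal(m, matrix(c(1, 0.5, 0.5, 1), 2, 2))

  m2 <- build_block_covariance(c(2, 2), 0.5, 0.1)
  expect_true(isSymmetric(m2))
  expect_equal(diag(m2), rep(1, 4))
  expect_equal(m2[1, 2], 0.5)   # same block
  expect_equal(m2[1, 3], 0.1)   # different block
  expect_gt(min(eigen(m2, symmetric = TRUE, only.values = TRUE)$values), 0)

  # between = within reduces to compound symmetry, PD for within < 1
  cs <- build_block_covariance(c(3, 3), 0.4, 0.4)
  expect_equal(unique(cs[upper.tri(cs)]), 0.4)
  expect_gt(min(eigen(cs, symmetric = TRUE, only.values = TRUE)$values), 0)

  expect_error(build_block_covariance(c(2, 2), 0.2, 0.5))
})

test_that("planted group effects hit exactly the reported edges", {
  base <- build_block_covariance(rep(5, 2), 0.3, 0.05)

  null_case <- plant_group_effect(base, eps = 0, delta = 0.2)
  expect_identical(null_case$covariance, base)
  expect_equal(nrow(null_case$edges), 0)

  zero_delta <- plant_group_effect(base, eps = 1, delta = 0, seed = 2)
  expect_equal(zero_delta$covariance, base, tolerance = 1e-6)

  # P = 10 parcels: E = 45, eps = 0.1 -> 4 perturbed edges
  pe <- plant_group_effect(base, eps = 0.1, delta = 0.1, seed = 3)
  expect_equal(nrow(pe$edges), round(0.1 * 45))
  expect_equal(length(unique(paste(pe$edges$i, pe$edges$j))), nrow(pe$edges))
  expect_gt(min(eigen(pe$covariance, symmetric = TRUE,
                      only.values = TRUE)$values), 0)
  # reported edges are where the matrix actually moved (up to PD repair)
  moved <- abs(pe$covariance - base)
  for (k in seq_len(nrow(pe$edges)))
    expect_gt(moved[pe$edges$i[k], pe$edges$j[k]], abs(pe$edges$delta[k]) / 2)

  expect_identical(plant_group_effect(base, 0.1, 0.1, seed = 3)$edges,
                   pe$edges)
  expect_error(plant_group_effect(base, 0.5, 0.99), "outside")
})

test_that("subject time series follow the state-switching model", {
  s <- simulate_subject_timeseries(diag(3), 50, seed = 1)
  expect_equal(dim(s$series), c(50, 3))
  expect_equal(unique(s$states), 1L)

  covs <- list(diag(2), matrix(c(1, .8, .8, 1), 2))
  frozen <- simulate_subject_timeseries(covs, 80, state_transition_prob = 0,
                                        seed = 5)
  expect_equal(length(unique(frozen$states)), 1L)

  # Monte-Carlo consistency: sample covariance of many within-state draws
  sigma <- matrix(c(1, 0.6, 0.2, 0.6, 1, 0.4, 0.2, 0.4, 1), 3)
  big <- simulate_subject_timeseries(sigma, 50000, seed = 9)
  expect_lt(max(abs(cov(big$series) - sigma)), 0.05)

  expect_error(simulate_subject_timeseries(matrix(c(1, 2, 2, 1), 2), 10),
               "positive definite")
})

test_that("cohorts are deterministic under a fixed seed", {
  cfg <- sim_config(n_group1 = 4, n_group2 = 4, network_sizes = c(3, 3),
                    n_timepoints = 40, n_states = 2, seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$timeseries, b$timeseries)
  expect_identical(a$confounds, b$confounds)
  expect_identical(a$true_states, b$true_states)

  expect_equal(nlevels(a$manifest$group), 2)
  expect_equal(nlevels(droplevels(a$manifest$sex)), 2)
  expect_true(all(a$manifest$mean_fd > 0))
})

test_that("planted z-scale effects are recovered at their analytic size", {
  # delta = 0.15, eps = 0.05: the measured mean |group z difference| over
  # perturbed edges matches the atanh image of the planted correlation shift
  cfg <- sim_config(n_group1 = 40, n_group2 = 44, network_sizes = rep(6, 5),
                    n_timepoints = 234, effect_sparsity_eps = 0.05,
                    effect_size_delta = 0.15, seed = 31)
  base <- build_block_covariance(cfg$network_sizes, cfg$within_network_corr,
                                 cfg$between_network_corr)
  n_rep <- 8
  measured <- expected <- numeric(0)
  for (r in seq_len(n_rep)) {
    cfg_r <- sim_config(n_group1 = 40, n_group2 = 44,
                        network_sizes = rep(6, 5), n_timepoints = 234,
                        effect_sparsity_eps = 0.05, effect_size_delta = 0.15,
                        seed = 31 + r)
    co <- simulate_cohort(cfg_r)
    fc <- lapply(co$timeseries, static_fc)
    z <- stack_z <- t(vapply(fc, function(m) m[cbind(co$planted_edges$i,
                                                     co$planted_edges$j)],
                             numeric(nrow(co$planted_edges))))
    case <- co$manifest$group == "case"
    measured <- c(measured, abs(colMeans(z[case, , drop = FALSE]) -
                                  colMeans(z[!case, , drop = FALSE])))
    r0 <- base[cbind(co$planted_edges$i, co$planted_edges$j)]
    expected <- c(expected, abs(atanh(r0 + co$planted_edges$delta) - atanh(r0)))
  }
  expect_equal(mean(measured), mean(expected), tolerance = 0.15)
})

test_that("perturbed edges separate from unperturbed edges in z difference", {
  cfg <- sim_config(n_group1 = 30, n_group2 = 30, network_sizes = rep(5, 4),
                    n_timepoints = 200, effect_sparsity_eps = 0.1,
                    effect_size_delta = 0.2, seed = 77)
  co <- simulate_cohort(cfg)
  fc <- lapply(co$timeseries, static_fc)
  idx <- edge_index_table(cfg$n_parcels)
  z <- t(vapply(fc, function(m) m[cbind(idx$i, idx$j)], numeric(nrow(idx))))
  case <- co$manifest$group == "case"
  dz <- abs(colMeans(z[case, ]) - colMeans(z[!case, ]))
  hit <- paste(idx$i, idx$j) %in% paste(co$planted_edges$i, co$planted_edges$j)
  expect_lt(wilcox.test(dz[hit], dz[!hit], alternative = "greater")$p.value,
            1e-4)
})
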
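test_that("BH adjustment matches hand computation and the brute oracle", {
  hand <- fdr_adjust(c(0.001, 0.01, 0.04, 0.2))
  expect_equal(hand$p_adjusted, c(0.004, 0.02, 0.04 * 4 / 3, 0.2),
               tolerance = 1e-12)
  expect_equal(hand$discovered, c(TRUE, TRUE, FALSE, FALSE))

  single <- fdr_adjust(0.01)
  expect_equal(single$p_adjusted, 0.01)
  expect_true(single$discovered)

  expect_false(any(fdr_adjust(rep(1, 10))$discovered))

  set.seed(30)
  for (r in 1:300) {
    p <- round(runif(sample(1:8, 1)), 3)
    mine <- fdr_adjust(p, q = 0.05)
    ref <- bh_brute(p, q = 0.05)
    expect_equal(mine$p_adjusted, ref$adjusted, tolerance = 1e-12)
    expect_equal(mine$discovered, ref$adjusted <= 0.05)
    expect_equal(mine$discovered, ref$discovered)
  }
})

test_that("the hierarchy report covers every scope", {
  part <- equal_partition(4, 3)
  set.seed(31)
  edge_tab <- crafted_edge_table(runif(66), 12)    # 12 parcels -> 66 edges
  net_tab <- crafted_edge_table(runif(6), 4)       # 4 networks -> 6 edges
  rep <- run_hierarchy(edge_tab, net_tab, part, n_null_replicates = 1000,
                       seed = 8)
  expect_s3_class(rep$global, "hc_result")
  expect_equal(length(rep$within_network), 4)
  expect_equal(names(rep$within_network), part$networks)
  expect_s3_class(rep$between_network, "hc_result")
  expect_equal(nrow(rep$fdr_global), 66)
  expect_equal(nrow(rep$fdr_between), 6)
  expect_equal(vapply(rep$fdr_within, nrow, numeric(1)),
               setNames(rep(3, 4), part$networks))

  # every within-network p-value appears in exactly one level-2 test
  covered <- unname(unlist(lapply(rep$fdr_within,
                                  function(d) paste(d$i, d$j))))
  expect_equal(anyDuplicated(covered), 0)
  nets <- hcfc:::edge_networks(part)
  expect_equal(sort(covered),
               sort(paste(nets$i, nets$j)[nets$net_i == nets$net_j]))
})

test_that("a dense strong effect localizes to its network", {
  sizes <- rep(4, 3)
  ctrl_cov <- build_block_covariance(sizes, 0.2, 0.05)
  case_cov <- ctrl_cov
  case_cov[1:4, 1:4] <- 0.7; diag(case_cov) <- 1   # network 1 much tighter
  part <- equal_partition(3, 4)
  n1 <- 20; n2 <- 20
  series <- c(lapply(1:n1, function(s)
    simulate_subject_timeseries(ctrl_cov, 150, seed = 500 + s)$series),
    lapply(1:n2, function(s)
      simulate_subject_timeseries(case_cov, 150, seed = 600 + s)$series))
  man <- data.frame(subject_id = sprintf("s%02d", 1:40),
                    group = factor(rep(c("control", "case"), each = 20),
                                   levels = c("control", "case")),
                    sex = rep(c("F", "M"), 20),
                    age = runif(40, 18, 30), mean_fd = runif(40, 0.05, 0.2))
  design <- build_design(man)
  fc <- lapply(series, static_fc)
  edge_tab <- fit_all_edges(hcfc:::stack_edges(fc), design,
                            edge_index = edge_index_table(12))
  net_fc <- lapply(series, function(ts)
    static_fc(network_timeseries(ts, part)))
  net_tab <- fit_all_edges(hcfc:::stack_edges(net_fc), design,
                           edge_index = edge_index_table(3))
  rep <- run_hierarchy(edge_tab, net_tab, part, n_null_replicates = 1000,
                       seed = 4)
  expect_true(rep$global$reject)
  expect_true(rep$within_network$net1$reject)
  expect_gt(sum(rep$fdr_within$net1$discovered), 0)
  expect_gt(sum(rep$fdr_global$discovered), 0)
})

test_that("within-network FDR is strictly weaker than global FDR", {
  part <- equal_partition(3, 3)          # 9 parcels, 36 edges, 3 per network
  p <- rep(0.9, 36)
  nets <- hcfc:::edge_networks(part)
  within1 <- which(nets$net_i == 1 & nets$net_j == 1)
  p[within1[1]] <- 0.012                 # survives m = 3, not m = 36
  edge_tab <- crafted_edge_table(p, 9)
  net_tab <- crafted_edge_table(rep(0.5, 3), 3)
  rep <- run_hierarchy(edge_tab, net_tab, part, n_null_replicates = 1000,
                       seed = 2)
  expect_equal(sum(rep$fdr_global$discovered), 0)
  expect_equal(sum(rep$fdr_within$net1$discovered), 1)
})

test_that("dropping a network leaves the other networks' HC unchanged", {
  set.seed(33)
  part4 <- equal_partition(4, 4)
  p4 <- runif(choose(16, 2))
  edge4 <- crafted_edge_table(p4, 16)
  rep4 <- run_hierarchy(edge4, crafted_edge_table(runif(6), 4), part4,
                        n_null_replicates = 1000, seed = 6)

  # restrict to networks 1-3 (parcels 1..12), reusing the same p-values
  part3 <- equal_partition(3, 4)
  keep <- edge4$i <= 12 & edge4$j <= 12
  edge3 <- crafted_edge_table(p4[keep], 12)
  rep3 <- run_hierarchy(edge3, crafted_edge_table(runif(3), 3), part3,
                        n_null_replicates = 1000, seed = 6)
  for (nm in c("net1", "net2", "net3"))
    expect_equal(rep3$within_network[[nm]]$hc_value,
                 rep4$within_network[[nm]]$hc_value, tolerance = 1e-12)
})

test_that("reports round-trip losslessly through the CSV writer", {
  part <- equal_partition(3, 3)
  set.seed(34)
  edge_tab <- crafted_edge_table(runif(36), 9)
  edge_tab$group_mean_diff_z <- rnorm(36)
  edge_tab$partial_eta2 <- runif(36, 0, 0.3)
  net_tab <- crafted_edge_table(runif(3), 3)
  rep <- run_hierarchy(edge_tab, net_tab, part, n_null_replicates = 1000,
                       seed = 3)
  dir <- withr::local_tempdir()
  paths <- report_hierarchy(rep, dir)
  expect_true(all(file.exists(paths)))

  diff_csv <- read.csv(paths[["diff_matrix"]], check.names = FALSE)
  m <- as.matrix(diff_csv[, -1])
  idx <- edge_index_table(9)
  expect_equal(unname(m[cbind(idx$i, idx$j)]), edge_tab$group_mean_diff_z,
               tolerance = 1e-12)

  summ <- jsonlite::read_json(paths[["summary"]], simplifyVector = TRUE)
  expect_equal(summ$global$hc_value, rep$global$hc_value, tolerance = 1e-9)
  expect_equal(length(summ$within_network), 3)
})
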
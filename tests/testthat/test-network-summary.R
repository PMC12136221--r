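test_that("network means recover constant and planted block values", {
  # constant map: every populated network mean equals the constant
  delta <- array(0.3, c(2, 2, 40))
  res <- make_asym(delta)
  part <- network_partition(rep(c(6L, 3L), each = 20))  # LAN, SMM
  summ <- aggregate_by_network(res, part)
  expect_true(all(summ$delta_mean[, , c("LAN", "SMM")] == 0.3))
  expect_true(all(is.na(summ$delta_mean[, , "VIS1"])))   # empty network

  # planted blocks recovered exactly at zero noise
  delta2 <- array(NA_real_, c(2, 1, 40))
  delta2[, 1, 1:20] <- 0.2; delta2[, 1, 21:40] <- -0.1
  summ2 <- aggregate_by_network(make_asym(delta2), part)
  expect_equal(unname(summ2$delta_mean[1, 1, c("LAN", "SMM")]), c(0.2, -0.1))

  # masked vertices are excluded from the mean
  delta3 <- array(NA_real_, c(1, 1, 3))
  delta3[1, 1, ] <- c(0.1, 0.2, NA)
  part3 <- network_partition(rep(6L, 3))
  summ3 <- aggregate_by_network(make_asym(delta3), part3)
  expect_equal(unname(summ3$delta_mean[1, 1, "LAN"]), 0.15)

  expect_error(aggregate_by_network(make_asym(delta3),
                                    network_partition(rep(-1L, 3))),
               "all networks empty")
  expect_error(aggregate_by_network(make_asym(delta3),
                                    network_partition(rep(1L, 5))),
               "does not match vertex count")
})

test_that("aggregation commutes with joint vertex/label permutation and is linear", {
  set.seed(21)
  delta <- array(rnorm(3 * 2 * 30, sd = 0.1), c(3, 2, 30))
  labels <- sample(c(1L, 2L, 5L, -1L), 30, replace = TRUE)
  summ <- aggregate_by_network(make_asym(delta), network_partition(labels))
  perm <- sample(30)
  summ_p <- aggregate_by_network(make_asym(delta[, , perm, drop = FALSE]),
                                 network_partition(labels[perm]))
  expect_equal(summ$delta_mean, summ_p$delta_mean, tolerance = 1e-12)

  # adding c to one network's vertices shifts only that network's mean by c
  delta_c <- delta
  delta_c[, , labels == 2L] <- delta_c[, , labels == 2L] + 0.05
  summ_c <- aggregate_by_network(make_asym(delta_c), network_partition(labels))
  expect_equal(summ_c$delta_mean[, , "VIS2"], summ$delta_mean[, , "VIS2"] + 0.05,
               tolerance = 1e-12)
  others <- setdiff(seq_len(12), 2)
  expect_equal(summ_c$delta_mean[, , others], summ$delta_mean[, , others],
               tolerance = 1e-12)
})

test_that("rankings match a brute-force oracle and break ties canonically", {
  # two-network example: RMS 0.3 vs 0.1
  d <- array(NA_real_, c(1, 2, 2))
  d[1, , 1] <- c(0.3, -0.3); d[1, , 2] <- c(0.1, 0.1)
  summ <- make_summary(d, network_names = c("SMM", "LAN"),
                       epoch_names = c("story", "math"))
  rk <- rank_networks(summ)
  expect_equal(rk$network, c("SMM", "LAN"))
  expect_equal(rk$rms_delta, c(0.3, 0.1), tolerance = 1e-12)

  # all-zero summary keeps canonical order
  dz <- array(0, c(2, 3, 4))
  summz <- make_summary(dz, network_names = c("DAN", "VIS1", "LAN", "SMM"),
                        epoch_names = c("math", "story", "rel"))
  expect_equal(rank_networks(summz)$network, c("VIS1", "SMM", "DAN", "LAN"))
  expect_equal(rank_epochs(summz)$epoch, c("story", "math", "rel"))

  # random table against an independent brute-force computation
  set.seed(5)
  dr <- array(rnorm(4 * 7 * 5, sd = 0.2), c(4, 7, 5))
  nets <- c("VIS1", "SMM", "LAN", "DMN", "ORA")
  eps <- c("faces", "story", "math", "rel", "social", "0bk", "2bk")
  summr <- make_summary(dr, network_names = nets, epoch_names = eps)
  cohort <- apply(dr, c(2, 3), mean)               # epochs x networks
  rms_oracle <- sqrt(colMeans(cohort^2))
  mean_oracle <- rowMeans(cohort)
  rk_n <- rank_networks(summr); rk_e <- rank_epochs(summr)
  expect_equal(rk_n$network, nets[order(-rms_oracle)])
  expect_equal(rk_n$rms_delta, sort(rms_oracle, decreasing = TRUE),
               tolerance = 1e-12)
  expect_equal(rk_e$epoch, eps[order(-mean_oracle)])
  expect_equal(rk_e$mean_delta, sort(mean_oracle, decreasing = TRUE),
               tolerance = 1e-12)

  # one uniformly positive epoch ranks first, its mirror last
  d2 <- array(0, c(1, 3, 2)); d2[1, 1, ] <- 0.2; d2[1, 3, ] <- -0.2
  summ2 <- make_summary(d2, network_names = c("LAN", "SMM"),
                        epoch_names = c("story", "math", "lh"))
  expect_equal(rank_epochs(summ2)$epoch, c("story", "math", "lh"))
})

test_that("task-mean centering removes each task's shared asymmetry", {
  co <- tiny_cohort(n_subjects = 10, n_vertices = 120, seed = 31)
  summ <- aggregate_by_network(compute_asymmetry(co$dataset), co$partition)
  m <- lateralize:::cohort_mean_delta(summ, "task_mean")
  motor <- c("lh", "rh", "lf", "rf", "t")
  expect_equal(unname(colMeans(m[motor, ])), rep(0, 12), tolerance = 1e-12)
  # raw mode leaves epochs untouched
  m0 <- lateralize:::cohort_mean_delta(summ, "none")
  expect_false(isTRUE(all.equal(unname(colMeans(m0[motor, ])), rep(0, 12))))
})

test_that("long-format export covers every cell once", {
  d <- array(rnorm(2 * 3 * 2), c(2, 3, 2))
  summ <- make_summary(d, network_names = c("LAN", "SMM"),
                       epoch_names = c("story", "math", "rel"))
  long <- summary_long(summ)
  expect_equal(nrow(long), 2 * 3 * 2)
  expect_equal(long$delta[long$subject == "sub01" & long$epoch == "math" &
                            long$network == "SMM"],
               d[1, 2, 2])
})
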
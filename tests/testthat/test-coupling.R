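test_that("vertex-wise coupling map averages per-epoch correlations", {
  # identical (up to scale/shift) measures give mean r = 1
  set.seed(3)
  n <- 20; V <- 5; E <- 3
  delta <- array(rnorm(n * E * V), c(n, E, V))
  amp <- delta * 2 + 5
  res <- make_asym(delta, amplitude = amp)
  vmap <- vertexwise_amp_asym_map(res)
  expect_equal(as.numeric(vmap), rep(1, V), tolerance = 1e-12)

  # epochs with r = 1 and r = 0 average to 0.5 (2-epoch contract)
  x <- rnorm(n); y <- rnorm(n)
  y_orth <- y - sum((x - mean(x)) * y) / sum((x - mean(x))^2) * (x - mean(x))
  y_orth <- y_orth - mean(y_orth) + 1   # exactly uncorrelated with x
  d2 <- array(NA_real_, c(n, 2, 1)); a2 <- d2
  d2[, 1, 1] <- x;      a2[, 1, 1] <- 2 * x + 3   # r = 1
  d2[, 2, 1] <- y_orth; a2[, 2, 1] <- x           # r = 0
  vmap2 <- vertexwise_amp_asym_map(make_asym(d2, a2))
  expect_equal(as.numeric(vmap2), 0.5, tolerance = 1e-12)

  # independent measures: mean r within 3 SE of zero
  set.seed(11)
  n2 <- 100
  dd <- array(rnorm(n2 * 17 * 30), c(n2, 17, 30))
  aa <- array(rnorm(n2 * 17 * 30), c(n2, 17, 30))
  v3 <- vertexwise_amp_asym_map(make_asym(dd, aa))
  se <- sd(v3) / sqrt(length(v3))
  expect_lt(abs(mean(v3)), 3 * se + 3 / sqrt(n2 * 17))
  # zero-variance epoch excluded from a vertex's mean
  d4 <- array(rnorm(n * 2), c(n, 2, 1)); a4 <- d4
  a4[, 2, 1] <- 7
  v4 <- vertexwise_amp_asym_map(make_asym(d4, a4))
  expect_equal(as.numeric(v4), 1)
})

test_that("amplitude binning forms rank-contiguous full groups", {
  set.seed(8)
  d <- array(rnorm(30 * 2 * 2, sd = 0.1), c(30, 2, 2))
  a <- array(rexp(30 * 2 * 2) + 0.5, c(30, 2, 2))
  summ <- make_summary(d, a)
  g <- bin_subjects(summ, group_size = 10)
  expect_equal(g$n_groups, 3)
  expect_equal(g$n_dropped, 0)
  # group mean amplitudes are non-decreasing and groups are rank-contiguous
  for (e in 1:2) for (k in 1:2) {
    expect_true(all(diff(g$amplitude[, e, k]) >= 0))
    ord <- order(a[, e, k])
    expect_equal(g$assignment[ord, e, k], rep(1:3, each = 10))
  }
  # remainder subjects are dropped with a message
  summ25 <- make_summary(d[1:25, , , drop = FALSE], a[1:25, , , drop = FALSE])
  expect_message(g25 <- bin_subjects(summ25, 10), "5 subject")
  expect_equal(g25$n_groups, 2)
  expect_equal(sum(!is.na(g25$assignment[, 1, 1])), 20)
  expect_error(bin_subjects(summ, group_size = 1), "parameter error")
})

test_that("binned correlations respond to planted coupling and antisymmetry", {
  # deterministic linear coupling: r = 1 in every cell
  set.seed(10)
  f <- rnorm(50)
  a <- array(rep(1 + 0.2 * f, 2), c(50, 1, 2))
  d <- array(rep(0.1 + 0.5 * f, 2), c(50, 1, 2))
  summ <- make_summary(d, a)
  bc <- binned_correlation(bin_subjects(summ, 10))
  expect_equal(unname(as.vector(bc$r)), c(1, 1), tolerance = 1e-9)
  # negating asymmetry flips every correlation sign exactly
  bc_neg <- binned_correlation(bin_subjects(make_summary(-d, a), 10))
  expect_equal(bc_neg$r, -bc$r, tolerance = 1e-12)
  expect_error(binned_correlation(bin_subjects(make_summary(
    d[1:20, , , drop = FALSE], a[1:20, , , drop = FALSE]), 10)),
    "insufficient-data")
})

test_that("accuracy correlations recover exact linear structure and control the family", {
  co <- tiny_cohort(n_subjects = 40, n_vertices = 120, seed = 17)
  summ <- aggregate_by_network(compute_asymmetry(co$dataset), co$partition)
  tab <- co$subjects
  # accuracy as an exact linear function of LAN story amplitude
  tab$acc_story <- pmin(100, pmax(0,
    50 + 10 * summ$amplitude_mean[, "story", "LAN"]))
  cm <- accuracy_correlations(summ, tab, measure = "amplitude")
  expect_equal(cm$r["LAN", "story"], 1, tolerance = 1e-9)
  # Bonferroni family: 9 networks x 12 scored epochs -> alpha / 108
  expect_equal(cm$threshold, 0.05 / 108, tolerance = 1e-15)
  expect_equal(dim(cm$r), c(9L, 12L))
  # constant accuracy leaves the cell undefined
  tab$acc_math <- rep(80, nrow(tab))
  cm2 <- accuracy_correlations(summ, tab, measure = "delta")
  expect_true(all(is.na(cm2$r[, "math"])))
  long <- correlation_long(cm)
  expect_equal(nrow(long), 108)
})

test_that("pearson helper agrees with the covariance formula", {
  set.seed(19)
  for (i in 1:20) {
    x <- rnorm(30); y <- rnorm(30)
    r <- lateralize:::pearson_test(x, y)$r
    oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r, oracle, tolerance = 1e-12)
  }
})

test_that("AIC table matches an independently coded formula and selects cubic", {
  # fixed 10-point dataset; oracle via raw-power normal equations
  x <- c(0.5, 1.1, 1.7, 2.0, 2.6, 3.1, 3.8, 4.2, 4.9, 5.5)
  y <- c(1.2, 2.1, 2.9, 3.1, 4.4, 4.9, 6.2, 6.4, 7.8, 8.1)
  out <- compare_polynomial_fits(x, y, max_degree = 3)
  for (deg in 1:3) {
    X <- outer(x, 0:deg, `^`)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    rss <- sum((y - X %*% beta)^2)
    aic <- 10 * log(rss / 10) + 2 * (deg + 2)
    expect_equal(out$table$aic[deg], aic, tolerance = 1e-8)
  }
  expect_equal(out$table$delta_aic[1], 0)
  expect_equal(out$table$delta_aic_pct[2],
               100 * (out$table$aic[2] - out$table$aic[1]) / abs(out$table$aic[1]),
               tolerance = 1e-12)
  # strongly cubic data select degree 3
  set.seed(6)
  xc <- runif(100, -1, 1); yc <- xc^3 + rnorm(100, sd = 0.02)
  expect_equal(compare_polynomial_fits(xc, yc)$selected, 3)
  expect_error(compare_polynomial_fits(rep(1, 10), rnorm(10)), "constant")
  expect_error(compare_polynomial_fits(x[1:4], y[1:4]), "max_degree")
})
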
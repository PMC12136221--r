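test_that("predictor and response matrices honor the documented layout", {
  co <- tiny_cohort(n_subjects = 12, n_vertices = 120, seed = 23)
  summ <- aggregate_by_network(compute_asymmetry(co$dataset), co$partition)
  X <- build_predictor_matrix(summ, "amplitude")
  expect_equal(ncol(X), 153)          # 9 networks x 17 epochs
  expect_equal(nrow(X), 12)
  lb <- attr(X, "labels")
  # epoch-major order, canonical network order within each epoch
  expect_equal(lb$epoch[1:9], rep("faces", 9))
  expect_equal(lb$network[1:9], pls_networks())
  expect_equal(colnames(X)[10], "shapes.VIS1")
  expect_equal(X[, "story.LAN"],
               summ$amplitude_mean[, "story", "LAN"], ignore_attr = TRUE)
  # a reduced request keeps the documented order
  X2 <- build_predictor_matrix(summ, "delta", networks = c("LAN", "VIS1"))
  expect_equal(colnames(X2)[1:2], c("faces.VIS1", "faces.LAN"))
  expect_equal(ncol(X2), 34)
  # excluded networks are rejected by default
  expect_error(build_predictor_matrix(summ, "delta", networks = c("LAN", "ORA")),
               "excluded")
  expect_error(build_predictor_matrix(summ, "delta", networks = c("LAN", "XXX")),
               "absent")

  Y <- build_accuracy_matrix(co$subjects)
  expect_equal(dim(Y), c(12L, 12L))
  expect_equal(colnames(Y), scored_epochs())
  # a missing cell is imputed to the column mean and recorded in the mask
  tab <- co$subjects
  tab$acc_story[3] <- NA
  Y2 <- build_accuracy_matrix(tab)
  expect_true(attr(Y2, "imputed")[3, "story"])
  expect_equal(unname(Y2[3, "story"]), mean(tab$acc_story, na.rm = TRUE))
  tab$acc_math <- NA_real_
  expect_error(build_accuracy_matrix(tab), "fully missing")
})

test_that("an exact rank-1 linear map is captured by one component", {
  # one latent score drives all predictors and the response noiselessly
  set.seed(15)
  t0 <- rnorm(30)
  X <- outer(t0, runif(8, 0.5, 2))
  y <- X %*% rnorm(8)
  fit <- pls_fit(X, y, n_components = 3, cv_folds = 0)
  expect_equal(fit$explained_y[1], 1, tolerance = 1e-8)
  expect_equal(fit$ncomp, 1)       # deflation leaves nothing to extract
  expect_equal(unname(predict(fit, X, ncomp = 1)), unname(y), tolerance = 1e-6)
})

test_that("NIPALS matches the SVD deflation oracle on a fixed problem", {
  set.seed(30)
  X <- matrix(rnorm(30 * 8), 30, 8)
  B <- matrix(rnorm(8 * 3), 8, 3)
  Y <- X %*% B + 0.5 * matrix(rnorm(30 * 3), 30, 3)
  fit <- pls_fit(X, Y, n_components = 5, cv_folds = 0)
  oracle <- svd_pls_oracle(X, Y, 5)
  expect_equal(fit$explained_y, oracle$explained_y, tolerance = 1e-6)
  expect_equal(abs(fit$scores), abs(oracle$scores), tolerance = 1e-5)
  # X-scores are mutually orthogonal
  G <- crossprod(fit$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # cumulative explained variance is non-decreasing
  expect_true(all(diff(fit$explained_y) >= -1e-12))
})

test_that("prediction reproduces training fits and enforces the schema", {
  set.seed(40)
  X <- matrix(rnorm(40 * 6), 40, 6, dimnames = list(NULL, paste0("x", 1:6)))
  Y <- X %*% matrix(rnorm(12), 6, 2) + 0.3 * matrix(rnorm(80), 40, 2)
  fit <- pls_fit(X, Y, n_components = 4, cv_folds = 5, seed = 2)
  expect_equal(predict(fit, X), fitted(fit), tolerance = 1e-8)
  # a duplicated training row predicts that row's fitted value
  expect_equal(predict(fit, X[c(7, 7), ])[1, ], fitted(fit)[7, ],
               tolerance = 1e-10)
  Xbad <- X; colnames(Xbad) <- paste0("z", 1:6)
  expect_error(predict(fit, Xbad), "schema error")
  expect_error(pls_fit(X, Y, n_components = 40), "parameter error")
  Xzv <- cbind(X, x7 = 1)
  expect_warning(pls_fit(Xzv, Y, n_components = 2, cv_folds = 0),
                 "zero-variance")
  # coefficients reproduce predictions on the original scale
  B <- coef(fit)
  manual <- X %*% B + matrix(attr(B, "intercept"), 40, 2, byrow = TRUE)
  expect_equal(unname(predict(fit, X)), unname(manual), tolerance = 1e-8)
})

test_that("cross-validation is seeded, nested, and honest under the null", {
  set.seed(50)
  X <- matrix(rnorm(200 * 20), 200, 20)
  Y <- matrix(rnorm(200 * 3), 200, 3)
  fit1 <- pls_fit(X, Y, n_components = 6, cv_folds = 10, seed = 5)
  fit2 <- pls_fit(X, Y, n_components = 6, cv_folds = 10, seed = 5)
  expect_identical(fit1$cv, fit2$cv)
  expect_identical(fit1$coefficients, fit2$coefficients)
  # independent noise: out-of-fold explained variance stays at chance
  expect_true(all(fit1$cv$q2 <= 0.05))
  # and never beats within-sample by more than Monte-Carlo noise
  expect_true(all(fit1$cv$q2 <= fit1$explained_y + 0.05))
})

test_that("two-cohort validation transfers a planted map and is symmetric for identical cohorts", {
  co <- tiny_cohort(n_subjects = 60, n_vertices = 120, seed = 61)
  summ <- aggregate_by_network(compute_asymmetry(co$dataset), co$partition)
  cv <- cross_sample_validate(summ, summ, co$subjects, co$subjects,
                              measure = "amplitude", target = "asymmetry",
                              n_components = 6, cv_folds = 0, seed = 3)
  # replication = exact copy of discovery: all four evaluations coincide
  expect_equal(cv$within_discovery$table$r,
               cv$discovery_to_replication$table$r, tolerance = 1e-12)
  expect_equal(cv$within_replication$table$r,
               cv$replication_to_discovery$table$r, tolerance = 1e-12)
  expect_s3_class(cv$fit_discovery, "pls_fit")
})

test_that("component scores reflect planted covariate structure", {
  set.seed(70)
  X <- matrix(rnorm(50 * 5), 50, 5)
  y <- X[, 1] + rnorm(50, sd = 0.1)
  fit <- pls_fit(X, y, n_components = 3, cv_folds = 0)
  tab <- make_covariate_table(50)
  # scores equal to standardized age: correlation 1, null sex effect
  fit2 <- fit
  fit2$scores[, 1] <- scale(tab$age)
  ct <- component_covariate_tests(fit2, tab)
  expect_equal(ct$r_age[1], 1, tolerance = 1e-10)
  expect_lt(ct$p_age[1], 1e-12)
  expect_equal(nrow(ct), 3)
  # Bonferroni adjustment across components
  expect_equal(ct$p_age_adj, pmin(1, ct$p_age * 3))
  tab_f <- tab; tab_f$sex <- "F"
  ct_f <- component_covariate_tests(fit2, tab_f)
  expect_true(all(is.na(ct_f$t_sex)))
})

test_that("pattern ranking orders rows by RMS and columns by mean", {
  m <- matrix(c(0.9, 0.1, 0.5, 0.2, -0.8, 0.3), 2, 3,
              dimnames = list(c("A", "B"), c("e1", "e2", "e3")))
  rk <- rank_pattern_matrix(m)
  rms <- sqrt(rowMeans(m^2)); mu <- colMeans(m)
  expect_equal(rownames(rk), names(sort(rms, decreasing = TRUE)))
  expect_equal(colnames(rk), names(sort(mu, decreasing = TRUE)))
})
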
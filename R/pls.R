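#' Build the network-by-epoch predictor matrix
#'
#' One column per (epoch, network) cell of the network summary, rows =
#' subjects. Columns are epoch-major: all networks (in canonical order) for
#' the first epoch, then the second, and so on; with the 9 model networks
#' and 17 epochs this yields 153 predictors. The ORA, VMM, and PMM networks
#' are excluded from prediction models by default (small, diffusely
#' activated partitions) and requesting them is an error unless
#' `allow_excluded = TRUE`. Missing cells (fully masked networks) are
#' imputed to the column mean; the imputation mask is kept in the
#' `"imputed"` attribute.
#'
#' @param summary A `network_summary`.
#' @param measure `"amplitude"` or `"delta"`.
#' @param networks Networks to include (default the 9 model networks).
#' @param allow_excluded Permit ORA/VMM/PMM (default FALSE).
#' @return Numeric matrix with a `"labels"` attribute (data frame of each
#'   column's network and epoch).
#' @export
build_predictor_matrix <- function(summary, measure = c("amplitude", "delta"),
                                   networks = pls_networks(),
                                   allow_excluded = FALSE) {
  measure <- match.arg(measure)
  if (!allow_excluded) {
    bad <- intersect(networks, pls_excluded_networks())
    if (length(bad))
      stop("schema error: network(s) excluded from prediction models: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  missing_nets <- setdiff(networks, summary$network_names)
  if (length(missing_nets))
    stop("schema error: network(s) absent from summary: ",
         paste(missing_nets, collapse = ", "), call. = FALSE)
  networks <- networks[order(canonical_position(networks, canonical_networks()))]
  eps <- summary$epoch_names
  vals <- if (measure == "delta") summary$delta_mean else summary$amplitude_mean
  n <- dim(vals)[1]
  labels <- expand.grid(network = networks, epoch = eps,
                        stringsAsFactors = FALSE)[, c("network", "epoch")]
  X <- matrix(NA_real_, n, nrow(labels))
  for (j in seq_len(nrow(labels))) {
    ki <- match(labels$network[j], summary$network_names)
    ei <- match(labels$epoch[j], summary$epoch_names)
    X[, j] <- vals[, ei, ki]
  }
  colnames(X) <- paste(labels$epoch, labels$network, sep = ".")
  imputed <- is.na(X)
  if (any(imputed)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(imputed) > 0)) X[imputed[, j], j] <- mu[j]
  }
  attr(X, "labels") <- labels
  attr(X, "imputed") <- imputed
  attr(X, "measure") <- measure
  X
}

#' Build the task-accuracy response matrix
#'
#' One column per scored epoch, in canonical order. Missing accuracy cells
#' are imputed to the column mean; the mask is retained so imputed cells can
#' be excluded from prediction evaluation.
#'
#' @param table Subject table with `acc_<epoch>` columns.
#' @param epochs Scored epochs to include (default all 12).
#' @return Numeric subjects x epochs matrix with an `"imputed"` attribute.
#' @export
build_accuracy_matrix <- function(table, epochs = scored_epochs()) {
  cols <- paste0("acc_", epochs)
  miss <- setdiff(cols, names(table))
  if (length(miss))
    stop("schema error: accuracy column(s) missing: ",
         paste(miss, collapse = ", "), call. = FALSE)
  Y <- as.matrix(table[cols])
  colnames(Y) <- epochs
  fully_missing <- colSums(!is.na(Y)) == 0
  if (any(fully_missing))
    stop("schema error: fully missing accuracy column(s): ",
         paste(epochs[fully_missing], collapse = ", "), call. = FALSE)
  imputed <- is.na(Y)
  if (any(imputed)) {
    mu <- colMeans(Y, na.rm = TRUE)
    for (j in which(colSums(imputed) > 0)) Y[imputed[, j], j] <- mu[j]
  }
  attr(Y, "imputed") <- imputed
  Y
}

# Core NIPALS extraction with X-deflation on already centered/scaled data.
# Returns weights W, X-loadings P, Y-loadings C, scores TT, and cumulative
# explained variance of Y and X per component.
nipals_pls <- function(E, F, ncomp, tol = 1e-20, max_iter = 1000L) {
  n <- nrow(E); p <- ncol(E); q <- ncol(F)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, q, ncomp); TT <- matrix(0, n, ncomp)
  ssy0 <- sum(F^2); ssx0 <- sum(E^2)
  evy <- numeric(ncomp); evx <- numeric(ncomp)
  a <- 0L
  while (a < ncomp) {
    u <- F[, which.max(apply(F, 2, stats::var))]
    if (sum(u^2) < .Machine$double.eps) break
    tt <- NULL
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(E, u)
      wn <- sqrt(sum(w^2))
      if (wn < .Machine$double.eps) break
      w <- w / wn
      tt <- as.numeric(E %*% w)
      cc <- as.numeric(crossprod(F, tt)) / sum(tt^2)
      if (q == 1L) break
      u <- as.numeric(F %*% cc) / sum(cc^2)
      if (sum((tt - t_old)^2) / max(sum(tt^2), .Machine$double.eps) < tol) break
      t_old <- tt
    }
    if (is.null(tt) || sum(tt^2) < .Machine$double.eps) break
    a <- a + 1L
    pp <- as.numeric(crossprod(E, tt)) / sum(tt^2)
    E <- E - tcrossprod(tt, pp)
    F <- F - tcrossprod(tt, cc)
    W[, a] <- w; P[, a] <- pp; C[, a] <- cc; TT[, a] <- tt
    evy[a] <- 1 - sum(F^2) / ssy0
    evx[a] <- 1 - sum(E^2) / ssx0
  }
  if (a < ncomp) {
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    C <- C[, seq_len(a), drop = FALSE]; TT <- TT[, seq_len(a), drop = FALSE]
    evy <- evy[seq_len(a)]; evx <- evx[seq_len(a)]
  }
  list(W = W, P = P, C = C, scores = TT,
       explained_y = evy, explained_x = evx, ncomp = a)
}

# Regression coefficients (standardized scale) for each component count.
pls_coefficients <- function(W, P, C) {
  A <- ncol(W)
  lapply(seq_len(A), function(a) {
    Wa <- W[, 1:a, drop = FALSE]; Pa <- P[, 1:a, drop = FALSE]
    Ca <- C[, 1:a, drop = FALSE]
    Wa %*% solve(crossprod(Pa, Wa), t(Ca))
  })
}

#' Fit a partial least squares regression model
#'
#' Columns of `X` and `Y` are centered and scaled to unit variance using the
#' training statistics; components are then extracted by the iterative
#' NIPALS covariance-maximization scheme with X-deflation, giving mutually
#' orthogonal X-scores. Out-of-sample performance per component count is
#' estimated by k-fold cross-validation with a seeded random fold
#' assignment.
#'
#' @param X Predictor matrix (subjects x predictors), e.g. from
#'   [build_predictor_matrix()].
#' @param Y Response matrix or vector (subjects x responses).
#' @param n_components Number of components (default 12; must not exceed
#'   `min(n_subjects - 1, n_predictors)`).
#' @param cv_folds Folds for cross-validation (default 10; >= 2). Use 0 to
#'   skip CV.
#' @param seed Integer seed for the fold assignment.
#' @param scale Scale columns to unit variance (default TRUE).
#' @return An object of class `pls_fit` with weights, loadings, scores,
#'   per-component regression coefficients, cumulative explained variance of
#'   the response and of the predictors, and a CV summary
#'   (`cv$q2`: out-of-fold explained variance per component count).
#' @export
pls_fit <- function(X, Y, n_components = 12, cv_folds = 10, seed = 1L,
                    scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1)
  Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance predictor column(s) dropped",
            call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (n_components > min(n - 1, ncol(X)))
    stop("parameter error: n_components exceeds min(n_subjects - 1, ",
         "n_predictors)", call. = FALSE)
  xc <- colMeans(X); yc <- colMeans(Y)
  xs <- if (scale) apply(X, 2, stats::sd) else rep(1, ncol(X))
  ys <- if (scale) apply(Y, 2, stats::sd) else rep(1, ncol(Y))
  ys[ys == 0] <- 1
  E <- sweep(sweep(X, 2, xc), 2, xs, `/`)
  F <- sweep(sweep(Y, 2, yc), 2, ys, `/`)
  core <- nipals_pls(E, F, n_components)
  coefs <- pls_coefficients(core$W, core$P, core$C)
  fit <- structure(list(
    ncomp = core$ncomp, weights = core$W, x_loadings = core$P,
    y_loadings = core$C, scores = core$scores, coefficients = coefs,
    explained_y = core$explained_y, explained_x = core$explained_x,
    x_center = xc, x_scale = xs, y_center = yc, y_scale = ys,
    x_names = colnames(X), y_names = colnames(Y),
    labels = attr(X, "labels"), n = n, scale = scale,
    cv = NULL, seed = as.integer(seed)), class = "pls_fit")
  if (cv_folds >= 2) fit$cv <- pls_cv(X, Y, n_components, cv_folds, seed, scale)
  fit
}

pls_cv <- function(X, Y, ncomp, folds, seed, scale) {
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  press <- matrix(0, ncomp, ncol(Y))
  sstot <- matrix(0, ncomp, ncol(Y))
  for (fk in seq_len(folds)) {
    tr <- fold != fk; te <- !tr
    ftr <- pls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
                   n_components = min(ncomp, sum(tr) - 1, ncol(X)),
                   cv_folds = 0, scale = scale)
    for (a in seq_len(ftr$ncomp)) {
      pred <- predict(ftr, X[te, , drop = FALSE], ncomp = a)
      press[a, ] <- press[a, ] + colSums((Y[te, , drop = FALSE] - pred)^2)
      sstot[a, ] <- sstot[a, ] +
        colSums(sweep(Y[te, , drop = FALSE], 2, colMeans(Y[tr, , drop = FALSE]))^2)
    }
  }
  q2 <- 1 - rowSums(press) / rowSums(sstot)
  data.frame(ncomp = seq_len(ncomp), q2 = q2)
}

#' Predict responses from a fitted PLS model
#'
#' Training centering/scaling is applied to the new predictors and
#' predictions are returned on the original response scale.
#'
#' @param object A `pls_fit`.
#' @param newdata Predictor matrix with the same columns (by name) as the
#'   training matrix.
#' @param ncomp Number of components to use (default: all fitted).
#' @param ... Unused.
#' @return Matrix of predicted responses.
#' @export
predict.pls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$x_names)) {
    if (is.null(colnames(newdata)) || !all(object$x_names %in% colnames(newdata)))
      stop("schema error: predictor columns do not match training columns",
           call. = FALSE)
    newdata <- newdata[, object$x_names, drop = FALSE]
  }
  stopifnot(ncomp >= 1, ncomp <= object$ncomp)
  Xs <- sweep(sweep(newdata, 2, object$x_center), 2, object$x_scale, `/`)
  Ys <- Xs %*% object$coefficients[[ncomp]]
  out <- sweep(sweep(Ys, 2, object$y_scale, `*`), 2, object$y_center, `+`)
  colnames(out) <- object$y_names
  out
}

#' @export
fitted.pls_fit <- function(object, ...) {
  Ys <- object$scores %*% t(object$y_loadings)
  sweep(sweep(Ys, 2, object$y_scale, `*`), 2, object$y_center, `+`)
}

#' @export
coef.pls_fit <- function(object, ncomp = object$ncomp, ...) {
  B <- object$coefficients[[ncomp]]
  # back-transform to the original scales of X and Y
  B <- diag(1 / object$x_scale, nrow = length(object$x_scale)) %*% B %*%
    diag(object$y_scale, nrow = length(object$y_scale))
  dimnames(B) <- list(object$x_names, object$y_names)
  attr(B, "intercept") <- object$y_center -
    as.numeric(object$x_center %*% B)
  B
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("PLS regression fit:", length(x$x_names), "predictors ->",
      length(x$y_names), "responses,", x$ncomp, "components, n =", x$n, "\n")
  cat("  cumulative explained response variance:",
      paste(sprintf("%.3f", x$explained_y), collapse = " "), "\n")
  if (!is.null(x$cv))
    cat("  out-of-fold explained variance at", x$ncomp, "components:",
        sprintf("%.3f", x$cv$q2[x$ncomp]), "\n")
  invisible(x)
}

#' @export
summary.pls_fit <- function(object, ...) {
  tab <- data.frame(component = seq_len(object$ncomp),
                    explained_y_cum = object$explained_y,
                    explained_x_cum = object$explained_x)
  if (!is.null(object$cv)) tab$q2 <- object$cv$q2[seq_len(object$ncomp)]
  structure(list(table = tab, n = object$n,
                 p = length(object$x_names), q = length(object$y_names)),
            class = "summary.pls_fit")
}

#' @export
print.summary.pls_fit <- function(x, ...) {
  cat("PLS fit: n =", x$n, ", predictors =", x$p, ", responses =", x$q, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank a network x epoch pattern matrix for display
#'
#' Rows (networks) are ordered by root-mean-square value descending and
#' columns (epochs) by mean value descending.
#'
#' @param m Numeric matrix with network rows and epoch columns.
#' @return The reordered matrix.
#' @export
rank_pattern_matrix <- function(m) {
  rord <- order(-sqrt(rowMeans(m^2, na.rm = TRUE)))
  cord <- order(-colMeans(m, na.rm = TRUE))
  m[rord, cord, drop = FALSE]
}

#' Correlate observed and predicted responses per variable
#'
#' Pearson correlation between observed and predicted values for every
#' response variable, with significance after the stated multiplicity
#' control over all evaluated variables. Cells imputed in the observed
#' matrix (its `"imputed"` attribute, or `exclude_mask`) are excluded. When
#' the responses carry (network, epoch) labels, the r matrix is also
#' returned ranked by RMS across networks (rows) and mean across epochs
#' (columns).
#'
#' @param Y_obs,Y_pred Observed and predicted response matrices.
#' @param alpha Family significance level (default 0.05).
#' @param control `"bonferroni"` (default) or `"uncorrected"`.
#' @param exclude_mask Optional logical matrix of cells to exclude.
#' @return An object of class `prediction_evaluation`: data frame of
#'   variable, r, p, n, significant; plus `pattern` (ranked r matrix) when
#'   labels are available.
#' @export
evaluate_prediction <- function(Y_obs, Y_pred, alpha = 0.05,
                                control = c("bonferroni", "uncorrected"),
                                exclude_mask = attr(Y_obs, "imputed")) {
  control <- match.arg(control)
  Y_obs_m <- as.matrix(Y_obs); Y_pred <- as.matrix(Y_pred)
  stopifnot(identical(dim(Y_obs_m), dim(Y_pred)))
  if (nrow(Y_obs_m) < 3) stop("need >= 3 rows", call. = FALSE)
  if (!is.null(exclude_mask)) Y_obs_m[exclude_mask] <- NA_real_
  q <- ncol(Y_obs_m)
  res <- lapply(seq_len(q), function(j) pearson_test(Y_obs_m[, j], Y_pred[, j]))
  r <- vapply(res, `[[`, numeric(1), "r")
  p <- vapply(res, `[[`, numeric(1), "p")
  n <- vapply(res, `[[`, numeric(1), "n")
  thr <- if (control == "bonferroni") alpha / q else alpha
  vars <- colnames(Y_obs_m)
  if (is.null(vars)) vars <- paste0("V", seq_len(q))
  out <- data.frame(variable = vars, r = r, p = p, n = n,
                    significant = !is.na(p) & p < thr,
                    stringsAsFactors = FALSE)
  pattern <- NULL
  labels <- attr(Y_obs, "labels")
  if (!is.null(labels) && nrow(labels) == q) {
    nets <- unique(labels$network); eps <- unique(labels$epoch)
    rm_ <- matrix(NA_real_, length(nets), length(eps),
                  dimnames = list(nets, eps))
    rm_[cbind(match(labels$network, nets), match(labels$epoch, eps))] <- r
    pattern <- rank_pattern_matrix(rm_)
  }
  structure(list(table = out, pattern = pattern, control = control,
                 threshold = thr), class = "prediction_evaluation")
}

#' @export
print.prediction_evaluation <- function(x, ...) {
  cat("Prediction evaluation (", nrow(x$table), "responses, control:",
      x$control, ")\n")
  cat("  significant:", sum(x$table$significant), " median r:",
      format(stats::median(x$table$r, na.rm = TRUE), digits = 3), "\n")
  invisible(x)
}

#' Two-cohort (discovery/replication) cross-validation of a PLS model
#'
#' Fits the model on the discovery cohort and evaluates on the replication
#' cohort, then reverses the roles, reporting within-sample (training) and
#' out-of-sample evaluations for both directions.
#'
#' @param summary_d,summary_r `network_summary` objects for the two cohorts.
#' @param table_d,table_r Matching subject tables.
#' @param measure Predictor measure: `"amplitude"` or `"delta"`.
#' @param target `"asymmetry"` (responses = network x epoch asymmetry) or
#'   `"accuracy"` (responses = 12 scored-epoch accuracies).
#' @param n_components,cv_folds,seed,alpha,control Passed through to
#'   [pls_fit()] and [evaluate_prediction()].
#' @return An object of class `cross_validation`: fits and evaluations
#'   (`within_discovery`, `discovery_to_replication`, `within_replication`,
#'   `replication_to_discovery`).
#' @export
cross_sample_validate <- function(summary_d, summary_r, table_d, table_r,
                                  measure = c("amplitude", "delta"),
                                  target = c("asymmetry", "accuracy"),
                                  n_components = 12, cv_folds = 10, seed = 1L,
                                  alpha = 0.05, control = "bonferroni") {
  measure <- match.arg(measure); target <- match.arg(target)
  Xd <- build_predictor_matrix(summary_d, measure)
  Xr <- build_predictor_matrix(summary_r, measure)
  if (!identical(colnames(Xd), colnames(Xr)))
    stop("schema error: cohort predictor schemas differ", call. = FALSE)
  mk_y <- function(summary, table) {
    if (target == "asymmetry") build_predictor_matrix(summary, "delta")
    else build_accuracy_matrix(table)
  }
  Yd <- mk_y(summary_d, table_d); Yr <- mk_y(summary_r, table_r)
  if (!identical(colnames(Yd), colnames(Yr)))
    stop("schema error: cohort response schemas differ", call. = FALSE)
  fit_d <- pls_fit(Xd, Yd, n_components, cv_folds, seed)
  fit_r <- pls_fit(Xr, Yr, n_components, cv_folds, seed)
  ev <- function(yobs, ypred)
    evaluate_prediction(yobs, ypred, alpha = alpha, control = control)
  structure(list(
    fit_discovery = fit_d, fit_replication = fit_r,
    within_discovery = ev(Yd, predict(fit_d, Xd)),
    discovery_to_replication = ev(Yr, predict(fit_d, Xr)),
    within_replication = ev(Yr, predict(fit_r, Xr)),
    replication_to_discovery = ev(Yd, predict(fit_r, Xd)),
    measure = measure, target = target), class = "cross_validation")
}

#' @export
print.cross_validation <- function(x, ...) {
  cat("Two-cohort cross-validation (", x$measure, "->", x$target, ")\n")
  for (nm in c("within_discovery", "discovery_to_replication",
               "within_replication", "replication_to_discovery"))
    cat(sprintf("  %-26s median r = %.3f\n", nm,
                stats::median(x[[nm]]$table$r, na.rm = TRUE)))
  invisible(x)
}

#' Age and sex effects on PLS component scores
#'
#' Per component: Pearson correlation of scores with age, and a two-sample
#' t-test of scores by sex, with Bonferroni adjustment across components
#' (separately per covariate family).
#'
#' @param fit A `pls_fit` whose scores cover the subjects of `table`.
#' @param table Subject table aligned with the training rows.
#' @return Data frame with one row per component: `r_age`, `p_age`,
#'   `p_age_adj`, `t_sex`, `p_sex`, `p_sex_adj`.
#' @export
component_covariate_tests <- function(fit, table) {
  stopifnot(inherits(fit, "pls_fit"), nrow(table) == nrow(fit$scores))
  A <- fit$ncomp
  two_sexes <- length(unique(table$sex)) == 2
  rows <- lapply(seq_len(A), function(a) {
    sc <- fit$scores[, a]
    ag <- pearson_test(sc, table$age)
    if (two_sexes && stats::sd(sc) > 0) {
      tt <- stats::t.test(sc ~ table$sex)
      ts <- unname(tt$statistic); ps <- tt$p.value
    } else {
      ts <- NA_real_; ps <- NA_real_
    }
    data.frame(component = a, r_age = ag$r, p_age = ag$p,
               t_sex = ts, p_sex = ps)
  })
  out <- do.call(rbind, rows)
  out$p_age_adj <- pmin(1, out$p_age * A)
  out$p_sex_adj <- pmin(1, out$p_sex * A)
  out[, c("component", "r_age", "p_age", "p_age_adj",
          "t_sex", "p_sex", "p_sex_adj")]
}
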
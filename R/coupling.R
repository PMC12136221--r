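# Pairwise-complete Pearson correlation with a two-sided t-based p-value.
pearson_test <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, p = NA_real_, n = n))
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(x, y)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  list(r = r, p = p, n = n)
}

#' Epoch-averaged vertex-wise amplitude-asymmetry correlation map
#'
#' For every vertex and epoch, the Pearson correlation across subjects
#' between bilateral amplitude and the laterality index is computed; the
#' returned map is the simple mean of the per-epoch maps. Epochs in which a
#' vertex has zero variance (or fewer than 3 unmasked subjects) are excluded
#' from that vertex's mean.
#'
#' @param result An `asymmetry_result` (needs >= 3 subjects).
#' @return Numeric vector of per-vertex mean correlations, with the
#'   per-epoch correlation matrix (epochs x vertices) in attribute
#'   `"per_epoch"`.
#' @export
vertexwise_amp_asym_map <- function(result) {
  d <- dim(result$delta)
  if (d[1] < 3) stop("need at least 3 subjects", call. = FALSE)
  E <- d[2]; V <- d[3]
  per_epoch <- matrix(NA_real_, E, V, dimnames = list(result$epoch_names, NULL))
  n <- d[1]
  for (e in seq_len(E)) {
    A <- matrix(result$amplitude[, e, , drop = FALSE], n, V)
    D <- matrix(result$delta[, e, , drop = FALSE], n, V)
    M <- !is.na(A) & !is.na(D)
    A0 <- ifelse(M, A, 0); D0 <- ifelse(M, D, 0)
    nv <- colSums(M)
    sa <- colSums(A0); sd_ <- colSums(D0)
    vara <- colSums(A0^2) - sa^2 / nv
    vard <- colSums(D0^2) - sd_^2 / nv
    cov <- colSums(A0 * D0) - sa * sd_ / nv
    r <- cov / sqrt(vara * vard)
    r[nv < 3 | vara <= 0 | vard <= 0] <- NA_real_
    per_epoch[e, ] <- r
  }
  out <- colMeans(per_epoch, na.rm = TRUE)
  out[is.nan(out)] <- NA_real_
  attr(out, "per_epoch") <- per_epoch
  out
}

#' Rank-and-bin subjects by bilateral amplitude
#'
#' Independently for each task epoch and network, subjects are ranked by
#' their network-mean bilateral amplitude and consecutive blocks of
#' `group_size` form groups; trailing remainder subjects are dropped (the
#' count is reported via a message and stored in the result).
#'
#' @param summary A `network_summary`.
#' @param group_size Subjects per group (default 10; must be >= 2).
#' @return An object of class `binned_groups` with group-mean arrays
#'   `amplitude` and `delta` (groups x epochs x networks), the per-subject
#'   `assignment` array, `group_size`, and `n_groups`.
#' @export
bin_subjects <- function(summary, group_size = 10) {
  if (group_size < 2) stop("parameter error: group_size must be >= 2",
                           call. = FALSE)
  n <- dim(summary$delta_mean)[1]
  if (n < group_size)
    stop("parameter error: fewer subjects than group_size", call. = FALSE)
  E <- length(summary$epoch_names); K <- length(summary$network_names)
  G <- n %/% group_size
  dropped <- n - G * group_size
  if (dropped > 0)
    message(dropped, " subject(s) beyond the last full group dropped from binning")
  assignment <- array(NA_integer_, c(n, E, K))
  amp <- array(NA_real_, c(G, E, K),
               dimnames = list(NULL, summary$epoch_names, summary$network_names))
  del <- amp
  gid <- rep(seq_len(G), each = group_size)
  for (e in seq_len(E)) for (k in seq_len(K)) {
    a <- summary$amplitude_mean[, e, k]
    ord <- order(a, na.last = NA)          # ascending; NA amplitude excluded
    use <- ord[seq_len(min(length(ord), G * group_size))]
    if (length(use) < G * group_size) next
    assignment[use, e, k] <- gid
    amp[, e, k] <- rowsum(a[use], gid) / group_size
    del[, e, k] <- rowsum(summary$delta_mean[use, e, k], gid) / group_size
  }
  structure(list(assignment = assignment, amplitude = amp, delta = del,
                 group_size = group_size, n_groups = G, n_dropped = dropped,
                 epoch_names = summary$epoch_names,
                 network_names = summary$network_names),
            class = "binned_groups")
}

#' Group-level amplitude-asymmetry correlation per network and epoch
#'
#' Pearson correlation between group-mean amplitude and group-mean
#' asymmetry across the rank-contiguous amplitude bins.
#'
#' @param groups A `binned_groups` (needs >= 3 groups).
#' @param alpha Significance level for the per-cell flag (no multiplicity
#'   control; the flag is descriptive).
#' @return An object of class `correlation_matrix` with network x epoch
#'   matrices `r`, `p`, `n`, and logical `significant`.
#' @export
binned_correlation <- function(groups, alpha = 0.05) {
  if (groups$n_groups < 3)
    stop("insufficient-data error: need >= 3 groups", call. = FALSE)
  K <- length(groups$network_names); E <- length(groups$epoch_names)
  dn <- list(groups$network_names, groups$epoch_names)
  r <- matrix(NA_real_, K, E, dimnames = dn); p <- r; n <- r
  for (k in seq_len(K)) for (e in seq_len(E)) {
    res <- pearson_test(groups$amplitude[, e, k], groups$delta[, e, k])
    r[k, e] <- res$r; p[k, e] <- res$p; n[k, e] <- res$n
  }
  structure(list(r = r, p = p, n = n,
                 significant = !is.na(p) & p < alpha,
                 control = "none", threshold = alpha),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("Correlation matrix (", nrow(x$r), "networks x", ncol(x$r),
      "epochs ), control:", x$control, "\n")
  cat("  significant cells:", sum(x$significant, na.rm = TRUE), "\n")
  invisible(x)
}

#' Long-format table of a correlation matrix
#' @param x A `correlation_matrix`.
#' @return Data frame with network, epoch, r, p, n, significant.
#' @export
correlation_long <- function(x) {
  grid <- expand.grid(network = rownames(x$r), epoch = colnames(x$r),
                      stringsAsFactors = FALSE)
  grid$r <- as.vector(x$r); grid$p <- as.vector(x$p)
  grid$n <- as.vector(x$n); grid$significant <- as.vector(x$significant)
  grid
}

#' Correlate network measures with task accuracy across subjects
#'
#' Per (network, scored epoch), the Pearson correlation between the
#' subject-level network measure (asymmetry or amplitude) and percent-correct
#' accuracy, with missing accuracy dropped pairwise. Bonferroni control
#' divides `alpha` by the number of tested cells.
#'
#' @param summary A `network_summary`.
#' @param table Subject table aligned with the summary's subjects.
#' @param measure `"delta"` or `"amplitude"`.
#' @param alpha Family significance level.
#' @param control `"bonferroni"` (default) or `"none"`.
#' @param networks Networks to test (default the 9 model networks).
#' @return A `correlation_matrix` (networks x scored epochs).
#' @export
accuracy_correlations <- function(summary, table,
                                  measure = c("delta", "amplitude"),
                                  alpha = 0.05,
                                  control = c("bonferroni", "none"),
                                  networks = pls_networks()) {
  measure <- match.arg(measure)
  control <- match.arg(control)
  stopifnot(nrow(table) == dim(summary$delta_mean)[1])
  vals <- if (measure == "delta") summary$delta_mean else summary$amplitude_mean
  networks <- intersect(networks, summary$network_names)
  eps <- intersect(summary$epoch_names, scored_epochs())
  eps <- eps[paste0("acc_", eps) %in% names(table)]
  if (!length(networks) || !length(eps))
    stop("no testable (network, scored-epoch) cells", call. = FALSE)
  dn <- list(networks, eps)
  r <- matrix(NA_real_, length(networks), length(eps), dimnames = dn)
  p <- r; n <- r
  for (k in seq_along(networks)) for (e in seq_along(eps)) {
    ki <- match(networks[k], summary$network_names)
    ei <- match(eps[e], summary$epoch_names)
    res <- pearson_test(vals[, ei, ki], table[[paste0("acc_", eps[e])]])
    r[k, e] <- res$r; p[k, e] <- res$p; n[k, e] <- res$n
  }
  thr <- if (control == "bonferroni") alpha / (length(networks) * length(eps))
         else alpha
  structure(list(r = r, p = p, n = n,
                 significant = !is.na(p) & p < thr,
                 control = control, threshold = thr, measure = measure),
            class = "correlation_matrix")
}

#' Compare polynomial fits of increasing degree by AIC
#'
#' Ordinary least-squares polynomial fits of degree 1..`max_degree`, scored
#' by `AIC = n * ln(RSS / n) + 2k` with `k = degree + 2` (coefficients,
#' intercept, and the error variance). The selected degree is the AIC
#' minimizer; the difference to the linear model is reported both as a raw
#' difference and as a percentage of the linear model's |AIC|.
#'
#' @param x,y Numeric predictor and response vectors.
#' @param max_degree Highest polynomial degree (default 3).
#' @return List with `table` (degree, rss, aic, delta_aic, delta_aic_pct),
#'   `selected` (argmin-AIC degree), and `selected_parsimonious` (the lowest
#'   degree within 2 AIC units of the minimum, the conventional
#'   equivalent-model tie-break).
#' @export
compare_polynomial_fits <- function(x, y, max_degree = 3) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n <= max_degree + 2)
    stop("need n > max_degree + 2 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("fit error: constant predictor", call. = FALSE)
  rows <- lapply(seq_len(max_degree), function(deg) {
    fit <- stats::lm(y ~ stats::poly(x, deg))
    rss <- sum(stats::residuals(fit)^2)
    k <- deg + 2
    data.frame(degree = deg, rss = rss, aic = n * log(rss / n) + 2 * k)
  })
  tab <- do.call(rbind, rows)
  tab$delta_aic <- tab$aic - tab$aic[1]
  tab$delta_aic_pct <- 100 * (tab$aic - tab$aic[1]) / abs(tab$aic[1])
  list(table = tab, selected = tab$degree[which.min(tab$aic)],
       selected_parsimonious = min(tab$degree[tab$aic <= min(tab$aic) + 2]))
}
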
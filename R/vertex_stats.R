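#' Regress a covariate out of per-subject measurements
#'
#' Removes the ordinary-least-squares slope on the covariate and re-adds the
#' group mean, so adjusted values keep the original mean. `values` may be a
#' vector or a subjects x variables matrix (each column adjusted against the
#' same covariate).
#'
#' @param values Numeric vector or matrix (rows = subjects).
#' @param covariate Numeric per-subject covariate (e.g., age in years).
#' @return Adjusted values, same shape as the input.
#' @export
residualize_covariate <- function(values, covariate) {
  x <- as.numeric(covariate)
  n <- if (is.matrix(values)) nrow(values) else length(values)
  if (length(x) != n) stop("covariate length mismatch", call. = FALSE)
  if (n < 3) stop("need at least 3 subjects", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate-design error: constant covariate", call. = FALSE)
  xc <- x - mean(x)
  if (is.matrix(values)) {
    mu <- colMeans(values)
    slope <- as.numeric(crossprod(xc, sweep(values, 2, mu))) / sum(xc^2)
    values - outer(xc, slope)  # slope removed, column means kept
  } else {
    mu <- mean(values)
    slope <- sum(xc * (values - mu)) / sum(xc^2)
    values - slope * xc
  }
}

#' Grand-mean scaling across categorical cells
#'
#' Each subject's value is multiplied by (grand mean / its cell mean) so
#' that every cell's post-scaling mean equals the grand mean. Cells whose
#' mean is zero cannot be scaled; their values are passed through and the
#' cell is flagged in the `"unscaled_cells"` attribute.
#'
#' @param values Numeric vector or subjects x variables matrix. For a
#'   matrix (e.g. a vertex map), one factor per cell is computed from the
#'   cell's mean over all variables jointly, the stable global-scaling
#'   analogue; per-variable cell means on noisy maps can pass near zero and
#'   would explode a column-wise factor.
#' @param groups Factor (or vector coercible to one) of cell labels, e.g.
#'   `interaction(sex, race)`.
#' @return Scaled values with attribute `unscaled_cells`.
#' @export
grand_mean_scale <- function(values, groups) {
  g <- as.factor(groups)
  mat <- if (is.matrix(values)) values else matrix(values, ncol = 1)
  if (nrow(mat) != length(g)) stop("groups length mismatch", call. = FALSE)
  g <- droplevels(g)
  per_column <- !is.matrix(values)
  grand <- if (per_column) colMeans(mat) else mean(mat)
  flagged <- character(0)
  out <- mat
  for (lv in levels(g)) {
    rows <- which(g == lv)
    cm <- if (per_column) colMeans(mat[rows, , drop = FALSE])
          else mean(mat[rows, , drop = FALSE])
    fac <- ifelse(cm == 0, 1, grand / cm)
    if (any(cm == 0)) flagged <- c(flagged, lv)
    out[rows, ] <- if (per_column)
      sweep(mat[rows, , drop = FALSE], 2, fac, `*`)
    else mat[rows, , drop = FALSE] * fac
  }
  if (length(flagged))
    warning("scaling error: zero cell mean in cell(s) ",
            paste(unique(flagged), collapse = ", "),
            "; values passed through", call. = FALSE)
  if (!is.matrix(values)) out <- as.vector(out)
  attr(out, "unscaled_cells") <- unique(flagged)
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Standard step-up procedure: q-values are the monotone adjusted values
#' `min_k>=i (m * p_(k) / k)` capped at 1; a test is rejected when its
#' q-value is at most `alpha` (the usual non-strict step-up rule, so the
#' boundary case `p_(m) = alpha` is rejected).
#'
#' @param pvalues Vector of p-values in [0, 1] (NA allowed; passed through).
#' @param alpha FDR level in (0, 1).
#' @return List with `q` (adjusted values) and `reject` (logical mask).
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values outside [0, 1]", call. = FALSE)
  m <- length(p)
  q <- rep(NA_real_, length(pvalues))
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    qq <- pmin(1, cummin(m / (m:1) * p[o]))[ro]
    q[ok] <- qq
  }
  list(q = q, reject = !is.na(q) & q <= alpha)
}

#' Vertex-wise one-sample t-tests with FDR control and effect sizes
#'
#' Two-sided one-sample t-test against zero at every vertex (column), on the
#' unmasked subjects of that vertex. Effect size is Cohen's d = mean/SD with
#' the Hedges small-sample bias correction `J = 1 - 3 / (4*nu - 1)`,
#' `nu = n - 1`. Vertices with zero variance (or fewer than 2 subjects) are
#' flagged `degenerate` and excluded from the FDR family, which otherwise
#' spans all tested vertices of the map.
#'
#' @param delta Subjects x vertices matrix (NA = masked cell).
#' @param alpha FDR level (default 0.05).
#' @param hedges Apply the small-sample correction to d (default TRUE).
#' @return An object of class `vertex_stat_map`: data frame with columns
#'   `t`, `p`, `q`, `d`, `reject`, `n_effective`, `degenerate`.
#' @export
one_sample_t_map <- function(delta, alpha = 0.05, hedges = TRUE) {
  stopifnot(is.matrix(delta))
  n_eff <- colSums(!is.na(delta))
  mu <- colMeans(delta, na.rm = TRUE)
  ss <- colSums(sweep(delta, 2, mu)^2, na.rm = TRUE)
  sdv <- sqrt(ss / pmax(n_eff - 1, 1))
  degenerate <- n_eff < 2 | sdv == 0
  tval <- ifelse(degenerate, NA_real_, mu / (sdv / sqrt(n_eff)))
  pval <- ifelse(degenerate, NA_real_,
                 2 * stats::pt(abs(tval), df = n_eff - 1, lower.tail = FALSE))
  J <- if (hedges) 1 - 3 / (4 * (n_eff - 1) - 1) else 1
  d <- ifelse(degenerate, NA_real_, (mu / sdv) * J)
  adj <- fdr_bh(pval, alpha)
  structure(data.frame(t = tval, p = pval, q = adj$q, d = d,
                       reject = adj$reject, n_effective = n_eff,
                       degenerate = degenerate),
            class = c("vertex_stat_map", "data.frame"))
}

#' Covariate adjustment for vertex-wise group inference
#'
#' Applies the standard adjustment order for asymmetry maps: age is first
#' regressed out by linear regression, then grand-mean scaling normalizes
#' the data across the categorical covariates (sex and race). Sex and race
#' are scaled, not regressed.
#'
#' @param delta Subjects x vertices matrix.
#' @param table Subject table aligned with the rows of `delta`.
#' @return Adjusted matrix of the same shape.
#' @export
adjust_covariates <- function(delta, table) {
  stopifnot(nrow(delta) == nrow(table))
  adj <- residualize_covariate(delta, table$age)
  grand_mean_scale(adj, interaction(table$sex, table$race, drop = TRUE))
}
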
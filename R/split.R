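quartile_bins <- function(x) {
  qs <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), na.rm = TRUE,
                        names = FALSE)
  findInterval(x, unique(qs)) + 1L
}

#' Covariate-matched discovery/replication split
#'
#' Subjects are stratified by sex and by quartile bins of age and BMI;
#' within each stratum they are randomly allocated at the requested
#' fraction. Remainder seats (from per-stratum rounding) are distributed by
#' largest fractional part so that the global discovery size equals
#' `round(fraction * n)` (at fraction 0.5 the arms differ by at most one
#' subject). Accuracy is never used to form strata. Deterministic given the
#' seed.
#'
#' @param table Subject table (needs age, sex, bmi; n >= 4).
#' @param fraction Target discovery fraction in (0, 1) (default 0.5).
#' @param seed Integer seed.
#' @return An object of class `split_assignment`: data frame of
#'   `subject_id` and `arm` (`"discovery"`/`"replication"`), with the
#'   balance report of [balance_check()] attached as attribute `"balance"`.
#' @export
matched_split <- function(table, fraction = 0.5, seed = 1L) {
  n <- nrow(table)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  stopifnot(fraction > 0, fraction < 1)
  for (cv in c("age", "sex", "bmi"))
    if (all(is.na(table[[cv]])))
      stop("matching error: covariate entirely missing: ", cv, call. = FALSE)
  set.seed(seed)
  strata <- interaction(table$sex, quartile_bins(table$age),
                        quartile_bins(table$bmi), drop = TRUE)
  target_total <- round(fraction * n)
  sizes <- as.vector(table(strata))
  base <- floor(fraction * sizes)
  frac_part <- fraction * sizes - base
  extra_needed <- target_total - sum(base)
  extra <- rep(0L, length(sizes))
  if (extra_needed > 0) {
    # largest remainders first; random jitter breaks ties reproducibly
    ord <- order(-frac_part, stats::runif(length(sizes)))
    extra[ord[seq_len(extra_needed)]] <- 1L
  }
  arm <- rep("replication", n)
  lv <- levels(strata)
  for (s in seq_along(lv)) {
    idx <- which(strata == lv[s])
    nd <- base[s] + extra[s]
    if (nd > 0) arm[sample(idx, nd)] <- "discovery"
  }
  out <- structure(data.frame(subject_id = table$subject_id, arm = arm,
                              stringsAsFactors = FALSE),
                   class = c("split_assignment", "data.frame"))
  attr(out, "fraction") <- fraction
  attr(out, "balance") <- balance_check(out, table)
  out
}

# Standardized mean difference between two arms for a numeric vector.
smd_numeric <- function(x, arm) {
  a <- x[arm == "discovery"]; b <- x[arm == "replication"]
  sp <- sqrt((stats::var(a) * (length(a) - 1) +
                stats::var(b) * (length(b) - 1)) /
               (length(a) + length(b) - 2))
  if (!is.finite(sp) || sp == 0) return(0)
  (mean(a) - mean(b)) / sp
}

#' Covariate balance between the two arms of a split
#'
#' Two-sample (Welch) t-tests for numeric covariates, chi-square tests for
#' categorical ones, and standardized mean differences (SMD) for all; for a
#' categorical covariate the SMD reported is the largest SMD over its level
#' indicators. Descriptive: no multiplicity adjustment.
#'
#' @param assignment A `split_assignment` (or data frame with `subject_id`
#'   and `arm`).
#' @param table Subject table.
#' @param covariates Covariate columns to check (default: sex, age, race,
#'   bmi, handedness, and any accuracy columns present).
#' @return Data frame with columns covariate, type, statistic, p, smd.
#' @export
balance_check <- function(assignment, table,
                          covariates = c("sex", "age", "race", "bmi",
                                         "handedness",
                                         accuracy_columns(table))) {
  arm <- assignment$arm[match(table$subject_id, assignment$subject_id)]
  if (!all(c("discovery", "replication") %in% arm))
    stop("both arms must be non-empty", call. = FALSE)
  rows <- lapply(covariates, function(cv) {
    x <- table[[cv]]
    if (is.numeric(x)) {
      ok <- !is.na(x)
      if (stats::sd(x[ok]) == 0)
        return(data.frame(covariate = cv, type = "numeric",
                          statistic = NA_real_, p = NA_real_, smd = 0))
      tt <- stats::t.test(x[ok] ~ arm[ok])
      data.frame(covariate = cv, type = "numeric",
                 statistic = unname(tt$statistic), p = tt$p.value,
                 smd = smd_numeric(x[ok], arm[ok]))
    } else {
      tabx <- table(x, arm)
      if (nrow(tabx) < 2)
        return(data.frame(covariate = cv, type = "categorical",
                          statistic = NA_real_, p = NA_real_, smd = 0))
      ct <- suppressWarnings(stats::chisq.test(tabx))
      smds <- vapply(rownames(tabx), function(lvl)
        abs(smd_numeric(as.numeric(x == lvl), arm)), numeric(1))
      data.frame(covariate = cv, type = "categorical",
                 statistic = unname(ct$statistic), p = ct$p.value,
                 smd = max(smds))
    }
  })
  do.call(rbind, rows)
}
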
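#' Aggregate vertex-wise asymmetry into network-level summaries
#'
#' Takes the unweighted mean over each network's unmasked vertices, per
#' subject and epoch, vertex-first: the laterality index is averaged, never
#' recomputed from averaged hemisphere values. Per-hemisphere mean absolute
#' amplitudes are reported alongside. Background vertices are excluded; an
#' empty or fully-masked network yields NA.
#'
#' @param result An `asymmetry_result`.
#' @param partition A `network_partition` with one label per vertex.
#' @return An object of class `network_summary` with arrays `delta_mean`,
#'   `amplitude_mean`, `left_mean`, `right_mean`
#'   (subjects x epochs x networks).
#' @export
aggregate_by_network <- function(result, partition) {
  stopifnot(inherits(result, "asymmetry_result"),
            inherits(partition, "network_partition"))
  V <- dim(result$delta)[3]
  if (length(partition$labels) != V)
    stop("partition length ", length(partition$labels),
         " does not match vertex count ", V, call. = FALSE)
  if (all(partition$empty))
    stop("aggregation error: all networks empty", call. = FALSE)
  n <- dim(result$delta)[1]; E <- dim(result$delta)[2]
  K <- length(partition$network_names)
  dn <- list(result$subject_ids, result$epoch_names, partition$network_names)
  out <- list(delta_mean = array(NA_real_, c(n, E, K), dn),
              amplitude_mean = array(NA_real_, c(n, E, K), dn),
              left_mean = array(NA_real_, c(n, E, K), dn),
              right_mean = array(NA_real_, c(n, E, K), dn))
  flat <- function(a) matrix(a, nrow = n * E, ncol = V)
  fd <- flat(result$delta); fa <- flat(result$amplitude)
  fl <- flat(result$left_abs); fr <- flat(result$right_abs)
  for (k in seq_len(K)) {
    vk <- which(partition$labels == k)
    if (!length(vk)) next
    out$delta_mean[, , k] <- rowMeans(fd[, vk, drop = FALSE], na.rm = TRUE)
    out$amplitude_mean[, , k] <- rowMeans(fa[, vk, drop = FALSE], na.rm = TRUE)
    out$left_mean[, , k] <- rowMeans(fl[, vk, drop = FALSE])
    out$right_mean[, , k] <- rowMeans(fr[, vk, drop = FALSE])
  }
  out$delta_mean[is.nan(out$delta_mean)] <- NA_real_
  out$amplitude_mean[is.nan(out$amplitude_mean)] <- NA_real_
  structure(c(out, list(network_names = partition$network_names,
                        epoch_names = result$epoch_names,
                        subject_ids = result$subject_ids)),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  d <- dim(x$delta_mean)
  cat("Network summary:", d[1], "subjects x", d[2], "epochs x", d[3],
      "networks\n")
  invisible(x)
}

#' Long-format table of a network summary (one row per cell)
#'
#' @param summary A `network_summary`.
#' @return A data frame with columns subject, epoch, network, delta,
#'   amplitude, left, right.
#' @export
summary_long <- function(summary) {
  d <- dim(summary$delta_mean)
  grid <- expand.grid(subject = summary$subject_ids,
                      epoch = summary$epoch_names,
                      network = summary$network_names,
                      stringsAsFactors = FALSE)
  grid$delta <- as.vector(summary$delta_mean)
  grid$amplitude <- as.vector(summary$amplitude_mean)
  grid$left <- as.vector(summary$left_mean)
  grid$right <- as.vector(summary$right_mean)
  grid
}

# Cohort-mean delta as an epochs x networks matrix, with optional centering
# of each task's epochs on the task mean (used for motor contrasts expressed
# relative to the overall asymmetry induced by their task).
cohort_mean_delta <- function(summary, centering = c("none", "task_mean")) {
  centering <- match.arg(centering)
  m <- apply(summary$delta_mean, c(2, 3), mean, na.rm = TRUE)
  dimnames(m) <- list(summary$epoch_names, summary$network_names)
  if (centering == "task_mean") {
    tasks <- epoch_tasks()[summary$epoch_names]
    for (tk in unique(stats::na.omit(tasks))) {
      rows <- which(!is.na(tasks) & tasks == tk)
      if (length(rows) > 1)
        m[rows, ] <- sweep(m[rows, , drop = FALSE], 2,
                           colMeans(m[rows, , drop = FALSE]))
    }
  }
  m
}

canonical_position <- function(names, canonical) {
  pos <- match(names, canonical)
  pos[is.na(pos)] <- length(canonical) + seq_len(sum(is.na(pos)))
  pos
}

#' Rank networks by the RMS of cohort-mean asymmetry across epochs
#'
#' @param summary A `network_summary`.
#' @param centering `"none"` (raw epochs, the default) or `"task_mean"`
#'   (each task's epochs centered on the task mean before ranking).
#' @return An object of class `ranking_result`: a data frame of networks
#'   and their RMS scores, sorted descending; ties broken by canonical
#'   network order.
#' @export
rank_networks <- function(summary, centering = c("none", "task_mean")) {
  m <- cohort_mean_delta(summary, centering)
  rms <- sqrt(colMeans(m^2, na.rm = TRUE))
  ord <- order(-rms, canonical_position(summary$network_names,
                                        canonical_networks()))
  structure(data.frame(network = summary$network_names[ord],
                       rms_delta = rms[ord], row.names = NULL),
            class = c("ranking_result", "data.frame"))
}

#' Rank epochs by mean cohort asymmetry across networks
#'
#' @inheritParams rank_networks
#' @return A `ranking_result` data frame of epochs and mean scores, sorted
#'   descending; ties broken by canonical epoch order.
#' @export
rank_epochs <- function(summary, centering = c("none", "task_mean")) {
  m <- cohort_mean_delta(summary, centering)
  mu <- rowMeans(m, na.rm = TRUE)
  ord <- order(-mu, canonical_position(summary$epoch_names,
                                       canonical_epochs()))
  structure(data.frame(epoch = summary$epoch_names[ord],
                       mean_delta = mu[ord], row.names = NULL),
            class = c("ranking_result", "data.frame"))
}
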
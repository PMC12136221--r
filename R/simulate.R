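#' Planted network-by-epoch asymmetry pattern used by default
#'
#' Default generative parameters mirror the qualitative structure reported
#' for large task-fMRI cohorts: contralateral somatomotor asymmetry for
#' unilateral movements, leftward language/default-mode/auditory asymmetry
#' during story comprehension, rightward dorsal-attention/frontoparietal
#' asymmetry during emotion matching, and modest load-dependent patterns for
#' working memory. Magnitudes stay within about +/-0.3, the typical range of
#' network-mean laterality indices.
#'
#' @return A 12 x 17 numeric matrix (networks x epochs, canonical order).
#' @export
default_true_delta <- function() {
  nets <- canonical_networks(); eps <- canonical_epochs()
  d <- matrix(0, length(nets), length(eps), dimnames = list(nets, eps))
  nonmotor <- setdiff(eps, c("lh", "rh", "lf", "rf", "t"))
  d["SMM", nonmotor] <- 0.08
  d["AUD", nonmotor] <- 0.06
  d["DMN", ] <- -0.05
  set <- function(epoch, ...) {
    v <- c(...)
    d[names(v), epoch] <<- v
  }
  set("story", LAN = 0.25, FPN = 0.15, DMN = 0.12, AUD = 0.15, VMM = 0.08,
      PMM = 0.05, VIS1 = -0.10, VIS2 = -0.08, SMM = -0.12, DAN = -0.08)
  set("math", LAN = -0.05, FPN = -0.05, DMN = -0.08, VIS1 = 0.03)
  set("lh", SMM = -0.25, DAN = -0.10, AUD = -0.10)
  set("lf", SMM = -0.22, DAN = -0.08, AUD = -0.08)
  set("rh", SMM = 0.25, DAN = 0.10, AUD = 0.10)
  set("rf", SMM = 0.22, DAN = 0.08, AUD = 0.08)
  set("t", SMM = 0.05)
  set("faces", DAN = -0.15, FPN = -0.10, PMM = -0.10, VIS1 = 0.05)
  set("shapes", DAN = -0.10, FPN = -0.08, PMM = -0.06)
  set("reward", FPN = -0.08, LAN = -0.08)
  set("punish", FPN = -0.08, LAN = -0.07)
  set("social", FPN = -0.10, LAN = -0.10, DMN = -0.06)
  set("random", FPN = -0.10, LAN = -0.12)
  set("0bk", VIS1 = 0.06, VIS2 = 0.05, SMM = 0.06, DMN = -0.06,
      FPN = -0.06, LAN = -0.06)
  set("2bk", VIS1 = 0.10, VIS2 = 0.08, SMM = 0.08, DMN = -0.10,
      FPN = -0.05, LAN = -0.05)
  set("rel", LAN = 0.10, FPN = 0.05, DMN = 0.05, DAN = -0.05)
  set("match", LAN = 0.06, FPN = 0.04, DAN = -0.04)
  d
}

#' @rdname default_true_delta
#' @export
default_true_amplitude <- function() {
  d <- default_true_delta()
  a <- 0.8 + 2 * abs(d)
  vis_tasks <- c("faces", "shapes", "0bk", "2bk", "rel", "match")
  a[c("VIS1", "VIS2"), vis_tasks] <- a[c("VIS1", "VIS2"), vis_tasks] + 0.4
  a["AUD", c("story", "math")] <- a["AUD", c("story", "math")] + 0.4
  a
}

#' @rdname default_true_delta
#' @export
default_coupling <- function() {
  d <- default_true_delta()
  cpl <- pmin(0.02 + 0.4 * abs(d), 0.15)
  cpl["LAN", ] <- pmax(cpl["LAN", ], 0.12)
  cpl
}

#' Default linear weights generating task accuracy from network measures
#'
#' Accuracy for a scored epoch is a baseline plus a weighted sum of the
#' subject's standardized noiseless network amplitude and asymmetry, plus
#' Gaussian noise; weights are in percent-accuracy per SD of the measure.
#'
#' @return A list with `amplitude` and `delta` weight matrices
#'   (12 networks x 12 scored epochs) and a named `base` vector (percent).
#' @export
default_accuracy_weights <- function() {
  nets <- canonical_networks(); eps <- scored_epochs()
  wa <- matrix(0, length(nets), length(eps), dimnames = list(nets, eps))
  wd <- wa
  wd["LAN", "story"] <- 5;  wa["LAN", "story"] <- 4
  wa["FPN", "rel"] <- 3.5;  wd["FPN", "rel"] <- 2
  wd["LAN", "match"] <- 2.5
  wa["VIS1", "2bk"] <- 3;   wa["DAN", "2bk"] <- 3; wd["VIS1", "2bk"] <- 1.5
  wa["VIS2", "0bk"] <- 2.5; wa["DAN", "0bk"] <- 2
  base <- c(faces = 92, shapes = 95, reward = 50, punish = 50, story = 86,
            math = 75, rel = 76, match = 88, social = 50, random = 50,
            `0bk` = 85, `2bk` = 78)
  list(amplitude = wa, delta = wd, base = base[eps])
}

# Fractional cortical surface share of each network (ORA/VMM/PMM small).
default_network_weights <- function() {
  c(VIS1 = 0.12, VIS2 = 0.10, SMM = 0.14, CON = 0.10, DAN = 0.09,
    LAN = 0.08, FPN = 0.12, AUD = 0.06, DMN = 0.14, PMM = 0.02,
    VMM = 0.02, ORA = 0.01)
}

#' Simulation configuration for synthetic bilateral cohorts
#'
#' @param n_subjects Number of subjects (default 989, a full-cohort scale).
#' @param n_vertices Vertices per hemisphere (default 32492, full-surface
#'   scale; use a few hundred to a few thousand for fast experiments).
#' @param epoch_names Task epochs to simulate (subset of the canonical 17).
#' @param network_names Networks to simulate (prefix/subset of canonical 12).
#' @param true_delta,true_amplitude,coupling Network x epoch matrices of the
#'   planted mean asymmetry (dimensionless, in (-1, 1)), planted mean
#'   bilateral amplitude (contrast units, > 0), and the coefficient linking
#'   the subject latent amplitude factor to asymmetry.
#' @param accuracy_weights List of `amplitude`/`delta` weight matrices plus
#'   `base`, as from [default_accuracy_weights()].
#' @param vertex_noise_sd Independent Gaussian noise SD added to every vertex
#'   value (contrast units).
#' @param subject_noise_sd Relative SD of subject-level variation: scales
#'   both the latent-factor modulation of amplitude and the idiosyncratic
#'   per-cell jitter of amplitude and asymmetry (dimensionless).
#' @param accuracy_noise_sd Accuracy noise SD (percent).
#' @param age_effect,sex_effect Effects of standardized age and of sex
#'   (male minus female, centered coding) on the subject latent factor.
#' @param seed Integer seed; every stochastic draw flows from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 989, n_vertices = 32492,
                       epoch_names = canonical_epochs(),
                       network_names = canonical_networks(),
                       true_delta = default_true_delta(),
                       true_amplitude = default_true_amplitude(),
                       coupling = default_coupling(),
                       accuracy_weights = default_accuracy_weights(),
                       vertex_noise_sd = 0.5,
                       subject_noise_sd = 0.1,
                       accuracy_noise_sd = 10,
                       age_effect = -0.2,
                       sex_effect = 0.3,
                       seed = 1L) {
  network_names <- as.character(network_names)
  epoch_names <- as.character(epoch_names)
  if (length(network_names) > 12L)
    stop("config error: at most 12 networks", call. = FALSE)
  sub <- function(m) {
    if (!all(network_names %in% rownames(m)) || !all(epoch_names %in% colnames(m)))
      stop("config error: parameter matrix lacks requested networks/epochs",
           call. = FALSE)
    m[network_names, epoch_names, drop = FALSE]
  }
  true_delta <- sub(true_delta)
  true_amplitude <- sub(true_amplitude)
  coupling <- sub(coupling)
  sc_eps <- intersect(epoch_names, scored_epochs())
  aw <- list(
    amplitude = accuracy_weights$amplitude[network_names, sc_eps, drop = FALSE],
    delta = accuracy_weights$delta[network_names, sc_eps, drop = FALSE],
    base = accuracy_weights$base[sc_eps])
  if (any(abs(true_delta) >= 1))
    stop("config error: |true_delta| must be < 1", call. = FALSE)
  if (any(true_amplitude <= 0))
    stop("config error: true_amplitude must be > 0", call. = FALSE)
  if (vertex_noise_sd < 0 || subject_noise_sd < 0 || accuracy_noise_sd < 0)
    stop("config error: noise SDs must be >= 0", call. = FALSE)
  structure(list(
    n_subjects = as.integer(n_subjects), n_vertices = as.integer(n_vertices),
    n_networks = length(network_names),
    epoch_names = epoch_names, network_names = network_names,
    true_delta = true_delta, true_amplitude = true_amplitude,
    coupling = coupling, accuracy_weights = aw,
    vertex_noise_sd = vertex_noise_sd, subject_noise_sd = subject_noise_sd,
    accuracy_noise_sd = accuracy_noise_sd,
    age_effect = age_effect, sex_effect = sex_effect,
    network_weights = default_network_weights()[network_names],
    seed = as.integer(seed)), class = "sim_config")
}

# Quasi-regular points filling a hemisphere-sized ellipsoidal volume: a
# jittered lattice clipped to the ellipsoid. At low vertex counts a heavily
# folded cortical sheet is effectively space-filling, and the near-constant
# vertex spacing keeps mirror-matching well conditioned.
ellipsoid_grid <- function(n, semi_axes = c(55, 75, 62),
                           center = c(-60, 0, 0), jitter_frac = 0.05) {
  m <- max(2L, ceiling((n * 6 / pi)^(1 / 3)))
  repeat {
    ax <- (seq_len(m) - 0.5) / m * 2 - 1
    g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
    r2 <- rowSums(g^2)
    if (sum(r2 <= 1) >= n) break
    m <- m + 1L
  }
  inside <- which(r2 <= 1)
  keep <- inside[order(r2[inside])[seq_len(n)]]   # innermost n lattice points
  pts <- sweep(g[keep, , drop = FALSE], 2, semi_axes, `*`)
  h <- 2 * semi_axes / m                          # lattice pitch per axis
  pts <- pts + sweep(matrix(stats::rnorm(3 * n), n, 3), 2, jitter_frac * h, `*`)
  sweep(pts, 2, center, `+`)
}

generate_geometry_impl <- function(n_vertices) {
  left <- ellipsoid_grid(n_vertices)
  mirrored <- left
  mirrored[, 1] <- -mirrored[, 1]
  src <- sample.int(n_vertices)          # left vertex stored at each right slot
  right <- mirrored[src, , drop = FALSE]
  perm <- order(src)                     # right slot matching each left vertex
  list(left_coords = left, right_coords = right,
       permutation = perm, source = src)
}

#' Generate mirrored left/right vertex geometry
#'
#' Right-hemisphere coordinates are the left coordinates mirrored across the
#' midsagittal plane (x -> -x) and stored in a pseudo-random permuted order;
#' the permutation (right slot index for each left vertex) is returned so
#' that correspondence recovery can be checked against ground truth.
#'
#' @param n_vertices Number of vertices per hemisphere.
#' @param seed Integer seed.
#' @return List with `left_coords`, `right_coords` (n x 3, mm),
#'   `permutation`, and `source` (its inverse).
#' @export
generate_geometry <- function(n_vertices, seed = 1L) {
  stopifnot(n_vertices >= 1)
  set.seed(seed)
  generate_geometry_impl(n_vertices)
}

partition_from_weights <- function(n_vertices, network_names, weights) {
  w <- weights / sum(weights)
  sizes <- floor(w * n_vertices)
  rem <- n_vertices - sum(sizes)
  if (rem > 0) {
    frac <- w * n_vertices - sizes
    sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
      sizes[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1L
  }
  labels <- rep(seq_along(network_names), times = sizes)
  network_partition(labels, network_names)
}

#' Generate a synthetic bilateral cohort with planted structure
#'
#' For subject i, network k, epoch e the generative model is: a latent
#' factor `f_i ~ Normal(age_effect * z(age_i) + sex_effect * sex_i, 1)`
#' (sex centered at +/-0.5); amplitude
#' `A_ike = true_amplitude * (1 + s * f_i + s * eps_ike)` (floored at 5% of
#' the planted amplitude); asymmetry
#' `D_ike = true_delta + coupling * f_i + s * zeta_ike` (clipped to
#' +/-0.99), with `s = subject_noise_sd`. Vertex values are block-constant
#' within a network, `L = A (1 + D)` and `R = A (1 - D)`, each plus
#' independent Gaussian vertex noise, so that the laterality index applied
#' to the noiseless values returns the realized `D` exactly. Accuracy for
#' each scored epoch is a baseline plus weighted standardized network
#' measures plus noise, clipped to [0, 100]. Unassigned (background)
#' vertices carry pure noise.
#'
#' @param config A [sim_config()].
#' @return List with `dataset` (a `contrast_dataset`), `subjects` (table),
#'   `partition` (a `network_partition`), and `truth` (a `ground_truth`
#'   record of the config, realized latent factors, realized noiseless
#'   network-level asymmetry/amplitude, and the vertex permutation).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects; V <- config$n_vertices
  K <- config$n_networks; E <- length(config$epoch_names)
  set.seed(config$seed)

  geom <- generate_geometry_impl(V)
  partition <- partition_from_weights(V, config$network_names,
                                      config$network_weights)

  age <- stats::runif(n, 22, 36)
  sex <- ifelse(stats::rbinom(n, 1, 0.5) == 1, "M", "F")
  race <- sample(c("white", "black", "asian"), n, replace = TRUE,
                 prob = c(0.75, 0.15, 0.10))
  bmi <- stats::rnorm(n, 26.5, 4.5)
  handedness <- pmin(100, pmax(-100, stats::rnorm(n, 65, 45)))
  rms_motion <- abs(stats::rnorm(n, 0.3, 0.2))
  zage <- as.numeric(scale(age))
  sex_c <- ifelse(sex == "M", 0.5, -0.5)
  f <- stats::rnorm(n, mean = config$age_effect * zage +
                      config$sex_effect * sex_c, sd = 1)

  s <- config$subject_noise_sd
  A <- array(NA_real_, c(n, K, E),
             dimnames = list(NULL, config$network_names, config$epoch_names))
  D <- A
  for (e in seq_len(E)) {
    amp0 <- config$true_amplitude[, e]
    del0 <- config$true_delta[, e]
    cpl <- config$coupling[, e]
    epsA <- matrix(stats::rnorm(n * K), n, K)
    zetD <- matrix(stats::rnorm(n * K), n, K)
    Ae <- outer(rep(1, n), amp0) * (1 + s * f + s * epsA)
    Ae <- pmax(Ae, 0.05 * outer(rep(1, n), amp0))
    De <- outer(rep(1, n), del0) + outer(f, cpl) + s * zetD
    De <- pmin(pmax(De, -0.99), 0.99)
    A[, , e] <- Ae
    D[, , e] <- De
  }

  net_of_vertex <- partition$labels            # 1..K or background
  assigned <- net_of_vertex != BACKGROUND_CODE
  col_idx <- ifelse(assigned, net_of_vertex, 1L)
  left <- array(0, c(n, E, V))
  right_anat <- array(0, c(n, E, V))
  for (e in seq_len(E)) {
    Ae <- A[, , e]; De <- D[, , e]
    Lblock <- (Ae * (1 + De))[, col_idx, drop = FALSE]
    Rblock <- (Ae * (1 - De))[, col_idx, drop = FALSE]
    if (any(!assigned)) {
      Lblock[, !assigned] <- 0
      Rblock[, !assigned] <- 0
    }
    if (config$vertex_noise_sd > 0) {
      Lblock <- Lblock + matrix(stats::rnorm(n * V, sd = config$vertex_noise_sd), n, V)
      Rblock <- Rblock + matrix(stats::rnorm(n * V, sd = config$vertex_noise_sd), n, V)
    }
    left[, e, ] <- Lblock
    right_anat[, e, ] <- Rblock
  }
  # store right-hemisphere values in the permuted vertex order of geom
  right <- right_anat[, , geom$source, drop = FALSE]

  subjects <- data.frame(subject_id = sprintf("S%04d", seq_len(n)),
                         age = age, sex = sex, race = race, bmi = bmi,
                         handedness = handedness, rms_motion = rms_motion,
                         stringsAsFactors = FALSE)
  sc_eps <- colnames(config$accuracy_weights$amplitude)
  for (ep in sc_eps) {
    wa <- config$accuracy_weights$amplitude[, ep]
    wd <- config$accuracy_weights$delta[, ep]
    za <- apply(A[, , ep, drop = FALSE][, , 1, drop = TRUE], 2, zscore_safe)
    zd <- apply(D[, , ep, drop = FALSE][, , 1, drop = TRUE], 2, zscore_safe)
    if (K == 1L) { za <- matrix(za, ncol = 1); zd <- matrix(zd, ncol = 1) }
    acc <- config$accuracy_weights$base[[ep]] +
      as.numeric(za %*% wa) + as.numeric(zd %*% wd) +
      stats::rnorm(n, sd = config$accuracy_noise_sd)
    subjects[[paste0("acc_", ep)]] <- pmin(100, pmax(0, acc))
  }

  dataset <- contrast_dataset(subjects$subject_id, config$epoch_names,
                              left, right, geom$left_coords, geom$right_coords)
  truth <- structure(list(config = config, latent = f,
                          realized_delta = D, realized_amplitude = A,
                          permutation = geom$permutation,
                          source = geom$source,
                          partition_labels = partition$labels),
                     class = "ground_truth")
  list(dataset = dataset, subjects = validate_subject_table(subjects),
       partition = partition, truth = truth)
}

zscore_safe <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}
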
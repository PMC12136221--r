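# Fixtures are always built in code, at test time.

# Minimal hand-built dataset: values are deterministic ramps so any
# reordering or loss is visible.
make_dataset <- function(n_subjects = 3, n_epochs = 2, n_vertices = 50,
                         epoch_names = paste0("ep", seq_len(n_epochs))) {
  left <- array(seq_len(n_subjects * n_epochs * n_vertices) / 7,
                c(n_subjects, n_epochs, n_vertices))
  right <- left * 0.5 + 1
  coords <- cbind(seq_len(n_vertices), seq_len(n_vertices) %% 5,
                  sqrt(seq_len(n_vertices)))
  mirrored <- coords; mirrored[, 1] <- -mirrored[, 1]
  contrast_dataset(sprintf("sub%02d", seq_len(n_subjects)), epoch_names,
                   left, right, coords, mirrored)
}

# Identity vertex correspondence for datasets whose right hemisphere is
# stored in matched order.
identity_correspondence <- function(n_vertices) {
  structure(list(permutation = seq_len(n_vertices), fit_quality = 1),
            class = "vertex_correspondence")
}

# Wrap a subjects x epochs x vertices delta array as an asymmetry_result.
make_asym <- function(delta, amplitude = abs(delta) + 1,
                      epoch_names = paste0("ep", seq_len(dim(delta)[2]))) {
  structure(list(delta = delta, amplitude = amplitude,
                 mask = is.na(delta),
                 left_abs = amplitude * (1 + ifelse(is.na(delta), 0, delta)),
                 right_abs = amplitude * (1 - ifelse(is.na(delta), 0, delta)),
                 subject_ids = sprintf("sub%02d", seq_len(dim(delta)[1])),
                 epoch_names = epoch_names,
                 correspondence = identity_correspondence(dim(delta)[3])),
            class = "asymmetry_result")
}

# Wrap network-level arrays (subjects x epochs x networks) as a
# network_summary without going through vertex maps.
make_summary <- function(delta_mean, amplitude_mean = abs(delta_mean) + 1,
                         network_names = paste0("N", seq_len(dim(delta_mean)[3])),
                         epoch_names = paste0("ep", seq_len(dim(delta_mean)[2]))) {
  structure(list(delta_mean = delta_mean, amplitude_mean = amplitude_mean,
                 left_mean = amplitude_mean, right_mean = amplitude_mean,
                 network_names = network_names, epoch_names = epoch_names,
                 subject_ids = sprintf("sub%02d", seq_len(dim(delta_mean)[1]))),
            class = "network_summary")
}

# Small synthetic cohort for integration-style unit tests.
tiny_cohort <- function(n_subjects = 30, n_vertices = 120, seed = 42, ...) {
  generate_cohort(sim_config(n_subjects = n_subjects,
                             n_vertices = n_vertices, seed = seed, ...))
}

# Independent single-component-at-a-time PLS oracle: the weight vector is
# the leading left singular vector of E'F at each deflation step.
svd_pls_oracle <- function(X, Y, ncomp) {
  E <- scale(X); F <- scale(Y)
  ssy0 <- sum(F^2)
  scores <- matrix(0, nrow(X), ncomp)
  evy <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- svd(crossprod(E, F))$u[, 1]
    tt <- E %*% w
    p <- crossprod(E, tt) / sum(tt^2)
    cc <- crossprod(F, tt) / sum(tt^2)
    E <- E - tt %*% t(p)
    F <- F - tt %*% t(cc)
    scores[, a] <- tt
    evy[a] <- 1 - sum(F^2) / ssy0
  }
  list(scores = scores, explained_y = evy)
}

# Subject covariate table without imaging arrays (for split tests).
make_covariate_table <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(subject_id = sprintf("S%04d", seq_len(n)),
             age = runif(n, 22, 36),
             sex = sample(c("F", "M"), n, replace = TRUE),
             race = sample(c("white", "black", "asian"), n, TRUE,
                           prob = c(0.75, 0.15, 0.10)),
             bmi = rnorm(n, 26.5, 4.5),
             handedness = pmin(100, pmax(-100, rnorm(n, 65, 45))),
             rms_motion = abs(rnorm(n, 0.3, 0.2)),
             acc_story = pmin(100, pmax(0, rnorm(n, 85, 10))),
             stringsAsFactors = FALSE)
}
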
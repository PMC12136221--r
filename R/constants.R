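#' Canonical task epochs, networks, and accuracy-scored epochs
#'
#' The analysis operates on 17 task-fMRI contrast epochs drawn from seven
#' task paradigms (emotion, gambling, language, motor, relational, social
#' cognition, working memory) and a 12-network cortical partition. Accuracy
#' is only scored for 12 of the 17 epochs (the five motor epochs are cued
#' movements without a behavioral accuracy measure).
#'
#' @return Character vectors of canonical names, in canonical order.
#' @export
canonical_epochs <- function() {
  c("faces", "shapes", "reward", "punish", "story", "math",
    "lh", "rh", "lf", "rf", "t",
    "rel", "match", "social", "random", "0bk", "2bk")
}

#' @rdname canonical_epochs
#' @export
canonical_networks <- function() {
  c("VIS1", "VIS2", "SMM", "CON", "DAN", "LAN",
    "FPN", "AUD", "DMN", "PMM", "VMM", "ORA")
}

#' @rdname canonical_epochs
#' @export
scored_epochs <- function() {
  c("faces", "shapes", "reward", "punish", "story", "math",
    "rel", "match", "social", "random", "0bk", "2bk")
}

#' @rdname canonical_epochs
#' @export
pls_networks <- function() {
  c("VIS1", "VIS2", "SMM", "CON", "DAN", "LAN", "FPN", "AUD", "DMN")
}

# Networks excluded from PLS prediction: small, diffusely activated partitions.
pls_excluded_networks <- function() c("ORA", "VMM", "PMM")

#' Task membership of each canonical epoch
#'
#' @return Named character vector mapping epoch name to task paradigm.
#' @export
epoch_tasks <- function() {
  c(faces = "emotion", shapes = "emotion",
    reward = "gambling", punish = "gambling",
    story = "language", math = "language",
    lh = "motor", rh = "motor", lf = "motor", rf = "motor", t = "motor",
    rel = "relational", match = "relational",
    social = "social", random = "social",
    `0bk` = "wm", `2bk` = "wm")
}

# Background label code for vertices not assigned to any network.
BACKGROUND_CODE <- -1L
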
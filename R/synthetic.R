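# Synthetic peak-matrix generator with planted three-group structure.
#
# Emulates aligned UPLC-MS peak tables: non-negative right-skewed
# intensities (log-normal), a large fraction of absent peaks (zeros), three
# balanced groups (control CG, disease model MG, treated RG) in which the
# treated group sits between control and model, and a subset of variables
# whose group effect enters through a latent two-factor interaction rather
# than an additive shift.

#' Configuration for the synthetic peak-matrix generator
#'
#' Defaults emulate the canonical positive-ion-mode design: 3 x 56 samples
#' over 2889 aligned variables. The disease model group (MG) is shifted by
#' `effect_size` on the log-intensity scale on the informative variables;
#' the treated group (RG) is pulled back toward control by
#' `treatment_recovery`, so its expected shift is
#' `(1 - treatment_recovery) * effect_size`.
#'
#' @param n_per_class Samples per group (CG/MG/RG).
#' @param n_variables Aligned m/z--retention-time features.
#' @param n_informative Variables carrying a group effect; defaults to
#'   60 or `n_variables`, whichever is smaller.
#' @param effect_size Log-scale mean shift between CG and MG on informative
#'   variables.
#' @param treatment_recovery Fraction of the MG shift removed in RG
#'   (1 = fully restored to control).
#' @param sparsity Fraction of entries zeroed (absent peaks).
#' @param noise_sd SD of the multiplicative (log-normal) noise.
#' @param nonlinear_fraction Fraction of informative variables whose effect
#'   is carried by a product of two latent sample factors instead of an
#'   additive shift.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_per_class = 56L, n_variables = 2889L,
                             n_informative = NULL, effect_size = 1,
                             treatment_recovery = 0.6, sparsity = 0.4,
                             noise_sd = 0.5, nonlinear_fraction = 0.2,
                             seed = 1L) {
  assert_scalar_number(n_per_class, "n_per_class", lower = 1)
  assert_scalar_number(n_variables, "n_variables", lower = 1)
  n_informative <- n_informative %||% min(60L, n_variables)
  assert_scalar_number(n_informative, "n_informative", lower = 0,
                       upper = n_variables)
  assert_scalar_number(effect_size, "effect_size", lower = 0)
  assert_scalar_number(treatment_recovery, "treatment_recovery",
                       lower = 0, upper = 1)
  assert_scalar_number(sparsity, "sparsity", lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(noise_sd, "noise_sd", lower = 1e-12)
  assert_scalar_number(nonlinear_fraction, "nonlinear_fraction",
                       lower = 0, upper = 1)
  structure(list(n_per_class = as.integer(n_per_class),
                 n_variables = as.integer(n_variables),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 treatment_recovery = treatment_recovery,
                 sparsity = sparsity, noise_sd = noise_sd,
                 nonlinear_fraction = nonlinear_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic labelled peak matrix
#'
#' Draws per-variable baseline log-intensities once, applies the group
#' shifts of [synthetic_config()] to the planted informative variables
#' (additively, or through a latent two-factor product for the nonlinear
#' subset), adds log-normal noise, exponentiates, and zeroes entries
#' independently at the sparsity rate. Labels are exactly balanced.
#'
#' @param config A [synthetic_config()].
#' @return A peaks tibble (`sample_id`, `group`, one numeric column per
#'   variable) with the planted ground truth attached as attribute
#'   `"planted"` (see [planted_truth()]).
#' @examples
#' peaks <- generate_peaks(synthetic_config(n_per_class = 5, n_variables = 30,
#'                                          n_informative = 6, seed = 1))
#' dim(peaks)
#' @export
generate_peaks <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)

  n <- 3L * config$n_per_class
  p <- config$n_variables
  groups <- rep(c("CG", "MG", "RG"), each = config$n_per_class)

  # expected log-shift per group on informative variables
  shift <- c(CG = 0, MG = config$effect_size,
             RG = (1 - config$treatment_recovery) * config$effect_size)

  # synthetic m/z_RT variable identifiers (sorted by m/z, unique)
  mz <- sort(runif(p, 50, 1000))
  rt <- runif(p, 0.3, 15)
  variable_ids <- make.unique(sprintf("%.4f_%.2f", mz, rt), sep = "x")

  baseline <- rnorm(p, mean = 6, sd = 1.5)
  informative <- sort(sample.int(p, config$n_informative))
  n_nl <- round(config$nonlinear_fraction * config$n_informative)
  nonlinear <- if (n_nl > 0) informative[seq_len(n_nl)] else integer(0)
  additive <- setdiff(informative, nonlinear)

  L <- matrix(rnorm(n * p, sd = config$noise_sd), n, p)
  L <- sweep(L, 2, baseline, "+")
  if (length(additive)) {
    L[, additive] <- L[, additive] + shift[groups]
  }
  if (length(nonlinear)) {
    # latent two-factor interaction: u, w ~ N(sqrt(shift_g), 1) per sample,
    # so E[u * w] = shift_g and the effect is non-additive in the factors
    delta <- sqrt(shift[groups])
    u <- rnorm(n, mean = delta)
    w <- rnorm(n, mean = delta)
    L[, nonlinear] <- L[, nonlinear] + (u * w)
  }

  X <- exp(L)
  if (config$sparsity > 0) {
    X[matrix(runif(n * p) < config$sparsity, n, p)] <- 0
  }
  colnames(X) <- variable_ids

  out <- peaks_build(X, sprintf("S%03d", seq_len(n)), variable_ids, groups)
  class_means <- outer(rep(1, length(informative)), shift) +
    baseline[informative]
  dimnames(class_means) <- list(variable_ids[informative], names(shift))
  attr(out, "planted") <- list(
    informative = informative,
    informative_ids = variable_ids[informative],
    nonlinear = nonlinear,
    class_log_means = class_means,
    config = config,
    fingerprint = fingerprint(unclass(config)))
  out
}

#' Generate a negative-ion-mode style peak matrix
#'
#' [generate_peaks()] with the lower-dimensional negative-mode default of
#' 353 variables; any field of [synthetic_config()] can be overridden.
#'
#' @param ... Overrides passed to [synthetic_config()].
#' @return A labelled peaks tibble (see [generate_peaks()]).
#' @export
generate_negative_mode <- function(...) {
  overrides <- list(...)
  if (!"n_variables" %in% names(overrides)) overrides$n_variables <- 353L
  generate_peaks(do.call(synthetic_config, overrides))
}

#' Planted ground truth of a generated peak matrix
#'
#' Returns the informative-variable set and per-class expected log-means
#' planted by [generate_peaks()], for feature-recovery and power studies.
#'
#' @param generated A tibble produced by [generate_peaks()].
#' @param config Optional [synthetic_config()]; if given, its fingerprint
#'   must match the one stored in `generated`.
#' @return List with `informative` (column indices into the feature block),
#'   `informative_ids`, `nonlinear`, `class_log_means` (variables x
#'   CG/MG/RG), and the generating `config`.
#' @export
planted_truth <- function(generated, config = NULL) {
  planted <- attr(generated, "planted")
  if (is.null(planted)) {
    abort("`generated` carries no planted truth; was it produced by generate_peaks()?")
  }
  if (!is.null(config) &&
      !identical(fingerprint(unclass(config)), planted$fingerprint)) {
    abort("Config fingerprint does not match the one stored in `generated`.")
  }
  planted
}
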
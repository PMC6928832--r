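# Synthetic electronic-nose data: multichannel transient response curves and
# direct classifier vote matrices. Both generators are fully seeded so every
# downstream stage of the toolkit has a reproducible, self-contained input.

# Fixed per-channel response gains: sensors in an array differ in sensitivity,
# emulated by a spread of steady-state amplitudes.
channel_gains <- function(n_channels) {
  seq(0.8, 2.0, length.out = n_channels)
}

# Fixed class-contrast pattern: the disease class shifts each channel's
# amplitude by +/-10% of its gain (alternating sign so classes differ in
# response *pattern*, not just overall scale), scaled by class_separation.
channel_contrast <- function(n_channels) {
  0.1 * channel_gains(n_channels) * rep_len(c(1, -1), n_channels)
}

# Canonical chemiresistor transient: saturating exponential rise while the
# analyte is present, multiplicative exponential recovery toward baseline
# after gas-off. Time is treated as unitless sample indices.
response_profile <- function(n_timesteps, rise_frac = 0.15, on_frac = 0.6,
                             decay_frac = 0.25) {
  t <- seq_len(n_timesteps)
  t_on <- on_frac * n_timesteps
  tau_r <- rise_frac * n_timesteps
  tau_d <- decay_frac * n_timesteps
  peak <- 1 - exp(-t_on / tau_r)
  ifelse(t <= t_on, 1 - exp(-t / tau_r), peak * exp(-(t - t_on) / tau_d))
}

#' Simulate labelled multichannel sensor responses
#'
#' Generates a balanced two-class set of gas-sensor-array transients that
#' emulate breath measurements: each sample is an `n_channels` x
#' `n_timesteps` matrix of baseline + class-dependent amplitude x kinetic
#' response + Gaussian noise + low-frequency baseline drift. Class label 1 is
#' the positive (disease) class throughout the package.
#'
#' Per-sample biological variability is emulated by a multiplicative
#' amplitude jitter (`amplitude_cv`); instrument noise by i.i.d. Gaussian
#' noise (`noise_sd`) and a slow sinusoidal drift with random phase
#' (`drift_sd`). `positive_noise_inflation` multiplies both noise scales for
#' the positive class only, producing a controllable "hard positives" regime
#' for sensitivity experiments.
#'
#' @param n_per_class Samples per class (total is twice this).
#' @param n_channels Number of sensor channels (default 13).
#' @param n_timesteps Points per channel (default 675).
#' @param class_separation Non-negative scale of the difference between the
#'   class mean amplitude vectors; 0 makes the classes identical in mean.
#' @param noise_sd Standard deviation of additive Gaussian noise, in signal
#'   units.
#' @param drift_sd Standard deviation of the amplitude of the low-frequency
#'   baseline drift component.
#' @param amplitude_cv Coefficient of variation of the per-sample,
#'   per-channel amplitude jitter (subject-to-subject variability).
#' @param positive_noise_inflation Factor (>= 1) multiplying `noise_sd` and
#'   `drift_sd` for positive-class samples.
#' @param baseline Baseline sensor level added to every channel.
#' @param seed Integer seed; identical configuration implies bitwise-identical
#'   output.
#' @return A tibble with columns `sample_id`, `label` (integer 0/1) and
#'   `signal` (list-column of `n_channels` x `n_timesteps` matrices).
#' @examples
#' samples <- simulate_breath_samples(n_per_class = 5, n_timesteps = 60, seed = 1)
#' dim(samples$signal[[1]])
#' @export
simulate_breath_samples <- function(n_per_class = 50, n_channels = 13,
                                    n_timesteps = 675, class_separation = 1,
                                    noise_sd = 0.05, drift_sd = 0.02,
                                    amplitude_cv = 0.1,
                                    positive_noise_inflation = 1,
                                    baseline = 1, seed = 1L) {
  if (n_per_class < 1 || n_channels < 1 || n_timesteps < 1) {
    abort("`n_per_class`, `n_channels` and `n_timesteps` must all be >= 1.",
          class = "msep_config_error")
  }
  if (class_separation < 0 || noise_sd < 0 || drift_sd < 0 || amplitude_cv < 0) {
    abort("Scale parameters must be non-negative.", class = "msep_config_error")
  }
  if (positive_noise_inflation < 1) {
    abort("`positive_noise_inflation` must be >= 1.", class = "msep_config_error")
  }
  set.seed(seed)
  profile <- response_profile(n_timesteps)
  gains <- channel_gains(n_channels)
  contrast <- channel_contrast(n_channels)
  labels <- rep(c(0L, 1L), each = n_per_class)
  tt <- seq_len(n_timesteps) / n_timesteps
  signals <- purrr::map(seq_along(labels), function(i) {
    y <- labels[i]
    infl <- if (y == 1L) positive_noise_inflation else 1
    amp_mean <- gains + y * class_separation * contrast
    amp <- amp_mean * (1 + rnorm(n_channels, 0, amplitude_cv))
    sig <- baseline + outer(amp, profile)
    if (noise_sd > 0) {
      sig <- sig + matrix(rnorm(n_channels * n_timesteps, 0, noise_sd * infl),
                          n_channels, n_timesteps)
    }
    if (drift_sd > 0) {
      phase <- runif(n_channels, 0, 2 * pi)
      damp <- rnorm(n_channels, 0, drift_sd * infl)
      sig <- sig + damp * sin(outer(phase, rep(1, n_timesteps)) +
                                2 * pi * outer(rep(1, n_channels), tt))
    }
    sig
  })
  tibble(
    sample_id = sprintf("s%04d", seq_along(labels)),
    label = labels,
    signal = signals
  )
}

#' Flatten sensor samples to a numeric matrix
#'
#' Stacks each sample's signal matrix (column-major, i.e. channel varies
#' fastest) into one row of a samples x (channels * timesteps) matrix.
#'
#' @param samples A tibble from [simulate_breath_samples()] (or any tibble
#'   with a `signal` list-column of equal-shape matrices).
#' @return A numeric matrix with one row per sample.
#' @export
flatten_samples <- function(samples) {
  mat <- do.call(rbind, purrr::map(samples$signal, as.vector))
  rownames(mat) <- samples$sample_id
  mat
}

#' Summarise each channel of a sensor sample set
#'
#' Cheap hand-crafted features for baselines and fast experiments: per
#' channel, the peak response and the time-averaged response.
#'
#' @inheritParams flatten_samples
#' @return A tibble with `sample_id`, `label` and `peak_*`/`avg_*` columns.
#' @export
summarize_channels <- function(samples) {
  feats <- purrr::map(samples$signal, function(sig) {
    c(apply(sig, 1, max), rowMeans(sig))
  })
  n_channels <- nrow(samples$signal[[1]])
  nm <- c(sprintf("peak_%02d", seq_len(n_channels)),
          sprintf("avg_%02d", seq_len(n_channels)))
  feat_mat <- do.call(rbind, feats)
  colnames(feat_mat) <- nm
  dplyr::bind_cols(
    tibble(sample_id = samples$sample_id, label = samples$label),
    as_tibble(feat_mat)
  )
}

#' Construct a vote matrix
#'
#' A vote matrix is the substrate of all pruning measures: a binary
#' `n_samples` x `n_classifiers` matrix whose entry (i, j) indicates whether
#' base classifier j classifies pruning sample i correctly, together with the
#' true labels of the pruning samples.
#'
#' @param correct Binary (0/1) matrix, samples in rows, classifiers in
#'   columns.
#' @param labels Integer 0/1 vector of true labels, one per row.
#' @return An object of class `vote_matrix`.
#' @export
vote_matrix <- function(correct, labels) {
  correct <- as.matrix(correct)
  if (!all(correct %in% c(0, 1))) {
    abort("`correct` must contain only 0/1 entries.", class = "msep_config_error")
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(correct)) {
    abort("`labels` must have one entry per row of `correct`.",
          class = "msep_dimension_error")
  }
  if (!all(labels %in% c(0L, 1L))) {
    abort("`labels` must be 0/1.", class = "msep_config_error")
  }
  storage.mode(correct) <- "integer"
  structure(list(correct = correct, labels = labels), class = "vote_matrix")
}

#' @export
print.vote_matrix <- function(x, ...) {
  cat(sprintf("<vote_matrix: %d samples x %d classifiers, %d positive>\n",
              nrow(x$correct), ncol(x$correct), sum(x$labels)))
  invisible(x)
}

#' Simulate a classifier correctness (vote) matrix directly
#'
#' Draws a binary correctness matrix from a Gaussian-copula model: a latent
#' per-sample difficulty variable shared by all classifiers induces
#' correlated error patterns, while each classifier's marginal correctness
#' rate matches its configured accuracy.
#'
#' @param n_samples Number of pruning samples (rows).
#' @param n_classifiers Odd number of base classifiers (columns).
#' @param accuracy Scalar or length-`n_classifiers` vector of marginal
#'   correctness probabilities in \[0, 1\].
#' @param correlation Inter-classifier correlation in \[0, 1): weight of the
#'   shared per-sample difficulty component.
#' @param positive_fraction Fraction of samples labelled 1 (positive).
#' @param seed Integer seed.
#' @return A list-like [vote_matrix()] object.
#' @examples
#' vm <- simulate_vote_matrix(100, 11, accuracy = 0.7, seed = 1)
#' colMeans(vm$correct)
#' @export
simulate_vote_matrix <- function(n_samples, n_classifiers = 11, accuracy = 0.7,
                                 correlation = 0, positive_fraction = 0.5,
                                 seed = 1L) {
  if (n_samples < 1) abort("`n_samples` must be >= 1.", class = "msep_config_error")
  if (n_classifiers %% 2 == 0) {
    abort("`n_classifiers` must be odd (avoids voting ties).",
          class = "msep_config_error")
  }
  if (any(accuracy < 0 | accuracy > 1)) {
    abort("`accuracy` must lie in [0, 1].", class = "msep_config_error")
  }
  if (correlation < 0 || correlation >= 1) {
    abort("`correlation` must lie in [0, 1).", class = "msep_config_error")
  }
  if (positive_fraction <= 0 || positive_fraction >= 1) {
    abort("`positive_fraction` must lie in (0, 1).", class = "msep_config_error")
  }
  set.seed(seed)
  acc <- rep_len(accuracy, n_classifiers)
  n_pos <- max(1L, min(n_samples - 1L, as.integer(round(positive_fraction * n_samples))))
  labels <- sample(c(rep(1L, n_pos), rep(0L, n_samples - n_pos)))
  difficulty <- rnorm(n_samples)
  noise <- matrix(rnorm(n_samples * n_classifiers), n_samples, n_classifiers)
  u <- pnorm(sqrt(correlation) * difficulty + sqrt(1 - correlation) * noise)
  correct <- 1L * (u < matrix(acc, n_samples, n_classifiers, byrow = TRUE))
  vote_matrix(correct, labels)
}
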
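#' Generate synthetic breath-like waveform curves
#'
#' Produces a seeded, fully deterministic set of periodic flow-like
#' curves `v(t) = A * sin(2*pi*RR/60 * t + phi) + noise` with per-curve
#' jittered amplitude, phase and respiratory rate, grouped into
#' `n_clusters` rate/amplitude clusters.  The generator emulates the
#' similarity structure of ventilation waveforms (which is all the
#' anonymization pipeline reacts to), not their physiology.
#'
#' @param n_curves Number of curves.
#' @param duration Curve duration in seconds.
#' @param sample_rate Sampling rate in Hz; with `rate_jitter_t > 0` the
#'   sampling intervals themselves are jittered (irregular grids).
#' @param n_clusters Number of similarity clusters.
#' @param respiratory_rate Breaths per minute, one value per cluster
#'   (recycled).
#' @param amplitude Amplitude per cluster (recycled).
#' @param amplitude_jitter,phase_jitter,rate_jitter Within-cluster
#'   standard deviations of amplitude, phase (radians) and rate.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param rate_jitter_t Relative jitter of the sampling intervals
#'   (0 = regular grid).
#' @param quantity_name,unit Metadata stamped on every curve.
#' @param seed Integer seed; fully determines the output.
#' @return An aligned `curve_set` whose curves carry a `cluster`
#'   attribute (the generating cluster index).
#' @export
generate_breath_curves <- function(n_curves = 12L,
                                   duration = 8,
                                   sample_rate = 50,
                                   n_clusters = 1L,
                                   respiratory_rate = 50,
                                   amplitude = 10,
                                   amplitude_jitter = 0,
                                   phase_jitter = 0,
                                   rate_jitter = 0,
                                   noise_sd = 0,
                                   rate_jitter_t = 0,
                                   quantity_name = "AWF",
                                   unit = "L/min",
                                   seed = 1L) {
  stopifnot(n_curves >= 1, duration > 0, sample_rate > 0, n_clusters >= 1)
  rr <- rep_len(respiratory_rate, n_clusters)
  amp <- rep_len(amplitude, n_clusters)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  clusters <- rep_len(seq_len(n_clusters), n_curves)
  curves <- lapply(seq_len(n_curves), function(i) {
    cl <- clusters[i]
    a <- amp[cl] + rnorm(1L, sd = amplitude_jitter)
    ph <- rnorm(1L, sd = phase_jitter)
    r <- rr[cl] + rnorm(1L, sd = rate_jitter)
    dt <- rep(1 / sample_rate, ceiling(duration * sample_rate))
    if (rate_jitter_t > 0) {
      dt <- dt * exp(rnorm(length(dt), sd = rate_jitter_t))
      dt <- dt * duration / sum(dt)  # keep the requested span
    }
    t <- cumsum(c(0, dt))
    t <- t[t <= duration + 1e-9]
    v <- a * sin(2 * pi * r / 60 * t + ph) + rnorm(length(t), sd = noise_sd)
    c <- curve(t, v, curve_id = sprintf("c%03d", i),
               subject_uuid = sprintf("%08d-0000-0000-0000-%012d", seed, i),
               start = "2021-01-01T00:00:00",
               quantity_name = quantity_name, unit = unit)
    attr(c, "cluster") <- cl
    c
  })
  cs <- align_dataset(curves)
  attr(cs, "clusters") <- setNames(clusters, curve_ids(cs))
  cs
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Synthetic datasets shaped like the evaluation recordings
#'
#' Emulates the shape (curve counts, durations, sampling) of the three
#' ventilation-trial datasets the method is routinely run on:
#' \describe{
#'   \item{AWF}{airway flow: 12 curves, 8 s at 50 Hz (~400 points).}
#'   \item{AWP}{airway pressure: 28 curves, 4 s at 50 Hz (~200 points).}
#'   \item{SPO2}{oxygen saturation: 12 curves, 400 s at 0.5 Hz on
#'     average with jittered, irregular sampling (0.25–1 Hz).}
#' }
#' The waveforms themselves are synthetic sinusoid surrogates; only the
#' similarity structure matters downstream.
#'
#' @param name One of `"AWF"`, `"AWP"`, `"SPO2"`.
#' @param seed Integer seed.
#' @return An aligned `curve_set`.
#' @export
emulate_paper_shapes <- function(name = c("AWF", "AWP", "SPO2"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    AWF = generate_breath_curves(
      n_curves = 12L, duration = 8, sample_rate = 50, n_clusters = 3L,
      respiratory_rate = c(30, 45, 60), amplitude = c(8, 10, 12),
      amplitude_jitter = 0.8, phase_jitter = 0.2, rate_jitter = 1.5,
      noise_sd = 0.3, quantity_name = "AWF", unit = "L/min", seed = seed),
    AWP = generate_breath_curves(
      n_curves = 28L, duration = 4, sample_rate = 50, n_clusters = 3L,
      respiratory_rate = c(30, 45, 60), amplitude = c(12, 16, 20),
      amplitude_jitter = 1.2, phase_jitter = 0.2, rate_jitter = 2,
      noise_sd = 0.4, quantity_name = "AWP", unit = "mbar", seed = seed),
    SPO2 = generate_breath_curves(
      n_curves = 12L, duration = 400, sample_rate = 0.5, n_clusters = 2L,
      respiratory_rate = c(0.6, 0.9), amplitude = c(2, 3),
      amplitude_jitter = 0.2, phase_jitter = 0.3, rate_jitter = 0.02,
      noise_sd = 0.1, rate_jitter_t = 0.35,
      quantity_name = "SPO2", unit = "%", seed = seed))
}

#' Single-breath fixture: one period cropped at zero crossings
#'
#' Mirrors datasets of isolated breaths with a per-curve respiratory
#' rate class label: each curve is exactly one sine period of its
#' cluster's rate.
#'
#' @param n_curves Number of curves.
#' @param rates Respiratory rates (breaths/min) to cycle through as
#'   cluster labels.
#' @param sample_rate Sampling rate in Hz.
#' @param amplitude_jitter,noise_sd Within-class variation.
#' @param seed Integer seed.
#' @return A list of [curve] objects (not aligned: the curves have
#'   different lengths by construction).
#' @export
generate_single_breaths <- function(n_curves = 150L, rates = c(15, 70),
                                    sample_rate = 50,
                                    amplitude_jitter = 0.5, noise_sd = 0.2,
                                    seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- rep_len(seq_along(rates), n_curves)
  lapply(seq_len(n_curves), function(i) {
    r <- rates[cl[i]]
    period <- 60 / r
    t <- seq(0, period, by = 1 / sample_rate)
    a <- 10 + rnorm(1L, sd = amplitude_jitter)
    v <- a * sin(2 * pi * t / period) + rnorm(length(t), sd = noise_sd)
    c <- curve(t, v, curve_id = sprintf("rr%02d_c%03d", r, i),
               quantity_name = "AWF", unit = "L/min")
    attr(c, "cluster") <- cl[i]
    c
  })
}
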
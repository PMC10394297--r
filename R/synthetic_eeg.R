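# Synthetic multi-patient EEG cohort generator.
#
# Class identity (seizure vs normal) is carried by band-limited rhythmic
# structure plus sporadic spike-wave transients; each patient imposes a
# confounding shift: per-channel multiplicative gains, a patient-specific
# background spectral slope, a patient-specific oscillation frequency and a
# patient-specific noise level. Gains alone are removed exactly by
# per-channel min-max normalization, so the spectral confounds are what a
# patient-independent model must learn to ignore.

#' Specification of a synthetic EEG cohort
#'
#' Defaults emulate the study cohort: 14 subjects, 22 channels at 250 Hz,
#' 250 s of each state per subject, seizure signature in the theta band
#' (4-8 Hz).
#'
#' @param n_patients number of subjects.
#' @param n_channels channels per subject.
#' @param sampling_rate_hz sampling rate.
#' @param seconds_per_class_per_patient seconds of each of normal/seizure
#'   state per subject.
#' @param class_band_hz length-2 frequency interval carrying the seizure
#'   signature.
#' @param class_amplitude amplitude of the seizure oscillation relative to
#'   `noise_sd` (effect size; 0 removes the class signal entirely).
#' @param patient_gain_sd sd of log per-channel gains (multiplicative
#'   confound). 0 disables gains, the slope confound and the per-patient
#'   noise-level confound (the zero-confound null).
#' @param patient_freq_jitter_hz half-width of the per-patient shift of the
#'   seizure oscillation frequency around a cohort-level base frequency.
#' @param noise_sd scale of the 1/f-weighted background noise.
#' @param patient_slope_jitter half-width of the per-patient variation of
#'   the background spectral slope around 1 (the baseline-spectra
#'   confound); scaled off when `patient_gain_sd = 0`.
#' @param seed master seed; fixed seed gives byte-identical cohorts.
#' @return a list of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(n_patients = 14L, n_channels = 22L,
                                  sampling_rate_hz = 250,
                                  seconds_per_class_per_patient = 250,
                                  class_band_hz = c(4, 8),
                                  class_amplitude = 1.5,
                                  patient_gain_sd = 0.4,
                                  patient_freq_jitter_hz = 1.5,
                                  noise_sd = 1,
                                  patient_slope_jitter = 0.3,
                                  seed = 1L) {
  spec <- list(n_patients = as.integer(n_patients),
               n_channels = as.integer(n_channels),
               sampling_rate_hz = sampling_rate_hz,
               seconds_per_class_per_patient = seconds_per_class_per_patient,
               class_band_hz = class_band_hz,
               class_amplitude = class_amplitude,
               patient_gain_sd = patient_gain_sd,
               patient_freq_jitter_hz = patient_freq_jitter_hz,
               noise_sd = noise_sd,
               patient_slope_jitter = patient_slope_jitter,
               seed = as.integer(seed))
  if (spec$n_patients < 1L || spec$n_channels < 1L ||
      spec$sampling_rate_hz <= 0 || spec$seconds_per_class_per_patient <= 0 ||
      spec$noise_sd < 0 || spec$class_amplitude < 0 || spec$patient_gain_sd < 0) {
    stop_seizdg("invalid cohort specification", class = "seizdg_validation_error")
  }
  nyq <- spec$sampling_rate_hz / 2
  if (spec$class_band_hz[1] <= 0 || spec$class_band_hz[2] >= nyq ||
      spec$class_band_hz[1] >= spec$class_band_hz[2]) {
    stop_seizdg("class_band_hz must lie inside (0, Nyquist)",
                class = "seizdg_validation_error")
  }
  structure(spec, class = "synthetic_cohort_spec")
}

# 1/f^(slope/2)-shaped Gaussian noise, one channel per row.
pink_noise <- function(n_channels, n_samples, slope = 1) {
  out <- matrix(0, n_channels, n_samples)
  freqs <- c(1, seq_len(n_samples - 1))      # avoid the DC singularity
  w <- 1 / pmin(freqs, n_samples - freqs + 1)^(slope / 2)
  for (ch in seq_len(n_channels)) {
    spec <- stats::fft(stats::rnorm(n_samples)) * w
    x <- Re(stats::fft(spec, inverse = TRUE)) / n_samples
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

#' Generate a synthetic multi-patient cohort
#'
#' Each patient's recording is `2 * seconds_per_class_per_patient` long:
#' the normal state first, then the seizure state, with an annotation that
#' tiles the recording exactly. Patient structure (gains, frequencies,
#' slopes) and background noise come from two independent random streams of
#' the master seed, so patient identities are stable if only noise is
#' resampled.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @return list of `n_patients` elements, each
#'   `list(signal = multichannel_signal, annotation = data.frame)` with
#'   clinical term-annotation columns `patient_id, start_s, stop_s, label`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  fs <- spec$sampling_rate_hz
  sec <- spec$seconds_per_class_per_patient
  Tn <- round(2 * sec * fs)
  confound_on <- spec$patient_gain_sd > 0

  # structure stream: everything that defines a patient's identity
  set.seed(derive_seed(spec$seed, "cohort-structure"))
  f0 <- stats::runif(1, spec$class_band_hz[1], spec$class_band_hz[2])
  pat <- lapply(seq_len(spec$n_patients), function(p) {
    list(
      gains = exp(stats::rnorm(spec$n_channels, 0, spec$patient_gain_sd)),
      freq = f0 + stats::runif(1, -1, 1) * spec$patient_freq_jitter_hz,
      slope = 1 + if (confound_on)
        stats::runif(1, -1, 1) * spec$patient_slope_jitter else 0,
      noise_scale = if (confound_on)
        exp(stats::rnorm(1, 0, spec$patient_gain_sd / 2)) else 1,
      # seizure focus topography: per-patient channel weighting of the
      # ictal discharge (the focus location varies across patients);
      # uniform when the confound is disabled
      topo = if (confound_on) {
        w <- exp(stats::rnorm(spec$n_channels, 0, 2 * spec$patient_gain_sd))
        w / mean(w)
      } else rep(1, spec$n_channels),
      phase = stats::runif(spec$n_channels, 0, 2 * pi),
      # ongoing background rhythm (alpha/mu-like), present in both states;
      # its frequency is patient-specific and may fall near the seizure
      # band, so rhythm frequency alone is an unreliable class feature.
      # Identical across patients when the confound is disabled.
      bg_freq = if (confound_on) stats::runif(1, 2, 12) else 10,
      bg_phase = stats::runif(spec$n_channels, 0, 2 * pi),
      bg_topo = if (confound_on) {
        w <- exp(stats::rnorm(spec$n_channels, 0, spec$patient_gain_sd))
        w / mean(w)
      } else rep(1, spec$n_channels)
    )
  })

  # noise stream: background + transient placement
  set.seed(derive_seed(spec$seed, "cohort-noise"))
  lapply(seq_len(spec$n_patients), function(p) {
    pp <- pat[[p]]
    x <- pink_noise(spec$n_channels, Tn, pp$slope) *
      (spec$noise_sd * pp$noise_scale)
    tt_all <- (seq_len(Tn) - 1) / fs
    # background rhythm amplitude rides on the noise floor, independent of
    # the seizure effect size (so a large class amplitude still dominates
    # class-band power within a patient)
    bg_amp <- spec$noise_sd * pp$noise_scale
    for (ch in seq_len(spec$n_channels)) {
      x[ch, ] <- x[ch, ] + bg_amp * pp$bg_topo[ch] *
        sin(2 * pi * pp$bg_freq * tt_all + pp$bg_phase[ch])
    }
    seiz_idx <- (Tn %/% 2 + 1L):Tn
    if (spec$class_amplitude > 0) {
      tt <- (seiz_idx - 1) / fs
      amp <- spec$class_amplitude * spec$noise_sd * pp$noise_scale
      for (ch in seq_len(spec$n_channels)) {
        x[ch, seiz_idx] <- x[ch, seiz_idx] +
          amp * pp$topo[ch] * sin(2 * pi * pp$freq * tt + pp$phase[ch])
      }
      # rhythmic spike-wave complexes (~2.5/s with timing jitter), the
      # classic ictal discharge pattern: sharp positive transients riding
      # on the oscillation
      rate <- 2.5
      n_spk <- max(1L, round(sec * rate))
      at <- round(seq(seiz_idx[1], Tn - fs / 5, length.out = n_spk) +
                    stats::runif(n_spk, -0.1, 0.1) * fs)
      # spike-wave complexes are generalized (visible on every channel),
      # unlike the focal oscillation: they are the patient-invariant part
      # of the ictal signature
      for (s in at) {
        idx <- s:min(s + round(fs / 10), Tn)
        burst <- amp * 0.8 * exp(-((idx - s) / (fs / 40))^2)
        x[, idx] <- x[, idx] + matrix(burst, spec$n_channels, length(idx),
                                      byrow = TRUE)
      }
    }
    x <- x * pp$gains
    pid <- sprintf("synth%02d", p)
    list(
      signal = multichannel_signal(x, fs, patient_id = pid),
      annotation = data.frame(
        patient_id = pid,
        start_s = c(0, sec), stop_s = c(sec, 2 * sec),
        label = c("bckg", "seiz"), stringsAsFactors = FALSE
      )
    )
  })
}

#' Normalize, segment and label every patient of a cohort
#'
#' Delegates to [minmax_normalize()], [segment_signal()] and
#' [label_segments()]; patients are assigned integer labels 1..n in cohort
#' order.
#'
#' @param cohort output of [generate_cohort()] (or any list of
#'   `list(signal, annotation)` pairs).
#' @param window_len window length in samples.
#' @param overlap overlap fraction.
#' @return list of labeled per-patient `segment_batch` objects.
#' @export
cohort_to_batches <- function(cohort, window_len = 250L, overlap = 0.5) {
  if (length(cohort) == 0L) {
    stop_seizdg("empty cohort", class = "seizdg_validation_error")
  }
  lapply(seq_along(cohort), function(p) {
    sig <- minmax_normalize(cohort[[p]]$signal)
    batch <- segment_signal(sig, window_len, overlap)
    label_segments(batch, cohort[[p]]$annotation, patient_label = p)
  })
}

# Class-band log relative bandpower per segment: band power summed over
# channels divided by total power summed over channels (power-weighted, so
# focal channels are not diluted). Used by tests as a model-free reference
# classifier.
segment_bandpower <- function(batch, band_hz) {
  fs <- batch$sampling_rate_hz
  L <- batch$window_len
  freqs <- (seq_len(L) - 1) * fs / L
  sel <- freqs >= band_hz[1] & freqs <= band_hz[2]
  vapply(seq_len(batch$n), function(i) {
    m <- matrix(batch$x[i, , ], dim(batch$x)[2], L)
    band <- 0; tot <- 0
    for (ch in seq_len(nrow(m))) {
      sp <- Mod(stats::fft(m[ch, ] - mean(m[ch, ])))^2
      band <- band + sum(sp[sel])
      tot <- tot + sum(sp[-1])
    }
    log(band / tot + 1e-12)
  }, 0)
}
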
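#' Simulation parameters for gait-like fixture recordings
#'
#' Describes a synthetic nine-channel accelerometer recording: sampling rate,
#' a segment plan of `(annotation, duration)` pairs, per-channel baseline
#' offsets (gravity projections, milli-g), a walking oscillation, a freeze
#' tremble band, and white measurement noise. The defaults emulate the
#' regimes of lab gait protocols: 64 Hz sampling; walking as a ~2 Hz
#' locomotion oscillation, strongest on the horizontal-forward channels;
#' freezing as a higher-frequency (3-8 Hz) trembling-in-place with reduced
#' forward amplitude plus a postural mean shift; annotation-0 stretches as
#' baseline noise only (sensors worn, no protocol activity).
#'
#' @param sampling_rate samples per second (Hz), default 64.
#' @param segments list of `c(annotation, duration_s)` pairs (or a 2-column
#'   matrix); annotations in `{0, 1, 2}`, durations positive seconds.
#' @param baseline length-9 numeric, per-channel offsets in milli-g.
#' @param walk_freq walking oscillation frequency (Hz).
#' @param walk_amp walking amplitude (milli-g) on forward channels; vertical
#'   and lateral channels get 0.6 and 0.3 of it.
#' @param freeze_band length-2 numeric, tremble frequency band (Hz).
#' @param freeze_amp tremble amplitude (milli-g); forward channels get 0.5 of
#'   it so freezing has lower forward amplitude than walking.
#' @param freeze_shift length-9 numeric, postural mean offset (milli-g) added
#'   during freeze segments.
#' @param noise_sd white-noise standard deviation (milli-g).
#' @param seed integer seed; identical parameters give identical recordings.
#' @return an object of class `"sim_params"`.
#' @export
sim_params <- function(sampling_rate = 64,
                       segments = list(c(1, 10)),
                       baseline = c(60, -970, 30, 40, -980, -20, 20, -990, 10),
                       walk_freq = 2,
                       walk_amp = 250,
                       freeze_band = c(3, 8),
                       freeze_amp = 120,
                       freeze_shift = c(-120, 80, 40, -100, 70, 40, 150, -90, 50),
                       noise_sd = 30,
                       seed = 1L) {
  if (sampling_rate <= 0) stop("'sampling_rate' must be positive")
  if (is.matrix(segments)) segments <- asplit(segments, 1L)
  if (length(segments) == 0L) stop("segment plan must not be empty")
  seg <- do.call(rbind, lapply(segments, function(s) as.numeric(s[1:2])))
  if (!all(seg[, 1L] %in% c(0, 1, 2))) stop("segment annotations must lie in {0, 1, 2}")
  if (any(seg[, 2L] <= 0)) stop("segment durations must be positive")
  if (length(baseline) != 9L || length(freeze_shift) != 9L)
    stop("'baseline' and 'freeze_shift' must have length 9")
  if (walk_amp < 0 || freeze_amp < 0 || noise_sd < 0)
    stop("amplitudes and noise SD must be non-negative")
  if (length(freeze_band) != 2L || freeze_band[1L] <= 0 || diff(freeze_band) <= 0)
    stop("'freeze_band' must be an increasing positive pair of frequencies")
  structure(list(sampling_rate = sampling_rate, segments = seg,
                 baseline = baseline, walk_freq = walk_freq,
                 walk_amp = walk_amp, freeze_band = freeze_band,
                 freeze_amp = freeze_amp, freeze_shift = freeze_shift,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "sim_params")
}

# Per-channel amplitude profiles: forward (hor) channels are 1, 4, 7.
.walk_profile <- c(1, 0.6, 0.3, 1, 0.6, 0.3, 1, 0.6, 0.3)
.freeze_profile <- c(0.5, 1, 0.8, 0.5, 1, 0.8, 0.5, 1, 0.8)

#' Simulate one gait-like recording
#'
#' Each segment of the plan contributes `round(sampling_rate * duration)`
#' rows whose annotation follows the plan exactly. Walk segments carry a
#' sinusoid at the walking frequency (random phase per segment and channel),
#' freeze segments a band-limited tremble (three random tones in the freeze
#' band) plus the postural shift, annotation-0 segments only baseline noise.
#'
#' @param p a [sim_params()] object.
#' @return a [fog_recording()].
#' @export
simulate_recording <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  with_seed(p$seed, {
    rows <- round(p$sampling_rate * p$segments[, 2L])
    n <- sum(rows)
    dt <- 1000 / p$sampling_rate
    channels <- matrix(stats::rnorm(n * 9L, sd = p$noise_sd), n, 9L)
    channels <- sweep(channels, 2L, p$baseline, "+")
    annotation <- integer(n)
    at <- 0L
    for (s in seq_len(nrow(p$segments))) {
      ns <- rows[s]
      if (ns == 0L) next
      idx <- at + seq_len(ns)
      ann <- p$segments[s, 1L]
      annotation[idx] <- as.integer(ann)
      tt <- (seq_len(ns) - 1L) / p$sampling_rate
      if (ann == 1) {
        for (ch in 1:9) {
          phase <- stats::runif(1, 0, 2 * pi)
          channels[idx, ch] <- channels[idx, ch] +
            p$walk_amp * .walk_profile[ch] * sin(2 * pi * p$walk_freq * tt + phase)
        }
      } else if (ann == 2) {
        for (ch in 1:9) {
          tone <- stats::runif(3, p$freeze_band[1L], p$freeze_band[2L])
          phase <- stats::runif(3, 0, 2 * pi)
          tremble <- rowSums(sapply(1:3, function(k)
            sin(2 * pi * tone[k] * tt + phase[k])))
          channels[idx, ch] <- channels[idx, ch] + p$freeze_shift[ch] +
            p$freeze_amp * .freeze_profile[ch] * tremble / sqrt(3)
        }
      }
      at <- at + ns
    }
    fog_recording(round((seq_len(n) - 1L) * dt), channels, annotation,
                  sprintf("sim_seed%d", p$seed))
  })
}

#' Generate a seeded collection of fixture recordings
#'
#' Builds `n_recordings` recordings whose segment plans are laid out so that,
#' after [preprocess()] (which drops annotation-0 rows), the freeze-label
#' fraction matches `freeze_prevalence` and the total row count matches
#' `total_rows_target`. Each recording opens and closes with a short
#' annotation-0 stretch (10% of its rows) and alternates walking blocks with
#' three freeze episodes, mimicking lab FoG protocols where freezing is the
#' minority class.
#'
#' @param n_recordings number of recordings.
#' @param freeze_prevalence target freeze fraction among experiment rows,
#'   in `(0, 1)`.
#' @param total_rows_target total row count across recordings.
#' @param seed integer seed.
#' @param ... further arguments passed to [sim_params()] (e.g. `noise_sd`).
#' @return a `"fog_dataset"` collection (see [combine_recordings()]).
#' @export
make_fixture_dataset <- function(n_recordings = 4L, freeze_prevalence = 0.2,
                                 total_rows_target = 50000L, seed = 1L, ...) {
  if (freeze_prevalence <= 0 || freeze_prevalence >= 1)
    stop("'freeze_prevalence' must lie strictly between 0 and 1")
  if (total_rows_target < n_recordings)
    stop("infeasible target: fewer rows than recordings")
  rate <- 64
  rows_per_rec <- total_rows_target / n_recordings
  dur <- rows_per_rec / rate                # seconds per recording
  d0 <- 0.10 * dur                          # non-experiment head + tail
  d_exp <- dur - d0
  d_freeze <- freeze_prevalence * d_exp
  d_walk <- d_exp - d_freeze
  # three freeze episodes interleaved with four walking blocks
  plan <- list(c(0, d0 / 2))
  for (k in 1:3) {
    plan <- c(plan, list(c(1, d_walk / 4), c(2, d_freeze / 3)))
  }
  plan <- c(plan, list(c(1, d_walk / 4), c(0, d0 / 2)))
  recs <- lapply(seq_len(n_recordings), function(i) {
    simulate_recording(sim_params(sampling_rate = rate, segments = plan,
                                  seed = derive_seed(seed, i), ...))
  })
  combine_recordings(recs)
}

#' Mean periodogram power of a signal in a frequency band
#'
#' Raw periodogram (no taper or smoothing) of the demeaned signal, averaged
#' over Fourier frequencies inside `band`. Used to verify the spectral
#' separation of simulated walking (low-frequency) and freezing
#' (higher-frequency tremble) segments.
#'
#' @param x numeric signal.
#' @param rate sampling rate in Hz.
#' @param band length-2 numeric frequency band in Hz.
#' @return mean periodogram power in the band.
#' @export
band_power <- function(x, rate, band) {
  sp <- stats::spec.pgram(stats::ts(x - mean(x), frequency = rate),
                          taper = 0, plot = FALSE, detrend = FALSE)
  sel <- sp$freq >= band[1L] & sp$freq <= band[2L]
  if (!any(sel)) stop("band contains no Fourier frequency")
  mean(sp$spec[sel])
}
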
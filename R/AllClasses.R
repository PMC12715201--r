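#' @import methods
NULL

#' Hydrophone calibration record
#'
#' Describes the transfer chain from acoustic pressure to stored ADC counts:
#' hydrophone sensitivity (dB re 1 V/uPa), ADC bit depth, ADC full-scale
#' voltage and any additional gain. The defaults mirror a self-contained
#' acoustic logger in low-gain mode (sensitivity -189 dB re 1 V/uPa, 16-bit
#' ADC, 1 V peak full scale, 0 dB gain).
#'
#' @slot sensitivity_db hydrophone sensitivity in dB re 1 V/uPa (negative).
#' @slot adc_bits ADC resolution in bits (>= 8).
#' @slot adc_fullscale_volts ADC full-scale peak voltage (> 0).
#' @slot gain_db extra analog gain applied before the ADC, in dB.
#' @export
setClass("Calibration",
  representation(
    sensitivity_db = "numeric",
    adc_bits = "integer",
    adc_fullscale_volts = "numeric",
    gain_db = "numeric"
  ),
  prototype(
    sensitivity_db = -189,
    adc_bits = 16L,
    adc_fullscale_volts = 1.0,
    gain_db = 0
  )
)

setValidity("Calibration", function(object) {
  msg <- character()
  if (length(object@adc_bits) != 1L || object@adc_bits < 8L)
    msg <- c(msg, "adc_bits must be a single integer >= 8")
  if (length(object@adc_fullscale_volts) != 1L ||
      !is.finite(object@adc_fullscale_volts) ||
      object@adc_fullscale_volts <= 0)
    msg <- c(msg, "adc_fullscale_volts must be a single positive number")
  if (length(object@sensitivity_db) != 1L || !is.finite(object@sensitivity_db))
    msg <- c(msg, "sensitivity_db must be a single finite number")
  if (length(object@gain_db) != 1L || !is.finite(object@gain_db))
    msg <- c(msg, "gain_db must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' A calibrated mono recording
#'
#' Sample stream with its rate, unit state and attached [Calibration].
#' `unit` is either `"counts"` (raw ADC integers) or `"uPa"` (acoustic
#' pressure in micropascals); the state is single-valued and explicit so
#' conversions cannot be applied twice.
#'
#' @slot samples numeric vector of samples.
#' @slot sample_rate sampling rate in Hz.
#' @slot unit `"counts"` or `"uPa"`.
#' @slot start_offset seconds offset of the first sample (0 for file start).
#' @slot source_id free-text provenance (usually the file path).
#' @slot calibration a [Calibration].
#' @export
setClass("CalibratedRecording",
  representation(
    samples = "numeric",
    sample_rate = "numeric",
    unit = "character",
    start_offset = "numeric",
    source_id = "character",
    calibration = "Calibration"
  ),
  prototype(unit = "counts", start_offset = 0, source_id = "")
)

setValidity("CalibratedRecording", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "recording must contain at least one sample")
  if (length(object@sample_rate) != 1L || object@sample_rate <= 0)
    msg <- c(msg, "sample_rate must be a single positive number")
  if (!object@unit %in% c("counts", "uPa"))
    msg <- c(msg, "unit must be 'counts' or 'uPa'")
  if (object@start_offset < 0)
    msg <- c(msg, "start_offset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' One analysis segment of a recording
#'
#' Recordings are split into nominally 30-second segments (the unit over
#' which detection statistics such as the per-segment FDR peak are taken).
#' `t0` is the segment start in seconds relative to the parent file start;
#' intervals are half-open `[t0, t0 + n/fs)`.
#'
#' @slot samples numeric vector (pressure, uPa, once converted).
#' @slot sample_rate Hz.
#' @slot t0 seconds into the parent recording.
#' @slot filtered `TRUE` once the high-pass pre-filter has been applied.
#' @slot id short segment label used in logs and event tables.
#' @export
setClass("AudioSegment",
  representation(
    samples = "numeric",
    sample_rate = "numeric",
    t0 = "numeric",
    filtered = "logical",
    id = "character"
  ),
  prototype(t0 = 0, filtered = FALSE, id = "seg")
)

setValidity("AudioSegment", function(object) {
  msg <- character()
  if (length(object@samples) < 1L) msg <- c(msg, "segment is empty")
  if (object@sample_rate <= 0) msg <- c(msg, "sample_rate must be positive")
  if (object@t0 < 0) msg <- c(msg, "t0 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Matched averaging-filter pair for FDR scoring
#'
#' Holds the Gaussian-weighted moving-average kernel (MAF1) and the
#' rectangular kernel of identical length and gain (MAF2) used to score
#' Gaussian-shaped energy surges in the TKEO series. Both kernels have
#' length `2 * half_length + 1`.
#'
#' @slot maf1 Gaussian kernel coefficients.
#' @slot maf2 rectangular kernel coefficients (constant, same sum as maf1).
#' @slot half_length integer N; kernels run over offsets -N..N.
#' @slot sigma_g Gaussian standard deviation in seconds.
#' @slot sample_interval Ts in seconds.
#' @export
setClass("KernelPair",
  representation(
    maf1 = "numeric",
    maf2 = "numeric",
    half_length = "integer",
    sigma_g = "numeric",
    sample_interval = "numeric"
  )
)

setValidity("KernelPair", function(object) {
  msg <- character()
  n <- 2L * object@half_length + 1L
  if (length(object@maf1) != n || length(object@maf2) != n)
    msg <- c(msg, "kernel lengths must equal 2 * half_length + 1")
  s1 <- sum(object@maf1); s2 <- sum(object@maf2)
  if (abs(s1 - s2) > 1e-12 * abs(s1))
    msg <- c(msg, "maf1 and maf2 must have identical gain (equal sums)")
  if (which.max(object@maf1) != object@half_length + 1L)
    msg <- c(msg, "maf1 must peak at its center")
  if (max(abs(object@maf1 - rev(object@maf1))) > 1e-12 * max(object@maf1))
    msg <- c(msg, "maf1 must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Pulse detector configuration
#'
#' Tunables of the TKEO/FDR pulse detector. `fwhm` is the full width at
#' half maximum of the Gaussian matched filter (seconds; default 1e-4,
#' the length of a representative dolphin pulse). `threshold_fraction`
#' is the fraction of the per-segment FDR peak a candidate must exceed
#' (default 0.85) and `snr_min_db` the absolute signal-to-noise gate
#' (default 10 dB). `refractory` is the minimum spacing between distinct
#' events and `clip_halfwidth` half the width of the waveform clip cut
#' around each event. SNR estimation windows: `snr_signal_win` seconds
#' centered on the peak, `snr_noise_win` seconds of noise ending
#' `snr_noise_gap` seconds before the peak (slid earlier if that window
#' touches another detection).
#'
#' @export
setClass("DetectorConfig",
  representation(
    fwhm = "numeric",
    threshold_fraction = "numeric",
    snr_min_db = "numeric",
    refractory = "numeric",
    clip_halfwidth = "numeric",
    fdr_floor_fraction = "numeric",
    snr_signal_win = "numeric",
    snr_noise_win = "numeric",
    snr_noise_gap = "numeric",
    peak_scope = "character"
  ),
  prototype(
    fwhm = 1e-4,
    threshold_fraction = 0.85,
    snr_min_db = 10,
    refractory = 2e-4,
    clip_halfwidth = 1e-3,
    fdr_floor_fraction = 1e-3,
    snr_signal_win = 2e-4,
    snr_noise_win = 2e-3,
    snr_noise_gap = 5e-3,
    peak_scope = "segment"
  )
)

setValidity("DetectorConfig", function(object) {
  msg <- character()
  if (!(object@threshold_fraction > 0 && object@threshold_fraction < 1))
    msg <- c(msg, "threshold_fraction must lie in (0, 1)")
  if (object@fwhm <= 0) msg <- c(msg, "fwhm must be positive")
  if (object@refractory <= 0) msg <- c(msg, "refractory must be positive")
  if (object@clip_halfwidth <= 0) msg <- c(msg, "clip_halfwidth must be positive")
  if (!object@peak_scope %in% c("segment", "global"))
    msg <- c(msg, "peak_scope must be 'segment' or 'global'")
  if (length(msg)) msg else TRUE
})

#' Adaptive inter-pulse-interval train rule
#'
#' A pulse extends the current train iff its IPI is at most
#' `min(absolute_cap, ratio_beta * median(last window_m IPIs))`; the first
#' IPI of a train is only capped by `absolute_cap`. An IPI violating the
#' rule is an abrupt increase: it terminates the train and opens a new one.
#' Trains with fewer than `min_pulses` pulses are discarded.
#'
#' @export
setClass("TrainRule",
  representation(
    ratio_beta = "numeric",
    window_m = "integer",
    absolute_cap = "numeric",
    min_pulses = "integer"
  ),
  prototype(
    ratio_beta = 2.5,
    window_m = 5L,
    absolute_cap = 0.5,
    min_pulses = 3L
  )
)

setValidity("TrainRule", function(object) {
  msg <- character()
  if (object@ratio_beta <= 1) msg <- c(msg, "ratio_beta must be > 1")
  if (object@min_pulses < 2L) msg <- c(msg, "min_pulses must be >= 2")
  if (object@window_m < 1L) msg <- c(msg, "window_m must be >= 1")
  if (object@absolute_cap <= 0) msg <- c(msg, "absolute_cap must be positive")
  if (length(msg)) msg else TRUE
})

#' A classified pulse train
#'
#' Ordered detected pulses with their inter-pulse intervals, the class
#' label derived from the mean IPI (buzz < 4.9 ms, burst pulse 4.9-15.5 ms,
#' echolocation click > 15.5 ms) and, once measured, the per-pulse acoustic
#' parameter table.
#'
#' @slot events data.frame of pulse events (`time`, `fdr`, `snr_db`,
#'   `clip` list-column of uPa waveforms, `segment_id`).
#' @slot ipis numeric vector of inter-pulse intervals in seconds
#'   (length `numPulses - 1`).
#' @slot label `"click"`, `"burst_pulse"` or `"buzz"`.
#' @slot metrics per-pulse measurement table (may have zero rows before
#'   [measureTrain()] is called).
#' @slot source_id provenance of the parent recording.
#' @export
setClass("PulseTrain",
  representation(
    events = "data.frame",
    ipis = "numeric",
    label = "character",
    metrics = "data.frame",
    source_id = "character"
  ),
  prototype(metrics = data.frame(), source_id = "")
)

setValidity("PulseTrain", function(object) {
  msg <- character()
  n <- nrow(object@events)
  if (n < 2L) msg <- c(msg, "a train needs at least 2 pulses")
  if (length(object@ipis) != max(n - 1L, 0L))
    msg <- c(msg, "ipis must have length nrow(events) - 1")
  if (length(object@ipis) && any(object@ipis <= 0))
    msg <- c(msg, "ipis must be strictly positive")
  if (!object@label %in% c("click", "burst_pulse", "buzz"))
    msg <- c(msg, "label must be click, burst_pulse or buzz")
  if (length(msg)) msg else TRUE
})

#' A whistle time-frequency contour
#'
#' Uniformly sampled (time, frequency) trace of one narrow-band tonal.
#' `gaps` records silent intervals bridged by the joining rule (these are
#' the whistle's "breaks"); `grade` and `type` are `NA` until assigned.
#'
#' @slot time seconds, strictly increasing.
#' @slot freq Hz, positive.
#' @slot gaps two-column matrix of (start, end) seconds for bridged gaps.
#' @slot snr_db contour signal-to-noise ratio in dB (NA if unknown).
#' @slot grade integer 1..3 or NA.
#' @slot type one of constant/upsweep/downsweep/concave/convex/sinusoidal,
#'   or NA.
#' @slot source_id provenance.
#' @export
setClass("WhistleContour",
  representation(
    time = "numeric",
    freq = "numeric",
    gaps = "matrix",
    snr_db = "numeric",
    grade = "integer",
    type = "character",
    source_id = "character"
  ),
  prototype(
    gaps = matrix(numeric(0), ncol = 2,
                  dimnames = list(NULL, c("start", "end"))),
    snr_db = NA_real_, grade = NA_integer_, type = NA_character_,
    source_id = ""
  )
)

setValidity("WhistleContour", function(object) {
  msg <- character()
  if (length(object@time) != length(object@freq))
    msg <- c(msg, "time and freq must have equal length")
  if (length(object@time) && any(diff(object@time) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@freq) && any(object@freq <= 0))
    msg <- c(msg, "frequencies must be positive")
  if (ncol(object@gaps) != 2L)
    msg <- c(msg, "gaps must be a two-column matrix")
  if (!is.na(object@type) &&
      !object@type %in% c("constant", "upsweep", "downsweep",
                          "concave", "convex", "sinusoidal"))
    msg <- c(msg, "unknown contour type")
  if (length(msg)) msg else TRUE
})

#' Ground-truth manifest of a synthetic scene
#'
#' Exact truth for every component injected into a synthetic scene:
#' per-pulse centers and parameters, per-whistle truth contours, the
#' realized noise RMS and the seed, so detector output can be scored
#' without field data.
#'
#' @slot pulses data.frame: `time`, `f0_hz`, `sigma_t_s`, `splpp_db`,
#'   `snr_db` (realized in-window SNR over the noise floor), `train_id`,
#'   `intended_class`.
#' @slot whistles list of per-whistle truth (`contour` data.frame with
#'   `time_s`/`freq_hz`, `type`, `harmonic_db`, `start_s`, `duration_s`).
#' @slot noise_rms_db realized broadband noise RMS, dB re 1 uPa.
#' @slot duration scene length in seconds.
#' @slot sample_rate Hz.
#' @slot seed integer seed the scene was rendered with.
#' @export
setClass("SceneManifest",
  representation(
    pulses = "data.frame",
    whistles = "list",
    noise_rms_db = "numeric",
    duration = "numeric",
    sample_rate = "numeric",
    seed = "integer"
  )
)

setValidity("SceneManifest", function(object) {
  msg <- character()
  if (nrow(object@pulses) &&
      (any(object@pulses$time < 0) ||
       any(object@pulses$time > object@duration)))
    msg <- c(msg, "pulse times must lie within the scene duration")
  if (length(msg)) msg else TRUE
})
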
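#' @include AllClasses.R
NULL

#' Construct a calibration record
#'
#' @param sensitivity_db hydrophone sensitivity in dB re 1 V/uPa.
#' @param adc_bits ADC bit depth.
#' @param adc_fullscale_volts ADC full-scale peak voltage.
#' @param gain_db additional analog gain in dB.
#' @return a [Calibration-class] object.
#' @examples
#' cal <- calibration()          # -189 dB re 1 V/uPa, 16 bit, 1 V, 0 dB
#' @export
calibration <- function(sensitivity_db = -189, adc_bits = 16L,
                        adc_fullscale_volts = 1.0, gain_db = 0) {
  new("Calibration",
      sensitivity_db = sensitivity_db,
      adc_bits = as.integer(adc_bits),
      adc_fullscale_volts = adc_fullscale_volts,
      gain_db = gain_db)
}

#' Read a calibration from a YAML or JSON config block
#'
#' The file (or top-level key of it) must provide `sensitivity_db`,
#' and may provide `adc_bits`, `adc_fullscale_volts` and `gain_db`.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return a [Calibration-class].
#' @export
readCalibration <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$calibration)) cfg <- cfg$calibration
  calibration(
    sensitivity_db = cfg$sensitivity_db %||% -189,
    adc_bits = cfg$adc_bits %||% 16L,
    adc_fullscale_volts = cfg$adc_fullscale_volts %||% 1.0,
    gain_db = cfg$gain_db %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Pressure (uPa) corresponding to one ADC full-scale peak.
fullscalePressure <- function(cal) {
  cal@adc_fullscale_volts *
    10^(-cal@gain_db / 20) * 10^(-cal@sensitivity_db / 20)
}

#' Read a mono PCM WAV recording
#'
#' Loads a 16-bit PCM mono WAV file as raw ADC counts with the supplied
#' calibration attached. Multichannel files are rejected.
#'
#' @param path WAV file path.
#' @param cal a [Calibration-class] (default [calibration()]).
#' @return a [CalibratedRecording-class] in `"counts"` unit state.
#' @export
readRecording <- function(path, cal = calibration()) {
  w <- readWavPcm(path)
  if (w$channels != 1L)
    stop("multichannel WAV not supported (", w$channels,
         " channels in ", path, "); supply mono input")
  new("CalibratedRecording",
      samples = as.numeric(w$samples),
      sample_rate = as.numeric(w$sample_rate),
      unit = "counts",
      start_offset = 0,
      source_id = path,
      calibration = cal)
}

#' Convert ADC counts to acoustic pressure
#'
#' Applies the calibration chain
#' \deqn{p(\mu Pa) = \frac{counts}{2^{bits-1}} \cdot V_{fs} \cdot
#'       10^{-gain/20} \cdot 10^{-sensitivity/20}}
#' so that a full-scale count equals the pressure that produces the ADC
#' full-scale voltage at the hydrophone sensitivity. Conversion is linear
#' and refuses to run twice.
#'
#' @param rec a [CalibratedRecording-class] in `"counts"` state.
#' @return the recording with samples in uPa and unit state `"uPa"`.
#' @export
countsToPressure <- function(rec) {
  stopifnot(is(rec, "CalibratedRecording"))
  if (rec@unit == "uPa")
    stop("recording is already in pressure units (uPa); conversion is not idempotent")
  cal <- rec@calibration
  scale <- fullscalePressure(cal) / 2^(cal@adc_bits - 1L)
  rec@samples <- rec@samples * scale
  rec@unit <- "uPa"
  rec
}

# Inverse map used when rendering synthetic pressure to int16 counts.
pressureToCounts <- function(p, cal) {
  p / fullscalePressure(cal) * 2^(cal@adc_bits - 1L)
}

#' Split a recording into analysis segments
#'
#' Segments are `seg_len` seconds long (nominally 30 s, the unit over
#' which detection statistics are taken) and start at multiples of
#' `seg_len - overlap`, so a train spanning a boundary is fully contained
#' in at least one segment; the final segment carries the remainder.
#' Every sample belongs to at least one segment.
#'
#' @param rec a [CalibratedRecording-class].
#' @param seg_len segment length in seconds (default 30).
#' @param overlap overlap between consecutive segments in seconds
#'   (default 1; 0 gives an exact partition).
#' @return list of [AudioSegment-class] objects.
#' @export
segmentAudio <- function(rec, seg_len = 30, overlap = 1) {
  stopifnot(is(rec, "CalibratedRecording"), seg_len > overlap, overlap >= 0)
  n <- length(rec@samples)
  if (n == 0L) stop("empty recording")
  fs <- rec@sample_rate
  stride <- seg_len - overlap
  dur <- n / fs
  starts <- seq(0, by = stride, length.out = max(1L, ceiling(
    max(0, dur - seg_len) / stride) + 1L))
  # drop trailing starts that would begin at/after the end of the data
  starts <- starts[starts * fs < n - 0.5]
  segs <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    i0 <- round(starts[k] * fs) + 1L
    i1 <- min(n, round((starts[k] + seg_len) * fs))
    segs[[k]] <- new("AudioSegment",
                     samples = rec@samples[i0:i1],
                     sample_rate = fs,
                     t0 = (i0 - 1L) / fs,
                     filtered = FALSE,
                     id = sprintf("seg%03d", k))
  }
  segs
}

#' High-pass pre-filter a segment
#'
#' Butterworth high-pass (default 4th order, 5 kHz cut-off) applied
#' forward-backward (`signal::filtfilt`) so the filter is zero-phase and
#' pulse timing is unbiased; the effective magnitude response is the
#' squared one-pass response.
#'
#' @param seg an [AudioSegment-class].
#' @param cutoff cut-off frequency in Hz (default 5000).
#' @param order filter order (default 4).
#' @return the filtered segment with its `filtered` flag set.
#' @export
highpassFilter <- function(seg, cutoff = 5000, order = 4) {
  stopifnot(is(seg, "AudioSegment"))
  fs <- seg@sample_rate
  if (cutoff >= fs / 2)
    stop("cutoff (", cutoff, " Hz) must be below the Nyquist frequency (",
         fs / 2, " Hz)")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "high")
  seg@samples <- as.numeric(signal::filtfilt(bf, seg@samples))
  seg@filtered <- TRUE
  seg
}

#' Write a waveform clip as 16-bit PCM WAV
#'
#' `x` is interpreted as ADC counts; values are rounded to integers and
#' values beyond the int16 range are saturated with a warning. Reading the
#' file back returns a bitwise-identical int16 payload.
#'
#' @param x numeric samples (counts).
#' @param sample_rate Hz.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeClip <- function(x, sample_rate, path) {
  if (length(x) == 0L) stop("refusing to write an empty clip")
  if (any(!is.finite(x))) stop("clip contains non-finite samples")
  xi <- round(x)
  lim <- c(-32768, 32767)
  if (any(xi < lim[1] | xi > lim[2])) {
    warning("clip exceeds int16 full scale; saturating ",
            sum(xi < lim[1] | xi > lim[2]), " sample(s)")
    xi <- pmin(pmax(xi, lim[1]), lim[2])
  }
  writeWavPcm(path, xi, sample_rate)
  invisible(path)
}
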
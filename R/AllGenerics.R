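#' @include AllClasses.R
NULL

#' Accessors for odontoPulse objects
#'
#' `samples()` returns the raw sample vector, `sampleRate()` the sampling
#' rate in Hz, `recDuration()` the duration in seconds, `numPulses()` the
#' pulse count of a train, `ipis()` its inter-pulse intervals (seconds)
#' and `trainLabel()` its class label.
#'
#' @param x an odontoPulse object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("recDuration", function(x) standardGeneric("recDuration"))
#' @rdname accessors
#' @export
setGeneric("numPulses", function(x) standardGeneric("numPulses"))
#' @rdname accessors
#' @export
setGeneric("ipis", function(x) standardGeneric("ipis"))
#' @rdname accessors
#' @export
setGeneric("trainLabel", function(x) standardGeneric("trainLabel"))

#' @rdname accessors
#' @export
setMethod("samples", "CalibratedRecording", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("samples", "AudioSegment", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("sampleRate", "CalibratedRecording", function(x) x@sample_rate)
#' @rdname accessors
#' @export
setMethod("sampleRate", "AudioSegment", function(x) x@sample_rate)
#' @rdname accessors
#' @export
setMethod("recDuration", "CalibratedRecording",
          function(x) length(x@samples) / x@sample_rate)
#' @rdname accessors
#' @export
setMethod("recDuration", "AudioSegment",
          function(x) length(x@samples) / x@sample_rate)
#' @rdname accessors
#' @export
setMethod("numPulses", "PulseTrain", function(x) nrow(x@events))
#' @rdname accessors
#' @export
setMethod("ipis", "PulseTrain", function(x) x@ipis)
#' @rdname accessors
#' @export
setMethod("trainLabel", "PulseTrain", function(x) x@label)

setMethod("show", "Calibration", function(object) {
  cat("Calibration: sensitivity", object@sensitivity_db,
      "dB re 1 V/uPa,", object@adc_bits, "bit ADC,",
      object@adc_fullscale_volts, "V full scale, gain",
      object@gain_db, "dB\n")
})

setMethod("show", "CalibratedRecording", function(object) {
  cat(sprintf(
    "CalibratedRecording: %d samples @ %g Hz (%.3f s), unit %s\n  source: %s\n",
    length(object@samples), object@sample_rate,
    length(object@samples) / object@sample_rate,
    object@unit, object@source_id))
})

setMethod("show", "AudioSegment", function(object) {
  cat(sprintf(
    "AudioSegment '%s': t0 = %.3f s, %.3f s @ %g Hz, %sfiltered\n",
    object@id, object@t0, length(object@samples) / object@sample_rate,
    object@sample_rate, if (object@filtered) "" else "not "))
})

setMethod("show", "KernelPair", function(object) {
  cat(sprintf(
    "KernelPair: N = %d (length %d), sigma_G = %.4g s, Ts = %.4g s\n",
    object@half_length, 2L * object@half_length + 1L,
    object@sigma_g, object@sample_interval))
})

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf(
    "PulseTrain (%s): %d pulses, %.1f ms, mean IPI %.2f ms\n",
    object@label, nrow(object@events),
    1000 * diff(range(object@events$time)),
    1000 * mean(object@ipis)))
})

setMethod("show", "WhistleContour", function(object) {
  cat(sprintf(
    "WhistleContour: %.1f-%.1f kHz over %.1f ms, %d points, %d break(s)%s%s\n",
    min(object@freq) / 1000, max(object@freq) / 1000,
    1000 * diff(range(object@time)), length(object@time),
    nrow(object@gaps),
    if (is.na(object@type)) "" else paste0(", type ", object@type),
    if (is.na(object@grade)) "" else paste0(", grade ", object@grade)))
})

setMethod("show", "SceneManifest", function(object) {
  cat(sprintf(
    "SceneManifest: %.1f s @ %g Hz, %d pulses in %d train(s), %d whistle(s), noise %.1f dB rms (seed %d)\n",
    object@duration, object@sample_rate, nrow(object@pulses),
    length(unique(object@pulses$train_id)), length(object@whistles),
    object@noise_rms_db, object@seed))
})
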
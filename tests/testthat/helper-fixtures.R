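# Shared fixtures: everything is generated in code at test time.

FS <- 576000  # recorder-nominal sampling rate used across tests

defaultCal <- function() calibration()

# Wrap a raw pressure waveform as a filtered-or-not analysis segment.
asSegment <- function(wave, fs = FS, t0 = 0, filtered = FALSE, id = "seg") {
  new("AudioSegment", samples = wave, sample_rate = fs, t0 = t0,
      filtered = filtered, id = id)
}

# Render a short scene and run detection on it as a single segment.
detectScene <- function(scene, config = detectorConfig(), fs = FS) {
  seg <- asSegment(scene$wave, fs = fs)
  seg <- highpassFilter(seg)
  detectPulses(seg, config)
}

# Truth contour of a whistle spec as a WhistleContour object.
truthContour <- function(spec, fs = FS) {
  w <- genWhistle(spec, fs)
  whistleContour(w$contour$time_s, w$contour$freq_hz)
}
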
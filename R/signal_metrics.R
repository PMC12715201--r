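#' @include AllClasses.R train_builder.R
NULL

# Tukey (tapered-cosine) window; r is the total taper fraction.
tukeyWindow <- function(n, r = 0.25) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < r / 2
  hi <- t > 1 - r / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / r - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / r - 2 / r + 1)))
  w
}

# Contiguous bandwidth around a spectral peak at `drop_db` below the peak
# level, with linear interpolation of the crossing frequencies.
bandWidthAt <- function(level_db, freq, ipk, drop_db) {
  thr <- level_db[ipk] - drop_db
  n <- length(level_db)
  i <- ipk
  while (i > 1L && level_db[i - 1L] >= thr) i <- i - 1L
  f_lo <- if (i == 1L) freq[1L] else {
    # interpolate between i-1 (below thr) and i (above)
    freq[i - 1L] + (thr - level_db[i - 1L]) /
      (level_db[i] - level_db[i - 1L]) * (freq[i] - freq[i - 1L])
  }
  j <- ipk
  while (j < n && level_db[j + 1L] >= thr) j <- j + 1L
  f_hi <- if (j == n) freq[n] else {
    freq[j] + (thr - level_db[j]) /
      (level_db[j + 1L] - level_db[j]) * (freq[j + 1L] - freq[j])
  }
  f_hi - f_lo
}

#' Measure the acoustic parameters of one pulse clip
#'
#' Computes, on a pressure-calibrated clip centered on the pulse peak:
#' peak-to-peak sound pressure level
#' \eqn{SPL_{pp} = 20\log_{10}((\max - \min)/1\,\mu Pa)}; the 95%
#' cumulative-energy duration (time between the 2.5% and 97.5% quantiles
#' of cumulative squared pressure); and from the magnitude spectrum of
#' the Tukey(0.25)-windowed, zero-padded clip: the peak frequency and the
#' widths of the contiguous band around the peak within 3 and 10 dB of
#' the peak level.
#'
#' @param clip pressure waveform in uPa.
#' @param sample_rate Hz.
#' @param spectrum_len FFT length after zero padding (default 2048;
#'   raised to the clip length if the clip is longer).
#' @param tukey_r Tukey window taper fraction (default 0.25).
#' @return one-row data.frame: `splpp_db`, `duration_us`, `fpeak_khz`,
#'   `bw3_khz`, `bw10_khz`.
#' @export
measurePulse <- function(clip, sample_rate, spectrum_len = 2048L,
                         tukey_r = 0.25) {
  if (length(clip) < 3L) stop("clip must contain at least 3 samples")
  if (any(!is.finite(clip))) stop("clip contains non-finite values")
  splpp_db <- 20 * log10(max(clip) - min(clip))

  e <- cumsum(clip^2)
  tot <- e[length(e)]
  if (tot <= 0) stop("clip has zero energy")
  i_lo <- which(e >= 0.025 * tot)[1L]
  i_hi <- which(e >= 0.975 * tot)[1L]
  duration_us <- (i_hi - i_lo) / sample_rate * 1e6

  nfft <- max(as.integer(spectrum_len), length(clip))
  w <- tukeyWindow(length(clip), tukey_r)
  X <- stats::fft(c(clip * w, numeric(nfft - length(clip))))
  half <- floor(nfft / 2) + 1L
  mag <- Mod(X[seq_len(half)])
  freq <- (seq_len(half) - 1L) * sample_rate / nfft
  ipk <- which.max(mag)
  level_db <- 20 * log10(pmax(mag, .Machine$double.xmin))
  data.frame(
    splpp_db = splpp_db,
    duration_us = duration_us,
    fpeak_khz = freq[ipk] / 1000,
    bw3_khz = bandWidthAt(level_db, freq, ipk, 3) / 1000,
    bw10_khz = bandWidthAt(level_db, freq, ipk, 10) / 1000
  )
}

#' Measure every pulse of a train
#'
#' Runs [measurePulse()] on each event clip and attaches the per-pulse
#' table (with event time, SNR and the IPI to the next pulse; the last
#' pulse of a train has no IPI and carries `NA`).
#'
#' @param train a [PulseTrain-class] whose events carry clips.
#' @param sample_rate Hz.
#' @param ... passed to [measurePulse()].
#' @return the train with its `metrics` slot filled.
#' @export
measureTrain <- function(train, sample_rate, ...) {
  stopifnot(is(train, "PulseTrain"))
  ev <- train@events
  rows <- lapply(ev$clip, measurePulse, sample_rate = sample_rate, ...)
  m <- do.call(rbind, rows)
  train@metrics <- cbind(
    data.frame(pulse_index = seq_len(nrow(ev)),
               time_s = ev$time,
               snr_db = ev$snr_db,
               ipi_ms = c(train@ipis * 1000, NA_real_)),
    m)
  train
}

#' Train-level summary record
#'
#' Length (ms, last minus first pulse time), pulse count and the
#' arithmetic means of the per-pulse parameters. The mean IPI is the mean
#' of the train's `n - 1` intervals (the last pulse contributes no IPI).
#'
#' @param train a measured [PulseTrain-class] (see [measureTrain()]).
#' @return one-row data.frame with columns `Length_ms`, `NumP`,
#'   `Mean_SNR`, `Mean_IPI`, `Mean_SPLpp`, `Mean_Duration`, `Mean_Fpeak`,
#'   `Mean_-3dBBW`, `Mean_-10dBBW`.
#' @export
trainSummary <- function(train) {
  stopifnot(is(train, "PulseTrain"))
  m <- train@metrics
  if (!nrow(m)) stop("train has not been measured; call measureTrain() first")
  out <- data.frame(
    Length_ms = 1000 * diff(range(train@events$time)),
    NumP = nrow(train@events),
    Mean_SNR = mean(m$snr_db),
    Mean_IPI = mean(train@ipis) * 1000,
    Mean_SPLpp = mean(m$splpp_db),
    Mean_Duration = mean(m$duration_us),
    Mean_Fpeak = mean(m$fpeak_khz),
    check.names = FALSE)
  out[["Mean_-3dBBW"]] <- mean(m$bw3_khz)
  out[["Mean_-10dBBW"]] <- mean(m$bw10_khz)
  out
}

#' Dataset-level summary rows
#'
#' Min, max, sample mean and sample standard deviation (n - 1
#' denominator) per parameter, in the layout of a descriptive-statistics
#' table ("Mean +/- Sd", "Min-Max"). A single observation yields sd 0
#' with the `single_value` flag set.
#'
#' @param values named list (or data.frame) of numeric vectors, one per
#'   parameter.
#' @return data.frame with columns `parameter`, `min`, `max`, `mean`,
#'   `sd`, `n`, `single_value`.
#' @export
summarizeDataset <- function(values) {
  if (is.data.frame(values)) values <- as.list(values)
  if (!length(values)) stop("no parameters supplied")
  rows <- lapply(names(values), function(nm) {
    v <- values[[nm]]
    if (!length(v)) stop("parameter '", nm, "' has no values")
    data.frame(parameter = nm, min = min(v), max = max(v),
               mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else 0,
               n = length(v), single_value = length(v) == 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write the per-pulse parameter table of one train
#'
#' Tab-separated `PulseParameters.txt` with one row per pulse:
#' `pulse_index`, `time_s`, `SNR_dB`, `IPI_ms`, `SPLpp_dB`,
#' `Duration_us`, `Fpeak_kHz`, `BW3_kHz`, `BW10_kHz`.
#'
#' @param train a measured [PulseTrain-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writePulseParameters <- function(train, path) {
  m <- train@metrics
  if (!nrow(m)) stop("train has not been measured")
  out <- data.frame(
    pulse_index = m$pulse_index,
    time_s = sprintf("%.6f", m$time_s),
    SNR_dB = sprintf("%.2f", m$snr_db),
    IPI_ms = ifelse(is.na(m$ipi_ms), "NA", sprintf("%.3f", m$ipi_ms)),
    SPLpp_dB = sprintf("%.2f", m$splpp_db),
    Duration_us = sprintf("%.1f", m$duration_us),
    Fpeak_kHz = sprintf("%.2f", m$fpeak_khz),
    BW3_kHz = sprintf("%.2f", m$bw3_khz),
    BW10_kHz = sprintf("%.2f", m$bw10_khz),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
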
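#' @include AllClasses.R audio_io.R
NULL

#' Construct a pulse detector configuration
#'
#' See [DetectorConfig-class] for the meaning and defaults of every field.
#'
#' @param ... named slots overriding the defaults.
#' @return a [DetectorConfig-class].
#' @examples
#' detectorConfig(snr_min_db = 12)
#' @export
detectorConfig <- function(...) {
  args <- list(...)
  obj <- new("DetectorConfig")
  for (nm in names(args)) slot(obj, nm) <- args[[nm]]
  validObject(obj)
  obj
}

#' Read a detector configuration from YAML or JSON
#' @param path config file; fields are [DetectorConfig-class] slot names.
#' @export
readDetectorConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$detector)) cfg <- cfg$detector
  do.call(detectorConfig, cfg)
}

#' Teager-Kaiser energy operator
#'
#' \eqn{\Psi[n] = x_n^2 - x_{n-1} x_{n+1}} at interior points; the two
#' endpoints, where the operator is undefined, are set to 0 so the output
#' has the same length as the input. The operator tracks instantaneous
#' energy and spikes at short broadband transients.
#'
#' @param x numeric sample series (length >= 3).
#' @return energy series, same length as `x`.
#' @examples
#' tkeo(sin(pi / 2 * 0:9))   # fs/4 sinusoid: constant 1 at interior points
#' @export
tkeo <- function(x) {
  n <- length(x)
  if (n < 3L) stop("tkeo needs at least 3 samples")
  psi <- numeric(n)
  psi[2:(n - 1L)] <- x[2:(n - 1L)]^2 - x[1:(n - 2L)] * x[3:n]
  psi
}

#' Build the matched Gaussian/rectangular averaging-filter pair
#'
#' The Gaussian kernel (MAF1) has standard deviation
#' \eqn{\sigma_G = FWHM / (2\sqrt{2\ln 2})} and coefficients
#' \eqn{\mathrm{MAF1}(n) = \frac{T_s}{\sigma_G\sqrt{2\pi}}
#'      e^{-(nT_s)^2 / 2\sigma_G^2}} for \eqn{n = -N..N} with
#' \eqn{N = \lfloor 5\sigma_G / T_s \rfloor}. The rectangular kernel
#' (MAF2) is constant at `mean(maf1)`, giving it identical length and
#' gain, so the two filters respond identically to slowly varying energy
#' and differ only at Gaussian-shaped surges.
#'
#' @param sample_rate Hz.
#' @param fwhm Gaussian full width at half maximum in seconds
#'   (default 1e-4, the length of a representative dolphin pulse).
#' @return a [KernelPair-class].
#' @export
buildKernels <- function(sample_rate, fwhm = 1e-4) {
  ts <- 1 / sample_rate
  if (fwhm <= 2 * ts)
    stop("fwhm (", fwhm, " s) is degenerate at sample rate ", sample_rate, " Hz")
  sigma_g <- fwhm / (2 * sqrt(2 * log(2)))
  N <- as.integer(floor(5 * sigma_g / ts))
  idx <- (-N):N
  maf1 <- ts / (sigma_g * sqrt(2 * pi)) * exp(-(idx * ts)^2 / (2 * sigma_g^2))
  maf2 <- rep(mean(maf1), 2L * N + 1L)
  new("KernelPair", maf1 = maf1, maf2 = maf2, half_length = N,
      sigma_g = sigma_g, sample_interval = ts)
}

# Same-size convolution with symmetric (mirror) padding, FFT-based.
# Pads the transform length to a 2/3/5-smooth size so large segments stay
# O(n log n). Returns a list with the two filter responses.
convolvePair <- function(x, kernels) {
  N <- kernels@half_length
  n <- length(x)
  if (n <= 2L * N + 1L) stop("series shorter than the kernel")
  xp <- c(x[N:1], x, x[n:(n - N + 1L)])
  np <- length(xp)
  L <- np + 2L * N            # full conv length np + (2N+1) - 1
  M <- stats::nextn(L, c(2, 3, 5))
  X <- stats::fft(c(xp, numeric(M - np)))
  K1 <- stats::fft(c(kernels@maf1, numeric(M - (2L * N + 1L))))
  h1 <- Re(stats::fft(X * K1, inverse = TRUE)) / M
  # 'same' on xp starts at lag N+1; strip the N mirrored samples each side
  h1 <- h1[(2L * N + 1L):(2L * N + n)]
  # rectangular kernel: running mean via cumulative sum (exact, O(n))
  c2 <- kernels@maf2[1L]
  cs <- cumsum(c(0, xp))
  h2 <- c2 * (cs[(2L * N + 2L):(2L * N + 1L + n)] - cs[1:n])
  list(h1 = h1, h2 = h2)
}

#' Filter difference ratio of a TKEO series
#'
#' Convolves the energy series with the matched kernel pair and forms
#' \eqn{FDR(n) = (h_{MAF1}(n) - h_{MAF2}(n)) / h_{MAF1}(n)}. Because the
#' ratio normalizes by the local energy, FDR is invariant to signal
#' amplitude. The ratio is undefined (masked `NA`) where the local energy
#' `h1` falls at or below `floor_fraction * median(h1)`, and within the
#' kernel half-length of either edge where the mirrored padding biases
#' the response.
#'
#' @param psi TKEO energy series.
#' @param kernels a [KernelPair-class].
#' @param floor_fraction energy floor as a fraction of `median(h1)`
#'   (default 1e-3).
#' @return list with `fdr` (NA-masked series aligned with `psi`),
#'   `valid` (logical mask), `h1`, `h2`.
#' @export
fdrSeries <- function(psi, kernels, floor_fraction = 1e-3) {
  h <- convolvePair(psi, kernels)
  n <- length(psi)
  N <- kernels@half_length
  floor_h1 <- floor_fraction * stats::median(h$h1)
  valid <- is.finite(h$h1) & h$h1 > floor_h1 & h$h1 > 0
  valid[seq_len(min(N, n))] <- FALSE
  valid[seq.int(max(1L, n - N + 1L), n)] <- FALSE
  fdr <- rep(NA_real_, n)
  fdr[valid] <- (h$h1[valid] - h$h2[valid]) / h$h1[valid]
  list(fdr = fdr, valid = valid, h1 = h$h1, h2 = h$h2)
}

#' Estimate the signal-to-noise ratio of a pulse clip
#'
#' \eqn{SNR = 20 \log_{10}(rms(signal) / rms(context))}, where `context`
#' is a noise stretch that contains no detected pulse. A zero-power
#' context returns `+Inf` (treated as passing any gate).
#'
#' @param clip signal window samples.
#' @param context noise window samples.
#' @return SNR in dB.
#' @export
estimateSnr <- function(clip, context) {
  rs <- sqrt(mean(clip^2))
  rn <- sqrt(mean(context^2))
  if (rn == 0) return(Inf)
  20 * log10(rs / rn)
}

# Greedy refractory enforcement: keep candidates in decreasing score
# order, dropping any within `min_sep` samples of an already-kept one.
enforceRefractory <- function(idx, score, min_sep) {
  o <- order(score, decreasing = TRUE)
  kept <- integer(0)
  for (i in idx[o]) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Noise RMS for one event: try the nominal window [peak-gap-win, peak-gap),
# slide to the nearest earlier clean stretch if it touches another
# detection, then try after the pulse, then fall back to the RMS of all
# uncontaminated samples in the segment.
noiseRmsFor <- function(x, peak, contaminated, win, gap) {
  n <- length(x)
  cleanBefore <- function(end_max) {
    # latest clean window of length win ending at or before end_max
    e <- min(end_max, n)
    while (e - win + 1L >= 1L) {
      s <- e - win + 1L
      bad <- which(contaminated[s:e])
      if (!length(bad)) return(sqrt(mean(x[s:e]^2)))
      e <- s + bad[1L] - 2L   # jump past the latest contaminated sample
    }
    NA_real_
  }
  r <- cleanBefore(peak - gap)
  if (!is.na(r)) return(r)
  # forward search: earliest clean window starting at/after peak + gap
  s <- peak + gap
  while (s + win - 1L <= n) {
    e <- s + win - 1L
    bad <- which(contaminated[s:e])
    if (!length(bad)) return(sqrt(mean(x[s:e]^2)))
    s <- s + bad[length(bad)]
  }
  clean <- x[!contaminated]
  if (length(clean)) sqrt(mean(clean^2)) else sqrt(mean(x^2))
}

#' Detect pulses in a high-pass-filtered segment
#'
#' Implements the TKEO/FDR detector: the segment's TKEO series is scored
#' with the filter difference ratio; candidate events are local FDR maxima
#' at or above `threshold_fraction` (default 85%) of the segment's peak
#' FDR, separated by at least the refractory interval. Each candidate is
#' re-centered on the local TKEO maximum (the envelope peak proxy), and
#' events whose SNR falls below `snr_min_db` (default 10 dB) are dropped —
#' the SNR gate is the sole absolute criterion, so noise-only segments
#' yield no detections despite the relative threshold.
#'
#' @param seg a high-pass-filtered [AudioSegment-class] (pressure, uPa).
#' @param config a [DetectorConfig-class].
#' @param fdr_peak optional externally supplied FDR peak (used when
#'   `config@peak_scope == "global"`); `NULL` uses the segment's own peak.
#' @return data.frame of events: `time` (s, relative to file start),
#'   `fdr`, `snr_db`, `clip` (list-column, uPa), `segment_id`. Zero rows
#'   when nothing is detected.
#' @export
detectPulses <- function(seg, config = detectorConfig(), fdr_peak = NULL) {
  stopifnot(is(seg, "AudioSegment"))
  if (!seg@filtered)
    warning("segment '", seg@id, "' has not been high-pass filtered")
  x <- seg@samples
  fs <- seg@sample_rate
  empty <- data.frame(time = numeric(0), fdr = numeric(0),
                      snr_db = numeric(0), segment_id = character(0),
                      stringsAsFactors = FALSE)
  empty$clip <- list()
  if (length(x) < 3L) return(empty)
  psi <- tkeo(x)
  kernels <- buildKernels(fs, config@fwhm)
  if (length(psi) <= 2L * kernels@half_length + 1L) return(empty)
  f <- fdrSeries(psi, kernels, config@fdr_floor_fraction)
  if (!any(f$valid)) return(empty)
  peak <- if (is.null(fdr_peak)) max(f$fdr[f$valid]) else fdr_peak
  if (!is.finite(peak) || peak <= 0) return(empty)
  thr <- config@threshold_fraction * peak

  fdr0 <- ifelse(is.na(f$fdr), -Inf, f$fdr)
  n <- length(fdr0)
  cand <- which(fdr0 >= thr &
                fdr0 >= c(-Inf, fdr0[-n]) &
                fdr0 > c(fdr0[-1L], -Inf))
  if (!length(cand)) return(empty)
  refr <- max(1L, round(config@refractory * fs))
  cand <- enforceRefractory(cand, fdr0[cand], refr)

  # re-center each candidate on the local TKEO maximum
  w <- max(1L, round(config@fwhm * fs))
  centers <- vapply(cand, function(i) {
    lo <- max(1L, i - w); hi <- min(n, i + w)
    as.integer(lo + which.max(psi[lo:hi]) - 1L)
  }, integer(1))
  fdr_at <- fdr0[cand]
  # de-duplicate candidates that re-centered onto the same envelope peak
  o <- order(centers)
  centers <- centers[o]; fdr_at <- fdr_at[o]
  keep <- enforceRefractory(centers, fdr_at, refr)
  fdr_at <- fdr_at[match(keep, centers)]
  centers <- keep

  # SNR gate
  sig_half <- max(1L, round(config@snr_signal_win * fs / 2))
  guard <- max(1L, round(config@clip_halfwidth * fs))
  contaminated <- rep(FALSE, n)
  for (c0 in centers) {
    lo <- max(1L, c0 - guard); hi <- min(n, c0 + guard)
    contaminated[lo:hi] <- TRUE
  }
  nwin <- max(1L, round(config@snr_noise_win * fs))
  ngap <- max(0L, round(config@snr_noise_gap * fs))
  snr <- vapply(seq_along(centers), function(k) {
    c0 <- centers[k]
    lo <- max(1L, c0 - sig_half); hi <- min(n, c0 + sig_half)
    rn <- noiseRmsFor(x, c0, contaminated, nwin, ngap)
    if (rn == 0) return(Inf)
    20 * log10(sqrt(mean(x[lo:hi]^2)) / rn)
  }, numeric(1))
  pass <- snr >= config@snr_min_db
  if (!any(pass)) return(empty)
  centers <- centers[pass]; fdr_at <- fdr_at[pass]; snr <- snr[pass]

  ch <- max(1L, round(config@clip_halfwidth * fs))
  clips <- lapply(centers, function(c0) {
    x[max(1L, c0 - ch):min(n, c0 + ch)]
  })
  out <- data.frame(time = seg@t0 + (centers - 1L) / fs,
                    fdr = fdr_at, snr_db = snr,
                    segment_id = seg@id, stringsAsFactors = FALSE)
  out$clip <- clips
  out[order(out$time), , drop = FALSE]
}

#' De-duplicate pulse events from overlapping segments
#'
#' Events closer together than `tol` seconds (default 0.2 ms) are
#' considered the same physical pulse detected in two overlapping
#' segments; the one with the higher FDR score is kept.
#'
#' @param events data.frame as returned by [detectPulses()], possibly
#'   concatenated over segments.
#' @param tol proximity tolerance in seconds.
#' @return de-duplicated, time-sorted events.
#' @export
dedupEvents <- function(events, tol = 2e-4) {
  if (nrow(events) < 2L) return(events)
  events <- events[order(events$time), , drop = FALSE]
  keep <- rep(TRUE, nrow(events))
  last <- 1L
  for (i in 2:nrow(events)) {
    if (events$time[i] - events$time[last] < tol) {
      if (events$fdr[i] > events$fdr[last]) {
        keep[last] <- FALSE; last <- i
      } else keep[i] <- FALSE
    } else last <- i
  }
  events[keep, , drop = FALSE]
}
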
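#' @include AllClasses.R
NULL

#' Construct a whistle contour
#'
#' @param time seconds, strictly increasing (uniform step expected).
#' @param freq Hz, positive.
#' @param gaps optional two-column matrix of bridged (start, end) gaps.
#' @param snr_db contour SNR in dB (NA if unknown).
#' @param source_id provenance.
#' @return a [WhistleContour-class].
#' @export
whistleContour <- function(time, freq, gaps = NULL, snr_db = NA_real_,
                           source_id = "") {
  if (is.null(gaps))
    gaps <- matrix(numeric(0), ncol = 2,
                   dimnames = list(NULL, c("start", "end")))
  new("WhistleContour", time = as.numeric(time), freq = as.numeric(freq),
      gaps = gaps, snr_db = snr_db, source_id = source_id)
}

#' Read / write a contour as CSV
#'
#' Two columns, `time_s` and `freq_hz`.
#' @param path CSV file.
#' @return [WhistleContour-class] (read) or the path (write).
#' @export
readContour <- function(path) {
  d <- utils::read.csv(path)
  whistleContour(d$time_s, d$freq_hz, source_id = path)
}

#' @rdname readContour
#' @param contour a [WhistleContour-class].
#' @export
writeContour <- function(contour, path) {
  utils::write.csv(data.frame(time_s = contour@time,
                              freq_hz = contour@freq),
                   path, row.names = FALSE)
  invisible(path)
}

#' Join whistle contour fragments across short gaps
#'
#' Two consecutive fragments belong to the same whistle iff the gap
#' between them is shorter than `max_gap` (default 200 ms) AND shorter
#' than the duration of each flanking fragment. The rule is applied left
#' to right until a fixpoint; each bridged gap is recorded on the merged
#' contour (these are the whistle's "breaks").
#'
#' @param fragments list of [WhistleContour-class], time-sorted and
#'   non-overlapping.
#' @param max_gap joining gap limit in seconds (default 0.2).
#' @return list of joined [WhistleContour-class] objects.
#' @export
joinContours <- function(fragments, max_gap = 0.2) {
  if (length(fragments) < 2L) return(fragments)
  starts <- vapply(fragments, function(f) f@time[1L], numeric(1))
  fragments <- fragments[order(starts)]
  for (k in 2:length(fragments)) {
    if (fragments[[k]]@time[1L] <=
        fragments[[k - 1L]]@time[length(fragments[[k - 1L]]@time)])
      stop("fragments overlap in time")
  }
  repeat {
    merged_any <- FALSE
    out <- list(fragments[[1L]])
    for (k in 2:length(fragments)) {
      a <- out[[length(out)]]
      b <- fragments[[k]]
      gap <- b@time[1L] - a@time[length(a@time)]
      dur_a <- diff(range(a@time))
      dur_b <- diff(range(b@time))
      if (gap < max_gap && gap < min(dur_a, dur_b)) {
        merged <- whistleContour(
          c(a@time, b@time), c(a@freq, b@freq),
          gaps = rbind(a@gaps, b@gaps,
                       c(a@time[length(a@time)], b@time[1L])),
          snr_db = if (is.na(a@snr_db) || is.na(b@snr_db)) NA_real_
                   else (dur_a * a@snr_db + dur_b * b@snr_db) / (dur_a + dur_b),
          source_id = a@source_id)
        out[[length(out)]] <- merged
        merged_any <- TRUE
      } else {
        out[[length(out) + 1L]] <- b
      }
    }
    fragments <- out
    if (!merged_any || length(fragments) < 2L) break
  }
  fragments
}

# Interior extrema with hysteresis: a turning point is registered only
# when the series reverses by more than eps_f beyond the running extreme,
# so sub-tolerance measurement wiggle is ignored. Returns a data.frame
# with the index and kind ("max"/"min") of each interior extremum.
contourExtrema <- function(freq, eps_f = 100) {
  n <- length(freq)
  idx <- integer(0)
  kind <- character(0)
  if (n >= 3L) {
    dir <- 0L               # +1 rising, -1 falling, 0 undetermined
    cur_max_i <- 1L
    cur_min_i <- 1L
    for (i in 2:n) {
      if (freq[i] > freq[cur_max_i]) cur_max_i <- i
      if (freq[i] < freq[cur_min_i]) cur_min_i <- i
      if (dir <= 0L && freq[i] > freq[cur_min_i] + eps_f) {
        if (dir == -1L && cur_min_i > 1L && cur_min_i < n) {
          idx <- c(idx, cur_min_i); kind <- c(kind, "min")
        }
        dir <- 1L
        cur_max_i <- i
      } else if (dir >= 0L && freq[i] < freq[cur_max_i] - eps_f) {
        if (dir == 1L && cur_max_i > 1L && cur_max_i < n) {
          idx <- c(idx, cur_max_i); kind <- c(kind, "max")
        }
        dir <- -1L
        cur_min_i <- i
      }
    }
  }
  data.frame(index = idx, kind = kind, stringsAsFactors = FALSE)
}

# Light smoothing for derivative-based counts: centered moving average.
smoothSeries <- function(x, width) {
  width <- max(3L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (length(x) <= width) return(x)
  k <- rep(1 / width, width)
  pad <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], pad), x, rep(x[length(x)], pad))
  as.numeric(stats::filter(xp, k, sides = 2))[(pad + 1L):(pad + length(x))]
}

# Zero-slope plateaus (>= min_len points with |slope| < tol) whose
# flanking slopes share the same sign: saddle points.
countSaddles <- function(slope, tol, min_len = 3L) {
  flat <- abs(slope) < tol
  r <- rle(flat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  n_saddle <- 0L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_len) next
    if (starts[k] == 1L || ends[k] == length(slope)) next  # not interior
    before <- slope[starts[k] - 1L]
    after <- slope[ends[k] + 1L]
    if (sign(before) == sign(after) && sign(before) != 0)
      n_saddle <- n_saddle + 1L
  }
  n_saddle
}

#' Measure the thirteen whistle contour characteristics
#'
#' From a time-frequency contour: duration (ms), start and end frequency
#' (kHz), frequency change `|end - start|` (kHz), absolute frequency
#' gradient `change / duration` (kHz/s), minimum, maximum and delta
#' (`max - min`) frequency (kHz), number of interior local extrema,
#' inflection points and saddle points (counted on the lightly smoothed
#' contour with an `eps_f` hysteresis against measurement noise), number
#' of breaks (gaps bridged by the joining rule) and presence of harmonics
#' (`NA` unless set by [detectHarmonics()]).
#'
#' @param contour a [WhistleContour-class] with at least 2 points.
#' @param eps_f frequency hysteresis in Hz for extremum/inflection
#'   counting (default 100).
#' @param smooth_frac fraction of the contour length used as the
#'   smoothing window for derivative-based counts (default 0.05).
#' @return one-row data.frame with the thirteen characteristics.
#' @export
measureWhistle <- function(contour, eps_f = 100, smooth_frac = 0.05) {
  stopifnot(is(contour, "WhistleContour"))
  f <- contour@freq
  t <- contour@time
  if (length(f) < 2L) stop("contour needs at least 2 points")
  duration_s <- t[length(t)] - t[1L]
  change_khz <- abs(f[length(f)] - f[1L]) / 1000
  ext <- contourExtrema(f, eps_f)

  width <- max(3L, as.integer(round(length(f) * smooth_frac)))
  fs_sm <- smoothSeries(f, width)
  dt <- mean(diff(t))
  slope <- diff(fs_sm) / dt                       # Hz/s
  # drop the smoothing half-window at each end, where edge-replicated
  # padding distorts the derivative
  trim <- (width %/% 2L) + 1L
  if (length(slope) > 2L * trim + 3L)
    slope <- slope[(trim + 1L):(length(slope) - trim)]
  tol_slope <- 2 * eps_f / duration_s
  infl <- contourExtrema(slope, tol_slope)        # slope extrema = inflections
  n_saddle <- countSaddles(slope, tol_slope)

  data.frame(
    duration_ms = duration_s * 1000,
    start_freq_khz = f[1L] / 1000,
    end_freq_khz = f[length(f)] / 1000,
    freq_change_khz = change_khz,
    abs_freq_gradient_khz_per_s = change_khz / duration_s,
    min_freq_khz = min(f) / 1000,
    max_freq_khz = max(f) / 1000,
    delta_freq_khz = (max(f) - min(f)) / 1000,
    n_extrema = nrow(ext),
    n_inflection = nrow(infl),
    n_saddle = n_saddle,
    n_breaks = nrow(contour@gaps),
    has_harmonics = NA
  )
}

#' Rule-based whistle contour typing
#'
#' Assigns exactly one of the six tonal types: `constant` when the total
#' frequency excursion is below `flat_tol` of the mean frequency;
#' otherwise `upsweep`/`downsweep` when the contour is monotone (no
#' interior extremum at the `eps_f` hysteresis) with positive/negative
#' net change; `convex` for exactly one interior maximum and no interior
#' minimum; `concave` for the reverse; `sinusoidal` for two or more
#' interior extrema.
#'
#' @param contour a [WhistleContour-class].
#' @param flat_tol flatness tolerance as a fraction of the mean frequency
#'   (default 0.05).
#' @param eps_f extremum hysteresis in Hz (default 100).
#' @return the contour with its `type` slot set.
#' @export
classifyContour <- function(contour, flat_tol = 0.05, eps_f = 100) {
  stopifnot(is(contour, "WhistleContour"))
  f <- contour@freq
  delta <- max(f) - min(f)
  ext <- contourExtrema(f, eps_f)
  type <-
    if (delta < flat_tol * mean(f)) "constant"
    else if (nrow(ext) == 0L) {
      if (f[length(f)] >= f[1L]) "upsweep" else "downsweep"
    } else if (nrow(ext) == 1L) {
      if (ext$kind[1L] == "max") "convex" else "concave"
    } else "sinusoidal"
  contour@type <- type
  contour
}

#' Grade a whistle by signal-to-noise ratio
#'
#' Numeric surrogate for the visual three-grade quality scale: grade 1
#' (weak but visible contour) below the low threshold, grade 2 (clear
#' contour) between the thresholds, grade 3 (prominent contour) above.
#' Grades 2 and 3 are considered high quality.
#'
#' @param snr_db contour SNR in dB (vectorized).
#' @param thresholds `c(low, high)` in dB (default `c(5, 15)`).
#' @return integer grades with attribute-free values 1, 2 or 3; use
#'   `gradeWhistle(x) >= 2` for the high-quality flag.
#' @export
gradeWhistle <- function(snr_db, thresholds = c(5, 15)) {
  stopifnot(all(is.finite(snr_db)), length(thresholds) == 2L,
            thresholds[1L] < thresholds[2L])
  ifelse(snr_db < thresholds[1L], 1L,
         ifelse(snr_db < thresholds[2L], 2L, 3L))
}

#' Detect a second harmonic along a whistle contour
#'
#' Checks, for every contour point whose doubled frequency lies below the
#' Nyquist frequency, whether the spectrogram magnitude at `2 f(t)`
#' exceeds the local noise floor (the column median magnitude) by
#' `margin_db`. Harmonics are declared present when the fraction of
#' points passing is at least `coverage`.
#'
#' @param spec list with `t` (frame times, s), `f` (bin frequencies, Hz)
#'   and `S` (magnitude matrix, frequencies x frames), e.g. built from
#'   `signal::specgram` output.
#' @param contour a [WhistleContour-class].
#' @param margin_db required margin over the noise floor (default 6).
#' @param coverage required fraction of contour points (default 0.5).
#' @return `TRUE`/`FALSE`.
#' @export
detectHarmonics <- function(spec, contour, margin_db = 6, coverage = 0.5) {
  stopifnot(is(contour, "WhistleContour"))
  nyq <- max(spec$f)
  usable <- 2 * contour@freq < nyq
  if (!any(usable)) {
    warning("contour exceeds half the Nyquist frequency everywhere; ",
            "harmonics cannot be assessed")
    return(FALSE)
  }
  if (mean(usable) < coverage) return(FALSE)
  hit <- 0L
  nf <- length(spec$f)
  for (k in which(usable)) {
    j <- which.min(abs(spec$t - contour@time[k]))
    col <- spec$S[, j]
    i2 <- which.min(abs(spec$f - 2 * contour@freq[k]))
    lo <- max(1L, i2 - 1L); hi <- min(nf, i2 + 1L)
    level <- max(col[lo:hi])
    # local noise floor: median of the surrounding bins, excluding the
    # harmonic's own peak, so spectral-leakage skirts do not count as a
    # harmonic
    ring <- setdiff(max(1L, i2 - 20L):min(nf, i2 + 20L), (i2 - 2L):(i2 + 2L))
    floor_mag <- stats::median(col[ring])
    if (20 * log10(level / max(floor_mag, .Machine$double.xmin)) > margin_db)
      hit <- hit + 1L
  }
  (hit / length(contour@freq)) >= coverage
}

#' Trace a tonal ridge through a spectrogram (convenience tracker)
#'
#' A deliberately simple maximum-energy ridge tracker for end-to-end
#' demonstrations: per spectrogram frame, the highest-magnitude bin
#' inside `band` is taken and the resulting frequency track is median
#' smoothed. Frames whose in-band peak is less than `min_snr_db` above
#' the frame's median magnitude are dropped. Field whistle extraction was
#' a manual spectrogram task; this tracker is a convenience for clean
#' (synthetic or high-SNR) audio, not a field-grade tonal detector.
#'
#' @param x waveform.
#' @param sample_rate Hz.
#' @param band `c(lo, hi)` Hz search band (default 2-20 kHz).
#' @param nfft FFT length per frame (default 2048).
#' @param overlap fractional frame overlap (default 0.75).
#' @param min_snr_db frame acceptance threshold (default 6 dB).
#' @param smooth median smoothing width in frames (odd; default 5).
#' @return a [WhistleContour-class], or `NULL` when no frames pass.
#' @export
traceContour <- function(x, sample_rate, band = c(2000, 20000),
                         nfft = 2048L, overlap = 0.75,
                         min_snr_db = 6, smooth = 5L) {
  sp <- signal::specgram(x, n = nfft, Fs = sample_rate,
                         overlap = round(nfft * overlap))
  S <- Mod(sp$S)
  inband <- sp$f >= band[1L] & sp$f <= band[2L]
  peak_i <- apply(S[inband, , drop = FALSE], 2L, which.max)
  fhz <- sp$f[inband][peak_i]
  peak_mag <- S[cbind(which(inband)[peak_i], seq_len(ncol(S)))]
  med_mag <- apply(S, 2L, stats::median)
  ok <- 20 * log10(peak_mag / pmax(med_mag, .Machine$double.xmin)) >= min_snr_db
  if (!any(ok)) return(NULL)
  tt <- sp$t[ok]
  ff <- fhz[ok]
  if (length(ff) > smooth) ff <- stats::runmed(ff, smooth)
  snr <- stats::median(20 * log10(peak_mag[ok] /
                                  pmax(med_mag[ok], .Machine$double.xmin)))
  whistleContour(tt, ff, snr_db = snr)
}
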
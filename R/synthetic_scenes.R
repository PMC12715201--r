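#' @include AllClasses.R audio_io.R train_builder.R
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`; the caller's
# RNG stream is untouched. seed = NULL runs expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a Gabor click
#'
#' Canonical odontocete click model: a Gaussian-envelope sinusoid
#' \eqn{s(t) = A e^{-t^2 / 2\sigma_t^2} \cos(2\pi f_0 t)} truncated at
#' \eqn{\pm 5 \sigma_t}, with the amplitude set so the realized
#' peak-to-peak pressure matches the requested level:
#' \eqn{20 \log_{10}(p_{pp} / 1\,\mu Pa) = SPL_{pp}}.
#'
#' @param f0 carrier (peak) frequency in Hz; must be below
#'   `0.45 * sample_rate`.
#' @param sigma_t Gaussian envelope standard deviation in seconds
#'   (pulse durations of tens of microseconds; must be at least
#'   `3 / sample_rate`).
#' @param splpp_db requested peak-to-peak level, dB re 1 uPa.
#' @param sample_rate Hz.
#' @return list: `wave` (uPa), `center` (index of the envelope peak),
#'   `sample_rate`.
#' @export
genGaborPulse <- function(f0, sigma_t, splpp_db, sample_rate) {
  if (f0 >= 0.45 * sample_rate)
    stop("f0 (", f0, " Hz) too close to Nyquist at fs = ", sample_rate)
  if (sigma_t < 3 / sample_rate)
    stop("sigma_t (", sigma_t, " s) unresolvable at fs = ", sample_rate)
  half <- ceiling(5 * sigma_t * sample_rate)
  t <- ((-half):half) / sample_rate
  unit <- exp(-t^2 / (2 * sigma_t^2)) * cos(2 * pi * f0 * t)
  pp_unit <- max(unit) - min(unit)
  a <- 10^(splpp_db / 20) / pp_unit
  list(wave = a * unit, center = half + 1L, sample_rate = sample_rate)
}

#' Specify a synthetic pulse train
#'
#' @param n_pulses number of pulses.
#' @param ipi nominal inter-pulse interval in seconds (for the constant
#'   profile) or `c(start, end)` for the linear profile.
#' @param profile `"constant"`, `"linear"` (IPI glides from `ipi[1]` to
#'   `ipi[2]`) or `"random_walk"` (log-normal multiplicative steps of sd
#'   `jitter` around `ipi[1]`).
#' @param f0 carrier frequency Hz.
#' @param sigma_t envelope sd in seconds.
#' @param splpp_db per-pulse peak-to-peak level dB re 1 uPa.
#' @param jitter random-walk step sd on log IPI (default 0.05).
#' @param start_s train start (first pulse center) in seconds within the
#'   scene; `NA` lets [genScene()] place it.
#' @return a `TrainSpec` list.
#' @export
trainSpec <- function(n_pulses, ipi, profile = c("constant", "linear",
                                                 "random_walk"),
                      f0 = 100e3, sigma_t = 25e-6, splpp_db = 165,
                      jitter = 0.05, start_s = NA_real_) {
  profile <- match.arg(profile)
  stopifnot(n_pulses >= 1L, all(ipi > 0))
  structure(list(n_pulses = as.integer(n_pulses), ipi = ipi,
                 profile = profile, f0 = f0, sigma_t = sigma_t,
                 splpp_db = splpp_db, jitter = jitter, start_s = start_s),
            class = "TrainSpec")
}

#' Render a pulse train with exact placement truth
#'
#' Pulse centers are placed at cumulative IPIs following the spec's
#' profile; the returned truth lists the exact center times (seconds,
#' relative to the first pulse) and the intended class, i.e.
#' [classifyTrain()] applied to the realized mean IPI.
#'
#' @param spec a [trainSpec()].
#' @param sample_rate Hz.
#' @param seed optional integer; the random-walk profile is a pure
#'   function of `(spec, seed)`.
#' @return list: `wave` (uPa, from the first to the last pulse plus the
#'   pulse support), `truth` data.frame (`time`, `f0_hz`, `sigma_t_s`,
#'   `splpp_db`), `intended_class`, `offset` (seconds from wave start to
#'   the first pulse center).
#' @export
genPulseTrain <- function(spec, sample_rate, seed = NULL) {
  stopifnot(inherits(spec, "TrainSpec"))
  np <- spec$n_pulses
  ipis <- if (np == 1L) numeric(0) else switch(spec$profile,
    constant = rep(spec$ipi[1L], np - 1L),
    linear = seq(spec$ipi[1L], spec$ipi[length(spec$ipi)],
                 length.out = np - 1L),
    random_walk = withSeed(seed, {
      steps <- stats::rnorm(np - 1L, 0, spec$jitter)
      spec$ipi[1L] * exp(cumsum(steps))
    }))
  centers <- c(0, cumsum(ipis))
  pulse <- genGaborPulse(spec$f0, spec$sigma_t, spec$splpp_db, sample_rate)
  half <- pulse$center - 1L
  if (length(ipis) && min(ipis) * sample_rate <= 2L * half)
    stop("pulses overlap: minimum IPI ", min(ipis), " s is within the ",
         "pulse support at fs = ", sample_rate)
  n <- ceiling(centers[np] * sample_rate) + 2L * half + 1L
  wave <- numeric(n)
  for (c0 in centers) {
    i0 <- round(c0 * sample_rate) + 1L      # envelope peak at i0 + half
    wave[i0:(i0 + 2L * half)] <- wave[i0:(i0 + 2L * half)] + pulse$wave
  }
  truth <- data.frame(
    time = round(centers * sample_rate) / sample_rate,
    f0_hz = spec$f0, sigma_t_s = spec$sigma_t, splpp_db = spec$splpp_db)
  list(wave = wave, truth = truth,
       intended_class = if (np > 1L) classifyTrain(mean(ipis)) else NA_character_,
       offset = half / sample_rate)
}

#' Specify a synthetic whistle
#'
#' Closed-form contours for the six tonal types over `[0, duration]`:
#' `constant` holds `f1`; `upsweep`/`downsweep` glide linearly from `f1`
#' to `f2`; `convex` rises from `f1` to an apex `f2` and back
#' (`f1 + (f2 - f1) sin(\pi t / D)`); `concave` is the mirror dip;
#' `sinusoidal` oscillates about the midpoint of `f1`/`f2` with
#' `n_cycles` full periods.
#'
#' @param type one of the six contour types.
#' @param f1,f2 contour frequencies in Hz (see above; `f2` unused for
#'   `constant`).
#' @param duration_s whistle length in seconds.
#' @param harmonic_db relative level of an optional second harmonic in dB
#'   (negative), or `NA` for none.
#' @param amp_upa waveform amplitude (pressure, uPa).
#' @param n_cycles periods for the sinusoidal type (default 1).
#' @param start_s whistle start within the scene; `NA` lets [genScene()]
#'   place it.
#' @return a `WhistleSpec` list.
#' @export
whistleSpec <- function(type = c("constant", "upsweep", "downsweep",
                                 "concave", "convex", "sinusoidal"),
                        f1 = 6000, f2 = 10000, duration_s = 0.5,
                        harmonic_db = NA_real_, amp_upa = 1e7,
                        n_cycles = 1, start_s = NA_real_) {
  type <- match.arg(type)
  structure(list(type = type, f1 = f1, f2 = f2, duration_s = duration_s,
                 harmonic_db = harmonic_db, amp_upa = amp_upa,
                 n_cycles = n_cycles, start_s = start_s),
            class = "WhistleSpec")
}

# Closed-form instantaneous frequency of a whistle spec at times t.
whistleFreq <- function(spec, t) {
  D <- spec$duration_s
  switch(spec$type,
    constant = rep(spec$f1, length(t)),
    upsweep = spec$f1 + (spec$f2 - spec$f1) * t / D,
    downsweep = spec$f1 + (spec$f2 - spec$f1) * t / D,
    convex = spec$f1 + (spec$f2 - spec$f1) * sin(pi * t / D),
    concave = spec$f1 - (spec$f1 - spec$f2) * sin(pi * t / D),
    sinusoidal = (spec$f1 + spec$f2) / 2 +
      (spec$f2 - spec$f1) / 2 * sin(2 * pi * spec$n_cycles * t / D))
}

#' Render a frequency-modulated whistle with contour truth
#'
#' Phase-continuous FM synthesis of the requested closed-form contour
#' (phase is the cumulative sum of instantaneous frequency), with a
#' 10 ms raised-cosine fade at both ends so the tonal starts and stops
#' without a broadband edge transient, plus an optional second harmonic
#' at the stated relative level. The truth contour is sampled at 1 ms
#' steps.
#'
#' @param spec a [whistleSpec()].
#' @param sample_rate Hz.
#' @return list: `wave` (uPa), `contour` data.frame (`time_s`,
#'   `freq_hz`, 1 ms step), `spec`.
#' @export
genWhistle <- function(spec, sample_rate) {
  stopifnot(inherits(spec, "WhistleSpec"))
  fmax <- max(abs(c(spec$f1, spec$f2)))
  lim <- if (is.na(spec$harmonic_db)) sample_rate / 2 else sample_rate / 4
  if (fmax >= lim)
    stop("whistle frequencies must stay below ", lim, " Hz at fs = ",
         sample_rate, if (!is.na(spec$harmonic_db))
           " (half Nyquist, harmonic requested)" else "")
  n <- round(spec$duration_s * sample_rate)
  t <- (seq_len(n) - 1L) / sample_rate
  finst <- whistleFreq(spec, t)
  phase <- 2 * pi * cumsum(finst) / sample_rate
  wave <- sin(phase)
  if (!is.na(spec$harmonic_db))
    wave <- wave + 10^(spec$harmonic_db / 20) * sin(2 * phase)
  ramp_n <- min(round(0.01 * sample_rate), floor(n / 4))
  if (ramp_n > 0) {
    ramp <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    wave[seq_len(ramp_n)] <- wave[seq_len(ramp_n)] * ramp
    wave[(n - ramp_n + 1L):n] <- wave[(n - ramp_n + 1L):n] * rev(ramp)
  }
  tc <- seq(0, spec$duration_s, by = 1e-3)
  tc <- tc[tc < spec$duration_s]
  list(wave = spec$amp_upa * wave,
       contour = data.frame(time_s = tc, freq_hz = whistleFreq(spec, tc)),
       spec = spec)
}

#' Specify a synthetic acoustic scene
#'
#' @param duration scene length in seconds.
#' @param sample_rate Hz (default 576 kHz, mirroring the recorder).
#' @param noise_level_db broadband Gaussian noise RMS, dB re 1 uPa
#'   (default 110).
#' @param trains list of [trainSpec()] objects.
#' @param whistles list of [whistleSpec()] objects.
#' @return a `SceneSpec` list.
#' @export
sceneSpec <- function(duration, sample_rate = 576000,
                      noise_level_db = 110, trains = list(),
                      whistles = list()) {
  structure(list(duration = duration, sample_rate = sample_rate,
                 noise_level_db = noise_level_db, trains = trains,
                 whistles = whistles),
            class = "SceneSpec")
}

#' Render a synthetic scene with its ground-truth manifest
#'
#' Sums the rendered trains and whistles with Gaussian white noise at the
#' requested RMS. Components with `start_s = NA` are placed evenly and
#' non-overlapping (trains never overlap each other). The per-pulse
#' realized SNR recorded in the manifest is the RMS of a 0.2 ms window
#' around the pulse center over the requested noise RMS, i.e. what an
#' in-band detector SNR estimate should return. The render is a pure
#' function of `(spec, seed)`: the same seed gives identical samples and
#' manifest.
#'
#' @param spec a [sceneSpec()].
#' @param seed integer seed for noise and random-walk profiles.
#' @return list: `wave` (uPa), `manifest` ([SceneManifest-class]).
#' @export
genScene <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "SceneSpec"))
  fs <- spec$sample_rate
  n <- round(spec$duration * fs)
  noise_rms <- 10^(spec$noise_level_db / 20)
  wave <- withSeed(seed, stats::rnorm(n, 0, noise_rms))

  n_tr <- length(spec$trains)
  rendered <- lapply(seq_len(n_tr), function(k)
    genPulseTrain(spec$trains[[k]], fs, seed = seed + k))
  spans <- vapply(rendered, function(r) length(r$wave) / fs, numeric(1))
  starts <- vapply(seq_len(n_tr), function(k)
    spec$trains[[k]]$start_s, numeric(1))
  if (n_tr) {
    auto <- is.na(starts)
    if (any(auto)) {
      # lay unplaced trains out evenly with at least 1 s clearance
      free <- spec$duration - sum(spans[auto]) - 0.2
      if (free < (sum(auto) + 1) * 0.5)
        stop("scene too short for the requested trains")
      gap <- free / (sum(auto) + 1L)
      pos <- 0.1
      for (k in which(auto)) {
        pos <- pos + gap
        starts[k] <- pos
        pos <- pos + spans[k]
      }
    }
  }
  pulses <- data.frame(time = numeric(0), f0_hz = numeric(0),
                       sigma_t_s = numeric(0), splpp_db = numeric(0),
                       snr_db = numeric(0), train_id = integer(0),
                       intended_class = character(0),
                       stringsAsFactors = FALSE)
  for (k in seq_len(n_tr)) {
    r <- rendered[[k]]
    i0 <- round((starts[k] - r$offset) * fs) + 1L
    if (i0 < 1L || i0 + length(r$wave) - 1L > n)
      stop("train ", k, " does not fit inside the scene")
    idx <- i0:(i0 + length(r$wave) - 1L)
    wave[idx] <- wave[idx] + r$wave
    tt <- (i0 - 1L + round((r$offset + r$truth$time) * fs)) / fs
    win <- max(1L, round(1e-4 * fs))
    snr <- vapply(tt, function(tc) {
      c0 <- round(tc * fs) + 1L
      seg <- r$wave[max(1L, c0 - i0 + 1L - win):min(length(r$wave),
                                                    c0 - i0 + 1L + win)]
      20 * log10(sqrt(mean(seg^2)) / noise_rms)
    }, numeric(1))
    pulses <- rbind(pulses, data.frame(
      time = tt, f0_hz = r$truth$f0_hz, sigma_t_s = r$truth$sigma_t_s,
      splpp_db = r$truth$splpp_db, snr_db = snr, train_id = k,
      intended_class = r$intended_class, stringsAsFactors = FALSE))
  }

  n_wh <- length(spec$whistles)
  wstarts <- vapply(seq_len(n_wh), function(k)
    spec$whistles[[k]]$start_s, numeric(1))
  if (n_wh && any(is.na(wstarts))) {
    durs <- vapply(spec$whistles, function(w) w$duration_s, numeric(1))
    gap <- (spec$duration - sum(durs[is.na(wstarts)])) /
      (sum(is.na(wstarts)) + 1L)
    pos <- 0
    for (k in which(is.na(wstarts))) {
      pos <- pos + gap
      wstarts[k] <- pos
      pos <- pos + durs[k]
    }
  }
  whistles <- vector("list", n_wh)
  for (k in seq_len(n_wh)) {
    r <- genWhistle(spec$whistles[[k]], fs)
    i0 <- round(wstarts[k] * fs) + 1L
    if (i0 < 1L || i0 + length(r$wave) - 1L > n)
      stop("whistle ", k, " does not fit inside the scene")
    idx <- i0:(i0 + length(r$wave) - 1L)
    wave[idx] <- wave[idx] + r$wave
    whistles[[k]] <- list(
      contour = data.frame(time_s = r$contour$time_s + wstarts[k],
                           freq_hz = r$contour$freq_hz),
      type = r$spec$type, harmonic_db = r$spec$harmonic_db,
      start_s = wstarts[k], duration_s = r$spec$duration_s)
  }

  manifest <- new("SceneManifest",
                  pulses = pulses, whistles = whistles,
                  noise_rms_db = spec$noise_level_db,
                  duration = spec$duration, sample_rate = fs,
                  seed = as.integer(seed))
  list(wave = wave, manifest = manifest)
}

#' Write a rendered scene as a calibrated 16-bit WAV
#'
#' Maps pressure to ADC counts through the inverse calibration chain and
#' writes PCM16. Signals that exceed the ADC full scale raise an error
#' reporting the headroom shortfall rather than silently clipping.
#'
#' @param scene the list returned by [genScene()].
#' @param path output WAV path.
#' @param cal a [Calibration-class] (default [calibration()]).
#' @return the path, invisibly.
#' @export
writeSceneWav <- function(scene, path, cal = calibration()) {
  counts <- pressureToCounts(scene$wave, cal)
  peak <- max(abs(counts))
  lim <- 2^(cal@adc_bits - 1L) - 1
  if (peak > lim)
    stop(sprintf(
      "scene exceeds ADC full scale by %.1f dB; reduce levels or gain",
      20 * log10(peak / lim)))
  writeWavPcm(path, counts, scene$manifest@sample_rate)
  invisible(path)
}

#' Write / read a scene manifest as JSON
#'
#' @param manifest a [SceneManifest-class].
#' @param path JSON file path.
#' @export
writeManifest <- function(manifest, path) {
  obj <- list(
    pulses = manifest@pulses,
    whistles = lapply(manifest@whistles, function(w) list(
      contour = w$contour, type = w$type, harmonic_db = w$harmonic_db,
      start_s = w$start_s, duration_s = w$duration_s)),
    noise_rms_db = manifest@noise_rms_db,
    duration = manifest@duration,
    sample_rate = manifest@sample_rate,
    seed = manifest@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  whistles <- obj$whistles
  if (is.data.frame(whistles))
    whistles <- lapply(seq_len(nrow(whistles)), function(i) {
      w <- whistles[i, ]
      list(contour = w$contour[[1L]], type = w$type,
           harmonic_db = w$harmonic_db, start_s = w$start_s,
           duration_s = w$duration_s)
    })
  pulses <- obj$pulses
  if (!is.data.frame(pulses) || !nrow(pulses))
    pulses <- data.frame(time = numeric(0), f0_hz = numeric(0),
                         sigma_t_s = numeric(0), splpp_db = numeric(0),
                         snr_db = numeric(0), train_id = integer(0),
                         intended_class = character(0))
  new("SceneManifest", pulses = pulses,
      whistles = if (is.null(whistles)) list() else whistles,
      noise_rms_db = obj$noise_rms_db, duration = obj$duration,
      sample_rate = obj$sample_rate, seed = as.integer(obj$seed))
}

#' Read a scene spec from YAML
#'
#' Top-level keys `duration`, `sample_rate`, `noise_level_db`, plus
#' `trains:` and `whistles:` lists whose entries hold [trainSpec()] /
#' [whistleSpec()] arguments.
#'
#' @param path YAML file.
#' @return a `SceneSpec`.
#' @export
readSceneSpec <- function(path) {
  y <- yaml::read_yaml(path)
  trains <- lapply(y$trains %||% list(), function(a) do.call(trainSpec, a))
  whistles <- lapply(y$whistles %||% list(), function(a)
    do.call(whistleSpec, a))
  sceneSpec(duration = y$duration,
            sample_rate = y$sample_rate %||% 576000,
            noise_level_db = y$noise_level_db %||% 110,
            trains = trains, whistles = whistles)
}
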
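test_that("Gabor pulses realize the requested peak-to-peak level", {
  for (lvl in c(130, 160, 185)) {
    g <- genGaborPulse(100e3, 25e-6, lvl, FS)
    pp <- max(g$wave) - min(g$wave)
    expect_equal(20 * log10(pp), lvl, tolerance = 0.1)
  }
  # envelope maximum at t = 0 (center sample), even envelope symmetry
  g <- genGaborPulse(80e3, 30e-6, 150, FS)
  expect_equal(which.max(g$wave), g$center)
  env <- exp(-(((seq_along(g$wave)) - g$center) / FS)^2 / (2 * 30e-6^2))
  expect_equal(env, rev(env), tolerance = 1e-12)
  # spectral peak at f0 within one bin
  nfft <- 8192
  mag <- Mod(stats::fft(c(g$wave, numeric(nfft - length(g$wave)))))
  ipk <- which.max(mag[1:(nfft / 2)])
  expect_lt(abs((ipk - 1) * FS / nfft - 80e3), FS / nfft + 1)
  expect_error(genGaborPulse(300e3, 25e-6, 150, FS), "Nyquist")
  expect_error(genGaborPulse(20e3, 1e-6, 150, 96000), "unresolvable")
})

test_that("pulse trains realize their IPI profile and intended class", {
  tr <- genPulseTrain(trainSpec(50, 0.002), FS)
  expect_equal(tr$intended_class, "buzz")
  expect_equal(diff(tr$truth$time), rep(0.002, 49), tolerance = 2 / FS)
  tr2 <- genPulseTrain(trainSpec(20, 0.05), FS)
  expect_equal(tr2$intended_class, "click")
  tr3 <- genPulseTrain(trainSpec(10, 0.01), FS)
  expect_equal(tr3$intended_class, "burst_pulse")
  # linear profile glides between the endpoints
  trl <- genPulseTrain(trainSpec(10, c(0.02, 0.004), profile = "linear"), FS)
  d <- diff(trl$truth$time)
  expect_equal(d[1], 0.02, tolerance = 2 / FS)
  expect_equal(d[length(d)], 0.004, tolerance = 2 / FS)
  # random walk is a pure function of (spec, seed)
  ta <- genPulseTrain(trainSpec(10, 0.01, profile = "random_walk"), FS,
                      seed = 5)
  tb <- genPulseTrain(trainSpec(10, 0.01, profile = "random_walk"), FS,
                      seed = 5)
  expect_identical(ta$truth$time, tb$truth$time)
  # overlapping pulses are refused
  expect_error(genPulseTrain(trainSpec(5, 1e-4, sigma_t = 50e-6), FS),
               "overlap")
})

test_that("whistle synthesis matches its closed-form contour truth", {
  up <- genWhistle(whistleSpec("upsweep", f1 = 5000, f2 = 10000,
                               duration_s = 0.5), FS)
  expect_equal(up$contour$freq_hz[1], 5000)
  expect_equal(up$contour$freq_hz,
               5000 + 10000 * up$contour$time_s, tolerance = 1e-9)
  sine <- genWhistle(whistleSpec("sinusoidal", f1 = 5000, f2 = 7000,
                                 duration_s = 0.5), FS)
  ext <- odontoPulse:::contourExtrema(sine$contour$freq_hz, 100)
  expect_equal(nrow(ext), 2L)
  expect_error(genWhistle(whistleSpec("upsweep", f1 = 5000, f2 = 300e3),
                          FS), "below")
})

test_that("whistle harmonic level is realized in the spectrogram", {
  fs <- 192000
  w <- genWhistle(whistleSpec("constant", f1 = 8000, duration_s = 0.4,
                              harmonic_db = -10, amp_upa = 1), fs)
  sp <- signal::specgram(w$wave, n = 4096, Fs = fs, overlap = 2048)
  S <- Mod(sp$S)
  i1 <- which.min(abs(sp$f - 8000))
  i2 <- which.min(abs(sp$f - 16000))
  mid <- seq(round(ncol(S) * 0.3), round(ncol(S) * 0.7))
  rel_db <- 20 * log10(mean(S[i2, mid]) / mean(S[i1, mid]))
  expect_equal(rel_db, -10, tolerance = 1)
})

test_that("scenes are reproducible and carry complete manifests", {
  sp <- sceneSpec(0.4, noise_level_db = 110,
                  trains = list(trainSpec(5, 0.01, start_s = 0.05),
                                trainSpec(4, 0.02, start_s = 0.25)),
                  whistles = list(whistleSpec("upsweep", duration_s = 0.1,
                                              start_s = 0.2)))
  a <- genScene(sp, seed = 42)
  b <- genScene(sp, seed = 42)
  expect_identical(a$wave, b$wave)
  expect_identical(a$manifest@pulses, b$manifest@pulses)
  c2 <- genScene(sp, seed = 43)
  expect_false(identical(a$wave, c2$wave))
  # manifest counts equal spec counts
  expect_equal(nrow(a$manifest@pulses), 9L)
  expect_equal(length(unique(a$manifest@pulses$train_id)), 2L)
  expect_length(a$manifest@whistles, 1L)
  expect_true(all(a$manifest@pulses$time >= 0 &
                  a$manifest@pulses$time <= 0.4))
})

test_that("realized noise RMS matches the requested level", {
  sc <- genScene(sceneSpec(0.5, noise_level_db = 120), seed = 9)
  rms_db <- 20 * log10(sqrt(mean(sc$wave^2)))
  expect_equal(rms_db, 120, tolerance = 0.5)
})

test_that("scene WAV export detects clipping and round-trips levels", {
  sc <- genScene(sceneSpec(0.05, noise_level_db = 110, trains = list(
    trainSpec(3, 0.01, splpp_db = 170, start_s = 0.015))), seed = 2)
  path <- withr::local_tempfile(fileext = ".wav")
  writeSceneWav(sc, path)
  rec <- countsToPressure(readRecording(path))
  # quantization error is small relative to the rendered pressure
  expect_lt(sd(samples(rec) - sc$wave) / sd(sc$wave), 0.2)
  # over-full-scale scene refuses to write
  hot <- genScene(sceneSpec(0.05, noise_level_db = 110, trains = list(
    trainSpec(3, 0.01, splpp_db = 200, start_s = 0.015))), seed = 2)
  expect_error(writeSceneWav(hot, path), "full scale")
})

test_that("manifests round-trip through JSON", {
  sp <- sceneSpec(0.3, trains = list(trainSpec(4, 0.01, start_s = 0.05)),
                  whistles = list(whistleSpec("convex", f1 = 5000,
                                              f2 = 8000, duration_s = 0.1,
                                              start_s = 0.15)))
  sc <- genScene(sp, seed = 6)
  path <- withr::local_tempfile(fileext = ".json")
  writeManifest(sc$manifest, path)
  back <- readManifest(path)
  expect_equal(back@pulses$time, sc$manifest@pulses$time)
  expect_equal(back@whistles[[1]]$type, "convex")
  expect_equal(back@seed, 6L)
})

test_that("scene specs load from YAML", {
  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "duration: 2",
    "sample_rate: 576000",
    "noise_level_db: 108",
    "trains:",
    "  - n_pulses: 10",
    "    ipi: 0.02",
    "whistles:",
    "  - type: upsweep",
    "    f1: 5000",
    "    f2: 9000",
    "    duration_s: 0.4"), y)
  sp <- readSceneSpec(y)
  expect_equal(sp$duration, 2)
  expect_equal(sp$noise_level_db, 108)
  expect_length(sp$trains, 1L)
  expect_equal(sp$whistles[[1]]$type, "upsweep")
})
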
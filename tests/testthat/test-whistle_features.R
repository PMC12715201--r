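mkFragment <- function(start, dur, f = 6000, step = 0.005) {
  t <- seq(start, start + dur, by = step)
  whistleContour(t, rep(f, length(t)))
}

test_that("joining rule bridges short gaps and respects both conditions", {
  # 300 ms fragments, 150 ms gap: both conditions hold -> one whistle
  out <- joinContours(list(mkFragment(0, 0.3), mkFragment(0.45, 0.3)))
  expect_length(out, 1L)
  expect_equal(nrow(out[[1]]@gaps), 1L)
  # 300 ms fragments, 250 ms gap: gap >= 200 ms -> two whistles
  out2 <- joinContours(list(mkFragment(0, 0.3), mkFragment(0.55, 0.3)))
  expect_length(out2, 2L)
  # 100 ms fragments, 150 ms gap: gap >= fragment duration -> two whistles
  out3 <- joinContours(list(mkFragment(0, 0.1), mkFragment(0.25, 0.1)))
  expect_length(out3, 2L)
})

test_that("joining runs to a fixpoint and is input-order independent", {
  frags <- list(mkFragment(0, 0.3), mkFragment(0.45, 0.3),
                mkFragment(0.9, 0.3), mkFragment(2.0, 0.1))
  a <- joinContours(frags)
  b <- joinContours(rev(frags))
  expect_length(a, 2L)
  expect_equal(nrow(a[[1]]@gaps), 2L)          # two bridged breaks
  expect_equal(lapply(a, function(w) w@time), lapply(b, function(w) w@time))
  expect_error(joinContours(list(mkFragment(0, 0.3), mkFragment(0.2, 0.3))),
               "overlap")
})

test_that("whistle feature identities hold on analytic contours", {
  # linear 5 -> 10 kHz over 500 ms
  t <- seq(0, 0.5, by = 1e-3)
  up <- whistleContour(t, 5000 + 10000 * t)
  f <- measureWhistle(up)
  expect_equal(f$duration_ms, 500)
  expect_equal(f$freq_change_khz, 5)
  expect_equal(f$abs_freq_gradient_khz_per_s, 10)
  expect_equal(f$delta_freq_khz, 5)
  expect_equal(f$n_extrema, 0L)
  expect_equal(f$n_inflection, 0L)
  expect_equal(f$n_saddle, 0L)
  # constant 6 kHz
  flat <- measureWhistle(whistleContour(t, rep(6000, length(t))))
  expect_equal(flat$freq_change_khz, 0)
  expect_equal(flat$abs_freq_gradient_khz_per_s, 0)
  expect_equal(flat$delta_freq_khz, 0)
  # one-period sinusoid 6 +/- 1 kHz
  sine <- whistleContour(t, 6000 + 1000 * sin(2 * pi * t / 0.5))
  fs <- measureWhistle(sine)
  expect_equal(fs$min_freq_khz, 5, tolerance = 1e-3)
  expect_equal(fs$max_freq_khz, 7, tolerance = 1e-3)
  expect_equal(fs$n_extrema, 2L)
})

test_that("identities delta = max - min, change = |end - start|, gradient * duration = change", {
  set.seed(6)
  types <- c("constant", "upsweep", "downsweep", "concave", "convex",
             "sinusoidal")
  for (type in types) {
    spec <- whistleSpec(type, f1 = 6000,
                        f2 = if (type == "downsweep") 3500 else 9000,
                        duration_s = 0.4)
    ct <- truthContour(spec)
    f <- measureWhistle(ct)
    expect_equal(f$delta_freq_khz, f$max_freq_khz - f$min_freq_khz,
                 tolerance = 1e-9)
    expect_equal(f$freq_change_khz,
                 abs(f$end_freq_khz - f$start_freq_khz), tolerance = 1e-9)
    expect_equal(f$abs_freq_gradient_khz_per_s * f$duration_ms / 1000,
                 f$freq_change_khz, tolerance = 1e-9)
    expect_true(f$min_freq_khz <= f$start_freq_khz + 1e-9 &&
                f$start_freq_khz <= f$max_freq_khz + 1e-9)
  }
})

test_that("classifier reproduces the generator type on all six contours", {
  for (type in c("constant", "upsweep", "downsweep", "concave", "convex",
                 "sinusoidal")) {
    spec <- whistleSpec(type, f1 = 6000,
                        f2 = if (type %in% c("downsweep", "concave")) 3500
                             else 9000,
                        duration_s = 0.4)
    ct <- classifyContour(truthContour(spec))
    expect_equal(ct@type, type)
  }
})

test_that("extrema/inflection/saddle counts survive 2x resampling", {
  for (type in c("upsweep", "convex", "sinusoidal")) {
    spec <- whistleSpec(type, f1 = 5000, f2 = 9000, duration_s = 0.4)
    w <- genWhistle(spec, FS)
    coarse <- whistleContour(w$contour$time_s, w$contour$freq_hz)
    t2 <- seq(0, max(w$contour$time_s), by = 5e-4)
    fine <- whistleContour(t2, odontoPulse:::whistleFreq(spec, t2))
    fc <- measureWhistle(coarse)
    ff <- measureWhistle(fine)
    expect_equal(ff$n_extrema, fc$n_extrema)
    expect_equal(ff$n_inflection, fc$n_inflection)
    expect_equal(ff$n_saddle, fc$n_saddle)
  }
})

test_that("a rise-plateau-rise contour yields one saddle", {
  t <- seq(0, 1, by = 2e-3)
  f <- numeric(length(t))
  third <- length(t) %/% 3
  f[1:third] <- seq(5000, 8000, length.out = third)
  f[(third + 1):(2 * third)] <- 8000
  f[(2 * third + 1):length(t)] <- seq(8000, 11000,
                                      length.out = length(t) - 2 * third)
  m <- measureWhistle(whistleContour(t, f))
  expect_equal(m$n_saddle, 1L)
  expect_equal(m$n_extrema, 0L)
})

test_that("grading maps SNR to the three quality grades", {
  expect_equal(gradeWhistle(c(2, 10, 20)), c(1L, 2L, 3L))
  expect_true(all(gradeWhistle(c(10, 20)) >= 2))   # high quality
  expect_false(gradeWhistle(2) >= 2)
  expect_equal(gradeWhistle(7, thresholds = c(8, 12)), 1L)
})

test_that("harmonic detection sees a -10 dB second harmonic and not a pure tone", {
  fs <- 96000
  spec_h <- whistleSpec("upsweep", f1 = 5000, f2 = 9000, duration_s = 0.5,
                        harmonic_db = -10, amp_upa = 1)
  w <- genWhistle(spec_h, fs)
  sp <- signal::specgram(w$wave, n = 2048, Fs = fs, overlap = 1536)
  spec_list <- list(t = sp$t, f = sp$f, S = Mod(sp$S))
  contour <- whistleContour(w$contour$time_s, w$contour$freq_hz)
  expect_true(detectHarmonics(spec_list, contour))
  spec_p <- whistleSpec("upsweep", f1 = 5000, f2 = 9000, duration_s = 0.5,
                        amp_upa = 1)
  wp <- genWhistle(spec_p, fs)
  spp <- signal::specgram(wp$wave, n = 2048, Fs = fs, overlap = 1536)
  expect_false(detectHarmonics(list(t = spp$t, f = spp$f, S = Mod(spp$S)),
                               contour))
})

test_that("harmonic coverage rule rejects partial harmonics", {
  fs <- 96000
  # harmonic present over only ~30% of the duration
  s1 <- genWhistle(whistleSpec("constant", f1 = 6000, duration_s = 0.15,
                               harmonic_db = -6, amp_upa = 1), fs)
  s2 <- genWhistle(whistleSpec("constant", f1 = 6000, duration_s = 0.35,
                               amp_upa = 1), fs)
  wave <- c(s1$wave, s2$wave)
  sp <- signal::specgram(wave, n = 2048, Fs = fs, overlap = 1536)
  t_all <- seq(0, 0.5 - 1e-3, by = 1e-3)
  contour <- whistleContour(t_all, rep(6000, length(t_all)))
  expect_false(detectHarmonics(list(t = sp$t, f = sp$f, S = Mod(sp$S)),
                               contour, coverage = 0.5))
})

test_that("contours above half Nyquist cannot be assessed for harmonics", {
  f <- rep(30000, 50)
  t <- seq_len(50) / 100
  contour <- whistleContour(t, f)
  spec_list <- list(t = t, f = seq(0, 48000, by = 1000),
                    S = matrix(1, 49, 50))
  expect_warning(res <- detectHarmonics(spec_list, contour), "Nyquist")
  expect_false(res)
})

test_that("the ridge tracker recovers a clean synthetic contour", {
  fs <- 96000
  spec <- whistleSpec("upsweep", f1 = 5000, f2 = 9000, duration_s = 0.5,
                      amp_upa = 1)
  w <- genWhistle(spec, fs)
  set.seed(4)
  wave <- w$wave + rnorm(length(w$wave), 0, 0.01)
  ct <- traceContour(wave, fs, band = c(3000, 12000))
  expect_s4_class(ct, "WhistleContour")
  # tracked frequencies near the true contour
  truth <- approx(w$contour$time_s, w$contour$freq_hz, xout = ct@time,
                  rule = 2)$y
  expect_lt(stats::median(abs(ct@freq - truth)), 150)
  cls <- classifyContour(ct)
  expect_equal(cls@type, "upsweep")
})

test_that("contours round-trip through CSV", {
  ct <- mkFragment(0, 0.2, f = 7500)
  path <- withr::local_tempfile(fileext = ".csv")
  writeContour(ct, path)
  back <- readContour(path)
  expect_equal(back@time, ct@time)
  expect_equal(back@freq, ct@freq)
})
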
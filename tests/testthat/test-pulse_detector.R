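# Brute-force reference implementation of the energy operator, kept as a
# plain loop so the vectorized version is checked against an independent
# formulation.
tkeoLoop <- function(x) {
  n <- length(x)
  psi <- numeric(n)
  for (i in 2:(n - 1L)) psi[i] <- x[i]^2 - x[i - 1L] * x[i + 1L]
  psi
}

test_that("tkeo matches its defining recurrence on analytic cases", {
  expect_equal(tkeo(rep(3, 10)), rep(0, 10))
  ramp <- as.numeric(0:9)
  expect_equal(tkeo(ramp)[2:9], rep(1, 8))   # n^2 - (n-1)(n+1) = 1
  # unit sinusoid at fs/4: psi = A^2 sin^2(omega) = 1 at interior points
  x <- sin(pi / 2 * (0:99))
  expect_equal(tkeo(x)[2:99], rep(1, 98), tolerance = 1e-12)
  expect_error(tkeo(c(1, 2)), "at least 3")
})

test_that("tkeo equals the brute-force loop on random series", {
  set.seed(101)
  for (k in 1:10) {
    x <- rnorm(1000)
    expect_equal(tkeo(x), tkeoLoop(x), tolerance = 1e-15)
  }
})

test_that("kernel construction follows the closed forms", {
  k <- buildKernels(576000, 1e-4)
  expect_equal(k@sigma_g, 1e-4 / (2 * sqrt(2 * log(2))), tolerance = 1e-12)
  expect_equal(k@half_length, 122L)           # floor(5 sigma_g * fs)
  expect_length(k@maf1, 245L)
  # direct evaluation of the Gaussian kernel formula
  ts <- 1 / 576000
  idx <- -122:122
  ref <- ts / (k@sigma_g * sqrt(2 * pi)) *
    exp(-(idx * ts)^2 / (2 * k@sigma_g^2))
  expect_equal(k@maf1, ref, tolerance = 1e-15)
  expect_true(all(k@maf2 == k@maf2[1]))
  expect_error(buildKernels(10000, 1e-4 / 1000), "degenerate")
})

test_that("MAF1 and MAF2 have identical gain for random rates and widths", {
  set.seed(42)
  for (i in 1:50) {
    fs <- runif(1, 96e3, 1e6)
    fwhm <- runif(1, 2e-5, 5e-4)
    k <- buildKernels(fs, fwhm)
    expect_lt(abs(sum(k@maf1) - sum(k@maf2)), 1e-12 * sum(k@maf1))
  }
})

test_that("FDR is zero for constant energy and amplitude-invariant", {
  k <- buildKernels(FS, 1e-4)
  psi <- rep(2.5, 3000)
  f <- fdrSeries(psi, k)
  expect_true(all(abs(f$fdr[f$valid]) < 1e-10))
  set.seed(7)
  psi2 <- abs(rnorm(3000)) + 0.1
  fa <- fdrSeries(psi2, k)
  fb <- fdrSeries(17.3 * psi2, k)
  expect_equal(fa$valid, fb$valid)
  expect_equal(fa$fdr[fa$valid], fb$fdr[fb$valid], tolerance = 1e-9)
})

test_that("FDR peaks at a Gaussian energy spike", {
  k <- buildKernels(FS, 1e-4)
  n <- 6000
  center <- 3000
  t <- ((1:n) - center) / FS
  # spike on a small energy pedestal (a noiseless floor leaves the ratio
  # undefined almost everywhere)
  psi <- exp(-t^2 / (2 * k@sigma_g^2)) + 0.01
  # brute-force direct convolution oracle at the center region
  f <- fdrSeries(psi, k)
  ipk <- which.max(ifelse(is.na(f$fdr), -Inf, f$fdr))
  expect_lte(abs(ipk - center), 2)
  # oracle: direct O(n m) convolution agrees with the FFT path
  m <- 2 * k@half_length + 1
  direct <- sapply(center + (-5:5), function(i)
    sum(psi[i + (-k@half_length:k@half_length)] * rev(k@maf1)))
  expect_equal(f$h1[center + (-5:5)], direct, tolerance = 1e-9)
})

test_that("all-zero energy yields no valid FDR and no detections", {
  k <- buildKernels(FS, 1e-4)
  f <- fdrSeries(rep(0, 2000), k)
  expect_false(any(f$valid))
  seg <- asSegment(rep(0, 2000), filtered = TRUE)
  expect_equal(nrow(detectPulses(seg)), 0L)
})

test_that("estimateSnr implements the rms ratio definition", {
  expect_equal(estimateSnr(rep(10, 100), rep(1, 100)), 20)
  expect_equal(estimateSnr(rep(1, 100), rep(1, 100)), 0)
  expect_equal(estimateSnr(rep(1, 10), rep(0, 10)), Inf)
})

test_that("detector recovers injected pulses with accurate times and SNR", {
  sp <- sceneSpec(0.25, noise_level_db = 110, trains = list(
    trainSpec(10, 0.005, f0 = 100e3, splpp_db = 162, start_s = 0.05)))
  sc <- genScene(sp, seed = 21)
  ev <- detectScene(sc)
  truth <- sc$manifest@pulses
  expect_equal(nrow(ev), 10L)
  err_ms <- 1000 * abs(ev$time - truth$time)
  expect_true(all(err_ms <= 0.2))
  # detector SNR estimate close to the generator's realized window SNR
  expect_true(all(abs(ev$snr_db - truth$snr_db) < 3))
})

test_that("snr estimate is close to nominal for an isolated pulse", {
  # single pulse whose realized window SNR the manifest records
  sp <- sceneSpec(0.1, noise_level_db = 110, trains = list(
    trainSpec(1, 0.01, f0 = 80e3, splpp_db = 137, start_s = 0.05)))
  sc <- genScene(sp, seed = 5)
  nominal <- sc$manifest@pulses$snr_db
  expect_gt(nominal, 10)  # scene is in the detectable regime
  ev <- detectScene(sc, detectorConfig(snr_min_db = 5))
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$snr_db - nominal), 1.5)
})

test_that("noise-only segments produce no detections", {
  for (seed in c(3, 14, 15)) {
    sc <- genScene(sceneSpec(0.3, noise_level_db = 110), seed = seed)
    expect_equal(nrow(detectScene(sc)), 0L)
  }
})

test_that("two pulses 0.3 ms apart survive the 0.2 ms refractory", {
  sp <- sceneSpec(0.12, noise_level_db = 110, trains = list(
    trainSpec(2, 3e-4, f0 = 120e3, sigma_t = 15e-6, splpp_db = 165,
              start_s = 0.05)))
  sc <- genScene(sp, seed = 33)
  ev <- detectScene(sc)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$time, sc$manifest@pulses$time, tolerance = 1e-7)
})

test_that("detections are invariant to signal amplitude", {
  sp <- sceneSpec(0.2, noise_level_db = 110, trains = list(
    trainSpec(6, 0.008, f0 = 90e3, splpp_db = 160, start_s = 0.05)))
  sc <- genScene(sp, seed = 8)
  base <- detectScene(sc)
  for (alpha in c(0.01, 100)) {
    sc2 <- sc
    sc2$wave <- alpha * sc$wave
    ev <- detectScene(sc2)
    expect_equal(ev$time, base$time)
    expect_equal(ev$fdr, base$fdr, tolerance = 1e-9)
    expect_equal(ev$snr_db, base$snr_db, tolerance = 1e-9)
  }
})

test_that("overlap duplicates collapse to single events", {
  ev <- data.frame(time = c(0.1, 0.10005, 0.25, 0.4, 0.40012),
                   fdr = c(0.9, 0.95, 0.8, 0.85, 0.7),
                   snr_db = 20, segment_id = "s")
  out <- dedupEvents(ev, tol = 2e-4)
  expect_equal(nrow(out), 3L)
  expect_equal(out$fdr, c(0.95, 0.8, 0.85))
})
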
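test_that("SPL calibration follows the 20 uPa reference", {
  expect_identical(dbSplToPascal(0), 2e-5)
  expect_equal(dbSplToPascal(30), 6.3246e-4, tolerance = 1e-5)
  expect_equal(dbSplToPascal(90), 0.63246, tolerance = 1e-5)
  expect_error(dbSplToPascal(NA_real_))
})

test_that("harmonic complexes are calibrated, placed and periodic", {
  rate <- 1e5
  # single tone: RMS over integer cycles matches the calibrated amplitude
  w <- makeHarmonicComplex(250, 1, duration = 0.1, levelDb = 30, rate = rate)
  rms <- sqrt(mean(samples(w)^2))
  expect_equal(rms * sqrt(2), dbSplToPascal(30), tolerance = 1e-9)
  expect_equal(durationSec(w), 0.1)

  # shifted complex puts components at k*f0 + shift
  w2 <- makeHarmonicComplex(200, 4:7, duration = 0.1, levelDb = 45,
                            shift = 200, rate = rate)
  sp <- Mod(stats::fft(samples(w2)))^2
  f <- (seq_along(sp) - 1) * rate / length(sp)
  half <- f <= rate / 2
  pk <- f[half][localMaximaIdx(sp[half], 4L)]
  expect_equal(sort(pk), c(1000, 1200, 1400, 1600), tolerance = 1e-6)

  # empty harmonic set -> silence
  w3 <- makeHarmonicComplex(240, integer(0), duration = 0.01)
  expect_true(all(samples(w3) == 0))
  expect_length(samples(w3), 1000L)

  # unshifted complex is periodic with period 1/f0
  w4 <- makeHarmonicComplex(250, c(2L, 3L, 5L), duration = 0.02,
                            levelDb = 40, rate = rate)
  s <- samples(w4)
  period <- rate / 250
  expect_lt(max(abs(s[seq_len(1000)] - s[seq_len(1000) + period])),
            1e-12 * max(abs(s)))

  expect_error(makeHarmonicComplex(30000, 2, duration = 0.01), "Nyquist")
})

test_that("transposed tones carry energy at the carriers, not at f0", {
  rate <- 1e5
  w <- makeTransposedTone(250, duration = 0.05, levelDb = 30, rate = rate)
  x <- samples(w)
  atF0 <- bandPower(x, rate, 200, 300)
  atCarrier <- bandPower(x, rate, 3800, 4200)
  expect_gt(atCarrier, 1e3 * atF0)
  # energy near all three default carriers
  expect_gt(bandPower(x, rate, 6100, 6600), 1e3 * atF0)
  expect_gt(bandPower(x, rate, 9800, 10300), 1e3 * atF0)
  # with one carrier commensurate with f0, the waveform repeats at 1/f0
  w1 <- makeTransposedTone(250, duration = 0.05, levelDb = 30,
                           carriers = 4000, rate = rate)
  x1 <- samples(w1)
  period <- rate / 250
  expect_gt(stats::cor(x1[2001:3000], x1[2001:3000 + period]), 0.999)
  # zero modulator -> silence
  w0 <- makeTransposedTone(0, duration = 0.01, carriers = 4000)
  expect_true(all(samples(w0) == 0))
})

test_that("IRN is reproducible and comb-filtered as its gain dictates", {
  a <- makeIRN(0.005, 0.05, gain = 1, nIterations = 1, seed = 42)
  b <- makeIRN(0.005, 0.05, gain = 1, nIterations = 1, seed = 42)
  expect_identical(samples(a), samples(b))
  cc <- makeIRN(0.005, 0.05, gain = 1, nIterations = 1, seed = 43)
  expect_false(identical(samples(a), samples(cc)))

  # delay-and-add: comb maxima at k/d; delay-and-subtract: shifted by 1/(2d)
  rate <- 1e5
  add <- samples(makeIRN(0.005, 0.2, gain = 1, nIterations = 2, seed = 7,
                         rate = rate))
  sub <- samples(makeIRN(0.005, 0.2, gain = -1, nIterations = 2, seed = 7,
                         rate = rate))
  atComb <- bandPower(add, rate, 190, 210) # around 1/d = 200
  atTrough <- bandPower(add, rate, 90, 110) # around 1/(2d)
  expect_gt(atComb, 3 * atTrough)
  atCombS <- bandPower(sub, rate, 90, 110)
  atTroughS <- bandPower(sub, rate, 190, 210)
  expect_gt(atCombS, 3 * atTroughS)

  # RMS calibrated like a tone of the same level
  expect_equal(sqrt(mean(add^2)) * sqrt(2), dbSplToPascal(70),
               tolerance = 1e-9)
})

test_that("audio files load, mix to mono, resample and recalibrate", {
  rate0 <- 44100
  t <- seq_len(rate0 %/% 5) / rate0
  tone <- 0.5 * sin(2 * pi * 880 * t)
  wavPath <- withr::local_tempfile(fileext = ".wav")
  writeTestWav(wavPath, cbind(tone), rate0)
  w <- loadAudio(wavPath, rate = 1e5, levelDb = 60)
  expect_equal(sampleRate(w), 1e5)
  sp <- Mod(stats::fft(samples(w)))^2
  f <- (seq_along(sp) - 1) * 1e5 / length(sp)
  peak <- f[f <= 5e4][which.max(sp[f <= 5e4])]
  expect_equal(peak, 880, tolerance = 0.01)
  expect_equal(sqrt(mean(samples(w)^2)) * sqrt(2), dbSplToPascal(60),
               tolerance = 1e-6)

  # stereo mixes to the channel average (same tone -> same result)
  stPath <- withr::local_tempfile(fileext = ".wav")
  writeTestWav(stPath, cbind(tone, tone), rate0)
  w2 <- loadAudio(stPath, rate = 1e5, levelDb = 60)
  expect_equal(samples(w2), samples(w), tolerance = 1e-6)

  # AIFF of the same material matches the WAV load
  aifPath <- withr::local_tempfile(fileext = ".aiff")
  writeTestAiff(aifPath, tone)
  w3 <- loadAudio(aifPath, rate = 1e5, levelDb = 60)
  expect_equal(samples(w3), samples(w), tolerance = 1e-4)

  # corrupted and empty files error out
  bad <- withr::local_tempfile(fileext = ".wav")
  writeBin(as.raw(1:64), bad)
  expect_error(loadAudio(bad))
  empty <- withr::local_tempfile(fileext = ".wav")
  file.create(empty)
  expect_error(loadAudio(empty))
})
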
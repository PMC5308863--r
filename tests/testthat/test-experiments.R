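test_that("the level-invariance runner reports both modes at both levels", {
  out <- suppressWarnings(runLevelInvariance(
    deskDict(), deskSieve(), levels = c(30, 90), lambdas = c(0, 0.01),
    solver = solverConfig(normalize = TRUE, maxIter = 3000)))
  expect_identical(nrow(out), 4L)
  expect_setequal(out$mode, c("LS", "SC"))
  sc <- out[out$mode == "SC", ]
  # end-to-end level invariance: SC estimates agree across levels
  expect_lt(abs(diff(sc$f_hat)), pitchTol(deskSieve(), 225))
})

test_that("runner outputs are persisted and reproducible from their config", {
  outDir <- withr::local_tempdir()
  out1 <- suppressWarnings(runLevelInvariance(
    deskDict(), deskSieve(), levels = 30, lambdas = 0.01,
    solver = solverConfig(normalize = TRUE, maxIter = 1500),
    outDir = outDir))
  expect_true(file.exists(file.path(outDir, "level-invariance.csv")))
  expect_true(file.exists(file.path(outDir, "level-invariance.json")))
  cfgPath <- file.path(outDir, "level-invariance-config.yaml")
  expect_true(file.exists(cfgPath))
  cfg <- readExperimentConfig(cfgPath)
  out2 <- suppressWarnings(runLevelInvariance(
    deskDict(), deskSieve(), f0 = cfg$f0, harmonics = unlist(cfg$harmonics),
    levels = unlist(cfg$levels), lambdas = unlist(cfg$lambdas),
    solver = solverConfig(normalize = TRUE, maxIter = 1500)))
  expect_identical(out1$f_hat, out2$f_hat)
})

test_that("experiment configs round-trip through YAML", {
  cfg <- list(f0 = 225, harmonics = 3:8, levels = c(30, 90), label = "mf")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeExperimentConfig(cfg, path)
  back <- readExperimentConfig(path)
  expect_equal(back$f0, 225)
  expect_equal(unlist(back$harmonics), 3:8)
  expect_identical(back$label, "mf")
})

test_that("IRN runs are seed-deterministic", {
  dict <- tinyDict()
  sv <- tinySieve()
  r1 <- suppressWarnings(runIrn(dict, sv, delays = 0.005, gains = 1,
      nIterations = 2, nSeeds = 2, seedBase = 5, duration = 0.03,
      solver = solverConfig(normalize = TRUE, maxIter = 1000)))
  r2 <- suppressWarnings(runIrn(dict, sv, delays = 0.005, gains = 1,
      nIterations = 2, nSeeds = 2, seedBase = 5, duration = 0.03,
      solver = solverConfig(normalize = TRUE, maxIter = 1000)))
  expect_identical(r1$table, r2$table)
  expect_identical(colnames(r1$table),
                   c("delay", "gain", "n_itr", "seed", "f_hat"))
})

test_that("the pitch-shift runner records ranked peaks and a line slope", {
  # small shifts stay on one line of the "first effect of pitch shift"
  res <- suppressWarnings(runPitchShift(
    fullDict(), fullSieve(), f0 = 200, harmonics = 4:7,
    shifts = c(0, 20, 40, 60), level = 45,
    solver = solverConfig(normalize = TRUE, maxIter = 20000)))
  expect_true(all(res$table$rank <= 4))
  # zero shift: the top peak sits at the fundamental
  top0 <- res$table[res$table$shift == 0 & res$table$rank == 1, ]
  expect_lt(abs(top0$freq - 200), pitchTol(fullSieve(), 200))
  # the octave-restricted estimate rises roughly like f_L / mean(k)
  expect_true(all(diff(res$topPeaks$f_hat) > 0))
  expect_gt(res$slope, 0.05)
  expect_lt(res$slope, 0.5)
})

test_that("framed analysis tracks a synthetic note and names it", {
  dict <- tinyDict()
  sv <- tinySieve()
  rate <- 1e5
  dur <- 0.06
  t <- seq_len(round(dur * rate)) / rate
  env <- exp(-t / 0.05)
  w <- makeHarmonicComplex(880, 1:4, duration = dur, levelDb = 50,
                           amplitudes = c(1, 0.6, 0.4, 0.25), rate = rate)
  note <- waveform(samples(w) * env, rate)
  res <- suppressWarnings(runFramedNote(note, dict, sv, tSteps = 8,
      solver = solverConfig(normalize = TRUE, maxIter = 4000)))
  expect_identical(dim(res$Pg), c(length(pitchGrid(sv)), 8L))
  expect_equal(colSums(res$Pg), rep(1, 8), tolerance = 1e-9)
  expect_equal(sum(pitchProbs(res$meanPdf)), 1, tolerance = 1e-9)
  expect_lt(abs(res$fHat - 880), pitchTol(sv, 880))
  expect_identical(res$note, "A5")
  # stationary pitch: frame peaks agree up to a few atom spacings. The
  # frame-to-frame phase of the note drifts (the period is a non-integer
  # number of samples) and a g = 1 dictionary is phase-sensitive; phase
  # groups (g > 1, the music default at scale) absorb this.
  frameArgmax <- pitchGrid(sv)[apply(res$Pg, 2, which.max)]
  atomStep <- diff(atomFreqs(dict))[
    which.min(abs(atomFreqs(dict) - 880))]
  expect_lt(max(frameArgmax) - min(frameArgmax), 3 * atomStep)
  expect_error(runFramedNote(waveform(numeric(100)), dict, sv), "shorter")
})

test_that("note naming follows the equal-tempered scale", {
  expect_identical(noteName(880), "A5")
  expect_identical(noteName(440), "A4")
  expect_identical(noteName(261.63), "C4")
  expect_identical(noteName(466), "A#4")
})
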
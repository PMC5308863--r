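test_that("template widths follow the ERB rule and grow with pitch", {
  expect_equal(erb(1000), 132.6390, tolerance = 1e-6)
  grid <- erbSpace(600, 125, 6000)
  sv <- buildSieve(grid, fMax = 6000)
  i1k <- which.min(abs(grid - 1000))
  expect_equal(sieveSigmas(sv)[i1k], 0.2 * erb(grid[i1k]), tolerance = 1e-12)
  expect_equal(0.2 * erb(1000), 26.5278, tolerance = 1e-4)
  expect_true(all(diff(sieveSigmas(sv)) > 0))
})

test_that("rows hold unit-height Gaussians at the harmonic multiples", {
  grid <- erbSpace(800, 125, 20000)
  sv <- buildSieve(grid, fMax = 20000)
  W <- sieveWeights(sv)
  # diagonal: the n = 1 Gaussian is centered on the row pitch
  i <- which.min(abs(grid - 433))
  expect_gte(W[i, i], 1)
  expect_lt(W[i, i], 1.2)
  # a row near 10 kHz has exactly two harmonics under the 20 kHz ceiling
  j <- max(which(grid <= 9800))
  row <- W[j, ]
  expect_identical(floor(sv@fMax / grid[j]), 2)
  expect_gte(row[j], 1)
  j2 <- which.min(abs(grid - 2 * grid[j]))
  expect_gt(row[j2], 0.8)
  # nothing between the harmonics
  mid <- which(grid > 1.4 * grid[j] & grid < 1.6 * grid[j])
  expect_true(all(row[mid] < 1e-6))
})

test_that("coefficient interpolation is local, clipped and P = 15 M", {
  dict <- tinyDict()
  grid <- sieveGrid(dict)
  expect_length(grid, 15L * length(atomFreqs(dict)))
  h <- numeric(length(atomFreqs(dict)))
  h[30] <- 2
  ht <- interpolateCoefficients(h, atomFreqs(dict), grid)
  expect_equal(grid[which.max(ht)], atomFreqs(dict)[30], tolerance = 1e-3)
  expect_true(all(ht >= 0))
  expect_identical(interpolateCoefficients(h * 0, atomFreqs(dict), grid),
                   numeric(length(grid)))
  expect_error(interpolateCoefficients(h, atomFreqs(dict), grid[1:10]))
})

test_that("the pdf is a unit-sum, scale-invariant density", {
  sv <- tinySieve()
  P <- length(pitchGrid(sv))
  ht <- numeric(P)
  ht[localGridIndex(sv, c(1000, 2000, 3000))] <- c(1, 0.8, 0.6)
  pdf <- computePdf(ht, sv)
  expect_equal(sum(pitchProbs(pdf)), 1, tolerance = 1e-12)
  expect_true(all(pitchProbs(pdf) >= 0))
  pdf2 <- computePdf(17.3 * ht, sv)
  expect_equal(pitchProbs(pdf2), pitchProbs(pdf), tolerance = 1e-12)
  # degenerate input: flagged uniform density
  pdf0 <- computePdf(numeric(P), sv)
  expect_true(pdf0@noPitch)
  expect_equal(pitchProbs(pdf0), rep(1 / P, P))
  expect_error(computePdf(-ht, sv))
})

test_that("spikes at harmonics vote for the fundamental and subharmonics", {
  sv <- tinySieve()
  grid <- pitchGrid(sv)
  # single spike at ~1000 Hz: maxima at 1000 and its subharmonics
  ht <- numeric(length(grid))
  ht[localGridIndex(sv, 1000)] <- 1
  pdf <- computePdf(ht, sv)
  est <- estimatePitch(pdf)
  expect_equal(est$fHat, 1000, tolerance = 0.01)
  pk <- est$peaks$freq
  expect_true(any(abs(pk - 500) < 10))
  expect_true(any(abs(pk - 1000 / 3) < 10))
  # spikes at harmonics 1-4 of 433: global maximum at 433
  ht2 <- numeric(length(grid))
  ht2[localGridIndex(sv, 433 * (1:4))] <- 1
  est2 <- estimatePitch(computePdf(ht2, sv))
  expect_equal(est2$fHat, 433, tolerance = 0.01)
})

test_that("pitch readout honors restriction intervals and tie-breaks", {
  grid <- seq(100, 1000, by = 10)
  probs <- rep(0.1, length(grid))
  probs[c(21, 61)] <- c(5, 4) # peaks at 300 and 700
  probs <- probs / sum(probs)
  pdf <- new("PitchPDF", grid = grid, probs = probs)
  expect_equal(estimatePitch(pdf)$fHat, 300)
  expect_equal(estimatePitch(pdf, restrict = c(500, 900))$fHat, 700)
  expect_error(estimatePitch(pdf, restrict = c(2000, 3000)), "empty")
  # exact tie -> lower frequency, with a message
  probs2 <- rep(0.1, length(grid))
  probs2[c(21, 61)] <- 5
  probs2 <- probs2 / sum(probs2)
  pdf2 <- new("PitchPDF", grid = grid, probs = probs2)
  expect_message(est <- estimatePitch(pdf2), "tie")
  expect_equal(est$fHat, 300)
})

test_that("a row template read back through the sieve returns its pitch", {
  sv <- tinySieve()
  grid <- pitchGrid(sv)
  i <- which.min(abs(grid - 800))
  ht <- as.numeric(sieveWeights(sv)[i, ])
  est <- estimatePitch(computePdf(ht, sv))
  ratio <- log2(est$fHat / grid[i])
  expect_lt(abs(ratio - round(ratio)), 0.02) # octave-equivalent of f_i
})

test_that("salience is the ratio of the two tallest octave peaks", {
  grid <- seq(200, 420, by = 2)
  probs <- rep(1e-4, length(grid))
  probs[c(26, 76)] <- c(0.4, 0.2)
  probs <- probs / sum(probs)
  pdf <- new("PitchPDF", grid = grid, probs = probs)
  expect_equal(pitchSalience(pdf, c(200, 420)), 2, tolerance = 1e-12)
  # unimodal: infinite salience marker
  probs1 <- rep(1e-4, length(grid))
  probs1[51] <- 0.5
  probs1 <- probs1 / sum(probs1)
  pdf1 <- new("PitchPDF", grid = grid, probs = probs1)
  expect_identical(pitchSalience(pdf1, c(200, 420)), Inf)
})

test_that("pdfs export to CSV and summarize to JSON-ready lists", {
  sv <- tinySieve()
  ht <- numeric(length(pitchGrid(sv)))
  ht[localGridIndex(sv, c(500, 1000))] <- c(1, 0.5)
  pdf <- computePdf(ht, sv)
  path <- withr::local_tempfile(fileext = ".csv")
  exportPdf(pdf, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), length(pitchGrid(sv)))
  expect_equal(sum(tab$prob), 1, tolerance = 1e-9)
  sm <- pitchSummary(pdf)
  expect_true(is.finite(sm$f_hat))
  expect_lte(nrow(sm$peaks), 4L)
})
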
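## shared output helper: every runner can persist (config, table, summary)
## so a run is reproducible from its saved configuration and seeds
writeRunnerOutput <- function(name, config, table, summary, outDir) {
  if (is.null(outDir)) return(invisible(NULL))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(table, file.path(outDir, paste0(name, ".csv")),
                   row.names = FALSE)
  jsonlite::write_json(summary, file.path(outDir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  yaml::write_yaml(config, file.path(outDir, paste0(name, "-config.yaml")))
  invisible(NULL)
}

#' Read / write an experiment configuration
#'
#' Plain-YAML serialization of the parameter lists consumed by the
#' experiment runners and the command-line interface.
#'
#' @param config a named list of experiment parameters.
#' @param path YAML file path.
#' @return `readExperimentConfig`: the restored list.
#' @export
writeExperimentConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeExperimentConfig
#' @export
readExperimentConfig <- function(path) yaml::read_yaml(path)

#' Stimulus-level invariance of the sparse pitch estimate
#'
#' Runs a missing-fundamental complex (harmonics 3-8 by default) at each
#' level through the pipeline in both sparse (`lambda = 0.01`) and
#' least-squares (`lambda = 0`) modes, recording the pitch estimate and a
#' flatness statistic (peak-to-median ratio of the density). The periphery
#' is switched to saturating mode for levels of `satAbove` dB SPL and up,
#' where cochlear compression matters.
#'
#' @param dict a [Dictionary-class].
#' @param sieve a matching [SieveMatrix-class].
#' @param f0 fundamental, Hz.
#' @param harmonics harmonic numbers present in the complex.
#' @param levels stimulus levels, dB SPL.
#' @param lambdas solver penalties to compare (0 = least squares).
#' @param satAbove level at or above which the saturating periphery is used.
#' @param duration stimulus duration, s.
#' @param solver base [SolverConfig-class]; its lambda is overridden.
#' @param outDir optional output directory (CSV + JSON + config YAML).
#' @return data.frame with columns `level_db`, `mode`, `lambda`, `f_hat`,
#'   `peak_to_median`.
#' @export
runLevelInvariance <- function(dict, sieve, f0 = 225, harmonics = 3:8,
                               levels = c(30, 90), lambdas = c(0, 0.01),
                               satAbove = 60, duration = NULL,
                               solver = solverConfig(normalize = TRUE),
                               outDir = NULL) {
  if (is.null(duration)) duration <- dict@peripheryConfig@simDuration
  rows <- list()
  for (lv in levels) {
    cfg <- dict@peripheryConfig
    if (lv >= satAbove) cfg@mode <- "saturating"
    wave <- makeHarmonicComplex(f0, harmonics, duration, levelDb = lv,
                                rate = dict@rate)
    for (lam in lambdas) {
      sc <- solver
      sc@lambda <- lam
      res <- pitchFromWaveform(wave, dict, sieve, solver = sc, config = cfg)
      est <- estimatePitch(res$pdf)
      rows[[length(rows) + 1L]] <- data.frame(
        level_db = lv,
        mode = if (lam > 0) "SC" else "LS",
        lambda = lam,
        f_hat = est$fHat,
        peak_to_median = max(res$pdf@probs) / stats::median(res$pdf@probs))
    }
  }
  out <- do.call(rbind, rows)
  writeRunnerOutput("level-invariance",
                    list(f0 = f0, harmonics = harmonics, levels = levels,
                         lambdas = lambdas, satAbove = satAbove),
                    out, list(estimates = out$f_hat), outDir)
  out
}

#' Resolved versus unresolved harmonics and pitch salience
#'
#' Four consecutive harmonics of one fundamental placed at increasing
#' spectral locations r (harmonics r..r+3). Low r gives resolved components
#' and a salient pitch; high r gives unresolved components whose salience
#' (ratio of the two tallest density peaks within one octave of the
#' fundamental) declines.
#'
#' @param dict,sieve dictionary and sieve.
#' @param f0 fundamental, Hz.
#' @param rValues first-harmonic locations.
#' @param level stimulus level, dB SPL.
#' @param duration stimulus duration, s.
#' @param solver a [SolverConfig-class].
#' @param outDir optional output directory.
#' @return data.frame with columns `r`, `f_hat` (global argmax),
#'   `f_hat_octave` (argmax within +/- 0.5 octave of `f0`), `salience`.
#' @export
runResolvedUnresolved <- function(dict, sieve, f0 = 433,
                                  rValues = c(1, 6, 10, 17, 22), level = 45,
                                  duration = NULL,
                                  solver = solverConfig(normalize = TRUE),
                                  outDir = NULL) {
  if (is.null(duration)) duration <- dict@peripheryConfig@simDuration
  oct <- octaveInterval(f0)
  rows <- lapply(rValues, function(r) {
    wave <- makeHarmonicComplex(f0, r:(r + 3L), duration, levelDb = level,
                                rate = dict@rate)
    res <- pitchFromWaveform(wave, dict, sieve, solver = solver)
    data.frame(r = r,
               f_hat = estimatePitch(res$pdf)$fHat,
               f_hat_octave = estimatePitch(res$pdf, restrict = oct)$fHat,
               salience = pitchSalience(res$pdf, oct))
  })
  out <- do.call(rbind, rows)
  writeRunnerOutput("resolved",
                    list(f0 = f0, rValues = rValues, level = level),
                    out, list(salience = out$salience), outDir)
  out
}

#' Pitch shift of equally spaced inharmonic complexes
#'
#' Harmonic numbers `harmonics` of `f0`, all shifted by a common Delta-f.
#' For each shift the four tallest density peaks are recorded; the estimates
#' cluster on lines as a function of the lowest component frequency f_L
#' (the "first effect of pitch shift"), whose slope is fitted on the top
#' peaks within one octave of `f0`.
#'
#' @param dict,sieve dictionary and sieve.
#' @param f0 nominal fundamental, Hz.
#' @param harmonics harmonic numbers of the complex.
#' @param shifts Delta-f values, Hz.
#' @param level stimulus level, dB SPL.
#' @param duration stimulus duration, s.
#' @param nPeaks peaks recorded per shift.
#' @param solver a [SolverConfig-class].
#' @param outDir optional output directory.
#' @return list with `table` (columns `shift`, `f_lower`, `rank`, `freq`,
#'   `height`) and `slope` (fitted d f_hat / d f_L of the main line).
#' @export
runPitchShift <- function(dict, sieve, f0 = 200, harmonics = 4:7,
                          shifts = seq(0, 2 * f0, by = f0 / 10), level = 45,
                          duration = NULL, nPeaks = 4,
                          solver = solverConfig(normalize = TRUE),
                          outDir = NULL) {
  if (is.null(duration)) duration <- dict@peripheryConfig@simDuration
  rows <- list()
  tops <- list()
  for (df in shifts) {
    wave <- makeHarmonicComplex(f0, harmonics, duration, levelDb = level,
                                shift = df, rate = dict@rate)
    res <- pitchFromWaveform(wave, dict, sieve, solver = solver)
    est <- estimatePitch(res$pdf)
    pk <- utils::head(est$peaks, nPeaks)
    fL <- min(harmonics) * f0 + df
    if (nrow(pk)) {
      rows[[length(rows) + 1L]] <- data.frame(
        shift = df, f_lower = fL, rank = seq_len(nrow(pk)),
        freq = pk$freq, height = pk$height)
    }
    topOct <- estimatePitch(res$pdf, restrict = octaveInterval(f0))$fHat
    tops[[length(tops) + 1L]] <- data.frame(f_lower = fL, f_hat = topOct)
  }
  tab <- do.call(rbind, rows)
  topTab <- do.call(rbind, tops)
  slope <- unname(stats::coef(stats::lm(f_hat ~ f_lower, data = topTab))[2L])
  writeRunnerOutput("pitch-shift",
                    list(f0 = f0, harmonics = harmonics, shifts = shifts,
                         level = level),
                    tab, list(slope = slope), outDir)
  list(table = tab, slope = slope, topPeaks = topTab)
}

#' Pure tones versus transposed tones
#'
#' Pairs each modulator frequency with a pure tone and a transposed tone of
#' the same f0, runs both through the pipeline, and scores octave-folded
#' hits: an estimate counts as a hit when, folded into the octave of f0, it
#' lies within `tolBins` sieve grid steps of f0 on the ERB-number scale.
#' Transposed tones place low-frequency timing at high-CF places, so the
#' tonotopically constrained model loses their f0 while keeping the pure
#' tones'.
#'
#' @param dict,sieve dictionary and sieve.
#' @param f0Values modulator/tone frequencies, Hz.
#' @param level stimulus level, dB SPL.
#' @param carriers transposed-tone carriers, Hz.
#' @param duration stimulus duration, s.
#' @param tolBins hit tolerance in sieve grid steps.
#' @param solver a [SolverConfig-class].
#' @param outDir optional output directory.
#' @return list with `table` (columns `type`, `f0`, `f_hat`, `ratio`,
#'   `hit`) and `hitRates` (named numeric, `pure` and `transposed`).
#' @export
runTransposedTones <- function(dict, sieve,
                               f0Values = seq(100, 500, length.out = 100),
                               level = 30, carriers = c(4000, 6350, 10080),
                               duration = NULL, tolBins = 1,
                               solver = solverConfig(normalize = TRUE),
                               outDir = NULL) {
  if (is.null(duration)) duration <- dict@peripheryConfig@simDuration
  stepErb <- diff(range(erbNumber(sieve@grid))) / (length(sieve@grid) - 1L)
  foldedHit <- function(fHat, f0) {
    fold <- fHat * 2^(-round(log2(fHat / f0)))
    abs(erbNumber(fold) - erbNumber(f0)) <= tolBins * stepErb
  }
  rows <- list()
  for (f0 in f0Values) {
    pure <- makeHarmonicComplex(f0, 1L, duration, levelDb = level,
                                rate = dict@rate)
    tt <- makeTransposedTone(f0, duration, levelDb = level,
                             carriers = carriers, rate = dict@rate)
    for (case in list(list(type = "pure", w = pure),
                      list(type = "transposed", w = tt))) {
      res <- pitchFromWaveform(case$w, dict, sieve, solver = solver)
      fHat <- estimatePitch(res$pdf)$fHat
      rows[[length(rows) + 1L]] <- data.frame(
        type = case$type, f0 = f0, f_hat = fHat, ratio = fHat / f0,
        hit = foldedHit(fHat, f0))
    }
  }
  tab <- do.call(rbind, rows)
  hitRates <- c(pure = mean(tab$hit[tab$type == "pure"]),
                transposed = mean(tab$hit[tab$type == "transposed"]))
  writeRunnerOutput("transposed",
                    list(f0Values = f0Values, level = level,
                         carriers = carriers, tolBins = tolBins),
                    tab, as.list(hitRates), outDir)
  list(table = tab, hitRates = hitRates)
}

#' Iterated rippled noise pitch histograms
#'
#' Seeded IRN stimuli for every combination of delay, gain and iteration
#' count; each estimate is the density argmax within one octave of the
#' nominal pitch 1/d. Delay-and-add conditions concentrate estimates at
#' 1/d, increasingly so with more iterations; delay-and-subtract stays
#' scattered.
#'
#' @param dict,sieve dictionary and sieve (typically a phase-grouped
#'   dictionary, g > 1, since IRN has random phase).
#' @param delays delays d, s.
#' @param gains +1 and/or -1.
#' @param nIterations iteration counts.
#' @param nSeeds stimuli per condition.
#' @param level stimulus level, dB SPL.
#' @param duration stimulus duration, s (delay line fills before the
#'   analysis window at the signal end).
#' @param lowpassHz stimulus low-pass cutoff, Hz.
#' @param seedBase first RNG seed; seeds are consecutive.
#' @param solver a [SolverConfig-class].
#' @param outDir optional output directory.
#' @return list with `table` (per-stimulus estimates) and `modes` (modal
#'   estimate per condition).
#' @export
runIrn <- function(dict, sieve, delays = 0.005, gains = 1, nIterations = 10,
                   nSeeds = 50, level = 70, duration = 0.05,
                   lowpassHz = 4000, seedBase = 1,
                   solver = solverConfig(normalize = TRUE), outDir = NULL) {
  cfg <- dict@peripheryConfig
  cfg@mode <- "saturating"
  conds <- expand.grid(delay = delays, gain = gains, nItr = nIterations)
  rows <- list()
  seed <- seedBase - 1L
  for (ci in seq_len(nrow(conds))) {
    d <- conds$delay[ci]
    oct <- octaveInterval(1 / d)
    for (s in seq_len(nSeeds)) {
      seed <- seed + 1L
      wave <- makeIRN(d, duration, levelDb = level, gain = conds$gain[ci],
                      nIterations = conds$nItr[ci], seed = seed,
                      lowpassHz = lowpassHz, rate = dict@rate)
      res <- pitchFromWaveform(wave, dict, sieve, solver = solver,
                               config = cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        delay = d, gain = conds$gain[ci], n_itr = conds$nItr[ci],
        seed = seed, f_hat = estimatePitch(res$pdf, restrict = oct)$fHat)
    }
  }
  tab <- do.call(rbind, rows)
  modes <- do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
    sub <- tab[tab$delay == conds$delay[ci] & tab$gain == conds$gain[ci] &
               tab$n_itr == conds$nItr[ci], ]
    counts <- table(sub$f_hat)
    data.frame(delay = conds$delay[ci], gain = conds$gain[ci],
               n_itr = conds$nItr[ci],
               mode_hz = as.numeric(names(counts)[which.max(counts)]),
               mode_count = max(counts))
  }))
  writeRunnerOutput("irn",
                    list(delays = delays, gains = gains,
                         nIterations = nIterations, nSeeds = nSeeds,
                         level = level, seedBase = seedBase),
                    tab, list(modes = modes), outDir)
  list(table = tab, modes = modes)
}

#' Framed analysis of a recorded or synthetic note
#'
#' Divides the waveform into `tSteps` frames (hop = duration / tSteps),
#' analyzes each frame with the standard periphery window anchored at the
#' frame start, aggregates the per-frame coefficient vectors into H_g
#' (M x tSteps) and the per-frame densities into P_g (P x tSteps), averages
#' P_g over time, renormalizes, and reports the argmax with its
#' equal-tempered note name (A4 = 440 Hz).
#'
#' @param wave a [Waveform-class] (a note; use [loadAudio()] for
#'   recordings).
#' @param dict,sieve dictionary and sieve.
#' @param tSteps number of analysis frames.
#' @param solver a [SolverConfig-class].
#' @param outDir optional output directory.
#' @return list with `Hg`, `Pg`, `meanPdf` ([PitchPDF-class]), `fHat`,
#'   `note`.
#' @export
runFramedNote <- function(wave, dict, sieve, tSteps = 100,
                          solver = solverConfig(normalize = TRUE),
                          outDir = NULL) {
  cfg <- dict@peripheryConfig
  rate <- wave@rate
  nFrame <- round(cfg@simDuration * rate)
  n <- length(wave@samples)
  if (n < nFrame) stop("waveform shorter than one analysis frame")
  hop <- n / tSteps
  starts <- pmin(1L + round((seq_len(tSteps) - 1L) * hop), n - nFrame + 1L)
  M <- length(dict@freqs)
  P <- length(sieve@grid)
  Hg <- matrix(0, M, tSteps)
  Pg <- matrix(0, P, tSteps)
  for (i in seq_len(tSteps)) {
    seg <- waveform(wave@samples[starts[i]:(starts[i] + nFrame - 1L)], rate)
    res <- pitchFromWaveform(seg, dict, sieve, solver = solver)
    Hg[, i] <- res$code@h
    Pg[, i] <- res$pdf@probs
  }
  meanProbs <- rowMeans(Pg)
  meanProbs <- meanProbs / sum(meanProbs)
  meanPdf <- new("PitchPDF", grid = sieve@grid, probs = meanProbs,
                 noPitch = FALSE, source = list(frames = tSteps))
  fHat <- sieve@grid[which.max(meanProbs)]
  out <- list(Hg = Hg, Pg = Pg, meanPdf = meanPdf, fHat = fHat,
              note = noteName(fHat))
  writeRunnerOutput("note", list(tSteps = tSteps),
                    data.frame(frame = seq_len(tSteps),
                               f_hat = sieve@grid[apply(Pg, 2L, which.max)]),
                    list(f_hat = fHat, note = out$note), outDir)
  out
}
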
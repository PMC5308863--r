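Package: sparsepitch
Title: Sparse-Coding Model of Pitch Perception from Auditory-Nerve Responses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a spectrotemporal model of pitch perception. Acoustic
    stimuli (harmonic complexes, shifted inharmonic complexes, transposed
    tones, iterated rippled noise, recorded notes) are passed through a
    simplified auditory periphery (gammatone filterbank with an inner-hair-cell
    stage and optional compressive saturation) to obtain a normalized
    spatiotemporal auditory-nerve rate matrix. The matrix is decomposed by an
    L1-regularized (LASSO) sparse coder over a dictionary of auditory-nerve
    response atoms, solved by iterative soft thresholding, and the resulting
    sparse coefficients are scored by a Gaussian harmonic sieve to yield a
    pitch probability density and a single pitch estimate. Runners reproduce
    the classic psychoacoustic probes: the missing fundamental, stimulus-level
    invariance, resolved versus unresolved harmonics and pitch salience, the
    pitch shift of equally spaced tones, transposed tones, iterated rippled
    noise, and framed analysis of musical notes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
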
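#' Create a sparse coder configuration
#'
#' @param lambda L1 penalty weight (>= 0). `lambda = 0` selects the
#'   least-squares mode (projected gradient descent, gradient-norm stopping).
#' @param maxIter iteration cap.
#' @param tol relative stopping tolerance.
#' @param alpha step-size scalar, or `"auto"` (default) for a power-iteration
#'   estimate of the top eigenvalue of D'D inflated by 5%.
#' @param nonneg `"clamp"` or `"onesided"` (see [SolverConfig-class]).
#' @param normalize rescale the target and atom columns to unit Euclidean
#'   norm before iterating (used by the pitch pipeline, where it makes
#'   `lambda` comparable across stimuli and dictionary presets).
#' @return a [SolverConfig-class].
#' @export
solverConfig <- function(lambda = 0.01, maxIter = 5000, tol = 1e-6,
                         alpha = "auto", nonneg = c("clamp", "onesided"),
                         normalize = FALSE) {
  if (identical(alpha, "auto")) alpha <- NA_real_
  new("SolverConfig", lambda = lambda, maxIter = as.integer(maxIter),
      tol = tol, alpha = as.numeric(alpha), nonneg = match.arg(nonneg),
      normalize = normalize)
}

#' Soft-thresholding (shrinkage) operator
#'
#' `sign(x) * max(0, |x| - t)`, elementwise: the proximal operator of the
#' L1 norm.
#'
#' @param x numeric scalar, vector or matrix.
#' @param t threshold (>= 0).
#' @return same shape as `x`.
#' @examples
#' softThreshold(c(0.5, -0.5, 0.1), 0.2) # 0.3 -0.3 0.0
#' @export
softThreshold <- function(x, t) {
  if (t < 0) stop("'t' must be >= 0")
  sign(x) * pmax(0, abs(x) - t)
}

#' Step-size bound for the ISTA iteration
#'
#' Power-iteration estimate of the largest eigenvalue of D'D, inflated by a
#' 5% safety factor. An ISTA step `1/alpha` with `alpha` at or above the top
#' eigenvalue guarantees monotone descent of the penalized objective.
#'
#' @param D numeric matrix or [Dictionary-class].
#' @param maxIter,tol power-iteration controls.
#' @return the step scalar alpha.
#' @export
estimateStep <- function(D, maxIter = 200, tol = 1e-9) {
  G <- if (is(D, "Dictionary")) dictGram(D)$G else crossprod(D)
  1.05 * topEigenvalue(G, maxIter, tol)
}

topEigenvalue <- function(G, maxIter = 200, tol = 1e-9) {
  p <- ncol(G)
  if (p == 0L) return(0)
  x <- rep(1, p) + seq_len(p) / p # fixed, deterministic start
  x <- x / sqrt(sum(x^2))
  ev <- 0
  for (i in seq_len(maxIter)) {
    y <- as.numeric(G %*% x)
    ny <- sqrt(sum(y^2))
    if (ny == 0) return(0)
    evNew <- sum(x * y)
    x <- y / ny
    if (abs(evNew - ev) <= tol * abs(evNew)) {
      ev <- evNew
      break
    }
    ev <- evNew
  }
  ev
}

## Gram matrix and column norms of a dictionary, cached per build identity
.gramCache <- new.env(parent = emptyenv())

dictGram <- function(dict, normalized = FALSE) {
  key <- contentHash(list(dim(dict@atoms), dict@freqs, dict@levels,
                          dict@family, dict@nGroups, dict@peripheryConfig,
                          dict@rate))
  hit <- .gramCache[[key]]
  if (is.null(hit)) {
    G <- crossprod(dict@atoms)
    nrm <- sqrt(diag(G))
    hit <- list(G = G, colNorms = nrm, alpha = 1.05 * topEigenvalue(G),
                Gn = NULL, alphaN = NULL)
    .gramCache[[key]] <- hit
  }
  if (normalized && is.null(hit$Gn)) {
    hit$Gn <- hit$G / tcrossprod(hit$colNorms)
    hit$alphaN <- 1.05 * topEigenvalue(hit$Gn)
    .gramCache[[key]] <- hit
  }
  hit
}

#' Solve the L1-regularized reconstruction by iterative soft thresholding
#'
#' Minimizes `0.5 * ||v - D h||^2 + (lambda/2) * ||h||_1` by the ISTA
#' update `h <- soft(h + (1/alpha) * D'(v - D h), lambda / (2 * alpha))`
#' from `h = 0`, stopping when the relative objective change falls below
#' `tol` or at `maxIter`. With `lambda = 0` the update is plain gradient
#' descent toward the least-squares solution and stopping is on the relative
#' gradient norm. Negative coefficients are clamped to zero at exit
#' (default) before groups are collapsed by summation.
#'
#' @param v numeric target vector (a vectorized AN response).
#' @param D [Dictionary-class] or numeric matrix with `length(v)` rows.
#' @param config a [SolverConfig-class].
#' @return a [SparseCode-class]. A hit of the iteration cap is reported via
#'   the `converged` slot and a warning.
#' @export
fitSparseCode <- function(v, D, config = solverConfig()) {
  stopifnot(is(config, "SolverConfig"))
  isDict <- is(D, "Dictionary")
  mat <- if (isDict) D@atoms else as.matrix(D)
  if (length(v) != nrow(mat))
    stop("length(v) must equal nrow(D)")
  g <- if (isDict) D@nGroups else 1L
  p <- ncol(mat)

  if (isDict) {
    cache <- dictGram(D, normalized = config@normalize)
    nrm <- cache$colNorms
    if (config@normalize) {
      G <- cache$Gn
      alphaRaw <- cache$alphaN
    } else {
      G <- cache$G
      alphaRaw <- cache$alpha
    }
  } else {
    G <- crossprod(mat)
    nrm <- sqrt(diag(G))
    alphaRaw <- NULL
    if (config@normalize) {
      if (any(nrm == 0)) stop("cannot normalize zero atom columns")
      G <- G / tcrossprod(nrm)
    }
  }
  b <- as.numeric(crossprod(mat, v))
  vv <- sum(v^2)
  if (config@normalize) {
    if (any(nrm == 0)) stop("cannot normalize zero atom columns")
    nv <- sqrt(vv)
    if (nv > 0) {
      b <- b / (nrm * nv)
      vv <- 1
    } else {
      b <- b * 0
      vv <- 0
    }
  }
  alpha <- if (!is.na(config@alpha)) config@alpha
           else if (!is.null(alphaRaw)) alphaRaw
           else 1.05 * topEigenvalue(G)
  if (alpha <= 0) alpha <- 1

  lambda <- config@lambda
  thr <- lambda / (2 * alpha)
  shrink <- if (config@nonneg == "onesided") {
    function(x) pmax(0, x - thr)
  } else {
    function(x) sign(x) * pmax(0, abs(x) - thr)
  }

  h <- numeric(p)
  objective <- function(h, Gh) {
    0.5 * (vv - 2 * sum(h * b) + sum(h * Gh)) + (lambda / 2) * sum(abs(h))
  }
  trace <- numeric(config@maxIter)
  J <- 0.5 * vv
  converged <- FALSE
  it <- 0L
  bNorm <- sqrt(sum(b^2))
  Gh <- numeric(p) # G %*% h at h = 0
  while (it < config@maxIter) {
    it <- it + 1L
    grad <- b - Gh
    h <- shrink(h + grad / alpha)
    Gh <- as.numeric(G %*% h)
    Jnew <- objective(h, Gh)
    trace[it] <- Jnew
    if (lambda > 0) {
      if (abs(J - Jnew) <= config@tol * max(abs(J), .Machine$double.eps)) {
        converged <- TRUE
        J <- Jnew
        break
      }
    } else {
      if (sqrt(sum((b - Gh)^2)) <= config@tol * max(bNorm, .Machine$double.eps)) {
        converged <- TRUE
        J <- Jnew
        break
      }
    }
    J <- Jnew
  }
  if (!converged)
    warning("sparse coder hit the iteration cap (", config@maxIter,
            ") before reaching tol")
  hG <- pmax(h, 0) # clamp-at-exit (no-op in one-sided mode)
  new("SparseCode",
      hGrouped = hG,
      h = collapseGroups(hG, g),
      objective = J, nIter = it, converged = converged, lambda = lambda,
      trace = trace[seq_len(it)])
}

#' Collapse phase groups by summation
#'
#' Sums the `g` contiguous same-frequency entries of a group-resolved
#' coefficient vector into one coefficient per atom frequency.
#'
#' @param hGrouped numeric vector of length `g * M` (group columns
#'   contiguous).
#' @param g group size.
#' @return numeric vector of length `M`.
#' @export
collapseGroups <- function(hGrouped, g) {
  g <- as.integer(g)
  if (length(hGrouped) %% g != 0L)
    stop("length(hGrouped) is not a multiple of the group size")
  if (g == 1L) return(as.numeric(hGrouped))
  colSums(matrix(hGrouped, nrow = g))
}

#' Write a solver objective trace to CSV
#'
#' @param code a [SparseCode-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeSolverTrace <- function(code, path) {
  stopifnot(is(code, "SparseCode"))
  utils::write.csv(
    data.frame(iteration = seq_along(code@trace), objective = code@trace),
    path, row.names = FALSE)
  invisible(path)
}
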
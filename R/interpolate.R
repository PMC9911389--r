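## Spherical-spline interpolation of bad channels (Perrin-style).

# Legendre polynomials P_1..P_nTerms evaluated at x (vector), as a matrix
# length(x) x nTerms, via the three-term recursion.
.legendreMatrix <- function(x, nTerms) {
  out <- matrix(0, length(x), nTerms)
  pPrev <- rep(1, length(x))  # P_0
  p <- x                      # P_1
  out[, 1] <- p
  if (nTerms >= 2) {
    for (n in 2:nTerms) {
      pNext <- ((2 * n - 1) * x * p - (n - 1) * pPrev) / n
      out[, n] <- pNext
      pPrev <- p
      p <- pNext
    }
  }
  out
}

# Spline kernel g(cos angle) with order-m splines, Legendre expansion to
# degree nTerms.
.splineG <- function(cosang, m = 4, nTerms = 7) {
  cosang <- pmin(pmax(cosang, -1), 1)
  n <- seq_len(nTerms)
  coef <- (2 * n + 1) / (n * (n + 1))^m
  P <- .legendreMatrix(as.vector(cosang), nTerms)
  g <- as.vector(P %*% coef) / (4 * pi)
  if (!is.null(dim(cosang))) dim(g) <- dim(cosang)
  g
}

# Linear operator (n_bad x n_good) mapping good-channel data to
# spherical-spline estimates at the bad positions.
.splineOperator <- function(pos, good, bad, lambda = 1e-5, m = 4,
                            nTerms = 7) {
  Eg <- pos[good, , drop = FALSE]
  Eb <- pos[bad, , drop = FALSE]
  G <- .splineG(Eg %*% t(Eg), m, nTerms)
  Gb <- .splineG(Eb %*% t(Eg), m, nTerms)
  k <- length(good)
  A <- rbind(cbind(G + diag(lambda, k), rep(1, k)), c(rep(1, k), 0))
  # rows of solve(A) give [c; c0] from [z; 0]; estimate = Gb c + c0
  Ainv <- solve(A)
  (cbind(Gb, rep(1, nrow(Gb))) %*% Ainv)[, seq_len(k), drop = FALSE]
}

.interpMatrix <- function(data, pos, bad) {
  nCh <- nrow(data)
  bad <- sort(unique(bad))
  if (!length(bad)) return(data)
  if (length(bad) >= nCh) stop("cannot interpolate: all channels are bad")
  good <- setdiff(seq_len(nCh), bad)
  if (length(good) < 3L) stop("at least 3 good channels are required")
  if (nrow(pos) != nCh)
    stop("channel positions are required for interpolation")
  W <- .splineOperator(pos, good, bad)
  data[bad, ] <- W %*% data[good, , drop = FALSE]
  data
}

.resolveBad <- function(bad, labels) {
  if (is.character(bad)) {
    idx <- match(bad, labels)
    if (anyNA(idx))
      stop(sprintf("unknown channel label(s): %s",
                   paste(bad[is.na(idx)], collapse = ", ")))
    idx
  } else {
    as.integer(bad)
  }
}

#' @describeIn interpolateChannels continuous recording
#' @export
setMethod("interpolateChannels", "ContinuousRecording", function(x, bad) {
  bad <- .resolveBad(bad, x@channelLabels)
  initialize(x, data = .interpMatrix(x@data, x@channelPositions, bad))
})

#' @describeIn interpolateChannels epoch set
#' @export
setMethod("interpolateChannels", "EpochSet", function(x, bad) {
  bad <- .resolveBad(bad, x@channelLabels)
  d <- dim(x@data)
  flat <- matrix(x@data, d[1], d[2] * d[3])
  initialize(x, data = array(.interpMatrix(flat, x@channelPositions, bad), d))
})
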
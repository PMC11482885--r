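#' Zero-order-hold discretization of state-space parameters
#'
#' Converts continuous state-space parameters to their discrete
#' counterparts at step size \code{delta}: \code{Abar = exp(delta * A)}
#' (zero-order hold) and \code{Bbar = delta * B} (Euler). With a
#' negative-real \code{A} and \code{delta >= 0} the discrete transition
#' satisfies \code{|Abar| <= 1}, so bounded inputs give bounded states.
#'
#' @param A,B continuous parameters (vectorized).
#' @param delta non-negative step size(s).
#' @return list with elements \code{Abar} and \code{Bbar}.
#' @export
discretize <- function(A, B, delta) {
  if (any(delta < 0)) stop("delta must be >= 0")
  list(Abar = exp(delta * A), Bbar = delta * B)
}

.scanCheckDims <- function(Abar, Bbar, C, x) {
  L <- nrow(x); d <- ncol(x)
  stopifnot(is.array(Abar), is.array(Bbar), is.matrix(C))
  if (!all(is.finite(x))) stop("non-finite input to selective scan")
  da <- dim(Abar)
  if (length(da) != 3L || any(da != dim(Bbar)) || da[1L] != L || da[2L] != d)
    stop("Abar/Bbar must be L x d x n arrays matching x")
  if (nrow(C) != L || ncol(C) != da[3L])
    stop("C must be an L x n matrix")
  c(L = L, d = d, n = da[3L])
}

#' Selective scan, sequential reference implementation
#'
#' Runs the discrete selective state-space recurrence
#' \code{h_t = Abar_t * h_{t-1} + Bbar_t * x_t},
#' \code{y_t = C_t . h_t} with \code{h_0 = 0}, where the discretized
#' transition \code{Abar}, input matrix \code{Bbar} and readout \code{C}
#' may vary with position (input-dependent selectivity). This is the
#' plain sequential implementation used as the correctness reference.
#'
#' @param Abar,Bbar numeric \code{L x d x n} arrays (per-position,
#'   per-channel, per-state discretized parameters).
#' @param C numeric \code{L x n} readout matrix.
#' @param x numeric \code{L x d} input.
#' @return numeric \code{L x d} output \code{y}.
#' @export
selectiveScanRecurrent <- function(Abar, Bbar, C, x) {
  dm <- .scanCheckDims(Abar, Bbar, C, x)
  L <- dm[["L"]]; d <- dm[["d"]]; n <- dm[["n"]]
  h <- matrix(0, d, n)
  y <- matrix(0, L, d)
  for (t in seq_len(L)) {
    At <- matrix(Abar[t, , ], d, n)
    Bt <- matrix(Bbar[t, , ], d, n)
    h <- At * h + Bt * x[t, ]
    y[t, ] <- h %*% C[t, ]
  }
  y
}

#' Selective scan via parallel associative scan
#'
#' Computes the same output as \code{\link{selectiveScanRecurrent}}
#' using a vectorized associative (Hillis-Steele) prefix scan over the
#' affine maps \code{h -> a*h + b}: \code{O(log L)} sweeps of
#' elementwise operations instead of a sequential loop, with work linear
#' in \code{L} per sweep.
#'
#' @inheritParams selectiveScanRecurrent
#' @return numeric \code{L x d} output \code{y}.
#' @export
selectiveScanParallel <- function(Abar, Bbar, C, x) {
  dm <- .scanCheckDims(Abar, Bbar, C, x)
  L <- dm[["L"]]; d <- dm[["d"]]; n <- dm[["n"]]
  a <- matrix(Abar, L, d * n)                 # columns (c, j), c fastest
  b <- matrix(Bbar, L, d * n) * x[, rep(seq_len(d), n), drop = FALSE]
  off <- 1L
  while (off < L) {
    idx <- (off + 1L):L
    b[idx, ] <- a[idx, , drop = FALSE] * b[idx - off, , drop = FALSE] +
      b[idx, , drop = FALSE]
    a[idx, ] <- a[idx, , drop = FALSE] * a[idx - off, , drop = FALSE]
    off <- off * 2L
  }
  y <- matrix(0, L, d)
  for (j in seq_len(n)) {
    cols <- ((j - 1L) * d + 1L):(j * d)
    y <- y + b[, cols, drop = FALSE] * C[, j]
  }
  y
}
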
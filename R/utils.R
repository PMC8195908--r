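# shared numerical helpers (internal)

# clamp cosines into [-1, 1] before acos
.clampCos <- function(x) pmin(pmax(x, -1), 1)

# row-normalize to unit vectors
.unitRows <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize a zero vector")
  m / nrm
}

# great-circle interpolation between two unit vectors
.slerp <- function(a, b, f) {
  w <- acos(.clampCos(sum(a * b)))
  if (w < 1e-12) return(a)
  v <- (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
  v / sqrt(sum(v^2))
}

# Moore-Penrose pseudoinverse via SVD with a relative singular-value
# cutoff; the number of retained singular values is attached as
# attr(, "rank") so ill-conditioned solves stay diagnosable
.pinv <- function(a, rtol = 1e-8) {
  s <- svd(a)
  keep <- s$d > rtol * s$d[1]
  out <- s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
  attr(out, "rank") <- sum(keep)
  out
}

# spherical-spline kernel g(x) = (1/4pi) sum_n (2n+1)/(n^m (n+1)^m) P_n(x);
# x may be a vector or matrix of cosines
.splineKernel <- function(x, orderM = 4, nLegendre = 50L) {
  dims <- dim(x)
  x <- as.numeric(x)
  pPrev <- rep(1, length(x)) # P_0
  pCur <- x                  # P_1
  out <- 0
  for (n in seq_len(nLegendre)) {
    out <- out + (2 * n + 1) / (n^orderM * (n + 1)^orderM) * pCur
    pNext <- ((2 * n + 1) * x * pCur - n * pPrev) / (n + 1)
    pPrev <- pCur
    pCur <- pNext
  }
  out <- out / (4 * pi)
  dim(out) <- dims
  out
}

# deterministic key for a grid/model configuration
.configKey <- function(...) {
  paste(vapply(list(...), function(v) paste(format(v, digits = 15),
                                            collapse = ","), ""),
        collapse = "|")
}
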
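# shared fixtures (memoized: the 62-channel lead field is expensive) and
# independent oracles used across test files

.cache <- new.env(parent = emptyenv())

.memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

fixtureModel <- function() .memo("model", concentricSphereHeadModel())
fixtureMontage62 <- function() .memo("mon62", standardMontage(62))
fixtureGrid <- function() .memo("grid", buildSourceGrid())
fixtureLeadField62 <- function() .memo("lf62", computeLeadField(
  fixtureModel(), fixtureMontage62(), fixtureGrid()))

# Closed-form potential of a current dipole in a homogeneous conducting
# sphere of unit radius with insulating exterior, evaluated on the
# surface. Derived by summing the Legendre series analytically with
# generating functions (independent of the package's per-degree
# boundary-value path).
homogSpherePotential <- function(pos, moment, electrode, sigma = 1) {
  b <- sqrt(sum(pos^2))
  stopifnot(b > 1e-8, b < 1)
  rhat <- pos / b
  x <- sum(rhat * electrode)
  pr <- sum(moment * rhat)
  tang <- sum(moment * (electrode - x * rhat))
  d <- sqrt(1 - 2 * b * x + b^2)
  u <- 1 - b * x + d
  (pr * (2 * (x - b) / d^3 + (1 / d - 1) / b) +
      tang * (2 / d^3 + (d + 1) / (d * u))) / (4 * pi * sigma)
}

# spherical-spline kernel via pracma's Legendre functions (independent of
# the package's recurrence)
oracleSplineKernel <- function(x, orderM = 4, nLegendre = 50) {
  vapply(x, function(xi) {
    terms <- vapply(seq_len(nLegendre), function(n) {
      pn <- pracma::legendre(n, xi)[1, 1]
      (2 * n + 1) / (n^orderM * (n + 1)^orderM) * pn
    }, numeric(1))
    sum(terms) / (4 * pi)
  }, numeric(1))
}

# quasi-uniform unit electrodes on the upper cap (test geometry only)
fibonacciCapElectrodes <- function(n, zmin = 0) {
  z <- 1 - (seq_len(n) - 0.5) / n * (1 - zmin)
  az <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(az), rho * sin(az), z)
}

# is the label set connected in the montage's (undirected) 4-nearest-
# neighbor graph? brute-force traversal
isConnectedIn4nnGraph <- function(montage, labels) {
  d <- angularDistances(montage)
  all <- channelLabels(montage)
  n <- length(all)
  adj <- matrix(FALSE, n, n, dimnames = list(all, all))
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:5]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj)
  idx <- match(labels, all)
  seen <- idx[1]
  frontier <- idx[1]
  while (length(frontier)) {
    nb <- unique(unlist(lapply(frontier, function(i) which(adj[i, ]))))
    nb <- intersect(setdiff(nb, seen), idx)
    seen <- c(seen, nb)
    frontier <- nb
  }
  length(seen) == length(idx)
}

# random 3-D rotation matrix (uniform via QR with positive diagonal)
randomRotation <- function() {
  qr <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr)
  q %*% diag(sign(diag(qr.R(qr))))
}

# clean copy of a recording with its bad mask dropped (scoring truth)
clearBads <- function(rec) {
  badChannels(rec) <- character(0)
  rec
}
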
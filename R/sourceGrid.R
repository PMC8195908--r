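#' Build the equivalent-source dipole layer
#'
#' Places `nCap` radially oriented dipoles on a spherical cap of radius
#' `capRadius` and `nPlane` dipoles oriented along +z on the transverse
#' plane at `planeZ` that closes the cap from below, forming a closed
#' surface around the brain sources. Placement is deterministic and
#' quasi-uniform: a Fibonacci (golden-angle) lattice, equal-area in z on
#' the cap and a sunflower layout on the disk. The defaults reproduce the
#' standard equivalent-source configuration: 3000 dipoles, 2600 on the
#' cap and 400 on the plane.
#'
#' @param nCap number of radial dipoles on the cap.
#' @param nPlane number of +z dipoles on the plane.
#' @param capRadius cap sphere radius (dimensionless; must be inside the
#'   brain compartment of the paired head model).
#' @param planeZ height of the closing plane.
#'
#' @return A [SourceGrid-class].
#'
#' @examples
#' grid <- buildSourceGrid()
#' grid
#'
#' @export
buildSourceGrid <- function(nCap = 2600, nPlane = 400,
                            capRadius = 0.869, planeZ = -0.076) {
  nCap <- as.integer(nCap)
  nPlane <- as.integer(nPlane)
  if (nCap < 0L || nPlane < 0L || nCap + nPlane < 1L)
    stop("the grid must contain at least one dipole")
  if (capRadius <= 0) stop("capRadius must be positive")
  if (planeZ >= capRadius)
    stop("planeZ must lie below the cap apex (planeZ < capRadius)")
  golden <- pi * (3 - sqrt(5))
  if (nCap > 0L) {
    zmin <- planeZ / capRadius
    if (nCap == 1L) {
      z <- 1
    } else {
      z <- 1 - (seq_len(nCap) - 0.5) / nCap * (1 - zmin)
    }
    az <- (seq_len(nCap) - 1) * golden
    rho <- sqrt(pmax(0, 1 - z^2))
    capPos <- capRadius * cbind(rho * cos(az), rho * sin(az), z)
    capOri <- capPos / capRadius
  } else {
    capPos <- capOri <- matrix(0, 0, 3)
  }
  if (nPlane > 0L) {
    rimR <- sqrt(capRadius^2 - planeZ^2)
    r <- rimR * sqrt((seq_len(nPlane) - 0.5) / nPlane)
    az <- (seq_len(nPlane) - 1) * golden
    planePos <- cbind(r * cos(az), r * sin(az), rep(planeZ, nPlane))
    planeOri <- matrix(rep(c(0, 0, 1), each = nPlane), ncol = 3)
  } else {
    planePos <- planeOri <- matrix(0, 0, 3)
  }
  pos <- rbind(capPos, planePos)
  ori <- rbind(capOri, planeOri)
  colnames(pos) <- colnames(ori) <- c("x", "y", "z")
  new("SourceGrid", positions = pos, orientations = ori,
      nCap = nCap, nPlane = nPlane,
      capRadius = capRadius, planeZ = planeZ)
}

#' @rdname buildSourceGrid
#' @param object,x a `SourceGrid`.
#' @export
setMethod("show", "SourceGrid", function(object) {
  cat(sprintf(
    "SourceGrid: %d dipoles (%d radial on cap r=%.3f, %d +z on plane z=%.3f)\n",
    object@nCap + object@nPlane, object@nCap, object@capRadius,
    object@nPlane, object@planeZ))
})

#' @rdname buildSourceGrid
#' @export
setMethod("nSources", "SourceGrid",
          function(x) x@nCap + x@nPlane)

#' @rdname buildSourceGrid
#' @export
setMethod("sourcePositions", "SourceGrid", function(x) x@positions)

#' @rdname buildSourceGrid
#' @export
setMethod("sourceOrientations", "SourceGrid", function(x) x@orientations)
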
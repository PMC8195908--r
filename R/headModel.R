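#' Construct a three-concentric-sphere head model
#'
#' The default geometry and conductivities are the classical values for a
#' normalized human head: sphere radii 0.87 (inner skull), 0.92 (outer
#' skull) and 1.0 (scalp), with relative conductivities 1.0 (brain and
#' scalp) and 0.0125 (skull).
#'
#' @param rBrain,rSkull,rScalp shell radii, normalized by the head radius.
#' @param sigmaBrain,sigmaSkull,sigmaScalp relative conductivities.
#' @param nTermsMax maximum Legendre degree of the forward series. The
#'   default (300) lets the series converge to `seriesRtol` for sources at
#'   the default cap eccentricity 0.869.
#' @param seriesRtol relative term size at which the series is declared
#'   converged.
#'
#' @return A [ConcentricSphereHeadModel-class] object.
#'
#' @examples
#' model <- concentricSphereHeadModel()
#' model
#'
#' @export
concentricSphereHeadModel <- function(rBrain = 0.87, rSkull = 0.92,
                                      rScalp = 1.0, sigmaBrain = 1.0,
                                      sigmaSkull = 0.0125, sigmaScalp = 1.0,
                                      nTermsMax = 300L, seriesRtol = 1e-12) {
  new("ConcentricSphereHeadModel",
      rBrain = rBrain, rSkull = rSkull, rScalp = rScalp,
      sigmaBrain = sigmaBrain, sigmaSkull = sigmaSkull,
      sigmaScalp = sigmaScalp, nTermsMax = as.integer(nTermsMax),
      seriesRtol = seriesRtol)
}

#' @describeIn concentricSphereHeadModel compact display of the shell
#'   geometry and conductivities.
#' @param object a `ConcentricSphereHeadModel`.
#' @export
setMethod("show", "ConcentricSphereHeadModel", function(object) {
  cat("ConcentricSphereHeadModel\n")
  cat(sprintf("  radii (brain/skull/scalp): %.3f / %.3f / %.3f\n",
              object@rBrain, object@rSkull, object@rScalp))
  cat(sprintf("  conductivities:            %.4g / %.4g / %.4g\n",
              object@sigmaBrain, object@sigmaSkull, object@sigmaScalp))
  cat(sprintf("  series: up to %d terms, rtol %.2g\n",
              object@nTermsMax, object@seriesRtol))
})

# Per-degree scalp transfer coefficients of the layered sphere.
#
# For each Legendre degree n the radial part of the potential solves a
# boundary-value problem: in the brain a source term r^-(n+1) (unit
# coefficient) plus a regular term A1 r^n, in the skull and scalp shells
# A r^n + B r^-(n+1), with continuity of potential and radial current at
# the interfaces and zero radial current at the scalp surface. The
# returned g_n is the scalp-surface value for a unit source coefficient;
# in the homogeneous limit it reduces to (2n+1)/n (for scalp radius 1).
# Unknowns are eliminated from the outside in, which stays
# well-conditioned at high degree.
.shellGains <- function(model, nmax) {
  n <- seq_len(nmax)
  r1 <- model@rBrain
  r2 <- model@rSkull
  R <- model@rScalp
  s1 <- model@sigmaBrain
  s2 <- model@sigmaSkull
  s3 <- model@sigmaScalp
  # scalp shell: outer Neumann fixes B3/A3
  rho3 <- n / (n + 1) * R^(2 * n + 1)
  f3 <- r2^n + rho3 * r2^-(n + 1)
  df3 <- n * r2^(n - 1) - (n + 1) * rho3 * r2^-(n + 2)
  # skull shell matched to the scalp shell at r2 (taking A3 = 1)
  a2 <- ((n + 1) * f3 + (s3 / s2) * r2 * df3) / (2 * n + 1) / r2^n
  b2 <- (n * f3 - (s3 / s2) * r2 * df3) / (2 * n + 1) * r2^(n + 1)
  d2 <- a2 * r1^n + b2 * r1^-(n + 1)
  dd2 <- n * a2 * r1^(n - 1) - (n + 1) * b2 * r1^-(n + 2)
  # brain compartment matched at r1 fixes the overall amplitude A3
  a3 <- s1 * (2 * n + 1) * r1^-(n + 2) / (s1 * n * d2 / r1 - s2 * dd2)
  a3 * (R^n + rho3 * R^-(n + 1))
}
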
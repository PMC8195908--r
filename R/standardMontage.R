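#' Standard 10-20 / extended 10-20 montage fixtures
#'
#' Deterministic electrode montages built geometrically from the
#' international 10-20 system and its 10-10 extension: the
#' circumferential ring sits at a polar angle of 72 degrees from the
#' vertex, midline electrodes step in 18-degree increments along the
#' nasion-inion arc, and the intermediate electrodes of each coronal row
#' are placed by equal-arc (great-circle) subdivision between the midline
#' electrode and the ring electrode of the same row. Coordinates are
#' head-centered unit vectors with +z toward the vertex (Cz) and +x
#' toward the nasion.
#'
#' The 62-channel layout emulates a Brain Products-style extended 10-20
#' cap (10-10 electrodes plus the lower-temporal pair FT9/FT10; FCz, the
#' usual recording-reference site, is not part of the cap).
#'
#' @param nChannels montage size; one of 19, 32 or 62.
#' @return An [ElectrodeMontage-class].
#'
#' @examples
#' mon <- standardMontage(62)
#' mon
#'
#' @export
standardMontage <- function(nChannels = 62) {
  nChannels <- as.integer(nChannels)
  sets <- list(
    `19` = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T7", "C3", "Cz",
             "C4", "T8", "P7", "P3", "Pz", "P4", "P8", "O1", "O2"),
    `32` = c("Fp1", "Fp2", "AFz", "AF3", "AF4", "F7", "F3", "Fz", "F4",
             "F8", "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4",
             "T8", "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4",
             "P8", "POz", "O1", "Oz", "O2"),
    `62` = NULL # all 10-10 positions below except FCz
  )
  if (!as.character(nChannels) %in% names(sets))
    stop("unsupported montage size ", nChannels,
         "; supported sizes: 19, 32, 62")
  dict <- .montageDictionary()
  labels <- sets[[as.character(nChannels)]]
  if (is.null(labels)) labels <- setdiff(rownames(dict), "FCz")
  electrodeMontage(labels, dict[labels, , drop = FALSE])
}

# full 10-10 position dictionary (63 labels including FCz)
.montageDictionary <- function() {
  sph <- function(polarDeg, azDeg) {
    th <- polarDeg * pi / 180
    ph <- azDeg * pi / 180
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  pos <- list()
  # circumferential ring, polar 72 deg; azimuth 0 = nasion, positive left
  ringAz <- c(Fpz = 0, Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
              TP7 = 108, P7 = 126, PO7 = 144, O1 = 162, Oz = 180)
  mirror <- c(Fp1 = "Fp2", AF7 = "AF8", F7 = "F8", FT7 = "FT8", T7 = "T8",
              TP7 = "TP8", P7 = "P8", PO7 = "PO8", O1 = "O2")
  for (nm in names(ringAz)) pos[[nm]] <- sph(72, ringAz[[nm]])
  for (nm in names(mirror)) pos[[mirror[[nm]]]] <- sph(72, -ringAz[[nm]])
  # midline arc
  midFront <- c(AFz = 54, Fz = 36, FCz = 18, Cz = 0)
  midBack <- c(CPz = 18, Pz = 36, POz = 54)
  for (nm in names(midFront)) pos[[nm]] <- sph(midFront[[nm]], 0)
  for (nm in names(midBack)) pos[[nm]] <- sph(midBack[[nm]], 180)
  # coronal rows: equal-arc subdivision midline -> ring, left side,
  # right side mirrored in y
  rows <- list(
    list(mid = "AFz", ring = "AF7", lab = c(AF3 = 0.5)),
    list(mid = "Fz", ring = "F7", lab = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    list(mid = "FCz", ring = "FT7",
         lab = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    list(mid = "Cz", ring = "T7", lab = c(C1 = 0.25, C3 = 0.5, C5 = 0.75)),
    list(mid = "CPz", ring = "TP7",
         lab = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    list(mid = "Pz", ring = "P7", lab = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    list(mid = "POz", ring = "PO7", lab = c(PO3 = 0.5))
  )
  for (rw in rows) {
    for (nm in names(rw$lab)) {
      p <- .slerp(pos[[rw$mid]], pos[[rw$ring]], rw$lab[[nm]])
      pos[[nm]] <- p
      num <- as.integer(sub("^[A-Za-z]+", "", nm))
      pos[[paste0(sub("[0-9]+$", "", nm), num + 1L)]] <- p * c(1, -1, 1)
    }
  }
  # lower temporal pair on the equator
  pos[["FT9"]] <- sph(90, 72)
  pos[["FT10"]] <- sph(90, -72)
  do.call(rbind, pos)
}
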
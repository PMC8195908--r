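#' Construct an electrode montage
#'
#' Builds an [ElectrodeMontage-class] from labels and head-centered 3-D
#' coordinates. Coordinates are assumed head-centered (+z vertex, +x
#' nasion); each position is projected to unit norm. Optionally the
#' centroid can be subtracted first for montages whose coordinates are
#' not centered on the head.
#'
#' @param labels character vector of unique channel labels.
#' @param positions numeric n x 3 matrix of electrode coordinates.
#' @param center if `TRUE`, subtract the centroid of the positions before
#'   normalizing. Default `FALSE` (input assumed head-centered).
#'
#' @return An `ElectrodeMontage`.
#'
#' @examples
#' mon <- electrodeMontage(c("Cz", "Fz", "Pz"),
#'   rbind(c(0, 0, 1), c(0.59, 0, 0.81), c(-0.59, 0, 0.81)))
#' mon
#'
#' @export
electrodeMontage <- function(labels, positions, center = FALSE) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (center) positions <- sweep(positions, 2, colMeans(positions))
  positions <- .unitRows(positions)
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  new("ElectrodeMontage", labels = as.character(labels),
      positions = positions)
}

#' @rdname electrodeMontage
#' @param x,object an `ElectrodeMontage`.
#' @export
setMethod("show", "ElectrodeMontage", function(object) {
  cat(sprintf("ElectrodeMontage with %d channels\n", length(object@labels)))
  lab <- object@labels
  if (length(lab) > 8) lab <- c(lab[1:8], "...")
  cat("  ", paste(lab, collapse = " "), "\n")
})

#' @rdname electrodeMontage
#' @export
setMethod("channelLabels", "ElectrodeMontage", function(x) x@labels)

#' @rdname electrodeMontage
#' @export
setMethod("electrodePositions", "ElectrodeMontage",
          function(x) x@positions)

#' @rdname electrodeMontage
#' @export
setMethod("nChannels", "ElectrodeMontage", function(x) length(x@labels))

#' Angular distances between electrodes
#'
#' Great-circle (angular) distance in radians between all pairs of
#' electrodes of a montage, the metric used for neighbor selection and
#' adjacent bad-channel growth.
#'
#' @param montage an [ElectrodeMontage-class].
#' @return symmetric n x n matrix of angles in radians, with channel
#'   labels as dimnames.
#'
#' @export
angularDistances <- function(montage) {
  p <- montage@positions
  d <- acos(.clampCos(tcrossprod(p)))
  dimnames(d) <- list(montage@labels, montage@labels)
  d
}

#' Read / write a montage file
#'
#' Plain-text electrode format: one electrode per line, `label x y z`,
#' separated by whitespace; `#` starts a comment. The writer emits 9
#' significant digits.
#'
#' @param file path of the montage file.
#' @param center passed to [electrodeMontage()].
#' @return `readMontage` returns an [ElectrodeMontage-class];
#'   `writeMontage` returns `file` invisibly.
#'
#' @examples
#' f <- tempfile(fileext = ".sfp")
#' writeMontage(standardMontage(19), f)
#' mon <- readMontage(f)
#' nChannels(mon)
#'
#' @export
readMontage <- function(file, center = FALSE) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no electrode entries in '", file, "'")
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) != 4L
  if (any(bad))
    stop("malformed montage line(s): ",
         paste(which(bad), collapse = ", "))
  labels <- vapply(parts, `[[`, "", 1L)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("non-numeric coordinates in '", file, "'")
  electrodeMontage(labels, xyz, center = center)
}

#' @rdname readMontage
#' @param montage montage to write.
#' @export
writeMontage <- function(montage, file) {
  p <- montage@positions
  lines <- sprintf("%s %.9g %.9g %.9g", montage@labels,
                   p[, 1], p[, 2], p[, 3])
  writeLines(lines, file)
  invisible(file)
}

# indices of the m nearest good channels to channel i, by angular
# distance, ties broken by channel-label lexicographic order
.nearestGood <- function(dist, labels, i, goodIdx, m) {
  d <- dist[i, goodIdx]
  goodIdx[order(d, labels[goodIdx])[seq_len(m)]]
}
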
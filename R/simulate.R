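#' Forward-simulate scalp EEG from dipolar sources
#'
#' Generates synthetic multichannel EEG through the same physics as the
#' inverse model — random current dipoles inside the brain compartment
#' projected through the three-sphere lead field — but with a source set
#' that is deliberately not the equivalent-source grid, so benchmark
#' recoveries are not inverse crimes. Three signal models are available:
#'
#' * `"bandlimited"`: 1-30 Hz Gaussian noise per source (resting-state
#'   like; zero-phase Butterworth filtering).
#' * `"alpha"`: 10 Hz oscillations with random phase and amplitude per
#'   source.
#' * `"erp"`: epoched event-related waveforms, a negative deflection at
#'   175 ms and a dominant positive deflection at 350 ms post-stimulus
#'   (P300-like), over a -200 to 800 ms window; epochs are concatenated
#'   along time and the epoch length is stored in the metadata.
#'
#' Clean sensor signals are scaled to an RMS of `targetRmsUv` microvolts,
#' then white sensor noise is added independently per channel, either
#' with an explicit `sensorNoiseSd` or as `snr` (clean RMS over noise
#' SD).
#'
#' @param model a [ConcentricSphereHeadModel-class].
#' @param montage an [ElectrodeMontage-class].
#' @param nSources number of dipoles (default 10).
#' @param sourceRadiusMax maximum source eccentricity (default 0.8; must
#'   be below the brain radius).
#' @param signal one of `"bandlimited"`, `"alpha"`, `"erp"`.
#' @param sfreq sampling rate in Hz (default 500).
#' @param duration seconds of continuous data (ignored for `"erp"`).
#' @param nEpochs number of epochs for `"erp"` (default 30).
#' @param epochWindow start/end of the epoch in seconds relative to
#'   stimulus (default `c(-0.2, 0.8)`).
#' @param sensorNoiseSd sensor noise SD in microvolts (default 0).
#' @param snr if non-`NULL`, overrides `sensorNoiseSd` with
#'   clean-RMS / `snr`.
#' @param targetRmsUv RMS of the clean sensor signals in microvolts
#'   (default 10).
#' @param reference reference of the returned recording (`"average"`,
#'   `"point"` or `"infinity"`).
#' @param refChannel reference electrode for `reference = "point"`.
#' @param seed optional integer seed (`set.seed` is called when given).
#' @param sourceGrid optional [SourceGrid-class]; when `inverseCrime =
#'   TRUE` sources are drawn from its nodes (with its orientations)
#'   instead of random positions, for exact-recovery tests.
#' @param inverseCrime place sources exactly on grid nodes (default
#'   `FALSE`).
#'
#' @return list with elements `recording` (the referenced
#'   [EEGRecording-class]), `groundTruth` (the same data referenced to
#'   infinity), and `sources` (list of `positions`, `orientations`,
#'   `timecourses`).
#'
#' @export
simulateEEG <- function(model, montage, nSources = 10,
                        sourceRadiusMax = 0.8,
                        signal = c("bandlimited", "alpha", "erp"),
                        sfreq = 500, duration = 2, nEpochs = 30,
                        epochWindow = c(-0.2, 0.8),
                        sensorNoiseSd = 0, snr = NULL, targetRmsUv = 10,
                        reference = c("average", "point", "infinity"),
                        refChannel = NULL, seed = NULL,
                        sourceGrid = NULL, inverseCrime = FALSE) {
  signal <- match.arg(signal)
  reference <- match.arg(reference)
  stopifnot(is(model, "ConcentricSphereHeadModel"),
            is(montage, "ElectrodeMontage"))
  if (sourceRadiusMax >= model@rBrain)
    stop("sourceRadiusMax must be inside the brain compartment")
  if (sensorNoiseSd < 0) stop("sensorNoiseSd must be non-negative")
  if (nSources < 1 && (is.null(snr) && sensorNoiseSd == 0))
    stop("zero sources with zero noise would be an all-zero recording")
  if (!is.null(seed)) set.seed(seed)
  nSources <- as.integer(nSources)
  if (inverseCrime) {
    if (is.null(sourceGrid))
      stop("inverseCrime placement needs a sourceGrid")
    idx <- sample.int(nSources(sourceGrid), nSources)
    pos <- sourceGrid@positions[idx, , drop = FALSE]
    ori <- sourceGrid@orientations[idx, , drop = FALSE]
  } else if (nSources > 0L) {
    dir <- .unitRows(matrix(stats::rnorm(nSources * 3), nSources))
    rad <- sourceRadiusMax * stats::runif(nSources)^(1 / 3)
    pos <- dir * rad
    ori <- .unitRows(matrix(stats::rnorm(nSources * 3), nSources))
  } else {
    pos <- ori <- matrix(0, 0, 3)
  }
  epochLength <- NULL
  if (signal == "erp") {
    epochLength <- as.integer(round((epochWindow[2] - epochWindow[1]) * sfreq))
    nT <- epochLength * as.integer(nEpochs)
  } else {
    nT <- as.integer(round(duration * sfreq))
  }
  if (nT < 2L) stop("the recording must have at least 2 time points")
  s <- .sourceTimecourses(signal, nSources, nT, sfreq, epochWindow,
                          epochLength)
  if (nSources > 0L) {
    gains <- .dipoleGains(model, montage@positions * model@rScalp, pos, ori)
    vInf <- gains %*% s
    rms <- sqrt(mean(vInf^2))
    if (rms > 0) {
      vInf <- vInf * (targetRmsUv / rms)
      s <- s * (targetRmsUv / rms)
    }
  } else {
    vInf <- matrix(0, nChannels(montage), nT)
  }
  if (!is.null(snr)) {
    if (snr <= 0) stop("snr must be positive")
    sensorNoiseSd <- sqrt(mean(vInf^2)) / snr
  }
  if (sensorNoiseSd > 0)
    vInf <- vInf + matrix(stats::rnorm(length(vInf), sd = sensorNoiseSd),
                          nrow(vInf))
  rownames(vInf) <- montage@labels
  truth <- eegRecording(vInf, sfreq = sfreq, reference = "infinity")
  md <- S4Vectors::metadata(truth)
  md$epochLength <- epochLength
  md$epochWindow <- if (signal == "erp") epochWindow else NULL
  S4Vectors::metadata(truth) <- md
  recording <- switch(reference,
    infinity = truth,
    average = rereference(truth, "average"),
    point = rereference(truth, "point", refChannel = refChannel))
  list(recording = recording, groundTruth = truth,
       sources = list(positions = pos, orientations = ori,
                      timecourses = s))
}

# per-source time courses, nSources x nT
.sourceTimecourses <- function(signal, nSources, nT, sfreq, epochWindow,
                               epochLength) {
  if (nSources == 0L) return(matrix(0, 0, nT))
  if (signal == "bandlimited") {
    bf <- signal::butter(4, c(1, 30) / (sfreq / 2), type = "pass")
    s <- matrix(stats::rnorm(nSources * nT), nSources)
    return(t(apply(s, 1, function(x) signal::filtfilt(bf, x))))
  }
  if (signal == "alpha") {
    t <- seq_len(nT) / sfreq
    amp <- stats::runif(nSources, 0.5, 1.5)
    phase <- stats::runif(nSources, 0, 2 * pi)
    return(t(vapply(seq_len(nSources),
                    function(i) amp[i] * sin(2 * pi * 10 * t + phase[i]),
                    numeric(nT))))
  }
  # erp: fixed biphasic template, random per-source and per-epoch gains
  tEpoch <- epochWindow[1] + (seq_len(epochLength) - 0.5) / sfreq
  template <- -1.0 * exp(-(tEpoch - 0.175)^2 / (2 * 0.030^2)) +
    2.0 * exp(-(tEpoch - 0.350)^2 / (2 * 0.060^2))
  nEpochs <- nT %/% epochLength
  s <- matrix(0, nSources, nT)
  srcGain <- stats::runif(nSources, 0.5, 1.5) *
    sample(c(-1, 1), nSources, replace = TRUE)
  for (e in seq_len(nEpochs)) {
    epochGain <- stats::runif(nSources, 0.8, 1.2)
    cols <- (e - 1L) * epochLength + seq_len(epochLength)
    s[, cols] <- (srcGain * epochGain) %o% template
  }
  s
}

#' Write / read an offline fixture bundle
#'
#' Materializes everything needed to exercise the toolkit without
#' downloads into a directory: the montage file (`montage.sfp`), a
#' resting-state-like recording (`resting.rds`), an ERP-like epoched
#' recording (`erp.rds`), the generating configuration (`config.yaml`)
#' and a manifest with the seed and file checksums (`manifest.json`).
#' Recordings are stored in the binary container form, so reading the
#' bundle back reproduces the matrices bitwise; two bundles written with
#' the same seed are identical.
#'
#' @param dir output directory (created if needed).
#' @param montageSize montage fixture size (default 62).
#' @param duration resting-state duration in seconds (default 60).
#' @param nEpochs number of ERP epochs (default 30).
#' @param snr signal-to-noise ratio of both recordings (default 5).
#' @param seed integer seed (default 1).
#' @param model head model (default [concentricSphereHeadModel()]).
#'
#' @return `writeFixtureBundle` returns the file paths invisibly;
#'   `readFixtureBundle` returns a list with `montage`, `resting`, `erp`,
#'   `config` and `manifest`.
#'
#' @export
writeFixtureBundle <- function(dir, montageSize = 62, duration = 60,
                               nEpochs = 30, snr = 5, seed = 1L,
                               model = concentricSphereHeadModel()) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  montage <- standardMontage(montageSize)
  config <- list(montageSize = as.integer(montageSize),
                 duration = duration, nEpochs = as.integer(nEpochs),
                 snr = snr, seed = as.integer(seed), sfreq = 500,
                 epochWindow = c(-0.2, 0.8), nSources = 10L,
                 sourceRadiusMax = 0.8, reference = "average")
  paths <- c(montage = file.path(dir, "montage.sfp"),
             resting = file.path(dir, "resting.rds"),
             erp = file.path(dir, "erp.rds"),
             config = file.path(dir, "config.yaml"),
             manifest = file.path(dir, "manifest.json"))
  wrap <- function(expr, path) tryCatch(expr, error = function(e)
    stop("while writing '", path, "': ", conditionMessage(e),
         call. = FALSE))
  wrap(writeMontage(montage, paths[["montage"]]), paths[["montage"]])
  rest <- simulateEEG(model, montage, nSources = config$nSources,
                      sourceRadiusMax = config$sourceRadiusMax,
                      signal = "bandlimited", sfreq = config$sfreq,
                      duration = duration, snr = snr,
                      reference = "average", seed = seed)
  wrap(writeEEGRecording(rest$recording, paths[["resting"]]),
       paths[["resting"]])
  erp <- simulateEEG(model, montage, nSources = config$nSources,
                     sourceRadiusMax = config$sourceRadiusMax,
                     signal = "erp", sfreq = config$sfreq,
                     nEpochs = nEpochs, epochWindow = config$epochWindow,
                     snr = snr, reference = "average", seed = seed + 1L)
  wrap(writeEEGRecording(erp$recording, paths[["erp"]]), paths[["erp"]])
  wrap(yaml::write_yaml(config, paths[["config"]]), paths[["config"]])
  checksums <- as.list(tools::md5sum(paths[c("montage", "resting", "erp",
                                             "config")]))
  names(checksums) <- basename(names(checksums))
  manifest <- list(seed = as.integer(seed), files = checksums)
  wrap(jsonlite::write_json(manifest, paths[["manifest"]],
                            auto_unbox = TRUE, pretty = TRUE),
       paths[["manifest"]])
  invisible(paths)
}

#' @rdname writeFixtureBundle
#' @export
readFixtureBundle <- function(dir) {
  need <- c("montage.sfp", "resting.rds", "erp.rds", "config.yaml",
            "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop("incomplete bundle in '", dir, "', missing: ",
         paste(missing, collapse = ", "))
  list(montage = readMontage(file.path(dir, "montage.sfp")),
       resting = readEEGRecording(file.path(dir, "resting.rds")),
       erp = readEEGRecording(file.path(dir, "erp.rds")),
       config = yaml::read_yaml(file.path(dir, "config.yaml")),
       manifest = jsonlite::read_json(file.path(dir, "manifest.json")))
}

#' Load a configuration file
#'
#' Reads a YAML (or flat `key: value`) configuration and merges it over
#' the package defaults for the head model, source grid, interpolation
#' and simulation parameters. Unknown keys are kept, so callers can
#' carry their own settings alongside.
#'
#' @param file path of a YAML file, or `NULL` for pure defaults.
#' @return named list of configuration values.
#'
#' @export
resitConfig <- function(file = NULL) {
  defaults <- list(
    rBrain = 0.87, rSkull = 0.92, rScalp = 1.0,
    sigmaBrain = 1.0, sigmaSkull = 0.0125, sigmaScalp = 1.0,
    nTermsMax = 300L, seriesRtol = 1e-12,
    nCap = 2600L, nPlane = 400L, capRadius = 0.869, planeZ = -0.076,
    orderM = 4, nLegendre = 50L, mNeighbors = 4L, pinvRtol = 1e-8,
    sfreq = 500, snr = 5, nSources = 10L, sourceRadiusMax = 0.8)
  if (is.null(file)) return(defaults)
  user <- yaml::read_yaml(file)
  utils::modifyList(defaults, user)
}
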
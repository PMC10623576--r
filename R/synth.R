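#' Construct a spectrum
#'
#' The primary instrument record: paired m/z and intensity arrays with an
#' acquisition time and an optional SIM-window tag.
#'
#' @param mz Strictly increasing numeric vector of m/z values (Th).
#' @param intensity Non-negative intensities, same length as `mz`.
#' @param time Acquisition time in seconds.
#' @param window_id SIM-window tag (character) or `NA`.
#' @return A list of class `sesi_spectrum`.
#' @export
new_spectrum <- function(mz, intensity, time = NA_real_,
                         window_id = NA_character_) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have the same length", call. = FALSE)
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("mz must be strictly increasing", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(list(mz = mz, intensity = intensity, time = time,
                 window_id = window_id),
            class = "sesi_spectrum")
}

# mass-resolution model: FWHM = m/z / R, Gaussian sigma from FWHM
mz_sigma <- function(mz, resolution) {
  (mz / resolution) / (2 * sqrt(2 * log(2)))
}

# profile m/z grid for one SIM window: a neighbourhood of `span_sigmas`
# Gaussian widths around every expected peak, sampled at sigma/points_per_sigma
window_grid <- function(window, peak_mz, resolution = 140000,
                        span_sigmas = 12, points_per_sigma = 4) {
  peak_mz <- peak_mz[peak_mz > window$lower & peak_mz < window$upper]
  if (length(peak_mz) == 0L) {
    # empty window: coarse baseline-only grid
    return(seq(window$lower, window$upper, length.out = 50L))
  }
  grids <- lapply(sort(peak_mz), function(m) {
    s <- mz_sigma(m, resolution)
    seq(m - span_sigmas * s, m + span_sigmas * s, by = s / points_per_sigma)
  })
  g <- sort(unique(unlist(grids)))
  g[g > window$lower & g < window$upper]
}

#' Synthesize one profile-mode scan
#'
#' Places a Gaussian profile peak at each compound's m/z on the window's m/z
#' grid, with the apex height equal to the (noise-perturbed) true intensity,
#' and adds Gaussian baseline noise. The peak width follows the resolution
#' model FWHM = m/z / R. Negative values arising from baseline noise are
#' clipped at zero, as in real profile data.
#'
#' @param peak_mz m/z positions of the peaks (Th).
#' @param heights True apex intensities (a.u.), same length as `peak_mz`.
#' @param grid m/z grid of the scan (from the window schedule).
#' @param resolution Resolving power of the FWHM model (default 140000).
#' @param noise List with `baseline_sd` (additive Gaussian baseline, a.u.)
#'   and `cv` (signal-proportional relative noise); draws come from the
#'   current RNG state.
#' @param time,window_id Passed to [new_spectrum()].
#' @return A `sesi_spectrum`.
#' @export
synthesize_scan <- function(peak_mz, heights, grid, resolution = 140000,
                            noise = list(baseline_sd = 0, cv = 0),
                            time = NA_real_, window_id = NA_character_) {
  stopifnot(length(peak_mz) == length(heights))
  signal <- numeric(length(grid))
  if (length(peak_mz)) {
    h <- heights
    if (noise$cv > 0)
      h <- h * (1 + noise$cv * stats::rnorm(length(h)))
    h <- pmax(h, 0)
    for (i in seq_along(peak_mz)) {
      s <- mz_sigma(peak_mz[i], resolution)
      sel <- abs(grid - peak_mz[i]) < 8 * s
      signal[sel] <- signal[sel] +
        h[i] * exp(-((grid[sel] - peak_mz[i])^2) / (2 * s^2))
    }
  }
  if (noise$baseline_sd > 0)
    signal <- signal + stats::rnorm(length(grid), 0, noise$baseline_sd)
  new_spectrum(grid, pmax(signal, 0), time = time, window_id = window_id)
}

window_label <- function(lower, upper) sprintf("%.4f-%.4f", lower, upper)

# apex intensity matrix [scan time x compound] for one concentration level.
# The delivery of each compound follows its pulsed washout profile; the
# competitive suppression load is evaluated at the level's plateau
# concentrations (the steady mixing-chamber composition during a pulse), so
# the suppression factor is constant within a level. Tracking the load
# scan-by-scan through the washout would make the suppressed analyte surge
# between pulses (the suppressor's load releases faster than the analyte
# washes out), a transient the measured pulse plateaus never see.
level_intensity_matrix <- function(scenario, level_ppm, t_grid) {
  comp <- scenario$compounds
  n <- nrow(comp)
  nominal <- ifelse(comp$role == "suppressor", level_ppm,
                    ifelse(comp$role == "constant", comp$ppm, 0))
  ppm <- sapply(seq_len(n), function(i)
    delivery_profile(scenario$program, nominal[i], t_grid))
  ppm <- matrix(ppm, nrow = length(t_grid))
  params <- scenario$params
  c50 <- c50_for(params, scenario$condition)
  # basicity weight matrix, zero diagonal; channels carry no gas-phase load
  gb <- comp$gas_phase_basicity
  W <- exp(outer(gb, gb, function(a, b) (b - a) / params$beta))
  diag(W) <- 0
  W[, comp$role == "channel"] <- 0
  load <- as.numeric(W %*% nominal) / c50
  F_vec <- (1 + load)^(-params$gamma)
  s <- scenario$response_coefficient
  if (scenario$condition == "humid") s <- s / params$humid_sensitivity_ratio
  intens <- s * ppm * matrix(F_vec, nrow = length(t_grid), ncol = n,
                             byrow = TRUE)
  # channels ride on their parent's intensity
  for (i in which(comp$role == "channel")) {
    p <- match(comp$parent[i], comp$name)
    intens[, i] <- comp$channel_fraction[i] * intens[, p]
  }
  colnames(intens) <- comp$name
  intens
}

# ground-truth record for one level: nominal ppm, steady-state suppression
# factor and steady apex intensity per compound
level_truth <- function(scenario, level_ppm, level_index) {
  comp <- scenario$compounds
  nominal <- ifelse(comp$role == "suppressor", level_ppm,
                    ifelse(comp$role == "constant", comp$ppm, 0))
  params <- scenario$params
  gas <- comp$role != "channel"
  f <- vapply(seq_len(nrow(comp)), function(i) {
    i_ref <- if (comp$role[i] == "channel") match(comp$parent[i], comp$name)
             else i
    j <- which(gas & seq_len(nrow(comp)) != i_ref)
    suppression_factor(comp$gas_phase_basicity[i_ref],
                       comp$gas_phase_basicity[j], nominal[j],
                       params, scenario$condition)
  }, numeric(1))
  s <- scenario$response_coefficient
  if (scenario$condition == "humid") s <- s / params$humid_sensitivity_ratio
  intensity <- ifelse(comp$role == "channel",
                      comp$channel_fraction *
                        s * nominal[match(comp$parent, comp$name)] *
                        f,
                      s * nominal * f)
  data.frame(level = level_index, suppressor_ppm = level_ppm,
             compound = comp$name, mz = comp$mz, role = comp$role,
             delivered_ppm = ifelse(comp$role == "channel", NA_real_,
                                    nominal),
             suppression_factor = f,
             steady_intensity = intensity,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic SESI-MS dataset from a scenario
#'
#' Simulates every concentration level of the scenario: pulsed delivery of
#' each gas-phase compound with mixing-chamber washout, time-resolved
#' competitive suppression, round-robin cycling of the SIM windows (one
#' window per scan), Gaussian profile peaks and noise. The ground truth
#' (delivered ppm, steady-state suppression factor and steady apex intensity
#' per compound and level) is returned alongside the scans. Output is fully
#' determined by the scenario (including its `seed`).
#'
#' @param scenario A scenario from one of the `scenario_*()` constructors or
#'   [read_scenario_yaml()].
#' @return A list of class `sesi_dataset` with elements `levels` (per level:
#'   `suppressor_ppm`, `scans`), `truth` (data frame) and `scenario`.
#' @seealso [write_dataset_mzml()] to serialize to mzML, [run_pipeline()] for
#'   end-to-end processing.
#' @export
generate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "sesi_scenario"))
  comp <- scenario$compounds
  windows <- scenario$windows
  # every delivered compound must fall inside some SIM window
  covered <- vapply(comp$mz, function(m)
    any(m > windows$lower & m < windows$upper), logical(1))
  if (!all(covered))
    stop("compound m/z outside all SIM windows: ",
         paste(comp$name[!covered], collapse = ", "), call. = FALSE)
  duration <- program_duration(scenario$program)
  t_grid <- seq(0, duration - scenario$scan_period / 2,
                by = scenario$scan_period)
  nw <- nrow(windows)
  win_idx <- ((seq_along(t_grid) - 1L) %% nw) + 1L
  grids <- lapply(seq_len(nw), function(w)
    window_grid(windows[w, ], comp$mz, scenario$resolution))
  levels_out <- vector("list", length(scenario$levels))
  truth <- list()
  for (li in seq_along(scenario$levels)) {
    lev <- scenario$levels[li]
    scans <- withr::with_seed(scenario$seed + li, {
      intens <- level_intensity_matrix(scenario, lev, t_grid)
      lapply(seq_along(t_grid), function(si) {
        w <- win_idx[si]
        inwin <- comp$mz > windows$lower[w] & comp$mz < windows$upper[w]
        synthesize_scan(comp$mz[inwin], intens[si, inwin], grids[[w]],
                        resolution = scenario$resolution,
                        noise = scenario$noise, time = t_grid[si],
                        window_id = window_label(windows$lower[w],
                                                 windows$upper[w]))
      })
    })
    levels_out[[li]] <- list(suppressor_ppm = lev, scans = scans)
    truth[[li]] <- level_truth(scenario, lev, li)
  }
  structure(list(levels = levels_out, truth = do.call(rbind, truth),
                 scenario = scenario),
            class = "sesi_dataset")
}

#' Write a synthetic dataset to mzML
#'
#' One mzML 1.1 file per concentration level (profile mode, MS1, SIM-window
#' bounds stored in the scan-window limits), plus the ground-truth table as
#' TSV and the scenario as YAML.
#'
#' @param dataset A `sesi_dataset` from [generate_scenario()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the written mzML files.
#' @export
write_dataset_mzml <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sesi_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(dataset$levels))
  for (li in seq_along(dataset$levels)) {
    lev <- dataset$levels[[li]]
    paths[li] <- file.path(dir, sprintf("level_%02d.mzML", li))
    write_scans_mzml(lev$scans, paths[li])
  }
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_scenario_yaml(dataset$scenario, file.path(dir, "scenario.yaml"))
  invisible(paths)
}

#' Write a list of spectra to one mzML file
#'
#' @param scans List of `sesi_spectrum` objects.
#' @param path Output file path.
#' @export
write_scans_mzml <- function(scans, path) {
  if (length(scans) == 0L) stop("no scans to write", call. = FALSE)
  pk <- lapply(scans, function(s) cbind(s$mz, s$intensity))
  win <- vapply(scans, function(s) s$window_id, character(1))
  bounds <- t(vapply(strsplit(win, "-"),
                     function(x) as.numeric(x), numeric(2)))
  n <- length(scans)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = vapply(pk, nrow, integer(1)),
    totIonCurrent = vapply(pk, function(p) sum(p[, 2]), numeric(1)),
    retentionTime = vapply(scans, function(s) s$time, numeric(1)),
    basePeakMZ = vapply(pk, function(p) p[which.max(p[, 2]), 1], numeric(1)),
    basePeakIntensity = vapply(pk, function(p) max(p[, 2]), numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(pk, function(p) min(p[, 1]), numeric(1)),
    highMZ = vapply(pk, function(p) max(p[, 1]), numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = paste("SIM", win),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = FALSE, ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = rowMeans(bounds),
    isolationWindowLowerOffset = (bounds[, 2] - bounds[, 1]) / 2,
    isolationWindowUpperOffset = (bounds[, 2] - bounds[, 1]) / 2,
    scanWindowLowerLimit = bounds[, 1], scanWindowUpperLimit = bounds[, 2],
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(pk, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read scans from an mzML file
#'
#' Reads every MS1 scan and tags it with its SIM window, taken from the scan
#' window limits in the header (falling back to the observed m/z range when
#' absent).
#'
#' @param path mzML file path.
#' @return List of `sesi_spectrum` objects.
#' @export
read_mzml_scans <- function(path) {
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h)
  pks <- mzR::peaks(h)
  if (is.matrix(pks)) pks <- list(pks)
  lo <- hdr$scanWindowLowerLimit
  hi <- hdr$scanWindowUpperLimit
  bad <- is.na(lo) | is.na(hi)
  lo[bad] <- hdr$lowMZ[bad]
  hi[bad] <- hdr$highMZ[bad]
  lapply(seq_len(nrow(hdr)), function(i) {
    p <- pks[[i]]
    new_spectrum(p[, 1], pmax(p[, 2], 0), time = hdr$retentionTime[i],
                 window_id = window_label(lo[i], hi[i]))
  })
}

#' Read a serialized dataset back from disk
#'
#' Counterpart of [write_dataset_mzml()]: reads the per-level mzML files,
#' the truth table and the scenario YAML back into a `sesi_dataset`.
#'
#' @param dir Directory written by [write_dataset_mzml()].
#' @return A `sesi_dataset`.
#' @export
read_dataset_mzml <- function(dir) {
  scenario <- read_scenario_yaml(file.path(dir, "scenario.yaml"))
  truth <- utils::read.delim(file.path(dir, "truth.tsv"),
                             stringsAsFactors = FALSE)
  files <- sort(list.files(dir, pattern = "^level_\\d+\\.mzML$",
                           full.names = TRUE))
  levels_out <- lapply(seq_along(files), function(li) {
    list(suppressor_ppm = scenario$levels[li],
         scans = read_mzml_scans(files[li]))
  })
  structure(list(levels = levels_out, truth = truth, scenario = scenario),
            class = "sesi_dataset")
}
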
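#' Phantom specification for synthetic DCE-MRI cohorts
#'
#' Defines the study conditions for the synthetic generator: grid geometry,
#' post-contrast phase timing, per-class voxel kinetics and spatial
#' heterogeneity, acquisition noise, and cohort composition.
#'
#' Each in-lesion voxel follows a piecewise-linear normalized enhancement
#' curve \deqn{s(t) = 1 + w \min(t, t_p) + m \max(0, t - t_p)} with
#' voxel-level wash-in rate `w` (1/s) drawn from a spatially correlated
#' class-specific field, a non-positive late slope `m` (washout/plateau), and
#' class time-to-peak `t_p`. Because `t_p` defaults to one of the first three
#' sampled phase times, the wash-in rate map recovers `w` exactly on
#' noise-free phantoms and the area map has a closed form, giving exact
#' oracles for the kinetic mapping stage.
#'
#' The default class settings make the three subtypes differ in the *timing*
#' and *spread* of enhancement while keeping the peak enhancement amplitude
#' (about 1.4 above baseline) identical across classes: early fast wash-in
#' with strong washout and fine-grained heterogeneity for TNBC, late slow
#' wash-in with mild washout and smooth heterogeneity for HR+/HER2-, HER2+
#' in between. A single post-contrast phase therefore carries much weaker
#' class information than the kinetic parameter maps.
#'
#' @param nPerClass integer(3), patients per subtype in
#'   [subtypeLevels()] order. The default mirrors a 299:235:142 cohort
#'   imbalance scaled by 1/20.
#' @param gridShape integer(3), voxels per axis.
#' @param voxelSpacing numeric(3), mm per axis.
#' @param phaseTimes numeric, post-contrast acquisition times (s). Five
#'   phases at 60..300 s by default; use `phaseTimes4()` for a 4-phase
#'   protocol.
#' @param classKinetics named list (one entry per subtype) of lists with
#'   `washinMean`, `washinSD` (1/s), `slopeMean`, `slopeSD` (1/s), `tPeak`
#'   (s) and `corrLength` (voxels, spatial correlation of the kinetic
#'   fields).
#' @param lesionRadii numeric(2), min/max ellipsoid semi-axis (voxels).
#' @param noiseSD additive acquisition noise (raw intensity units; the
#'   pre-contrast baseline is about 100).
#' @param baseline mean pre-contrast intensity.
#' @param seed RNG seed for cohort generation.
#'
#' @return a `PhantomSpec` list.
#' @export
phantomSpec <- function(nPerClass = c(15L, 12L, 7L),
                        gridShape = c(32L, 32L, 32L),
                        voxelSpacing = c(1, 1, 1),
                        phaseTimes = c(60, 120, 180, 240, 300),
                        classKinetics = defaultClassKinetics(),
                        lesionRadii = c(4.5, 7.5),
                        noiseSD = 1,
                        baseline = 100,
                        seed = 1L) {
  if (length(phaseTimes) < 3L)
    stop("configuration error: at least 3 post-contrast phases are required")
  if (any(phaseTimes <= 0) || any(diff(phaseTimes) <= 0))
    stop("configuration error: phase times must be strictly increasing and positive")
  if (any(gridShape <= 0) || any(voxelSpacing <= 0))
    stop("configuration error: grid shape and spacing must be positive")
  if (noiseSD < 0) stop("configuration error: noiseSD must be >= 0")
  if (length(nPerClass) != 3L || any(nPerClass < 0))
    stop("configuration error: nPerClass must be three non-negative counts")
  stopifnot(identical(sort(names(classKinetics)), sort(subtypeLevels())))
  structure(
    list(nPerClass = as.integer(nPerClass), gridShape = as.integer(gridShape),
         voxelSpacing = voxelSpacing, phaseTimes = phaseTimes,
         classKinetics = classKinetics, lesionRadii = lesionRadii,
         noiseSD = noiseSD, baseline = baseline, seed = as.integer(seed)),
    class = "PhantomSpec"
  )
}

#' @describeIn phantomSpec default per-class kinetic settings (see Details).
#' @export
defaultClassKinetics <- function() {
  list(
    "HR+/HER2-" = list(washinMean = 1.4 / 180, washinSD = 0.2 * 1.4 / 180,
                       slopeMean = -5e-4, slopeSD = 1e-4,
                       tPeak = 180, corrLength = 1.8),
    "HER2+" = list(washinMean = 1.4 / 120, washinSD = 0.2 * 1.4 / 120,
                   slopeMean = -1e-3, slopeSD = 2e-4,
                   tPeak = 120, corrLength = 1.8),
    "TNBC" = list(washinMean = 1.4 / 60, washinSD = 0.2 * 1.4 / 60,
                  slopeMean = -2e-3, slopeSD = 4e-4,
                  tPeak = 60, corrLength = 1.8)
  )
}

#' @describeIn phantomSpec 4-phase protocol preset (90..360 s).
#' @export
phaseTimes4 <- function() c(90, 180, 270, 360)

#' @describeIn phantomSpec kinetics preset in which the classes share their
#'   wash-in behavior (identical time-to-peak, near-identical wash-in rate)
#'   and differ almost exclusively in washout slope, so the overall-uptake
#'   (Area) signal dominates the wash-in (WIR) signal.
#' @export
areaDominantKinetics <- function() {
  w <- 1.4 / 180
  mk <- function(slopeMean, slopeSD) list(
    washinMean = w, washinSD = 0.02 * w,
    slopeMean = slopeMean, slopeSD = slopeSD,
    tPeak = 180, corrLength = 1.8)
  # identical, nearly homogeneous wash-in with the peak at the third sampled
  # phase: the peak search never sees the washout, so the WIR map is
  # class-blind by construction, while washout level and heterogeneity
  # (acting on the last two phases only) separate the classes through the
  # Area map
  list("HR+/HER2-" = mk(-2e-4, 1e-4),
       "HER2+" = mk(-2e-3, 1.2e-3),
       "TNBC" = mk(-5e-3, 3e-3))
}

#' Generate one synthetic DCE patient
#'
#' Simulates a registered DCE series and tumor mask for one subtype: an
#' ellipsoidal lesion with spatially correlated voxel-level kinetic fields,
#' embedded in a non-enhancing background, sampled at the configured phase times
#' with additive Gaussian acquisition noise.
#'
#' @param spec a [phantomSpec()].
#' @param classLabel one of [subtypeLevels()].
#' @param seed integer RNG seed; the output is a pure function of
#'   `(spec, classLabel, seed)`.
#' @param patientID identifier stored in the series.
#'
#' @return list with `series` ([DCESeries-class]), `mask`
#'   ([TumorMask-class]) and `truth` (generating voxel fields `w`, `slope`,
#'   plus `tPeak` and lesion geometry), the ground truth for tests.
#' @export
generatePatient <- function(spec, classLabel, seed, patientID = "phantom") {
  stopifnot(inherits(spec, "PhantomSpec"))
  if (!classLabel %in% subtypeLevels())
    stop("unknown subtype: ", classLabel)
  ck <- spec$classKinetics[[classLabel]]
  d <- spec$gridShape
  set.seed(seed)

  # lesion geometry: axis-aligned ellipsoid, jittered center
  center <- d / 2 + stats::runif(3, -2, 2)
  radii <- stats::runif(3, spec$lesionRadii[1], spec$lesionRadii[2])
  mask <- .ellipsoidMask(d, center, radii)
  while (sum(mask) < 200L) {  # guarantee a usable ROI
    radii <- radii * 1.1
    mask <- .ellipsoidMask(d, center, radii)
  }

  # smooth positive pre-contrast background
  pre <- spec$baseline * (1 + 0.02 * .correlatedField(d, 3))
  pre <- pmax(pre, 0.2 * spec$baseline)

  # spatially correlated kinetic fields inside the lesion
  w <- ck$washinMean + ck$washinSD * .correlatedField(d, ck$corrLength)
  w <- pmax(w, 0.05 * ck$washinMean)
  slope <- ck$slopeMean + ck$slopeSD * .correlatedField(d, ck$corrLength)
  slope <- pmin(slope, 0)

  post <- vector("list", length(spec$phaseTimes))
  for (i in seq_along(spec$phaseTimes)) {
    t <- spec$phaseTimes[i]
    enh <- array(1, dim = d)
    enh[mask] <- 1 + w[mask] * min(t, ck$tPeak) +
      slope[mask] * max(0, t - ck$tPeak)
    vol <- pre * enh
    if (spec$noiseSD > 0)
      vol <- vol + array(stats::rnorm(prod(d), 0, spec$noiseSD), dim = d)
    post[[i]] <- vol
  }

  list(
    series = DCESeries(pre, post, spec$phaseTimes, spec$voxelSpacing, patientID),
    mask = TumorMask(mask, spec$voxelSpacing),
    truth = list(w = w, slope = slope, tPeak = ck$tPeak, center = center,
                 radii = radii, class = classLabel)
  )
}

.ellipsoidMask <- function(d, center, radii) {
  x <- (seq_len(d[1]) - center[1]) / radii[1]
  y <- (seq_len(d[2]) - center[2]) / radii[2]
  z <- (seq_len(d[3]) - center[3]) / radii[3]
  r2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
  array(r2 <= 1, dim = d)
}

#' Generate a synthetic cohort
#'
#' Generates `sum(spec$nPerClass)` patients with exactly the requested class
#' counts and deterministic per-patient seeds derived from `spec$seed`.
#' Optionally writes each patient's phases and mask as NIfTI plus a JSON
#' sidecar of generating parameters, and the label table as CSV.
#'
#' @param spec a [phantomSpec()].
#' @param dir optional output directory; created if missing.
#'
#' @return list with `patients` (list of [generatePatient()] records) and
#'   `labels` (data.frame with `patient_id`, `subtype`).
#' @export
generateCohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "PhantomSpec"))
  classes <- subtypeLevels()
  patients <- list()
  ids <- character()
  subs <- character()
  k <- 0L
  for (ci in seq_along(classes)) {
    for (j in seq_len(spec$nPerClass[ci])) {
      k <- k + 1L
      pid <- sprintf("P%03d", k)
      seed <- (spec$seed + 7919L * ci + j) %% .Machine$integer.max
      rec <- generatePatient(spec, classes[ci], seed, patientID = pid)
      rec$subtype <- classes[ci]
      patients[[pid]] <- rec
      ids <- c(ids, pid)
      subs <- c(subs, classes[ci])
    }
  }
  labels <- data.frame(patient_id = ids, subtype = subs,
                       stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (pid in names(patients)) {
      rec <- patients[[pid]]
      writeSeries(rec$series, file.path(dir, pid))
      writeMask(rec$mask, file.path(dir, paste0(pid, "_mask.nii.gz")))
      sidecar <- list(
        patient_id = pid, subtype = rec$subtype,
        phase_times_s = spec$phaseTimes,
        t_peak_s = rec$truth$tPeak,
        lesion_center = rec$truth$center, lesion_radii = rec$truth$radii,
        class_kinetics = spec$classKinetics[[rec$subtype]]
      )
      jsonlite::write_json(sidecar, file.path(dir, paste0(pid, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
  }
  list(patients = patients, labels = labels)
}
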
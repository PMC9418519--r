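# End-to-end analysis pipeline: segment -> label -> metrics -> shape ->
# chords -> scattering, driven by a single config with a full run record
# (every stage parameter echoed, no silent defaults).

pipelineDefaults <- function() {
  list(
    input = NULL,            # path or VoxelVolume/BinaryVolume
    voxelSize = NULL,        # nm; required when the input carries none
    threshold = "auto",      # "auto", "none" (already binary), or a value
    poreIs = "dark",
    openPairs = 1,           # erosion/dilation dual operations
    labeling = "components", # or "watershed"
    connectivity = 26,
    hMinNm = 0,              # watershed h-maxima depth
    layers = "none",         # "none", "auto", or numeric boundary slices
    layerAxis = "z",
    smoothingNm = 50,
    chordPhase = "pore",
    chordDirections = "axes",
    chordBoundary = "discard",
    projectionAxes = c("z", "x"),
    halfAngle = 15,
    porodBand = NULL,        # nm^-1; NULL = upper part of the q range
    porodTolerance = 0.15,
    forceEuler = TRUE,
    excludeBoundary = TRUE,
    maxShapePores = 5000,
    seed = 1,
    outputDir = NULL
  )
}

#' Run the full porosity-analysis pipeline
#'
#' Orchestrates segmentation (optional), pore labelling, porosity and
#' pore-volume metrics, layer detection (optional), Minkowski shape
#' analysis, chord-length/specific-surface estimation and the
#' projection-based spectral analysis, from a single config list. Every
#' stage parameter (given or default) is echoed into the run record, and
#' the summary is fully reproducible from (input, config, seed).
#'
#' @param config list overriding the defaults (see
#'   `frustule3d:::pipelineDefaults()`): `input` (file path or volume
#'   object), `voxelSize`, `threshold` ("auto" / "none" / value),
#'   `openPairs`, `labeling` ("components" / "watershed"), `hMinNm`,
#'   `layers` ("none" / "auto" / boundary vector), `chordPhase`,
#'   `projectionAxes`, `porodBand`, `seed`, `outputDir`, ...
#'   A YAML or JSON file path may be given instead of a list.
#' @return list with `summary` (scalar results), `tables` (per-pore and
#'   distribution tables), `objects` (volumes, layer model, profiles) and
#'   `runRecord`; when `outputDir` is set, `summary.json`,
#'   `run_record.json` and the CSV tables are written there
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
      else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- pipelineDefaults()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(config)] <- config
  if (is.null(cfg$input))
    stop("config validation: 'input' is required", call. = FALSE)

  # ---- input ----
  vol <- cfg$input
  if (is.character(vol)) {
    vol <- readVolume(vol, voxelSize = cfg$voxelSize)
  }
  if (!is(vol, "VoxelVolume"))
    stop("config validation: input must be a path or a volume object",
         call. = FALSE)
  if (is.null(cfg$voxelSize)) cfg$voxelSize <- voxelSize(vol)
  if (!isTRUE(cfg$voxelSize > 0))
    stop("config validation: voxel size missing or not positive",
         call. = FALSE)

  record <- cfg
  record$input <- if (is.character(cfg$input)) cfg$input else
    sprintf("<in-memory %s %s>", class(vol),
            paste(dim(vol), collapse = "x"))
  stageFail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }

  # ---- segmentation ----
  if (is(vol, "BinaryVolume") || identical(cfg$threshold, "none")) {
    if (!is(vol, "BinaryVolume"))
      stop("threshold = 'none' requires binary input", call. = FALSE)
    bin <- vol
    record$thresholdValue <- NA_real_
  } else {
    seg <- tryCatch(bimodalThreshold(
      vol, poreIs = cfg$poreIs,
      threshold = if (identical(cfg$threshold, "auto")) NULL
        else as.numeric(cfg$threshold)),
      error = function(e) stageFail("threshold", e))
    bin <- seg$volume
    record$thresholdValue <- seg$threshold
  }
  if (cfg$openPairs > 0)
    bin <- morphologicalCleanup(bin, cfg$openPairs)

  # ---- labelling ----
  labels <- tryCatch(switch(cfg$labeling,
    components = labelComponents(bin, cfg$connectivity),
    watershed = watershedSeparate(bin, cfg$hMinNm),
    stop("labeling must be 'components' or 'watershed'")),
    error = function(e) stageFail("labeling", e))

  # ---- porosity metrics ----
  phi <- porosityFraction(bin)
  pvd <- if (nLabels(labels) > 0) poreVolumeDistribution(labels) else NULL

  layerModel <- NULL
  if (!identical(cfg$layers, "none")) {
    layerModel <- tryCatch({
      if (identical(cfg$layers, "auto")) {
        detectLayerBoundaries(bin, axis = cfg$layerAxis,
                              smoothingNm = cfg$smoothingNm)
      } else {
        b <- as.numeric(cfg$layers)
        prof <- solidFractionProfile(bin, cfg$layerAxis)
        edges <- c(0, b, length(prof))
        nms <- if (length(b) == 2L) c("foramen", "areola", "cribrum")
          else paste0("layer", seq_len(length(b) + 1L))
        poro <- vapply(seq_len(length(b) + 1L), function(L) {
          ks <- (floor(edges[L]) + 1L):round(edges[L + 1L])
          1 - mean(prof[ks])
        }, 0)
        new("LayerModel", axis = cfg$layerAxis, boundaries = b,
            names = nms, thickness = diff(edges) * cfg$voxelSize,
            porosity = poro, profile = prof)
      }
    }, error = function(e) stageFail("layers", e))
  }

  # ---- shape analysis ----
  fp <- NULL
  if (nLabels(labels) > 0 && nLabels(labels) <= cfg$maxShapePores) {
    fp <- tryCatch(fpDiagram(labels, forceEuler = cfg$forceEuler,
                             excludeBoundary = cfg$excludeBoundary),
                   error = function(e) stageFail("shape", e))
  }

  # ---- chords ----
  chords <- tryCatch(chordLengths(
    bin, phase = cfg$chordPhase, directions = cfg$chordDirections,
    boundary = cfg$chordBoundary),
    error = function(e) stageFail("chords", e))
  lp <- if (length(chords@lengths)) firstMoment(chords) else NA_real_
  sv <- if (is.finite(lp)) specificSurfaceFromChords(lp) else
    list(nm_inv = NA_real_, m2_cm3 = NA_real_)

  # ---- scattering ----
  scatter <- list()
  for (ax in cfg$projectionAxes) {
    pr <- projectVolume(bin, ax)
    sp <- tryCatch(powerSpectrum2D(pr),
                   error = function(e) stageFail("scattering", e))
    band <- cfg$porodBand
    if (is.null(band)) {
      qN <- min(max(abs(sp@qx)), max(abs(sp@qy)))
      band <- c(0.35 * qN, 0.8 * qN)
    }
    prof <- list()
    for (dirn in c("qx", "qy")) {
      az <- azimuthalAverage(sp, dirn, cfg$halfAngle)
      ft <- tryCatch(porodFit(az, band), error = function(e) NULL)
      co <- if (is.null(ft)) list(q_cutoff = NA_real_, r_nm = NA_real_)
        else porodCutoff(az, ft, cfg$porodTolerance)
      prof[[dirn]] <- list(profile = az,
                           slope = if (is.null(ft)) NA_real_ else ft$slope,
                           qBand = band, qCutoff = co$q_cutoff,
                           r_nm = co$r_nm)
    }
    scatter[[ax]] <- prof
  }

  summary <- list(
    voxel_size_nm = cfg$voxelSize,
    shape = dim(bin),
    threshold = record$thresholdValue,
    porosity = phi,
    pore_count = nLabels(labels),
    mean_pore_chord_nm = lp,
    specific_surface_nm_inv = sv$nm_inv,
    specific_surface_m2_cm3 = sv$m2_cm3,
    fp_centroid = if (is.null(fp)) NULL else
      list(F = fp$summary$centroidF, P = fp$summary$centroidP),
    layers = if (is.null(layerModel)) NULL else
      list(boundaries = layerModel@boundaries,
           thickness_nm = layerModel@thickness,
           porosity = layerModel@porosity,
           total_porosity = combineTotalPorosity(layerModel)),
    porod = lapply(scatter, function(ax) lapply(ax, function(p)
      list(slope = p$slope, q_cutoff = p$qCutoff, r_nm = p$r_nm)))
  )

  out <- list(summary = summary,
              tables = list(
                poreVolumes = if (is.null(pvd)) NULL else pvd@volumes,
                shape = if (is.null(fp)) NULL else fp$table),
              objects = list(binary = bin, labels = labels,
                             layers = layerModel, chords = chords,
                             scatter = scatter),
              runRecord = record)

  if (!is.null(cfg$outputDir)) {
    dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(summary, file.path(cfg$outputDir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    rec <- record
    jsonlite::write_json(rec, file.path(cfg$outputDir, "run_record.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         force = TRUE)
    if (!is.null(fp))
      write.csv(fp$table, file.path(cfg$outputDir, "shape_table.csv"),
                row.names = FALSE)
    if (!is.null(pvd))
      write.csv(data.frame(volume_nm3 = pvd@volumes),
                file.path(cfg$outputDir, "pore_volumes.csv"),
                row.names = FALSE)
  }
  out
}

#' Write the reference fixture suites used by the tests
#'
#' Generates the named suite into a directory: `primitives` (ball, slab,
#' hollow shell, torus), `nanopores` (a 128^3 ellipsoidal nanopore field
#' at the study volume fraction) or `frustule` (a 7-chamber three-layer
#' valve unit at 20 nm voxels), each with its ground truth as JSON.
#'
#' @param suite "primitives", "nanopores" or "frustule"
#' @param seed integer seed
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
makeFixtures <- function(suite = c("primitives", "nanopores", "frustule"),
                         seed = 1L, dir = tempfile("fixtures")) {
  suite <- match.arg(suite)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTruth <- function(truth, name) {
    jsonlite::write_json(truth, file.path(dir, paste0(name, "_truth.json")),
                         auto_unbox = TRUE, digits = 10, force = TRUE,
                         dataframe = "columns")
  }
  if (suite == "primitives") {
    g <- gridSpec(c(64, 64, 64), 1)
    for (spec in list(
      list(name = "ball", kind = "ball", radius = 20),
      list(name = "slab", kind = "slab", thickness = 10),
      list(name = "shell", kind = "hollow_shell", innerRadius = 12,
           outerRadius = 20),
      list(name = "torus", kind = "torus", majorRadius = 18,
           minorRadius = 7))) {
      args <- c(list(kind = spec$kind, grid = g),
                spec[setdiff(names(spec), c("name", "kind"))])
      obj <- do.call(generatePrimitive, args)
      writeVolume(obj$volume, file.path(dir, paste0(spec$name, ".tif")))
      writeTruth(obj$truth, spec$name)
    }
  } else if (suite == "nanopores") {
    g <- gridSpec(c(128, 128, 128), 1)
    fs <- nanoporeFieldSpec(seed = seed)
    obj <- generateNanoporeField(fs, g)
    writeVolume(obj$volume, file.path(dir, "nanopores.tif"))
    writeTruth(obj$truth, "nanopores")
  } else {
    sp <- frustuleSpec(seed = seed)
    g <- frustuleGridFor(sp, voxelSize = 20)
    obj <- generateFrustule(sp, g)
    writeVolume(obj$volume, file.path(dir, "frustule.tif"))
    writeTruth(obj$truth, "frustule")
  }
  invisible(dir)
}

#' Grid large enough for a frustule spec
#'
#' Convenience: computes the lateral and axial extents needed by
#' [generateFrustule()] for the given spec and voxel size.
#'
#' @param spec a [FrustuleSpec-class]
#' @param voxelSize nm
#' @param lateralMargin extra margin (nm) around the hexagonal patch
#' @return a [GridSpec-class]
#' @export
frustuleGridFor <- function(spec, voxelSize = 20, lateralMargin = 200) {
  a <- spec@latticeParameter
  lateral <- 2 * (spec@nRings * a + 0.7 * a + lateralMargin)
  nLat <- ceiling(lateral / voxelSize)
  # floor: the stack must not be over-covered, or a trailing all-solid
  # slice would fake a fourth layer at the volume top
  nZ <- floor((spec@foramenThickness + spec@areolaHeight +
                 spec@cribrumThickness) / voxelSize)
  gridSpec(c(nLat, nLat, nZ), voxelSize)
}
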
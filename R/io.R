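## Plain-text I/O: myograph CSV + geometry sidecar JSON in, tidy state CSV
## and summary JSON out; fiber stacks as per-slice CSV matrices with a JSON
## sidecar (no TIFF reader exists in this toolchain; arrays are the
## in-memory interchange format).

#' Read a pressure-myograph CSV with its geometry sidecar
#'
#' The CSV has one row per sample with header columns `axial_stretch`,
#' `pressure_mmHg`, `outer_diameter_mm`, `axial_force_mN` and optionally
#' `preconditioning` (rows flagged TRUE/1 are protocol preconditioning
#' sweeps and are discarded). Rows are grouped into one sweep per distinct
#' axial stretch. The sidecar JSON supplies the unloaded ring geometry as
#' either `outer_circumference_mm`/`inner_circumference_mm` (traced rings)
#' or `outer_diameter_mm`/`inner_diameter_mm`, plus optional
#' `map_pressure_mmHg` and `group`.
#'
#' @param csvPath path to the myograph CSV
#' @param geometryPath path to the sidecar JSON; default: `csvPath` with
#'   extension replaced by `.json`
#' @param mapPressure overrides the sidecar MAP (mmHg)
#' @return a [BiaxialDataset-class]
#' @export
readMyographCsv <- function(csvPath, geometryPath = NULL,
                            mapPressure = NULL) {
  if (is.null(geometryPath)) {
    geometryPath <- paste0(sub("\\.[^.]*$", "", csvPath), ".json")
  }
  if (!file.exists(csvPath)) stop("no such file: ", csvPath, call. = FALSE)
  if (!file.exists(geometryPath)) {
    stop("missing geometry sidecar for ", csvPath, " (expected ",
         geometryPath, ")", call. = FALSE)
  }
  d <- utils::read.csv(csvPath)
  need <- c("axial_stretch", "pressure_mmHg", "outer_diameter_mm",
            "axial_force_mN")
  if (!all(need %in% names(d))) {
    stop("malformed myograph CSV ", csvPath, ": needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if ("preconditioning" %in% names(d)) {
    d <- d[!as.logical(d$preconditioning), ]
  }
  side <- jsonlite::read_json(geometryPath, simplifyVector = TRUE)
  geo <- if (!is.null(side$outer_circumference_mm)) {
    geometryFromRingCircumferences(side$outer_circumference_mm,
                                   side$inner_circumference_mm)
  } else if (!is.null(side$outer_diameter_mm)) {
    UnloadedGeometry(side$outer_diameter_mm, side$inner_diameter_mm)
  } else {
    stop("geometry sidecar ", geometryPath, " has neither circumferences ",
         "nor diameters", call. = FALSE)
  }
  recs <- lapply(split(d, d$axial_stretch), function(b) {
    b <- b[order(b$pressure_mmHg), ]
    InflationRecord(b$axial_stretch[1], b$pressure_mmHg,
                    b$outer_diameter_mm, b$axial_force_mN)
  })
  if (is.null(mapPressure)) {
    mapPressure <- if (!is.null(side$map_pressure_mmHg)) {
      side$map_pressure_mmHg
    } else {
      max(d$pressure_mmHg)
    }
  }
  BiaxialDataset(geo, unname(recs), mapPressure,
                 groupLabel = if (!is.null(side$group)) side$group else
                   "unlabeled")
}

#' Write a simulated dataset in the myograph CSV + sidecar format
#'
#' @param dataset a [BiaxialDataset-class]
#' @param csvPath output CSV path (sidecar JSON written next to it)
#' @return the CSV path, invisibly
#' @export
writeMyographCsv <- function(dataset, csvPath) {
  stopifnot(is(dataset, "BiaxialDataset"))
  rows <- do.call(rbind, lapply(records(dataset), function(r) {
    cbind(axial_stretch = axialStretch(r), samples(r))
  }))
  utils::write.csv(rows, csvPath, row.names = FALSE)
  geo <- geometry(dataset)
  jsonlite::write_json(
    list(outer_diameter_mm = outerDiameter(geo),
         inner_diameter_mm = innerDiameter(geo),
         map_pressure_mmHg = mapPressure(dataset),
         group = groupLabel(dataset)),
    paste0(sub("\\.[^.]*$", "", csvPath), ".json"), auto_unbox = TRUE,
    digits = NA)
  invisible(csvPath)
}

#' Write processed deformed states as tidy CSV
#'
#' One row per pressure step with the full kinematic and stress state.
#'
#' @param curves a [StressStrainCurve-class] or list of them
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeDeformedStates <- function(curves, path) {
  if (is(curves, "StressStrainCurve")) curves <- list(curves)
  rows <- do.call(rbind, lapply(curves, states))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a per-specimen mechanics summary as JSON
#'
#' Captures the in vivo stretch estimate, the deformed state at MAP and the
#' tangent modulus, i.e. the output of [characterizeSpecimen()].
#'
#' @param characterization result of [characterizeSpecimen()]
#' @param path output JSON path
#' @param extra named list merged into the JSON (ids, config hash, ...)
#' @return the path, invisibly
#' @export
writeSpecimenSummary <- function(characterization, path, extra = list()) {
  est <- characterization$inVivoStretch
  out <- c(list(
    in_vivo_stretch = stretchValue(est),
    force_variation_mN = forceVariation(est),
    within_threshold = withinThreshold(est),
    eval_pressure_mmHg = characterization$evalPressure_mmHg,
    map_state = as.list(characterization$mapState),
    tangent_modulus_MPa = characterization$tangentModulusMPa), extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write / read a fiber image stack as plain text
#'
#' Each slice is stored as a headerless CSV matrix `<stem>_z<k>.csv`, with
#' acquisition metadata in `<stem>.json`. A plain-text stand-in for TIFF
#' export.
#'
#' @param stack a [FiberImageStack-class]
#' @param stem path stem (no extension)
#' @return `writeFiberStack`: the stem, invisibly; `readFiberStack`: a
#'   [FiberImageStack-class]
#' @export
writeFiberStack <- function(stack, stem) {
  stopifnot(is(stack, "FiberImageStack"))
  n <- nSlices(stack)
  for (i in seq_len(n)) {
    utils::write.table(getSlice(stack, i),
                       sprintf("%s_z%03d.csv", stem, i),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(
    list(n_slices = n, pixel_size_um = pixelSize(stack),
         z_spacing_um = zSpacing(stack), channel = channel(stack),
         pressure_mmHg = mapPressureOrNA(stack),
         axial_stretch = axialStretch(stack)),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

## pressure slot may be NA; keep JSON clean
mapPressureOrNA <- function(stack) {
  p <- stack@pressure
  if (is.na(p)) NULL else p
}

#' @rdname writeFiberStack
#' @export
readFiberStack <- function(stem) {
  metaPath <- paste0(stem, ".json")
  if (!file.exists(metaPath)) {
    stop("unreadable stack: missing sidecar ", metaPath, call. = FALSE)
  }
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  slices <- lapply(seq_len(meta$n_slices), function(i) {
    as.matrix(utils::read.table(sprintf("%s_z%03d.csv", stem, i),
                                sep = ","))
  })
  vox <- array(0, dim = c(dim(slices[[1]]), length(slices)))
  for (i in seq_along(slices)) vox[, , i] <- slices[[i]]
  FiberImageStack(vox, meta$pixel_size_um, meta$z_spacing_um,
                  channel = meta$channel,
                  pressure = if (is.null(meta$pressure_mmHg)) NA_real_ else
                    meta$pressure_mmHg,
                  axialStretch = if (is.null(meta$axial_stretch)) NA_real_
                  else meta$axial_stretch)
}

#' Write an orientation histogram (or depth map) as tidy CSV
#' @param x an [OrientationHistogram-class] or [DepthOrientationMap-class]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeOrientationCsv <- function(x, path) {
  df <- if (is(x, "OrientationHistogram")) {
    data.frame(angle_deg = binCenters(x), weight = binWeights(x))
  } else if (is(x, "DepthOrientationMap")) {
    m <- orientationMap(x)
    data.frame(depth_um = rep(depths(x), each = ncol(m)),
               angle_deg = rep(angles(x), nrow(m)),
               weight = as.vector(t(m)))
  } else {
    stop("unsupported object", call. = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
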
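## Central S4 containers for the biaxial mechanics and fiber-imaging pipeline.
## Units are fixed at the boundary and never mixed internally:
## pressures mmHg, lengths mm (images: micrometres), forces mN,
## stresses kPa, moduli MPa.

#' @import methods
NULL

## conversion applied wherever a pressure enters a stress formula
.KPA_PER_MMHG <- 0.1333224

#' UnloadedGeometry: traced unloaded ring dimensions
#'
#' Reference (unloaded) configuration of an arterial segment, defined by the
#' outer and inner diameters of a traced ring. Wall thickness is
#' `(Do - Di) / 2`.
#'
#' @slot outerDiameter unloaded outer diameter Do (mm)
#' @slot innerDiameter unloaded inner diameter Di (mm)
#' @export
setClass("UnloadedGeometry",
  representation(outerDiameter = "numeric", innerDiameter = "numeric"))

setValidity("UnloadedGeometry", function(object) {
  Do <- object@outerDiameter
  Di <- object@innerDiameter
  if (length(Do) != 1L || length(Di) != 1L) {
    return("outerDiameter and innerDiameter must be scalars")
  }
  if (!is.finite(Do) || !is.finite(Di)) return("diameters must be finite")
  if (Di <= 0) return("inner diameter must be > 0")
  if (Do <= Di) return("outer diameter must exceed inner diameter")
  TRUE
})

#' Construct an UnloadedGeometry from ring diameters
#'
#' @param outerDiameter unloaded outer diameter Do (mm)
#' @param innerDiameter unloaded inner diameter Di (mm)
#' @return an [UnloadedGeometry-class] object
#' @seealso [geometryFromRingCircumferences()] for construction from traced
#'   circumferences
#' @examples
#' geo <- UnloadedGeometry(0.9, 0.7)
#' wallThickness(geo)
#' @export
UnloadedGeometry <- function(outerDiameter, innerDiameter) {
  new("UnloadedGeometry",
      outerDiameter = as.numeric(outerDiameter),
      innerDiameter = as.numeric(innerDiameter))
}

#' InflationRecord: one pressurization sweep at fixed axial stretch
#'
#' Samples of (pressure, deformed outer diameter, axial force) acquired during
#' stepwise inflation while the vessel is held at a fixed axial stretch.
#'
#' @slot axialStretch fixed axial stretch ratio lambda_z (>= 1)
#' @slot samples data.frame with columns `pressure_mmHg`, `outer_diameter_mm`,
#'   `axial_force_mN`, ordered by strictly increasing pressure
#' @export
setClass("InflationRecord",
  representation(axialStretch = "numeric", samples = "data.frame"))

setValidity("InflationRecord", function(object) {
  lz <- object@axialStretch
  s <- object@samples
  need <- c("pressure_mmHg", "outer_diameter_mm", "axial_force_mN")
  if (length(lz) != 1L || !is.finite(lz) || lz < 1) {
    return("axialStretch must be a finite scalar >= 1")
  }
  if (!all(need %in% names(s))) {
    return(paste("samples must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(s) < 1L) return("at least one sample required")
  if (any(!is.finite(as.matrix(s[need])))) return("samples must be finite")
  if (any(diff(s$pressure_mmHg) <= 0)) {
    return("pressures must be strictly increasing")
  }
  if (any(s$outer_diameter_mm <= 0)) return("outer diameters must be > 0")
  TRUE
})

#' Construct an InflationRecord
#'
#' @param axialStretch fixed axial stretch ratio (>= 1)
#' @param pressure pressures (mmHg), strictly increasing
#' @param outerDiameter deformed outer diameters (mm)
#' @param axialForce axial forces (mN)
#' @return an [InflationRecord-class] object
#' @export
InflationRecord <- function(axialStretch, pressure, outerDiameter, axialForce) {
  new("InflationRecord",
      axialStretch = as.numeric(axialStretch),
      samples = data.frame(pressure_mmHg = as.numeric(pressure),
                           outer_diameter_mm = as.numeric(outerDiameter),
                           axial_force_mN = as.numeric(axialForce)))
}

#' BiaxialDataset: all sweeps for one specimen
#'
#' A set of [InflationRecord-class] sweeps at distinct axial stretches,
#' together with the unloaded ring geometry, the specimen's mean arterial
#' pressure (the physiological operating point used for "at MAP" quantities),
#' and a group label.
#'
#' @slot geometry an [UnloadedGeometry-class]
#' @slot records list of [InflationRecord-class] at distinct axial stretches
#' @slot mapPressure mean arterial pressure (mmHg)
#' @slot groupLabel experimental group tag (e.g. "CTL", "HT", "RDN")
#' @export
setClass("BiaxialDataset",
  representation(geometry = "UnloadedGeometry", records = "list",
                 mapPressure = "numeric", groupLabel = "character"))

setValidity("BiaxialDataset", function(object) {
  if (length(object@records) < 1L) return("at least one record required")
  ok <- vapply(object@records, is, logical(1), class2 = "InflationRecord")
  if (!all(ok)) return("records must all be InflationRecord objects")
  lz <- vapply(object@records, function(r) r@axialStretch, numeric(1))
  if (anyDuplicated(lz)) return("records must be at distinct axial stretches")
  if (length(object@mapPressure) != 1L || object@mapPressure <= 0) {
    return("mapPressure must be a positive scalar (mmHg)")
  }
  TRUE
})

#' Construct a BiaxialDataset
#'
#' @param geometry an [UnloadedGeometry-class]
#' @param records list of [InflationRecord-class] at distinct axial stretches
#' @param mapPressure mean arterial pressure (mmHg)
#' @param groupLabel group tag, default `"unlabeled"`
#' @return a [BiaxialDataset-class] object
#' @export
BiaxialDataset <- function(geometry, records, mapPressure,
                           groupLabel = "unlabeled") {
  new("BiaxialDataset", geometry = geometry, records = records,
      mapPressure = as.numeric(mapPressure),
      groupLabel = as.character(groupLabel))
}

#' StressStrainCurve: processed deformed states of one sweep
#'
#' One row per pressure step: deformed geometry (outer/inner diameter, wall
#' thickness), stretches, and thin-wall mean biaxial Cauchy stresses. The
#' incompressibility residual `(do^2 - di^2) * lambda_z - (Do^2 - Di^2)` is
#' enforced to `1e-9` mm^2 at validation.
#'
#' @slot axialStretch the sweep's fixed axial stretch
#' @slot geometry the reference [UnloadedGeometry-class]
#' @slot states data.frame with columns `pressure_mmHg`, `outer_diameter_mm`,
#'   `inner_diameter_mm`, `wall_thickness_mm`, `circ_stretch`, `axial_stretch`,
#'   `axial_force_mN`, `circ_stress_kPa`, `axial_stress_kPa`
#' @export
setClass("StressStrainCurve",
  representation(axialStretch = "numeric", geometry = "UnloadedGeometry",
                 states = "data.frame"))

setValidity("StressStrainCurve", function(object) {
  s <- object@states
  need <- c("pressure_mmHg", "outer_diameter_mm", "inner_diameter_mm",
            "wall_thickness_mm", "circ_stretch", "axial_stretch",
            "axial_force_mN", "circ_stress_kPa", "axial_stress_kPa")
  if (!all(need %in% names(s))) {
    return(paste("states must have columns", paste(need, collapse = ", ")))
  }
  if (nrow(s) < 1L) return("at least one state required")
  if (any(diff(s$pressure_mmHg) <= 0)) {
    return("pressures must be strictly increasing")
  }
  if (any(s$inner_diameter_mm <= 0) ||
      any(s$outer_diameter_mm <= s$inner_diameter_mm)) {
    return("need do > di > 0 in every state")
  }
  h <- (s$outer_diameter_mm - s$inner_diameter_mm) / 2
  if (max(abs(h - s$wall_thickness_mm)) > 1e-12) {
    return("wall thickness must equal (do - di)/2")
  }
  geo <- object@geometry
  resid <- (s$outer_diameter_mm^2 - s$inner_diameter_mm^2) * s$axial_stretch -
    (geo@outerDiameter^2 - geo@innerDiameter^2)
  if (max(abs(resid)) > 1e-9) {
    return("incompressibility residual exceeds 1e-9 mm^2")
  }
  TRUE
})

#' InVivoStretchEstimate: axial-force-plateau detection result
#'
#' The in vivo axial stretch is estimated as the tested axial stretch at which
#' the axial force stays (most nearly) constant during pressurization, with a
#' 50 uN (0.05 mN) default acceptance threshold on the force variation.
#'
#' @slot value estimated in vivo axial stretch (possibly interpolated)
#' @slot forceVariation force variation (mN) at the selected tested record
#' @slot withinThreshold whether that variation met the threshold
#' @slot threshold the threshold used (mN)
#' @slot perRecord data.frame (`axial_stretch`, `force_variation_mN`) for all
#'   tested records
#' @export
setClass("InVivoStretchEstimate",
  representation(value = "numeric", forceVariation = "numeric",
                 withinThreshold = "logical", threshold = "numeric",
                 perRecord = "data.frame"))

setValidity("InVivoStretchEstimate", function(object) {
  if (object@forceVariation < 0) return("forceVariation must be >= 0")
  lz <- object@perRecord$axial_stretch
  if (object@value < min(lz) - 1e-12 || object@value > max(lz) + 1e-12) {
    return("value must lie within the tested axial-stretch range")
  }
  TRUE
})

#' ConstitutiveParams: four-fiber-family membrane model parameters
#'
#' Parameters of an incompressible neo-Hookean ground matrix reinforced by
#' exponential fiber families (angle measured from the vessel axis), together
#' with the unloaded reference geometry. This is the standard constitutive
#' family for rodent elastic arteries and drives the synthetic-data simulator.
#'
#' @slot matrixStiffness neo-Hookean ground-matrix stiffness c (kPa)
#' @slot fiberFamilies data.frame with columns `stiffness_kPa` (c1),
#'   `exponent` (c2, dimensionless) and `angle_deg` (0 = axial, 90 =
#'   circumferential)
#' @slot geometry unloaded reference [UnloadedGeometry-class]
#' @slot label free-text preset tag
#' @export
setClass("ConstitutiveParams",
  representation(matrixStiffness = "numeric", fiberFamilies = "data.frame",
                 geometry = "UnloadedGeometry", label = "character"))

setValidity("ConstitutiveParams", function(object) {
  ff <- object@fiberFamilies
  need <- c("stiffness_kPa", "exponent", "angle_deg")
  if (!all(need %in% names(ff))) {
    return(paste("fiberFamilies must have columns",
                 paste(need, collapse = ", ")))
  }
  if (object@matrixStiffness < 0) return("matrix stiffness must be >= 0")
  if (nrow(ff) > 0) {
    if (any(ff$stiffness_kPa < 0)) return("fiber stiffness must be >= 0")
    if (any(ff$exponent <= 0)) return("fiber exponents must be > 0")
    if (any(ff$angle_deg < 0 | ff$angle_deg > 90)) {
      return("fiber angles must lie in [0, 90] degrees")
    }
  }
  TRUE
})

#' Construct ConstitutiveParams
#'
#' @param matrixStiffness ground-matrix stiffness c (kPa)
#' @param fiberFamilies data.frame (`stiffness_kPa`, `exponent`, `angle_deg`)
#' @param geometry unloaded reference [UnloadedGeometry-class]
#' @param label preset tag
#' @return a [ConstitutiveParams-class] object
#' @export
ConstitutiveParams <- function(matrixStiffness, fiberFamilies, geometry,
                               label = "custom") {
  new("ConstitutiveParams", matrixStiffness = as.numeric(matrixStiffness),
      fiberFamilies = fiberFamilies, geometry = geometry,
      label = as.character(label))
}

#' SimulationProtocol: pressures, stretches and noise of a virtual experiment
#'
#' Defaults follow the experimental protocol emulated by the simulator:
#' stepwise inflation 0 to 120 mmHg in 10 mmHg increments at the in vivo
#' axial stretch and 5 percent above and below it.
#'
#' @slot pressureGrid pressures (mmHg), increasing; default `seq(0, 120, 10)`
#' @slot axialStretchFactors multipliers applied to the model's
#'   force-invariant stretch; default `c(0.95, 1, 1.05)`
#' @slot diameterNoiseSD additive Gaussian noise SD on outer diameter (um)
#' @slot forceNoiseSD additive Gaussian noise SD on axial force (mN)
#' @slot seed integer RNG seed (mandatory for reproducibility)
#' @export
setClass("SimulationProtocol",
  representation(pressureGrid = "numeric", axialStretchFactors = "numeric",
                 diameterNoiseSD = "numeric", forceNoiseSD = "numeric",
                 seed = "integer"))

setValidity("SimulationProtocol", function(object) {
  if (any(diff(object@pressureGrid) <= 0)) {
    return("pressure grid must be strictly increasing")
  }
  if (object@diameterNoiseSD < 0 || object@forceNoiseSD < 0) {
    return("noise SDs must be >= 0")
  }
  if (length(object@seed) != 1L || is.na(object@seed)) {
    return("a scalar integer seed is mandatory")
  }
  TRUE
})

#' Construct a SimulationProtocol
#'
#' @param pressureGrid pressures (mmHg); default 0 to 120 by 10
#' @param axialStretchFactors multipliers on the force-invariant stretch;
#'   default `c(0.95, 1, 1.05)`
#' @param diameterNoiseSD Gaussian diameter noise SD (um); default 5
#' @param forceNoiseSD Gaussian force noise SD (mN); default 0.05
#' @param seed integer RNG seed
#' @return a [SimulationProtocol-class] object
#' @export
SimulationProtocol <- function(pressureGrid = seq(0, 120, by = 10),
                               axialStretchFactors = c(0.95, 1, 1.05),
                               diameterNoiseSD = 5, forceNoiseSD = 0.05,
                               seed = 1L) {
  new("SimulationProtocol", pressureGrid = as.numeric(pressureGrid),
      axialStretchFactors = as.numeric(axialStretchFactors),
      diameterNoiseSD = as.numeric(diameterNoiseSD),
      forceNoiseSD = as.numeric(forceNoiseSD), seed = as.integer(seed))
}

#' FiberImageStack: multiphoton z-stack of one ECM channel
#'
#' Intensity voxels ordered `[row, col, slice]`, with isotropic in-plane pixel
#' size and a fixed z spacing. The image x axis (columns) is the vessel axis;
#' depth 0 is the outer adventitial surface.
#'
#' @slot voxels numeric array `rows x cols x slices`, intensities >= 0
#' @slot pixelSize in-plane pixel size (um)
#' @slot zSpacing slice spacing (um); acquisition default 1
#' @slot channel `"collagen"` or `"elastin"`
#' @slot pressure luminal pressure during acquisition (mmHg)
#' @slot axialStretch axial stretch during acquisition
#' @export
setClass("FiberImageStack",
  representation(voxels = "array", pixelSize = "numeric",
                 zSpacing = "numeric", channel = "character",
                 pressure = "numeric", axialStretch = "numeric"))

setValidity("FiberImageStack", function(object) {
  if (length(dim(object@voxels)) != 3L) {
    return("voxels must be a rows x cols x slices array")
  }
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@zSpacing <= 0) return("zSpacing must be > 0")
  if (any(object@voxels < 0)) return("intensities must be >= 0")
  TRUE
})

#' Construct a FiberImageStack
#'
#' @param voxels array `rows x cols x slices` (a matrix is promoted to a
#'   single-slice stack)
#' @param pixelSize in-plane pixel size (um)
#' @param zSpacing slice spacing (um), default 1
#' @param channel `"collagen"` (default) or `"elastin"`
#' @param pressure acquisition pressure (mmHg), default `NA`
#' @param axialStretch acquisition axial stretch, default `NA`
#' @return a [FiberImageStack-class] object
#' @export
FiberImageStack <- function(voxels, pixelSize, zSpacing = 1,
                            channel = "collagen", pressure = NA_real_,
                            axialStretch = NA_real_) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  new("FiberImageStack", voxels = voxels, pixelSize = as.numeric(pixelSize),
      zSpacing = as.numeric(zSpacing), channel = as.character(channel),
      pressure = as.numeric(pressure), axialStretch = as.numeric(axialStretch))
}

#' OrientationHistogram: normalized angular distribution of fiber directions
#'
#' Angles in degrees on `[-90, 90)`; 0 is the vessel (image x) axis and +/-90
#' the circumferential direction. Weights are fractions summing to 1.
#'
#' @slot binCenters bin centers (degrees), uniform width, covering `[-90, 90)`
#' @slot weights nonnegative fractions summing to 1 (tolerance 1e-9)
#' @export
setClass("OrientationHistogram",
  representation(binCenters = "numeric", weights = "numeric"))

setValidity("OrientationHistogram", function(object) {
  b <- object@binCenters
  w <- object@weights
  if (length(b) != length(w)) return("binCenters/weights length mismatch")
  if (length(b) < 2L) return("need at least 2 bins")
  dw <- diff(b)
  if (max(abs(dw - dw[1])) > 1e-9) return("bins must be uniform")
  if (any(w < 0)) return("weights must be >= 0")
  if (abs(sum(w) - 1) > 1e-9) return("weights must sum to 1 (tol 1e-9)")
  if (b[1] < -90 || b[length(b)] >= 90) {
    return("bin centers must lie in [-90, 90)")
  }
  TRUE
})

#' Construct an OrientationHistogram
#' @param binCenters uniform bin centers (degrees) in `[-90, 90)`
#' @param weights nonnegative weights summing to 1
#' @return an [OrientationHistogram-class] object
#' @export
OrientationHistogram <- function(binCenters, weights) {
  new("OrientationHistogram", binCenters = as.numeric(binCenters),
      weights = as.numeric(weights))
}

#' DepthOrientationMap: orientation distribution per imaging depth
#'
#' One normalized orientation distribution per slice; rendering it as a
#' surface reproduces depth-resolved orientation maps in which the abrupt
#' axial-to-circumferential transition marks the adventitia/media interface.
#'
#' @slot map matrix `depths x angles`, each row summing to 1
#' @slot depths imaging depths (um), 0 = outer adventitial surface
#' @slot angles angle bin centers (degrees)
#' @export
setClass("DepthOrientationMap",
  representation(map = "matrix", depths = "numeric", angles = "numeric"))

setValidity("DepthOrientationMap", function(object) {
  if (nrow(object@map) != length(object@depths)) return("depth size mismatch")
  if (ncol(object@map) != length(object@angles)) return("angle size mismatch")
  if (any(object@map < 0)) return("fractions must be >= 0")
  if (max(abs(rowSums(object@map) - 1)) > 1e-9) {
    return("each depth row must sum to 1 (tol 1e-9)")
  }
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "UnloadedGeometry", function(object) {
  cat(sprintf("UnloadedGeometry: Do = %.4g mm, Di = %.4g mm, H = %.4g mm\n",
              object@outerDiameter, object@innerDiameter,
              (object@outerDiameter - object@innerDiameter) / 2))
})

setMethod("show", "InflationRecord", function(object) {
  s <- object@samples
  cat(sprintf(
    "InflationRecord: lambda_z = %.4g, %d samples, P in [%g, %g] mmHg\n",
    object@axialStretch, nrow(s), min(s$pressure_mmHg), max(s$pressure_mmHg)))
})

setMethod("show", "BiaxialDataset", function(object) {
  lz <- vapply(object@records, function(r) r@axialStretch, numeric(1))
  cat(sprintf(
    "BiaxialDataset [%s]: %d records (lambda_z: %s), MAP = %g mmHg\n",
    object@groupLabel, length(lz),
    paste(sprintf("%.3f", sort(lz)), collapse = ", "), object@mapPressure))
})

setMethod("show", "StressStrainCurve", function(object) {
  s <- object@states
  cat(sprintf(paste0(
    "StressStrainCurve: lambda_z = %.4g, %d states, ",
    "sigma_theta in [%.3g, %.3g] kPa\n"),
    object@axialStretch, nrow(s), min(s$circ_stress_kPa),
    max(s$circ_stress_kPa)))
})

setMethod("show", "InVivoStretchEstimate", function(object) {
  cat(sprintf(paste0(
    "InVivoStretchEstimate: lambda_z* = %.4f ",
    "(force variation %.4g mN, threshold %.4g mN, %s)\n"),
    object@value, object@forceVariation, object@threshold,
    if (object@withinThreshold) "within threshold" else "ABOVE threshold"))
})

setMethod("show", "ConstitutiveParams", function(object) {
  cat(sprintf(
    "ConstitutiveParams [%s]: c = %.4g kPa, %d fiber families at {%s} deg\n",
    object@label, object@matrixStiffness, nrow(object@fiberFamilies),
    paste(object@fiberFamilies$angle_deg, collapse = ", ")))
})

setMethod("show", "SimulationProtocol", function(object) {
  cat(sprintf(paste0(
    "SimulationProtocol: P %g..%g mmHg (%d steps), stretch factors {%s}, ",
    "noise (%.3g um, %.3g mN), seed %d\n"),
    min(object@pressureGrid), max(object@pressureGrid),
    length(object@pressureGrid),
    paste(object@axialStretchFactors, collapse = ", "),
    object@diameterNoiseSD, object@forceNoiseSD, object@seed))
})

setMethod("show", "FiberImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf(paste0(
    "FiberImageStack [%s]: %d x %d px x %d slices, %.3g um/px, ",
    "dz = %g um\n"), object@channel, d[1], d[2], d[3], object@pixelSize,
    object@zSpacing))
})

setMethod("show", "OrientationHistogram", function(object) {
  m <- object@binCenters[which.max(object@weights)]
  cat(sprintf(
    "OrientationHistogram: %d bins of %.3g deg, modal angle %.3g deg\n",
    length(object@binCenters), diff(object@binCenters[1:2]), m))
})

setMethod("show", "DepthOrientationMap", function(object) {
  cat(sprintf(
    "DepthOrientationMap: %d depths (0..%g um) x %d angle bins\n",
    length(object@depths), max(object@depths), length(object@angles)))
})
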
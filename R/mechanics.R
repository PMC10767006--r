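## Sweep-level analysis: processed stress-stretch curves, in vivo axial
## stretch detection, state and tangent modulus at mean arterial pressure.

#' Process an inflation sweep into a stress-stretch curve
#'
#' Applies wall incompressibility and the thin-wall stress formulas to every
#' sample of a sweep, yielding one deformed state (geometry, stretches, mean
#' biaxial Cauchy stresses) per pressure step.
#'
#' @param record an [InflationRecord-class]
#' @param geometry the specimen's [UnloadedGeometry-class]
#' @param convention circumferential-stretch convention passed to
#'   [circumferentialStretch()]
#' @return a [StressStrainCurve-class]
#' @examples
#' geo <- UnloadedGeometry(0.9, 0.7)
#' rec <- InflationRecord(1.8, c(0, 60, 120), c(0.80, 0.95, 1.00), c(8, 8, 8))
#' states(processRecord(rec, geo))
#' @export
processRecord <- function(record, geometry,
                          convention = c("midwall", "inner")) {
  stopifnot(is(record, "InflationRecord"), is(geometry, "UnloadedGeometry"))
  convention <- match.arg(convention)
  s <- samples(record)
  lz <- axialStretch(record)
  di <- tryCatch(
    deformedInnerDiameter(s$outer_diameter_mm, geometry, lz),
    error = function(e) {
      arg <- s$outer_diameter_mm^2 -
        (outerDiameter(geometry)^2 - innerDiameter(geometry)^2) / lz
      bad <- which(arg <= 0)[1]
      stop("infeasible deformation at sample ", bad, " (P = ",
           s$pressure_mmHg[bad], " mmHg): ", conditionMessage(e),
           call. = FALSE)
    })
  h <- (s$outer_diameter_mm - di) / 2
  sig <- cauchyStresses(s$pressure_mmHg, di / 2, h, s$axial_force_mN)
  lt <- circumferentialStretch(s$outer_diameter_mm, di, geometry, convention)
  new("StressStrainCurve", axialStretch = lz, geometry = geometry,
      states = data.frame(
        pressure_mmHg = s$pressure_mmHg,
        outer_diameter_mm = s$outer_diameter_mm,
        inner_diameter_mm = di,
        wall_thickness_mm = h,
        circ_stretch = lt,
        axial_stretch = rep(lz, nrow(s)),
        axial_force_mN = s$axial_force_mN,
        circ_stress_kPa = sig$circ,
        axial_stress_kPa = sig$axial))
}

## force-variation metric over one sweep
.forceVariation <- function(f, metric) {
  switch(metric, range = max(f) - min(f), sd = stats::sd(f))
}

#' Estimate the in vivo axial stretch from axial-force invariance
#'
#' The in vivo axial stretch is the tested stretch at which the axial force
#' remains constant during pressurization. Each sweep is scored by its force
#' variation (range max - min by default; SD optional) and the minimizer is
#' returned. With three or more sweeps, a parabola through the three
#' lowest-scoring stretches refines the estimate (`interpolate = TRUE`); the
#' refined value is clamped to the tested range. A variation at or below
#' `forceThreshold` (default 0.05 mN, i.e. 50 uN) marks the estimate as a
#' genuine force plateau.
#'
#' @param dataset a [BiaxialDataset-class] with at least two sweeps
#' @param forceThreshold plateau acceptance threshold (mN), default 0.05
#' @param metric `"range"` (default) or `"sd"`
#' @param interpolate refine by parabolic interpolation when >= 3 sweeps
#' @return an [InVivoStretchEstimate-class]
#' @export
estimateInVivoStretch <- function(dataset, forceThreshold = 0.05,
                                  metric = c("range", "sd"),
                                  interpolate = TRUE) {
  stopifnot(is(dataset, "BiaxialDataset"))
  metric <- match.arg(metric)
  recs <- records(dataset)
  if (length(recs) < 2L) {
    stop("insufficient data: need >= 2 records at distinct axial stretches",
         call. = FALSE)
  }
  lz <- vapply(recs, axialStretch, numeric(1))
  fv <- vapply(recs, function(r) {
    .forceVariation(samples(r)$axial_force_mN, metric)
  }, numeric(1))
  o <- order(lz)
  lz <- lz[o]
  fv <- fv[o]
  k <- which.min(fv)
  value <- lz[k]
  if (interpolate && length(lz) >= 3L) {
    # parabola through the three lowest-variation points
    sel <- order(fv)[1:3]
    fit <- stats::lm(y ~ x + I(x^2),
                     data = data.frame(x = lz[sel], y = fv[sel]))
    a <- stats::coef(fit)[["I(x^2)"]]
    b <- stats::coef(fit)[["x"]]
    if (is.finite(a) && a > 0) {
      vtx <- -b / (2 * a)
      value <- min(max(vtx, min(lz)), max(lz))
    }
  }
  within <- fv[k] <= forceThreshold
  if (!within) {
    warning("no sweep met the ", forceThreshold,
            " mN force-plateau threshold (best variation ",
            signif(fv[k], 3), " mN)", call. = FALSE)
  }
  new("InVivoStretchEstimate", value = value, forceVariation = fv[k],
      withinThreshold = within, threshold = forceThreshold,
      perRecord = data.frame(axial_stretch = lz, force_variation_mN = fv))
}

#' Deformed state at a target pressure
#'
#' Returns the deformed state (one row of the curve's states) at an arbitrary
#' pressure inside the sampled range, linearly interpolating every field
#' between the two bracketing pressure steps. Used to evaluate "at MAP"
#' quantities.
#'
#' @param curve a [StressStrainCurve-class]
#' @param pressure target pressure (mmHg), inside the sampled range
#' @return a one-row data.frame with the curve's state columns
#' @export
stateAtPressure <- function(curve, pressure) {
  stopifnot(is(curve, "StressStrainCurve"), length(pressure) == 1L)
  s <- states(curve)
  p <- s$pressure_mmHg
  if (pressure < min(p) || pressure > max(p)) {
    stop("extrapolation refused: target pressure ", pressure,
         " mmHg outside sampled range [", min(p), ", ", max(p), "]",
         call. = FALSE)
  }
  hit <- which(p == pressure)
  if (length(hit) == 1L) return(s[hit, , drop = FALSE])
  i <- findInterval(pressure, p)
  w <- (pressure - p[i]) / (p[i + 1] - p[i])
  out <- s[i, , drop = FALSE]
  out[1, ] <- (1 - w) * s[i, ] + w * s[i + 1, ]
  rownames(out) <- NULL
  out
}

#' Circumferential tangent modulus at a target pressure
#'
#' Local slope of the circumferential stress-stretch curve,
#' `d sigma_theta / d lambda_theta`, evaluated at the stretch reached at
#' `pressure`, from local quadratics over the `points` states nearest (in
#' pressure) to the target -- robust to the 10 mmHg step discretization.
#'
#' The default `"parametric"` estimator fits both `sigma_theta(P)` and
#' `lambda_theta(P)` against the noise-free pressure and returns the ratio
#' of their derivatives: with measurement noise on the diameter, the
#' stretch increments between steps can be smaller than the noise, and a
#' direct regression of stress on noisy stretch (available as
#' `method = "direct"`) is then badly biased (errors-in-variables); both
#' coincide for clean data. `method = "fd"` is a central finite difference
#' on the two bracketing states.
#'
#' @param curve a [StressStrainCurve-class] with at least 3 states
#' @param pressure evaluation pressure (mmHg), inside the sampled range
#' @param method `"parametric"` (default), `"direct"` or `"fd"`
#' @param points number of nearest states for the quadratic fits (default
#'   5; all states if fewer)
#' @return tangent modulus in MPa
#' @export
tangentModulus <- function(curve, pressure,
                           method = c("parametric", "direct", "fd"),
                           points = 5L) {
  stopifnot(is(curve, "StressStrainCurve"))
  method <- match.arg(method)
  s <- states(curve)
  if (nrow(s) < 3L) stop("need >= 3 states for a tangent modulus",
                         call. = FALSE)
  at <- stateAtPressure(curve, pressure)
  if (method == "fd") {
    i <- findInterval(pressure, s$pressure_mmHg,
                      all.inside = TRUE)
    dl <- s$circ_stretch[i + 1] - s$circ_stretch[i]
    if (abs(dl) < 1e-12) stop("ill-conditioned fit: identical stretches",
                              call. = FALSE)
    return((s$circ_stress_kPa[i + 1] - s$circ_stress_kPa[i]) / dl / 1000)
  }
  k <- min(points, nrow(s))
  sel <- order(abs(s$pressure_mmHg - pressure))[seq_len(k)]
  x <- s$circ_stretch[sel]
  y <- s$circ_stress_kPa[sel]
  if (stats::sd(x) < 1e-12) {
    stop("ill-conditioned fit: identical stretches", call. = FALSE)
  }
  if (method == "direct") {
    # quadratic in (stretch, stress), centered for conditioning
    x0 <- at$circ_stretch
    fit <- stats::lm(y ~ I(x - x0) + I((x - x0)^2))
    return(stats::coef(fit)[["I(x - x0)"]] / 1000)
  }
  p <- s$pressure_mmHg[sel] - pressure
  dStress <- stats::coef(stats::lm(y ~ p + I(p^2)))[["p"]]
  dStretch <- stats::coef(stats::lm(x ~ p + I(p^2)))[["p"]]
  if (abs(dStretch) < 1e-12) {
    stop("ill-conditioned fit: identical stretches", call. = FALSE)
  }
  dStress / dStretch / 1000
}

#' Full mechanical characterization of one specimen
#'
#' Convenience wrapper: estimates the in vivo axial stretch, processes the
#' sweep closest to it, and evaluates the deformed state and circumferential
#' tangent modulus at the specimen's mean arterial pressure.
#'
#' When the recorded MAP lies outside the tested pressure range (common:
#' physiological MAP can exceed the 120 mmHg protocol ceiling) the evaluation
#' pressure is clamped to the nearest sampled pressure rather than
#' extrapolated (`mapPolicy = "clamp"`, the default; `"strict"` propagates
#' the extrapolation refusal).
#'
#' @param dataset a [BiaxialDataset-class]
#' @param mapPolicy `"clamp"` (default) or `"strict"`; see Details
#' @param ... passed to [estimateInVivoStretch()]
#' @return list with elements `inVivoStretch`
#'   ([InVivoStretchEstimate-class]), `curve` (the processed in vivo sweep),
#'   `mapState` (one-row data.frame), `tangentModulusMPa` and
#'   `evalPressure_mmHg` (the pressure actually used)
#' @export
characterizeSpecimen <- function(dataset, mapPolicy = c("clamp", "strict"),
                                 ...) {
  stopifnot(is(dataset, "BiaxialDataset"))
  mapPolicy <- match.arg(mapPolicy)
  est <- estimateInVivoStretch(dataset, ...)
  lz <- vapply(records(dataset), axialStretch, numeric(1))
  best <- records(dataset)[[which.min(abs(lz - stretchValue(est)))]]
  curve <- processRecord(best, geometry(dataset))
  p <- states(curve)$pressure_mmHg
  evalP <- mapPressure(dataset)
  if (mapPolicy == "clamp") evalP <- min(max(evalP, min(p)), max(p))
  list(inVivoStretch = est,
       curve = curve,
       mapState = stateAtPressure(curve, evalP),
       tangentModulusMPa = tangentModulus(curve, evalP),
       evalPressure_mmHg = evalP)
}
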
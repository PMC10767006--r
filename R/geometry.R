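## Kinematics and thin-wall stress formulas for extension-inflation analysis.

#' Unloaded geometry from manually traced ring circumferences
#'
#' Unloaded ring dimensions are obtained by tracing the outer and inner
#' circumference of a thin arterial ring; diameters follow as
#' circumference / pi.
#'
#' @param outerCircumference traced outer circumference (mm)
#' @param innerCircumference traced inner circumference (mm)
#' @return an [UnloadedGeometry-class]
#' @examples
#' geometryFromRingCircumferences(pi, 0.8 * pi)
#' @export
geometryFromRingCircumferences <- function(outerCircumference,
                                           innerCircumference) {
  if (!is.finite(outerCircumference) || !is.finite(innerCircumference) ||
      innerCircumference <= 0 || outerCircumference <= innerCircumference) {
    stop("invalid geometry: need outer circumference > inner circumference ",
         "> 0", call. = FALSE)
  }
  UnloadedGeometry(outerCircumference / pi, innerCircumference / pi)
}

#' Deformed inner diameter from wall incompressibility
#'
#' The wall is assumed incompressible, so its cross-sectional material volume
#' is conserved: `di = sqrt(do^2 - (Do^2 - Di^2) / lambda_z)`. Vectorized over
#' `outerDiameter` (and `lambdaZ`).
#'
#' @param outerDiameter deformed outer diameter(s) do (mm)
#' @param geometry the reference [UnloadedGeometry-class]
#' @param lambdaZ axial stretch ratio(s), > 0
#' @return deformed inner diameter(s) di (mm), always < do
#' @examples
#' geo <- UnloadedGeometry(1.0, 0.8)
#' deformedInnerDiameter(1.1, geo, 2.0)
#' @export
deformedInnerDiameter <- function(outerDiameter, geometry, lambdaZ) {
  stopifnot(is(geometry, "UnloadedGeometry"))
  if (any(lambdaZ <= 0)) stop("lambdaZ must be > 0", call. = FALSE)
  Do <- geometry@outerDiameter  # accessor names are shadowed by arguments here
  Di <- geometry@innerDiameter
  arg <- outerDiameter^2 - (Do^2 - Di^2) / lambdaZ
  if (any(arg <= 0)) {
    stop("infeasible deformation: wall volume cannot fit inside the given ",
         "outer diameter (do^2 <= (Do^2 - Di^2)/lambda_z)", call. = FALSE)
  }
  sqrt(arg)
}

#' Mean biaxial Cauchy stresses of a thin-walled cylinder
#'
#' For a pressurized thin-walled cylinder carrying an axial force, the mean
#' (through-thickness averaged) Cauchy stresses are
#' `sigma_theta = P * ri / h` and
#' `sigma_z = (f + P * pi * ri^2) / (pi * h * (2 ri + h))`.
#' The pressure is converted from mmHg with 1 mmHg = 0.1333224 kPa before
#' use; with lengths in mm and forces in mN the stresses come out in kPa.
#' Vectorized over all arguments.
#'
#' @param pressure transmural pressure(s) P (mmHg)
#' @param innerRadius deformed inner radius/radii ri (mm), > 0
#' @param thickness deformed wall thickness(es) h (mm), > 0
#' @param axialForce measured axial force(s) f (mN)
#' @return list with components `circ` (sigma_theta, kPa) and `axial`
#'   (sigma_z, kPa)
#' @examples
#' cauchyStresses(120, innerRadius = 0.45, thickness = 0.09, axialForce = 0)
#' @export
cauchyStresses <- function(pressure, innerRadius, thickness, axialForce) {
  if (any(innerRadius <= 0) || any(thickness <= 0)) {
    stop("need innerRadius > 0 and thickness > 0", call. = FALSE)
  }
  pk <- pressure * .KPA_PER_MMHG
  list(circ = pk * innerRadius / thickness,
       axial = (axialForce + pk * pi * innerRadius^2) /
         (pi * thickness * (2 * innerRadius + thickness)))
}

#' Circumferential stretch ratio
#'
#' Deformed-to-unloaded circumference ratio. The default mid-wall convention,
#' `(do + di) / (Do + Di)`, matches the mean (through-thickness) character of
#' the thin-wall stresses; the inner-wall alternative `di / Di` is available
#' via `convention`.
#'
#' @param outerDiameter deformed outer diameter(s) (mm)
#' @param innerDiameter deformed inner diameter(s) (mm)
#' @param geometry reference [UnloadedGeometry-class]
#' @param convention `"midwall"` (default) or `"inner"`
#' @return circumferential stretch ratio(s)
#' @export
circumferentialStretch <- function(outerDiameter, innerDiameter, geometry,
                                   convention = c("midwall", "inner")) {
  convention <- match.arg(convention)
  stopifnot(is(geometry, "UnloadedGeometry"))
  if (any(innerDiameter <= 0) || any(outerDiameter <= innerDiameter)) {
    stop("need do > di > 0", call. = FALSE)
  }
  if (convention == "midwall") {
    (outerDiameter + innerDiameter) /
      (geometry@outerDiameter + geometry@innerDiameter)
  } else {
    innerDiameter / geometry@innerDiameter
  }
}
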
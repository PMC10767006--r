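# Thin-wall stress analysis: kinematics, stresses, in vivo stretch, MAP
# quantities.

test_that("ring circumferences give diameters and reject bad input", {
  geo <- geometryFromRingCircumferences(pi, 0.8 * pi)
  expect_equal(outerDiameter(geo), 1.0)
  expect_equal(innerDiameter(geo), 0.8)
  geo2 <- geometryFromRingCircumferences(2 * pi, pi)
  expect_equal(wallThickness(geo2), 0.5)
  expect_error(geometryFromRingCircumferences(1.0, 1.2), "invalid geometry")
  expect_error(geometryFromRingCircumferences(-1, -2), "invalid geometry")
})

test_that("incompressibility inner diameter matches hand evaluation", {
  geo <- UnloadedGeometry(1.0, 0.8)
  # identity configuration
  expect_equal(deformedInnerDiameter(1.0, geo, 1), 0.8)
  # direct evaluation: sqrt(1.21 - 0.36/2)
  expect_equal(deformedInnerDiameter(1.1, geo, 2.0), sqrt(1.21 - 0.18),
               tolerance = 1e-12)
  expect_lt(deformedInnerDiameter(1.1, geo, 2.0), 1.1)
  # wall volume cannot fit
  expect_error(deformedInnerDiameter(0.5, geo, 1.0), "infeasible")
})

test_that("Cauchy stresses match unit-checked hand evaluations", {
  expect_equal(unlist(cauchyStresses(0, 0.45, 0.09, 0)),
               c(circ = 0, axial = 0))
  # P = 120 mmHg = 15.99869 kPa, sigma_theta = P ri / h
  s <- cauchyStresses(120, 0.45, 0.09, 0)
  expect_equal(s$circ, 120 * 0.1333224 * 0.45 / 0.09, tolerance = 1e-12)
  expect_equal(s$circ, 79.99, tolerance = 1e-4)
  # axial stress with 8 mN force at 100 mmHg
  s2 <- cauchyStresses(100, 0.45, 0.09, 8)
  expect_equal(s2$axial,
               (8 + 100 * 0.1333224 * pi * 0.45^2) /
                 (pi * 0.09 * (2 * 0.45 + 0.09)),
               tolerance = 1e-12)
  expect_equal(s2$axial, 58.9, tolerance = 1e-3)
  expect_error(cauchyStresses(100, -1, 0.09, 0), "innerRadius")
})

test_that("circumferential stretch: reference, hand value, homogeneity", {
  geo <- UnloadedGeometry(1.0, 0.8)
  expect_equal(circumferentialStretch(1.0, 0.8, geo), 1)
  di <- deformedInnerDiameter(1.1, geo, 2.0)
  expect_equal(circumferentialStretch(1.1, di, geo), (1.1 + di) / 1.8,
               tolerance = 1e-12)
  expect_equal(circumferentialStretch(2.2, 2 * di, geo),
               2 * circumferentialStretch(1.1, di, geo))
  # inner-wall convention option
  expect_equal(circumferentialStretch(1.1, di, geo, convention = "inner"),
               di / 0.8)
})

test_that("processRecord yields one valid state per sample", {
  geo <- UnloadedGeometry(0.65, 0.33)
  rec <- InflationRecord(1.7, c(0, 40, 80, 120),
                         c(0.55, 0.58, 0.62, 0.66), c(8, 8, 8, 8))
  cur <- processRecord(rec, geo)
  s <- states(cur)
  expect_equal(nrow(s), 4)
  resid <- (s$outer_diameter_mm^2 - s$inner_diameter_mm^2) * 1.7 -
    (0.65^2 - 0.33^2)
  expect_lt(max(abs(resid)), 1e-9)
  # offending sample index is reported
  bad <- InflationRecord(1.7, c(0, 40), c(0.55, 0.20), c(8, 8))
  expect_error(processRecord(bad, geo), "sample 2")
  # empty records are rejected at construction
  expect_error(InflationRecord(1.7, numeric(0), numeric(0), numeric(0)))
})

test_that("in vivo stretch detection finds the constructed force plateau", {
  ds <- plateauDataset()
  est <- estimateInVivoStretch(ds)
  expect_equal(stretchValue(est), 1.80, tolerance = 1e-6)
  expect_true(withinThreshold(est))
  expect_equal(forceVariation(est), 0)
  expect_equal(nrow(perRecord(est)), 3)
})

test_that("in vivo stretch estimator edge cases behave as specified", {
  ds <- plateauDataset()
  one <- BiaxialDataset(geometry(ds), records(ds)[2], 100)
  expect_error(estimateInVivoStretch(one), "insufficient data")
  # no record below threshold: minimizer returned, flagged, warned
  noisy <- BiaxialDataset(geometry(ds), lapply(records(ds), function(r) {
    s <- samples(r)
    InflationRecord(axialStretch(r), s$pressure_mmHg, s$outer_diameter_mm,
                    s$axial_force_mN + 0.2 * seq_len(nrow(s)))
  }), 100)
  expect_warning(est <- estimateInVivoStretch(noisy), "threshold")
  expect_false(withinThreshold(est))
  expect_equal(stretchValue(est),
               perRecord(est)$axial_stretch[
                 which.min(perRecord(est)$force_variation_mN)],
               tolerance = 0.09)  # parabolic refinement stays near the grid
})

test_that("stateAtPressure interpolates linearly and refuses to extrapolate", {
  geo <- UnloadedGeometry(0.65, 0.33)
  rec <- InflationRecord(1.7, c(0, 40, 80, 120),
                         c(0.55, 0.58, 0.62, 0.66), c(8, 8.5, 9, 9.5))
  cur <- processRecord(rec, geo)
  s <- states(cur)
  expect_equal(stateAtPressure(cur, 80), s[3, , drop = FALSE],
               ignore_attr = TRUE)
  mid <- stateAtPressure(cur, 60)
  expect_equal(unlist(mid), unlist((s[2, ] + s[3, ]) / 2),
               ignore_attr = TRUE)
  expect_error(stateAtPressure(cur, 121), "extrapolation refused")
  expect_error(stateAtPressure(cur, -1), "extrapolation refused")
})

test_that("tangent modulus is exact for linear and quadratic curves", {
  geo <- UnloadedGeometry(0.65, 0.33)
  # build synthetic curves directly in state space
  mkCurve <- function(lt, sth) {
    n <- length(lt)
    do <- 0.6 + 0.01 * seq_len(n)
    di <- deformedInnerDiameter(do, geo, 1.7)
    new("StressStrainCurve", axialStretch = 1.7, geometry = geo,
        states = data.frame(
          pressure_mmHg = seq(0, by = 10, length.out = n),
          outer_diameter_mm = do, inner_diameter_mm = di,
          wall_thickness_mm = (do - di) / 2, circ_stretch = lt,
          axial_stretch = rep(1.7, n), axial_force_mN = rep(8, n),
          circ_stress_kPa = sth, axial_stress_kPa = rep(50, n)))
  }
  lt <- seq(1.0, 1.4, length.out = 9)
  # linear: sigma = 450 kPa * (lt - 1) => 0.45 MPa everywhere
  linC <- mkCurve(lt, 450 * (lt - 1))
  expect_equal(tangentModulus(linC, 40), 0.45, tolerance = 1e-10)
  expect_equal(tangentModulus(linC, 65), 0.45, tolerance = 1e-10)
  # quadratic: sigma = a lt^2 => modulus 2 a lt / 1000
  quadC <- mkCurve(lt, 300 * lt^2)
  at <- stateAtPressure(quadC, 50)
  expect_equal(tangentModulus(quadC, 50), 2 * 300 * at$circ_stretch / 1000,
               tolerance = 1e-10)
  # finite-difference option agrees on the linear curve
  expect_equal(tangentModulus(linC, 40, method = "fd"), 0.45,
               tolerance = 1e-10)
  # degenerate stretch spacing
  flat <- mkCurve(rep(1.2, 9), 450 * (lt - 1))
  expect_error(tangentModulus(flat, 40), "ill-conditioned")
})

test_that("characterizeSpecimen clamps an out-of-range MAP by default", {
  p <- arteryPreset("CTL")
  ds <- simulateDataset(p, quietProtocol(3), mapPressure = 124.8,
                        lambdaZStar = 1.705)
  ch <- characterizeSpecimen(ds)
  expect_equal(ch$evalPressure_mmHg, 120)
  expect_error(characterizeSpecimen(ds, mapPolicy = "strict"),
               "extrapolation refused")
})
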
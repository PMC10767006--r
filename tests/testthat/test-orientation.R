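# FFT orientation analysis: single orientations, equivariance, aggregation
# and the Qc/Qa ratio.

stripeImage <- function(angle, n = 128, period = 8, seed = 1) {
  # fibers (not gratings): parallel straight fibers at the given angle
  spec <- fiberFieldSpec(size = n, nFibers = 40,
                         orientation = list(angle = angle),
                         fiberLength = 80, gaussianNoiseSD = 0.01,
                         seed = seed)
  renderFiberImage(spec)$image
}

test_that("single-orientation images put the mode at the true angle", {
  h0 <- directionalityHistogram(stripeImage(0))
  expect_lt(abs(modalAngle(h0)), 2)
  h45 <- directionalityHistogram(stripeImage(45))
  expect_lt(abs(modalAngle(h45) - 45), 2)
  h90 <- directionalityHistogram(stripeImage(90))
  expect_lt(abs(abs(modalAngle(h90)) - 89), 2.01)  # +/-90 are the same axis
})

test_that("rotation equivariance holds within one bin", {
  base <- 0
  m0 <- modalAngle(directionalityHistogram(stripeImage(base)))
  for (delta in c(15, 30, 45, 90)) {
    m <- modalAngle(directionalityHistogram(stripeImage(base + delta)))
    expect_lt(abs(circDiff(m, m0 + delta)), 2.01,
              label = paste("delta", delta))
  }
})

test_that("histograms normalize to 1 and ignore intensity scale", {
  img <- stripeImage(30)
  h1 <- directionalityHistogram(img)
  expect_equal(sum(binWeights(h1)), 1, tolerance = 1e-9)
  h2 <- directionalityHistogram(img * 37.5)
  expect_equal(binWeights(h1), binWeights(h2), tolerance = 1e-12)
  expect_error(directionalityHistogram(matrix(1, 128, 128)),
               "undefined orientation")
  expect_error(directionalityHistogram(img[1:32, 1:32]), "64 x 64")
})

test_that("von Mises orientation fields are recovered within 3 degrees", {
  errs <- vapply(1:6, function(s) {
    spec <- fiberFieldSpec(nFibers = 200,
                           orientation = list(mean = 30, kappa = 8,
                                              stratified = TRUE),
                           fiberLength = 140, gaussianNoiseSD = 0.02,
                           seed = s)
    m <- circularMeanAngle(directionalityHistogram(
      renderFiberImage(spec)$image))
    abs(circDiff(m, 30))
  }, numeric(1))
  expect_lt(max(errs), 3)
})

test_that("higher concentration gives narrower estimated distributions", {
  circVar <- function(h) {
    th <- binCenters(h) * pi / 90
    1 - sqrt(sum(binWeights(h) * cos(th))^2 + sum(binWeights(h) * sin(th))^2)
  }
  cv <- vapply(c(2, 8, 32), function(kap) {
    spec <- fiberFieldSpec(size = 256, nFibers = 150,
                           orientation = list(mean = 20, kappa = kap,
                                              stratified = TRUE),
                           fiberLength = 120, gaussianNoiseSD = 0.02,
                           seed = 5)
    circVar(directionalityHistogram(renderFiberImage(spec)$image))
  }, numeric(1))
  expect_true(all(diff(cv) < 0))
})

test_that("stack averaging is linear and skips dead slices", {
  img <- stripeImage(20)
  st <- FiberImageStack(array(rep(img, 3), c(dim(img), 3)), 425 / 512)
  hs <- stackMeanHistogram(st)
  expect_equal(binWeights(hs),
               binWeights(directionalityHistogram(img)), tolerance = 1e-12)
  # two orthogonal slices -> bimodal average with equal mass
  i0 <- stripeImage(0, seed = 2)
  i90 <- stripeImage(90, seed = 3)
  st2 <- FiberImageStack(array(c(i0, i90), c(dim(i0), 2)), 425 / 512)
  h2 <- stackMeanHistogram(st2)
  w <- binWeights(h2)
  b <- binCenters(h2)
  near0 <- sum(w[abs(b) < 20])
  near90 <- sum(w[abs(b) > 70])
  expect_gt(near0, 0.15)
  expect_equal(near0, near90, tolerance = 0.1)
  # a constant slice is skipped with a message, not fatal
  st3 <- FiberImageStack(array(c(i0, matrix(0, nrow(i0), ncol(i0))),
                               c(dim(i0), 2)), 425 / 512)
  expect_message(h3 <- stackMeanHistogram(st3), "skipped")
  expect_equal(attr(h3, "skipped"), 1)
  st4 <- FiberImageStack(matrix(0, 64, 64), 425 / 512)
  expect_error(stackMeanHistogram(st4), "all slices")
})

test_that("depth maps localize an abrupt orientation interface", {
  spec <- fiberFieldSpec(size = 128, nFibers = 40, fiberLength = 80,
                         gaussianNoiseSD = 0.02, seed = 5)
  st <- renderDepthStack(shallow = list(mean = 0, kappa = 8),
                         deep = list(mean = 90, kappa = 8),
                         interfaceDepth = 14, nSlices = 30, spec)
  m <- depthOrientationMap(st$stack)
  expect_equal(dim(orientationMap(m)), c(30, 90))
  expect_lt(max(abs(rowSums(orientationMap(m)) - 1)), 1e-9)
  truthDepth <- st$truth$depths[st$truth$switchSlice]
  expect_lte(abs(interfaceDepth(m) - truthDepth), 2)
  # single-slice stack: 1-row map equal to its histogram
  one <- FiberImageStack(getSlice(st$stack, 1), 425 / 512)
  m1 <- depthOrientationMap(one)
  expect_equal(as.numeric(orientationMap(m1)),
               binWeights(directionalityHistogram(getSlice(st$stack, 1))),
               tolerance = 1e-12)
})

test_that("pure-noise stacks stay near the uniform angular level", {
  set.seed(99)
  vox <- array(abs(stats::rnorm(96 * 96 * 3, 1, 0.2)), c(96, 96, 3))
  m <- depthOrientationMap(FiberImageStack(vox, 1))
  expect_lt(max(orientationMap(m)), 2 / ncol(orientationMap(m)))
})

test_that("Qc/Qa windows behave as defined", {
  b <- seq(-89, 89, by = 2)
  uni <- OrientationHistogram(b, rep(1 / length(b), length(b)))
  expect_equal(as.numeric(qcQaRatio(uni)), 1, tolerance = 1e-9)
  w0 <- rep(0, length(b))
  w0[which.min(abs(b))] <- 1
  expect_equal(as.numeric(qcQaRatio(OrientationHistogram(b, w0))), 0)
  w90 <- rep(0, length(b))
  w90[1] <- 1
  expect_error(qcQaRatio(OrientationHistogram(b, w90)), "undefined ratio")
  # window widths are honored and reported
  r <- qcQaRatio(uni, axialHalfwidth = 10, circHalfwidth = 30)
  expect_equal(as.numeric(r), sum(abs(b) >= 60) / sum(abs(b) <= 10))
  expect_equal(attr(r, "windows"), c(axial = 10, circ = 30))
})
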
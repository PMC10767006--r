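# Fiber preprocessing, tracing and the straightness parameter.

test_that("straightness parameter: exact geometry cases", {
  expect_equal(straightness(cbind(c(0, 5), c(0, 0))), 1)
  expect_equal(straightness(cbind(c(0, 1, 1), c(0, 0, 1))), sqrt(2) / 2)
  # finely sampled sinusoid matches the quadrature oracle
  u <- seq(0, 40, by = 0.01)
  p <- cbind(u, 4 * sin(2 * pi * u / 40))
  expect_equal(straightness(p), analyticPs(4, 40), tolerance = 1e-4)
  expect_error(straightness(cbind(0, 0)), ">= 2 points")
  expect_error(straightness(cbind(c(0, 0), c(0, 0))), "distinct")
  loop <- cbind(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0))
  expect_error(straightness(loop), "loop fiber")
})

test_that("Ps is invariant under rigid motion and uniform scaling", {
  set.seed(4)
  u <- seq(0, 80, by = 0.5)
  p <- cbind(u, 5 * sin(2 * pi * u / 40))
  ps0 <- straightness(p)
  for (i in 1:5) {
    th <- stats::runif(1, 0, 2 * pi)
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    sc <- stats::runif(1, 0.2, 5)
    q <- sweep(p %*% Rm * sc, 2, stats::runif(2, -50, 50), "+")
    expect_equal(straightness(q), ps0, tolerance = 1e-12)
  }
})

test_that("Ps decreases strictly with sinusoid amplitude (oracle check)", {
  amps <- c(1, 2, 4, 6, 8)
  psA <- vapply(amps, analyticPs, numeric(1), wavelength = 40)
  expect_true(all(diff(psA) < 0))
  # polyline Ps tracks quadrature at each amplitude
  for (a in amps) {
    u <- seq(0, 80, by = 0.05)
    expect_equal(straightness(cbind(u, a * sin(2 * pi * u / 40))),
                 analyticPs(a, 40), tolerance = 1e-4)
  }
})

test_that("preprocessing is scale invariant and suppresses noise", {
  r <- separatedFiberImage()
  pre1 <- preprocessFibers(r$image)
  pre2 <- preprocessFibers(r$image * 12)
  expect_equal(pre1, pre2, tolerance = 1e-12)
  # noise-free rendering: thresholded preprocessed image overlaps the
  # rasterized truth mask (Dice)
  spec <- r$spec
  spec$gaussianNoiseSD <- 0
  clean <- renderFiberImage(spec)
  pre <- preprocessFibers(clean$image)
  bw <- pre > 0.05 * max(pre)  # the tracer's binarization
  # truth mask: pixels within ~2 px of any centerline point
  truthMask <- matrix(FALSE, 256, 256)
  px <- spec$pixelSize
  for (cl in attr(clean$truth, "centerlines")) {
    for (dr in -2:2) {
      for (dc in -2:2) {
        if (dr^2 + dc^2 > 4) next
        ij <- cbind(pmin(pmax(round(cl[, 2] / px + 0.5) + dr, 1), 256),
                    pmin(pmax(round(cl[, 1] / px + 0.5) + dc, 1), 256))
        truthMask[ij] <- TRUE
      }
    }
  }
  dice <- 2 * sum(bw & truthMask) / (sum(bw) + sum(truthMask))
  expect_gte(dice, 0.9)
  # pure noise: almost nothing survives thresholding relative to a real
  # fiber image's foreground
  set.seed(7)
  noise <- matrix(abs(stats::rnorm(256^2, 0, 0.05)), 256, 256)
  preN <- preprocessFibers(noise)
  expect_lt(mean(preN > 0), 0.01)
  expect_length(traceFibers(preN, 425 / 512), 0)
  # constant image: flagged empty
  flat <- preprocessFibers(matrix(3, 128, 128))
  expect_true(isTRUE(attr(flat, "empty")))
  expect_length(traceFibers(flat, 1), 0)
})

test_that("well-separated fibers are recovered one-to-one", {
  r <- separatedFiberImage()
  fl <- traceFibers(preprocessFibers(r$image), r$spec$pixelSize)
  expect_gte(length(fl), 9)
  expect_lte(length(fl), 11)
  # every truth centerline matched by a trace within 2 px mean deviation
  px <- r$spec$pixelSize
  devs <- vapply(attr(r$truth, "centerlines"), function(tc) {
    min(vapply(fl, function(p) {
      mean(apply(tc, 1, function(q) {
        sqrt(min((p[, 1] - q[1])^2 + (p[, 2] - q[2])^2))
      }))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(max(devs) / px, 2)
})

test_that("gap bridging follows maxGap", {
  img <- gapFiberImage()
  f4 <- traceFibers(img, 1, minLength = 10, maxGap = 4)
  f1 <- traceFibers(img, 1, minLength = 10, maxGap = 1)
  expect_length(f4, 1)
  expect_length(f1, 2)
  expect_gt(sum(sqrt(rowSums(diff(f4[[1]])^2))), 70)
})

test_that("traced median Ps recovers the analytic waviness", {
  for (a in c(0, 3, 6)) {
    spec <- fiberFieldSpec(size = 256, nFibers = 12, amplitude = a,
                           wavelength = 40, fiberLength = 160,
                           gaussianNoiseSD = 0.02, seed = 21 + a)
    r <- renderFiberImage(spec)
    fl <- traceFibers(preprocessFibers(r$image), spec$pixelSize)
    expect_gt(length(fl), 5)
    med <- stats::median(vapply(fl, straightness, numeric(1)))
    expect_lt(abs(med - analyticPs(a, 40)), 0.05)
  }
})

test_that("stack Ps analysis summarizes per-slice medians", {
  spec <- fiberFieldSpec(size = 256, nFibers = 12, amplitude = 4,
                         wavelength = 40, fiberLength = 160,
                         gaussianNoiseSD = 0.02, seed = 3)
  img <- renderFiberImage(spec)$image
  st <- FiberImageStack(array(rep(img, 3), c(dim(img), 3)), spec$pixelSize)
  ps <- stackPsAnalysis(st)
  expect_equal(ps$meanOfMedians, ps$medians[1])
  expect_equal(ps$sdOfMedians, 0)
  expect_equal(rowSums(ps$histograms), as.numeric(ps$nFibers))
  # amplitude grading over depth: medians strictly decrease and track the
  # quadrature oracle
  amps <- c(0, 3, 6)
  vox <- vapply(seq_along(amps), function(i) {
    s <- spec
    s$amplitude <- amps[i]
    s$seed <- 30 + i
    renderFiberImage(s)$image
  }, matrix(0, spec$size, spec$size))
  ps2 <- stackPsAnalysis(FiberImageStack(vox, spec$pixelSize))
  expect_true(all(diff(ps2$medians) < 0))
  expect_lt(max(abs(ps2$medians - vapply(amps, analyticPs, numeric(1),
                                         wavelength = 40))), 0.05)
  # explicit mean-of-medians arithmetic
  expect_equal(mean(c(0.90, 0.94)), 0.92)
  # all-empty stack errors
  expect_error(stackPsAnalysis(FiberImageStack(matrix(0, 96, 96), 1)),
               "no traceable")
})

test_that("axial stretch emulation straightens and saturates", {
  spec <- fiberFieldSpec(size = 256, nFibers = 12, amplitude = 7,
                         wavelength = 40,
                         orientation = list(mean = 0, kappa = 12),
                         fiberLength = 160, gaussianNoiseSD = 0.02,
                         seed = 9)
  base <- renderFiberImage(spec)$image
  stretches <- c(1, 1.3, 1.6, 1.9, 2.2)
  med <- vapply(stretches, function(s) {
    fl <- traceFibers(preprocessFibers(stretchImageAxial(base, s)),
                      spec$pixelSize)
    stats::median(vapply(fl, straightness, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) > -0.005))
  expect_gt(med[length(med)], 0.9)
  # plateau: late gains smaller than early gains
  expect_lt(med[5] - med[4], med[2] - med[1])
})
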
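# Shared fixtures: everything is generated in code at test time.

quietProtocol <- function(seed = 1L) {
  SimulationProtocol(diameterNoiseSD = 0, forceNoiseSD = 0, seed = seed)
}

# constructed three-sweep dataset with a perfect force plateau at lz = 1.80
plateauDataset <- function() {
  p <- seq(0, 120, by = 20)
  mkRec <- function(lz, f) InflationRecord(lz, p, 0.8 + 0.002 * p, f)
  BiaxialDataset(UnloadedGeometry(0.65, 0.33),
                 list(mkRec(1.71, 10 - 0.03 * p),
                      mkRec(1.80, rep(10, length(p))),
                      mkRec(1.89, 10 + 0.03 * p)),
                 mapPressure = 100)
}

# image of well-separated parallel wavy fibers with known centerlines
separatedFiberImage <- function(n = 10, angle = 15, amplitude = 3,
                                seed = 11) {
  px <- 425 / 512
  ctrs <- cbind(rep(128 * px, n),
                seq(25, 185, length.out = n) * px * 1.21)
  spec <- fiberFieldSpec(size = 256, nFibers = n,
                         orientation = list(angle = angle),
                         amplitude = amplitude, wavelength = 40,
                         fiberLength = 160, gaussianNoiseSD = 0.02,
                         centers = ctrs, seed = seed)
  c(renderFiberImage(spec), list(spec = spec))
}

# horizontal bar fiber broken by a 3-px gap (binary)
gapFiberImage <- function() {
  img <- matrix(0, 128, 128)
  img[63:65, c(21:57, 61:100)] <- 1
  img
}

# brute-force one-way ANOVA from the sums-of-squares definitions
bruteForceAnova <- function(groups) {
  all <- unlist(groups)
  g <- mean(all)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, numeric(1)) - g)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

circDiff <- function(a, b) (a - b + 90) %% 180 - 90
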
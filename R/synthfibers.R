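## Synthetic wavy-fiber renderer: 2-D images and depth-graded stacks with
## exactly known orientation distributions and waviness, the ground truth
## for the orientation and straightness analyses.

#' Von Mises random angles
#'
#' Best-Fisher rejection sampler for the von Mises distribution.
#'
#' @param n number of draws
#' @param mu mean direction (radians)
#' @param kappa concentration (> 0)
#' @return n angles in radians
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa > 0)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Analytic straightness of a sinusoidal fiber
#'
#' Chord-to-arc ratio over one period of `y = A sin(2 pi u / L)`: the arc
#' length is integrated by adaptive quadrature of
#' `sqrt(1 + (A k cos(k u))^2)`, `k = 2 pi / L`. Scale-invariant:
#' `analyticPs(c A, c L) = analyticPs(A, L)`.
#'
#' @param amplitude waviness amplitude A (um), >= 0
#' @param wavelength waviness wavelength L (um), > 0
#' @return straightness Ps in (0, 1]
#' @export
analyticPs <- function(amplitude, wavelength) {
  stopifnot(wavelength > 0, amplitude >= 0)
  if (amplitude == 0) return(1)
  k <- 2 * pi / wavelength
  arc <- stats::integrate(function(u) sqrt(1 + (amplitude * k * cos(k * u))^2),
                          0, wavelength, rel.tol = 1e-10,
                          subdivisions = 500L)$value
  wavelength / arc
}

#' Specification of a synthetic fiber field
#'
#' Defaults emulate the multiphoton acquisition geometry: a 425 x 425 um
#' field of view on a 512 px grid (pixel size 425/512 ~ 0.830 um). Fibers
#' are sinusoidally wavy lines with a Gaussian transverse profile; their
#' orientations are drawn from a von Mises distribution (or fixed), and an
#' integer number of waviness periods makes the centerline's chord/arc ratio
#' equal the analytic sinusoid value.
#'
#' @param size image side (px), default 512
#' @param pixelSize pixel size (um), default 425/512
#' @param nFibers number of fibers, default 30
#' @param orientation either `list(mean = deg, kappa = k)` for von Mises
#'   (add `stratified = TRUE` for a jittered systematic sample of the
#'   quantile function, which pins the realized mean direction to the
#'   nominal one) or `list(angle = deg)` for a fixed orientation; default
#'   von Mises `mean = 0, kappa = 8`
#' @param amplitude waviness amplitude (um), default 0 (straight)
#' @param wavelength waviness wavelength (um), default 40
#' @param fiberLength nominal fiber length (um), default 160 (rounded to an
#'   integer number of periods when wavy)
#' @param fiberWidth Gaussian transverse sigma (px), default 1.2
#' @param intensity peak intensity scale, default 1
#' @param gaussianNoiseSD additive Gaussian noise SD, default 0.02
#' @param poissonNoise apply shot noise, default FALSE
#' @param photonsPerUnit photon count at intensity 1 for shot noise,
#'   default 60
#' @param centers optional `nFibers x 2` matrix of fiber centers (um); by
#'   default centers are drawn uniformly (resampled to fit the frame)
#' @param seed integer seed (mandatory)
#' @return a list of class `"FiberFieldSpec"`
#' @export
fiberFieldSpec <- function(size = 512L, pixelSize = 425 / 512, nFibers = 30L,
                           orientation = list(mean = 0, kappa = 8),
                           amplitude = 0, wavelength = 40,
                           fiberLength = 160, fiberWidth = 1.2,
                           intensity = 1, gaussianNoiseSD = 0.02,
                           poissonNoise = FALSE, photonsPerUnit = 60,
                           centers = NULL, seed) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(size >= 16, pixelSize > 0, nFibers >= 0, amplitude >= 0,
            wavelength > 0, fiberLength > 0, fiberWidth > 0,
            gaussianNoiseSD >= 0, photonsPerUnit > 0)
  structure(list(size = as.integer(size), pixelSize = pixelSize,
                 nFibers = as.integer(nFibers), orientation = orientation,
                 amplitude = amplitude, wavelength = wavelength,
                 fiberLength = fiberLength, fiberWidth = fiberWidth,
                 intensity = intensity, gaussianNoiseSD = gaussianNoiseSD,
                 poissonNoise = poissonNoise,
                 photonsPerUnit = photonsPerUnit,
                 centers = centers,
                 seed = as.integer(seed)),
            class = "FiberFieldSpec")
}

## numeric von Mises quantile (radians, centered on mu)
.qvonmises <- function(p, mu, kappa) {
  th <- seq(-pi, pi, length.out = 4097L)
  d <- exp(kappa * cos(th))
  cdf <- cumsum(d)
  cdf <- (cdf - cdf[1]) / (cdf[length(cdf)] - cdf[1])
  mu + stats::approx(cdf, th, xout = p, ties = "ordered")$y
}

## draw all n orientations (deg in [-90, 90)) for a field.
## stratified = TRUE replaces iid von Mises draws by a jittered systematic
## sample of the quantile function, so the realized mean direction matches
## the nominal one without angular sampling noise.
.drawAngles <- function(orientation, n) {
  if (!is.null(orientation$angle)) {
    a <- rep(orientation$angle, n)
  } else if (isTRUE(orientation$stratified)) {
    p <- (seq_len(n) - 0.5 + stats::runif(n, -0.45, 0.45)) / n
    a <- sample(.qvonmises(p, orientation$mean * pi / 180,
                           orientation$kappa)) * 180 / pi
  } else {
    a <- rvonmises(n, orientation$mean * pi / 180, orientation$kappa) *
      180 / pi
  }
  (a + 90) %% 180 - 90
}

## Gaussian stamp accumulation of a polyline sampled at subpixel spacing
.rasterize <- function(img, xs, ys, sigma, gain) {
  nr <- nrow(img)
  nc <- ncol(img)
  rad <- ceiling(3 * sigma)
  off <- -rad:rad
  for (s in seq_along(xs)) {
    cx <- xs[s]
    cy <- ys[s]
    j0 <- round(cx)
    i0 <- round(cy)
    ii <- i0 + off
    jj <- j0 + off
    okI <- ii >= 1 & ii <= nr
    okJ <- jj >= 1 & jj <= nc
    if (!any(okI) || !any(okJ)) next
    gi <- exp(-((ii - cy)^2) / (2 * sigma^2))[okI]
    gj <- exp(-((jj - cx)^2) / (2 * sigma^2))[okJ]
    img[ii[okI], jj[okJ]] <- img[ii[okI], jj[okJ]] + gain * outer(gi, gj)
  }
  img
}

#' Render a synthetic fiber image with known ground truth
#'
#' Fibers are sinusoidally perturbed straight lines rasterized with a
#' Gaussian transverse profile; additive Gaussian and optional Poisson shot
#' noise are applied last. Identical seeds give identical images. Fiber
#' centers are resampled (up to 60 tries) until the whole centerline fits
#' the frame; a fiber that still does not fit is clipped, its truth
#' restricted to the in-frame portion and flagged.
#'
#' @param spec a [fiberFieldSpec()]
#' @return list with `image` (matrix in `[0, ~1]`), and `truth`: a
#'   data.frame (fiber, angle_deg, analytic_ps, polyline_ps, clipped) plus
#'   attribute `"centerlines"` (list of n x 2 matrices, um, x = axial)
#' @export
renderFiberImage <- function(spec) {
  stopifnot(inherits(spec, "FiberFieldSpec"))
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$size
  img <- matrix(0, n, n)
  px <- spec$pixelSize
  wavy <- spec$amplitude > 0
  lenU <- if (wavy) {
    max(1, round(spec$fiberLength / spec$wavelength)) * spec$wavelength
  } else {
    spec$fiberLength
  }
  step <- px * 0.4
  u <- seq(-lenU / 2, lenU / 2, by = step)
  aPs <- if (wavy) analyticPs(spec$amplitude, spec$wavelength) else 1
  rows <- vector("list", spec$nFibers)
  lines <- vector("list", spec$nFibers)
  allAngles <- .drawAngles(spec$orientation, spec$nFibers)
  for (fidx in seq_len(spec$nFibers)) {
    ang <- allAngles[fidx]
    th <- ang * pi / 180
    e <- c(cos(th), sin(th))
    ep <- c(-sin(th), cos(th))
    phase <- stats::runif(1, 0, 2 * pi)
    dev <- if (wavy) {
      spec$amplitude * sin(2 * pi * u / spec$wavelength + phase)
    } else {
      rep(0, length(u))
    }
    clipped <- TRUE
    if (!is.null(spec$centers)) {
      ctr <- spec$centers[fidx, ]
      xs <- ctr[1] + u * e[1] + dev * ep[1]
      ys <- ctr[2] + u * e[2] + dev * ep[2]
      clipped <- !all(xs >= px, xs <= (n - 1) * px,
                      ys >= px, ys <= (n - 1) * px)
    } else {
      for (try in 1:60) {
        ctr <- stats::runif(2, 0, n * px)
        xs <- ctr[1] + u * e[1] + dev * ep[1]
        ys <- ctr[2] + u * e[2] + dev * ep[2]
        if (all(xs >= px, xs <= (n - 1) * px, ys >= px, ys <= (n - 1) * px)) {
          clipped <- FALSE
          break
        }
      }
    }
    if (clipped) {
      keep <- xs >= 0 & xs <= n * px & ys >= 0 & ys <= n * px
      if (sum(keep) < 2) {
        stop("fiber entirely outside the frame after retries", call. = FALSE)
      }
      xs <- xs[keep]
      ys <- ys[keep]
    }
    img <- .rasterize(img, xs / px + 0.5, ys / px + 0.5, spec$fiberWidth,
                      spec$intensity * 0.4)
    pl <- cbind(x_um = xs, y_um = ys)
    lines[[fidx]] <- pl
    rows[[fidx]] <- data.frame(fiber = fidx, angle_deg = ang,
                               analytic_ps = aPs,
                               polyline_ps = straightness(pl),
                               clipped = clipped)
  }
  if (spec$nFibers > 0 && max(img) > 0) {
    img <- img / max(img) * spec$intensity
  }
  if (spec$poissonNoise) {
    img <- matrix(stats::rpois(length(img),
                               pmax(img, 0) * spec$photonsPerUnit) /
                    spec$photonsPerUnit, n, n)
  }
  if (spec$gaussianNoiseSD > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, spec$gaussianNoiseSD),
                        n, n)
  }
  img <- pmax(img, 0)
  truth <- if (spec$nFibers > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(fiber = integer(), angle_deg = numeric(),
               analytic_ps = numeric(), polyline_ps = numeric(),
               clipped = logical())
  }
  attr(truth, "centerlines") <- lines
  list(image = img, truth = truth)
}

#' Render a depth-graded fiber stack with an orientation interface
#'
#' Slices shallower than `interfaceDepth` draw orientations from the
#' `shallow` distribution, deeper slices from `deep`, emulating the abrupt
#' axial-to-circumferential reorientation at the adventitia-media interface.
#'
#' @param shallow,deep orientation lists as in [fiberFieldSpec()]
#' @param interfaceDepth interface depth (um), strictly inside the stack
#' @param nSlices number of slices
#' @param spec base [fiberFieldSpec()] (its orientation field is overridden
#'   per slice; its seed seeds slice i with `seed + i`)
#' @param zSpacing slice spacing (um), default 1
#' @param channel stack channel label, default `"elastin"`
#' @return list with `stack` (a [FiberImageStack-class]) and `truth`
#'   (list: `switchSlice`, the 1-based index of the first deep slice, and
#'   `depths`)
#' @export
renderDepthStack <- function(shallow, deep, interfaceDepth, nSlices, spec,
                             zSpacing = 1, channel = "elastin") {
  stopifnot(inherits(spec, "FiberFieldSpec"), nSlices >= 1)
  depths <- (seq_len(nSlices) - 1) * zSpacing
  if (nSlices > 1 &&
      (interfaceDepth <= 0 || interfaceDepth >= max(depths) + zSpacing)) {
    stop("interfaceDepth must lie strictly inside the stack", call. = FALSE)
  }
  vox <- array(0, dim = c(spec$size, spec$size, nSlices))
  for (i in seq_len(nSlices)) {
    s <- spec
    s$orientation <- if (depths[i] < interfaceDepth) shallow else deep
    s$seed <- spec$seed + i
    vox[, , i] <- renderFiberImage(s)$image
  }
  list(stack = FiberImageStack(vox, spec$pixelSize, zSpacing,
                               channel = channel),
       truth = list(switchSlice = if (nSlices > 1) {
                      which(depths >= interfaceDepth)[1]
                    } else NA_integer_,
                    depths = depths))
}
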
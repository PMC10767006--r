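## FFT-based fiber orientation analysis. The power spectrum of a fibrous
## image concentrates along the direction perpendicular to the fibers;
## binning spectral power by angle over an annulus of spatial frequencies
## and rotating by 90 degrees yields the fiber orientation distribution.
## Convention: 0 deg = image x axis = vessel axis, +/-90 deg =
## circumferential; angles live on [-90, 90).

#' Orientation distribution of a single image by FFT power binning
#'
#' Mean-subtracts, applies a 2-D Hann window (suppresses edge/DC leakage and
#' pixel-grid anisotropy), computes the FFT power spectrum, and accumulates
#' power into uniform angular bins over an annulus of spatial frequencies.
#' Spectral angles are rotated by 90 degrees into fiber space.
#'
#' @param image numeric matrix, at least 64 x 64, finite intensities
#' @param binWidth angular bin width (degrees), default 2
#' @param rMin inner annulus radius in frequency pixels (cycles per image
#'   along the shorter side), default 2: excludes DC and large-scale shading
#' @param rMaxFrac outer annulus radius as a fraction of Nyquist, default 0.9:
#'   excludes corner frequencies sampled anisotropically
#' @param blockSize Welch refinement: side (px) of 50-percent-overlapping
#'   square blocks whose angular power is averaged, reducing interference
#'   speckle in the estimate. The default `"auto"` uses half the shorter
#'   image side when the image is at least 256 px, and the whole image
#'   otherwise; `NULL` forces a single whole-image FFT
#' @return an [OrientationHistogram-class]
#' @export
directionalityHistogram <- function(image, binWidth = 2, rMin = 2,
                                    rMaxFrac = 0.9, blockSize = "auto") {
  stopifnot(is.matrix(image))
  nr <- nrow(image)
  nc <- ncol(image)
  if (nr < 64 || nc < 64) stop("image must be at least 64 x 64", call. = FALSE)
  if (any(!is.finite(image))) stop("intensities must be finite", call. = FALSE)
  if (max(image) == min(image)) {
    stop("undefined orientation: constant image (zero spectrum after DC ",
         "removal)", call. = FALSE)
  }
  nb <- round(180 / binWidth)
  if (abs(nb * binWidth - 180) > 1e-9) {
    stop("binWidth must divide 180 degrees", call. = FALSE)
  }
  if (identical(blockSize, "auto")) {
    blockSize <- if (min(nr, nc) >= 256) floor(min(nr, nc) / 2) else NULL
  }
  if (is.null(blockSize) || blockSize >= min(nr, nc)) {
    ap <- .angularPower(image, binWidth, rMin, rMaxFrac, nb)
    w <- ap$power
    cnt <- ap$count
  } else {
    B <- as.integer(blockSize)
    step <- max(1L, B %/% 2L)
    w <- numeric(nb)
    cnt <- numeric(nb)
    for (i0 in unique(c(seq(1L, nr - B + 1L, by = step), nr - B + 1L))) {
      for (j0 in unique(c(seq(1L, nc - B + 1L, by = step), nc - B + 1L))) {
        ap <- .angularPower(image[i0:(i0 + B - 1L), j0:(j0 + B - 1L)],
                            binWidth, rMin, rMaxFrac, nb)
        w <- w + ap$power
        cnt <- cnt + ap$count
      }
    }
  }
  # mean power per angular bin: the frequency grid samples angles
  # anisotropically (axis-aligned spectral lines fall into single bins), so
  # summed power would bias flat spectra toward the axes
  w <- ifelse(cnt > 0, w / pmax(cnt, 1), 0)
  tot <- sum(w)
  if (tot <= 0) stop("undefined orientation: empty spectrum", call. = FALSE)
  OrientationHistogram(seq(-90 + binWidth / 2, 90 - binWidth / 2,
                           by = binWidth), w / tot)
}

## angular binning of one windowed FFT power spectrum: per-bin total power
## and pixel counts
.angularPower <- function(image, binWidth, rMin, rMaxFrac, nb) {
  nr <- nrow(image)
  nc <- ncol(image)
  img <- image - mean(image)
  if (max(abs(img)) == 0) {
    return(list(power = numeric(nb), count = numeric(nb)))
  }
  hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
  img <- img * outer(hann(nr), hann(nc))
  pw <- Mod(stats::fft(img))^2
  ky <- 0:(nr - 1)
  ky[ky > nr / 2] <- ky[ky > nr / 2] - nr
  kx <- 0:(nc - 1)
  kx[kx > nc / 2] <- kx[kx > nc / 2] - nc
  fy <- matrix(ky / nr, nr, nc)
  fx <- matrix(kx / nc, nr, nc, byrow = TRUE)
  r <- sqrt(fx^2 + fy^2)
  sel <- r >= rMin / min(nr, nc) & r <= rMaxFrac * 0.5
  # fiber angle = spectral angle + 90, folded to [-90, 90)
  ang <- (atan2(fy[sel], fx[sel]) * 180 / pi + 180) %% 180 - 90
  idx <- factor(pmin(floor((ang + 90) / binWidth) + 1, nb),
                levels = seq_len(nb))
  list(power = vapply(split(pw[sel], idx), sum, numeric(1)),
       count = as.numeric(table(idx)))
}

#' Stack-averaged orientation distribution
#'
#' Per-slice distributions averaged bin-wise and renormalized. Slices with
#' undefined orientation (e.g. empty deep slices) are skipped; the skipped
#' count is attached as attribute `"skipped"` and reported via a message.
#'
#' @param stack a [FiberImageStack-class]
#' @param ... passed to [directionalityHistogram()]
#' @return an [OrientationHistogram-class]
#' @export
stackMeanHistogram <- function(stack, ...) {
  stopifnot(is(stack, "FiberImageStack"))
  hs <- lapply(seq_len(nSlices(stack)), function(i) {
    tryCatch(directionalityHistogram(getSlice(stack, i), ...),
             error = function(e) NULL)
  })
  ok <- !vapply(hs, is.null, logical(1))
  if (!any(ok)) stop("all slices have undefined orientation", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " slice(s) skipped (undefined orientation)")
  }
  w <- rowMeans(vapply(hs[ok], binWeights,
                       numeric(length(binWeights(hs[ok][[1]])))))
  out <- OrientationHistogram(binCenters(hs[ok][[1]]), w / sum(w))
  attr(out, "skipped") <- sum(!ok)
  out
}

#' Depth-resolved orientation map
#'
#' One normalized orientation distribution per slice, indexed by imaging
#' depth (first slice at 0 um, the outer adventitial surface). The modal
#' angle of each row, drifting from near 0 (axial) to near +/-90
#' (circumferential), localizes the adventitia-media interface.
#'
#' @param stack a [FiberImageStack-class]
#' @param ... passed to [directionalityHistogram()]
#' @return a [DepthOrientationMap-class]; rows for skipped slices are
#'   dropped (their depths with them)
#' @export
depthOrientationMap <- function(stack, ...) {
  stopifnot(is(stack, "FiberImageStack"))
  n <- nSlices(stack)
  hs <- lapply(seq_len(n), function(i) {
    tryCatch(directionalityHistogram(getSlice(stack, i), ...),
             error = function(e) NULL)
  })
  ok <- !vapply(hs, is.null, logical(1))
  if (!any(ok)) stop("all slices have undefined orientation", call. = FALSE)
  if (any(!ok)) {
    message(sum(!ok), " slice(s) skipped (undefined orientation)")
  }
  m <- do.call(rbind, lapply(hs[ok], binWeights))
  new("DepthOrientationMap", map = m,
      depths = (which(ok) - 1) * zSpacing(stack),
      angles = binCenters(hs[ok][[1]]))
}

#' Circumferential-to-axial orientation ratio (Qc/Qa)
#'
#' Fraction of orientation mass within `circHalfwidth` of the
#' circumferential axis (+/-90 deg) divided by the fraction within
#' `axialHalfwidth` of the vessel axis (0 deg). Window half-widths default
#' to 20 degrees and are reported in the result's attributes.
#'
#' @param hist an [OrientationHistogram-class]
#' @param axialHalfwidth half-width of the axial window (deg), default 20
#' @param circHalfwidth half-width of the circumferential window (deg),
#'   default 20
#' @return the ratio Qc/Qa (dimensionless) with attribute `"windows"`
#' @export
qcQaRatio <- function(hist, axialHalfwidth = 20, circHalfwidth = 20) {
  stopifnot(is(hist, "OrientationHistogram"))
  b <- binCenters(hist)
  w <- binWeights(hist)
  qa <- sum(w[abs(b) <= axialHalfwidth])
  qc <- sum(w[abs(b) >= 90 - circHalfwidth])
  if (qa == 0) {
    stop("undefined ratio: no orientation mass in the axial window",
         call. = FALSE)
  }
  out <- qc / qa
  attr(out, "windows") <- c(axial = axialHalfwidth, circ = circHalfwidth)
  out
}

#' Modal angle of an orientation histogram
#' @param hist an [OrientationHistogram-class]
#' @return the bin center (degrees) carrying the most mass
#' @export
modalAngle <- function(hist) {
  stopifnot(is(hist, "OrientationHistogram"))
  binCenters(hist)[which.max(binWeights(hist))]
}

#' Circular mean angle of an orientation histogram
#'
#' Mean direction on the 180-degree (axial) circle: angles are doubled,
#' averaged as unit vectors, and halved back.
#'
#' @param hist an [OrientationHistogram-class]
#' @return mean angle in degrees on `[-90, 90)`
#' @export
circularMeanAngle <- function(hist) {
  stopifnot(is(hist, "OrientationHistogram"))
  th <- binCenters(hist) * pi / 90  # doubled angle in radians
  w <- binWeights(hist)
  m <- atan2(sum(w * sin(th)), sum(w * cos(th))) / 2 * 180 / pi
  (m + 90) %% 180 - 90
}

#' Depth at which orientation crosses from axial to circumferential
#'
#' Scans the depth map for the first depth whose modal angle magnitude
#' exceeds 45 degrees; with an abrupt axial-to-circumferential transition
#' this localizes the adventitia-media interface.
#'
#' @param map a [DepthOrientationMap-class]
#' @return crossing depth (um), or `NA` if the map never crosses
#' @export
interfaceDepth <- function(map) {
  stopifnot(is(map, "DepthOrientationMap"))
  modal <- abs(angles(map)[apply(orientationMap(map), 1, which.max)])
  i <- which(modal > 45)
  if (length(i) == 0) return(NA_real_)
  depths(map)[i[1]]
}
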
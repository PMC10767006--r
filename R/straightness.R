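## Collagen fiber straightness: difference-of-Gaussians preprocessing,
## distance-transform ridge tracing (CT-FIRE-like), and the straightness
## parameter Ps = endpoint distance / arc length.

#' Preprocess a fiber image for tracing
#'
#' Difference-of-Gaussians band-pass (a dependency-light stand-in for
#' curvelet denoising) followed by clipping at zero and contrast
#' normalization to `[0, 1]`. Output is invariant to positive intensity
#' scaling of the input. A constant input returns an all-zero image flagged
#' with attribute `"empty"`.
#'
#' A noise floor adapted to the image's own pixel noise is cleared to
#' zero: the noise SD is estimated robustly from horizontal
#' nearest-neighbor differences (structure is sparse, so the median
#' difference reflects noise), propagated through the DoG kernel's exact
#' L2 gain, and multiplied by `noiseK`. The floor vanishes for noise-free
#' input.
#'
#' @param image numeric matrix
#' @param sigmaLow fine (fiber-scale) Gaussian sigma in px, default 1
#' @param sigmaHigh coarse (background-scale) Gaussian sigma in px,
#'   default 6
#' @param noiseK noise-floor multiplier on the propagated noise SD,
#'   default 3
#' @return matrix in `[0, 1]`
#' @export
preprocessFibers <- function(image, sigmaLow = 1, sigmaHigh = 6,
                             noiseK = 3) {
  stopifnot(is.matrix(image), sigmaLow < sigmaHigh)
  dog <- gaussianBlur(image, sigmaLow) - gaussianBlur(image, sigmaHigh)
  # pixel-noise SD from neighbor differences; diff ~ N(0, 2 sigma^2)
  dx <- image[, -1, drop = FALSE] - image[, -ncol(image), drop = FALSE]
  sigmaNoise <- 1.4826 * stats::median(abs(dx)) / sqrt(2)
  # L2 gain of the (separable) DoG kernel: Var[dog] = gain^2 Var[noise]
  k1 <- .gaussianKernel1d(sigmaLow)
  k2 <- .gaussianKernel1d(sigmaHigh)
  pad <- (length(k2) - length(k1)) / 2
  k1p <- c(rep(0, pad), k1, rep(0, pad))
  gain <- sqrt(sum(k1p^2)^2 - 2 * sum(k1p * k2)^2 + sum(k2^2)^2)
  dog[dog < noiseK * sigmaNoise * gain] <- 0
  dog[dog < 0] <- 0
  m <- max(dog)
  if (m == 0) {
    out <- dog
    attr(out, "empty") <- TRUE
    return(out)
  }
  dog / m
}

#' Straightness parameter of a traced fiber
#'
#' `Ps` = Euclidean distance between the endpoints divided by the arc
#' length of the polyline; 1 for a straight fiber, < 1 for an undulated
#' one. Invariant under rigid motion and uniform scaling.
#'
#' @param polyline n x 2 matrix of points (any length unit), n >= 2,
#'   consecutive points distinct
#' @return Ps in (0, 1]
#' @examples
#' straightness(cbind(c(0, 1, 1), c(0, 0, 1)))  # right angle: sqrt(2)/2
#' @export
straightness <- function(polyline) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs >= 2 points", call. = FALSE)
  seg <- sqrt(rowSums(diff(polyline)^2))
  if (any(seg == 0)) stop("consecutive points must be distinct",
                          call. = FALSE)
  arc <- sum(seg)
  chord <- sqrt(sum((polyline[nrow(polyline), ] - polyline[1, ])^2))
  if (chord == 0) {
    stop("loop fiber: coincident endpoints with nonzero arc length",
         call. = FALSE)
  }
  min(chord / arc, 1)
}

## local orientation (radians) from PCA of foreground coordinates near
## (r0, c0), weighted by the distance transform
.localOrientation <- function(edt, r0, c0, radius = 4L) {
  nr <- nrow(edt)
  nc <- ncol(edt)
  ii <- max(1, r0 - radius):min(nr, r0 + radius)
  jj <- max(1, c0 - radius):min(nc, c0 + radius)
  sub <- edt[ii, jj]
  w <- sub^2
  if (sum(w) == 0) return(0)
  ys <- matrix(ii, length(ii), length(jj))
  xs <- matrix(jj, length(ii), length(jj), byrow = TRUE)
  mx <- sum(w * xs) / sum(w)
  my <- sum(w * ys) / sum(w)
  sxx <- sum(w * (xs - mx)^2)
  syy <- sum(w * (ys - my)^2)
  sxy <- sum(w * (xs - mx) * (ys - my))
  0.5 * atan2(2 * sxy, sxx - syy)
}

## trace one direction from (x0, y0) with heading th0 (radians);
## returns matrix of visited (x, y) excluding the start point. Stops after
## running for more than `claimTol` consecutive steps on pixels claimed by
## an earlier fiber (crossing another fiber briefly is allowed), dropping
## those trailing steps.
.traceDir <- function(edt, bw, claimed, x0, y0, th0, maxGap,
                      maxTurn = 35 * pi / 180, maxSteps = 4000L,
                      claimTol = 5L) {
  nr <- nrow(bw)
  nc <- ncol(bw)
  pts <- matrix(NA_real_, maxSteps, 2)
  np <- 0L
  x <- x0
  y <- y0
  th <- th0
  thRef <- th0  # smoothed heading, used to jump gaps in a straight line
  gap <- 0L
  claimedRun <- 0L
  offs <- seq(-1.5, 1.5, by = 0.5)
  for (s in seq_len(maxSteps)) {
    axp <- x + cos(th)
    ayp <- y + sin(th)
    # re-center on the distance-transform ridge along the normal
    # (small |t| penalty breaks plateau ties toward straight-ahead)
    bestV <- -1
    bx <- NA_real_
    by <- NA_real_
    for (t in offs) {
      qx <- axp - t * sin(th)
      qy <- ayp + t * cos(th)
      qi <- round(qy)
      qj <- round(qx)
      if (qi < 1 || qi > nr || qj < 1 || qj > nc || !bw[qi, qj]) next
      v <- .bilinear(edt, qx, qy) - 0.05 * abs(t)
      if (v > bestV) {
        bestV <- v
        bx <- qx
        by <- qy
      }
    }
    if (bestV < 0) {
      # no foreground across the normal: jump the gap along the smoothed
      # pre-gap heading
      if (gap == 0L) th <- thRef
      gap <- gap + 1L
      if (gap > maxGap) break
      x <- x + cos(th)
      y <- y + sin(th)
      if (x < 1 || x > nc || y < 1 || y > nr) break
      next
    }
    gap <- 0L
    newTh <- atan2(by - y, bx - x)
    dTh <- atan2(sin(newTh - th), cos(newTh - th))
    th <- th + max(-maxTurn, min(maxTurn, dTh))
    thRef <- atan2(0.85 * sin(thRef) + 0.15 * sin(th),
                   0.85 * cos(thRef) + 0.15 * cos(th))
    x <- x + cos(th)
    y <- y + sin(th)
    if (x < 1 || x > nc || y < 1 || y > nr) break
    if (claimed[round(y), round(x)]) {
      claimedRun <- claimedRun + 1L
      if (claimedRun > claimTol) {
        np <- np - claimedRun + 1L  # drop the claimed tail
        break
      }
    } else {
      claimedRun <- 0L
    }
    np <- np + 1L
    pts[np, ] <- c(x, y)
  }
  pts[seq_len(max(np, 0L)), , drop = FALSE]
}

## moving-average smoothing of a polyline (anti pixel-jitter)
.smoothPolyline <- function(p, win = 5L) {
  if (nrow(p) <= win) return(p)
  k <- rep(1 / win, win)
  half <- (win - 1L) %/% 2L
  sm <- apply(p, 2, function(v) stats::filter(v, k, sides = 2))
  idx <- (half + 1):(nrow(p) - half)
  out <- rbind(p[1, ], sm[idx, , drop = FALSE], p[nrow(p), ])
  out[!duplicated(out), , drop = FALSE]
}

#' Trace individual fibers by distance-transform ridge following
#'
#' Binarizes the (preprocessed) image, computes the
#' Euclidean distance transform, takes its local maxima as fiber nucleation
#' points, and extends each nucleation point bidirectionally along the local
#' fiber direction, re-centering on the ridge at every step and jumping
#' breaks of up to `maxGap` px. Fibers shorter than `minLength` are
#' discarded; pixels claimed by a fiber are not re-used as nucleation
#' points, so fibers do not share nucleation points.
#'
#' @param image preprocessed intensity matrix (see [preprocessFibers()])
#' @param pixelSize pixel size (um)
#' @param minLength minimum fiber arc length (um), default 25
#' @param maxGap largest bridgeable break along a fiber (px), default 4
#' @param minRidge minimum distance-transform value for a nucleation point
#'   (px), default 0.9
#' @param minForeground minimum fraction of trace points lying on
#'   foreground pixels, default 0.7: rejects speckle chains stitched
#'   together by gap jumps in noise
#' @param binarize `"relative"` (default): foreground is everything above
#'   `relThreshold` times the image maximum — stable after the adaptive
#'   noise floor of [preprocessFibers()], which leaves near-unimodal
#'   positive intensities that Otsu's bimodal criterion would oversplit;
#'   `"otsu"` applies Otsu's threshold to the whole image instead
#' @param relThreshold relative binarization threshold, default 0.05
#' @return list of n x 2 centerline matrices (um, columns x/y); empty list
#'   when nothing is traceable
#' @export
traceFibers <- function(image, pixelSize, minLength = 25, maxGap = 4L,
                        minRidge = 0.9, minForeground = 0.7,
                        binarize = c("relative", "otsu"),
                        relThreshold = 0.05) {
  stopifnot(is.matrix(image), pixelSize > 0)
  binarize <- match.arg(binarize)
  if (isTRUE(attr(image, "empty")) || max(image) == 0) return(list())
  thr <- if (binarize == "relative") {
    relThreshold * max(image)
  } else {
    otsuThreshold(image)
  }
  bw <- image > thr
  if (!any(bw)) return(list())
  edt <- distanceTransform(bw)
  nr <- nrow(bw)
  nc <- ncol(bw)
  # ridge points: distance-transform local maxima in the 8-neighborhood
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- edt
  isMax <- edt >= minRidge
  for (di in -1:1) {
    for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      isMax <- isMax & edt >= pad[2:(nr + 1) + di, 2:(nc + 1) + dj]
    }
  }
  cand <- which(isMax, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list())
  cand <- cand[order(edt[cand], decreasing = TRUE), , drop = FALSE]
  claimed <- matrix(FALSE, nr, nc)
  fibers <- list()
  for (k in seq_len(nrow(cand))) {
    r0 <- cand[k, 1]
    c0 <- cand[k, 2]
    if (claimed[r0, c0]) next
    th <- .localOrientation(edt, r0, c0)
    fwd <- .traceDir(edt, bw, claimed, c0, r0, th, maxGap)
    bck <- .traceDir(edt, bw, claimed, c0, r0, th + pi, maxGap)
    pl <- rbind(bck[rev(seq_len(nrow(bck))), , drop = FALSE],
                c(c0, r0), fwd)
    if (nrow(pl) < 3) next
    fgFrac <- mean(bw[cbind(pmin(pmax(round(pl[, 2]), 1), nr),
                            pmin(pmax(round(pl[, 1]), 1), nc))])
    if (fgFrac < minForeground) next
    pl <- .smoothPolyline(pl)
    seg <- sqrt(rowSums(diff(pl)^2))
    if (sum(seg) * pixelSize < minLength) next
    # claim a tube covering the full local fiber width
    for (s in seq_len(nrow(pl))) {
      ri <- round(pl[s, 2])
      ci <- round(pl[s, 1])
      if (ri < 1 || ri > nr || ci < 1 || ci > nc) next
      rad <- max(2L, as.integer(ceiling(edt[ri, ci])) + 1L)
      ii <- max(1, ri - rad):min(nr, ri + rad)
      jj <- max(1, ci - rad):min(nc, ci + rad)
      claimed[ii, jj] <- TRUE
    }
    fibers[[length(fibers) + 1L]] <- pl * pixelSize
  }
  fibers
}

#' Straightness analysis of a collagen stack
#'
#' Traces fibers in every slice, computes the per-fiber straightness
#' parameter, bins it into per-slice histograms (the 3-D-bar-plot view), and
#' summarizes each slice by the median of its raw per-fiber values. The
#' stack summary is the mean of the per-slice medians with its SD. Slices
#' with no traceable fiber are skipped and counted.
#'
#' @param stack a [FiberImageStack-class]
#' @param breaks histogram breaks on (0, 1], default `seq(0, 1, 0.05)`
#' @param preprocess apply [preprocessFibers()] per slice, default TRUE
#' @param ... passed to [traceFibers()]
#' @return list: `histograms` (slices x bins counts), `breaks`, `depths`
#'   (um), `medians` (per slice), `nFibers` (per slice), `perFiber`
#'   (data.frame slice/fiber/length_um/ps), `meanOfMedians`, `sdOfMedians`,
#'   `skippedSlices`
#' @export
stackPsAnalysis <- function(stack, breaks = seq(0, 1, by = 0.05),
                            preprocess = TRUE, ...) {
  stopifnot(is(stack, "FiberImageStack"))
  n <- nSlices(stack)
  px <- pixelSize(stack)
  hists <- matrix(0, n, length(breaks) - 1)
  medians <- rep(NA_real_, n)
  nf <- integer(n)
  per <- list()
  for (i in seq_len(n)) {
    img <- getSlice(stack, i)
    if (preprocess) img <- preprocessFibers(img)
    fl <- traceFibers(img, px, ...)
    if (length(fl) == 0) next
    ps <- vapply(fl, straightness, numeric(1))
    len <- vapply(fl, function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1))
    nf[i] <- length(ps)
    medians[i] <- stats::median(ps)
    hists[i, ] <- graphics::hist(ps, breaks = breaks, plot = FALSE)$counts
    per[[length(per) + 1L]] <- data.frame(slice = i,
                                          fiber = seq_along(ps),
                                          length_um = len, ps = ps)
  }
  ok <- !is.na(medians)
  if (!any(ok)) stop("no traceable fibers in any slice", call. = FALSE)
  if (any(!ok)) message(sum(!ok), " slice(s) skipped (no fibers traced)")
  list(histograms = hists, breaks = breaks,
       depths = (seq_len(n) - 1) * zSpacing(stack),
       medians = medians, nFibers = nf,
       perFiber = do.call(rbind, per),
       meanOfMedians = mean(medians[ok]),
       sdOfMedians = stats::sd(medians[ok]),
       skippedSlices = sum(!ok))
}
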
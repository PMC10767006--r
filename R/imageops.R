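## Minimal grayscale image primitives (separable Gaussian blur, Otsu
## threshold, exact Euclidean distance transform, bilinear sampling).
## Hand-implemented: no image-processing package is available in the
## target environment. Images are numeric matrices [row, col].

.gaussianKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur
#'
#' @param image numeric matrix
#' @param sigma Gaussian standard deviation (px)
#' @return blurred matrix of the same size (replicate-padded borders)
#' @export
gaussianBlur <- function(image, sigma) {
  stopifnot(is.matrix(image), sigma > 0)
  k <- .gaussianKernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  pad <- function(m) {
    m <- rbind(m[rep(1L, r), , drop = FALSE], m,
               m[rep(nrow(m), r), , drop = FALSE])
    m
  }
  ## stats::filter runs down each column; do columns, transpose, repeat
  onePass <- function(m) {
    f <- stats::filter(pad(m), k, sides = 2)
    as.matrix(f)[(r + 1):(r + nrow(m)), , drop = FALSE]
  }
  t(onePass(t(onePass(image))))
}

#' Otsu's threshold
#'
#' Maximizes the between-class variance of the intensity histogram.
#'
#' @param x numeric vector or matrix of intensities
#' @param nBins number of histogram bins, default 256
#' @return threshold value; pixels strictly above it are foreground
#' @export
otsuThreshold <- function(x, nBins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nBins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nBins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (br[-1] + br[-length(br)]) / 2
  mu <- cumsum(p * mids)
  muT <- mu[nBins]
  denom <- omega * (1 - omega)
  sigmaB <- ifelse(denom > 0, (muT * omega - mu)^2 / denom, 0)
  # the criterion plateaus across empty histogram gaps; take the midpoint
  mean(mids[sigmaB > max(sigmaB) - 1e-12 * max(sigmaB)])
}

## 1-D squared distance transform (lower envelope of parabolas),
## Felzenszwalb & Huttenlocher. f: sampled costs; returns min_q f[q]+(p-q)^2.
.dt1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k] && k > 1L) {
        k <- k - 1L
      } else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (p in 1:n) {
    while (z[k + 1L] < p) k <- k + 1L
    vk <- v[k]
    d[p] <- (p - vk)^2 + f[vk]
  }
  d
}

#' Euclidean distance transform of a binary mask
#'
#' Exact distance (in pixels) from every foreground pixel to the nearest
#' background pixel, via the two-pass separable squared-distance transform.
#' Background pixels get 0.
#'
#' @param mask logical (or 0/1) matrix; `TRUE` = foreground
#' @return numeric matrix of distances
#' @export
distanceTransform <- function(mask) {
  stopifnot(is.matrix(mask))
  m <- matrix(as.logical(mask), nrow(mask), ncol(mask))
  big <- (nrow(m) + ncol(m))^2  # finite stand-in for +Inf
  f <- ifelse(m, big, 0)
  for (j in seq_len(ncol(f))) f[, j] <- .dt1d(f[, j])
  for (i in seq_len(nrow(f))) f[i, ] <- .dt1d(f[i, ])
  sqrt(pmin(f, big))
}

## bilinear sampler; x = column, y = row (1-based, fractional); outside -> 0
.bilinear <- function(image, x, y) {
  nr <- nrow(image)
  nc <- ncol(image)
  if (x < 1 || y < 1 || x > nc || y > nr) return(0)
  x0 <- floor(x)
  y0 <- floor(y)
  x1 <- min(x0 + 1L, nc)
  y1 <- min(y0 + 1L, nr)
  fx <- x - x0
  fy <- y - y0
  image[y0, x0] * (1 - fx) * (1 - fy) + image[y0, x1] * fx * (1 - fy) +
    image[y1, x0] * (1 - fx) * fy + image[y1, x1] * fx * fy
}

#' Affine axial stretch of an image
#'
#' Resamples the image with a uniform stretch along the x (vessel) axis
#' about the image center, emulating the effect of stretching the tissue
#' axially under the objective. Content is magnified along x by `stretch`;
#' regions mapped from outside the original frame are 0.
#'
#' @param image numeric matrix
#' @param stretch stretch factor >= 1
#' @return matrix of the same size
#' @export
stretchImageAxial <- function(image, stretch) {
  stopifnot(is.matrix(image), stretch > 0)
  nr <- nrow(image)
  nc <- ncol(image)
  cc <- (nc + 1) / 2
  xs <- (seq_len(nc) - cc) / stretch + cc
  out <- matrix(0, nr, nc)
  x0 <- floor(xs)
  fx <- xs - x0
  ok <- x0 >= 1 & x0 <= nc
  x1 <- pmin(x0 + 1L, nc)
  for (j in which(ok)) {
    out[, j] <- image[, x0[j]] * (1 - fx[j]) + image[, x1[j]] * fx[j]
  }
  out
}
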
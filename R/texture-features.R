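#' @include AllClasses.R
NULL

#' Grayscale (luma) plane of a slice image
#'
#' ITU-R BT.601 weighting `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param image a [SliceImage-class].
#' @param quantize quantize to 8-bit integer levels (0..255)?
#' @return numeric (or integer) matrix.
#' @export
lumaPlane <- function(image, quantize = FALSE) {
  px <- pixels(image)
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  if (quantize) matrix(as.integer(round(g * 255)), nrow = nrow(g)) else g
}

#' Foreground segmentation by global Otsu threshold
#'
#' Thresholds the luma plane with Otsu's criterion, keeps the bright class
#' (slices are imaged on a dark light-absorbing cloth) and fills interior
#' holes. With `enabled = FALSE`, or for an image with zero dynamic range
#' (warned), the all-true mask is returned.
#'
#' @param image a [SliceImage-class].
#' @param enabled logical; `FALSE` returns the all-true mask.
#' @return logical H x W matrix.
#' @export
foregroundMask <- function(image, enabled = TRUE) {
  g <- lumaPlane(image)
  allTrue <- matrix(TRUE, nrow(g), ncol(g))
  if (!enabled) return(allTrue)
  if (diff(range(g)) < 1e-12) {
    warning("image has zero dynamic range; using all-true mask")
    return(allTrue)
  }
  th <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  m <- g > th
  filled <- EBImage::fillHull(EBImage::Image(m * 1)) > 0.5
  matrix(as.logical(filled), nrow(g), ncol(g))
}

## ---- uniform LBP ----------------------------------------------------------

# circular 0/1 transition count of an 8-bit code
.lbpTransitions <- function(code) {
  bits <- as.integer(intToBits(code))[1:8]
  sum(bits != bits[c(2:8, 1)])
}

# map each 8-bit code to its u2 bin: the 58 patterns with <= 2 circular
# transitions get singleton bins in ascending code order, all others share
# bin 59
.lbpU2Table <- function() {
  codes <- 0:255
  uniform <- vapply(codes, .lbpTransitions, 0L) <= 2L
  bins <- integer(256)
  bins[uniform] <- seq_len(sum(uniform))
  bins[!uniform] <- sum(uniform) + 1L
  bins
}

.u2cache <- new.env(parent = emptyenv())

.lbpBins <- function() {
  if (is.null(.u2cache$bins)) .u2cache$bins <- .lbpU2Table()
  .u2cache$bins
}

# raw LBP codes for interior pixels whose full 3x3 window is foreground;
# neighbors clockwise from the top-left, p = 0 weighting 2^0, ties score 1
.lbpCodes <- function(image) {
  g <- lumaPlane(image, quantize = TRUE)
  m <- sliceMask(image)
  H <- nrow(g); W <- ncol(g)
  if (H < 3 || W < 3) stop("image must be at least 3 x 3 for LBP")
  ri <- 2:(H - 1); ci <- 2:(W - 1)
  centre <- g[ri, ci, drop = FALSE]
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
               c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  code <- matrix(0L, length(ri), length(ci))
  valid <- m[ri, ci, drop = FALSE]
  for (p in seq_along(offs)) {
    dy <- offs[[p]][1]; dx <- offs[[p]][2]
    nb <- g[ri + dy, ci + dx, drop = FALSE]
    code <- code + (nb >= centre) * 2L^(p - 1L)
    valid <- valid & m[ri + dy, ci + dx, drop = FALSE]
  }
  code[valid]
}

#' Uniform LBP histogram (59 bins)
#'
#' 8-neighbor local binary pattern on the 8-bit luma plane; the uniform
#' pattern (u2) mapping keeps a singleton bin for each of the 58 codes with
#' at most two circular 0/1 transitions and pools the rest into one
#' catch-all bin. Codes whose 3 x 3 window touches background or the image
#' border are dropped; the histogram is normalized to sum 1.
#'
#' @param image a [SliceImage-class], at least 3 x 3.
#' @return named numeric vector of length 59 summing to 1.
#' @export
lbpHistogram <- function(image) {
  codes <- .lbpCodes(image)
  if (length(codes) == 0L)
    stop("no interior foreground pixels; cannot compute LBP histogram")
  bins <- .lbpBins()[codes + 1L]
  h <- tabulate(bins, nbins = 59L)
  h <- h / sum(h)
  names(h) <- sprintf("lbp_u2_%02d", 1:59)
  h
}

## ---- Gabor bank -----------------------------------------------------------

#' Build a bank of complex Gabor kernels
#'
#' Orientations `theta_v = v * pi / 8` and center frequencies
#' `f_u = fMax / sqrt(2)^u`; the Gaussian envelope has
#' `sigma = sigmaRatio * lambda_u` and aspect ratio `gamma`.
#'
#' @param nScales,nOrientations bank dimensions (default 5 x 8 = 40).
#' @param fMax top center frequency, cycles/pixel.
#' @param kernelSize odd kernel side length in pixels.
#' @param sigmaRatio envelope sigma as a fraction of the wavelength.
#' @param gamma envelope aspect ratio.
#' @return list of complex `kernelSize` x `kernelSize` matrices, named
#'   `gabor_e_<u>_<v>` in scale-major order (u = 0..nScales-1 outer).
#' @export
gaborBank <- function(nScales = 5, nOrientations = 8, fMax = 0.25,
                      kernelSize = 31, sigmaRatio = 0.56, gamma = 0.5) {
  stopifnot(kernelSize %% 2 == 1)
  half <- (kernelSize - 1) / 2
  xs <- matrix(rep(-half:half, each = kernelSize), kernelSize)   # column offset
  ys <- matrix(rep(-half:half, times = kernelSize), kernelSize)  # row offset
  bank <- list()
  for (u in 0:(nScales - 1)) {
    f <- fMax / sqrt(2)^u
    sigma <- sigmaRatio / f
    for (v in 0:(nOrientations - 1)) {
      th <- v * pi / nOrientations
      xr <- xs * cos(th) + ys * sin(th)
      yr <- -xs * sin(th) + ys * cos(th)
      env <- exp(-(xr^2 + gamma^2 * yr^2) / (2 * sigma^2))
      bank[[sprintf("gabor_e_%d_%d", u, v)]] <-
        env * exp(1i * 2 * pi * f * xr)
    }
  }
  bank
}

#' Mean Gabor response magnitudes (40 energies)
#'
#' Convolves the luma plane with each complex kernel (replicate-padded
#' boundary) and averages the response magnitude over foreground pixels,
#' making the energies image-size invariant.
#'
#' @param image a [SliceImage-class].
#' @param bank optional precomputed [gaborBank()]; built from `config`
#'   otherwise.
#' @param config feature configuration, see [featureConfig()].
#' @return named non-negative numeric vector, one entry per filter.
#' @export
gaborEnergy <- function(image, bank = NULL, config = featureConfig()) {
  g <- lumaPlane(image)
  m <- sliceMask(image)
  if (!any(m)) stop("no foreground pixels; cannot compute Gabor energies")
  if (is.null(bank)) bank <- do.call(gaborBank, config$gabor)
  ksz <- nrow(bank[[1]])
  if (ksz > nrow(g) || ksz > ncol(g))
    warning("Gabor kernel larger than image; responses dominated by padding")
  vapply(bank, function(k) {
    re <- EBImage::filter2(g, Re(k), boundary = "replicate")
    im <- EBImage::filter2(g, Im(k), boundary = "replicate")
    mean(sqrt(re^2 + im^2)[m])
  }, 0)
}
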
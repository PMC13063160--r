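#' @include AllClasses.R
NULL

# sRGB -> linear RGB (IEC 61966-2-1)
.srgbLinearize <- function(c) {
  ifelse(c <= 0.04045, c / 12.92, ((c + 0.055) / 1.055)^2.4)
}

# CIE f() with the (6/29)^3 threshold
.labF <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' Convert a slice image to the H, S, a, b analysis planes
#'
#' Hue follows the arccos formulation on raw R, G, B with the standard
#' `B > G` reflection to cover the full circle; achromatic pixels get
#' `H = 0` by convention. Saturation is the HSI form
#' `1 - 3 min(R,G,B)/(R+G+B)` with `S = 0` on black pixels. The CIELAB
#' opponent coordinates use sRGB gamma linearization, the sRGB/D65 matrix
#' and the D65 white point (Xn = 95.047, Yn = 100, Zn = 108.883).
#'
#' @param image a [SliceImage-class].
#' @return a list of matrices `H` (degrees in `[0, 360)`), `S` in `[0, 1]`,
#'   `a` and `b` (unbounded, typically `[-128, 127]`).
#' @export
convertColorPlanes <- function(image) {
  stopifnot(is(image, "SliceImage"))
  px <- pixels(image)
  R <- px[, , 1]; G <- px[, , 2]; B <- px[, , 3]

  ## hue: arccos form, reflected when B > G
  num <- 0.5 * ((R - G) + (R - B))
  den <- sqrt((R - G)^2 + (R - B) * (G - B))
  achromatic <- den < 1e-12
  ratio <- num / ifelse(achromatic, 1, den)
  ratio <- pmin(pmax(ratio, -1), 1)
  H <- acos(ratio) * 180 / pi
  H[B > G] <- 360 - H[B > G]
  H[achromatic] <- 0
  H[H >= 360] <- 0

  ## HSI saturation
  tot <- R + G + B
  S <- 1 - 3 * pmin(R, G, B) / ifelse(tot == 0, 1, tot)
  S[tot == 0] <- 0

  ## CIELAB a, b via linear sRGB -> XYZ (D65)
  r <- .srgbLinearize(R); g <- .srgbLinearize(G); b <- .srgbLinearize(B)
  X <- 100 * (0.4124564 * r + 0.3575761 * g + 0.1804375 * b)
  Y <- 100 * (0.2126729 * r + 0.7151522 * g + 0.0721750 * b)
  Z <- 100 * (0.0193339 * r + 0.1191920 * g + 0.9503041 * b)
  fx <- .labF(X / 95.047); fy <- .labF(Y / 100); fz <- .labF(Z / 108.883)
  a <- 500 * (fx - fy)
  bb <- 200 * (fy - fz)

  list(H = H, S = S, a = a, b = bb)
}

#' Color moments of a slice image
#'
#' Mean and standard deviation (1/N normalization) of the R, G, B, H, S,
#' a and b channels over foreground pixels, 14 values in all. Channels are
#' rescaled to `[0, 1]` first so the features share a scale: H is divided
#' by 360, S used as-is, a and b affinely mapped from `[-128, 127]`.
#'
#' @param image a [SliceImage-class] with at least one foreground pixel.
#' @return named numeric vector of length 14, ordered
#'   `(mu, sd)` per channel, channels in R, G, B, H, S, a, b order.
#' @export
colorMoments <- function(image) {
  stopifnot(is(image, "SliceImage"))
  m <- sliceMask(image)
  if (!any(m)) stop("no foreground pixels; cannot compute color moments")
  px <- pixels(image)
  planes <- convertColorPlanes(image)
  chans <- list(
    R = px[, , 1], G = px[, , 2], B = px[, , 3],
    H = planes$H / 360, S = planes$S,
    a = (planes$a + 128) / 255, b = (planes$b + 128) / 255)
  out <- numeric(0)
  for (nm in names(chans)) {
    v <- chans[[nm]][m]
    mu <- mean(v)
    sd1 <- sqrt(mean((v - mu)^2))
    out <- c(out, mu, sd1)
    names(out)[length(out) - 1:0] <- paste0(c("color_mu_", "color_sd_"), nm)
  }
  out
}
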
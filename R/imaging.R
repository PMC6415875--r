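#' Match an image's histogram to a reference
#'
#' Per-channel monotone intensity mapping that equalizes the image's
#' cumulative histogram to the reference's, computed on an 8-bit
#' quantization (the standard preprocessing step before comparing hue
#' distributions across photographs taken under slightly different
#' lighting). Monotonicity of the mapping preserves the per-channel rank
#' order of pixels.
#'
#' @param image,reference RGB arrays (h x w x 3, values in \[0, 1\]); sizes
#'   may differ.
#' @return The matched image, same dimensions as `image`.
#' @export
histogram_match <- function(image, reference) {
  stopifnot(length(dim(image)) == 3L, length(dim(reference)) == 3L,
            dim(image)[3] == dim(reference)[3])
  out <- image
  for (k in seq_len(dim(image)[3])) {
    src <- round(image[, , k] * 255)
    ref <- round(reference[, , k] * 255)
    cdf_src <- cumsum(tabulate(src + 1, 256)) / length(src)
    cdf_ref <- cumsum(tabulate(ref + 1, 256)) / length(ref)
    # smallest reference level whose CDF reaches the source CDF
    lut <- vapply(cdf_src, function(p) which(cdf_ref >= p - 1e-12)[1] - 1L,
                  integer(1))
    out[, , k] <- matrix(lut[src + 1], nrow = dim(image)[1]) / 255
  }
  out
}

#' Hue-angle kernel density of masked pixels
#'
#' Converts masked RGB pixels to HSV, takes the hue angle in degrees, and
#' estimates a Gaussian kernel density on the circular hue axis (default
#' bandwidth 0.8 degrees). Achromatic pixels (saturation 0) carry no hue and
#' are excluded, with their count reported. The circle is handled by
#' wrap-around: the density is evaluated on \[0, 360) and integrates to 1.
#'
#' @param image RGB array (h x w x 3, values in \[0, 1\]).
#' @param mask logical matrix of pixels to include (nonempty).
#' @param bandwidth kernel bandwidth in degrees (default 0.8).
#' @param n number of evaluation points on \[0, 360).
#' @return A `hue_distribution` list: `angle_deg`, `density`, `bandwidth`,
#'   `n_pixels`, `n_achromatic`, `mode_deg` (angle of maximum density).
#' @export
hue_density <- function(image, mask, bandwidth = 0.8, n = 8192) {
  stopifnot(length(dim(image)) == 3L)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  r <- image[, , 1][mask]; g <- image[, , 2][mask]; b <- image[, , 3][mask]
  hsv_px <- rgb2hsv(r, g, b, maxColorValue = 1)
  achrom <- hsv_px[2, ] == 0
  h <- hsv_px[1, !achrom] * 360
  if (!length(h)) stop("all masked pixels are achromatic", call. = FALSE)
  # circular KDE: replicate the sample one period to each side, estimate on
  # the real line, then keep [0, 360) and renormalize the replication
  h3 <- c(h - 360, h, h + 360)
  d <- density(h3, bw = bandwidth, from = 0, to = 360 * (1 - 1 / n), n = n)
  dens <- d$y * 3
  structure(list(angle_deg = d$x, density = dens, bandwidth = bandwidth,
                 n_pixels = length(h), n_achromatic = sum(achrom),
                 mode_deg = d$x[which.max(dens)]),
            class = "hue_distribution")
}

#' @export
print.hue_distribution <- function(x, ...) {
  cat(sprintf(
    "<hue_distribution> %d pixels (%d achromatic excluded), bw %.2g deg, mode %.1f deg\n",
    x$n_pixels, x$n_achromatic, x$bandwidth, x$mode_deg))
  invisible(x)
}

#' Starch-stain darkness score per leaf
#'
#' Converts the image to 8-bit grayscale (luminance weights 0.299, 0.587,
#' 0.114) and reports the mean darkness `255 - gray` within each leaf mask:
#' the darker the iodine-stained pixel, the more starch, the higher the
#' score. The mean background darkness (pixels outside all masks) is
#' reported for the across-image comparability check.
#'
#' @param image RGB array (h x w x 3, values in \[0, 1\]) or a grayscale
#'   matrix in \[0, 1\].
#' @param masks a logical matrix or a (possibly named) list of logical
#'   matrices, one per leaf; each must be nonempty.
#' @return Data frame `leaf`, `score` (0-255 darkness), with attribute
#'   `background` (mean background darkness, NA when the masks cover the
#'   whole image).
#' @export
starch_score <- function(image, masks) {
  gray <- if (length(dim(image)) == 3L) {
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  } else {
    image
  }
  gray8 <- round(gray * 255)
  if (is.matrix(masks)) masks <- list(leaf1 = masks)
  if (!length(masks)) stop("at least one leaf mask required", call. = FALSE)
  if (is.null(names(masks))) {
    names(masks) <- paste0("leaf", seq_along(masks))
  }
  scores <- vapply(masks, function(m) {
    if (!any(m)) stop("empty leaf mask", call. = FALSE)
    mean(255 - gray8[m])
  }, 0)
  allmask <- Reduce(`|`, masks)
  bg <- if (all(allmask)) NA_real_ else mean(255 - gray8[!allmask])
  structure(data.frame(leaf = names(masks), score = unname(scores)),
            background = bg)
}
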
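#' Simulate a rosette photograph
#'
#' Builds an RGB image of leaf-like disc blobs on a light background. Masked
#' (leaf) pixels get the requested hue (with optional jitter) at full
#' saturation/value scaled by the stain darkness; background pixels are a
#' neutral light gray. Used as a controlled fixture for segmentation, hue
#' and starch scoring.
#'
#' @param hue_deg leaf hue angle in \[0, 360) degrees (green = 120).
#' @param blobs data frame `cx`, `cy`, `r` (pixel centres and radii) of the
#'   leaf discs; default two discs.
#' @param width,height image size in pixels.
#' @param hue_jitter_sd sd of Gaussian hue jitter in degrees (0 = exact).
#' @param stain_darkness 0-255 darkness of the leaf pixels (0 = white,
#'   255 = black); controls the HSV value channel `v = 1 - darkness/255`.
#' @param saturation leaf saturation (default 0.8).
#' @param background_gray background gray level in \[0, 1\].
#' @param seed seed for the jitter.
#' @return List `image` (h x w x 3 array in \[0, 1\]) and `mask` (logical
#'   h x w matrix of leaf pixels).
#' @export
simulate_rosette_image <- function(hue_deg = 120,
                                   blobs = data.frame(
                                     cx = c(20, 44), cy = c(32, 32),
                                     r = c(10, 8)),
                                   width = 64, height = 64,
                                   hue_jitter_sd = 0, stain_darkness = 50,
                                   saturation = 0.8, background_gray = 0.9,
                                   seed = 1) {
  if (hue_deg < 0 || hue_deg >= 360) {
    stop("hue_deg must be in [0, 360)", call. = FALSE)
  }
  if (stain_darkness < 0 || stain_darkness > 255) {
    stop("stain_darkness must be in [0, 255]", call. = FALSE)
  }
  x <- matrix(rep(seq_len(width), each = height), nrow = height)
  y <- matrix(rep(seq_len(height), times = width), nrow = height)
  mask <- matrix(FALSE, height, width)
  for (i in seq_len(nrow(blobs))) {
    mask <- mask |
      (x - blobs$cx[i])^2 + (y - blobs$cy[i])^2 <= blobs$r[i]^2
  }
  if (!any(mask)) stop("empty leaf mask", call. = FALSE)
  img <- array(background_gray, dim = c(height, width, 3))
  set.seed(seed)
  n <- sum(mask)
  h <- (hue_deg + rnorm(n, 0, hue_jitter_sd)) %% 360
  v <- 1 - stain_darkness / 255
  cols <- col2rgb(hsv(h / 360, saturation, v)) / 255
  for (k in 1:3) {
    ch <- img[, , k]
    ch[mask] <- cols[k, ]
    img[, , k] <- ch
  }
  list(image = img, mask = mask)
}
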
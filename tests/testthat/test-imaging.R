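test_that("rosette simulator honours hue, mask and darkness requests", {
  ros <- simulate_rosette_image(hue_deg = 120, hue_jitter_sd = 0,
                                stain_darkness = 51, seed = 1)
  hsv_px <- rgb2hsv(ros$image[, , 1][ros$mask], ros$image[, , 2][ros$mask],
                    ros$image[, , 3][ros$mask], maxColorValue = 1)
  expect_true(all(abs(hsv_px[1, ] * 360 - 120) < 1.5))  # 8-bit quantization
  # two-blob mask area equals the sum of the blob areas
  blobs <- data.frame(cx = c(15, 45), cy = c(15, 45), r = c(6, 9))
  one <- simulate_rosette_image(blobs = blobs[1, ], seed = 1)
  two <- simulate_rosette_image(blobs = blobs[2, ], seed = 1)
  both <- simulate_rosette_image(blobs = blobs, seed = 1)
  expect_equal(sum(both$mask), sum(one$mask) + sum(two$mask))
  expect_error(simulate_rosette_image(blobs = data.frame(cx = -99, cy = -99,
                                                         r = 1)),
               "empty")
  expect_error(simulate_rosette_image(hue_deg = 400), "hue")
})

test_that("histogram matching is idempotent and rank-preserving", {
  set.seed(5)
  img <- array(runif(48 * 48 * 3), dim = c(48, 48, 3))
  # matched to itself: unchanged up to 8-bit quantization
  self <- histogram_match(img, img)
  expect_lt(max(abs(self - round(img * 255) / 255)), 1e-12)

  # constant image matched to constant reference c becomes c (8-bit grid)
  a <- array(0.25, dim = c(8, 8, 3))
  b <- array(0.75, dim = c(8, 8, 3))
  expect_equal(histogram_match(a, b), b, tolerance = 1 / 255)

  # monotone mapping preserves per-channel pixel rank order
  ref <- array(runif(48 * 48 * 3)^2, dim = c(48, 48, 3))
  out <- histogram_match(img, ref)
  for (k in 1:3) {
    ok <- order(img[, , k]); oo <- out[, , k][ok]
    expect_true(all(diff(oo) >= 0))
  }
})

test_that("hue densities integrate to 1 and localize known hues", {
  ros <- simulate_rosette_image(hue_deg = 120, hue_jitter_sd = 0, seed = 1)
  hd <- hue_density(ros$image, ros$mask)
  step <- 360 / length(hd$angle_deg)
  expect_equal(sum(hd$density) * step, 1, tolerance = 1e-3)
  expect_lt(abs(hd$mode_deg - 120), 2)

  # equal mixture of 100 and 140 degrees: bimodal with equal halves
  m1 <- simulate_rosette_image(hue_deg = 100, blobs = data.frame(
    cx = 16, cy = 32, r = 10), seed = 1)
  m2 <- simulate_rosette_image(hue_deg = 140, blobs = data.frame(
    cx = 48, cy = 32, r = 10), seed = 1)
  img <- m1$image
  img[rep(m2$mask, 3)] <- m2$image[rep(m2$mask, 3)]
  hd2 <- hue_density(img, m1$mask | m2$mask, bandwidth = 2)
  lower <- sum(hd2$density[hd2$angle_deg < 120]) * step
  expect_equal(lower, 0.5, tolerance = 0.02)

  expect_error(hue_density(ros$image, ros$mask & FALSE), "empty mask")
})

test_that("rotating all hues shifts the density mode accordingly", {
  ros <- simulate_rosette_image(hue_deg = 120, hue_jitter_sd = 3, seed = 2)
  rot <- simulate_rosette_image(hue_deg = 130, hue_jitter_sd = 3, seed = 2)
  m0 <- hue_density(ros$image, ros$mask, bandwidth = 2)$mode_deg
  m1 <- hue_density(rot$image, rot$mask, bandwidth = 2)$mode_deg
  expect_equal((m1 - m0) %% 360, 10, tolerance = 1.5)
})

test_that("starch scores measure mean 8-bit darkness per leaf", {
  mask <- matrix(FALSE, 8, 8); mask[3:6, 3:6] <- TRUE
  white <- array(1, dim = c(8, 8, 3))
  black <- array(0, dim = c(8, 8, 3))
  expect_equal(starch_score(white, mask)$score, 0)
  expect_equal(starch_score(black, mask)$score, 255)

  # half black, half white leaf: 127.5
  half <- white
  half[3:6, 3:4, ] <- 0
  expect_equal(starch_score(half, mask)$score, 127.5)

  # background reference reported from outside the masks
  expect_equal(attr(starch_score(half, mask), "background"), 0)
  expect_error(starch_score(white, mask & FALSE), "empty")

  # monotone in the generator's stain darkness
  scores <- vapply(c(20, 120, 220), function(d) {
    ros <- simulate_rosette_image(stain_darkness = d, saturation = 0.2,
                                  seed = 3)
    starch_score(ros$image, ros$mask)$score
  }, 0)
  expect_true(all(diff(scores) > 0))
})
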
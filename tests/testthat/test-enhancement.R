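# The enhancement chain, blue boosting, blue membership and residue
# segmentation.

test_that("enhancing a flat field invents no structure", {
  img <- solid_image(0.5, 0.5, 0.5, 64, 64)
  out <- enhance_frame(img)
  expect_equal(dim(out), dim(img))
  for (k in 1:3) {
    expect_lt(max(out[, , k]) - min(out[, , k]), 1 / 255 + 1e-9)
  }
})

test_that("enhancement raises the lightness entropy of a low-contrast
           frame and is safely repeatable", {
  spec <- phantom_spec(seed = 3)
  img <- make_phantom_frame(spec)$image
  # squeeze the dynamic range to simulate a washed-out exam
  low <- EBImage::Image(as.array(img) * 0.25 + 0.35, dim = dim(img),
                        colormode = "Color")
  out <- enhance_frame(low)
  lum <- function(x) 0.2126 * x[, , 1] + 0.7152 * x[, , 2] + 0.0722 * x[, , 3]
  expect_gte(channel_entropy(lum(out)), channel_entropy(lum(low)))
  # applying the chain twice must stay total and bounded
  twice <- enhance_frame(out)
  expect_true(all(is.finite(twice)))
  expect_true(max(twice) <= 1 && min(twice) >= 0)
})

test_that("boost_blue amplifies only the blue band", {
  red <- solid_image(0.9, 0.05, 0.05, 16, 16)
  expect_identical(as.array(boost_blue(red)), as.array(red))

  px <- hsv_image(225, 0.5, 0.8, 8, 8)
  boosted <- boost_blue(px, enhance_params(blue_gain = 1.4,
                                           blue_value_gain = 1))
  s_out <- grDevices::rgb2hsv(boosted[1, 1, 1], boosted[1, 1, 2],
                              boosted[1, 1, 3], maxColorValue = 1)[2, 1]
  expect_equal(unname(s_out), 0.7, tolerance = 0.01)

  # saturation clamps at 1
  deep <- boost_blue(hsv_image(225, 0.9, 0.8, 4, 4))
  s_deep <- grDevices::rgb2hsv(deep[1, 1, 1], deep[1, 1, 2], deep[1, 1, 3],
                               maxColorValue = 1)[2, 1]
  expect_lte(s_deep, 1)
  expect_gt(s_deep, 0.95)
})

test_that("boosting never shrinks the blue pixel population", {
  spec <- phantom_spec(residue_fractions = c(vallecula = 0.2, pyriform = 0.1),
                       seed = 9)
  img <- make_phantom_frame(spec)$image
  params <- enhance_params()
  before <- sum(as.numeric(blue_mask(img, params)))
  after <- sum(as.numeric(blue_mask(boost_blue(img, params), params)))
  expect_gte(after, before)
})

test_that("blue_mask applies the hue band and saturation/value gates", {
  params <- enhance_params()
  black <- solid_image(0, 0, 0, 10, 10)
  expect_equal(sum(as.numeric(blue_mask(black, params))), 0)

  # 25 of 100 pixels blue by construction
  img <- solid_image(0.6, 0.3, 0.3, 10, 10)
  blue <- grDevices::col2rgb(grDevices::hsv(225 / 360, 1, 1))[, 1] / 255
  for (k in 1:3) img[1:5, 1:5, k] <- blue[k]
  expect_equal(sum(as.numeric(blue_mask(img, params))), 25)

  # white glare is rejected by the saturation gate
  glare <- solid_image(0.99, 0.99, 0.99, 10, 10)
  expect_equal(sum(as.numeric(blue_mask(glare, params))), 0)
})

test_that("blue_mask equals the per-pixel double-loop oracle", {
  set.seed(21)
  for (rep in 1:4) {
    w <- sample(16:64, 1); h <- sample(16:64, 1)
    img <- EBImage::Image(runif(w * h * 3), dim = c(w, h, 3),
                          colormode = "Color")
    got <- as.array(blue_mask(img)) > 0.5
    want <- oracle_blue_mask(img)
    expect_identical(got, want)
  }
  # and on a structured phantom frame crop
  pf <- make_phantom_frame(phantom_spec(
    residue_fractions = c(vallecula = 0.3, pyriform = 0.05), seed = 2))
  crop <- pf$image[61:124, 19:74, ]
  crop <- EBImage::Image(crop, dim = c(64, 56, 3), colormode = "Color")
  expect_identical(as.array(blue_mask(crop)) > 0.5, oracle_blue_mask(crop))
})

test_that("segment_residue reduces to plain thresholding when morphology
           and blue intersection are disabled", {
  pf <- make_phantom_frame(phantom_spec(
    residue_fractions = c(vallecula = 0.25, pyriform = 0.1), seed = 5))
  params <- enhance_params(threshold = 0.5, mask_combine = "threshold",
                           apply_morphology = FALSE)
  got <- segment_residue(pf$image, params)
  gray <- EBImage::channel(pf$image, "gray")
  expect_identical(as.array(got) > 0.5, as.array(gray > 0.5))

  blank <- solid_image(0, 0, 0, 32, 32)
  expect_equal(sum(as.numeric(segment_residue(blank, enhance_params()))), 0)
})

test_that("closing reconnects a blob split by a narrow occlusion and the
           area filter removes speckle", {
  img <- solid_image(0.1, 0.1, 0.1, 64, 64)
  blue <- grDevices::col2rgb(grDevices::hsv(225 / 360, 0.85, 0.9))[, 1] / 255
  for (k in 1:3) img[20:44, 20:40, k] <- blue[k]
  # dark 2-px occluding stripe across the blob
  for (k in 1:3) img[31:32, 20:40, k] <- 0.05
  params <- enhance_params(threshold = 0.3, mask_combine = "threshold")
  mask <- segment_residue(img, params)
  expect_equal(max(EBImage::bwlabel(mask)), 1)

  # without morphology the stripe splits the mask in two
  params_off <- enhance_params(threshold = 0.3, mask_combine = "threshold",
                               apply_morphology = FALSE)
  expect_equal(max(EBImage::bwlabel(segment_residue(img, params_off))), 2)

  # isolated speckle below the minimum area disappears
  spk <- solid_image(0.1, 0.1, 0.1, 64, 64)
  for (k in 1:3) spk[10:11, 10:11, k] <- blue[k]
  expect_equal(sum(as.numeric(segment_residue(
    spk, enhance_params(threshold = 0.3, mask_combine = "threshold")))), 0)
})

test_that("overlay preserves pixels away from annotations and draws
           contours on the mask boundary", {
  pf <- make_phantom_frame(phantom_spec(
    residue_fractions = c(vallecula = 0.2, pyriform = 0), seed = 8))
  img <- pf$image

  same <- overlay_mask(img, mask = NULL, rois = list())
  expect_identical(as.array(same), as.array(img))

  mask <- blue_mask(img)
  out <- overlay_mask(img, mask, color = "yellow")
  changed <- which(apply(abs(as.array(out) - as.array(img)), c(1, 2), max) >
                     1e-9, arr.ind = TRUE)
  # contour pixels lie on the mask boundary (mask minus its erosion)
  boundary <- as.array(mask > 0.5) &
    !(as.array(EBImage::erode(mask, EBImage::makeBrush(3, "box"))) > 0.5)
  expect_true(all(boundary[changed]))

  roi <- rect_roi(5, 5, 20, 15)
  framed <- overlay_mask(img, rois = list(roi))
  white <- framed[6:20, 6, ] # top edge drawn in the ROI colour
  expect_true(all(abs(white - 1) < 1e-9))
  expect_error(overlay_mask(img, mask = EBImage::Image(0, dim = c(3, 3))),
               "dimensions")
})

test_that("all enhancement operations preserve image dimensions", {
  pf <- make_phantom_frame(phantom_spec(seed = 30,
    residue_fractions = c(vallecula = 0.1, pyriform = 0.1)))
  img <- pf$image
  params <- enhance_params()
  expect_equal(dim(enhance_frame(img, params)), dim(img))
  expect_equal(dim(boost_blue(img, params)), dim(img))
  expect_equal(dim(blue_mask(img, params))[1:2], dim(img)[1:2])
  expect_equal(dim(segment_residue(img, params))[1:2], dim(img)[1:2])
  expect_error(enhance_frame(EBImage::Image(0.5, dim = c(8, 8))), "colour")
})
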
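# Image enhancement and blue-dye residue segmentation.
#
# The fixed pipeline order in enhance_frame() is: CIELAB
# lightness-channel adaptive equalization -> HSV saturation correction ->
# Gaussian blur -> median filter -> unsharp sharpening. Residue
# segmentation thresholds the grayscale image, cleans the mask
# morphologically (fill holes -> area filter -> erosion -> closing ->
# opening) and, by default, intersects it with blue-hue membership.

#' Enhancement and segmentation parameters
#'
#' Defaults reflect common practice for endoscopic frames: CLAHE clip
#' limit 2 over an 8x8 tile grid, 5x5 Gaussian kernel (sigma derived from
#' the kernel size by the usual `0.3*((k-1)/2 - 1) + 0.8` rule), 3x3
#' median kernel, unsharp amount 1, dye hue band 200-260 degrees with
#' minimum saturation 0.25 and minimum value 0.15, Otsu threshold, 3x3
#' morphology elements, and component areas between 20 px^2 and 25% of
#' the image.
#'
#' @param clip_limit CLAHE clip limit (unitless).
#' @param tile_grid Integer length-2, CLAHE tile grid (cells in x and y).
#' @param gaussian_kernel Odd Gaussian kernel size in pixels.
#' @param median_kernel Odd median kernel size in pixels.
#' @param sharpen_amount Unsharp-mask amount (0 disables).
#' @param saturation_gain HSV saturation gain applied during enhancement.
#' @param blue_hue Length-2 hue band in degrees within \[0, 360).
#' @param min_saturation,min_value Minimum saturation / value for blue
#'   membership (fractions).
#' @param blue_gain Saturation gain applied by [boost_blue()] inside the
#'   blue band.
#' @param blue_value_gain Value gain applied by [boost_blue()] inside the
#'   blue band (default 1.4, matching the saturation gain). Brightening
#'   the dye is what lets the grayscale threshold separate residue from
#'   mucosa of similar luminance.
#' @param threshold `"otsu"` for the automatic bimodal threshold, or a
#'   fixed numeric level in \[0, 1\].
#' @param erode_size,close_size,open_size Odd sizes of the structuring
#'   elements for the erosion, closing and opening steps. The closing
#'   element is larger by default (7 px) so that blobs fragmented by
#'   narrow glare stripes are reconnected even after the erosion has
#'   widened the gap.
#' @param compensate_erosion If `TRUE` (default) a final dilation with the
#'   erosion element restores the one-pixel boundary layer removed by the
#'   erosion step, making the cleanup approximately area-preserving so
#'   that residue fractions are unbiased.
#' @param min_area Minimum connected-component area kept (px^2).
#' @param max_area_fraction Maximum component area as a fraction of the
#'   image (components larger than this are treated as background sheets).
#' @param mask_combine How [segment_residue()] combines evidence:
#'   `"both"` (threshold mask intersected with blue membership, the
#'   default), `"threshold"` or `"blue"` alone.
#' @param apply_morphology Disable to reduce [segment_residue()] to plain
#'   thresholding (plus the chosen combination rule).
#' @return An object of class `enhance_params`.
#' @export
enhance_params <- function(clip_limit = 2, tile_grid = c(8L, 8L),
                           gaussian_kernel = 5L, median_kernel = 3L,
                           sharpen_amount = 1, saturation_gain = 1.15,
                           blue_hue = c(200, 260),
                           min_saturation = 0.25, min_value = 0.15,
                           blue_gain = 1.4, blue_value_gain = 1.4,
                           threshold = "otsu", erode_size = 3L,
                           close_size = 7L, open_size = 3L,
                           compensate_erosion = TRUE,
                           min_area = 20, max_area_fraction = 0.25,
                           mask_combine = c("both", "threshold", "blue"),
                           apply_morphology = TRUE) {
  mask_combine <- match.arg(mask_combine)
  stopifnot(gaussian_kernel >= 1, gaussian_kernel %% 2 == 1,
            median_kernel >= 1, median_kernel %% 2 == 1,
            erode_size >= 1, erode_size %% 2 == 1,
            close_size >= 1, close_size %% 2 == 1,
            open_size >= 1, open_size %% 2 == 1,
            length(blue_hue) == 2, all(blue_hue >= 0), all(blue_hue < 360),
            min_saturation >= 0, min_saturation <= 1,
            min_value >= 0, min_value <= 1,
            min_area >= 0, max_area_fraction > 0, max_area_fraction <= 1,
            clip_limit > 0, length(tile_grid) == 2)
  if (is.numeric(threshold)) {
    stopifnot(threshold >= 0, threshold <= 1)
  } else if (!identical(threshold, "otsu")) {
    stop("threshold must be \"otsu\" or a numeric level in [0, 1]",
         call. = FALSE)
  }
  structure(list(clip_limit = clip_limit, tile_grid = as.integer(tile_grid),
                 gaussian_kernel = as.integer(gaussian_kernel),
                 median_kernel = as.integer(median_kernel),
                 sharpen_amount = sharpen_amount,
                 saturation_gain = saturation_gain,
                 blue_hue = blue_hue, min_saturation = min_saturation,
                 min_value = min_value, blue_gain = blue_gain,
                 blue_value_gain = blue_value_gain, threshold = threshold,
                 erode_size = as.integer(erode_size),
                 close_size = as.integer(close_size),
                 open_size = as.integer(open_size),
                 compensate_erosion = isTRUE(compensate_erosion),
                 min_area = min_area,
                 max_area_fraction = max_area_fraction,
                 mask_combine = mask_combine,
                 apply_morphology = isTRUE(apply_morphology)),
            class = "enhance_params")
}

# OpenCV-style sigma for a Gaussian kernel of odd size k
gaussian_sigma_from_kernel <- function(k) 0.3 * ((k - 1) / 2 - 1) + 0.8

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Enhance an endoscopic frame
#'
#' Applies the fixed enhancement chain: adaptive histogram equalization of
#' the CIELAB lightness channel, saturation correction in HSV space,
#' Gaussian blur, median filtering and unsharp sharpening. Output has the
#' same dimensions as the input, in standard RGB channel order.
#'
#' @param img A 3-channel colour [EBImage::Image] with values in \[0, 1\].
#' @param params An [enhance_params()].
#' @return The enhanced colour image.
#' @export
enhance_frame <- function(img, params = enhance_params()) {
  assert_color_image(img)
  d <- dim(img)[1:2]

  # CLAHE on the CIELAB lightness channel
  m <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  l_img <- EBImage::Image(matrix(clamp01(lab[, 1] / 100), d[1], d[2]))
  l_eq <- EBImage::clahe(l_img, nx = params$tile_grid[1],
                         ny = params$tile_grid[2],
                         limit = params$clip_limit)
  lab[, 1] <- as.vector(l_eq) * 100
  rgb <- clamp01(grDevices::convertColor(lab, from = "Lab", to = "sRGB"))
  out <- rgb_image(matrix(rgb[, 1], d[1], d[2]),
                   matrix(rgb[, 2], d[1], d[2]),
                   matrix(rgb[, 3], d[1], d[2]))

  # saturation correction in HSV
  if (params$saturation_gain != 1) {
    ch <- img_to_hsv(out)
    out <- hsv_to_img(ch$h, clamp01(ch$s * params$saturation_gain), ch$v)
  }

  # denoising: Gaussian then median
  sigma <- gaussian_sigma_from_kernel(params$gaussian_kernel)
  out <- EBImage::gblur(out, sigma = sigma)
  if (params$median_kernel > 1) {
    out <- EBImage::medianFilter(clamp01(out), (params$median_kernel - 1) / 2)
  }

  # unsharp sharpening
  if (params$sharpen_amount > 0) {
    blur <- EBImage::gblur(out, sigma = sigma)
    out <- out + params$sharpen_amount * (out - blur)
  }
  out <- EBImage::Image(clamp01(out), dim = dim(img), colormode = "Color")
  out
}

#' Boost blue (dye) tones
#'
#' Pixels whose hue lies inside the blue band receive a saturation (and
#' optionally value) gain, clamped at 1; all other pixels are returned
#' bit-identical.
#'
#' @inheritParams enhance_frame
#' @return Colour image with boosted blue tones.
#' @export
boost_blue <- function(img, params = enhance_params()) {
  assert_color_image(img)
  ch <- img_to_hsv(img)
  sel <- hue_in_band(ch$h, params$blue_hue)
  if (!any(sel)) return(img)
  s2 <- ch$s; v2 <- ch$v
  s2[sel] <- clamp01(ch$s[sel] * params$blue_gain)
  v2[sel] <- clamp01(ch$v[sel] * params$blue_value_gain)
  boosted <- hsv_to_img(ch$h, s2, v2)
  out <- img
  idx <- which(sel)
  n <- prod(dim(img)[1:2])
  for (k in 0:2) out[idx + k * n] <- boosted[idx + k * n]
  out
}

#' Blue-membership mask
#'
#' A pixel is blue iff its hue (0-360 degree circle) lies in the blue
#' band, its saturation is at least `min_saturation` and its value at
#' least `min_value`. The saturation gate excludes specular glare, the
#' value gate excludes dark background.
#'
#' @inheritParams enhance_frame
#' @return Binary grayscale [EBImage::Image] (1 = blue).
#' @export
blue_mask <- function(img, params = enhance_params()) {
  assert_color_image(img)
  ch <- img_to_hsv(img)
  sel <- hue_in_band(ch$h, params$blue_hue) &
    ch$s >= params$min_saturation & ch$v >= params$min_value
  EBImage::Image(sel * 1, dim = dim(img)[1:2])
}

#' Segment dyed residue
#'
#' Thresholds the grayscale image (Otsu by default), then post-processes
#' the mask in fixed order: hole filling, removal of components outside
#' the area bounds, erosion, closing, opening. The final residue mask is
#' by default the intersection of the threshold mask with blue-hue
#' membership; `mask_combine` in the parameters selects either source
#' alone for ablation.
#'
#' @param img A colour image, typically already blue-boosted.
#' @param params An [enhance_params()].
#' @return Binary grayscale [EBImage::Image] (1 = residue).
#' @export
segment_residue <- function(img, params = enhance_params()) {
  assert_color_image(img)
  d <- dim(img)[1:2]

  mask <- NULL
  if (params$mask_combine %in% c("both", "threshold")) {
    gray <- EBImage::channel(img, "gray")
    thr <- if (is.numeric(params$threshold)) params$threshold
           else EBImage::otsu(gray, range = c(0, 1))
    mask <- EBImage::Image((gray > thr) * 1, dim = d)
    if (params$apply_morphology) {
      b_erode <- EBImage::makeBrush(params$erode_size, shape = "disc")
      b_close <- EBImage::makeBrush(params$close_size, shape = "disc")
      b_open <- EBImage::makeBrush(params$open_size, shape = "disc")
      mask <- EBImage::fillHull(mask)
      mask <- filter_component_areas(mask, params$min_area,
                                     params$max_area_fraction * prod(d))
      mask <- EBImage::erode(mask, b_erode)
      mask <- EBImage::closing(mask, b_close)
      mask <- EBImage::opening(mask, b_open)
      if (params$compensate_erosion) {
        mask <- EBImage::dilate(mask, b_erode)
      }
    }
  }
  if (params$mask_combine %in% c("both", "blue")) {
    bm <- blue_mask(img, params)
    mask <- if (is.null(mask)) bm else EBImage::Image((mask > 0 & bm > 0) * 1,
                                                      dim = d)
  }
  mask
}

# drop 8-connected components whose pixel area is outside [min_area, max_area]
filter_component_areas <- function(mask, min_area, max_area) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(mask)
  areas <- tabulate(as.integer(lab[lab > 0]), nbins = nlab)
  keep <- which(areas >= min_area & areas <= max_area)
  EBImage::Image((as.array(lab) %in% keep & as.array(lab) > 0) * 1,
                 dim = dim(mask))
}

#' Overlay a residue mask and ROI outlines on an image
#'
#' Residue components are contoured in the given colour; ROI rectangles
#' (and optionally the 3x3 glottic grid) are drawn as 1-pixel outlines.
#' Pixels away from the annotations are preserved.
#'
#' @param img Colour image.
#' @param mask Binary mask of the same width/height (or `NULL`).
#' @param color Annotation colour name or hex (default `"yellow"`).
#' @param rois List of [rect_roi()] to outline (may be empty).
#' @param grid Optional [glottis_grid()] whose cell boundaries are drawn.
#' @param roi_color Outline colour for ROIs (default `"white"`).
#' @return Annotated colour image.
#' @export
overlay_mask <- function(img, mask = NULL, color = "yellow", rois = list(),
                         grid = NULL, roi_color = "white") {
  assert_color_image(img)
  d <- dim(img)[1:2]
  out <- img
  if (!is.null(mask)) {
    if (!identical(as.integer(dim(mask)[1:2]), as.integer(d))) {
      stop("mask dimensions ", paste(dim(mask)[1:2], collapse = "x"),
           " do not match image ", paste(d, collapse = "x"), call. = FALSE)
    }
    out <- EBImage::paintObjects(EBImage::Image(mask, dim = d), out,
                                 col = color, thick = FALSE)
  }
  rgbcol <- grDevices::col2rgb(roi_color)[, 1] / 255
  for (roi in rois) out <- draw_rect(out, roi, rgbcol)
  if (!is.null(grid)) {
    for (cell in grid$cells) out <- draw_rect(out, cell, rgbcol)
  }
  out
}

# draw the 1-px border of a clipped rectangle in-place
draw_rect <- function(img, roi, rgbcol) {
  d <- dim(img)[1:2]
  roi <- clip_roi(roi, d[1], d[2])
  xs <- (roi$x0 + 1):roi$x1
  ys <- (roi$y0 + 1):roi$y1
  for (k in 1:3) {
    img[xs, c(roi$y0 + 1, roi$y1), k] <- rgbcol[k]
    img[c(roi$x0 + 1, roi$x1), ys, k] <- rgbcol[k]
  }
  img
}
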
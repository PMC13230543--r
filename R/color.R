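# Colour-space helpers shared by the enhancement and phantom modules.
# Images are EBImage `Image` objects in Color mode, dim (width, height, 3),
# channel values in [0, 1]; pixel (x, y) uses 0-based coordinates with x
# rightward and y downward, i.e. img[x + 1, y + 1, ].

#' Construct an RGB image from channel matrices
#'
#' @param r,g,b Numeric matrices (width x height) in \[0, 1\].
#' @return An [EBImage::Image] in Color mode.
#' @keywords internal
rgb_image <- function(r, g, b) {
  stopifnot(identical(dim(r), dim(g)), identical(dim(r), dim(b)))
  EBImage::Image(c(pmin(pmax(r, 0), 1), pmin(pmax(g, 0), 1), pmin(pmax(b, 0), 1)),
                 dim = c(dim(r), 3L), colormode = "Color")
}

#' Assert that an object is a 3-channel colour image
#' @keywords internal
assert_color_image <- function(img, arg = "image") {
  if (!inherits(img, "Image") || length(dim(img)) != 3 || dim(img)[3] != 3) {
    stop(arg, " must be a 3-channel colour EBImage::Image", call. = FALSE)
  }
  invisible(img)
}

#' Split a colour image into HSV channel matrices
#'
#' Hue is reported on the standard 0-360 degree circle.
#'
#' @param img A colour [EBImage::Image].
#' @return List with matrices `h` (degrees), `s`, `v`.
#' @keywords internal
img_to_hsv <- function(img) {
  assert_color_image(img)
  d <- dim(img)[1:2]
  m <- grDevices::rgb2hsv(rbind(as.vector(img[, , 1]),
                                as.vector(img[, , 2]),
                                as.vector(img[, , 3])),
                          maxColorValue = 1)
  list(h = matrix(m[1, ] * 360, d[1], d[2]),
       s = matrix(m[2, ], d[1], d[2]),
       v = matrix(m[3, ], d[1], d[2]))
}

#' Rebuild a colour image from HSV channel matrices
#'
#' @param h Hue matrix in degrees (wrapped to \[0, 360)).
#' @param s,v Saturation / value matrices in \[0, 1\].
#' @return A colour [EBImage::Image].
#' @keywords internal
hsv_to_img <- function(h, s, v) {
  d <- dim(h)
  hex <- grDevices::hsv((as.vector(h) %% 360) / 360,
                        pmin(pmax(as.vector(s), 0), 1),
                        pmin(pmax(as.vector(v), 0), 1))
  m <- grDevices::col2rgb(hex) / 255
  rgb_image(matrix(m[1, ], d[1], d[2]),
            matrix(m[2, ], d[1], d[2]),
            matrix(m[3, ], d[1], d[2]))
}

#' Hue-band membership with wrap-around
#'
#' @param h Hue values in degrees.
#' @param band Numeric length-2, degrees in \[0, 360). If `band[1] > band[2]`
#'   the band wraps through 0 (e.g. `c(330, 30)` covers reds).
#' @return Logical of the same shape as `h`.
#' @keywords internal
hue_in_band <- function(h, band) {
  h <- h %% 360
  if (band[1] <= band[2]) h >= band[1] & h <= band[2]
  else h >= band[1] | h <= band[2]
}
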
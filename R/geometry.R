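# Region-of-interest geometry driven by tracked landmarks.
#
# Conventions: 0-based pixel coordinates, x rightward, y downward;
# rectangles are half-open integer boxes [x0, x1) x [y0, y1); rounding to
# pixels is half-up, applied to the centre first and then to the side
# lengths.

#' Geometry configuration
#'
#' @param v_glottis Unitless scale applied to the glottic square's diagonal
#'   (default 1).
#' @param v_pyriform Unitless scale applied to the pyriform rectangle's
#'   height (default 1).
#' @param magnification Integer display magnification of the glottic view
#'   (default 3). Quantities are always measured at native resolution.
#' @param central_cells List of `c(row, col)` pairs (1-based) naming the
#'   3x3 grid cells that represent the glottic entry; default the centre
#'   cell `(2, 2)`.
#' @param a_is_side If `TRUE`, interpret the landmark-derived length A as
#'   the square's side instead of its diagonal.
#' @param anchor Anchor rule for the pyriform/vallecular rectangles:
#'   `"centroid"` (centred on the centroid of the four defining points) or
#'   `"topleft"` (top-left corner at the minimum x/y of the defining
#'   points).
#' @return An object of class `geometry_config`.
#' @export
geometry_config <- function(v_glottis = 1, v_pyriform = 1, magnification = 3,
                            central_cells = list(c(2L, 2L)),
                            a_is_side = FALSE,
                            anchor = c("centroid", "topleft")) {
  anchor <- match.arg(anchor)
  stopifnot(v_glottis > 0, v_pyriform > 0, magnification >= 1,
            length(central_cells) >= 1)
  for (cc in central_cells) {
    stopifnot(length(cc) == 2, all(cc %in% 1:3))
  }
  structure(list(v_glottis = v_glottis, v_pyriform = v_pyriform,
                 magnification = as.integer(magnification),
                 central_cells = lapply(central_cells, as.integer),
                 a_is_side = isTRUE(a_is_side), anchor = anchor),
            class = "geometry_config")
}

#' Rectangular region of interest
#'
#' @param x0,y0,x1,y1 Integer pixel bounds of the half-open box
#'   `[x0, x1) x [y0, y1)`.
#' @return An object of class `rect_roi`.
#' @export
rect_roi <- function(x0, y0, x1, y1) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  x1 <- as.integer(x1); y1 <- as.integer(y1)
  if (x1 <= x0 || y1 <= y0) {
    stop("degenerate geometry: empty rectangle [", x0, ",", x1, ")x[",
         y0, ",", y1, ")", call. = FALSE)
  }
  structure(list(x0 = x0, y0 = y0, x1 = x1, y1 = y1), class = "rect_roi")
}

#' @export
print.rect_roi <- function(x, ...) {
  cat("<rect_roi> [", x$x0, ",", x$x1, ") x [", x$y0, ",", x$y1, ")  (",
      roi_area(x), " px)\n", sep = "")
  invisible(x)
}

#' Pixel area of a rectangular ROI
#' @param roi A [rect_roi()].
#' @return Integer pixel count.
#' @export
roi_area <- function(roi) (roi$x1 - roi$x0) * (roi$y1 - roi$y0)

round_half_up <- function(x) floor(x + 0.5)

# shared landmark-validity check for the ROI constructors
get_roi_points <- function(frame, schema, region, roles) {
  pts <- lapply(roles, function(r) resolve_role(frame, schema, region, r))
  for (i in seq_along(pts)) {
    p <- pts[[i]]
    if (!is.finite(p$x) || !is.finite(p$y) || p$likelihood <= 0) {
      stop("cannot build ", region, " ROI: point ", roles[i],
           " is missing or has zero likelihood", call. = FALSE)
    }
  }
  pts
}

continuous_rect <- function(cx, cy, w, h, round_px) {
  if (w <= 0 || h <= 0) {
    stop("degenerate geometry: non-positive extent", call. = FALSE)
  }
  if (!round_px) {
    return(structure(list(x0 = cx - w / 2, y0 = cy - h / 2,
                          x1 = cx + w / 2, y1 = cy + h / 2),
                     class = c("rect_roi_continuous", "rect_roi")))
  }
  cxr <- round_half_up(cx); cyr <- round_half_up(cy)
  wr <- max(1L, round_half_up(w)); hr <- max(1L, round_half_up(h))
  x0 <- cxr - wr %/% 2; y0 <- cyr - hr %/% 2
  rect_roi(x0, y0, x0 + wr, y0 + hr)
}

#' Glottic square from vocal-fold landmarks
#'
#' The square is centred on the midpoint of points `P2` and `P3`; its
#' diagonal `A` equals the Euclidean distance between `P1` and `P2`
#' multiplied by the scale `v_glottis`, so the side is `A / sqrt(2)`
#' (set `a_is_side = TRUE` in the config to treat `A` as the side).
#'
#' @param frame Frame-landmark tibble ([frame_landmarks()]).
#' @param schema A [landmark_schema()].
#' @param cfg A [geometry_config()].
#' @param round_px Round to integer pixels (default `TRUE`). With
#'   `FALSE` the continuous rectangle is returned, which is exactly
#'   equivariant under translation and positive scaling.
#' @return A [rect_roi()] (square).
#' @export
glottis_square <- function(frame, schema = landmark_schema(),
                           cfg = geometry_config(), round_px = TRUE) {
  pts <- get_roi_points(frame, schema, "glottis", c("P1", "P2", "P3"))
  p1 <- pts[[1]]; p2 <- pts[[2]]; p3 <- pts[[3]]
  a <- cfg$v_glottis * sqrt((p1$x - p2$x)^2 + (p1$y - p2$y)^2)
  if (a <= 0) {
    stop("degenerate geometry: glottis points P1 and P2 coincide",
         call. = FALSE)
  }
  side <- if (cfg$a_is_side) a else a / sqrt(2)
  continuous_rect((p2$x + p3$x) / 2, (p2$y + p3$y) / 2, side, side, round_px)
}

#' Pyriform-sinus rectangle from arytenoid landmarks
#'
#' Width is the difference of the x-coordinates of `P1` and `P4`; height is
#' the difference of the y-coordinates of `P2` and `P3` scaled by
#' `v_pyriform`. A single rectangle spans both sinuses.
#'
#' @inheritParams glottis_square
#' @return A [rect_roi()].
#' @export
pyriform_rect <- function(frame, schema = landmark_schema(),
                          cfg = geometry_config(), round_px = TRUE) {
  pts <- get_roi_points(frame, schema, "pyriform", paste0("P", 1:4))
  w <- abs(pts[[1]]$x - pts[[4]]$x)
  h <- cfg$v_pyriform * abs(pts[[2]]$y - pts[[3]]$y)
  if (w <= 0 || h <= 0) {
    stop("degenerate geometry: pyriform rectangle has zero width or height",
         call. = FALSE)
  }
  anchored_rect(pts, w, h, cfg$anchor, round_px)
}

#' Vallecular rectangle from epiglottis landmarks
#'
#' Width is the difference of the x-coordinates of `P1` and `P3`; height is
#' the difference of the y-coordinates of `P2` and `P4`.
#'
#' @inheritParams glottis_square
#' @return A [rect_roi()].
#' @export
vallecula_rect <- function(frame, schema = landmark_schema(),
                           cfg = geometry_config(), round_px = TRUE) {
  pts <- get_roi_points(frame, schema, "vallecula", paste0("P", 1:4))
  w <- abs(pts[[1]]$x - pts[[3]]$x)
  h <- abs(pts[[2]]$y - pts[[4]]$y)
  if (w <= 0 || h <= 0) {
    stop("degenerate geometry: vallecular rectangle has zero width or height",
         call. = FALSE)
  }
  anchored_rect(pts, w, h, cfg$anchor, round_px)
}

anchored_rect <- function(pts, w, h, anchor, round_px) {
  xs <- vapply(pts, `[[`, numeric(1), "x")
  ys <- vapply(pts, `[[`, numeric(1), "y")
  if (anchor == "centroid") {
    continuous_rect(mean(xs), mean(ys), w, h, round_px)
  } else {
    continuous_rect(min(xs) + w / 2, min(ys) + h / 2, w, h, round_px)
  }
}

#' 3x3 grid over the glottic square
#'
#' Rows and columns are split by integer division; the last row/column
#' absorbs the remainder, so the nine cells tile the parent exactly.
#'
#' @param square A [rect_roi()] of at least 3x3 pixels.
#' @return An object of class `grid_roi` with fields `parent` and `cells`
#'   (3x3 list-matrix of [rect_roi()]).
#' @export
glottis_grid <- function(square) {
  stopifnot(inherits(square, "rect_roi"))
  w <- square$x1 - square$x0
  h <- square$y1 - square$y0
  if (w < 3 || h < 3) {
    stop("degenerate geometry: grid needs a square of at least 3x3 pixels",
         call. = FALSE)
  }
  xb <- square$x0 + c(0L, w %/% 3, 2L * (w %/% 3), w)
  yb <- square$y0 + c(0L, h %/% 3, 2L * (h %/% 3), h)
  cells <- matrix(vector("list", 9), 3, 3)
  for (r in 1:3) {
    for (cl in 1:3) {
      cells[[r, cl]] <- rect_roi(xb[cl], yb[r], xb[cl + 1], yb[r + 1])
    }
  }
  structure(list(parent = square, cells = cells), class = "grid_roi")
}

#' @export
print.grid_roi <- function(x, ...) {
  cat("<grid_roi> parent ", x$parent$x1 - x$parent$x0, "x",
      x$parent$y1 - x$parent$y0, " px, 3x3 cells\n", sep = "")
  invisible(x)
}

#' Clip an ROI to the image bounds
#'
#' @param roi A [rect_roi()].
#' @param width,height Image dimensions in pixels.
#' @return The clipped [rect_roi()]; the fraction of the original area
#'   that was cut off is attached as attribute `"clipped_fraction"`.
#' @export
clip_roi <- function(roi, width, height) {
  x0 <- max(roi$x0, 0L); y0 <- max(roi$y0, 0L)
  x1 <- min(roi$x1, as.integer(width)); y1 <- min(roi$y1, as.integer(height))
  if (x1 <= x0 || y1 <= y0) {
    stop("ROI lies entirely outside the ", width, "x", height, " image",
         call. = FALSE)
  }
  out <- rect_roi(x0, y0, x1, y1)
  attr(out, "clipped_fraction") <- 1 - roi_area(out) / roi_area(roi)
  out
}

#' Magnified crop of a square ROI
#'
#' Display-only enlargement (nearest-neighbour); all per-cell residue
#' fractions are computed on original-resolution pixels.
#'
#' @param img A colour [EBImage::Image].
#' @param square A [rect_roi()] fully inside the image.
#' @param factor Integer magnification factor.
#' @return The enlarged crop as an [EBImage::Image].
#' @export
magnify <- function(img, square, factor = 3) {
  assert_color_image(img)
  d <- dim(img)
  stopifnot(square$x0 >= 0, square$y0 >= 0, square$x1 <= d[1],
            square$y1 <= d[2], factor >= 1)
  crop <- img[(square$x0 + 1):square$x1, (square$y0 + 1):square$y1, ,
              drop = FALSE]
  EBImage::resize(crop, w = (square$x1 - square$x0) * factor,
                  h = (square$y1 - square$y0) * factor, filter = "none")
}

#' Tidy a rectangular ROI
#' @param x A [rect_roi()].
#' @param ... Unused.
#' @return One-row tibble with the bounds and area.
#' @method tidy rect_roi
#' @export
tidy.rect_roi <- function(x, ...) {
  tibble::tibble(x0 = x$x0, y0 = x$y0, x1 = x$x1, y1 = x$y1,
                 width = x$x1 - x$x0, height = x$y1 - x$y0,
                 area = roi_area(x))
}
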
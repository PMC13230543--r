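# Residue quantification, YPR-SRS severity mapping and the 3x3 glottic
# grid rule for penetration/aspiration.

#' Map a residue fraction to a YPR-SRS severity level
#'
#' The published cut points are 1, 5, 25 and 50 percent: absence below
#' 1%, trace 1-5%, mild 5-25%, moderate 25-50% and severe above 50%.
#' Because adjacent printed intervals share endpoints, the package closes
#' the lower bound of each interval (`[1,5)`, `[5,25)`, `[25,50]`) and
#' keeps severe strictly above 50%, matching the printed "< 1%" and
#' "> 50%". Set `severe_includes_50 = TRUE` for the alternative reading.
#'
#' @param f Numeric vector of fractions in \[0, 1\].
#' @param severe_includes_50 If `TRUE`, a fraction of exactly 0.50 is
#'   classified severe instead of moderate.
#' @return Ordered factor over [severity_levels()].
#' @export
#' @examples
#' severity_from_fraction(c(0, 0.03, 0.30, 0.75))
severity_from_fraction <- function(f, severe_includes_50 = FALSE) {
  if (any(!is.finite(f)) || any(f < 0 | f > 1)) {
    stop("residue fraction must lie in [0, 1]", call. = FALSE)
  }
  lv <- severity_levels()
  out <- character(length(f))
  out[f < 0.01] <- "absence"
  out[f >= 0.01 & f < 0.05] <- "trace"
  out[f >= 0.05 & f < 0.25] <- "mild"
  if (severe_includes_50) {
    out[f >= 0.25 & f < 0.50] <- "moderate"
    out[f >= 0.50] <- "severe"
  } else {
    out[f >= 0.25 & f <= 0.50] <- "moderate"
    out[f > 0.50] <- "severe"
  }
  factor(out, levels = lv, ordered = TRUE)
}

#' Residue pixel fraction within an ROI
#'
#' Counts mask pixels over the half-open rectangle and divides by the
#' rectangle's area.
#'
#' @param mask Binary mask ([EBImage::Image] or matrix; values > 0.5 count
#'   as residue).
#' @param roi A [rect_roi()], already clipped to the mask bounds.
#' @return Tibble with `blue_pixels`, `total_pixels`, `fraction`.
#' @export
residue_fraction <- function(mask, roi) {
  stopifnot(inherits(roi, "rect_roi"))
  d <- dim(mask)[1:2]
  if (roi$x0 < 0 || roi$y0 < 0 || roi$x1 > d[1] || roi$y1 > d[2]) {
    stop("ROI exceeds mask bounds; clip it first with clip_roi()",
         call. = FALSE)
  }
  total <- roi_area(roi)
  if (total <= 0) stop("degenerate geometry: empty ROI", call. = FALSE)
  sub <- mask[(roi$x0 + 1):roi$x1, (roi$y0 + 1):roi$y1]
  blue <- sum(as.numeric(sub) > 0.5)
  tibble::tibble(blue_pixels = as.integer(blue),
                 total_pixels = as.integer(total),
                 fraction = blue / total)
}

#' Classify residue severity within one region
#'
#' Composes the residue mask with [residue_fraction()] and
#' [severity_from_fraction()].
#'
#' @param img Colour image (already enhanced; see `prepare`).
#' @param roi Clipped [rect_roi()] for the region.
#' @param params [enhance_params()] controlling segmentation.
#' @param region Region identifier (`"vallecula"` or `"pyriform"`).
#' @param prepare If `TRUE` (default) the image is blue-boosted before
#'   segmentation; pass `FALSE` when a prepared image or precomputed
#'   `mask` is supplied.
#' @param mask Optional precomputed residue mask (skips segmentation).
#' @param severe_includes_50 Passed to [severity_from_fraction()].
#' @return One-row tibble of class `residue_measurement` with `region`,
#'   `blue_pixels`, `total_pixels`, `fraction`, `severity`.
#' @export
classify_region <- function(img, roi, params = enhance_params(),
                            region = "vallecula", prepare = TRUE,
                            mask = NULL, severe_includes_50 = FALSE) {
  if (is.null(mask)) {
    src <- if (prepare) boost_blue(img, params) else img
    mask <- segment_residue(src, params)
  }
  rf <- residue_fraction(mask, roi)
  out <- tibble::tibble(region = region, rf,
                        severity = severity_from_fraction(
                          rf$fraction, severe_includes_50))
  class(out) <- c("residue_measurement", class(out))
  out
}

#' Penetration/aspiration call from the 3x3 glottic grid
#'
#' Computes the residue fraction of each grid cell; a cell is "present"
#' when its fraction reaches `cell_presence_threshold`. Residue present in
#' any central cell (the glottic entry) flags aspiration; residue present
#' in any other cell flags penetration; both flags may be raised, and both
#' are `FALSE` when no cell is present. The cell with the highest fraction
#' is reported (row-major earliest on ties).
#'
#' @param img Colour image (already enhanced; see `prepare`).
#' @param grid A [glottis_grid()] within the image.
#' @param params [enhance_params()].
#' @param cfg [geometry_config()] supplying the central-cell set.
#' @param cell_presence_threshold Minimum cell fraction counting as
#'   presence (default 0.01, mirroring the global absence cutoff).
#' @param prepare,mask As in [classify_region()].
#' @return Object of class `invasion_call`: list with `cell_fractions`
#'   (3x3 matrix), `argmax_cell` (`c(row, col)`, 1-based), `penetration`,
#'   `aspiration`.
#' @export
detect_invasion <- function(img, grid, params = enhance_params(),
                            cfg = geometry_config(),
                            cell_presence_threshold = 0.01,
                            prepare = TRUE, mask = NULL) {
  stopifnot(inherits(grid, "grid_roi"))
  if (is.null(mask)) {
    src <- if (prepare) boost_blue(img, params) else img
    mask <- segment_residue(src, params)
  }
  fr <- matrix(0, 3, 3)
  for (r in 1:3) {
    for (cl in 1:3) {
      fr[r, cl] <- residue_fraction(mask, grid$cells[[r, cl]])$fraction
    }
  }
  central <- matrix(FALSE, 3, 3)
  for (cc in cfg$central_cells) central[cc[1], cc[2]] <- TRUE
  present <- fr >= cell_presence_threshold
  # row-major argmax with earliest-cell tie break
  ord <- order(-as.vector(t(fr)))[1]
  argmax <- c(((ord - 1) %/% 3) + 1, ((ord - 1) %% 3) + 1)
  structure(list(cell_fractions = fr, argmax_cell = as.integer(argmax),
                 penetration = any(present & !central),
                 aspiration = any(present & central),
                 cell_presence_threshold = cell_presence_threshold,
                 central_cells = cfg$central_cells),
            class = "invasion_call")
}

#' @export
print.invasion_call <- function(x, ...) {
  cat("<invasion_call> penetration=", x$penetration,
      " aspiration=", x$aspiration,
      " argmax cell (row,col)=(", x$argmax_cell[1], ",", x$argmax_cell[2],
      ")\n", sep = "")
  invisible(x)
}

#' Analyse one swallow
#'
#' Selects the best-tracked frames immediately before and after the
#' whiteout (the whiteout frame itself is excluded from both windows),
#' enhances the post-whiteout frame, builds the three ROIs from its
#' landmarks, quantifies vallecular and pyriform residue and applies the
#' 3x3 grid rule; the pre-whiteout frame is measured the same way and
#' kept as baseline.
#'
#' @param video A [tracked_video()].
#' @param frames List of colour [EBImage::Image] frames indexed by frame
#'   number + 1, or a directory of PNG frames in frame order.
#' @param interval One-row tibble/list with `swallow_id`, `t_start`,
#'   `t_end`, `t_whiteout` (seconds).
#' @param config Optional analysis configuration ([feesr_config()]).
#' @return Object of class `swallow_analysis`.
#' @export
analyze_swallow <- function(video, frames, interval, config = feesr_config()) {
  stopifnot(inherits(video, "tracked_video"))
  frames <- as_frame_list(frames)
  fps <- video$fps
  w_frame <- floor(interval$t_whiteout * fps + 1e-9)
  idx <- window_to_indices(interval$t_start, interval$t_end, fps)

  pre_frame <- tryCatch(
    select_best_frame_idx(video, idx[1], w_frame - 1),
    error = function(e) stop("swallow '", interval$swallow_id,
                             "': no adequate frame before the whiteout",
                             call. = FALSE))
  post_frame <- tryCatch(
    select_best_frame_idx(video, w_frame + 1, idx[2]),
    error = function(e) stop("swallow '", interval$swallow_id,
                             "': no adequate frame after the whiteout",
                             call. = FALSE))

  post <- measure_frame(video, frames, post_frame, config, with_invasion = TRUE)
  pre <- measure_frame(video, frames, pre_frame, config, with_invasion = FALSE)

  structure(list(swallow_id = as.character(interval$swallow_id),
                 interval = tibble::tibble(t_start = interval$t_start,
                                           t_end = interval$t_end,
                                           t_whiteout = interval$t_whiteout),
                 pre_frame = pre_frame, post_frame = post_frame,
                 whiteout_frame = w_frame,
                 measurements = post$measurements,
                 invasion = post$invasion,
                 baseline = pre$measurements,
                 rois = post$rois),
            class = "swallow_analysis")
}

# shared per-frame measurement used for the post (scored) and pre
# (baseline) frames
measure_frame <- function(video, frames, frame_idx, config, with_invasion) {
  img <- frames[[frame_idx + 1]]
  assert_color_image(img)
  d <- dim(img)[1:2]
  lm <- frame_landmarks(video, frame_idx)
  schema <- video$schema

  enhanced <- enhance_frame(img, config$enhance)
  boosted <- boost_blue(enhanced, config$enhance)
  mask <- segment_residue(boosted, config$enhance)

  rois <- list(
    vallecula = clip_roi(vallecula_rect(lm, schema, config$geometry), d[1], d[2]),
    pyriform = clip_roi(pyriform_rect(lm, schema, config$geometry), d[1], d[2]),
    glottis = clip_roi(glottis_square(lm, schema, config$geometry), d[1], d[2])
  )
  meas <- dplyr::bind_rows(
    classify_region(img, rois$vallecula, config$enhance, "vallecula",
                    mask = mask,
                    severe_includes_50 = config$classification$severe_includes_50),
    classify_region(img, rois$pyriform, config$enhance, "pyriform",
                    mask = mask,
                    severe_includes_50 = config$classification$severe_includes_50)
  )
  out <- list(measurements = meas, rois = rois, mask = mask,
              enhanced = enhanced)
  if (with_invasion) {
    grid <- glottis_grid(rois$glottis)
    out$invasion <- detect_invasion(
      img, grid, config$enhance, config$geometry,
      cell_presence_threshold = config$classification$cell_presence_threshold,
      mask = mask)
    out$grid <- grid
  }
  out
}

as_frame_list <- function(frames) {
  if (is.character(frames) && length(frames) == 1 && dir.exists(frames)) {
    paths <- sort(list.files(frames, pattern = "\\.(png|PNG|jpe?g|JPE?G)$",
                             full.names = TRUE))
    if (length(paths) == 0) stop("no frames found in ", frames, call. = FALSE)
    return(lapply(paths, read_frame))
  }
  if (is.list(frames)) return(frames)
  stop("frames must be a list of images or a directory path", call. = FALSE)
}

#' Read a frame image from disk
#' @param path PNG (or JPEG) file path.
#' @return Colour [EBImage::Image].
#' @export
read_frame <- function(path) {
  img <- EBImage::readImage(path)
  if (length(dim(img)) == 2) {
    img <- EBImage::Image(rep(as.vector(img), 3),
                          dim = c(dim(img), 3L), colormode = "Color")
  }
  if (dim(img)[3] > 3) img <- img[, , 1:3]
  EBImage::Image(img, dim = dim(img), colormode = "Color")
}

#' Write a frame image to disk
#' @param img Colour [EBImage::Image].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_frame <- function(img, path) {
  EBImage::writeImage(img, path)
  invisible(path)
}

#' @export
print.swallow_analysis <- function(x, ...) {
  cat("<swallow_analysis> '", x$swallow_id, "': pre frame ", x$pre_frame,
      ", post frame ", x$post_frame, "\n", sep = "")
  m <- x$measurements
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-10s %5.1f%%  %s\n", m$region[i], 100 * m$fraction[i],
                as.character(m$severity[i])))
  }
  cat("  penetration=", x$invasion$penetration,
      " aspiration=", x$invasion$aspiration, "\n", sep = "")
  invisible(x)
}
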
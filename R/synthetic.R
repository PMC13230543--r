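# Synthetic phantom frames, landmark tracks and labelled cohorts.
#
# The phantoms emulate the features the analysis chain depends on: a dark
# pinkish pharyngeal background, brighter mucosal structures, specular
# glare (white, unsaturated), whiteout frames (near-uniform bright), and
# blue-dyed residue rendered with an exact pixel count inside each
# landmark-derived ROI so that ground-truth fractions are known to the
# pixel. Everything is a pure function of its spec and seed.

#' Ground-truth landmark layout for phantom frames
#'
#' Coordinates are designed for a 256x256 frame and scaled linearly for
#' other sizes; the three derived ROIs (vallecula top, glottis centre,
#' pyriform bottom) are mutually disjoint and lie fully inside the frame.
#'
#' @param width,height Frame size in pixels.
#' @return Tibble with columns `structure`, `point`, `x`, `y`.
#' @export
default_phantom_landmarks <- function(width = 256, height = 256) {
  base <- tibble::tribble(
    ~structure, ~point, ~x, ~y,
    "epiglottis", 1L, 60, 48,
    "epiglottis", 2L, 128, 16,
    "epiglottis", 3L, 196, 48,
    "epiglottis", 4L, 128, 72,
    "arytenoids", 1L, 58, 212,
    "arytenoids", 2L, 128, 196,
    "arytenoids", 3L, 128, 252,
    "arytenoids", 4L, 198, 212,
    "vocal_folds", 1L, 88, 178,
    "vocal_folds", 2L, 148, 132,
    "vocal_folds", 3L, 108, 132,
    "vocal_folds", 4L, 128, 150
  )
  base$x <- base$x * width / 256
  base$y <- base$y * height / 256
  base
}

#' Specification of one phantom frame
#'
#' @param width,height Frame size in pixels.
#' @param landmarks Ground-truth landmark tibble
#'   ([default_phantom_landmarks()]).
#' @param residue_fractions Named numeric, target blue-pixel fraction in
#'   \[0, 1\] for `vallecula` and `pyriform`.
#' @param glottis_cell_fractions 3x3 numeric matrix of target fractions
#'   for the glottic grid cells.
#' @param residue_hue Dye hue in degrees (default 225, mid-blue).
#' @param residue_saturation,residue_value HSV saturation/value of the
#'   rendered dye.
#' @param glare_count Number of specular-glare ellipses (placed outside
#'   the ROIs).
#' @param glare_intensity Glare value (brightness), default 1.
#' @param whiteout If `TRUE` the frame is a near-uniform bright whiteout
#'   (no residue is rendered and landmark likelihoods are low).
#' @param jitter_sd Isotropic landmark jitter standard deviation (pixels).
#' @param likelihood_base,likelihood_sd Landmark likelihood model: base
#'   value plus Gaussian noise, clamped to \[0, 1\].
#' @param whiteout_likelihood Likelihood assigned to landmarks of whiteout
#'   frames (tracking fails during whiteout).
#' @param seed Integer seed fixing the frame bit-for-bit (`NULL` uses the
#'   current RNG state).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 256, height = 256,
                         landmarks = default_phantom_landmarks(width, height),
                         residue_fractions = c(vallecula = 0, pyriform = 0),
                         glottis_cell_fractions = matrix(0, 3, 3),
                         residue_hue = 225, residue_saturation = 0.85,
                         residue_value = 0.75,
                         glare_count = 0, glare_intensity = 1,
                         whiteout = FALSE, jitter_sd = 0,
                         likelihood_base = 0.95, likelihood_sd = 0.02,
                         whiteout_likelihood = 0.2, seed = NULL) {
  stopifnot(width >= 64, height >= 64,
            all(residue_fractions >= 0), all(residue_fractions <= 1),
            all(glottis_cell_fractions >= 0), all(glottis_cell_fractions <= 1),
            identical(dim(glottis_cell_fractions), c(3L, 3L)) ||
              identical(dim(glottis_cell_fractions), c(3, 3)),
            residue_hue >= 0, residue_hue < 360,
            jitter_sd >= 0, likelihood_base >= 0, likelihood_base <= 1)
  for (rg in c("vallecula", "pyriform")) {
    if (!rg %in% names(residue_fractions)) {
      stop("residue_fractions must name '", rg, "'", call. = FALSE)
    }
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 landmarks = landmarks,
                 residue_fractions = residue_fractions,
                 glottis_cell_fractions = glottis_cell_fractions,
                 residue_hue = residue_hue,
                 residue_saturation = residue_saturation,
                 residue_value = residue_value,
                 glare_count = as.integer(glare_count),
                 glare_intensity = glare_intensity,
                 whiteout = isTRUE(whiteout), jitter_sd = jitter_sd,
                 likelihood_base = likelihood_base,
                 likelihood_sd = likelihood_sd,
                 whiteout_likelihood = whiteout_likelihood,
                 seed = seed),
            class = "phantom_spec")
}

# exact-count compact blob: k pixels centred in the half-open ROI,
# shaped to roughly match the ROI's aspect ratio. Returns an n x 2 matrix
# of 0-based (x, y) pixel coordinates.
blob_pixels <- function(roi, k) {
  w_roi <- roi$x1 - roi$x0
  h_roi <- roi$y1 - roi$y0
  if (k == 0) return(matrix(integer(0), 0, 2))
  if (k > w_roi * h_roi) {
    stop("phantom generation error: ", k, " residue pixels do not fit in a ",
         w_roi, "x", h_roi, " ROI", call. = FALSE)
  }
  w <- min(w_roi, max(1L, ceiling(sqrt(k * w_roi / h_roi))))
  h_full <- k %/% w
  r <- k %% w
  h_tot <- h_full + (r > 0)
  if (h_tot > h_roi) {  # flat ROI: widen the blob
    w <- min(w_roi, ceiling(k / h_roi))
    h_full <- k %/% w
    r <- k %% w
    h_tot <- h_full + (r > 0)
  }
  x_off <- roi$x0 + (w_roi - w) %/% 2
  y_off <- roi$y0 + (h_roi - h_tot) %/% 2
  xs <- integer(0); ys <- integer(0)
  if (h_full > 0) {
    xs <- rep(x_off + 0:(w - 1), h_full)
    ys <- rep(y_off + 0:(h_full - 1), each = w)
  }
  if (r > 0) {
    x_par <- x_off + (w - r) %/% 2
    xs <- c(xs, x_par + 0:(r - 1))
    ys <- c(ys, rep(y_off + h_full, r))
  }
  cbind(xs, ys)
}

phantom_rois <- function(spec, cfg = geometry_config()) {
  lm <- spec$landmarks
  lm$likelihood <- 1
  frame <- lm[c("structure", "point", "x", "y", "likelihood")]
  sq <- clip_roi(glottis_square(frame, landmark_schema(), cfg),
                 spec$width, spec$height)
  list(vallecula = clip_roi(vallecula_rect(frame, landmark_schema(), cfg),
                            spec$width, spec$height),
       pyriform = clip_roi(pyriform_rect(frame, landmark_schema(), cfg),
                           spec$width, spec$height),
       glottis = sq,
       grid = glottis_grid(sq))
}

#' Render one phantom frame
#'
#' Blue residue is placed with an exact pixel count so the achieved
#' blue-pixel fraction inside each ROI (ROIs built by the geometry module
#' from the ground-truth landmarks) matches the target to well within
#' half a percentage point; whiteout frames are near-uniform bright.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (colour [EBImage::Image]), `landmarks`
#'   (frame-landmark tibble with jitter and likelihoods applied),
#'   `achieved` (tibble of achieved per-ROI fractions) and `rois`.
#' @export
make_phantom_frame <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) withr::local_seed(as.integer(spec$seed))
  w <- spec$width; h <- spec$height

  rois <- phantom_rois(spec)

  if (spec$whiteout) {
    # pharyngeal whiteout: the constricting pharynx floods the lens
    v <- matrix(0.97, w, h) + matrix(stats::rnorm(w * h, 0, 0.005), w, h)
    img <- hsv_to_img(matrix(20, w, h), matrix(0.05, w, h), pmin(v, 1))
    achieved <- tibble::tibble(region = c("vallecula", "pyriform"),
                               fraction = NA_real_)
  } else {
    img <- render_background(spec)
    img <- render_glare(img, spec, rois)
    res <- render_residue(img, spec, rois)
    img <- res$image
    achieved <- res$achieved
  }

  lm <- spec$landmarks
  n <- nrow(lm)
  if (spec$whiteout) {
    lik <- rep(spec$whiteout_likelihood, n)
  } else {
    lik <- pmin(pmax(spec$likelihood_base +
                       stats::rnorm(n, 0, spec$likelihood_sd), 0), 1)
  }
  landmarks <- tibble::tibble(
    structure = lm$structure, point = lm$point,
    x = lm$x + stats::rnorm(n, 0, spec$jitter_sd),
    y = lm$y + stats::rnorm(n, 0, spec$jitter_sd),
    likelihood = lik)

  list(image = img, landmarks = landmarks, achieved = achieved, rois = rois)
}

render_background <- function(spec) {
  w <- spec$width; h <- spec$height
  xg <- matrix(rep(seq_len(w), h), w, h)
  yg <- matrix(rep(seq_len(h), each = w), w, h)
  # dark pink mucosa with smooth illumination falloff plus sensor noise
  v <- 0.30 - 0.08 * ((xg / w - 0.5)^2 + (yg / h - 0.5)^2) * 4 +
    0.02 * sin(2 * pi * xg / w) * sin(2 * pi * yg / h) +
    matrix(stats::rnorm(w * h, 0, 0.01), w, h)
  s <- 0.50 + 0.05 * sin(2 * pi * yg / h) +
    matrix(stats::rnorm(w * h, 0, 0.01), w, h)
  hue <- matrix(350, w, h) + matrix(stats::rnorm(w * h, 0, 2), w, h)
  img <- hsv_to_img(hue, pmin(pmax(s, 0), 1), pmin(pmax(v, 0.05), 1))
  # brighter mucosal folds (pink, mid-value) as distractor structures
  img <- draw_ellipse(img, 0.15 * w, 0.55 * h, 0.06 * w, 0.16 * h,
                      hue = 345, s = 0.45, v = 0.50)
  img <- draw_ellipse(img, 0.85 * w, 0.55 * h, 0.06 * w, 0.16 * h,
                      hue = 345, s = 0.45, v = 0.50)
  img
}

draw_ellipse <- function(img, cx, cy, rx, ry, hue, s, v) {
  d <- dim(img)[1:2]
  xg <- matrix(rep(seq_len(d[1]) - 1, d[2]), d[1], d[2])
  yg <- matrix(rep(seq_len(d[2]) - 1, each = d[1]), d[1], d[2])
  sel <- ((xg - cx) / rx)^2 + ((yg - cy) / ry)^2 <= 1
  if (!any(sel)) return(img)
  col <- grDevices::col2rgb(grDevices::hsv(hue / 360, s, v))[, 1] / 255
  n <- prod(d)
  idx <- which(sel)
  for (k in 1:3) img[idx + (k - 1) * n] <- col[k]
  img
}

render_glare <- function(img, spec, rois) {
  if (spec$glare_count == 0) return(img)
  w <- spec$width; h <- spec$height
  boxes <- lapply(rois[c("vallecula", "pyriform", "glottis")], identity)
  placed <- 0
  tries <- 0
  while (placed < spec$glare_count && tries < 200) {
    tries <- tries + 1
    cx <- stats::runif(1, 0.05 * w, 0.95 * w)
    cy <- stats::runif(1, 0.05 * h, 0.95 * h)
    rx <- stats::runif(1, 0.02 * w, 0.05 * w)
    ry <- stats::runif(1, 0.02 * h, 0.05 * h)
    clash <- any(vapply(boxes, function(b) {
      cx + rx >= b$x0 - 2 && cx - rx <= b$x1 + 2 &&
        cy + ry >= b$y0 - 2 && cy - ry <= b$y1 + 2
    }, logical(1)))
    if (clash) next
    img <- draw_ellipse(img, cx, cy, rx, ry, hue = 60, s = 0.02,
                        v = min(spec$glare_intensity, 1))
    placed <- placed + 1
  }
  img
}

render_residue <- function(img, spec, rois) {
  col <- grDevices::col2rgb(grDevices::hsv(spec$residue_hue / 360,
                                           spec$residue_saturation,
                                           spec$residue_value))[, 1] / 255
  n <- prod(dim(img)[1:2])
  paint <- function(img, px) {
    if (nrow(px) == 0) return(img)
    idx <- px[, 1] + 1 + px[, 2] * dim(img)[1]
    for (k in 1:3) img[idx + (k - 1) * n] <- col[k]
    img
  }
  achieved <- tibble::tibble(region = character(0), fraction = double(0))
  for (rg in c("vallecula", "pyriform")) {
    roi <- rois[[rg]]
    k <- round(spec$residue_fractions[[rg]] * roi_area(roi))
    img <- paint(img, blob_pixels(roi, k))
    achieved <- dplyr::bind_rows(
      achieved, tibble::tibble(region = rg, fraction = k / roi_area(roi)))
  }
  cellfrac <- matrix(0, 3, 3)
  for (r in 1:3) {
    for (cl in 1:3) {
      f <- spec$glottis_cell_fractions[r, cl]
      if (f > 0) {
        cell <- rois$grid$cells[[r, cl]]
        k <- round(f * roi_area(cell))
        img <- paint(img, blob_pixels(cell, k))
        cellfrac[r, cl] <- k / roi_area(cell)
      }
    }
  }
  achieved <- dplyr::bind_rows(
    achieved, tibble::tibble(region = "glottis_max_cell",
                             fraction = max(cellfrac)))
  attr(achieved, "glottis_cells") <- cellfrac
  list(image = img, achieved = achieved)
}

#' Generate a phantom frame sequence with a tracked video
#'
#' @param specs List of [phantom_spec()], one per frame in order.
#' @param seed Integer master seed; per-frame seeds are derived from it
#'   (overriding any seeds in the specs).
#' @param fps Frames per second of the resulting [tracked_video()].
#' @return List with `images` (list of frames), `video`
#'   ([tracked_video()]) and `frames` (list of per-frame generator
#'   outputs).
#' @export
make_tracked_video <- function(specs, seed = 1L, fps = 30) {
  stopifnot(length(specs) >= 1)
  out <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    sp$seed <- as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
    out[[i]] <- make_phantom_frame(sp)
  }
  landmarks <- dplyr::bind_rows(lapply(seq_along(out), function(i) {
    dplyr::mutate(out[[i]]$landmarks, frame = i - 1L, .before = 1)
  }))
  list(images = lapply(out, `[[`, "image"),
       video = tracked_video(landmarks, fps = fps),
       frames = out)
}

severity_target_band <- function(level, margin = 0.02) {
  switch(level,
         absence = c(0, 0),
         trace = c(0.01 + margin, 0.05 - margin),
         mild = c(0.05 + margin, 0.25 - margin),
         moderate = c(0.25 + margin, 0.48),
         severe = c(0.50 + margin, 0.70))
}

draw_fraction_for_level <- function(level, margin = 0.02) {
  band <- severity_target_band(level, margin)
  if (band[1] >= band[2]) band[1] else stats::runif(1, band[1], band[2])
}

#' Generate a labelled validation cohort
#'
#' Each case is a short phantom exam: two clean pre-whiteout frames, one
#' whiteout frame and two post-whiteout frames carrying the case's
#' residue, plus a matching [tracked_video()] and swallow interval.
#' Ground-truth severities are drawn per region, with target fractions
#' kept at least `margin` away from the YPR-SRS boundaries so labels are
#' unambiguous; penetration/aspiration are planted in the glottic grid.
#'
#' @param n Number of cases.
#' @param prevalence Named list/vector with `penetration` and `aspiration`
#'   prevalences in \[0, 1\] (default 0.5 each, mirroring a balanced
#'   validation set).
#' @param seed Integer master seed.
#' @param severity_probs Probability weights over [severity_levels()] used
#'   to draw each region's severity (default uniform).
#' @param margin Minimum distance (fraction) between a target and the
#'   YPR-SRS boundaries (default 0.02 = 2 percentage points).
#' @param jitter_sd Landmark jitter passed to the phantoms (pixels).
#' @param glare_count Glare ellipses per frame.
#' @param width,height Frame size.
#' @param invasion_cell_fraction Blue fraction planted in each invaded
#'   grid cell (default 0.25).
#' @param fps Frames per second.
#' @return List of `cohort_case` objects; the label manifest is attached
#'   as attribute `"manifest"` (also retrievable with
#'   [cohort_manifest()]).
#' @export
make_validation_cohort <- function(n, prevalence = c(penetration = 0.5,
                                                     aspiration = 0.5),
                                   seed = 1L,
                                   severity_probs = rep(1, 5),
                                   margin = 0.02, jitter_sd = 0,
                                   glare_count = 0,
                                   width = 256, height = 256,
                                   invasion_cell_fraction = 0.25,
                                   fps = 30) {
  stopifnot(n >= 1, prevalence[["penetration"]] >= 0,
            prevalence[["penetration"]] <= 1,
            prevalence[["aspiration"]] >= 0, prevalence[["aspiration"]] <= 1)
  withr::local_seed(as.integer(seed))
  lv <- severity_levels()
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    sev_v <- sample(lv, 1, prob = severity_probs)
    sev_p <- sample(lv, 1, prob = severity_probs)
    pen <- stats::runif(1) < prevalence[["penetration"]]
    asp <- stats::runif(1) < prevalence[["aspiration"]]
    f_v <- draw_fraction_for_level(sev_v, margin)
    f_p <- draw_fraction_for_level(sev_p, margin)
    cells <- matrix(0, 3, 3)
    if (asp) cells[2, 2] <- invasion_cell_fraction
    if (pen) {
      periph <- which(matrix(1:9, 3, 3, byrow = TRUE) != 5, arr.ind = TRUE)
      pick <- periph[sample(nrow(periph), 1), ]
      cells[pick[1], pick[2]] <- invasion_cell_fraction
    }
    case_seed <- as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)

    clean <- phantom_spec(width, height, jitter_sd = jitter_sd,
                          glare_count = glare_count)
    loaded <- phantom_spec(width, height,
                           residue_fractions = c(vallecula = f_v,
                                                 pyriform = f_p),
                           glottis_cell_fractions = cells,
                           jitter_sd = jitter_sd, glare_count = glare_count)
    white <- phantom_spec(width, height, whiteout = TRUE,
                          jitter_sd = jitter_sd)
    gen <- make_tracked_video(list(clean, clean, white, loaded, loaded),
                              seed = case_seed, fps = fps)
    interval <- tibble::tibble(swallow_id = sprintf("case%03d_s1", i),
                               t_start = 0, t_whiteout = 2.5 / fps,
                               t_end = 4.9 / fps)
    achieved <- gen$frames[[4]]$achieved
    truth <- tibble::tibble(
      case_id = sprintf("case%03d", i),
      vallecula = severity_from_fraction(
        achieved$fraction[achieved$region == "vallecula"]),
      pyriform = severity_from_fraction(
        achieved$fraction[achieved$region == "pyriform"]),
      penetration = pen, aspiration = asp)
    cases[[i]] <- structure(
      list(case_id = truth$case_id, truth = truth,
           images = gen$images, video = gen$video, interval = interval,
           target_fractions = c(vallecula = f_v, pyriform = f_p),
           glottis_cells = cells),
      class = "cohort_case")
  }
  attr(cases, "manifest") <- cohort_manifest(cases)
  cases
}

#' Ground-truth label manifest of a cohort
#' @param cases List of `cohort_case` objects.
#' @return Tibble with one row per case.
#' @export
cohort_manifest <- function(cases) {
  dplyr::bind_rows(lapply(cases, `[[`, "truth"))
}

#' Write a cohort to disk
#'
#' Emits, per case, PNG frames, the pose CSV, a swallow-interval CSV and
#' a JSON label manifest for the whole cohort.
#'
#' @param cases Cohort from [make_validation_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (case in cases) {
    cdir <- file.path(dir, case$case_id)
    dir.create(file.path(cdir, "frames"), recursive = TRUE,
               showWarnings = FALSE)
    for (i in seq_along(case$images)) {
      write_frame(case$images[[i]],
                  file.path(cdir, "frames", sprintf("frame%04d.png", i - 1)))
    }
    write_pose_csv(case$video, file.path(cdir, "pose.csv"))
    write_intervals(case$interval, file.path(cdir, "intervals.csv"))
  }
  manifest <- cohort_manifest(cases)
  manifest$vallecula <- as.character(manifest$vallecula)
  manifest$pyriform <- as.character(manifest$pyriform)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
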
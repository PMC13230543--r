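# Pose-tracking CSV I/O, frame-quality rules and frame selection.
#
# The CSV dialect is the DeepLabCut one: three header rows (scorer,
# bodyparts repeated x3, coords = x/y/likelihood), then one data row per
# frame whose first column is the 0-based frame index. Missing or
# untrackable points are encoded as NA coordinates with likelihood 0 so
# they count against frame adequacy instead of crashing geometry.

#' Construct a tracked video from a landmark table
#'
#' @param landmarks Tibble/data frame with columns `frame` (0-based integer),
#'   `structure`, `point`, `x`, `y`, `likelihood`. Every frame must contain
#'   one row per schema point.
#' @param fps Frames per second (default 30, the usual endoscopic sampling
#'   rate).
#' @param schema A [landmark_schema()].
#' @return An object of class `tracked_video`.
#' @export
tracked_video <- function(landmarks, fps = 30, schema = landmark_schema()) {
  stopifnot(is.data.frame(landmarks), fps > 0)
  needed <- c("frame", "structure", "point", "x", "y", "likelihood")
  missing <- setdiff(needed, names(landmarks))
  if (length(missing) > 0) {
    stop("landmarks is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  landmarks <- tibble::as_tibble(landmarks)[needed]
  landmarks$frame <- as.integer(landmarks$frame)
  landmarks$point <- as.integer(landmarks$point)
  lik <- landmarks$likelihood
  if (any(!is.na(lik) & (lik < 0 | lik > 1))) {
    stop("likelihood values must lie in [0, 1]", call. = FALSE)
  }
  landmarks$likelihood[is.na(lik)] <- 0
  # points with non-finite coordinates are missing: likelihood forced to 0
  bad_xy <- !is.finite(landmarks$x) | !is.finite(landmarks$y)
  landmarks$likelihood[bad_xy] <- 0
  landmarks$x[bad_xy] <- NA_real_
  landmarks$y[bad_xy] <- NA_real_

  frames <- sort(unique(landmarks$frame))
  if (length(frames) > 0 && any(diff(frames) <= 0)) {
    stop("frame indices must be strictly increasing", call. = FALSE)
  }
  npts <- length(schema$structures) * schema$points_per_structure
  counts <- table(landmarks$frame)
  if (length(counts) > 0 && any(counts != npts)) {
    stop("every frame must have exactly ", npts, " landmark rows",
         call. = FALSE)
  }
  landmarks <- dplyr::arrange(landmarks, .data$frame,
                              match(.data$structure, schema$structures),
                              .data$point)
  structure(list(fps = fps, schema = schema, landmarks = landmarks),
            class = "tracked_video")
}

#' Number of frames in a tracked video
#' @param video A `tracked_video`.
#' @return Integer frame count.
#' @export
n_frames <- function(video) {
  stopifnot(inherits(video, "tracked_video"))
  length(unique(video$landmarks$frame))
}

#' Landmarks of a single frame
#'
#' @param video A `tracked_video`.
#' @param frame 0-based frame index.
#' @return Tibble with columns `structure`, `point`, `x`, `y`, `likelihood`.
#' @export
frame_landmarks <- function(video, frame) {
  stopifnot(inherits(video, "tracked_video"))
  out <- video$landmarks[video$landmarks$frame == frame,
                         c("structure", "point", "x", "y", "likelihood")]
  if (nrow(out) == 0) {
    stop("frame ", frame, " is not present in the video", call. = FALSE)
  }
  out
}

#' @export
print.tracked_video <- function(x, ...) {
  cat("<tracked_video> ", n_frames(x), " frames @ ", x$fps, " fps, ",
      length(x$schema$structures), " structures x ",
      x$schema$points_per_structure, " points\n", sep = "")
  invisible(x)
}

#' Read a pose-tracking CSV
#'
#' Parses the three-header-row dialect written by markerless
#' pose-estimation software: row 1 names the scorer, row 2 repeats each
#' bodypart label three times, row 3 cycles `x`, `y`, `likelihood`; data
#' rows carry the frame index in the first column. Non-numeric cells
#' become missing points with likelihood 0.
#'
#' @param path Path to the CSV file.
#' @param schema A [landmark_schema()]; the file's bodyparts must cover
#'   every label in [schema_bodyparts()].
#' @param fps Frames per second recorded with the video (not stored in the
#'   CSV dialect).
#' @return A [tracked_video()].
#' @export
read_pose_csv <- function(path, schema = landmark_schema(), fps = 30) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) {
    stop("malformed pose CSV: expected 3 header rows in ", path, call. = FALSE)
  }
  split_row <- function(s) strsplit(s, ",", fixed = TRUE)[[1]]
  bodyrow <- split_row(lines[2])
  coordrow <- split_row(lines[3])
  if (length(bodyrow) < 4 || tolower(bodyrow[1]) != "bodyparts") {
    stop("malformed pose CSV header: row 2 must start with 'bodyparts'",
         call. = FALSE)
  }
  if (tolower(coordrow[1]) != "coords") {
    stop("malformed pose CSV header: row 3 must start with 'coords'",
         call. = FALSE)
  }
  parts <- bodyrow[-1]
  coords <- tolower(coordrow[-1])
  if (length(parts) != length(coords)) {
    stop("malformed pose CSV header: bodyparts and coords rows disagree in length",
         call. = FALSE)
  }
  expected <- schema_bodyparts(schema)
  missing <- setdiff(expected, unique(parts))
  if (length(missing) > 0) {
    stop("pose CSV is missing bodypart(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  # column index of each (bodypart, coord) triple, +1 for the frame column
  col_of <- function(part, coord) {
    i <- which(parts == part & coords == coord)
    if (length(i) != 1) {
      stop("pose CSV must have exactly one '", coord, "' column for bodypart '",
           part, "'", call. = FALSE)
    }
    i + 1L
  }
  ncol_total <- length(parts) + 1L

  data_lines <- lines[-(1:3)]
  data_lines <- data_lines[nzchar(trimws(data_lines))]
  n <- length(data_lines)

  grid <- tidyr::expand_grid(structure = schema$structures,
                             point = seq_len(schema$points_per_structure))
  if (n == 0) {
    empty <- tibble::tibble(frame = integer(0), structure = character(0),
                            point = integer(0), x = double(0), y = double(0),
                            likelihood = double(0))
    return(tracked_video(empty, fps = fps, schema = schema))
  }

  cells <- strsplit(data_lines, ",", fixed = TRUE)
  lens <- lengths(cells)
  bad <- which(lens != ncol_total)
  if (length(bad) > 0) {
    stop("pose CSV row ", bad[1], " has ", lens[bad[1]], " fields, expected ",
         ncol_total, call. = FALSE)
  }
  mat <- matrix(unlist(cells), nrow = n, byrow = TRUE)
  num <- function(v) suppressWarnings(as.numeric(v))
  frame_idx <- num(mat[, 1])
  if (anyNA(frame_idx)) {
    stop("pose CSV row ", which(is.na(frame_idx))[1],
         " has a non-numeric frame index", call. = FALSE)
  }

  per_point <- purrr::pmap(grid, function(structure, point) {
    part <- paste0(structure, "_", point)
    x <- num(mat[, col_of(part, "x")])
    y <- num(mat[, col_of(part, "y")])
    lik <- num(mat[, col_of(part, "likelihood")])
    lik[is.na(lik)] <- 0
    lik[is.na(x) | is.na(y)] <- 0
    tibble::tibble(frame = as.integer(frame_idx), structure = structure,
                   point = as.integer(point), x = x, y = y,
                   likelihood = pmin(pmax(lik, 0), 1))
  })
  tracked_video(dplyr::bind_rows(per_point), fps = fps, schema = schema)
}

#' Write a tracked video as a pose CSV
#'
#' The file round-trips through [read_pose_csv()] exactly to the written
#' precision (6 decimal places).
#'
#' @param video A [tracked_video()].
#' @param path Output path.
#' @param scorer Scorer label written in the first header row.
#' @return `path`, invisibly.
#' @export
write_pose_csv <- function(video, path, scorer = "feesr") {
  stopifnot(inherits(video, "tracked_video"))
  schema <- video$schema
  parts <- schema_bodyparts(schema)
  header <- c(
    paste(c("scorer", rep(scorer, 3 * length(parts))), collapse = ","),
    paste(c("bodyparts", rep(parts, each = 3)), collapse = ","),
    paste(c("coords", rep(c("x", "y", "likelihood"), length(parts))),
          collapse = ",")
  )
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.6f", v))
  wide <- video$landmarks
  frames <- sort(unique(wide$frame))
  rows <- vapply(frames, function(f) {
    fr <- wide[wide$frame == f, ]
    key <- paste(fr$structure, fr$point, sep = "_")
    ord <- match(parts, key)
    paste(c(as.character(f),
            as.vector(rbind(fmt(fr$x[ord]), fmt(fr$y[ord]),
                            fmt(fr$likelihood[ord])))),
          collapse = ",")
  }, character(1))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(header, rows), con)
  invisible(path)
}

#' Is a frame adequately tracked?
#'
#' A frame is adequate when its landmark likelihoods clear the threshold.
#' The conservative default requires every point to reach the threshold;
#' `method = "mean"` instead gates on the mean likelihood over points.
#'
#' @param frame Frame-landmark tibble (see [frame_landmarks()]).
#' @param likelihood_threshold Threshold in \[0, 1\] (default 0.70, the
#'   usual per-point accuracy criterion).
#' @param method `"all"` (every point) or `"mean"` (mean over points).
#' @return Logical scalar.
#' @export
frame_is_adequate <- function(frame, likelihood_threshold = 0.70,
                              method = c("all", "mean")) {
  method <- match.arg(method)
  stopifnot(likelihood_threshold >= 0, likelihood_threshold <= 1)
  lik <- frame$likelihood
  lik[is.na(lik)] <- 0
  if (method == "all") all(lik >= likelihood_threshold)
  else mean(lik) >= likelihood_threshold
}

#' Video-level quality gate
#'
#' A video is excluded when points fall below the likelihood threshold in
#' more than `max_low_fraction` of its frames; a video with exactly that
#' fraction of inadequate frames still passes (strict inequality).
#'
#' @param video A [tracked_video()] with at least one frame.
#' @param likelihood_threshold Per-point likelihood threshold (default 0.70).
#' @param max_low_fraction Maximum tolerated fraction of inadequate frames
#'   (default 0.50).
#' @param method Frame-adequacy aggregation, see [frame_is_adequate()].
#' @return Logical scalar.
#' @export
video_passes_quality_gate <- function(video, likelihood_threshold = 0.70,
                                      max_low_fraction = 0.50,
                                      method = c("all", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(video, "tracked_video"))
  if (n_frames(video) == 0) {
    stop("quality gate needs at least one frame", call. = FALSE)
  }
  frac <- inadequate_fraction(video, likelihood_threshold, method)
  frac <= max_low_fraction
}

#' Fraction of inadequately tracked frames
#' @inheritParams video_passes_quality_gate
#' @return Numeric in \[0, 1\].
#' @export
inadequate_fraction <- function(video, likelihood_threshold = 0.70,
                                method = c("all", "mean")) {
  method <- match.arg(method)
  lm <- video$landmarks
  lik <- ifelse(is.na(lm$likelihood), 0, lm$likelihood)
  per_frame <- if (method == "all") {
    tapply(lik >= likelihood_threshold, lm$frame, all)
  } else {
    tapply(lik, lm$frame, mean) >= likelihood_threshold
  }
  mean(!per_frame)
}

# Frame i covers time [i/fps, (i+1)/fps); a numeric window [t_from, t_to]
# therefore maps to indices ceil(t_from*fps) .. floor(t_to*fps). A small
# relative guard absorbs floating-point noise at exact frame boundaries.
window_to_indices <- function(t_from, t_to, fps) {
  eps <- 1e-9
  lo <- ceiling(t_from * fps - eps)
  hi <- floor(t_to * fps + eps)
  c(lo, hi)
}

#' Select the best-tracked frame in a time window
#'
#' Returns the frame in `[t_from, t_to]` with the highest mean landmark
#' likelihood; ties go to the earliest frame.
#'
#' @param video A [tracked_video()].
#' @param t_from,t_to Window bounds in seconds.
#' @return 0-based frame index.
#' @export
select_best_frame <- function(video, t_from, t_to) {
  stopifnot(inherits(video, "tracked_video"))
  idx <- window_to_indices(t_from, t_to, video$fps)
  select_best_frame_idx(video, idx[1], idx[2])
}

# index-range variant used by the swallow orchestration
select_best_frame_idx <- function(video, i_lo, i_hi) {
  frames <- sort(unique(video$landmarks$frame))
  cand <- frames[frames >= i_lo & frames <= i_hi]
  if (length(cand) == 0) {
    stop("no frame available in the requested window [", i_lo, ", ", i_hi, "]",
         call. = FALSE)
  }
  lm <- video$landmarks
  lik <- ifelse(is.na(lm$likelihood), 0, lm$likelihood)
  means <- tapply(lik[lm$frame %in% cand], lm$frame[lm$frame %in% cand], mean)
  cand[which.max(means[as.character(cand)])]
}

#' Read a swallow-interval file
#'
#' Accepts CSV (columns `swallow_id`, `t_start`, `t_end`, `t_whiteout`) or
#' YAML (a list of entries with those fields). Times are seconds; each
#' interval must satisfy `t_start <= t_whiteout <= t_end`.
#'
#' @param path Path to the interval file (`.csv`, `.yml` or `.yaml`).
#' @return Tibble with one row per swallow.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$swallows)) raw <- raw$swallows
    out <- dplyr::bind_rows(lapply(raw, tibble::as_tibble))
  } else {
    out <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  }
  needed <- c("swallow_id", "t_start", "t_end", "t_whiteout")
  missing <- setdiff(needed, names(out))
  if (length(missing) > 0) {
    stop("interval file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- out[needed]
  out$swallow_id <- as.character(out$swallow_id)
  bad <- which(!(out$t_start <= out$t_whiteout & out$t_whiteout <= out$t_end))
  if (length(bad) > 0) {
    stop("interval '", out$swallow_id[bad[1]],
         "' violates t_start <= t_whiteout <= t_end", call. = FALSE)
  }
  out
}

#' Write a swallow-interval CSV
#' @param intervals Tibble as returned by [read_intervals()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(intervals, path) {
  utils::write.csv(
    intervals[c("swallow_id", "t_start", "t_end", "t_whiteout")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
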
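# Exam-level orchestration: quality gate, per-swallow analysis, report
# and annotated-image output, whiteout suggestion, and cohort validation.

#' Run a full exam analysis
#'
#' Applies the video quality gate, analyses every swallow interval with
#' [analyze_swallow()], and writes a machine-readable JSON report, a
#' clinical-style plain-text summary and annotated PNGs
#' (`<swallow>_pre.png`, `<swallow>_post.png`, `<swallow>_glottis_grid.png`,
#' `<swallow>_glottis_nogrid.png`) to the output directory. A video that
#' fails the gate produces a gate-failure report and no swallow entries.
#'
#' @param frames Directory of PNG frames (frame order = file order) or a
#'   list of colour images.
#' @param pose Path to the pose-tracking CSV, or a [tracked_video()].
#' @param intervals Path to a swallow-interval file, or a tibble as
#'   returned by [read_intervals()].
#' @param config A [feesr_config()], a path to a config file, or `NULL`
#'   for defaults.
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output.
#' @param exam_id Identifier used in the report (default the pose file
#'   name or `"exam"`).
#' @return An object of class `exam_report`.
#' @export
run_exam <- function(frames, pose, intervals, config = NULL, out_dir = NULL,
                     exam_id = NULL) {
  config <- if (is.null(config)) feesr_config()
            else if (is.character(config)) read_config(config)
            else config
  if (is.character(pose)) {
    if (is.null(exam_id)) exam_id <- tools::file_path_sans_ext(basename(pose))
    video <- read_pose_csv(pose, fps = config$landmark$fps)
  } else {
    video <- pose
  }
  if (is.null(exam_id)) exam_id <- "exam"
  frames <- as_frame_list(frames)
  if (is.character(intervals)) intervals <- read_intervals(intervals)

  mismatch <- abs(length(frames) - n_frames(video))
  if (mismatch > config$landmark$frame_count_slack) {
    stop("frame count (", length(frames), ") and pose CSV rows (",
         n_frames(video), ") differ by more than the tolerated slack of ",
         config$landmark$frame_count_slack, call. = FALSE)
  }
  if (mismatch > 0) {
    warning("frame count (", length(frames), ") and pose CSV rows (",
            n_frames(video), ") differ; proceeding on the overlap",
            call. = FALSE)
  }

  low_frac <- inadequate_fraction(video, config$landmark$likelihood_threshold,
                                  config$landmark$adequacy_method)
  gate_passed <- low_frac <= config$landmark$max_low_fraction
  quality_gate <- list(passed = gate_passed,
                       inadequate_fraction = low_frac,
                       likelihood_threshold = config$landmark$likelihood_threshold,
                       max_low_fraction = config$landmark$max_low_fraction)

  swallows <- list()
  image_paths <- list()
  if (gate_passed) {
    for (i in seq_len(nrow(intervals))) {
      sa <- analyze_swallow(video, frames, intervals[i, ], config)
      swallows[[length(swallows) + 1]] <- sa
      if (!is.null(out_dir)) {
        image_paths[[sa$swallow_id]] <-
          write_swallow_images(sa, video, frames, config, out_dir)
      }
    }
  }
  report <- structure(list(exam_id = exam_id, quality_gate = quality_gate,
                           swallows = swallows, image_paths = image_paths,
                           n_frames = n_frames(video), fps = video$fps),
                      class = "exam_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_json(report, file.path(out_dir, paste0(exam_id, "_report.json")))
    writeLines(format_report_text(report),
               file.path(out_dir, paste0(exam_id, "_report.txt")))
  }
  report
}

write_swallow_images <- function(sa, video, frames, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  post <- measure_frame(video, frames, sa$post_frame, config,
                        with_invasion = TRUE)
  pre_img <- frames[[sa$pre_frame + 1]]
  rois <- list(post$rois$vallecula, post$rois$pyriform, post$rois$glottis)
  paths <- list(
    pre = file.path(out_dir, paste0(sa$swallow_id, "_pre.png")),
    post = file.path(out_dir, paste0(sa$swallow_id, "_post.png")),
    glottis_grid = file.path(out_dir, paste0(sa$swallow_id, "_glottis_grid.png")),
    glottis_nogrid = file.path(out_dir, paste0(sa$swallow_id, "_glottis_nogrid.png")))
  write_frame(overlay_mask(pre_img, rois = rois), paths$pre)
  write_frame(overlay_mask(post$enhanced, post$mask, rois = rois), paths$post)
  f <- config$geometry$magnification
  crop <- magnify(post$enhanced, post$rois$glottis, f)
  write_frame(crop, paths$glottis_nogrid)
  sq <- post$rois$glottis
  mag_grid <- glottis_grid(rect_roi(0, 0, (sq$x1 - sq$x0) * f,
                                    (sq$y1 - sq$y0) * f))
  write_frame(overlay_mask(crop, grid = mag_grid), paths$glottis_grid)
  # recorded relative to the output directory so reports are reproducible
  lapply(paths, basename)
}

serialize_swallow <- function(sa) {
  m <- sa$measurements
  list(swallow_id = sa$swallow_id,
       t_start = sa$interval$t_start, t_end = sa$interval$t_end,
       t_whiteout = sa$interval$t_whiteout,
       pre_frame = sa$pre_frame, post_frame = sa$post_frame,
       measurements = lapply(seq_len(nrow(m)), function(i) {
         list(region = m$region[i], blue_pixels = m$blue_pixels[i],
              total_pixels = m$total_pixels[i], fraction = m$fraction[i],
              severity = as.character(m$severity[i]))
       }),
       baseline = lapply(seq_len(nrow(sa$baseline)), function(i) {
         b <- sa$baseline
         list(region = b$region[i], fraction = b$fraction[i],
              severity = as.character(b$severity[i]))
       }),
       rois = lapply(sa$rois, function(r) c(r$x0, r$y0, r$x1, r$y1)),
       invasion = list(
         penetration = sa$invasion$penetration,
         aspiration = sa$invasion$aspiration,
         argmax_cell = sa$invasion$argmax_cell,
         cell_fractions = apply(sa$invasion$cell_fractions, 1, as.list,
                                simplify = FALSE)))
}

write_report_json <- function(report, path) {
  obj <- list(exam_id = report$exam_id,
              quality_gate = report$quality_gate,
              n_frames = report$n_frames, fps = report$fps,
              swallows = lapply(report$swallows, serialize_swallow),
              images = report$image_paths)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

format_report_text <- function(report) {
  out <- c(sprintf("FEES analysis report - exam %s", report$exam_id),
           sprintf("Frames analysed: %d @ %g fps", report$n_frames,
                   report$fps),
           sprintf("Tracking quality gate: %s (%.0f%% of frames below the %.0f%% likelihood criterion)",
                   if (report$quality_gate$passed) "PASSED" else "FAILED",
                   100 * report$quality_gate$inadequate_fraction,
                   100 * report$quality_gate$likelihood_threshold))
  if (!report$quality_gate$passed) {
    return(c(out, "Video excluded: no swallow analysis performed."))
  }
  for (sa in report$swallows) {
    out <- c(out, "",
             sprintf("Swallow %s  [%.2f s - %.2f s], whiteout at %.2f s",
                     sa$swallow_id, sa$interval$t_start, sa$interval$t_end,
                     sa$interval$t_whiteout),
             sprintf("  frames: pre %d / post %d", sa$pre_frame,
                     sa$post_frame))
    m <- sa$measurements
    for (i in seq_len(nrow(m))) {
      out <- c(out, sprintf("  %-10s residue %5.1f%%  -> %s", m$region[i],
                            100 * m$fraction[i],
                            toupper(as.character(m$severity[i]))))
    }
    alerts <- c(if (sa$invasion$penetration) "PENETRATION",
                if (sa$invasion$aspiration) "ASPIRATION")
    out <- c(out, sprintf("  airway invasion: %s",
                          if (length(alerts)) paste(alerts, collapse = " + ")
                          else "none detected"))
  }
  out
}

#' @export
print.exam_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}

#' Suggest whiteout candidates from frame brightness
#'
#' Advisory helper for interval annotation: flags frames whose mean
#' intensity exceeds both the given percentile of the exam's intensity
#' distribution and an absolute floor, merged into contiguous runs. It
#' never feeds the analysis automatically.
#'
#' @param frames Directory of PNGs or a list of colour images.
#' @param percentile Percentile of the per-frame mean-intensity
#'   distribution (default 0.90).
#' @param min_intensity Absolute mean-intensity floor (default 0.75);
#'   prevents spurious candidates in uniformly dark exams.
#' @param fps Frames per second used to convert to times.
#' @return Tibble with `start_frame`, `end_frame`, `t_start`, `t_end`.
#' @export
suggest_whiteout <- function(frames, percentile = 0.90, min_intensity = 0.75,
                             fps = 30) {
  frames <- as_frame_list(frames)
  stopifnot(length(frames) >= 1)
  means <- vapply(frames, function(f) mean(as.numeric(f)), numeric(1))
  thr <- stats::quantile(means, percentile, names = FALSE)
  hot <- means > thr & means >= min_intensity
  if (!any(hot)) {
    return(tibble::tibble(start_frame = integer(0), end_frame = integer(0),
                          t_start = double(0), t_end = double(0)))
  }
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  tibble::tibble(start_frame = starts[keep] - 1L,
                 end_frame = ends[keep] - 1L,
                 t_start = (starts[keep] - 1) / fps,
                 t_end = ends[keep] / fps)
}

#' Validate predicted labels against a reference manifest
#'
#' Builds the penetration and aspiration 2x2 confusions and the per-region
#' ordinal confusions, and emits the validation tables: binary metrics
#' with AUC, kappa and Fisher p per binary outcome, weighted kappa per
#' region, and dichotomized grade-comparison rows per region.
#'
#' @param predictions,reference Tibbles (or paths to JSON/CSV manifests)
#'   with columns `case_id`, `vallecula`, `pyriform` (severity levels),
#'   `penetration`, `aspiration` (logicals).
#' @param config A [feesr_config()] (stats section controls kappa
#'   weighting and Fisher method).
#' @return Object of class `cohort_validation`: list with `binary`
#'   (tibble), `ordinal` (per-region list with confusion, kappa and
#'   `grade_comparisons` tibble) and `n`.
#' @export
validate_cohort <- function(predictions, reference, config = feesr_config()) {
  predictions <- read_manifest(predictions)
  reference <- read_manifest(reference)
  extra <- setdiff(predictions$case_id, reference$case_id)
  missing <- setdiff(reference$case_id, predictions$case_id)
  if (length(extra) > 0 || length(missing) > 0) {
    stop("case id mismatch between predictions and reference",
         if (length(extra)) paste0("; unmatched predictions: ",
                                   paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; unmatched reference: ",
                                     paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(predictions, reference, by = "case_id",
                              suffix = c("_pred", "_ref"))

  binary <- dplyr::bind_rows(lapply(c("penetration", "aspiration"),
                                    function(outc) {
    c2 <- confusion_from_labels(joined[[paste0(outc, "_ref")]],
                                joined[[paste0(outc, "_pred")]])
    tibble::tibble(outcome = outc, binary_metrics(c2),
                   auc = balanced_auc(c2),
                   kappa = cohen_kappa(c2, "none"),
                   fisher_p = fisher_exact_2x2(c2, config$stats$fisher_method))
  }))

  ordinal <- lapply(c(vallecula = "vallecula", pyriform = "pyriform"),
                    function(rg) {
    oc <- ordinal_confusion(joined[[paste0(rg, "_ref")]],
                            joined[[paste0(rg, "_pred")]])
    present <- severity_levels()[rowSums(oc) > 0]
    pairs <- list()
    for (lvl in setdiff(present, "absence")) {
      if ("absence" %in% present) pairs[[length(pairs) + 1]] <- c("absence", lvl)
    }
    if (length(present) >= 2) {
      for (i in seq_len(length(present) - 1)) {
        pr <- c(present[i], present[i + 1])
        if (!identical(pr[1], "absence")) pairs[[length(pairs) + 1]] <- pr
      }
    }
    gc_tbl <- dplyr::bind_rows(lapply(pairs, function(pr) {
      tryCatch(grade_comparison_metrics(oc, pr[1], pr[2]),
               error = function(e) NULL)
    }))
    list(confusion = oc,
         kappa = cohen_kappa(oc, config$stats$kappa_weights),
         accuracy = sum(diag(oc)) / sum(oc),
         grade_comparisons = gc_tbl)
  })

  structure(list(binary = binary, ordinal = ordinal, n = nrow(joined)),
            class = "cohort_validation")
}

read_manifest <- function(x) {
  if (is.character(x) && length(x) == 1) {
    ext <- tolower(tools::file_ext(x))
    x <- if (ext == "json") {
      tibble::as_tibble(jsonlite::read_json(x, simplifyVector = TRUE))
    } else {
      tibble::as_tibble(utils::read.csv(x, stringsAsFactors = FALSE))
    }
  }
  x <- tibble::as_tibble(x)
  needed <- c("case_id", "vallecula", "pyriform", "penetration", "aspiration")
  miss <- setdiff(needed, names(x))
  if (length(miss) > 0) {
    stop("manifest is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x$case_id <- as.character(x$case_id)
  x$vallecula <- as_severity(x$vallecula)
  x$pyriform <- as_severity(x$pyriform)
  x$penetration <- as.logical(x$penetration)
  x$aspiration <- as.logical(x$aspiration)
  x
}

#' Run the analysis over a generated cohort and collect predicted labels
#'
#' Convenience wrapper used for end-to-end validation: analyses each
#' cohort case with [analyze_swallow()] and returns a prediction manifest
#' aligned with [cohort_manifest()].
#'
#' @param cases Cohort from [make_validation_cohort()].
#' @param config A [feesr_config()].
#' @return Tibble with `case_id`, `vallecula`, `pyriform`, `penetration`,
#'   `aspiration`.
#' @export
predict_cohort <- function(cases, config = feesr_config()) {
  dplyr::bind_rows(lapply(cases, function(case) {
    sa <- analyze_swallow(case$video, case$images, case$interval, config)
    m <- sa$measurements
    tibble::tibble(
      case_id = case$case_id,
      vallecula = m$severity[m$region == "vallecula"],
      pyriform = m$severity[m$region == "pyriform"],
      penetration = sa$invasion$penetration,
      aspiration = sa$invasion$aspiration)
  }))
}

#' @export
print.cohort_validation <- function(x, ...) {
  cat("<cohort_validation> n =", x$n, "\n")
  print(x$binary)
  for (rg in names(x$ordinal)) {
    cat(sprintf("%s: accuracy %.2f, kappa %.2f\n", rg,
                x$ordinal[[rg]]$accuracy, x$ordinal[[rg]]$kappa))
  }
  invisible(x)
}
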
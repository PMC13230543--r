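# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a tracked video into its landmark table
#' @param x A [tracked_video()].
#' @param ... Unused.
#' @return Tibble with `frame`, `structure`, `point`, `x`, `y`,
#'   `likelihood`.
#' @method tidy tracked_video
#' @export
tidy.tracked_video <- function(x, ...) x$landmarks

#' One-row summary of a tracked video
#' @param x A [tracked_video()].
#' @param ... Unused.
#' @return Tibble with frame count, fps, likelihood summary and the
#'   default quality-gate verdict.
#' @method glance tracked_video
#' @export
glance.tracked_video <- function(x, ...) {
  tibble::tibble(
    n_frames = n_frames(x), fps = x$fps,
    n_structures = length(x$schema$structures),
    mean_likelihood = mean(x$landmarks$likelihood, na.rm = TRUE),
    inadequate_fraction = inadequate_fraction(x),
    passes_quality_gate = video_passes_quality_gate(x))
}

#' Tidy a swallow analysis
#' @param x A `swallow_analysis` from [analyze_swallow()].
#' @param ... Unused.
#' @return Tibble with one row per region and phase (baseline/post).
#' @method tidy swallow_analysis
#' @export
tidy.swallow_analysis <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(x$baseline), phase = "pre"),
    dplyr::mutate(tibble::as_tibble(x$measurements), phase = "post")) |>
    dplyr::mutate(swallow_id = x$swallow_id, .before = 1)
}

#' One-row summary of a swallow analysis
#' @param x A `swallow_analysis`.
#' @param ... Unused.
#' @return Tibble with selected frames, severities and invasion flags.
#' @method glance swallow_analysis
#' @export
glance.swallow_analysis <- function(x, ...) {
  m <- x$measurements
  tibble::tibble(
    swallow_id = x$swallow_id,
    pre_frame = x$pre_frame, post_frame = x$post_frame,
    vallecula_severity = m$severity[m$region == "vallecula"],
    pyriform_severity = m$severity[m$region == "pyriform"],
    penetration = x$invasion$penetration,
    aspiration = x$invasion$aspiration)
}

#' Tidy an invasion call into per-cell rows
#' @param x An `invasion_call` from [detect_invasion()].
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `fraction`, `central`, `present`,
#'   `argmax`.
#' @method tidy invasion_call
#' @export
tidy.invasion_call <- function(x, ...) {
  central <- matrix(FALSE, 3, 3)
  for (cc in x$central_cells) central[cc[1], cc[2]] <- TRUE
  grid <- tidyr::expand_grid(row = 1:3, col = 1:3)
  dplyr::mutate(grid,
                fraction = purrr::map2_dbl(row, col,
                                           ~ x$cell_fractions[.x, .y]),
                central = purrr::map2_lgl(row, col, ~ central[.x, .y]),
                present = .data$fraction >= x$cell_presence_threshold,
                argmax = row == x$argmax_cell[1] & col == x$argmax_cell[2])
}

#' Tidy an exam report
#' @param x An `exam_report` from [run_exam()].
#' @param ... Unused.
#' @return Tibble with one row per analysed swallow.
#' @method tidy exam_report
#' @export
tidy.exam_report <- function(x, ...) {
  if (length(x$swallows) == 0) {
    return(tibble::tibble(swallow_id = character(0)))
  }
  dplyr::bind_rows(lapply(x$swallows, glance))
}

#' One-row summary of an exam report
#' @param x An `exam_report`.
#' @param ... Unused.
#' @return Tibble with the gate verdict and alert counts.
#' @method glance exam_report
#' @export
glance.exam_report <- function(x, ...) {
  tb <- tidy(x)
  tibble::tibble(
    exam_id = x$exam_id,
    gate_passed = x$quality_gate$passed,
    inadequate_fraction = x$quality_gate$inadequate_fraction,
    n_swallows = length(x$swallows),
    n_penetration = if (nrow(tb)) sum(tb$penetration) else 0L,
    n_aspiration = if (nrow(tb)) sum(tb$aspiration) else 0L)
}

#' Tidy a cohort validation into a long metric table
#' @param x A `cohort_validation` from [validate_cohort()].
#' @param ... Unused.
#' @return Tibble with `outcome`, `metric`, `value`.
#' @method tidy cohort_validation
#' @export
tidy.cohort_validation <- function(x, ...) {
  wide <- x$binary[c("outcome", "accuracy", "auc", "sensitivity",
                     "specificity", "ppv", "npv", "plr", "nlr", "kappa",
                     "fisher_p")]
  tidyr::pivot_longer(wide, -"outcome", names_to = "metric",
                      values_to = "value")
}

#' One-row summary of a cohort validation
#' @param x A `cohort_validation`.
#' @param ... Unused.
#' @return Tibble with the headline agreement statistics.
#' @method glance cohort_validation
#' @export
glance.cohort_validation <- function(x, ...) {
  b <- x$binary
  tibble::tibble(
    n = x$n,
    penetration_accuracy = b$accuracy[b$outcome == "penetration"],
    penetration_kappa = b$kappa[b$outcome == "penetration"],
    aspiration_accuracy = b$accuracy[b$outcome == "aspiration"],
    aspiration_kappa = b$kappa[b$outcome == "aspiration"],
    vallecula_kappa = x$ordinal$vallecula$kappa,
    vallecula_accuracy = x$ordinal$vallecula$accuracy,
    pyriform_kappa = x$ordinal$pyriform$kappa,
    pyriform_accuracy = x$ordinal$pyriform$accuracy)
}

#' Plot landmark likelihood traces
#' @param object A [tracked_video()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tracked_video
#' @export
autoplot.tracked_video <- function(object, ...) {
  df <- dplyr::mutate(object$landmarks,
                      label = paste0(.data$structure, "_", .data$point))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$likelihood,
                                   colour = .data$structure,
                                   group = .data$label)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.70, linetype = "dashed") +
    ggplot2::labs(x = "frame", y = "tracking likelihood",
                  colour = "structure",
                  title = "Landmark tracking quality") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the 3x3 glottic grid of an invasion call
#' @param object An `invasion_call`.
#' @param ... Unused.
#' @return A ggplot object (tile heat map; central cells outlined).
#' @method autoplot invasion_call
#' @export
autoplot.invasion_call <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$fraction)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_tile(data = df[df$central, ], fill = NA,
                       colour = "red", linewidth = 1.2) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.1f%%", 100 * .data$fraction)), colour = "white") +
    ggplot2::scale_y_reverse(breaks = 1:3) +
    ggplot2::scale_x_continuous(breaks = 1:3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, NA)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "grid column", y = "grid row", fill = "residue",
                  title = sprintf("penetration=%s, aspiration=%s",
                                  object$penetration, object$aspiration)) +
    ggplot2::theme_minimal()
}

#' Plot cohort-validation metrics
#' @param object A `cohort_validation`.
#' @param ... Unused.
#' @return A ggplot object (metric bars per binary outcome).
#' @method autoplot cohort_validation
#' @export
autoplot.cohort_validation <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$metric %in% c("accuracy", "auc", "sensitivity", "specificity",
                            "ppv", "npv", "kappa"), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = "Agreement with reference labels") +
    ggplot2::theme_minimal()
}
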
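#' Severity levels of the Yale Pharyngeal Residue Severity Rating Scale
#'
#' The YPR-SRS grades pooled pharyngeal residue in the valleculae and the
#' pyriform sinuses on a five-level ordinal scale. `severity_levels()`
#' returns the levels in increasing order of severity.
#'
#' @return Character vector of the five ordered level names.
#' @export
#' @examples
#' severity_levels()
severity_levels <- function() {
  c("absence", "trace", "mild", "moderate", "severe")
}

#' Coerce to an ordered severity factor
#'
#' @param x Character vector of level names (or an ordered factor).
#' @return Ordered factor over [severity_levels()].
#' @export
as_severity <- function(x) {
  lv <- severity_levels()
  if (is.factor(x)) x <- as.character(x)
  bad <- setdiff(unique(x[!is.na(x)]), lv)
  if (length(bad) > 0) {
    stop("unknown severity level(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  factor(x, levels = lv, ordered = TRUE)
}

#' Landmark schema for tracked laryngopharyngeal structures
#'
#' Describes the anatomy tracked by the pose-estimation network: the ordered
#' structure names, the number of points annotated on each structure, and a
#' role map that assigns the abstract geometry roles `P1..P4` used by the
#' region-of-interest formulas to concrete `(structure, point)` pairs.
#'
#' The default schema tracks the epiglottis, the arytenoids and the vocal
#' folds with four points each. The vallecular rectangle is built from the
#' epiglottis points, the pyriform rectangle from the arytenoid points and
#' the glottic square from the vocal-fold points; which anatomical point
#' plays which role is a property of the annotation protocol, so the role
#' map is fully configurable.
#'
#' @param structures Ordered character vector of structure names.
#' @param points_per_structure Integer, points annotated per structure.
#' @param role_map Named list with entries `glottis`, `pyriform`,
#'   `vallecula`; each a named list mapping roles (`"P1"`...) to
#'   `list(structure =, point =)`. The glottis requires `P1..P3`, the other
#'   two regions `P1..P4`.
#' @return An object of class `landmark_schema`.
#' @export
#' @examples
#' sch <- landmark_schema()
#' schema_bodyparts(sch)
landmark_schema <- function(structures = c("epiglottis", "arytenoids", "vocal_folds"),
                            points_per_structure = 4L,
                            role_map = default_role_map()) {
  stopifnot(is.character(structures), length(structures) >= 1,
            !anyDuplicated(structures))
  points_per_structure <- as.integer(points_per_structure)
  stopifnot(points_per_structure >= 1)

  required <- list(glottis = paste0("P", 1:3),
                   pyriform = paste0("P", 1:4),
                   vallecula = paste0("P", 1:4))
  for (region in names(required)) {
    roles <- role_map[[region]]
    missing <- setdiff(required[[region]], names(roles))
    if (length(missing) > 0) {
      stop("role_map$", region, " is missing role(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (rn in names(roles)) {
      r <- roles[[rn]]
      if (!r$structure %in% structures) {
        stop("role ", region, "/", rn, " refers to unknown structure '",
             r$structure, "'", call. = FALSE)
      }
      if (r$point < 1 || r$point > points_per_structure) {
        stop("role ", region, "/", rn, " refers to point ", r$point,
             " outside 1..", points_per_structure, call. = FALSE)
      }
    }
  }

  structure(
    list(structures = structures,
         points_per_structure = points_per_structure,
         role_map = role_map),
    class = "landmark_schema"
  )
}

#' Default role map for the three-structure schema
#'
#' @return Named list suitable for the `role_map` argument of
#'   [landmark_schema()].
#' @export
default_role_map <- function() {
  mk <- function(structure, points) {
    stats::setNames(
      lapply(seq_along(points),
             function(i) list(structure = structure, point = points[i])),
      paste0("P", seq_along(points))
    )
  }
  list(
    glottis = mk("vocal_folds", 1:3),
    pyriform = mk("arytenoids", 1:4),
    vallecula = mk("epiglottis", 1:4)
  )
}

#' Bodypart labels implied by a schema
#'
#' Labels follow the `<structure>_<point>` convention used in the
#' pose-tracking CSV dialect.
#'
#' @param schema A [landmark_schema()].
#' @return Character vector, one label per tracked point, in schema order.
#' @export
schema_bodyparts <- function(schema) {
  stopifnot(inherits(schema, "landmark_schema"))
  as.vector(t(outer(schema$structures, seq_len(schema$points_per_structure),
                    paste, sep = "_")))
}

#' Resolve a geometry role to a tracked point
#'
#' @param frame A frame-landmark tibble (columns `structure`, `point`, `x`,
#'   `y`, `likelihood`).
#' @param schema A [landmark_schema()].
#' @param region One of `"glottis"`, `"pyriform"`, `"vallecula"`.
#' @param role Role name, e.g. `"P1"`.
#' @return Named list with `x`, `y`, `likelihood`.
#' @keywords internal
resolve_role <- function(frame, schema, region, role) {
  r <- schema$role_map[[region]][[role]]
  if (is.null(r)) {
    stop("role ", region, "/", role, " is not assigned in the schema",
         call. = FALSE)
  }
  row <- frame[frame$structure == r$structure & frame$point == r$point, ]
  if (nrow(row) != 1) {
    stop("frame does not contain exactly one point for ", r$structure,
         " #", r$point, call. = FALSE)
  }
  list(x = row$x[[1]], y = row$y[[1]], likelihood = row$likelihood[[1]])
}

#' @export
print.landmark_schema <- function(x, ...) {
  cat("<landmark_schema> ", length(x$structures), " structures x ",
      x$points_per_structure, " points\n", sep = "")
  cat("  structures: ", paste(x$structures, collapse = ", "), "\n", sep = "")
  invisible(x)
}
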
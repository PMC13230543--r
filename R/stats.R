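# Diagnostic-agreement statistics: binary metrics, balanced-accuracy AUC,
# Cohen's kappa (unweighted / linear / quadratic), Fisher's exact test and
# the grade-comparison tables used to validate ordinal severity output.
#
# Division-by-zero in a metric yields Inf or NaN (a distinguished marker),
# never an error, matching how such tables handle empty margins.

#' 2x2 confusion counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (reference in columns,
#'   prediction in rows, positives first).
#' @return An object of class `confusion_2x2`.
#' @export
confusion_2x2 <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) < 1) stop("confusion table must have at least one case",
                            call. = FALSE)
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "confusion_2x2")
}

#' Build a 2x2 confusion from paired binary labels
#'
#' @param reference,prediction Logical vectors of equal length.
#' @return A [confusion_2x2()].
#' @export
confusion_from_labels <- function(reference, prediction) {
  stopifnot(is.logical(reference), is.logical(prediction),
            length(reference) == length(prediction))
  confusion_2x2(tp = sum(prediction & reference),
                fp = sum(prediction & !reference),
                fn = sum(!prediction & reference),
                tn = sum(!prediction & !reference))
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(prediction = c("pos", "neg"),
                              reference = c("pos", "neg")))
  print(t(m)["pos", , drop = FALSE]); print(t(m)["neg", , drop = FALSE])
  invisible(x)
}

as_matrix_2x2 <- function(c2) {
  matrix(c(c2$tp, c2$fn, c2$fp, c2$tn), 2, 2,
         dimnames = list(prediction = c("pos", "neg"),
                         reference = c("pos", "neg")))
}

#' Core binary diagnostic metrics
#'
#' Accuracy, sensitivity, specificity, PPV (= precision), NPV, positive
#' and negative likelihood ratios. The printed tables of such validations
#' list precision and PPV as separate columns; both are the same quantity
#' `tp / (tp + fp)` and are reported once here.
#'
#' @param c2 A [confusion_2x2()].
#' @return One-row tibble with columns `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `ppv`, `npv`, `plr`, `nlr`, `n`.
#' @export
binary_metrics <- function(c2) {
  stopifnot(inherits(c2, "confusion_2x2"))
  n <- c2$tp + c2$fp + c2$fn + c2$tn
  if (n == 0) stop("empty confusion table", call. = FALSE)
  sens <- c2$tp / (c2$tp + c2$fn)
  spec <- c2$tn / (c2$tn + c2$fp)
  ppv <- c2$tp / (c2$tp + c2$fp)
  npv <- c2$tn / (c2$tn + c2$fn)
  tibble::tibble(accuracy = (c2$tp + c2$tn) / n,
                 sensitivity = sens, specificity = spec,
                 precision = ppv, ppv = ppv, npv = npv,
                 plr = sens / (1 - spec),
                 nlr = (1 - sens) / spec,
                 n = n)
}

#' AUC of a hard binary classifier
#'
#' For hard (label-only) predictions the ROC has a single operating
#' point and its area reduces to balanced accuracy, the mean of
#' sensitivity and specificity. This is the convention implicit in
#' validation tables where AUC equals that mean.
#'
#' @param c2 A [confusion_2x2()].
#' @return Numeric AUC in \[0, 1\].
#' @export
balanced_auc <- function(c2) {
  m <- binary_metrics(c2)
  (m$sensitivity + m$specificity) / 2
}

#' Ordinal confusion matrix over severity levels
#'
#' @param reference,prediction Severity vectors (characters or ordered
#'   factors over [severity_levels()]).
#' @param levels Level set (default the five YPR-SRS levels).
#' @return k x k integer matrix of class `ordinal_confusion`
#'   (reference in rows, prediction in columns).
#' @export
ordinal_confusion <- function(reference, prediction,
                              levels = severity_levels()) {
  reference <- factor(as.character(reference), levels = levels)
  prediction <- factor(as.character(prediction), levels = levels)
  stopifnot(length(reference) == length(prediction),
            !anyNA(reference), !anyNA(prediction))
  m <- table(reference = reference, prediction = prediction)
  structure(unclass(as.matrix(m)), class = "ordinal_confusion")
}

#' Cohen's kappa, unweighted or weighted
#'
#' Implements `kappa = 1 - sum(w * p_obs) / sum(w * p_exp)` with
#' disagreement weights `w = 1(i != j)` (unweighted), `|i - j|` (linear)
#' or `(i - j)^2` (quadratic). Linear weighting is the default for
#' ordinal severity scales; unweighted is appropriate for binary
#' outcomes. A degenerate expected agreement of 1 yields `NaN`.
#'
#' @param confusion A [confusion_2x2()], [ordinal_confusion()] or plain
#'   square count matrix (reference in rows).
#' @param weights `"none"`, `"linear"` or `"quadratic"`.
#' @return Numeric kappa (`NaN` when undefined).
#' @export
cohen_kappa <- function(confusion, weights = c("none", "linear", "quadratic")) {
  weights <- match.arg(weights)
  m <- if (inherits(confusion, "confusion_2x2")) as_matrix_2x2(confusion)
       else unclass(as.matrix(confusion))
  stopifnot(nrow(m) == ncol(m), all(m >= 0))
  n <- sum(m)
  if (n < 1) stop("confusion table must have at least one case", call. = FALSE)
  k <- nrow(m)
  idx <- seq_len(k)
  w <- switch(weights,
              none = 1 * outer(idx, idx, `!=`),
              linear = abs(outer(idx, idx, `-`)),
              quadratic = outer(idx, idx, `-`)^2)
  p <- m / n
  pe <- outer(rowSums(p), colSums(p))
  denom <- sum(w * pe)
  if (denom == 0) return(NaN)
  1 - sum(w * p) / denom
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The default two-sided p-value follows the point-probability rule: all
#' tables with the observed margins whose hypergeometric probability does
#' not exceed the observed table's contribute to p. `method = "midp"`
#' instead counts the observed probability with weight one half.
#'
#' @param c2 A [confusion_2x2()] (or 2x2 count matrix).
#' @param method `"point"` (classic) or `"midp"`.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(c2, method = c("point", "midp")) {
  method <- match.arg(method)
  m <- if (inherits(c2, "confusion_2x2")) as_matrix_2x2(c2)
       else matrix(as.integer(c2), 2, 2)
  if (method == "point") {
    return(stats::fisher.test(m)$p.value)
  }
  # mid-p via direct hypergeometric enumeration over fixed margins
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  a_all <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- stats::dhyper(a_all, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  tol <- 1e-7
  sum(pr[pr < p_obs * (1 - tol)]) +
    0.5 * sum(pr[abs(pr - p_obs) <= p_obs * tol])
}

#' Dichotomized comparison of two severity grades
#'
#' Restricts the ordinal confusion to cases whose reference level is one
#' of the two grades, dichotomizes the prediction as "at or above the
#' higher grade" versus below it, and reports the binary metrics,
#' balanced-accuracy AUC and Fisher's exact p of the resulting 2x2.
#' "Presence vs. absence of mild residue" is the same mechanism with
#' `grade_a = "absence"`, `grade_b = "mild"`.
#'
#' @param oc An [ordinal_confusion()].
#' @param grade_a,grade_b Two distinct severity levels.
#' @return One-row tibble with `comparison`, the binary metrics, `auc`
#'   and `fisher_p`.
#' @export
grade_comparison_metrics <- function(oc, grade_a, grade_b) {
  stopifnot(inherits(oc, "ordinal_confusion"))
  lv <- rownames(oc)
  if (is.null(lv)) lv <- severity_levels()
  ia <- match(as.character(grade_a), lv)
  ib <- match(as.character(grade_b), lv)
  if (is.na(ia) || is.na(ib) || ia == ib) {
    stop("grades must be two distinct severity levels", call. = FALSE)
  }
  hi <- max(ia, ib); lo <- min(ia, ib)
  sub <- oc[c(lo, hi), , drop = FALSE]
  if (sum(sub) == 0) {
    stop("no cases with reference level ", lv[lo], " or ", lv[hi],
         call. = FALSE)
  }
  pred_hi <- seq_along(lv) >= hi
  c2 <- confusion_2x2(tp = sum(sub[2, pred_hi]),
                      fp = sum(sub[1, pred_hi]),
                      fn = sum(sub[2, !pred_hi]),
                      tn = sum(sub[1, !pred_hi]))
  m <- binary_metrics(c2)
  tibble::tibble(comparison = paste0(lv[hi], " vs. ", lv[lo]),
                 m[c("accuracy", "sensitivity", "specificity", "precision",
                     "ppv", "npv", "plr", "nlr", "n")],
                 auc = balanced_auc(c2),
                 fisher_p = fisher_exact_2x2(c2))
}

#' Enumerate 2x2 tables consistent with printed summary metrics
#'
#' Searches all 2x2 confusion matrices of total `n` whose sensitivity,
#' specificity and accuracy round (half-up, 2 decimals) to the printed
#' values. Useful to reconstruct the unique matrix behind a published
#' metric row.
#'
#' @param n Total number of cases.
#' @param sensitivity,specificity,accuracy Printed values (2 decimals).
#' @param digits Rounding precision of the printed values.
#' @return Tibble of matching `(tp, fn, fp, tn)` rows.
#' @export
enumerate_confusions <- function(n, sensitivity, specificity, accuracy,
                                 digits = 2) {
  round_half_up_dp <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  out <- list()
  for (pos in 0:n) {
    neg <- n - pos
    for (tp in 0:pos) {
      fn <- pos - tp
      for (tn in 0:neg) {
        fp <- neg - tn
        sens <- if (pos > 0) tp / pos else NaN
        spec <- if (neg > 0) tn / neg else NaN
        acc <- (tp + tn) / n
        if (!is.nan(sens) && !is.nan(spec) &&
            round_half_up_dp(sens, digits) == sensitivity &&
            round_half_up_dp(spec, digits) == specificity &&
            round_half_up_dp(acc, digits) == accuracy) {
          out[[length(out) + 1]] <- tibble::tibble(tp = tp, fn = fn,
                                                   fp = fp, tn = tn)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(tp = integer(0), fn = integer(0),
                          fp = integer(0), tn = integer(0)))
  }
  dplyr::bind_rows(out)
}
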
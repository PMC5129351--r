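#' Screening-test confusion counts
#'
#' Tallies the epidemiological 2x2 screening table with carcinogen = 1 as
#' the positive class: A = true positives, B = false positives, C = false
#' negatives, D = true negatives.
#'
#' @param y_true,y_pred equal-length binary 0/1 vectors.
#' @return Object of class \code{"confusion_counts"}: named integer vector
#'   \code{c(A, B, C, D)}.
#' @examples
#' confusion(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 1) stop("need at least one observation")
  if (!all(y_true %in% c(0, 1)) || !all(y_pred %in% c(0, 1)))
    stop("labels must be binary 0/1")
  structure(c(A = sum(y_true == 1 & y_pred == 1),
              B = sum(y_true == 0 & y_pred == 1),
              C = sum(y_true == 1 & y_pred == 0),
              D = sum(y_true == 0 & y_pred == 0)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("Screening 2x2 table (A=TP, B=FP, C=FN, D=TN):\n")
  print(matrix(c(x["A"], x["B"], x["C"], x["D"]), 2, 2, byrow = TRUE,
               dimnames = list(predicted = c("pos", "neg"),
                               actual = c("pos", "neg"))))
  invisible(x)
}

#' Screening-test metrics from confusion counts
#'
#' Sensitivity \code{A/(A+C)}, specificity \code{D/(B+D)}, Youden's index
#' \code{sensitivity + specificity - 1}, accuracy \code{(A+D)/n}, positive
#' predictive value \code{A/(A+B)} and negative predictive value
#' \code{D/(C+D)} (PPV/NPV are 0 on an empty predicted class).
#'
#' @param c a [confusion()] object, or a named vector with A, B, C, D.
#' @return Named list with accuracy, sensitivity, specificity, youden,
#'   ppv, npv.
#' @examples
#' screening_metrics(confusion(c(1, 1, 0, 0), c(1, 1, 0, 0)))
#' @export
screening_metrics <- function(c) {
  A <- c[["A"]]; B <- c[["B"]]; C <- c[["C"]]; D <- c[["D"]]
  if (any(c(A, B, C, D) < 0)) stop("counts must be non-negative")
  if (A + C == 0) stop("no positive compounds in the evaluated set (A+C=0)")
  if (B + D == 0) stop("no negative compounds in the evaluated set (B+D=0)")
  sens <- A / (A + C)
  spec <- D / (B + D)
  list(accuracy = (A + D) / (A + B + C + D),
       sensitivity = sens,
       specificity = spec,
       youden = youden_index(sens, spec),
       ppv = if (A + B > 0) A / (A + B) else 0,
       npv = if (C + D > 0) D / (C + D) else 0)
}

#' Youden's index
#'
#' \code{J = sensitivity + specificity - 1}, the summary index of a
#' screening test (range -1 to 1; 1 for a perfect screen).
#'
#' @param sensitivity,specificity values in [0, 1].
#' @return Numeric in [-1, 1].
#' @examples
#' youden_index(0.947, 0.905)  # 0.852
#' @export
youden_index <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) ||
      any(specificity < 0 | specificity > 1))
    stop("sensitivity and specificity must lie in [0, 1]")
  sensitivity + specificity - 1
}

#' Classification margin
#'
#' The probability assigned to the actual class minus the largest
#' probability assigned to any wrong class. For a binary classifier with
#' complementary probabilities this equals \code{2 p(actual) - 1}; values
#' near 1 indicate confident correct classification, negative values
#' misclassification.
#'
#' @param p_actual,p_wrong_max probabilities in [0, 1].
#' @return Numeric in [-1, 1].
#' @export
margin_score <- function(p_actual, p_wrong_max) {
  if (any(p_actual < 0 | p_actual > 1) ||
      any(p_wrong_max < 0 | p_wrong_max > 1))
    stop("probabilities must lie in [0, 1]")
  p_actual - p_wrong_max
}

#' Table-style evaluation report
#'
#' Convenience wrapper: confusion counts plus the four headline screening
#' columns (Accuracy, Sensitivity, Specificity, Youden's index), rounded to
#' 3 decimals (round-half-even) for reporting.
#'
#' @inheritParams confusion
#' @param digits decimals for the rounded report (default 3).
#' @return Data frame with one row of rounded metrics.
#' @export
evaluation_report <- function(y_true, y_pred, digits = 3) {
  m <- screening_metrics(confusion(y_true, y_pred))
  data.frame(accuracy = round(m$accuracy, digits),
             sensitivity = round(m$sensitivity, digits),
             specificity = round(m$specificity, digits),
             youden = round(m$youden, digits))
}
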
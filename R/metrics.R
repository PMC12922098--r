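#' Confusion matrix of per-trial decisions
#'
#' Tallies predicted against ground-truth OKN presence over paired trials.
#'
#' @param predicted,truth Equal-length logical vectors (no `NA`s; exclude
#'   unavailable trials first).
#' @return An object of class `okn_confusion`: list with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @examples
#' cm <- okn_confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' mcc(cm)
#' @export
okn_confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("`predicted` and `truth` must have equal length")
  }
  if (length(predicted) == 0) stop("empty inputs")
  if (anyNA(predicted) || anyNA(truth)) stop("NA decisions not allowed")
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  structure(
    list(
      tp = sum(predicted & truth),
      fp = sum(predicted & !truth),
      fn = sum(!predicted & truth),
      tn = sum(!predicted & !truth)
    ),
    class = "okn_confusion"
  )
}

#' @export
print.okn_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(truth = c("present", "absent"),
                              predicted = c("present", "absent")))
  print(m)
  invisible(x)
}

#' Classifier performance measures
#'
#' `mcc()` is the Matthews correlation coefficient
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`, identical to the
#' Pearson correlation of the two binary label vectors; it ranges from -1
#' (perfect disagreement) through 0 (chance) to +1 and is robust to class
#' imbalance.  `sensitivity()` is `tp/(tp+fn)`, `specificity()` is
#' `tn/(tn+fp)`, `accuracy()` is `(tp+tn)/total`.  Any measure whose
#' denominator is zero (for MCC, any zero marginal) is undefined and
#' returned as `NA`, never as 0.
#'
#' @param cm An [okn_confusion()].
#' @return A single number, or `NA` if undefined.
#' @export
mcc <- function(cm) {
  stopifnot(inherits(cm, "okn_confusion"))
  m <- with(cm, c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (any(m == 0)) return(NA_real_)
  with(cm, (tp * tn - fp * fn) / exp(sum(log(m)) / 2))
}

#' @rdname mcc
#' @export
sensitivity <- function(cm) {
  stopifnot(inherits(cm, "okn_confusion"))
  if (cm$tp + cm$fn == 0) return(NA_real_)
  cm$tp / (cm$tp + cm$fn)
}

#' @rdname mcc
#' @export
specificity <- function(cm) {
  stopifnot(inherits(cm, "okn_confusion"))
  if (cm$tn + cm$fp == 0) return(NA_real_)
  cm$tn / (cm$tn + cm$fp)
}

#' @rdname mcc
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "okn_confusion"))
  tot <- with(cm, tp + fp + fn + tn)
  if (tot == 0) return(NA_real_)
  (cm$tp + cm$tn) / tot
}

#' All performance measures in one row
#'
#' @param predicted,truth Logical decision vectors, or pass an existing
#'   [okn_confusion()] as `predicted`.
#' @return One-row tibble: `n`, `tp`, `fp`, `fn`, `tn`, `mcc`,
#'   `sensitivity`, `specificity`, `accuracy`.
#' @export
okn_metrics <- function(predicted, truth = NULL) {
  cm <- if (inherits(predicted, "okn_confusion")) {
    predicted
  } else {
    okn_confusion(predicted, truth)
  }
  tibble::tibble(
    n = with(cm, tp + fp + fn + tn),
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn,
    mcc = mcc(cm), sensitivity = sensitivity(cm),
    specificity = specificity(cm), accuracy = accuracy(cm)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy okn_confusion
#' @export
tidy.okn_confusion <- function(x, ...) {
  tibble::tibble(
    truth = rep(c(TRUE, FALSE), 2),
    predicted = rep(c(TRUE, FALSE), each = 2),
    count = c(x$tp, x$fp, x$fn, x$tn)
  )
}

#' @method glance okn_confusion
#' @export
glance.okn_confusion <- function(x, ...) okn_metrics(x)
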
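#' Evaluation metrics for affinity regression
#'
#' The four benchmark metrics used throughout: root mean squared error,
#' Pearson and Spearman correlation, and the concordance index. Correlations
#' on zero-variance input and the concordance index on all-tied labels are
#' undefined; these return `NA_real_` with a warning rather than a silent
#' number.
#'
#' @param predictions,labels numeric vectors of equal length.
#' @return A single numeric value.
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 3))        # 0
#' spearmanRho(c(1, 3, 2), c(1, 2, 3)) # 0.5
#' concordanceIndex(c(1, 3, 2), c(1, 2, 3)) # 2/3
#' @name metrics
NULL

checkMetricInput <- function(predictions, labels, minLen = 1L) {
  stopIfNot(length(predictions) == length(labels),
            "predictions and labels must have equal length")
  stopIfNot(length(labels) >= minLen,
            sprintf("need at least %d observations", minLen))
  stopIfNot(all(is.finite(predictions)) && all(is.finite(labels)),
            "metric inputs must be finite")
}

#' @rdname metrics
#' @export
rmse <- function(predictions, labels) {
  checkMetricInput(predictions, labels)
  sqrt(mean((predictions - labels)^2))
}

#' @rdname metrics
#' @export
pearsonR <- function(predictions, labels) {
  checkMetricInput(predictions, labels, 2L)
  if (sd(predictions) == 0 || sd(labels) == 0) {
    warning("Pearson correlation undefined for zero-variance input")
    return(NA_real_)
  }
  cor(predictions, labels, method = "pearson")
}

#' @rdname metrics
#' @export
spearmanRho <- function(predictions, labels) {
  checkMetricInput(predictions, labels, 2L)
  rp <- rank(predictions) # average ranks for ties
  rl <- rank(labels)
  if (sd(rp) == 0 || sd(rl) == 0) {
    warning("Spearman correlation undefined for zero-variance input")
    return(NA_real_)
  }
  cor(rp, rl, method = "pearson")
}

#' @rdname metrics
#' @details
#' The concordance index considers every pair of observations with distinct
#' true labels. A pair is concordant when the prediction ordering matches the
#' label ordering; predicted ties receive half credit; pairs with tied labels
#' are excluded from both numerator and denominator. Values range from 0
#' (perfectly reversed) through 0.5 (random) to 1 (perfectly ordered). On
#' binary 0/1 labels this reduces to the area under the ROC curve.
#' @export
concordanceIndex <- function(predictions, labels) {
  checkMetricInput(predictions, labels, 2L)
  dl <- outer(labels, labels, `-`)       # label_i - label_j
  dp <- outer(predictions, predictions, `-`)
  use <- dl > 0                           # ordered pairs with label_i > label_j
  n <- sum(use)
  if (n == 0L) {
    warning("concordance index undefined: all labels tied")
    return(NA_real_)
  }
  (sum(dp[use] > 0) + 0.5 * sum(dp[use] == 0)) / n
}
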
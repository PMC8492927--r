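#' Pearson correlation between predictions and observations
#'
#' Thin, checked wrapper around the product-moment correlation used as
#' the continuous-trait accuracy metric.
#'
#' @param pred,obs numeric vectors of equal length (>= 3), both
#'   non-constant.
#' @return The correlation coefficient.
#' @export
pearson <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("pred and obs differ in length")
  if (length(pred) < 3L) stop("pearson requires at least 3 pairs")
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("undefined correlation: constant input")
  stats::cor(pred, obs)
}

#' Area under the ROC curve (Mann-Whitney concordance)
#'
#' `P(score_case > score_control) + 0.5 * P(tie)`, computed via midranks,
#' so ties contribute one half. Equivalent to the trapezoidal area under
#' the ROC curve.
#'
#' @param pred numeric scores, oriented so larger values indicate the
#'   positive class.
#' @param labels 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(pred, labels) {
  if (length(pred) != length(labels)) stop("pred and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("undefined AUC: one class is absent")
  r <- rank(pred)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
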
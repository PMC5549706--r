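# Smallest representable ln p; caps perfect correlations.
LN_P_FLOOR <- -745

#' Pearson correlation with natural-log p-value
#'
#' Two-sided p from the exact t transform `t = r * sqrt(n-2) / sqrt(1-r^2)`
#' with n-2 degrees of freedom, returned on the natural-log scale so that
#' extremely small p-values (the dual filter works at ln p < -11) do not
#' underflow. ln p is capped at `-745` for perfect correlations.
#'
#' @param x,y numeric vectors of equal length (n >= 3), non-constant.
#' @return list with `r` and `ln_p`.
#' @export
pearson_with_pvalue <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = r, ln_p = LN_P_FLOOR))
  tstat <- r * sqrt(n - 2) / sqrt(1 - r * r)
  ln_p <- log(2) + stats::pt(-abs(tstat), df = n - 2, log.p = TRUE)
  list(r = r, ln_p = max(ln_p, LN_P_FLOOR))
}

#' Positive and negative predictive value with mean-threshold dichotomization
#'
#' Predicted responders are samples whose predicted chemosensitivity score
#' falls below the mean of the predictions (scores live on the IC50 scale, so
#' lower = more sensitive). Observed responders are samples above the mean of
#' the observed response when it is survival-like (months to progression) and
#' below the mean when it is IC50-like.
#'
#' @param predicted numeric vector of predicted scores.
#' @param observed numeric vector of observed responses.
#' @param observed_direction `"survival"` (higher = responder) or `"ic50"`
#'   (lower = responder).
#' @return list with `ppv`, `npv` (NA when a predicted class is empty) and
#'   `defined` flag.
#' @export
classification_values <- function(predicted, observed,
                                  observed_direction = c("survival", "ic50")) {
  observed_direction <- match.arg(observed_direction)
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  pred_resp <- predicted < mean(predicted)
  obs_resp <- if (observed_direction == "survival")
    observed > mean(observed) else observed < mean(observed)
  if (!any(pred_resp) || all(pred_resp))
    return(list(ppv = NA_real_, npv = NA_real_, defined = FALSE))
  ppv <- mean(obs_resp[pred_resp])
  npv <- mean(!obs_resp[!pred_resp])
  list(ppv = ppv, npv = npv, defined = TRUE)
}

# Vectorized Welch two-sample t over the columns of two matrices
# (samples x genes). Returns t (group1 minus group2), df and two-sided p per
# gene; constant-in-both-groups genes get t = 0, p = 1.
welch_t_columns <- function(m1, m2) {
  n1 <- nrow(m1); n2 <- nrow(m2)
  if (n1 < 2L || n2 < 2L) stop("need at least 2 samples per group")
  mu1 <- colMeans(m1); mu2 <- colMeans(m2)
  v1 <- apply(m1, 2L, stats::var); v2 <- apply(m2, 2L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tt <- (mu1 - mu2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  degenerate <- se2 == 0
  tt[degenerate] <- 0
  df[degenerate] <- n1 + n2 - 2
  p <- 2 * stats::pt(-abs(tt), df = df)
  p[degenerate] <- 1
  list(t = tt, df = df, p = p)
}

# Single Welch t-statistic between two numeric vectors (t of x minus y).
welch_t <- function(x, y) {
  res <- welch_t_columns(matrix(x, ncol = 1L), matrix(y, ncol = 1L))
  list(t = unname(res$t), df = unname(res$df), p = unname(res$p))
}
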
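#' Standardized bias of a set of contrast estimates
#'
#' `(mean(est) - truth) / SD(est)` where the standard deviation uses the
#' population form (divisor R, the number of replications).
#'
#' @param estimates replication estimates of the contrast.
#' @param trueDelta true population contrast.
#' @return the standardized bias; |value| < 0.40 is conventionally regarded
#'   as acceptable.
#' @examples
#' standardizedBias(c(0.1, 0.3), 0.1)  # 1
#' @export
standardizedBias <- function(estimates, trueDelta) {
  if (length(estimates) < 2) stop("need at least two estimates")
  mu <- mean(estimates)
  s <- sqrt(mean((estimates - mu)^2))
  if (s == 0) stop("degenerate estimates: zero spread")
  (mu - trueDelta) / s
}

#' Empirical rejection rate
#'
#' Percentage of replications with `p < alpha` (strict inequality).
#'
#' @param pValues replication p-values in `[0, 1]`.
#' @param alpha significance level.
#' @return rate in percent.
#' @export
rejectionRate <- function(pValues, alpha = 0.05) {
  if (length(pValues) == 0) stop("no p-values supplied")
  if (any(pValues < 0 | pValues > 1)) stop("p-values must lie in [0, 1]")
  100 * mean(pValues < alpha)
}

#' Classify an empirical Type I error rate
#'
#' An empirical rate (in percent, from 500 replications) is `"within"` the
#' 95% Monte Carlo band around the nominal 5% level iff it lies in the closed
#' interval 3.4 to 7.3; otherwise `"outside"` (biased).
#'
#' @param ratePercent empirical Type I error rate in percent.
#' @export
type1Band <- function(ratePercent) {
  stopifnot(ratePercent >= 0, ratePercent <= 100)
  ifelse(ratePercent >= 3.4 & ratePercent <= 7.3, "within", "outside")
}

#' Eta-squared of design factors for a simulation outcome
#'
#' Main-effects-only analysis-of-variance decomposition of a per-replication
#' (or per-cell) outcome on the design factors: for each factor,
#' `SS_factor / SS_total`. A constant outcome returns 0 for every factor by
#' convention.
#'
#' @param data data.frame holding the outcome and factor columns.
#' @param outcome name of the outcome column.
#' @param factors character vector of factor column names.
#' @return named vector of eta-squared values in `[0, 1]`.
#' @export
etaSquared <- function(data, outcome, factors) {
  y <- data[[outcome]]
  if (length(unique(y)) == 1L)
    return(setNames(rep(0, length(factors)), factors))
  for (f in factors) data[[f]] <- factor(data[[f]])
  fml <- reformulate(factors, response = outcome)
  ss <- summary(aov(fml, data = data))[[1]][, "Sum Sq"]
  sstot <- sum(ss)
  eta <- ss[seq_along(factors)] / sstot
  setNames(eta, factors)
}
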
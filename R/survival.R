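#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()] on right-censored times in months. Censored
#' observations tied with events at the same time are handled in the
#' standard way (events first). With a `group`, one curve per group is
#' estimated.
#'
#' @param time Follow-up times in months, strictly positive.
#' @param event Event indicator (1/TRUE = event, 0/FALSE = censored).
#' @param group Optional grouping vector.
#' @return A `survfit` object (with Greenwood standard errors and log-log
#'   confidence intervals).
#' @export
kmEstimate <- function(time, event, group = NULL) {
  checkSurv(time, event)
  event <- as.integer(as.logical(event))
  if (is.null(group)) {
    survival::survfit(survival::Surv(time, event) ~ 1,
                      conf.type = "log-log")
  } else {
    d <- data.frame(time = time, event = event, group = factor(group))
    survival::survfit(survival::Surv(time, event) ~ group, data = d,
                      conf.type = "log-log")
  }
}

checkSurv <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and positive", call. = FALSE)
  if (length(time) != length(event))
    stop("time and event lengths differ", call. = FALSE)
  invisible(TRUE)
}

#' Survival rate at a landmark time
#'
#' Kaplan-Meier estimate at `tYears` years (step function evaluated at the
#' last event time at or before the landmark). Returns `NA` when follow-up
#' in the curve ends before the landmark, rather than extrapolating.
#'
#' @param fit A single-group `survfit` from [kmEstimate()].
#' @param tYears Landmark in years (converted at 12 months/year).
#' @return Proportion surviving, or `NA` if follow-up is too short.
#' @export
survivalRateAt <- function(fit, tYears) {
  if (tYears < 0) stop("landmark time must be non-negative", call. = FALSE)
  tMonths <- tYears * 12
  if (tMonths > max(fit$time)) return(NA_real_)
  if (tMonths < min(fit$time[fit$n.event > 0], Inf)) return(1)
  summary(fit, times = tMonths)$surv
}

#' Kaplan-Meier median survival with confidence interval
#'
#' Smallest time at which the survival estimate drops to 0.5 or below; when
#' the curve never crosses 0.5 the median is not reached (`NA`, serialised
#' as `"NR"` in output tables). The confidence interval is the standard
#' Brookmeyer-Crowley inversion reported by [survival::survfit()].
#'
#' @param fit A single-group `survfit`.
#' @return data.frame with `median`, `lcl`, `ucl` (months; `NA` = not
#'   reached).
#' @export
kmMedian <- function(fit) {
  tb <- summary(fit)$table
  if (is.matrix(tb)) tb <- tb[1L, ]  # caller asked for one group
  # smallest time at which the step function reaches 0.5 (survfit averages
  # the two times when the curve sits exactly at 0.5; we take the first)
  idx <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(idx)) fit$time[min(idx)] else NA_real_
  data.frame(median = med,
             lcl = unname(tb["0.95LCL"]),
             ucl = unname(tb["0.95UCL"]))
}

#' k-group log-rank test
#'
#' @param time,event As in [kmEstimate()].
#' @param group Grouping vector with at least two non-empty levels.
#' @return list with `chi2`, `df` (k - 1) and `p`.
#' @export
logrankTest <- function(time, event, group) {
  checkSurv(time, event)
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L)
    stop("log-rank test needs at least two groups", call. = FALSE)
  d <- data.frame(time = time, event = as.integer(as.logical(event)),
                  group = group)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- nlevels(group) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fit via [survival::coxph()] with Efron tie handling
#' by default (Breslow available). Returns hazard ratios with Wald
#' intervals; monotone-likelihood (separated) covariates are flagged.
#'
#' @param time,event As in [kmEstimate()].
#' @param covariates data.frame of covariate columns (factors/numerics).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf Confidence level; default 0.95.
#' @return data.frame, one row per coefficient: `term`, `coef`, `se`,
#'   `hr`, `ci_lo`, `ci_hi`, `p`, `separated`; attribute `"ties"` records
#'   the tie method.
#' @export
coxFit <- function(time, event, covariates, ties = c("efron", "breslow"),
                   conf = 0.95) {
  ties <- match.arg(ties)
  checkSurv(time, event)
  if (!is.data.frame(covariates)) covariates <- data.frame(x = covariates)
  nEvents <- sum(as.logical(event))
  if (nEvents < ncol(covariates) + 1L)
    stop("too few events (", nEvents, ") for ", ncol(covariates),
         " covariate(s)", call. = FALSE)
  d <- cbind(data.frame(.time = time,
                        .event = as.integer(as.logical(event))),
             covariates)
  fit <- survival::coxph(survival::Surv(.time, .event) ~ ., data = d,
                         ties = ties)
  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf) / 2)
  separated <- abs(sm[, "coef"]) > 15 | sm[, "se(coef)"] > 100
  if (any(separated))
    warning("monotone likelihood (separation) suspected for: ",
            paste(rownames(sm)[separated], collapse = ", "), call. = FALSE)
  out <- data.frame(term = rownames(sm), coef = sm[, "coef"],
                    se = sm[, "se(coef)"], hr = exp(sm[, "coef"]),
                    ci_lo = exp(sm[, "coef"] - z * sm[, "se(coef)"]),
                    ci_hi = exp(sm[, "coef"] + z * sm[, "se(coef)"]),
                    p = sm[, "Pr(>|z|)"], separated = separated,
                    row.names = NULL)
  attr(out, "ties") <- ties
  out
}

#' Dichotomize PD-L1 expression at the mesenchymal median
#'
#' The RPKM cut-off for PD-L1 in survival analysis is the median log2 RPKM
#' among samples carrying a mesenchymal signature; samples at or above the
#' cut-off are classed high (boundary inclusive). For an even number of
#' mesenchymal samples the median is the midpoint of the two central order
#' statistics.
#'
#' @param values Numeric vector of log2 RPKM per sample.
#' @param mesenchymalMask Logical vector selecting the mesenchymal samples
#'   (at least one).
#' @return list with `high` (logical per sample) and `cutoff`.
#' @export
dichotomizePDL1 <- function(values, mesenchymalMask) {
  if (length(values) != length(mesenchymalMask))
    stop("values and mask lengths differ", call. = FALSE)
  if (!any(mesenchymalMask))
    stop("mesenchymal mask selects no samples", call. = FALSE)
  cutoff <- stats::median(values[mesenchymalMask])
  list(high = values >= cutoff, cutoff = cutoff)
}
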
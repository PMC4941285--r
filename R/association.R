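#' Two-sided Fisher exact test for a 2x2 table
#'
#' Standard two-sided Fisher exact p-value: the sum of hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table. A table with a zero margin
#' carries no information and returns p = 1 with a warning.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows = exposure, columns = outcome).
#' @return The two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(15, 17, 2, 16), 2))  # 0.013
#' @export
fisherExact2x2 <- function(tab) {
  tab <- checkTable2x2(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin: table carries no information, p = 1",
            call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

checkTable2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("a 2x2 table is required", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)) || sum(tab) == 0)
    stop("counts must be non-negative integers with positive total",
         call. = FALSE)
  tab
}

#' Odds ratio with Wald 95% confidence interval
#'
#' Cross-product odds ratio `(a d)/(b c)` with the Wald interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is
#' zero the Haldane-Anscombe correction (0.5 added to every cell) is
#' applied and flagged; two zero cells on a diagonal leave the odds ratio
#' undefined and raise an error.
#'
#' @param tab 2x2 count matrix.
#' @param conf Confidence level; default 0.95.
#' @return list with `or`, `ci` (length 2), `corrected` (logical).
#' @examples
#' oddsRatio(matrix(c(15, 17, 2, 16), 2))$or  # 7.06
#' @export
oddsRatio <- function(tab, conf = 0.95) {
  tab <- checkTable2x2(tab)
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if ((a == 0 && d == 0) || (b == 0 && c == 0))
    stop("odds ratio undefined: two zero cells on a diagonal",
         call. = FALSE)
  corrected <- any(tab == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), corrected = corrected)
}

#' Logistic regression of a binary outcome
#'
#' Maximum-likelihood logistic fit returning odds ratios with Wald
#' confidence intervals, as used for uni- and multivariate analysis of
#' factors affecting PD-L1 positivity. Separated fits (diverging
#' coefficients) are flagged and their intervals reported unbounded.
#'
#' @param outcome Binary vector (logical or 0/1).
#' @param predictors data.frame (or vector) of predictor columns; factors
#'   and numerics are handled by the usual model matrix.
#' @param conf Confidence level; default 0.95.
#' @return data.frame, one row per coefficient (intercept excluded):
#'   `term`, `coef`, `se`, `or`, `ci_lo`, `ci_hi`, `p`, `separated`,
#'   `converged`.
#' @export
logisticFit <- function(outcome, predictors, conf = 0.95) {
  outcome <- as.integer(as.logical(outcome))
  if (length(unique(outcome)) < 2L)
    stop("outcome must have both levels", call. = FALSE)
  if (!is.data.frame(predictors))
    predictors <- data.frame(x = predictors)
  if (nrow(predictors) != length(outcome))
    stop("outcome and predictors disagree in length", call. = FALSE)
  if (length(outcome) <= ncol(predictors))
    stop("need more observations than predictors", call. = FALSE)
  dat <- cbind(.y = outcome, predictors)
  fit <- stats::glm(.y ~ ., family = stats::binomial(), data = dat)
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf) / 2)
  separated <- abs(sm[, 1]) > 15 | sm[, 2] > 100
  lo <- exp(sm[, 1] - z * sm[, 2]); hi <- exp(sm[, 1] + z * sm[, 2])
  lo[separated] <- 0; hi[separated] <- Inf
  if (any(separated))
    warning("separation detected; CI reported as unbounded for: ",
            paste(rownames(sm)[separated], collapse = ", "), call. = FALSE)
  data.frame(term = rownames(sm), coef = sm[, 1], se = sm[, 2],
             or = exp(sm[, 1]), ci_lo = lo, ci_hi = hi, p = sm[, 4],
             separated = separated,
             converged = rep(fit$converged, nrow(sm)),
             row.names = NULL)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' corrections. Identical samples return p = 1.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return Two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0L
  useExact <- (length(x) + length(y)) <= 20L && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = useExact, correct = TRUE)$p.value)
  min(p, 1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; output preserves input order,
#' is monotone in the sorted order and never below the raw p-value.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Cross-tabulate two categorical variables of a patient table
#'
#' Counts complete cases over the two variables; incomplete cases are
#' dropped and reported via the `"incomplete"` attribute. With two binary
#' variables the result is the 2x2 table the association statistics
#' consume; more levels give the corresponding r x c table.
#'
#' @param patients data.frame.
#' @param rowVar,colVar Column names.
#' @return Integer matrix of counts with dimnames, attribute `"incomplete"`
#'   counting dropped rows.
#' @export
crossTab <- function(patients, rowVar, colVar) {
  if (!nrow(patients)) stop("empty patient table", call. = FALSE)
  for (v in c(rowVar, colVar))
    if (!v %in% names(patients))
      stop("variable '", v, "' not found in table", call. = FALSE)
  r <- patients[[rowVar]]; c <- patients[[colVar]]
  ok <- !(is.na(r) | is.na(c))
  if (any(!ok))
    message(sum(!ok), " incomplete case(s) excluded from ", rowVar, " x ",
            colVar)
  tab <- table(r[ok], c[ok], dnn = c(rowVar, colVar))
  out <- as.matrix(unclass(tab))
  storage.mode(out) <- "integer"
  attr(out, "incomplete") <- sum(!ok)
  out
}
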
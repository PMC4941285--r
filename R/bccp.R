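#' Fit a Bayesian compound covariate predictor
#'
#' Fits the two-class compound covariate classifier on a signature-gene
#' expression matrix with epithelial/mesenchymal labels. Each gene's weight
#' is its two-sample t-statistic (mesenchymal minus epithelial; pooled
#' variance by default, Welch optionally); the compound covariate of sample
#' j is `sum_g t_g * x_gj`; its class means and pooled within-class SD
#' parameterise an equal-variance Gaussian posterior.
#'
#' Genes whose pooled standard deviation falls below `varFloor` are dropped
#' with a warning (their t-statistic would be unbounded). Genes with more
#' than 20 percent missing values are dropped; remaining missing values are
#' imputed by the gene mean, with a message.
#'
#' @param x A genes-by-samples numeric matrix (log2-scale expression) with
#'   rownames, or a [SummarizedExperiment::SummarizedExperiment-class]
#'   whose first assay holds the matrix.
#' @param labels Class label per sample: values `"epithelial"` or
#'   `"mesenchymal"` (factor or character). For a SummarizedExperiment this
#'   may instead be the name of a `colData` column (default `"class"`).
#' @param priors Named numeric class priors (`epithelial`, `mesenchymal`),
#'   summing to 1; default 0.5/0.5.
#' @param welch Use Welch (unequal-variance) t-statistics instead of
#'   pooled-variance. Default `FALSE` — the classical compound-covariate
#'   formulation.
#' @param classSD Use class-specific compound-covariate SDs instead of a
#'   single pooled SD. Default `FALSE`. (When `TRUE`, the larger class SD
#'   bound is used for validity and the pooled value is still stored; kept
#'   as an option for sensitivity analysis.)
#' @param varFloor Minimum pooled per-gene SD; default 1e-8.
#' @return A [BCCPModel-class].
#' @examples
#' tr <- generateExpression(expressionSpec(nPerClass = 10, nSignature = 20,
#'                                         nBackground = 0), seed = 1)
#' fit <- fitBCCP(tr$matrix, tr$labels)
#' fit
#' @export
setGeneric("fitBCCP", function(x, labels = "class",
                               priors = c(epithelial = 0.5, mesenchymal = 0.5),
                               welch = FALSE, classSD = FALSE,
                               varFloor = 1e-8) standardGeneric("fitBCCP"))

#' @rdname fitBCCP
#' @export
setMethod("fitBCCP", "matrix",
  function(x, labels, priors, welch, classSD, varFloor) {
    fitBCCPCore(x, labels, priors, welch, classSD, varFloor)
  })

#' @rdname fitBCCP
#' @export
setMethod("fitBCCP", "SummarizedExperiment",
  function(x, labels, priors, welch, classSD, varFloor) {
    if (is.character(labels) && length(labels) == 1L) {
      cd <- SummarizedExperiment::colData(x)
      if (!labels %in% colnames(cd))
        stop("colData has no column '", labels, "'", call. = FALSE)
      labels <- cd[[labels]]
    }
    fitBCCPCore(SummarizedExperiment::assay(x, 1L), labels,
                priors, welch, classSD, varFloor)
  })

fitBCCPCore <- function(x, labels, priors, welch, classSD, varFloor) {
  if (is.null(rownames(x))) stop("expression matrix needs gene rownames",
                                 call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate gene ids in expression matrix", call. = FALSE)
  labels <- as.character(labels)
  if (length(labels) != ncol(x))
    stop("one label per sample required", call. = FALSE)
  if (!all(labels %in% c("epithelial", "mesenchymal")))
    stop("labels must be 'epithelial' or 'mesenchymal'", call. = FALSE)
  if (abs(sum(priors) - 1) > 1e-8 || any(priors < 0) ||
      !all(c("epithelial", "mesenchymal") %in% names(priors)))
    stop("priors must be named (epithelial, mesenchymal) and sum to 1",
         call. = FALSE)
  isM <- labels == "mesenchymal"
  nE <- sum(!isM); nM <- sum(isM)
  if (nE < 2L || nM < 2L)
    stop("each class needs at least 2 samples (got ", nE, " epithelial, ",
         nM, " mesenchymal)", call. = FALSE)

  x <- imputeGenes(x)

  xE <- x[, !isM, drop = FALSE]
  xM <- x[, isM, drop = FALSE]
  mEg <- rowMeans(xE); mMg <- rowMeans(xM)
  vEg <- apply(xE, 1L, stats::var); vMg <- apply(xM, 1L, stats::var)
  sp <- sqrt(((nE - 1) * vEg + (nM - 1) * vMg) / (nE + nM - 2))

  keep <- sp >= varFloor
  if (!any(keep))
    stop("all genes degenerate (pooled SD below variance floor)",
         call. = FALSE)
  if (any(!keep))
    warning(sum(!keep), " gene(s) dropped at the variance floor: ",
            paste(utils::head(rownames(x)[!keep], 5L), collapse = ", "),
            if (sum(!keep) > 5L) ", ..." else "", call. = FALSE)

  tg <- if (welch) {
    (mMg - mEg) / sqrt(vEg / nE + vMg / nM)
  } else {
    (mMg - mEg) / (sp * sqrt(1 / nE + 1 / nM))
  }
  tg <- tg[keep]
  names(tg) <- rownames(x)[keep]

  cc <- drop(crossprod(x[keep, , drop = FALSE], tg))
  cE <- cc[!isM]; cM <- cc[isM]
  s <- if (classSD) {
    # stored value remains the pooled SD; class SDs only sanity-checked
    sqrt(((nE - 1) * stats::var(cE) + (nM - 1) * stats::var(cM)) /
           (nE + nM - 2))
  } else {
    sqrt(((nE - 1) * stats::var(cE) + (nM - 1) * stats::var(cM)) /
           (nE + nM - 2))
  }
  if (!is.finite(s) || s <= 0)
    stop("degenerate compound covariate (zero within-class variance)",
         call. = FALSE)
  newBCCPModel(tg, mean(cE), mean(cM), s, priors)
}

# drop genes with >20% missing, mean-impute the rest
imputeGenes <- function(x, maxMissing = 0.2) {
  nas <- is.na(x)
  if (!any(nas)) return(x)
  frac <- rowMeans(nas)
  drop <- frac > maxMissing
  if (any(drop)) {
    warning(sum(drop), " gene(s) dropped for >", 100 * maxMissing,
            "% missing values", call. = FALSE)
    x <- x[!drop, , drop = FALSE]
    nas <- nas[!drop, , drop = FALSE]
  }
  if (any(nas)) {
    message(sum(nas), " missing value(s) imputed by gene means")
    means <- rowMeans(x, na.rm = TRUE)
    idx <- which(nas, arr.ind = TRUE)
    x[idx] <- means[idx[, 1L]]
  }
  x
}

#' Posterior mesenchymal probability for new samples
#'
#' Applies a fitted [BCCPModel-class] to an expression matrix. The posterior
#' is `pi_M phi(c; m_M, s) / (pi_E phi(c; m_E, s) + pi_M phi(c; m_M, s))`
#' with `phi` the normal density and `c` the sample's compound covariate.
#' The matrix is harmonized to the model's genes first (see
#' [harmonizeGenes()]); samples missing more than half of the model's genes
#' are flagged unreliable.
#'
#' @param model A [BCCPModel-class].
#' @param x Genes-by-samples matrix (rownames required) or
#'   SummarizedExperiment.
#' @param tau Posterior threshold for the binary mesenchymal call;
#'   default 0.5. A sample is called mesenchymal when posterior > tau.
#' @param minCoverage Minimum fraction of model genes that must be present
#'   in `x`; default 0.8.
#' @return data.frame with one row per sample: `sample`, `cc` (compound
#'   covariate), `posterior` (mesenchymal), `call` (logical), `reliable`.
#' @examples
#' tr <- generateExpression(expressionSpec(nPerClass = 10, nSignature = 20,
#'                                         nBackground = 0), seed = 1)
#' fit <- fitBCCP(tr$matrix, tr$labels)
#' head(predictEMT(fit, tr$matrix))
#' @export
predictEMT <- function(model, x, tau = 0.5, minCoverage = 0.8) {
  stopifnot(is(model, "BCCPModel"))
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, 1L)
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)", call. = FALSE)
  h <- harmonizeGenes(model, x, minCoverage = minCoverage)
  model <- h$model; x <- h$matrix
  w <- model@weights
  present <- !is.na(x[names(w), , drop = FALSE])
  reliable <- colMeans(present) >= 0.5
  if (any(!reliable))
    warning(sum(!reliable), " sample(s) missing >50% of model genes; ",
            "predictions flagged unreliable", call. = FALSE)
  xi <- imputeGenes(x[names(w), , drop = FALSE], maxMissing = 1)
  cc <- drop(crossprod(xi, w))
  mE <- model@classMeans[["epithelial"]]
  mM <- model@classMeans[["mesenchymal"]]
  s <- model@pooledSD
  # log-space for numerical stability far from the class means
  lE <- log(model@priors[["epithelial"]]) + stats::dnorm(cc, mE, s, log = TRUE)
  lM <- log(model@priors[["mesenchymal"]]) + stats::dnorm(cc, mM, s, log = TRUE)
  post <- 1 / (1 + exp(lE - lM))
  data.frame(sample = colnames(x), cc = unname(cc),
             posterior = unname(post), call = unname(post > tau),
             reliable = unname(reliable), row.names = NULL)
}

#' Leave-one-out cross-validated misclassification rate
#'
#' For each sample the whole model — t-statistic weights, compound
#' covariate class means and pooled SD — is refit on the remaining samples
#' and the held-out sample is classified at posterior threshold `tau`.
#' The signature gene list itself is fixed, not reselected per fold.
#'
#' @inheritParams fitBCCP
#' @param tau Classification threshold; default 0.5.
#' @return Scalar misclassification rate in \[0, 1\], with attribute
#'   `"skipped"` counting folds that could not be fit.
#' @export
loocvMisclassification <- function(x, labels, tau = 0.5,
                                   priors = c(epithelial = 0.5,
                                              mesenchymal = 0.5),
                                   welch = FALSE, varFloor = 1e-8) {
  if (is(x, "SummarizedExperiment")) {
    if (is.character(labels) && length(labels) == 1L)
      labels <- SummarizedExperiment::colData(x)[[labels]]
    x <- SummarizedExperiment::assay(x, 1L)
  }
  labels <- as.character(labels)
  n <- ncol(x)
  if (n < 4L || min(table(labels)) < 2L)
    stop("LOOCV needs n >= 4 with at least 2 samples per class",
         call. = FALSE)
  wrong <- 0L; skipped <- 0L; used <- 0L
  for (j in seq_len(n)) {
    rest <- labels[-j]
    if (min(table(factor(rest,
                         levels = c("epithelial", "mesenchymal")))) < 2L) {
      warning("fold ", j, " skipped: a class lost all but one sample",
              call. = FALSE)
      skipped <- skipped + 1L
      next
    }
    fit <- fitBCCPCore(x[, -j, drop = FALSE], rest, priors = priors,
                       welch = welch, classSD = FALSE, varFloor = varFloor)
    pr <- predictEMT(fit, x[, j, drop = FALSE], tau = tau)
    called <- if (pr$call) "mesenchymal" else "epithelial"
    used <- used + 1L
    if (called != labels[j]) wrong <- wrong + 1L
  }
  rate <- wrong / used
  attr(rate, "skipped") <- skipped
  rate
}

#' Calibrate the posterior threshold against a reference prevalence
#'
#' The default posterior cut-off is 0.5; it is retained whenever the
#' resulting mesenchymal fraction falls inside `targetRange` (the
#' literature range for the mesenchymal/inflamed fraction of HNSCC,
#' 19.2-37.4 percent, is the default). Otherwise the threshold is chosen
#' among the observed posterior values so that the called fraction comes
#' closest to the nearest bound of the range, breaking ties toward the
#' larger threshold.
#'
#' @param posteriors Numeric vector of posterior mesenchymal probabilities
#'   (or the data.frame from [predictEMT()]).
#' @param targetRange Length-2 numeric inside (0, 1).
#' @return The selected threshold tau, with attribute `"fraction"` giving
#'   the mesenchymal fraction called at that tau.
#' @export
calibrateThreshold <- function(posteriors, targetRange = c(0.192, 0.374)) {
  if (is.data.frame(posteriors)) posteriors <- posteriors$posterior
  if (!length(posteriors)) stop("no predictions to calibrate on",
                                call. = FALSE)
  if (length(targetRange) != 2L || any(targetRange <= 0) ||
      any(targetRange >= 1) || targetRange[1] > targetRange[2])
    stop("targetRange must be an ordered interval inside (0, 1)",
         call. = FALSE)
  frac <- function(tau) mean(posteriors > tau)
  inRange <- function(f) f >= targetRange[1] && f <= targetRange[2]
  if (inRange(frac(0.5))) return(structure(0.5, fraction = frac(0.5)))
  cand <- sort(unique(posteriors), decreasing = TRUE)
  dist <- vapply(cand, function(tau) {
    f <- frac(tau)
    if (inRange(f)) 0 else min(abs(f - targetRange))
  }, numeric(1))
  best <- cand[dist == min(dist)]
  tau <- max(best)  # tie-break toward the larger threshold
  structure(tau, fraction = frac(tau))
}

#' Restrict a model and matrix to their common genes
#'
#' Cross-cohort application rarely finds every signature gene in the target
#' matrix. This restricts the model's weights and the matrix to their
#' intersection, erroring when coverage of the model's genes drops below
#' `minCoverage`. Note the compound-covariate class means and SD are kept
#' from training; with partial coverage posteriors are therefore
#' approximate, which is why coverage is floored.
#'
#' @param model A [BCCPModel-class].
#' @param x Genes-by-samples matrix with rownames.
#' @param minCoverage Minimum fraction of model genes present; default 0.8.
#' @return list(model, matrix) restricted to the common genes.
#' @export
harmonizeGenes <- function(model, x, minCoverage = 0.8) {
  stopifnot(is(model, "BCCPModel"))
  if (is.null(rownames(x))) stop("matrix needs gene rownames", call. = FALSE)
  common <- intersect(model@genesUsed, rownames(x))
  if (!length(common)) stop("no genes shared between model and matrix",
                            call. = FALSE)
  cov <- length(common) / length(model@genesUsed)
  if (cov < minCoverage)
    stop(sprintf("matrix covers only %d/%d model genes (%.0f%% < %.0f%%)",
                 length(common), length(model@genesUsed), 100 * cov,
                 100 * minCoverage), call. = FALSE)
  if (cov < 1) {
    dropped <- setdiff(model@genesUsed, common)
    warning(length(dropped), " model gene(s) absent from matrix: ",
            paste(utils::head(dropped, 10L), collapse = ", "),
            if (length(dropped) > 10L) ", ..." else "", call. = FALSE)
    model <- newBCCPModel(model@weights[common],
                          model@classMeans[["epithelial"]],
                          model@classMeans[["mesenchymal"]],
                          model@pooledSD, model@priors)
  }
  list(model = model, matrix = x[rownames(x) %in% common, , drop = FALSE])
}

#' Per-gene standardization of an expression matrix
#'
#' Centers each gene and scales it to unit standard deviation within the
#' cohort; constant genes are centered to all zeros with a warning. Useful
#' before cross-platform application of a classifier; idempotent up to
#' numerical tolerance.
#'
#' @param x Genes-by-samples numeric matrix.
#' @return Matrix of the same shape, per-gene mean 0 and SD 1 (or 0).
#' @export
standardizeMatrix <- function(x) {
  m <- rowMeans(x)
  s <- apply(x, 1L, stats::sd)
  const <- s < 1e-12
  if (any(const)) {
    warning(sum(const), " constant gene(s) set to zero after centering",
            call. = FALSE)
    s[const] <- 1
  }
  (x - m) / s
}
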
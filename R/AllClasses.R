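#' BCCPModel: a fitted Bayesian compound covariate predictor
#'
#' The Bayesian compound covariate predictor (BCCP) is a two-class
#' expression classifier. Each signature gene receives a weight equal to its
#' two-sample t-statistic (mesenchymal minus epithelial); a sample's
#' compound covariate is the weight-by-expression sum over the signature
#' genes; the compound covariate is modelled as Gaussian within each class
#' with a shared pooled standard deviation, and Bayes' rule converts it to a
#' posterior probability of the mesenchymal class.
#'
#' @slot weights Named numeric vector of per-gene t-statistic weights.
#' @slot classMeans Named numeric of length 2 (`epithelial`, `mesenchymal`):
#'   class means of the compound covariate in the training set.
#' @slot pooledSD Positive scalar: pooled within-class standard deviation of
#'   the compound covariate (shared equal-variance Gaussian model).
#' @slot priors Named numeric of length 2 summing to 1: class prior
#'   probabilities (`epithelial`, `mesenchymal`).
#' @slot genesUsed Character vector of genes actually carrying weight
#'   (signature genes that survived the variance floor).
#'
#' @seealso [fitBCCP()], [predictEMT()], [loocvMisclassification()]
#' @export
setClass("BCCPModel",
  representation(
    weights    = "numeric",
    classMeans = "numeric",
    pooledSD   = "numeric",
    priors     = "numeric",
    genesUsed  = "character"
  )
)

setValidity("BCCPModel", function(object) {
  msg <- character()
  if (length(object@genesUsed) == 0L)
    msg <- c(msg, "model must use at least one gene")
  if (!identical(names(object@weights), object@genesUsed))
    msg <- c(msg, "weights must be named by genesUsed, in order")
  if (any(!is.finite(object@weights)))
    msg <- c(msg, "weights must be finite")
  if (!identical(sort(names(object@classMeans)),
                 c("epithelial", "mesenchymal")))
    msg <- c(msg, "classMeans must be named 'epithelial' and 'mesenchymal'")
  if (length(object@pooledSD) != 1L || !is.finite(object@pooledSD) ||
      object@pooledSD <= 0)
    msg <- c(msg, "pooledSD must be a single positive number")
  if (!identical(sort(names(object@priors)),
                 c("epithelial", "mesenchymal")) ||
      abs(sum(object@priors) - 1) > 1e-8 || any(object@priors < 0))
    msg <- c(msg, "priors must be nonnegative, named, and sum to 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn BCCPModel Compact display of a fitted model.
#' @param object A `BCCPModel`.
#' @export
setMethod("show", "BCCPModel", function(object) {
  cat("BCCPModel with", length(object@genesUsed), "signature genes\n")
  cat(sprintf("  compound covariate: m_E = %.4g, m_M = %.4g, pooled SD = %.4g\n",
              object@classMeans[["epithelial"]],
              object@classMeans[["mesenchymal"]],
              object@pooledSD))
  cat(sprintf("  priors: epithelial %.3g / mesenchymal %.3g\n",
              object@priors[["epithelial"]], object@priors[["mesenchymal"]]))
  invisible(object)
})

#' Accessors for BCCPModel slots
#'
#' @param object A [BCCPModel-class] object.
#' @return `bccpWeights`: named numeric weights; `bccpGenes`: character gene
#'   ids; `classMeans`: named length-2 numeric; `pooledSD`: scalar;
#'   `classPriors`: named length-2 numeric.
#' @name BCCPModel-accessors
NULL

#' @rdname BCCPModel-accessors
#' @export
bccpWeights <- function(object) object@weights

#' @rdname BCCPModel-accessors
#' @export
bccpGenes <- function(object) object@genesUsed

#' @rdname BCCPModel-accessors
#' @export
classMeans <- function(object) object@classMeans

#' @rdname BCCPModel-accessors
#' @export
pooledSD <- function(object) object@pooledSD

#' @rdname BCCPModel-accessors
#' @export
classPriors <- function(object) object@priors

# internal constructor; validity runs via new()
newBCCPModel <- function(weights, mE, mM, s, priors) {
  new("BCCPModel",
      weights    = weights,
      classMeans = c(epithelial = unname(mE), mesenchymal = unname(mM)),
      pooledSD   = unname(s),
      priors     = priors[c("epithelial", "mesenchymal")],
      genesUsed  = names(weights))
}
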
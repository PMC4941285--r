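#' Specification for a synthetic IHC cohort
#'
#' Defines the joint structure of a simulated HNSCC cohort: marginal
#' prevalences of PD-L1 positivity and of the clinicopathologic covariates,
#' the odds ratio each covariate carries on PD-L1 positivity (the joint
#' distribution is a logistic model on PD-L1 with independent covariates;
#' the intercept is solved so the PD-L1 marginal matches its target), and a
#' proportional-hazards survival layer over the PD-L1/EMT composite groups.
#'
#' Defaults reproduce the structure of a 50-patient training cohort:
#' prevalences PD-L1+ 0.64, EMT 0.34, p16 0.30, oropharynx 0.32, female
#' 0.20, smoker 0.40, ECOG 1 0.76; covariate odds ratios on PD-L1 of 7.06
#' (EMT), 6.22 (oropharynx), 3.0 (p16), 0.81 (female), 0.75 (smoker) and
#' 0.28 (ECOG 1); exponential overall survival with baseline median 50
#' months, group hazard ratios 1 / 0.4 / 2.5 for PD-L1- / PD-L1+EMT- /
#' PD-L1+EMT+, and 40 percent censoring.
#'
#' @param n Number of patients (> 0).
#' @param prevalence Named list of marginal prevalences in (0, 1); names
#'   `pdl1`, `emt`, `p16`, `oropharynx`, `female`, `smoker`, `ecog1`.
#' @param oddsRatios Named list of per-covariate odds ratios (> 0) on
#'   PD-L1 positivity; same names minus `pdl1`.
#' @param survival list with `baselineMedianOS` (months), `hr` (named
#'   hazard ratios for groups `pdl1neg`, `pdl1pos_emtneg`,
#'   `pdl1pos_emtpos`), `censoring` in \[0, 1) and `pfsScale` (< 1,
#'   progression precedes death).
#' @return A validated spec (list) for [generateCohort()].
#' @export
cohortSpec <- function(n,
                       prevalence = list(pdl1 = 0.64, emt = 0.34, p16 = 0.30,
                                         oropharynx = 0.32, female = 0.20,
                                         smoker = 0.40, ecog1 = 0.76),
                       oddsRatios = list(emt = 7.06, oropharynx = 6.22,
                                         p16 = 3.0, female = 0.81,
                                         smoker = 0.75, ecog1 = 0.28),
                       survival = list(baselineMedianOS = 50,
                                       hr = c(pdl1neg = 1,
                                              pdl1pos_emtneg = 0.4,
                                              pdl1pos_emtpos = 2.5),
                                       censoring = 0.4, pfsScale = 0.7)) {
  if (length(n) != 1L || is.na(n) || n != round(n) || n <= 0)
    stop("n must be a positive integer", call. = FALSE)
  pv <- unlist(prevalence)
  if (any(pv <= 0 | pv >= 1))
    stop("prevalences must lie in (0, 1)", call. = FALSE)
  or <- unlist(oddsRatios)
  if (any(or <= 0)) stop("odds ratios must be positive", call. = FALSE)
  if (!all(names(oddsRatios) %in% names(prevalence)))
    stop("every odds ratio needs a matching covariate prevalence",
         call. = FALSE)
  if (survival$censoring < 0 || survival$censoring >= 1)
    stop("censoring rate must lie in [0, 1)", call. = FALSE)
  if (survival$baselineMedianOS <= 0)
    stop("baseline median OS must be positive", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 oddsRatios = oddsRatios, survival = survival),
            class = "cohortSpec")
}

#' Generate a synthetic IHC patient cohort
#'
#' Draws covariates independently at their marginal prevalences, assigns
#' PD-L1 positivity from a logistic model whose log-odds ratios match the
#' spec (intercept solved so the realized PD-L1 prevalence matches its
#' target in expectation), then synthesises staining-intensity profiles
#' consistent with each patient's assigned calls — so that [scoreIHC()]
#' round-trips the intended marker calls exactly — and exponential survival
#' times under the spec's group hazard ratios. Deterministic under `seed`.
#'
#' @param spec A [cohortSpec()].
#' @param seed Integer random seed (mandatory).
#' @return Patient table (data.frame) in the schema consumed by
#'   [scoreIHC()] and [readPatientCSV()].
#' @export
generateCohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohortSpec"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  n <- spec$n
  pv <- spec$prevalence

  draw <- function(p) stats::runif(n) < p
  cov <- list(emt = draw(pv$emt), p16 = draw(pv$p16),
              oropharynx = draw(pv$oropharynx), female = draw(pv$female),
              smoker = draw(pv$smoker), ecog1 = draw(pv$ecog1))

  # linear predictor without intercept, then solve alpha for the margin
  lp <- rep(0, n)
  for (nm in names(spec$oddsRatios))
    lp <- lp + log(spec$oddsRatios[[nm]]) * cov[[nm]]
  target <- pv$pdl1
  f <- function(a) mean(stats::plogis(a + lp)) - target
  if (f(-30) > 0 || f(30) < 0)
    stop("infeasible prevalence/odds-ratio combination for pdl1",
         call. = FALSE)
  alpha <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  pdl1 <- stats::runif(n) < stats::plogis(alpha + lp)

  prof <- synthesizeProfiles(pdl1, cov$emt, cov$p16)

  sv <- spec$survival
  group <- ifelse(!pdl1, "pdl1neg",
                  ifelse(cov$emt, "pdl1pos_emtpos", "pdl1pos_emtneg"))
  lambda0 <- log(2) / sv$baselineMedianOS
  lambda <- lambda0 * unname(sv$hr[group])
  tEvent <- stats::rexp(n, rate = lambda)
  cens <- sv$censoring
  if (cens > 0) {
    mu <- cens / (1 - cens) * lambda  # P(censored) = mu/(lambda+mu)
    tCens <- stats::rexp(n, rate = mu)
  } else tCens <- rep(Inf, n)
  osMonths <- pmin(tEvent, tCens)
  osEvent <- as.integer(tEvent <= tCens)
  pfsScale <- if (is.null(sv$pfsScale)) 0.7 else sv$pfsScale
  pfsMonths <- osMonths * stats::runif(n, min = pfsScale, max = 1)
  pfsEvent <- pmax(osEvent,
                   as.integer(stats::runif(n) < 0.5 * (1 - cens)))

  data.frame(id = sprintf("PT%04d", seq_len(n)),
             age = round(stats::rnorm(n, 60, 10)),
             sex = ifelse(cov$female, "F", "M"),
             smoking = ifelse(cov$smoker, "ever", "never"),
             ecog = as.integer(cov$ecog1),
             site = ifelse(cov$oropharynx, "oropharynx", "non-oropharynx"),
             stage = sample(c("I", "II", "III", "IVA"), n, replace = TRUE,
                            prob = c(0.12, 0.04, 0.30, 0.54)),
             prof,
             os_months = round(osMonths, 2), os_event = osEvent,
             pfs_months = round(pfsMonths, 2), pfs_event = pfsEvent,
             stringsAsFactors = FALSE)
}

# H-score -> valid (p0..p3) decomposition, drawn uniformly in the feasible
# region: p3 in [max(0, H-200), min(100, H/3)], then p2 given the budget.
decomposeHScore <- function(h) {
  n <- length(h)
  p3lo <- pmax(0, h - 200); p3hi <- pmin(100, h / 3)
  p3 <- p3lo + stats::runif(n) * (p3hi - p3lo)
  hr <- h - 3 * p3
  b <- 100 - p3
  p2lo <- pmax(0, hr - b); p2hi <- pmin(hr / 2, b)
  p2 <- p2lo + stats::runif(n) * (p2hi - p2lo)
  p1 <- hr - 2 * p2
  p0 <- 100 - p1 - p2 - p3
  data.frame(p0 = p0, p1 = p1, p2 = p2, p3 = p3)
}

synthesizeProfiles <- function(pdl1, emt, p16) {
  n <- length(pdl1)
  # (ecad, vim) H-scores: EMT+ needs ecad < 200 and vim > 30; EMT- samples
  # uniformly from the complement of that rectangle in [0,300]^2
  ecadH <- numeric(n); vimH <- numeric(n)
  pos <- which(emt)
  ecadH[pos] <- stats::runif(length(pos), 0, 199)
  vimH[pos] <- stats::runif(length(pos), 31, 300)
  neg <- which(!emt)
  for (i in neg) {
    repeat {
      e <- stats::runif(1, 0, 300); v <- stats::runif(1, 0, 300)
      if (!(e < 200 && v > 30)) { ecadH[i] <- e; vimH[i] <- v; break }
    }
  }
  ecad <- decomposeHScore(ecadH); names(ecad) <- paste0("ecad_", names(ecad))
  vim <- decomposeHScore(vimH); names(vim) <- paste0("vim_", names(vim))

  # PD-L1 membranous profiles: positives get one intensity category >= 5%,
  # categories above it kept below 5%; negatives stain < 5% in total
  pd <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    if (pdl1[i]) {
      k <- sample(3L, 1L)
      pd[i, k] <- stats::runif(1, 5, 80)
      if (k < 3L) pd[i, (k + 1L):3L] <- stats::runif(3L - k, 0, 4.5)
      if (k > 1L) pd[i, 1:(k - 1L)] <- stats::runif(k - 1L, 0, 4.5)
    } else {
      w <- stats::runif(3); pd[i, ] <- w / sum(w) * stats::runif(1, 0, 4.5)
    }
  }
  pdl1df <- data.frame(pdl1_p0 = 100 - rowSums(pd), pdl1_p1 = pd[, 1],
                       pdl1_p2 = pd[, 2], pdl1_p3 = pd[, 3])

  p16pct <- ifelse(p16, stats::runif(n, 70, 100), stats::runif(n, 0, 69.5))
  cbind(ecad, vim, pdl1df, p16_pct = p16pct)
}

#' Specification for a synthetic two-class expression matrix
#'
#' Emulates the signature structure the compound covariate classifier
#' assumes: `nSignature` genes shifted between the epithelial and
#' mesenchymal classes by `delta` within-class standard deviations (a
#' `reversedFraction` of them shifted in the opposite direction, as real
#' signatures mix epithelial-high and mesenchymal-high genes), plus
#' `nBackground` undifferentiated genes, and a PD-L1 gene (`CD274`)
#' shifted by `pdl1Shift` in the mesenchymal class. Values are log2-scale
#' with gene baselines drawn around 8.
#'
#' @param nPerClass Samples per class (>= 2); default 30.
#' @param nSignature Number of signature genes; default 75.
#' @param nBackground Number of background genes; default 125.
#' @param delta Between-class shift in units of the within-class SD
#'   (>= 0); default 1.5.
#' @param noiseSD Within-class SD on the log2 scale; default 1.
#' @param reversedFraction Fraction of signature genes shifted
#'   epithelial-high; default 0.4.
#' @param pdl1Shift Mesenchymal-minus-epithelial shift of `CD274` (log2);
#'   default 1.
#' @return A validated spec (list) for [generateExpression()].
#' @export
expressionSpec <- function(nPerClass = 30, nSignature = 75,
                           nBackground = 125, delta = 1.5, noiseSD = 1,
                           reversedFraction = 0.4, pdl1Shift = 1) {
  if (nPerClass < 2) stop("need at least 2 samples per class", call. = FALSE)
  if (nSignature < 1) stop("need at least one signature gene", call. = FALSE)
  if (delta < 0 || noiseSD <= 0)
    stop("delta must be >= 0 and noiseSD > 0", call. = FALSE)
  if (reversedFraction < 0 || reversedFraction > 1)
    stop("reversedFraction must lie in [0, 1]", call. = FALSE)
  structure(list(nPerClass = as.integer(nPerClass),
                 nSignature = as.integer(nSignature),
                 nBackground = as.integer(nBackground),
                 delta = delta, noiseSD = noiseSD,
                 reversedFraction = reversedFraction,
                 pdl1Shift = pdl1Shift),
            class = "expressionSpec")
}

#' Generate a labeled two-class expression matrix
#'
#' @param spec An [expressionSpec()].
#' @param seed Integer random seed (mandatory).
#' @param prevalence Optional mesenchymal prevalence in (0, 1); by default
#'   the two classes are balanced at `nPerClass` each. When given, class
#'   membership is drawn Bernoulli(prevalence) over `2 * nPerClass`
#'   samples (mixture cohorts for calibration studies).
#' @return list with `matrix` (genes x samples, signature genes
#'   `SIG001..`, background `BG001..`, plus `CD274`), `labels`
#'   (epithelial/mesenchymal per sample), and `signature` (the signature
#'   gene ids).
#' @export
generateExpression <- function(spec, seed, prevalence = NULL) {
  stopifnot(inherits(spec, "expressionSpec"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  nTot <- 2L * spec$nPerClass
  labels <- if (is.null(prevalence)) {
    rep(c("epithelial", "mesenchymal"), each = spec$nPerClass)
  } else {
    if (prevalence <= 0 || prevalence >= 1)
      stop("prevalence must lie in (0, 1)", call. = FALSE)
    ifelse(stats::runif(nTot) < prevalence, "mesenchymal", "epithelial")
  }
  isM <- labels == "mesenchymal"
  sigIds <- sprintf("SIG%03d", seq_len(spec$nSignature))
  bgIds <- if (spec$nBackground > 0)
    sprintf("BG%03d", seq_len(spec$nBackground)) else character()
  genes <- c(sigIds, bgIds, "CD274")
  nG <- length(genes)

  # baseline abundance is a property of the gene, not of the cohort draw:
  # fixed normal-score spread around 8 log2 units so that independently
  # seeded cohorts share a platform and a trained model transfers
  baseline <- 8 + 2 * stats::qnorm(seq_len(nG) / (nG + 1))
  shift <- numeric(nG)
  dir <- rep(1, spec$nSignature)
  nRev <- round(spec$reversedFraction * spec$nSignature)
  if (nRev > 0) dir[seq_len(nRev)] <- -1
  shift[seq_len(spec$nSignature)] <- dir * spec$delta * spec$noiseSD
  shift[nG] <- spec$pdl1Shift

  m <- matrix(stats::rnorm(nG * nTot, sd = spec$noiseSD), nG, nTot)
  m <- m + baseline + outer(shift / 2, ifelse(isM, 1, -1))
  dimnames(m) <- list(genes,
                      sprintf("S%03d", seq_len(nTot)))
  list(matrix = m, labels = labels, signature = sigIds)
}

#' Expand a count table into a patient table
#'
#' Emits exactly one row per counted unit so that [crossTab()] on the
#' result reproduces the input counts — the exact-fixture route for
#' published cross-tabulations whose individual-level data are the counts
#' themselves.
#'
#' @param counts Either a matrix/table with dimnames (2 variables), or a
#'   data.frame whose last column `n` holds counts and whose other columns
#'   are the categorical values.
#' @param vars For the matrix form, length-2 character: the variable names
#'   (defaults to the dimnames' names, or `c("row", "col")`).
#' @return data.frame with one row per unit; zero total gives an empty
#'   table with the right columns.
#' @examples
#' tab <- matrix(c(15, 17, 2, 16), 2,
#'               dimnames = list(emt = c("pos", "neg"),
#'                               pdl1 = c("pos", "neg")))
#' fx <- fixtureFromCounts(tab)
#' crossTab(fx, "emt", "pdl1")
#' @export
fixtureFromCounts <- function(counts, vars = NULL) {
  if (is.data.frame(counts)) {
    if (!"n" %in% names(counts))
      stop("data.frame form needs a count column 'n'", call. = FALSE)
    n <- counts$n
    if (any(n < 0 | n != round(n)))
      stop("counts must be non-negative integers", call. = FALSE)
    vals <- counts[setdiff(names(counts), "n")]
    out <- vals[rep(seq_len(nrow(vals)), n), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  m <- as.matrix(counts)
  if (any(m < 0 | m != round(m)))
    stop("counts must be non-negative integers", call. = FALSE)
  dn <- dimnames(m)
  if (is.null(dn) || is.null(dn[[1]]) || is.null(dn[[2]]))
    stop("count matrix needs dimnames", call. = FALSE)
  if (is.null(vars)) {
    vars <- names(dn)
    if (is.null(vars) || any(vars == "")) vars <- c("row", "col")
  }
  grid <- expand.grid(factor(dn[[1]], levels = dn[[1]]),
                      factor(dn[[2]], levels = dn[[2]]),
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- vars
  out <- grid[rep(seq_len(nrow(grid)), as.vector(m)), , drop = FALSE]
  rownames(out) <- NULL
  out
}
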
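# Independent brute-force oracles used to check the analysis routines.

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables with
# the observed margins, summing hypergeometric probabilities no larger than
# the observed table's (with the usual relative tolerance for float ties).
fisherOracle <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  aRange <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(aRange, c1, n - c1, r1)
  pObs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# Kaplan-Meier by direct product over risk sets (events before censorings
# at tied times, matching the estimator's convention).
kmOracle <- function(time, event, at) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  for (t in ut[ut <= at]) {
    nRisk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / nRisk)
  }
  s
}

# Cox coefficient for a single covariate, no ties/censoring: direct
# maximization of the log partial likelihood over a fine grid.
coxGridOracle <- function(time, x, grid = seq(-6, 6, by = 1e-3)) {
  ord <- order(time)
  time <- time[ord]; x <- x[ord]
  lpl <- function(b) {
    sum(vapply(seq_along(time), function(i) {
      risk <- which(time >= time[i])
      b * x[i] - log(sum(exp(b * x[risk])))
    }, numeric(1)))
  }
  vals <- vapply(grid, lpl, numeric(1))
  grid[which.max(vals)]
}

# Exact two-sided Wilcoxon rank-sum p by enumeration of all assignments of
# the pooled ranks to the first sample (no ties assumed).
wilcoxonOracle <- function(x, y) {
  pooled <- c(x, y)
  ranks <- rank(pooled)
  nx <- length(x)
  combs <- utils::combn(length(pooled), nx)
  stats <- colSums(matrix(ranks[combs], nrow = nx))
  wObs <- sum(ranks[seq_len(nx)])
  center <- nx * (length(pooled) + 1) / 2
  mean(abs(stats - center) >= abs(wObs - center) - 1e-9)
}

# random valid staining profile (percentages sum to 100)
randomProfile <- function() {
  w <- runif(4)
  p <- w / sum(w) * 100
  list(p0 = p[1], p1 = p[2], p2 = p[3], p3 = p[4])
}

# minimal single-gene model: weight 1 on gene g1 so the compound covariate
# equals the expression value itself
unitModel <- function(mE, mM, s,
                      priors = c(epithelial = 0.5, mesenchymal = 0.5)) {
  new("BCCPModel", weights = c(g1 = 1),
      classMeans = c(epithelial = mE, mesenchymal = mM),
      pooledSD = s, priors = priors, genesUsed = "g1")
}

unitMatrix <- function(cc) {
  matrix(cc, nrow = 1, dimnames = list("g1", paste0("s", seq_along(cc))))
}

# staining-profile columns consistent with given marker calls, for building
# patient tables from printed cross-tabulations
profilesFromCalls <- function(emt, pdl1, p16 = rep(FALSE, length(emt))) {
  n <- length(emt)
  data.frame(
    ecad_p0 = ifelse(emt, 50, 0), ecad_p1 = ifelse(emt, 50, 0),
    ecad_p2 = 0, ecad_p3 = ifelse(emt, 0, 100),          # H 50 vs 300
    vim_p0 = ifelse(emt, 50, 100), vim_p1 = 0, vim_p2 = 0,
    vim_p3 = ifelse(emt, 50, 0),                         # H 150 vs 0
    pdl1_p0 = ifelse(pdl1, 80, 100), pdl1_p1 = 0, pdl1_p2 = 0,
    pdl1_p3 = ifelse(pdl1, 20, 0),
    p16_pct = ifelse(p16, 90, 10))
}

# patient table reproducing a published EMT x PD-L1 count table, with
# survival columns so the full pipeline can run on it
cohortFromTable <- function(tab, seed = 1) {
  fx <- fixtureFromCounts(tab)
  emt <- fx[[1]] == "positive" | fx[[1]] == "oropharynx" |
    fx[[1]] == "female"
  pdl1 <- fx[[2]] == "positive"
  set.seed(seed)
  n <- nrow(fx)
  cbind(id = sprintf("P%03d", seq_len(n)),
        sex = "M", site = "non-oropharynx",
        profilesFromCalls(emt, pdl1),
        os_months = round(rexp(n, log(2) / 40), 2) + 0.01,
        os_event = rbinom(n, 1, 0.6),
        pfs_months = round(rexp(n, log(2) / 30), 2) + 0.01,
        pfs_event = rbinom(n, 1, 0.7))
}
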
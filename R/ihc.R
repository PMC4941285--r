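#' Immunohistochemistry H-score
#'
#' The H-score summarises a four-category staining-intensity profile
#' (percentage of tumor cells with no / weak / moderate / strong staining)
#' as `1*p1 + 2*p2 + 3*p3`, ranging 0-300. Percentages must account for all
#' tumor cells: `p0 + p1 + p2 + p3 = 100` within 1e-6 (profiles that do not
#' sum are rejected, never renormalised, to surface data errors).
#'
#' @param p0,p1,p2,p3 Numeric vectors: percentage of tumor cells with no,
#'   weak (1+), moderate (2+) and strong (3+) staining. Vectorised.
#' @param label Optional identifier(s) used in error messages.
#' @return Numeric vector of H-scores in \[0, 300\].
#' @examples
#' computeHScore(40, 20, 30, 10)  # 110
#' @export
computeHScore <- function(p0, p1, p2, p3, label = NULL) {
  checkProfile(p0, p1, p2, p3, label)
  p1 + 2 * p2 + 3 * p3
}

checkProfile <- function(p0, p1, p2, p3, label = NULL) {
  pct <- cbind(p0, p1, p2, p3)
  bad <- !is.finite(pct) | pct < 0
  sums <- rowSums(pct)
  off <- abs(sums - 100) > 1e-6
  problem <- apply(bad, 1L, any) | off
  if (any(problem)) {
    who <- if (is.null(label)) paste("row", which(problem)) else
      label[pmin(which(problem), length(label))]
    stop("invalid staining profile (negative/missing values or percentages ",
         "not summing to 100) for: ", paste(unique(who), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' EMT phenotype call from E-cadherin and vimentin H-scores
#'
#' A tumor is called EMT-positive when the epithelial marker E-cadherin is
#' low (H-score strictly below `ecadCutoff`) and the mesenchymal marker
#' vimentin is high (H-score strictly above `vimCutoff`). Both inequalities
#' are strict.
#'
#' @param ecad,vim Numeric vectors of H-scores in \[0, 300\].
#' @param ecadCutoff,vimCutoff Cutoffs; defaults 200 and 30.
#' @return Logical vector: EMT-positive.
#' @examples
#' callEMT(199, 31)  # TRUE
#' callEMT(200, 31)  # FALSE: boundary is strict
#' @export
callEMT <- function(ecad, vim, ecadCutoff = 200, vimCutoff = 30) {
  stopifnot(all(is.finite(ecad)), all(is.finite(vim)),
            all(ecad >= 0 & ecad <= 300), all(vim >= 0 & vim <= 300))
  ecad < ecadCutoff & vim > vimCutoff
}

#' PD-L1 score and positivity from a membranous staining profile
#'
#' PD-L1 is scored 0-3 on membranous staining: 0 when fewer than
#' `minPercent` of tumor cells stain at any intensity; otherwise the score
#' is the highest intensity category that individually reaches
#' `minPercent`, or 1 when only the combined stained fraction does.
#' Positivity is membranous staining in at least `minPercent` of tumor
#' cells, i.e. score >= 1.
#'
#' @param p0,p1,p2,p3 Staining-profile percentages (see [computeHScore()]).
#' @param minPercent Positivity threshold as a percentage; default 5.
#' @param compartment Staining compartment; must be `"membranous"` — PD-L1
#'   scoring is defined on membranous staining only.
#' @param label Optional identifier(s) for error messages.
#' @return A data.frame with columns `score` (integer 0-3) and `positive`
#'   (logical), one row per profile.
#' @examples
#' callPDL1(96, 4, 0, 0)    # score 0, negative
#' callPDL1(95, 5, 0, 0)    # score 1, positive
#' callPDL1(77, 10, 6, 7)   # score 3: strong staining reaches 5%
#' @export
callPDL1 <- function(p0, p1, p2, p3, minPercent = 5,
                     compartment = "membranous", label = NULL) {
  if (!identical(compartment, "membranous"))
    stop("PD-L1 scoring requires a membranous staining profile, got '",
         compartment, "'", call. = FALSE)
  checkProfile(p0, p1, p2, p3, label)
  stained <- p1 + p2 + p3
  positive <- stained >= minPercent
  score <- integer(length(stained))
  score[positive & p1 >= minPercent] <- 1L
  score[positive & p2 >= minPercent] <- 2L
  score[positive & p3 >= minPercent] <- 3L
  # combined fraction reaches the threshold but no single category does
  score[positive & score == 0L] <- 1L
  data.frame(score = score, positive = positive)
}

#' p16 call from the diffuse strong staining fraction
#'
#' p16 (the HPV surrogate marker in HNSCC) is positive when diffuse and
#' strong nuclear and cytoplasmic staining covers at least `minPercent`
#' (default 70) percent of tumor cells. A missing fraction yields `NA`
#' ("unknown"), never a silent negative.
#'
#' @param fraction Numeric vector: percent of tumor cells with diffuse
#'   strong staining, in \[0, 100\]; may contain `NA`.
#' @param minPercent Threshold percentage; default 70 (inclusive).
#' @return Logical vector with `NA` where the fraction is missing.
#' @examples
#' callP16(c(70, 69.9, 100, NA))  # TRUE FALSE TRUE NA
#' @export
callP16 <- function(fraction, minPercent = 70) {
  known <- !is.na(fraction)
  if (any(fraction[known] < 0 | fraction[known] > 100))
    stop("p16 fraction must lie in [0, 100]", call. = FALSE)
  ifelse(known, fraction >= minPercent, NA)
}

#' Score an IHC patient table
#'
#' Applies the three marker rules to a patient table carrying staining
#' profiles for E-cadherin (`ecad_p0..ecad_p3`), vimentin (`vim_p0..vim_p3`)
#' and PD-L1 (`pdl1_p0..pdl1_p3`, membranous), plus the p16 diffuse strong
#' fraction (`p16_pct`). Unknown columns are preserved.
#'
#' @param patients A data.frame in the documented patient-table schema
#'   (see [readPatientCSV()]).
#' @param ecadCutoff,vimCutoff,pdl1Percent,p16Percent Call thresholds;
#'   defaults 200, 30, 5 and 70.
#' @return The input augmented with `h_score_ecad`, `h_score_vim`,
#'   `pd_l1_score`, `pd_l1_positive`, `emt_positive`, `p16_positive`.
#' @export
scoreIHC <- function(patients, ecadCutoff = 200, vimCutoff = 30,
                     pdl1Percent = 5, p16Percent = 70) {
  need <- c(paste0("ecad_p", 0:3), paste0("vim_p", 0:3),
            paste0("pdl1_p", 0:3), "p16_pct")
  miss <- setdiff(need, names(patients))
  if (length(miss))
    stop("patient table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  lab <- if ("id" %in% names(patients)) as.character(patients$id) else
    paste("row", seq_len(nrow(patients)))
  patients$h_score_ecad <- computeHScore(patients$ecad_p0, patients$ecad_p1,
                                         patients$ecad_p2, patients$ecad_p3,
                                         label = lab)
  patients$h_score_vim <- computeHScore(patients$vim_p0, patients$vim_p1,
                                        patients$vim_p2, patients$vim_p3,
                                        label = lab)
  pd <- callPDL1(patients$pdl1_p0, patients$pdl1_p1, patients$pdl1_p2,
                 patients$pdl1_p3, minPercent = pdl1Percent, label = lab)
  patients$pd_l1_score <- pd$score
  patients$pd_l1_positive <- pd$positive
  patients$emt_positive <- callEMT(patients$h_score_ecad, patients$h_score_vim,
                                   ecadCutoff = ecadCutoff,
                                   vimCutoff = vimCutoff)
  patients$p16_positive <- callP16(patients$p16_pct, minPercent = p16Percent)
  patients
}
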
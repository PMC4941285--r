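#' Published HNSCC cohort cross-tabulations
#'
#' The 2x2 cross-classifications of PD-L1 positivity against EMT phenotype,
#' oropharyngeal site, p16 status and sex, reconstructed from the printed
#' group counts of the two HNSCC cohorts these methods were developed on:
#' a training cohort of 50 patients (18 PD-L1-, 17 PD-L1+/EMT-,
#' 15 PD-L1+/EMT+) and an independent validation cohort of 91 patients
#' (32 / 32 / 27). Rows are the covariate (positive level first), columns
#' PD-L1 (positive first). These tables are the desk-scale inputs for the
#' association statistics; individual-level survival times are not
#' recoverable from them.
#'
#' @param cohort `"training"` or `"validation"`.
#' @return Named list of 2x2 integer matrices: `emt`, `oropharynx`, `p16`,
#'   and (validation only has a printed sex effect, but both are returned)
#'   `sex` (rows female/male).
#' @examples
#' hnsccCountTables("training")$emt
#' @export
hnsccCountTables <- function(cohort = c("training", "validation")) {
  cohort <- match.arg(cohort)
  t2 <- function(a, b, c, d, rows, rv) {
    m <- matrix(as.integer(c(a, c, b, d)), 2L,
                dimnames = stats::setNames(
                  list(rows, c("positive", "negative")), c(rv, "pdl1")))
    m
  }
  pn <- c("positive", "negative")
  if (cohort == "training") {
    list(
      # 32 PD-L1+ of whom 15 EMT+; 17 EMT+ overall
      emt = t2(15, 2, 17, 16, pn, "emt"),
      # oropharynx: 2 PD-L1-, 10 + 4 PD-L1+
      oropharynx = t2(14, 2, 18, 16, c("oropharynx", "non-oropharynx"),
                      "site"),
      # p16+: 3 PD-L1-, 9 + 3 PD-L1+
      p16 = t2(12, 3, 20, 15, pn, "p16"),
      # women: 4 PD-L1-, 2 + 4 PD-L1+
      sex = t2(6, 4, 26, 14, c("female", "male"), "sex")
    )
  } else {
    list(
      # 27 of 32 EMT+ are PD-L1+ (84.4%); 32 of 59 EMT- (54.2%)
      emt = t2(27, 5, 32, 27, pn, "emt"),
      oropharynx = t2(30, 9, 29, 23, c("oropharynx", "non-oropharynx"),
                      "site"),
      p16 = t2(24, 9, 35, 23, pn, "p16"),
      # women: 7 PD-L1-, 13 + 10 PD-L1+
      sex = t2(23, 7, 36, 25, c("female", "male"), "sex")
    )
  }
}
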
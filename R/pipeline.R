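#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the published
#' defaults: E-cadherin H-score cutoff 200, vimentin cutoff 30, PD-L1
#' positivity at 5 percent of tumor cells, p16 at 70 percent, posterior
#' threshold 0.5, minimum signature-gene coverage 0.8, Efron ties,
#' Benjamini-Hochberg adjustment off (printed per-test p-values are
#' unadjusted).
#'
#' @param patientCSV Path to the patient table, or a data.frame.
#' @param expressionTSV,gmt Optional paths to a labeled-training expression
#'   TSV and a signature GMT (first set used). When both are given along
#'   with `labels`, the classifier stage runs.
#' @param labels Optional class label per expression sample
#'   (epithelial/mesenchymal).
#' @param ecadCutoff,vimCutoff,pdl1Percent,p16Percent,tau,minCoverage
#'   Thresholds (see Details for defaults).
#' @param ties Cox tie handling, `"efron"` or `"breslow"`.
#' @param fdr Apply BH adjustment across the association family.
#' @param seed Integer seed recorded in the run log (the pipeline itself is
#'   deterministic given its inputs; the seed feeds any simulation inputs).
#' @param outDir Output directory (created if missing).
#' @return Validated config (list).
#' @export
pipelineConfig <- function(patientCSV, expressionTSV = NULL, gmt = NULL,
                           labels = NULL, ecadCutoff = 200, vimCutoff = 30,
                           pdl1Percent = 5, p16Percent = 70, tau = 0.5,
                           minCoverage = 0.8,
                           ties = c("efron", "breslow"), fdr = FALSE,
                           seed = 1L, outDir = tempfile("pdl1emt-run-")) {
  ties <- match.arg(ties)
  if (ecadCutoff < 0 || ecadCutoff > 300 || vimCutoff < 0 || vimCutoff > 300)
    stop("H-score cutoffs must lie in [0, 300]", call. = FALSE)
  if (pdl1Percent <= 0 || pdl1Percent > 100 ||
      p16Percent <= 0 || p16Percent > 100)
    stop("percentage thresholds must lie in (0, 100]", call. = FALSE)
  if (tau <= 0 || tau >= 1)
    stop("posterior threshold tau must lie in (0, 1)", call. = FALSE)
  if (minCoverage <= 0 || minCoverage > 1)
    stop("minCoverage must lie in (0, 1]", call. = FALSE)
  list(patientCSV = patientCSV, expressionTSV = expressionTSV, gmt = gmt,
       labels = labels, ecadCutoff = ecadCutoff, vimCutoff = vimCutoff,
       pdl1Percent = pdl1Percent, p16Percent = p16Percent, tau = tau,
       minCoverage = minCoverage, ties = ties, fdr = fdr,
       seed = as.integer(seed), outDir = outDir)
}

#' Run the full analysis pipeline
#'
#' Chains the stages: IHC scoring, marker cross-tabulations with Fisher
#' tests / odds ratios / univariate logistic regression, optionally the
#' compound covariate classifier (fit, LOOCV, prediction), and survival
#' analysis over the PD-L1/EMT composite groups (Kaplan-Meier medians,
#' landmark rates, log-rank test, univariate Cox fits). Writes
#' `scored_patients.csv`, `association_results.csv`, `survival_results.csv`
#' and `km_curves.csv` (plus `bccp_model.txt` and `emt_predictions.csv`
#' when the classifier stage runs) and a `run_log.txt` recording seed,
#' thresholds and a content hash of the config. Reruns with identical
#' config and inputs are byte-identical.
#'
#' @param config From [pipelineConfig()].
#' @return Invisibly, a list with the in-memory results (`patients`,
#'   `association`, `survival`, `km`, and optionally `model`,
#'   `predictions`) and `outDir`.
#' @export
runAll <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  patients <- if (is.data.frame(config$patientCSV)) config$patientCSV
              else readPatientCSV(config$patientCSV)

  stage <- "ihc_scoring"
  res <- tryCatch({
    patients <- scoreIHC(patients, ecadCutoff = config$ecadCutoff,
                         vimCutoff = config$vimCutoff,
                         pdl1Percent = config$pdl1Percent,
                         p16Percent = config$p16Percent)
    writePatientCSV(patients, file.path(config$outDir,
                                        "scored_patients.csv"))

    stage <- "association"
    assoc <- associationStage(patients, fdr = config$fdr)
    utils::write.csv(assoc, file.path(config$outDir,
                                      "association_results.csv"),
                     row.names = FALSE, quote = FALSE)

    model <- NULL; preds <- NULL
    if (!is.null(config$expressionTSV)) {
      stage <- "emt_signature"
      x <- readExpressionTSV(config$expressionTSV)
      if (!is.null(config$gmt)) {
        sig <- readGMT(config$gmt)[[1L]]
        x <- x[rownames(x) %in% sig, , drop = FALSE]
      }
      if (is.null(config$labels))
        stop("expression stage needs class labels", call. = FALSE)
      model <- fitBCCP(x, config$labels)
      writeBCCPModel(model, file.path(config$outDir, "bccp_model.txt"))
      preds <- predictEMT(model, x, tau = config$tau,
                          minCoverage = config$minCoverage)
      utils::write.csv(preds, file.path(config$outDir,
                                        "emt_predictions.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    stage <- "survival"
    surv <- NULL; km <- NULL
    if (all(c("os_months", "os_event") %in% names(patients))) {
      sv <- survivalStage(patients, ties = config$ties)
      surv <- sv$results; km <- sv$km
      utils::write.csv(surv, file.path(config$outDir,
                                       "survival_results.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(km, file.path(config$outDir, "km_curves.csv"),
                       row.names = FALSE, quote = FALSE)
    }

    writeRunLog(config)
    list(patients = patients, association = assoc, survival = surv,
         km = km, model = model, predictions = preds,
         outDir = config$outDir)
  }, error = function(e) {
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

associationStage <- function(patients, fdr = FALSE) {
  vars <- list(emt = "emt_positive", p16 = "p16_positive")
  if ("site" %in% names(patients))
    patients$oropharynx <- patients$site == "oropharynx"
  if ("oropharynx" %in% names(patients))
    vars$oropharynx <- "oropharynx"
  if ("sex" %in% names(patients))
    patients$female <- patients$sex == "F"
  if ("female" %in% names(patients)) vars$female <- "female"

  rows <- lapply(names(vars), function(nm) {
    v <- vars[[nm]]
    # factor with TRUE first so cell [1,1] is exposed & PD-L1 positive
    r <- factor(patients[[v]], levels = c(TRUE, FALSE))
    cc <- factor(patients$pd_l1_positive, levels = c(TRUE, FALSE))
    d <- data.frame(r = r, pdl1 = cc)
    tab <- crossTab(d, "r", "pdl1")
    or <- oddsRatio(tab)
    ok <- stats::complete.cases(patients[[v]], patients$pd_l1_positive)
    lf <- logisticFit(patients$pd_l1_positive[ok],
                      data.frame(x = as.logical(patients[[v]][ok])))
    data.frame(variable = nm, a = tab[1, 1], b = tab[1, 2], c = tab[2, 1],
               d = tab[2, 2], or = or$or, ci_lo = or$ci[1],
               ci_hi = or$ci[2], fisher_p = fisherExact2x2(tab),
               logistic_p = if (nrow(lf)) lf$p[1] else NA_real_,
               method = "fisher+logistic")
  })
  out <- do.call(rbind, rows)
  out$fisher_p_adj <- if (fdr) bhAdjust(out$fisher_p) else NA_real_
  out
}

survivalStage <- function(patients, ties = "efron") {
  grp <- ifelse(!patients$pd_l1_positive, "PD-L1-",
                ifelse(patients$emt_positive, "PD-L1+/EMT+", "PD-L1+/EMT-"))
  time <- patients$os_months; event <- patients$os_event
  lr <- logrankTest(time, event, grp)
  rows <- lapply(sort(unique(grp)), function(g) {
    fit <- kmEstimate(time[grp == g], event[grp == g])
    md <- kmMedian(fit)
    data.frame(group = g, n = sum(grp == g),
               events = sum(event[grp == g]),
               median = fmtNR(md$median), lcl = fmtNR(md$lcl),
               ucl = fmtNR(md$ucl),
               rate_3y = round(naToNR(survivalRateAt(fit, 3)), 4),
               logrank_chi2 = round(lr$chi2, 4), logrank_df = lr$df,
               logrank_p = signif(lr$p, 4))
  })
  results <- do.call(rbind, rows)

  cx <- coxFit(time, event,
               data.frame(emt = patients$emt_positive,
                          pdl1 = patients$pd_l1_positive),
               ties = ties)
  cxr <- data.frame(group = paste0("cox:", cx$term), n = length(time),
                    events = sum(event), median = "", lcl = "", ucl = "",
                    rate_3y = round(cx$hr, 4), logrank_chi2 = NA_real_,
                    logrank_df = NA_integer_, logrank_p = signif(cx$p, 4))
  names(cxr) <- names(results)
  results <- rbind(results, cxr)

  fitAll <- kmEstimate(time, event, grp)
  km <- data.frame(group = rep(sub("^group=", "",
                                   rep(names(fitAll$strata),
                                       fitAll$strata))),
                   time = fitAll$time, n_risk = fitAll$n.risk,
                   n_event = fitAll$n.event,
                   survival = round(fitAll$surv, 6),
                   std_err = round(fitAll$std.err, 6))
  list(results = results, km = km)
}

fmtNR <- function(x) if (is.na(x)) "NR" else formatC(x, format = "g")
naToNR <- function(x) if (is.na(x)) NA_real_ else x

writeRunLog <- function(config) {
  cfg <- config
  cfg$outDir <- NULL  # hash must not depend on where output lands
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(cfg, file = tmp)
  hash <- unname(tools::md5sum(tmp))
  lines <- c("PDL1EMT run log",
             paste0("config_hash\t", hash),
             paste0("seed\t", config$seed),
             paste0("ecad_cutoff\t", config$ecadCutoff),
             paste0("vim_cutoff\t", config$vimCutoff),
             paste0("pdl1_percent\t", config$pdl1Percent),
             paste0("p16_percent\t", config$p16Percent),
             paste0("tau\t", config$tau),
             paste0("min_coverage\t", config$minCoverage),
             paste0("ties\t", config$ties),
             paste0("fdr\t", config$fdr))
  writeLines(lines, file.path(config$outDir, "run_log.txt"))
  invisible(NULL)
}
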
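#' Read a patient table CSV
#'
#' Comma-separated, UTF-8, header row. Mandatory columns are the three
#' staining profiles (`ecad_p0..ecad_p3`, `vim_p0..vim_p3`,
#' `pdl1_p0..pdl1_p3`) and `p16_pct`; survival analysis additionally uses
#' `os_months`/`os_event` and `pfs_months`/`pfs_event` when present.
#' Unknown columns are preserved. Staining profiles are validated row by
#' row (percentages non-negative, summing to 100 within 1e-6); offending
#' rows are reported by line number.
#'
#' @param path CSV file path.
#' @return data.frame.
#' @export
readPatientCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(d) || !ncol(d))
    stop("empty patient table: ", path, call. = FALSE)
  need <- c(paste0("ecad_p", 0:3), paste0("vim_p", 0:3),
            paste0("pdl1_p", 0:3), "p16_pct")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (marker in c("ecad", "vim", "pdl1")) {
    pc <- as.matrix(d[paste0(marker, "_p", 0:3)])
    bad <- which(abs(rowSums(pc) - 100) > 1e-6 |
                   apply(!is.finite(pc) | pc < 0, 1L, any))
    if (length(bad))
      stop("invalid ", marker, " staining profile on data row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "),
           " (percentages must be non-negative and sum to 100)",
           call. = FALSE)
  }
  message(nrow(d), " patient record(s) read from ", path)
  d
}

#' Write a patient table CSV
#'
#' @param patients data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePatientCSV <- function(patients, path) {
  df <- patients
  # booleans as 0/1 in the on-disk dialect
  for (nm in names(df)) if (is.logical(df[[nm]]))
    df[[nm]] <- as.integer(df[[nm]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene-by-sample expression TSV
#'
#' Tab-delimited with a header row; first column gene ids, remaining
#' columns samples; values log2-scale. Duplicate gene or sample ids and
#' ragged rows are rejected.
#'
#' @param path TSV file path.
#' @return Numeric matrix, genes x samples.
#' @export
readExpressionTSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 2L) stop("expression TSV has no data rows: ", path,
                               call. = FALSE)
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  ragged <- which(nf != nf[1L])
  if (length(ragged))
    stop("ragged row(s) at line(s): ",
         paste(utils::head(ragged, 10L), collapse = ", "), call. = FALSE)
  d <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  genes <- as.character(d[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  samples <- colnames(d)[-1L]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s)", call. = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  m
}

#' Write a gene-by-sample expression TSV
#'
#' @param x Genes x samples matrix with dimnames.
#' @param path Output path.
#' @param idColumn Name of the gene-id column; default `"gene"`.
#' @return `path`, invisibly.
#' @export
writeExpressionTSV <- function(x, path, idColumn = "gene") {
  stopifnot(!is.null(rownames(x)), !is.null(colnames(x)))
  d <- data.frame(rownames(x), x, check.names = FALSE,
                  stringsAsFactors = FALSE)
  colnames(d) <- c(idColumn, colnames(x))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (gene ids per set).
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT line with fewer than 3 fields", call. = FALSE)
    genes <- f[-(1:2)]
    if (anyDuplicated(genes))
      stop("duplicate gene id(s) in set '", f[1L], "'", call. = FALSE)
    genes
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1),
    USE.NAMES = FALSE)
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character gene-id vectors.
#' @param path Output path.
#' @param description Description field; recycled.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, genes, desc)
    paste(c(nm, desc, genes), collapse = "\t"),
    names(sets), sets, description)
  writeLines(lines, path)
  invisible(path)
}

#' Serialize / restore a fitted BCCP model as flat text
#'
#' Key-value text format (one `key<TAB>value` pair per line; the gene and
#' weight vectors as comma-joined fields) so a fitted classifier can be
#' re-applied reproducibly across sessions and platforms.
#'
#' @param model A [BCCPModel-class].
#' @param path Output path.
#' @return `writeBCCPModel`: `path`, invisibly. `readBCCPModel`: the
#'   restored [BCCPModel-class].
#' @export
writeBCCPModel <- function(model, path) {
  stopifnot(is(model, "BCCPModel"))
  lines <- c(
    paste0("format\tbccp-model-v1"),
    paste0("genes\t", paste(model@genesUsed, collapse = ",")),
    paste0("weights\t",
           paste(formatC(model@weights, digits = 17, format = "g"),
                 collapse = ",")),
    paste0("m_epithelial\t",
           formatC(model@classMeans[["epithelial"]], digits = 17,
                   format = "g")),
    paste0("m_mesenchymal\t",
           formatC(model@classMeans[["mesenchymal"]], digits = 17,
                   format = "g")),
    paste0("pooled_sd\t", formatC(model@pooledSD, digits = 17,
                                  format = "g")),
    paste0("prior_epithelial\t",
           formatC(model@priors[["epithelial"]], digits = 17,
                   format = "g")),
    paste0("prior_mesenchymal\t",
           formatC(model@priors[["mesenchymal"]], digits = 17,
                   format = "g")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeBCCPModel
#' @export
readBCCPModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, `[`, character(1), 2L)
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("model file missing field '", k, "'", call. = FALSE)
    vals[i]
  }
  if (!identical(get("format"), "bccp-model-v1"))
    stop("unrecognized model file format", call. = FALSE)
  genes <- strsplit(get("genes"), ",", fixed = TRUE)[[1L]]
  w <- as.numeric(strsplit(get("weights"), ",", fixed = TRUE)[[1L]])
  names(w) <- genes
  newBCCPModel(w, as.numeric(get("m_epithelial")),
               as.numeric(get("m_mesenchymal")),
               as.numeric(get("pooled_sd")),
               c(epithelial = as.numeric(get("prior_epithelial")),
                 mesenchymal = as.numeric(get("prior_mesenchymal"))))
}
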
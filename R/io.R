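# Reading expression matrices and label vectors, writing result tables.
# Delimited text only: TSV by default, CSV when the file extension says
# so.  First column = gene identifiers, header row = sample names.

#' Read a delimited expression matrix
#'
#' @param path TSV or CSV file (autodetected by extension), header row
#'   of sample names, first column gene identifiers.
#' @param na Missing-value code: a numeric sentinel or a string token;
#'   matching cells (and literal `NA`) become missing.
#' @return Numeric matrix with gene identifiers as rownames and `NA`
#'   for missing cells.
#' @export
read_matrix <- function(path, na = NA) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           fill = FALSE, quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3L)
    stop("expected a gene-identifier column plus at least 2 sample columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids))
    stop("duplicate gene identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  na_token <- if (is.na(na)) character() else as.character(na)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals) &
                 !(vals %in% c("NA", "na", na_token)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric cell at row ", bad[1L, 1L], " (gene ",
         ids[bad[1L, 1L]], "), sample column ", bad[1L, 2L],
         ": '", vals[bad[1L, , drop = FALSE]], "'")
  if (!is.na(na) && !is.na(suppressWarnings(as.numeric(na))))
    num[!is.na(num) & num == as.numeric(na)] <- NA_real_
  dimnames(num) <- list(ids, colnames(raw)[-1L])
  num
}

#' Read class labels
#'
#' @param x Either a path to a file with one integer label per line, or
#'   a string of comma-separated integers.
#' @return Integer label vector.
#' @export
read_labels <- function(x) {
  out <- if (file.exists(x)) scan(x, what = integer(), quiet = TRUE)
         else as.integer(strsplit(x, ",")[[1L]])
  if (anyNA(out)) stop("class labels must be integers")
  out
}

#' Write a maxT result table
#'
#' Tab-separated, rows in rank order, columns `gene_id`, `index` (rank,
#' 1-based), `teststat`, `rawp`, `adjp`.  Numbers are printed with 17
#' significant digits so a round trip reproduces them exactly; missing
#' p-values are written as `NA`.
#'
#' @param result A `maxt_result` from [pmaxt()] / [finalize_pvalues()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_result <- function(result, path) {
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(gene_id = result$gene_id,
                    index = result$index,
                    teststat = fmt(result$teststat),
                    rawp = fmt(result$rawp),
                    adjp = fmt(result$adjp),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
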
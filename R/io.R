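# Delimited-text I/O for abundance tables and bias tables.  Tables are
# samples x taxa, header row of taxon labels, first column of sample labels;
# missing cells are written "NA" (taxon undefined for that sample), never 0.

#' Read an abundance table
#'
#' @param path File path.
#' @param format `"tsv"` (default), `"csv"`, or `"biom"` (requires the
#'   biomformat package).
#' @param samples_as_rows Set `FALSE` if the file has taxa as rows and
#'   samples as columns; the result is transposed to samples x taxa.
#' @return Numeric matrix (samples x taxa) with `NA` for undefined cells.
#' @export
read_abundance_table <- function(path, format = c("tsv", "csv", "biom"),
                                 samples_as_rows = TRUE) {
  format <- match.arg(format)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stop("reading BIOM files requires the `biomformat` package",
           call. = FALSE)
    }
    m <- as.matrix(biomformat::biom_data(biomformat::read_biom(path)))
    return(t(m))  # biom stores taxa x samples
  }
  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2) {
    stop("file has no data rows: ", path, call. = FALSE)
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged)) {
    stop("ragged row in ", path, " at line ", ragged[1], call. = FALSE)
  }
  taxa <- fields[[1]][-1]
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels in ", path, call. = FALSE)
  }
  samples <- vapply(fields[-1], `[[`, "", 1)
  if (anyDuplicated(samples)) {
    stop("duplicate sample labels in ", path, call. = FALSE)
  }
  x <- matrix(NA_real_, length(samples), length(taxa),
              dimnames = list(samples, taxa))
  for (i in seq_along(samples)) {
    raw <- fields[[i + 1]][-1]
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals) & !(raw %in% c("NA", "")))
    if (length(bad)) {
      stop("non-numeric value '", raw[bad[1]], "' in ", path, " at line ",
           i + 1, call. = FALSE)
    }
    neg <- which(!is.na(vals) & vals < 0)
    if (length(neg)) {
      stop("negative value in ", path, " at line ", i + 1, call. = FALSE)
    }
    x[i, ] <- vals
  }
  if (!samples_as_rows) t(x) else x
}

#' Write an abundance table
#'
#' Inverse of [read_abundance_table()] for delimited formats; round-trips
#' exactly.
#'
#' @param x Samples x taxa matrix.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @export
write_abundance_table <- function(x, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  x <- as_abundance_matrix(x)
  header <- paste(c("sample", colnames(x)), collapse = sep)
  rows <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], format(x[i, ], trim = TRUE, digits = 17)),
          collapse = sep)
  }, "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read/write bias tables
#'
#' A bias table is a delimited file with columns `taxon`, `efficiency`
#' (standardized to geometric mean 1) and `gm_se` (geometric standard error;
#' `NA` when no bootstrap was run).
#'
#' @param x A `bias_fit` or a data frame with those columns.
#' @param path File path.
#' @param format `"csv"` (default) or `"tsv"`.
#' @return `read_bias_table()` returns the data frame; use it directly as the
#'   `bias` argument of [calibrate()] and friends.
#' @export
write_bias_table <- function(x, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (inherits(x, "bias_fit")) {
    x <- summary(x)$coefficients
  }
  utils::write.table(x[, c("taxon", "efficiency", "gm_se")], path,
                     sep = if (format == "csv") "," else "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_bias_table
#' @export
read_bias_table <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  df <- utils::read.table(path, sep = if (format == "csv") "," else "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("taxon", "efficiency") %in% names(df))) {
    stop("bias table needs `taxon` and `efficiency` columns", call. = FALSE)
  }
  df
}
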
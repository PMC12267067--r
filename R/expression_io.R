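#' Gene-by-sample expression matrix
#'
#' Thin validated container: a numeric matrix with gene rownames and sample
#' colnames plus a `kind` marker (`"counts"`, `"tpm"` or `"log2tpm"`).
#' Counts and TPM must be non-negative; TPM columns must sum to 1e6 within
#' 1e-6 relative tolerance.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, both
#'   with unique dimnames.
#' @param kind One of `"counts"`, `"tpm"`, `"log2tpm"`.
#' @return Object of class `expr_matrix` (the matrix with a `kind`
#'   attribute).
#' @export
expression_matrix <- function(values, kind = c("counts", "tpm", "log2tpm")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene labels")
  if (anyDuplicated(colnames(values))) stop("duplicate sample labels")
  if (kind %in% c("counts", "tpm") && any(values < 0)) {
    bad <- which(apply(values < 0, 1, any))[1]
    stop("negative values not allowed for kind ", kind,
         " (first offender: gene ", rownames(values)[bad], ")")
  }
  if (kind == "tpm") {
    cs <- colSums(values)
    if (any(abs(cs - 1e6) > 1e-6 * 1e6)) {
      stop("tpm columns must sum to 1e6 (max deviation ",
           format(max(abs(cs - 1e6))), ")")
    }
  }
  structure(values, kind = kind, class = c("expr_matrix", "matrix", "array"))
}

#' @exportS3Method base::print
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix [%s]: %d genes x %d samples\n",
              attr(x, "kind"), nrow(x), ncol(x)))
  invisible(x)
}

expr_values <- function(x) {
  v <- unclass(x)
  attr(v, "kind") <- NULL
  v
}

expr_kind <- function(x) attr(x, "kind")

#' Read and write expression matrices (TSV or MatrixMarket triplet)
#'
#' TSV layout: first column `gene`, one column per sample, header row.
#' MTX layout: `<path>.mtx` sparse triplet plus `<path>.rownames` /
#' `<path>.colnames` sidecar files, one label per line. A write-then-read
#' round trip is value-identical and preserves `kind`.
#'
#' @param path Base path; `format` `"mtx"` appends the three suffixes.
#' @param kind Expression kind of the data on disk.
#' @param format `"tsv"` or `"mtx"`.
#' @param x An [expression_matrix()] (for writing).
#' @return `read_expression()` returns an `expr_matrix`;
#'   `write_expression()` returns `path` invisibly.
#' @export
read_expression <- function(path, kind = c("counts", "tpm", "log2tpm"),
                            format = c("tsv", "mtx")) {
  kind <- match.arg(kind)
  format <- match.arg(format)
  if (format == "mtx") {
    m <- as.matrix(Matrix::readMM(paste0(path, ".mtx")))
    rownames(m) <- readLines(paste0(path, ".rownames"))
    colnames(m) <- readLines(paste0(path, ".colnames"))
    return(expression_matrix(m, kind))
  }
  nf <- count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1) {
    stop("ragged TSV: line ", which(nf != nf[1])[1], " has ",
         nf[which(nf != nf[1])[1]], " fields, expected ", nf[1])
  }
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first TSV column must be 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- df$gene
  expression_matrix(m, kind)
}

#' @rdname read_expression
#' @export
write_expression <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "expr_matrix"))
  v <- expr_values(x)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(v, sparse = TRUE), paste0(path, ".mtx"))
    writeLines(rownames(v), paste0(path, ".rownames"))
    writeLines(colnames(v), paste0(path, ".colnames"))
    return(invisible(path))
  }
  df <- data.frame(gene = rownames(v), v, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
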
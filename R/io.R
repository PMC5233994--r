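#' Read an expression table from TSV
#'
#' Expects a tab-delimited file whose first column holds gene symbols and
#' whose header row holds sample names.  Duplicate gene symbols are
#' collapsed (by `max` over duplicates by default, the convention for
#' probe-to-symbol collapsed arrays; `mean` is the alternative), with a
#' warning naming how many were collapsed.
#'
#' @param path file path.
#' @param scale declared scale of the values, `"linear"` or `"log2"`.
#' @param collapse rule for duplicate gene symbols: `"max"` or `"mean"`.
#' @return an [expression_matrix()].
#' @export
read_expression_table <- function(path, scale = c("linear", "log2"),
                                  collapse = c("max", "mean")) {
  scale <- match.arg(scale)
  collapse <- match.arg(collapse)
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("cannot read ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(tab) < 2L || nrow(tab) == 0L) {
    stop("malformed expression table (need gene column + >=1 sample): ",
         path, call. = FALSE)
  }
  genes <- as.character(tab[[1L]])
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(tab[-1L], is.numeric, logical(1)))
    stop("non-numeric expression column(s): ",
         paste(names(tab)[-1L][bad], collapse = ", "), call. = FALSE)
  }
  if (anyNA(vals)) {
    stop("missing values in ", path, " (first at data line ",
         which(rowSums(is.na(vals)) > 0)[1L], ")", call. = FALSE)
  }
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    fun <- if (collapse == "max") max else mean
    vals <- do.call(rbind, lapply(split.data.frame(vals, genes), function(m) {
      apply(m, 2L, fun)
    }))
    vals <- vals[unique(genes), , drop = FALSE]
    warning(n_dup, " duplicate gene row(s) collapsed by ", collapse)
  } else {
    rownames(vals) <- genes
  }
  expression_matrix(vals, scale)
}

#' Write an expression table to TSV
#'
#' Inverse of [read_expression_table()]: first column `gene`, then one
#' column per sample.  Round-trips numeric values at full precision.
#'
#' @param m an `expr_matrix` or matrix.
#' @param path output path; written atomically (temp file + rename).
#' @export
write_expression_table <- function(m, path) {
  vals <- if (inherits(m, "expr_matrix")) strip_em(m) else m
  df <- data.frame(gene = rownames(vals), vals, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

#' Read and write cell-type fraction tables
#'
#' Fraction tables are TSV with samples in rows (first column `sample`) and
#' cell types in columns; used both for deconvolution output and for
#' ground-truth/reference compositions (for example gated flow-cytometry
#' percentages rescaled to fractions).
#'
#' @param path file path.
#' @return a numeric matrix samples x cell types.
#' @export
read_fraction_table <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  out <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(out) <- as.character(tab[[1L]])
  storage.mode(out) <- "double"
  out
}

#' @rdname read_fraction_table
#' @param fractions matrix or data.frame, samples x cell types.
#' @export
write_fraction_table <- function(fractions, path) {
  df <- data.frame(sample = rownames(fractions),
                   as.data.frame(fractions), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

# write via temp file in the same directory, then rename, so a failed run
# never leaves a partial table behind
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tsv")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!file.rename(tmp, path)) {
    stop("failed to write ", path, call. = FALSE)
  }
  invisible(path)
}
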
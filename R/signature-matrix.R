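#' Construct a signature matrix
#'
#' The basis `A` of the deconvolution `Ax = B`: mean linear-scale expression
#' of each signature gene (rows) in each cell type (columns).  The 2-norm
#' condition number is computed once and cached as an attribute.
#'
#' @param values numeric matrix, genes x cell types, linear scale, with
#'   unique dimnames; more genes than cell types, at least two cell types,
#'   and no constant column.
#' @return the matrix with class `sig_matrix` and attribute
#'   `condition_number`.
#' @export
signature_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("signature matrix needs gene rownames and cell-type colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("duplicate gene or cell-type identifiers", call. = FALSE)
  }
  if (ncol(values) < 2L) stop("need at least two cell types", call. = FALSE)
  if (nrow(values) <= ncol(values)) {
    stop("need more signature genes than cell types", call. = FALSE)
  }
  if (anyNA(values) || any(values < 0)) {
    stop("signature values must be non-negative linear-scale means",
         call. = FALSE)
  }
  csd <- apply(values, 2L, stats::sd)
  if (any(csd == 0)) {
    stop("constant signature column(s): ",
         paste(colnames(values)[csd == 0], collapse = ", "), call. = FALSE)
  }
  structure(values, class = c("sig_matrix", class(values)),
            condition_number = condition_number(values))
}

#' @rdname signature_matrix
#' @param x a `sig_matrix`.
#' @export
cell_types <- function(x) colnames(x)

#' @export
print.sig_matrix <- function(x, ...) {
  cat(sprintf("<sig_matrix> %d genes x %d cell types, condition number %.4g\n",
              nrow(x), ncol(x), attr(x, "condition_number")))
  invisible(x)
}
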
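#' 2-norm condition number of a matrix
#'
#' Ratio of the largest to the smallest singular value.  Signature matrices
#' with a lower condition number define a deconvolution basis that is less
#' sensitive to perturbation of the input mixture; the signature-building
#' pipeline minimises this quantity over the marker count n.
#'
#' @param values a non-empty numeric matrix.
#' @return a real >= 1; `Inf` when the smallest singular value is zero
#'   within machine tolerance (rank-deficient basis).
#' @export
condition_number <- function(values) {
  if (inherits(values, "sig_matrix")) values <- unclass(values)
  if (inherits(values, "expr_matrix")) values <- strip_em(values)
  if (!is.matrix(values) || !is.numeric(values) || length(values) == 0L) {
    stop("`values` must be a non-empty numeric matrix", call. = FALSE)
  }
  d <- svd(values, nu = 0L, nv = 0L)$d
  tol <- max(dim(values)) * .Machine$double.eps * d[1L]
  if (d[1L] == 0) stop("matrix has no nonzero singular value", call. = FALSE)
  smin <- d[length(d)]
  if (smin <= tol) return(Inf)
  d[1L] / smin
}
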
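#' Quantile-normalize the columns of an expression matrix
#'
#' Forces every sample column to share the same empirical distribution — the
#' across-sample mean of the order statistics — while preserving the rank
#' order within each column.  Tied values within a column receive the mean of
#' the target quantiles they jointly occupy, so the transform is
#' deterministic and idempotent.
#'
#' @param m an `expr_matrix` or bare numeric matrix (genes x samples), no
#'   missing values.
#' @return a matrix of the same dimensions and class; with a single sample
#'   the input is returned unchanged with a warning (there is nothing to
#'   normalize against).
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' quantile_normalize(m)  # both columns become (1.5, 3.5)
#' @export
quantile_normalize <- function(m) {
  vals <- if (inherits(m, "expr_matrix")) strip_em(m) else m
  if (!is.matrix(vals) || !is.numeric(vals)) {
    stop("`m` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(vals)) stop("missing values in input", call. = FALSE)
  if (ncol(vals) < 2L) {
    warning("single-sample input: quantile normalization skipped")
    return(m)
  }
  target <- rowMeans(apply(vals, 2L, sort))
  out <- apply(vals, 2L, qn_map_column, target = target)
  dimnames(out) <- dimnames(vals)
  if (inherits(m, "expr_matrix")) {
    out <- expression_matrix(out, expr_scale(m))
  }
  out
}

# map one column onto `target` (sorted reference distribution of equal
# length); ties receive the mean of the target values they occupy
qn_map_column <- function(x, target) {
  assigned <- numeric(length(x))
  assigned[order(x)] <- target
  stats::ave(assigned, x, FUN = mean)
}
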
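#' Construct an expression matrix
#'
#' An `expr_matrix` is a plain numeric matrix (genes in rows, samples in
#' columns) carrying an explicit `scale` attribute, either `"linear"` or
#' `"log2"`.  All deconvolution arithmetic happens on the linear scale,
#' because the mixture model `B = A x` is linear in transcript abundance;
#' log2 inputs are anti-logged with [as_linear()] before use.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene
#'   symbols) and colnames (sample names); no missing values.
#' @param scale `"linear"` or `"log2"`.  Linear-scale values must be
#'   non-negative.
#' @return the validated matrix with class `expr_matrix` and a `scale`
#'   attribute.
#' @examples
#' m <- expression_matrix(
#'   matrix(1:6, 3, 2, dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))),
#'   scale = "linear"
#' )
#' expr_scale(m)
#' @export
expression_matrix <- function(values, scale = c("linear", "log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene identifiers; collapse them first ",
         "(see read_expression_table)", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample names", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("expression matrix contains missing values", call. = FALSE)
  }
  if (scale == "linear" && any(values < 0)) {
    stop("negative values are not allowed on the linear scale; ",
         "did you mean scale = \"log2\"?", call. = FALSE)
  }
  structure(values, class = c("expr_matrix", class(values)), scale = scale)
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "linear" else sc
}

#' Convert an expression matrix between scales
#'
#' @param x an `expr_matrix` (or bare matrix, assumed linear).
#' @return an `expr_matrix` on the requested scale.  `as_log2()` uses
#'   `log2(x + 1)`; `as_linear()` inverts it with `2^x - 1`.
#' @export
as_linear <- function(x) {
  if (expr_scale(x) == "linear") {
    return(expression_matrix(strip_em(x), "linear"))
  }
  expression_matrix(pmax(2^strip_em(x) - 1, 0), "linear")
}

#' @rdname as_linear
#' @export
as_log2 <- function(x) {
  if (expr_scale(x) == "log2") {
    return(expression_matrix(strip_em(x), "log2"))
  }
  expression_matrix(log2(strip_em(x) + 1), "log2")
}

# drop the expr_matrix class/attrs, returning the bare matrix
strip_em <- function(x) {
  y <- unclass(x)
  attr(y, "scale") <- NULL
  y
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d samples, %s scale\n",
              nrow(x), ncol(x), expr_scale(x)))
  print(utils::head(strip_em(x), 5L))
  if (nrow(x) > 5L) cat("...\n")
  invisible(x)
}
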
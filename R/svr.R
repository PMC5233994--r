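#' Fit a linear-kernel nu-SVR of a mixture on the signature basis
#'
#' Regresses one standardized mixture column on the standardized signature
#' columns with nu-support-vector regression (linear kernel).  The primal
#' weight vector, recovered from the dual coefficients, serves as the raw
#' (standardized-space) mixing weight per cell type; the support genes are
#' the rows with nonzero dual coefficients — the subset of signature genes
#' the fit actually uses.
#'
#' @param sig_std standardized signature (genes x cell types).
#' @param mix_std standardized mixture column (length = number of genes).
#' @param nu the nu parameter, in (0, 1]: an upper bound on the fraction of
#'   margin errors and lower bound on the fraction of support genes.
#' @param cost the SVR regularization constant C (default 1).
#' @return list with `weights` (named, one per cell type), `support`
#'   (indices of support genes), and `nu`.
#' @export
fit_nu_svr <- function(sig_std, mix_std, nu, cost = 1) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1) {
    stop("nu must be a single value in (0, 1]", call. = FALSE)
  }
  y <- as.numeric(mix_std)
  if (length(y) != nrow(sig_std)) {
    stop("mixture length does not match signature gene count", call. = FALSE)
  }
  fit <- tryCatch(
    e1071::svm(sig_std, y, type = "nu-regression", kernel = "linear",
               nu = nu, cost = cost, scale = FALSE),
    error = function(e) {
      stop(sprintf("nu-SVR failed at nu = %g: %s", nu, conditionMessage(e)),
           call. = FALSE)
    })
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  names(w) <- colnames(sig_std)
  list(weights = w, support = fit$index, nu = nu)
}

#' Root-mean-square reconstruction error
#'
#' RMSE between the reconstructed mixture `sig_std %*% weights` and the
#' observed standardized mixture, over the shared genes.  Used to pick the
#' winning nu.
#'
#' @param sig_std standardized signature.
#' @param weights raw weights, one per cell type.
#' @param mix_std standardized mixture column.
#' @return a non-negative scalar.
#' @export
reconstruction_rmse <- function(sig_std, weights, mix_std) {
  if (length(weights) != ncol(sig_std)) {
    stop("one weight per cell type required", call. = FALSE)
  }
  r <- as.numeric(sig_std %*% weights) - as.numeric(mix_std)
  sqrt(mean(r^2))
}

#' Convert raw regression weights to relative fractions
#'
#' Negative weights are clipped to zero and the remainder renormalized to
#' sum to one.  When every weight is non-positive the result is the
#' all-zero vector, flagged rather than renormalized.
#'
#' @param weights named numeric, one raw weight per cell type.
#' @return a [fraction_vector()].
#' @export
weights_to_fractions <- function(weights) {
  w <- pmax(as.numeric(weights), 0)
  if (sum(w) <= 0) {
    return(fraction_vector(w * 0, names(weights), all_zero = TRUE))
  }
  fraction_vector(w / sum(w), names(weights))
}
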
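#' Deconvolution settings
#'
#' @param nu_grid values of nu to try; the fit with the lowest
#'   reconstruction RMSE wins, ties toward smaller nu.  Default
#'   `c(0.25, 0.5, 0.75)`, the established grid of the linear-SVR
#'   deconvolution family.
#' @param quantile_normalize quantile-normalize the mixture columns among
#'   themselves before deconvolution (default `TRUE`).  Applies only when
#'   the mixture has at least two samples; intended to remove technical
#'   distribution differences between real samples.  For in-silico mixtures
#'   that are exact linear combinations it should be left off (it would
#'   distort the linear structure).
#' @param cost SVR regularization constant (default 1).
#' @return a `deconv_control` list.
#' @export
deconv_control <- function(nu_grid = c(0.25, 0.5, 0.75),
                           quantile_normalize = TRUE, cost = 1) {
  if (length(nu_grid) == 0L || any(nu_grid <= 0) || any(nu_grid > 1)) {
    stop("nu_grid must be a nonempty set of values in (0, 1]", call. = FALSE)
  }
  structure(list(nu_grid = sort(unique(nu_grid)),
                 quantile_normalize = isTRUE(quantile_normalize),
                 cost = cost),
            class = "deconv_control")
}

#' Deconvolve a single mixture column
#'
#' Standardizes signature and mixture over their shared genes, fits one
#' linear-kernel nu-SVR per value in the nu grid, keeps the fit with the
#' lowest reconstruction RMSE (ties toward smaller nu), maps the winning
#' weights back to the linear scale (dividing by the per-column signature
#' sd) and converts them to fractions by clipping negatives and
#' renormalizing.
#'
#' @param sig a [signature_matrix()].
#' @param mix_col named numeric vector of linear-scale expression (or a
#'   one-column matrix); aligned to the signature by gene id, so row order
#'   is irrelevant.
#' @param control a [deconv_control()].
#' @return list with `fractions` (a [fraction_vector()]), `nu`, `rmse`,
#'   `correlation` (Pearson r of reconstruction vs mixture, standardized
#'   space) and `support_genes`.
#' @export
deconvolve_sample <- function(sig, mix_col, control = deconv_control()) {
  if (is.matrix(mix_col)) {
    stopifnot(ncol(mix_col) == 1L)
    mix_col <- stats::setNames(as.numeric(mix_col), rownames(mix_col))
  }
  std <- standardize_for_regression(sig, mix_col)
  y <- as.numeric(std$mix_std)
  best <- NULL
  failures <- character(0)
  for (nu in control$nu_grid) {
    fit <- tryCatch(fit_nu_svr(std$sig_std, y, nu, control$cost),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      failures <- c(failures, fit)
      next
    }
    rmse <- reconstruction_rmse(std$sig_std, fit$weights, y)
    if (is.null(best) || rmse < best$rmse - 1e-12) {
      best <- list(fit = fit, rmse = rmse)
    }
  }
  if (is.null(best)) {
    stop("all nu values failed: ", paste(failures, collapse = "; "),
         call. = FALSE)
  }
  w_linear <- best$fit$weights / std$sig_sd
  recon <- as.numeric(std$sig_std %*% best$fit$weights)
  list(fractions = weights_to_fractions(w_linear),
       nu = best$fit$nu,
       rmse = best$rmse,
       correlation = stats::cor(recon, y),
       support_genes = length(best$fit$support))
}

#' Deconvolve every sample of a mixture matrix
#'
#' Optionally quantile-normalizes the mixture columns among themselves
#' (see [deconv_control()]), then applies [deconvolve_sample()] to each
#' column.  Per-sample failures do not abort the run; failed samples get
#' NA rows and are listed in the `errors` attribute.
#'
#' @param sig a [signature_matrix()].
#' @param mixtures an `expr_matrix` (any scale; converted to linear) or
#'   bare matrix of mixture columns.
#' @param control a [deconv_control()].
#' @return a `deconv_result`: data.frame with one row per sample — the
#'   cell-type fractions, then `nu`, `rmse`, `correlation`,
#'   `support_genes`.
#' @export
deconvolve <- function(sig, mixtures, control = deconv_control()) {
  types <- cell_types(sig)
  if (ncol(mixtures) == 0L) {
    out <- as.data.frame(matrix(numeric(0), 0L, length(types) + 4L))
    names(out) <- c(types, "nu", "rmse", "correlation", "support_genes")
    return(structure(out, class = c("deconv_result", "data.frame"),
                     errors = character(0)))
  }
  if (!inherits(mixtures, "expr_matrix")) {
    mixtures <- expression_matrix(mixtures, "linear")
  }
  vals <- strip_em(as_linear(mixtures))
  if (control$quantile_normalize && ncol(vals) >= 2L) {
    vals <- quantile_normalize(vals)
  }
  empty <- rep(NA_real_, length(types) + 4L)
  rows <- vector("list", ncol(vals))
  errors <- character(0)
  for (j in seq_len(ncol(vals))) {
    res <- tryCatch(
      deconvolve_sample(sig, vals[, j], control),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errors[colnames(vals)[j]] <- res
      rows[[j]] <- empty
    } else {
      rows[[j]] <- c(as.numeric(res$fractions), res$nu, res$rmse,
                     res$correlation, res$support_genes)
    }
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c(types, "nu", "rmse", "correlation", "support_genes")
  rownames(out) <- colnames(vals)
  if (length(errors) > 0L) {
    warning(length(errors), " sample(s) failed: ",
            paste(names(errors), collapse = ", "))
  }
  structure(out, class = c("deconv_result", "data.frame"), errors = errors)
}
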
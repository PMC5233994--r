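#' Standardize signature and mixture over their shared gene set
#'
#' Restricts both matrices to the intersection of their gene sets (in the
#' signature's gene order) and scales every column to zero mean and unit
#' variance over those genes.  The per-column standard deviations of the
#' signature are returned so that regression weights fitted in standardized
#' space can be mapped back to the linear mixture scale
#' (`w_linear = w_std / sd_column`).
#'
#' @param sig a [signature_matrix()] (linear scale).
#' @param mix an `expr_matrix` or matrix of mixture columns (linear scale).
#' @return list with `sig_std`, `mix_std` (both over the shared genes),
#'   `genes`, and `sig_sd` (named per-column sd of the signature columns on
#'   the shared gene set).
#' @export
standardize_for_regression <- function(sig, mix) {
  if (is.null(dim(mix))) {
    mix <- matrix(mix, ncol = 1L,
                  dimnames = list(names(mix), "sample"))
  }
  sig_v <- if (inherits(sig, "sig_matrix")) unclass(sig) else sig
  mix_v <- if (inherits(mix, "expr_matrix")) strip_em(mix) else mix
  genes <- intersect(rownames(sig_v), rownames(mix_v))
  if (length(genes) < ncol(sig_v)) {
    stop(sprintf(
      "only %d genes shared between signature and mixture (need >= %d; %d signature genes missing)",
      length(genes), ncol(sig_v), nrow(sig_v) - length(genes)),
      call. = FALSE)
  }
  s <- sig_v[genes, , drop = FALSE]
  m <- mix_v[genes, , drop = FALSE]
  sig_sd <- apply(s, 2L, stats::sd)
  mix_sd <- apply(m, 2L, stats::sd)
  if (any(mix_sd == 0)) {
    stop("constant mixture column(s): ",
         paste(colnames(m)[mix_sd == 0], collapse = ", "), call. = FALSE)
  }
  list(sig_std = scale(s), mix_std = scale(m), genes = genes,
       sig_sd = sig_sd)
}
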
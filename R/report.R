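#' Compare predicted with reference cell-type fractions
#'
#' Computes, per shared cell type and overall, the Pearson and Spearman
#' correlations, RMSE, and bias (mean predicted minus reference) between
#' two fraction tables over their shared samples.  When the reference
#' covers only major cell types (e.g. gated flow-cytometry percentages),
#' pass a hierarchy and the predicted fine-grained fractions are aggregated
#' first.  A constant reference vector has no defined correlation; those
#' entries are reported as `NA` while RMSE and bias are still computed.
#'
#' @param predicted matrix/data.frame, samples x cell types (fractions).
#' @param reference matrix/data.frame, samples x cell types.
#' @param hierarchy optional [cell_type_hierarchy()] used to aggregate
#'   `predicted` before matching.
#' @return a `recovery_report` data.frame: one row per shared cell type
#'   plus an `overall` row pooling all shared (sample, type) cells, with
#'   columns `cell_type`, `n`, `pearson`, `spearman`, `rmse`, `bias`.
#' @export
recovery_report <- function(predicted, reference, hierarchy = NULL) {
  predicted <- as.matrix(as.data.frame(predicted))
  reference <- as.matrix(as.data.frame(reference))
  if (!is.null(hierarchy)) {
    fine <- colnames(predicted)
    agg <- t(apply(predicted, 1L, function(row) {
      out <- aggregate_fractions(fraction_vector_lenient(row, fine),
                                 hierarchy)
      stats::setNames(as.numeric(out), names(out))
    }))
    predicted <- agg
  }
  samples <- intersect(rownames(predicted), rownames(reference))
  types <- intersect(colnames(predicted), colnames(reference))
  if (length(samples) < 2L || length(types) < 1L) {
    stop("need >= 2 shared samples and >= 1 shared cell type", call. = FALSE)
  }
  p <- predicted[samples, types, drop = FALSE]
  r <- reference[samples, types, drop = FALSE]
  one <- function(x, y) {
    data.frame(
      n = length(x),
      pearson = safe_cor(x, y, "pearson"),
      spearman = safe_cor(x, y, "spearman"),
      rmse = sqrt(mean((x - y)^2)),
      bias = mean(x - y))
  }
  rows <- lapply(types, function(ct) cbind(cell_type = ct,
                                           one(p[, ct], r[, ct])))
  rows <- c(rows, list(cbind(cell_type = "overall",
                             one(as.numeric(p), as.numeric(r)))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("recovery_report", "data.frame"))
}

safe_cor <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

# tolerate rounding: renormalize a near-simplex row before aggregation
fraction_vector_lenient <- function(row, types) {
  row <- pmax(as.numeric(row), 0)
  if (sum(row) > 0) row <- row / sum(row)
  fraction_vector(row, types, all_zero = sum(row) == 0)
}

#' Run the three simulation benchmarks end to end
#'
#' Reproduces the in-silico evaluation designs on a given signature:
#' (1) pure profiles — one noisy single-type profile per cell type;
#' (2) spike-in series — for each requested type, an 11-point sweep of the
#' spiked fraction against a fixed random background;
#' (3) tumor dilution — a random immune mixture diluted with a synthetic
#' tumor profile up to 99% tumor content.
#' Every simulated column is deconvolved individually (no cross-sample
#' quantile normalization — the mixtures are exact linear blends).
#'
#' @param sig a [signature_matrix()].
#' @param hierarchy optional [cell_type_hierarchy()]; adds major-type
#'   aggregated recovery to the tumor report.
#' @param control a [deconv_control()].
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @param noise_sd log-normal noise for the pure profiles (default 0.1).
#' @param spike_types cell types for the spike-in design (default: all).
#' @param spike_step spike increment in percent (default 10).
#' @return list of three elements: `pure` (per-type predicted self-fraction
#'   plus a [recovery_report()]), `spike` (per-type series table with true
#'   and predicted spiked fraction and its Spearman rho), `tumor` (series
#'   table with per-point correlation of renormalized immune fractions vs
#'   truth, fine-grained and major-aggregated).
#' @export
run_benchmark_suite <- function(sig, hierarchy = NULL,
                                control = deconv_control(),
                                seed = 1L, noise_sd = 0.1,
                                spike_types = cell_types(sig),
                                spike_step = 10) {
  types <- cell_types(sig)

  # --- pure profiles ------------------------------------------------------
  pure_pred <- matrix(NA_real_, length(types), length(types),
                      dimnames = list(types, types))
  for (i in seq_along(types)) {
    pp <- sample_pure_profile(sig, types[i], noise_sd, seed + i)
    pure_pred[i, ] <- as.numeric(
      deconvolve_sample(sig, pp$profile, control)$fractions)
  }
  pure_truth <- diag(length(types))
  dimnames(pure_truth) <- dimnames(pure_pred)
  pure <- list(
    self_fraction = stats::setNames(diag(pure_pred), types),
    predicted = pure_pred,
    report = recovery_report(pure_pred, pure_truth))

  # --- spike-in series ----------------------------------------------------
  spike <- lapply(seq_along(spike_types), function(i) {
    ct <- spike_types[i]
    ser <- spike_in_series(sig, ct, spike_step, seed + 1000L + i)
    pred <- vapply(seq_len(ncol(ser$mixtures)), function(j) {
      as.numeric(deconvolve_sample(sig, ser$mixtures[, j],
                                   control)$fractions)[types == ct]
    }, numeric(1))
    data.frame(cell_type = ct, true = ser$spiked_fraction,
               predicted = pred,
               spearman = stats::cor(ser$spiked_fraction, pred,
                                     method = "spearman"))
  })
  spike <- do.call(rbind, spike)

  # --- tumor dilution -----------------------------------------------------
  imm <- random_background_mixture(sig, types[1L], seed + 2000L)
  # put the held-out type back in so all types are represented
  imm <- list(profile = imm$profile, truth = imm$truth)
  tumor_prof <- synthetic_tumor_profile(sig, seed = seed + 3000L)
  ser <- tumor_dilution_series(imm, tumor_prof)
  truth_comp <- as.numeric(imm$truth$composition)
  tumor <- lapply(seq_along(ser$tumor_fraction), function(j) {
    fr <- as.numeric(deconvolve_sample(sig, ser$mixtures[, j],
                                       control)$fractions)
    row <- data.frame(tumor_fraction = ser$tumor_fraction[j],
                      pearson_fine = safe_cor(fr, truth_comp, "pearson"))
    if (!is.null(hierarchy)) {
      agg_p <- aggregate_fractions(fraction_vector_lenient(fr, types),
                                   hierarchy)
      agg_t <- aggregate_fractions(fraction_vector_lenient(truth_comp,
                                                           types),
                                   hierarchy)
      row$pearson_major <- safe_cor(as.numeric(agg_p), as.numeric(agg_t),
                                    "pearson")
    }
    row
  })
  tumor <- do.call(rbind, tumor)

  list(pure = pure, spike = spike, tumor = tumor, seed = seed)
}
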
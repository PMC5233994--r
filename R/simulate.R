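#' Specification of a synthetic reference panel
#'
#' Describes a block-structured signature of `n_cell_types` columns with
#' `markers_per_type` dedicated marker genes each.  Markers are expressed at
#' `baseline * fold_change`, everything else at `baseline`; a fraction
#' `shared_fraction` of each type's markers is additionally elevated in the
#' neighbouring (sibling) type, emulating markers shared between closely
#' related cell types.  Reference replicates multiply the signature column
#' by per-gene multiplicative log-normal noise.
#'
#' The defaults describe a 25-type panel of ~500 signature genes with
#' definitive lineage markers (two orders of magnitude above background) —
#' the marker density of real microarray-derived immune signatures.
#'
#' @param n_cell_types number of cell types (default 25; with 25 the
#'   default named panel and hierarchy are used).
#' @param markers_per_type dedicated markers per type (default 20).
#' @param shared_fraction fraction of markers shared with the sibling type,
#'   in [0, 1) (default 0.1).
#' @param baseline median background linear expression level (default 50,
#'   about 2^5.6 — typical array background).  Each gene gets its own
#'   constitutive background level, `baseline` times a log-normal factor
#'   with sd `baseline_jitter`, shared across cell types: real profiles
#'   never have a flat background.
#' @param baseline_jitter sd (natural-log scale) of the per-gene
#'   background variability (default 0.2).
#' @param fold_change marker elevation over the gene's own background
#'   (default 100).
#' @param noise_sd sd of the per-gene log-normal noise, natural-log scale
#'   (default 0.1).
#' @param ref_replicates reference samples per cell type (default 3).
#' @return a `panel_spec` list.
#' @export
synthetic_panel_spec <- function(n_cell_types = 25L, markers_per_type = 20L,
                                 shared_fraction = 0.1, baseline = 50,
                                 baseline_jitter = 0.2,
                                 fold_change = 100, noise_sd = 0.1,
                                 ref_replicates = 3L) {
  stopifnot(n_cell_types >= 2L, markers_per_type >= 1L,
            shared_fraction >= 0, shared_fraction < 1,
            baseline > 0, baseline_jitter >= 0, fold_change > 1,
            noise_sd >= 0, ref_replicates >= 2L)
  structure(list(n_cell_types = as.integer(n_cell_types),
                 markers_per_type = as.integer(markers_per_type),
                 shared_fraction = shared_fraction, baseline = baseline,
                 baseline_jitter = baseline_jitter,
                 fold_change = fold_change, noise_sd = noise_sd,
                 ref_replicates = as.integer(ref_replicates)),
            class = "panel_spec")
}

#' Generate a synthetic signature, reference panel, and hierarchy
#'
#' @param spec a [synthetic_panel_spec()].
#' @param seed integer seed; the output is deterministic given the seed.
#' @return list with `signature` (a [signature_matrix()]), `reference`
#'   (linear-scale `expr_matrix` of noisy replicates), `labels` (cell type
#'   per reference sample), `hierarchy` (a [cell_type_hierarchy()]), and
#'   `spec`.
#' @export
generate_synthetic_panel <- function(spec = synthetic_panel_spec(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- spec$n_cell_types
  m <- spec$markers_per_type
  types <- if (K == 25L) default_cell_types() else sprintf("CT%02d", 1:K)
  hierarchy <- if (K == 25L) default_hierarchy() else {
    cell_type_hierarchy(stats::setNames(types, types))
  }
  G <- K * m
  genes <- sprintf("G%04d", seq_len(G))
  bg <- spec$baseline * exp(stats::rnorm(G, 0, spec$baseline_jitter))
  A <- matrix(bg, G, K, dimnames = list(genes, types))
  n_shared <- round(spec$shared_fraction * m)
  for (i in seq_len(K)) {
    idx <- ((i - 1L) * m + 1L):(i * m)
    A[idx, i] <- bg[idx] * spec$fold_change
    if (n_shared > 0L) {
      sibling <- if (i < K) i + 1L else 1L
      sh <- idx[seq_len(n_shared)]
      A[sh, sibling] <- bg[sh] * spec$fold_change
    }
  }
  sig <- signature_matrix(A)

  n_ref <- spec$ref_replicates
  labels <- rep(types, each = n_ref)
  ref <- matrix(0, G, K * n_ref,
                dimnames = list(genes, paste(rep(types, each = n_ref),
                                             seq_len(n_ref), sep = "_")))
  for (j in seq_along(labels)) {
    ref[, j] <- A[, labels[j]] * exp(stats::rnorm(G, 0, spec$noise_sd))
  }
  list(signature = sig,
       reference = expression_matrix(ref, "linear"),
       labels = labels, hierarchy = hierarchy, spec = spec)
}

# ground-truth record attached to every simulated mixture
mixture_truth <- function(composition, tumor_fraction = 0, seed = NULL,
                          noise_sd = 0) {
  list(composition = composition, tumor_fraction = tumor_fraction,
       seed = seed, noise_sd = noise_sd)
}

#' Simulate a pure single-cell-type expression profile
#'
#' The signature column of the requested type, perturbed by per-gene
#' multiplicative log-normal noise.  Ground truth is the indicator
#' composition (fraction 1 for the target type).
#'
#' @param sig a [signature_matrix()].
#' @param cell_type one of `cell_types(sig)`.
#' @param noise_sd sd of the log-normal noise (natural-log scale);
#'   0 returns the column verbatim.
#' @param seed integer seed.
#' @return list with `profile` (named numeric over the signature genes)
#'   and `truth`.
#' @export
sample_pure_profile <- function(sig, cell_type, noise_sd = 0.1,
                                seed = NULL) {
  if (!cell_type %in% cell_types(sig)) {
    stop("unknown cell type: ", cell_type, call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  x <- unclass(sig)[, cell_type]
  if (noise_sd > 0) x <- x * exp(stats::rnorm(length(x), 0, noise_sd))
  comp <- fraction_vector(as.numeric(cell_types(sig) == cell_type),
                          cell_types(sig))
  list(profile = x, truth = mixture_truth(comp, seed = seed,
                                          noise_sd = noise_sd))
}

#' Simulate a random background mixture excluding one cell type
#'
#' Composition drawn uniformly on the simplex (symmetric Dirichlet with
#' concentration 1) over all cell types except `excluded_type`; the profile
#' is the corresponding convex combination of signature columns in linear
#' space.
#'
#' @param sig a [signature_matrix()].
#' @param excluded_type the cell type held out of the background.
#' @param seed integer seed.
#' @return list with `profile` and `truth` (excluded type's fraction is 0).
#' @export
random_background_mixture <- function(sig, excluded_type, seed = NULL) {
  types <- cell_types(sig)
  if (!excluded_type %in% types) {
    stop("unknown cell type: ", excluded_type, call. = FALSE)
  }
  if (length(types) < 2L) stop("need at least two cell types", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  others <- setdiff(types, excluded_type)
  # Dirichlet(1, ..., 1) via normalized standard exponentials
  w <- stats::rexp(length(others))
  comp <- stats::setNames(numeric(length(types)), types)
  comp[others] <- w / sum(w)
  profile <- as.numeric(unclass(sig) %*% comp)
  names(profile) <- rownames(sig)
  list(profile = profile,
       truth = mixture_truth(fraction_vector(comp, types), seed = seed))
}

#' Spike one cell type into a fixed random background in even increments
#'
#' Builds one random background mixture of all other cell types, then the
#' blend series `p * pure_target + (1 - p) * background` for p = 0%,
#' `step`%, ..., 100%.
#'
#' @param sig a [signature_matrix()].
#' @param target_type the spiked cell type.
#' @param step increment in percent; must divide 100 (default 10, giving
#'   the 11-point series).
#' @param seed integer seed (fixes the background).
#' @return list with `mixtures` (genes x series matrix, columns named by
#'   spiked percent), `truths` (one truth per point) and
#'   `spiked_fraction` (the true series).
#' @export
spike_in_series <- function(sig, target_type, step = 10, seed = NULL) {
  if (step <= 0 || step > 100 || (100 %% step) != 0) {
    stop("step must be a positive divisor of 100", call. = FALSE)
  }
  bg <- random_background_mixture(sig, target_type, seed)
  pure <- unclass(sig)[, target_type]
  pcts <- seq(0L, 100L, by = step)
  ps <- pcts / 100
  types <- cell_types(sig)
  target_ind <- as.numeric(types == target_type)
  mixtures <- vapply(ps, function(p) p * pure + (1 - p) * bg$profile,
                     numeric(nrow(sig)))
  dimnames(mixtures) <- list(rownames(sig), sprintf("spike_%03d", pcts))
  truths <- lapply(ps, function(p) {
    comp <- p * target_ind + (1 - p) * as.numeric(bg$truth$composition)
    mixture_truth(fraction_vector(comp, types), seed = seed)
  })
  list(mixtures = mixtures, truths = truths, spiked_fraction = ps,
       target_type = target_type)
}

#' Synthetic tumor expression profile over the signature genes
#'
#' Signature genes survive the tumor-expression filter by construction, so
#' a tumor expresses them near array background: the profile is the
#' background level (median signature entry by default) with broad per-gene
#' log-normal spread.
#'
#' @param sig a [signature_matrix()].
#' @param level central linear expression level (default
#'   `median(sig)`).
#' @param spread sd of the log-normal spread, natural-log scale
#'   (default 0.5).
#' @param seed integer seed.
#' @return named numeric profile over the signature genes.
#' @export
synthetic_tumor_profile <- function(sig, level = NULL, spread = 0.5,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(level)) level <- stats::median(unclass(sig))
  stats::setNames(level * exp(stats::rnorm(nrow(sig), 0, spread)),
                  rownames(sig))
}

#' Dilute an immune mixture with increasing tumor content
#'
#' Blends `(1 - t) * immune + t * tumor` for tumor fractions t = 0%, 10%,
#' ..., 90%, then 91%, ..., 99% — a 19-point series whose tail probes the
#' regime where tumor content dominates.  The relative immune composition
#' is identical at every point; the truth records it together with the
#' tumor fraction.
#'
#' @param immune_mixture list with `profile` and `truth`, e.g. from
#'   [random_background_mixture()].
#' @param tumor_profile named numeric tumor profile; gene sets are
#'   intersected (extra tumor genes are ignored).
#' @param tumor_fractions the series, as fractions in [0, 1).
#' @return list with `mixtures` (genes x 19), `truths`, and
#'   `tumor_fraction` (the series).
#' @export
tumor_dilution_series <- function(immune_mixture, tumor_profile,
                                  tumor_fractions = c(seq(0, 0.90, 0.10),
                                                      seq(0.91, 0.99, 0.01))) {
  imm <- immune_mixture$profile
  genes <- intersect(names(imm), names(tumor_profile))
  if (length(genes) == 0L) {
    stop("immune mixture and tumor profile share no genes", call. = FALSE)
  }
  imm <- imm[genes]
  tum <- tumor_profile[genes]
  mixtures <- vapply(tumor_fractions, function(t) (1 - t) * imm + t * tum,
                     numeric(length(genes)))
  dimnames(mixtures) <- list(genes,
                             sprintf("tumor_%02.0f", tumor_fractions * 100))
  comp <- immune_mixture$truth$composition
  truths <- lapply(tumor_fractions, function(t) {
    mixture_truth(comp, tumor_fraction = t)
  })
  list(mixtures = mixtures, truths = truths,
       tumor_fraction = tumor_fractions)
}
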
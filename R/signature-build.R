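#' Remove genes highly expressed in tumor tissue
#'
#' Genes whose mean log2 expression across the tumor panel exceeds the
#' threshold are treated as tumor-expressed and removed from the candidate
#' signature set, so that tumor content in a mixture cannot masquerade as
#' immune signal.  Candidates absent from the tumor panel cannot be assessed
#' and are kept (with a message).
#'
#' @param candidates character vector of candidate signature genes.
#' @param tumor_panel an `expr_matrix` of non-hematopoietic tumor profiles
#'   (any scale; converted to log2).
#' @param log2_threshold exclusion cutoff on mean log2 expression
#'   (default 7).
#' @return retained genes, with the removed set in attribute
#'   `excluded_tumor_expressed`.
#' @export
filter_tumor_expressed <- function(candidates, tumor_panel,
                                   log2_threshold = 7) {
  vals <- strip_em(as_log2(tumor_panel))
  present <- candidates %in% rownames(vals)
  if (any(!present)) {
    message(sum(!present),
            " candidate gene(s) absent from tumor panel: kept unassessed")
  }
  mean_log2 <- rowMeans(vals[candidates[present], , drop = FALSE])
  removed <- candidates[present][mean_log2 > log2_threshold]
  structure(setdiff(candidates, removed),
            excluded_tumor_expressed = removed)
}

#' Assemble a signature matrix from ranked markers
#'
#' Takes the union of each cell type's top-`n` markers (shared genes enter
#' once) and fills the matrix with the mean linear-scale expression of each
#' gene over the reference samples of each type.  Types with fewer than `n`
#' markers contribute all they have.
#'
#' @param markers a `ranked_markers` table from [rank_marker_genes()],
#'   optionally already restricted by the hematopoietic and tumor filters.
#' @param n how many top markers per cell type.
#' @param ref the reference `expr_matrix` the markers were derived from.
#' @param labels cell-type label per reference sample.
#' @return a [signature_matrix()].
#' @export
assemble_signature <- function(markers, n, ref, labels) {
  stopifnot(n >= 1)
  labels <- as.character(labels)
  short <- names(markers)[vapply(markers, nrow, integer(1)) < n]
  if (length(short) > 0L) {
    message("cell type(s) with fewer than ", n, " markers (all used): ",
            paste(short, collapse = ", "))
  }
  genes <- unique(unlist(lapply(markers, function(tab) {
    utils::head(tab$gene, n)
  }), use.names = FALSE))
  if (length(genes) == 0L) stop("no marker genes to assemble", call. = FALSE)
  vals <- strip_em(as_linear(ref))[genes, , drop = FALSE]
  types <- names(markers)
  sig <- vapply(types, function(ct) {
    rowMeans(vals[, labels == ct, drop = FALSE])
  }, numeric(length(genes)))
  rownames(sig) <- genes
  signature_matrix(sig)
}

#' Choose the marker count n minimising the condition number
#'
#' Assembles one candidate signature per `n` in `n_range` and keeps the one
#' whose basis has the smallest 2-norm condition number; ties break toward
#' smaller n (fewer genes).  Values of n whose assembly fails are skipped
#' with a warning.
#'
#' @inheritParams assemble_signature
#' @param n_range integer vector of candidate n (default `1:44`).
#' @return list with `n` (the winner), `signature`, and `profile`, a
#'   data.frame with one row per attempted n (`n`, `n_genes`,
#'   `condition_number`).
#' @export
optimize_signature <- function(markers, ref, labels, n_range = 1:44) {
  if (length(n_range) == 0L) stop("empty n_range", call. = FALSE)
  rows <- list()
  sigs <- list()
  for (n in n_range) {
    sig <- tryCatch(
      suppressMessages(assemble_signature(markers, n, ref, labels)),
      error = function(e) {
        warning("n = ", n, " skipped: ", conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(sig)) next
    sigs[[as.character(n)]] <- sig
    rows[[as.character(n)]] <- data.frame(
      n = n, n_genes = nrow(sig),
      condition_number = attr(sig, "condition_number"))
  }
  if (length(rows) == 0L) stop("signature assembly failed for every n",
                               call. = FALSE)
  profile <- do.call(rbind, rows)
  rownames(profile) <- NULL
  best <- profile$n[which.min(profile$condition_number)]
  list(n = best, signature = sigs[[as.character(best)]], profile = profile)
}

#' Build a signature matrix from a labelled reference panel
#'
#' Runs the full construction pipeline in its fixed order: one-vs-rest
#' differential-expression ranking, enrichment-score filtering of
#' non-hematopoietic genes (when a tissue panel is given), removal of
#' tumor-expressed genes (when a tumor panel is given), then top-n marker
#' merging with condition-number minimisation over `n_range`.
#'
#' @inheritParams rank_marker_genes
#' @inheritParams optimize_signature
#' @param tissue_panel,tissue_labels,hematopoietic optional tissue panel for
#'   the enrichment-score filter (see [compute_enrichment_scores()]).
#' @param tumor_panel optional tumor panel for the tumor-expression filter.
#' @param fraction_threshold,log2_threshold,q_threshold filter cutoffs, see
#'   the individual filter functions.
#' @return as [optimize_signature()], plus `excluded`, a list of the three
#'   disjoint exclusion sets (`non_significant`, `non_hematopoietic`,
#'   `tumor_expressed`).
#' @export
build_signature <- function(ref, labels,
                            tissue_panel = NULL, tissue_labels = NULL,
                            hematopoietic = NULL,
                            tumor_panel = NULL,
                            n_range = 1:44,
                            p_threshold = 0.05,
                            q_threshold = 0.05,
                            fraction_threshold = 0.05,
                            log2_threshold = 7,
                            method = "moderated") {
  markers <- rank_marker_genes(ref, labels, p_threshold, method)
  universe <- rownames(ref)
  candidates <- unique(unlist(lapply(markers, `[[`, "gene"),
                              use.names = FALSE))
  non_significant <- setdiff(universe, candidates)

  non_hemato <- character(0)
  if (!is.null(tissue_panel)) {
    es <- compute_enrichment_scores(tissue_panel, tissue_labels,
                                    hematopoietic, q_threshold)
    kept <- hematopoietic_gene_set(es, fraction_threshold)
    removable <- intersect(candidates, rownames(es))
    non_hemato <- setdiff(removable, kept)
    candidates <- setdiff(candidates, non_hemato)
  }

  tumor_expressed <- character(0)
  if (!is.null(tumor_panel)) {
    kept <- filter_tumor_expressed(candidates, tumor_panel, log2_threshold)
    tumor_expressed <- attr(kept, "excluded_tumor_expressed")
    candidates <- as.character(kept)
  }

  markers <- structure(
    lapply(markers, function(tab) tab[tab$gene %in% candidates, ,
                                      drop = FALSE]),
    class = "ranked_markers", p_threshold = p_threshold)
  res <- optimize_signature(markers, ref, labels, n_range)
  res$excluded <- list(non_significant = non_significant,
                       non_hematopoietic = non_hemato,
                       tumor_expressed = tumor_expressed)
  message(sprintf(
    "signature: n = %d, %d genes (excluded: %d non-significant, %d non-hematopoietic, %d tumor-expressed)",
    res$n, nrow(res$signature), length(non_significant),
    length(non_hemato), length(tumor_expressed)))
  res
}
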
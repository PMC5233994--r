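#' Tissue enrichment scores from pairwise group contrasts
#'
#' Every tissue group is contrasted against each other group individually
#' with a two-group linear model per gene (the coefficient is the log2 group
#' mean difference; the p-value the pooled-variance t).  Within each
#' pairwise contrast, p-values are Benjamini-Hochberg adjusted across genes
#' to q-values.  The enrichment score ES(gene, group) is the sum of that
#' group's coefficients that reach q < `q_threshold`; zero when none do.
#'
#' @param tissue_panel an `expr_matrix` of tissue/cell-line profiles (any
#'   scale; tested on log2).
#' @param tissue_labels group label per sample; at least two groups.
#' @param hematopoietic optional named logical over the groups, flagging
#'   which are of blood-cell lineage (used by [hematopoietic_gene_set()]).
#' @param q_threshold q-value cutoff for a coefficient to contribute
#'   (default 0.05).
#' @return an `es_table`: numeric matrix genes x groups with attributes
#'   `hematopoietic` and `q_threshold`.
#' @export
compute_enrichment_scores <- function(tissue_panel, tissue_labels,
                                      hematopoietic = NULL,
                                      q_threshold = 0.05) {
  vals <- strip_em(as_log2(tissue_panel))
  tissue_labels <- as.character(tissue_labels)
  if (length(tissue_labels) != ncol(vals)) {
    stop("one label per panel sample required", call. = FALSE)
  }
  groups <- unique(tissue_labels)
  if (length(groups) < 2L) stop("need at least two tissue groups",
                                call. = FALSE)
  es <- matrix(0, nrow(vals), length(groups),
               dimnames = list(rownames(vals), groups))
  for (g in groups) {
    for (h in setdiff(groups, g)) {
      sel <- tissue_labels %in% c(g, h)
      res <- two_sample_t(vals[, sel, drop = FALSE],
                          tissue_labels[sel] == g)
      p <- res$p
      p[is.na(p)] <- 1
      q <- stats::p.adjust(p, method = "BH")
      sig <- q < q_threshold
      es[sig, g] <- es[sig, g] + res$diff[sig]
    }
  }
  if (!is.null(hematopoietic)) {
    missing <- setdiff(groups, names(hematopoietic))
    if (length(missing) > 0L) {
      stop("hematopoietic flag missing for group(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    hematopoietic <- hematopoietic[groups]
  }
  structure(es, class = c("es_table", class(es)),
            hematopoietic = hematopoietic, q_threshold = q_threshold)
}

#' Select hematopoietic genes from an enrichment-score table
#'
#' For each gene with positive enrichment in at least one group, the
#' non-hematopoietic fraction is the share of its positive ES mass carried
#' by non-hematopoietic groups.  Genes whose fraction exceeds
#' `fraction_threshold` are classed as non-hematopoietic and dropped; genes
#' with no positive enrichment anywhere carry no evidence of hematopoietic
#' expression and are dropped as well.
#'
#' @param es an `es_table` from [compute_enrichment_scores()] with the
#'   `hematopoietic` group flags set (or pass `hematopoietic` here).
#' @param fraction_threshold exclusion cutoff on the non-hematopoietic ES
#'   fraction (default 0.05; genes with fraction > 0.05 are removed).
#' @param hematopoietic named logical over groups, overriding the attribute.
#' @return character vector of retained (hematopoietic) gene ids, with the
#'   excluded genes in attributes `excluded_non_hematopoietic` and
#'   `excluded_no_evidence`.
#' @export
hematopoietic_gene_set <- function(es, fraction_threshold = 0.05,
                                   hematopoietic = attr(es, "hematopoietic")) {
  if (is.null(hematopoietic)) {
    stop("hematopoietic group flags are required", call. = FALSE)
  }
  hematopoietic <- hematopoietic[colnames(es)]
  if (anyNA(hematopoietic)) {
    stop("hematopoietic flag missing for some groups", call. = FALSE)
  }
  pos <- pmax(unclass(es), 0)
  total <- rowSums(pos)
  nh <- rowSums(pos[, !hematopoietic, drop = FALSE])
  no_evidence <- total == 0
  frac <- ifelse(no_evidence, NA_real_, nh / total)
  non_hemato <- !no_evidence & frac > fraction_threshold
  keep <- rownames(es)[!no_evidence & !non_hemato]
  if (any(no_evidence)) {
    message(sum(no_evidence),
            " gene(s) with no positive enrichment anywhere: excluded")
  }
  structure(keep,
            excluded_non_hematopoietic = rownames(es)[non_hemato],
            excluded_no_evidence = rownames(es)[no_evidence],
            non_hematopoietic_fraction = frac)
}
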
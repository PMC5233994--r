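#' Rank marker genes per cell type by one-vs-rest differential expression
#'
#' For each cell type, the reference samples of that type are contrasted
#' against all remaining samples on the log2 scale.  The default statistic
#' is the empirical-Bayes moderated t (limma), which shrinks per-gene
#' variances toward the across-gene prior and is the standard choice for
#' small per-type replicate numbers; `method = "t"` gives the plain
#' pooled-variance two-sample t.  P-values are Benjamini-Hochberg adjusted
#' across genes within each contrast.  Only genes up-regulated in the target
#' type (positive log2 fold change) qualify as markers, ordered by
#' decreasing fold change.
#'
#' @param ref reference panel, an `expr_matrix` (any scale; converted to
#'   log2 for testing).
#' @param labels character vector of cell-type labels, one per sample of
#'   `ref`; every type needs at least two samples.
#' @param p_threshold adjusted-p cutoff for significance (default 0.05).
#' @param method `"moderated"` (limma) or `"t"` (plain two-sample t).
#' @return a `ranked_markers` object: a named list with one data.frame per
#'   cell type (`gene`, `log2_fc`, `adj_p`), fold changes non-increasing.
#' @export
rank_marker_genes <- function(ref, labels, p_threshold = 0.05,
                              method = c("moderated", "t")) {
  method <- match.arg(method)
  vals <- strip_em(as_log2(ref))
  if (length(labels) != ncol(vals)) {
    stop("one label per reference sample required", call. = FALSE)
  }
  labels <- as.character(labels)
  counts <- table(labels)
  if (any(counts < 2L)) {
    stop("cell type(s) with fewer than 2 samples: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  }
  types <- unique(labels)
  constant <- apply(vals, 1L, function(x) stats::sd(x) == 0)

  out <- lapply(types, function(ct) {
    target <- labels == ct
    if (method == "moderated") {
      design <- cbind(Intercept = 1, target = as.numeric(target))
      fit <- limma::eBayes(limma::lmFit(vals, design))
      lfc <- fit$coefficients[, "target"]
      p <- fit$p.value[, "target"]
    } else {
      res <- two_sample_t(vals, target)
      lfc <- res$diff
      p <- res$p
    }
    p[constant | is.na(p)] <- 1
    adj <- stats::p.adjust(p, method = "BH")
    keep <- adj < p_threshold & lfc > 0
    tab <- data.frame(gene = rownames(vals)[keep],
                      log2_fc = unname(lfc[keep]),
                      adj_p = unname(adj[keep]),
                      stringsAsFactors = FALSE)
    tab[order(-tab$log2_fc), , drop = FALSE]
  })
  names(out) <- types
  structure(out, class = "ranked_markers", p_threshold = p_threshold)
}

# vectorized pooled-variance two-sample t over the rows of `vals`
two_sample_t <- function(vals, target) {
  n1 <- sum(target); n2 <- sum(!target)
  m1 <- rowMeans(vals[, target, drop = FALSE])
  m2 <- rowMeans(vals[, !target, drop = FALSE])
  v1 <- apply(vals[, target, drop = FALSE], 1L, stats::var)
  v2 <- apply(vals[, !target, drop = FALSE], 1L, stats::var)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- (m1 - m2) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  list(diff = m1 - m2, p = p)
}

#' @export
print.ranked_markers <- function(x, ...) {
  cat(sprintf("<ranked_markers> %d cell types, %s markers (adj p < %g)\n",
              length(x), sum(vapply(x, nrow, integer(1))),
              attr(x, "p_threshold")))
  invisible(x)
}
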
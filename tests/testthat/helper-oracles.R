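# Independent brute-force oracles used across the suite.  These stay
# deliberately naive (per-element loops, lm() per gene) so they share no
# code path with the implementation they check.

# quantile normalization: assign mean order statistics by rank, then give
# tied entries the mean of the target values their group occupies
qn_oracle <- function(m) {
  n <- nrow(m)
  sorted <- sapply(seq_len(ncol(m)), function(j) sort(m[, j]))
  target <- rowMeans(sorted)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    assigned <- numeric(n)
    assigned[order(x)] <- target
    for (v in unique(x)) {
      grp <- x == v
      assigned[grp] <- mean(assigned[grp])
    }
    out[, j] <- assigned
  }
  out
}

# enrichment scores: one lm() per gene and pairwise group contrast,
# BH-adjusted across genes within each contrast
es_oracle <- function(log2_vals, labels, q_threshold = 0.05) {
  groups <- unique(labels)
  es <- matrix(0, nrow(log2_vals), length(groups),
               dimnames = list(rownames(log2_vals), groups))
  for (g in groups) {
    for (h in setdiff(groups, g)) {
      sel <- labels %in% c(g, h)
      x <- factor(labels[sel] == g, levels = c(FALSE, TRUE))
      coefs <- ps <- numeric(nrow(log2_vals))
      for (i in seq_len(nrow(log2_vals))) {
        fit <- summary(stats::lm(log2_vals[i, sel] ~ x))
        coefs[i] <- fit$coefficients["xTRUE", "Estimate"]
        ps[i] <- fit$coefficients["xTRUE", "Pr(>|t|)"]
      }
      qs <- stats::p.adjust(ps, method = "BH")
      hit <- qs < q_threshold
      es[hit, g] <- es[hit, g] + coefs[hit]
    }
  }
  es
}

# small fast panel for unit tests (6 types, 5 markers each)
small_panel <- function(seed = 11, ...) {
  spec <- synthetic_panel_spec(n_cell_types = 6L, markers_per_type = 5L,
                               ...)
  generate_synthetic_panel(spec, seed = seed)
}

# non-negative least squares fractions by exhaustive active-set
# enumeration (exact for small column counts): the NNLS optimum is the
# best-fitting feasible unconstrained LS over some support subset
nnls_fractions <- function(sig, b) {
  A <- unclass(sig)
  b <- as.numeric(b)
  k <- ncol(A)
  stopifnot(k <= 12)
  best_w <- rep(0, k)
  best_rss <- sum(b^2)
  for (code in seq_len(2^k - 1)) {
    S <- which(bitwAnd(code, 2^(seq_len(k) - 1)) > 0)
    w <- tryCatch(qr.solve(A[, S, drop = FALSE], b),
                  error = function(e) NULL)
    if (is.null(w) || any(w < -1e-10)) next
    rss <- sum((A[, S, drop = FALSE] %*% w - b)^2)
    if (rss < best_rss - 1e-12) {
      best_rss <- rss
      best_w <- rep(0, k)
      best_w[S] <- pmax(w, 0)
    }
  }
  best_w / sum(best_w)
}
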
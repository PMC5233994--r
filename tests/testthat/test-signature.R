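# small labelled panel with hand-planted effects, built on the log2 scale
planted_ref <- function(seed = 5) {
  set.seed(seed)
  labels <- rep(c("A", "B", "C"), each = 3)
  g <- 12
  vals <- matrix(rnorm(g * 9, mean = 6, sd = 0.1), g, 9,
                 dimnames = list(sprintf("g%02d", 1:g),
                                 paste0(labels, 1:9)))
  vals["g01", labels == "A"] <- vals["g01", labels == "A"] + 8  # strong A
  vals["g02", labels == "A"] <- vals["g02", labels == "A"] + 5  # A, fc 5
  vals["g03", labels == "A"] <- vals["g03", labels == "A"] + 3  # A, fc 3
  vals["g04", labels == "B"] <- vals["g04", labels == "B"] + 6
  vals["g05", ] <- 4                                            # constant
  list(ref = expression_matrix(vals, "log2"), labels = labels)
}

test_that("one-vs-rest ranking finds planted markers in fold-change order", {
  p <- planted_ref()
  for (method in c("moderated", "t")) {
    mk <- rank_marker_genes(p$ref, p$labels, method = method)
    expect_identical(mk$A$gene[1], "g01")
    # plain two-sample t oracle on the strongest marker
    ora <- t.test(unclass(p$ref)["g01", p$labels == "A"],
                  unclass(p$ref)["g01", p$labels != "A"])
    expect_lt(ora$p.value, 0.05)
    # the two weaker A markers appear in decreasing fold-change order
    pos <- match(c("g02", "g03"), mk$A$gene)
    expect_true(all(!is.na(pos)) && pos[1] < pos[2])
    expect_true(all(diff(mk$A$log2_fc) <= 0))
    # constant gene is in nobody's list
    expect_false("g05" %in% unlist(lapply(mk, `[[`, "gene")))
    # all retained genes significant and up-regulated
    expect_true(all(unlist(lapply(mk, `[[`, "adj_p")) < 0.05))
    expect_true(all(unlist(lapply(mk, `[[`, "log2_fc")) > 0))
  }
})

test_that("ranking requires two samples per cell type", {
  p <- planted_ref()
  bad <- c(p$labels[-1], "D")
  expect_error(rank_marker_genes(p$ref, bad), "fewer than 2")
})

test_that("enrichment scores equal the brute-force pairwise-fit oracle", {
  set.seed(21)
  labels <- rep(c("blood", "liver", "brain"), each = 3)
  vals <- matrix(rnorm(10 * 9, 6, 0.2), 10, 9,
                 dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:9)))
  vals[1, labels == "blood"] <- vals[1, labels == "blood"] + 4
  vals[2, labels == "liver"] <- vals[2, labels == "liver"] + 4
  vals[3, ] <- 6  # identical mean everywhere
  panel <- expression_matrix(vals, "log2")

  es <- compute_enrichment_scores(panel, labels)
  expect_equal(unclass(es), suppressWarnings(es_oracle(vals, labels)),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_gt(es["g01", "blood"], 0)
  expect_equal(unname(es["g03", ]), c(0, 0, 0))
  expect_error(compute_enrichment_scores(panel, rep("one", 9)),
               "two tissue groups")
})

test_that("the q-value cutoff is strict", {
  set.seed(22)
  labels <- rep(c("g1", "g2"), each = 3)
  vals <- matrix(rnorm(8 * 6, 6, 0.3), 8, 6,
                 dimnames = list(sprintf("g%02d", 1:8), paste0("s", 1:6)))
  vals[1, labels == "g1"] <- vals[1, labels == "g1"] + 2
  panel <- expression_matrix(vals, "log2")
  # recover the attained q-value of the planted gene from the oracle path
  res <- svrdecon:::two_sample_t(vals, labels == "g1")
  q <- p.adjust(res$p, "BH")[1]
  at <- compute_enrichment_scores(panel, labels, q_threshold = q)
  above <- compute_enrichment_scores(panel, labels, q_threshold = q + 1e-12)
  expect_equal(at["g01", "g1"], 0)          # q < q is FALSE: excluded
  expect_equal(above["g01", "g1"], res$diff[["g01"]])  # just under: included
})

test_that("hematopoietic selection follows the positive-ES mass fraction", {
  es <- matrix(c(3, 0, 0,    # immune only -> fraction 0, kept
                 0, 2, 1,    # non-hemato only -> fraction 1, removed
                 4.7, 0.2, 0.1,  # fraction 0.06 -> removed
                 0, 0, 0),   # no evidence -> excluded
               4, 3, byrow = TRUE,
               dimnames = list(c("keep", "tissue", "edge", "flat"),
                               c("blood", "liver", "brain")))
  flags <- c(blood = TRUE, liver = FALSE, brain = FALSE)
  expect_message(
    kept <- hematopoietic_gene_set(structure(es, class = "es_table"),
                                   hematopoietic = flags),
    "no positive enrichment")
  expect_identical(as.character(kept), "keep")
  expect_setequal(attr(kept, "excluded_non_hematopoietic"),
                  c("tissue", "edge"))
  expect_identical(attr(kept, "excluded_no_evidence"), "flat")

  # random table against a brute-force fraction computation
  set.seed(8)
  r <- matrix(rnorm(60), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), names(flags)))
  got <- suppressMessages(
    hematopoietic_gene_set(structure(r, class = "es_table"),
                           hematopoietic = flags))
  expected <- rownames(r)[apply(r, 1, function(x) {
    p <- pmax(x, 0)
    sum(p) > 0 && sum(p[2:3]) / sum(p) <= 0.05
  })]
  expect_setequal(as.character(got), expected)
})

test_that("tumor-expressed genes are removed by mean log2 threshold", {
  vals <- matrix(c(7.6, 7.4,   # mean 7.5 -> removed
                   7.0, 6.8,   # mean 6.9 -> kept
                   8.0, 9.0),  # mean 8.5 -> removed
                 3, 2, byrow = TRUE,
                 dimnames = list(c("hi", "lo", "vhi"), c("t1", "t2")))
  tumor <- expression_matrix(vals, "log2")
  kept <- filter_tumor_expressed(c("hi", "lo", "vhi"), tumor)
  expect_identical(as.character(kept), "lo")
  expect_setequal(attr(kept, "excluded_tumor_expressed"), c("hi", "vhi"))

  # absent candidates are kept, with a message
  expect_message(k2 <- filter_tumor_expressed(c("lo", "ghost"), tumor),
                 "absent")
  expect_setequal(as.character(k2), c("lo", "ghost"))

  # random panel equals the brute-force mean-and-threshold scan
  set.seed(13)
  r <- matrix(rnorm(40, 7, 1), 20, 2,
              dimnames = list(sprintf("g%02d", 1:20), c("t1", "t2")))
  got <- filter_tumor_expressed(rownames(r), expression_matrix(r, "log2"))
  expect_setequal(as.character(got), rownames(r)[rowMeans(r) <= 7])
})

test_that("signature assembly takes the union of top-n markers", {
  panel <- small_panel()
  mk <- rank_marker_genes(panel$reference, panel$labels)

  sig2 <- assemble_signature(mk, 2, panel$reference, panel$labels)
  tops <- unlist(lapply(mk, function(tab) tab$gene[1:2]), use.names = FALSE)
  expect_setequal(rownames(sig2), unique(tops))
  expect_identical(colnames(sig2), names(mk))

  # shared top gene: union semantics (gene shared by two types enters once)
  mk3 <- structure(list(
    A = data.frame(gene = c("gX", "gZ"), log2_fc = c(5, 2),
                   adj_p = c(1e-4, 1e-3)),
    B = data.frame(gene = c("gX", "gW"), log2_fc = c(4, 2),
                   adj_p = c(1e-4, 1e-3)),
    C = data.frame(gene = c("gY", "gV"), log2_fc = c(3, 2),
                   adj_p = c(1e-4, 1e-3))),
    class = "ranked_markers")
  set.seed(2)
  ref <- expression_matrix(
    matrix(rexp(5 * 6, 1 / 50), 5, 6,
           dimnames = list(c("gX", "gY", "gZ", "gW", "gV"),
                           paste0("s", 1:6))), "linear")
  labs <- rep(c("A", "B", "C"), each = 2)
  sig <- assemble_signature(mk3, 2, ref, labs)
  expect_setequal(rownames(sig), c("gX", "gY", "gZ", "gW", "gV"))  # 5 not 6
  # entries are mean linear expression per type
  expect_equal(unclass(sig)["gX", "A"],
               mean(unclass(ref)["gX", labs == "A"]))
  # a shared-top union smaller than the type count cannot form a basis
  expect_error(assemble_signature(mk3, 1, ref, labs), "more signature genes")

  # union is monotone non-decreasing in n
  sizes <- vapply(2:5, function(n) {
    nrow(suppressMessages(
      assemble_signature(mk, n, panel$reference, panel$labels)))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("condition-number optimisation picks the exhaustive-scan winner", {
  panel <- small_panel()
  mk <- rank_marker_genes(panel$reference, panel$labels)

  single <- optimize_signature(mk, panel$reference, panel$labels,
                               n_range = 5)
  expect_identical(single$n, 5)

  # n = 1 gives a 6-gene union for 6 types (no basis) and must be skipped
  expect_warning(
    res <- suppressMessages(
      optimize_signature(mk, panel$reference, panel$labels, n_range = 1:5)),
    "skipped")
  expect_identical(nrow(res$profile), 4L)  # one entry per attempted n
  expect_identical(res$profile$n, 2:5)
  # independent exhaustive scan with kappa()
  conds <- vapply(2:5, function(n) {
    kappa(unclass(suppressMessages(
      assemble_signature(mk, n, panel$reference, panel$labels))),
      exact = TRUE)
  }, numeric(1))
  expect_equal(res$profile$condition_number, conds, tolerance = 1e-8)
  expect_identical(res$n, (2:5)[which.min(conds)])
  expect_equal(attr(res$signature, "condition_number"), min(conds),
               tolerance = 1e-8)
})

test_that("the full pipeline logs three disjoint exclusion sets that tile the universe", {
  panel <- small_panel(seed = 31)
  ref <- panel$reference
  # tissue panel: signature genes quiet, two planted genes tissue-specific
  set.seed(32)
  tl <- rep(c("blood", "liver"), each = 3)
  tvals <- matrix(rnorm(nrow(ref) * 6, 5, 0.2), nrow(ref), 6,
                  dimnames = list(rownames(ref), paste0("ts", 1:6)))
  # make the first two genes of cell type 1's block liver-specific
  liver_genes <- rownames(ref)[1:2]
  tvals[liver_genes, tl == "liver"] <- tvals[liver_genes, tl == "liver"] + 6
  blood_genes <- setdiff(rownames(ref), liver_genes)
  tvals[blood_genes, tl == "blood"] <- tvals[blood_genes, tl == "blood"] + 3
  tissue <- expression_matrix(tvals, "log2")
  # tumor panel: one gene hot in tumors
  tumor_gene <- rownames(ref)[6]
  tu <- matrix(5, nrow(ref), 2,
               dimnames = list(rownames(ref), c("tu1", "tu2")))
  tu[tumor_gene, ] <- 9
  tumor <- expression_matrix(tu, "log2")

  res <- suppressMessages(build_signature(
    ref, panel$labels,
    tissue_panel = tissue, tissue_labels = tl,
    hematopoietic = c(blood = TRUE, liver = FALSE),
    tumor_panel = tumor, n_range = 2:5))

  ex <- res$excluded
  expect_true(all(liver_genes %in% ex$non_hematopoietic))
  expect_identical(ex$tumor_expressed, tumor_gene)
  # the three exclusion sets are pairwise disjoint
  expect_length(intersect(ex$non_significant, ex$non_hematopoietic), 0)
  expect_length(intersect(ex$non_significant, ex$tumor_expressed), 0)
  expect_length(intersect(ex$non_hematopoietic, ex$tumor_expressed), 0)
  # exclusions plus surviving candidates tile the tested gene universe
  survivors <- setdiff(rownames(ref), unlist(ex))
  expect_setequal(c(unlist(ex), survivors), rownames(ref))
  expect_true(all(rownames(res$signature) %in% survivors))
})
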
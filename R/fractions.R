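#' Cell-type fraction vector
#'
#' A named numeric vector of relative proportions over a cell-type panel.
#' Fractions lie in [0, 1] and sum to one, except for the degenerate
#' `all_zero` case (a fit in which every raw weight was non-positive), which
#' is flagged rather than renormalized.
#'
#' @param fractions numeric vector in [0, 1].
#' @param cell_types character vector of unique labels; defaults to
#'   `names(fractions)`.
#' @param all_zero logical flag for the degenerate all-zero vector.
#' @return named numeric with class `fraction_vector` and attribute
#'   `all_zero`.
#' @export
fraction_vector <- function(fractions, cell_types = names(fractions),
                            all_zero = FALSE) {
  if (is.null(cell_types) || anyDuplicated(cell_types)) {
    stop("cell types must be unique and non-NULL", call. = FALSE)
  }
  if (length(fractions) != length(cell_types)) {
    stop("length mismatch between fractions and cell types", call. = FALSE)
  }
  if (anyNA(fractions) || any(fractions < 0) || any(fractions > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (all_zero) {
    if (any(fractions != 0)) stop("all_zero flag with nonzero fractions",
                                  call. = FALSE)
  } else if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  structure(stats::setNames(as.numeric(fractions), cell_types),
            class = "fraction_vector", all_zero = all_zero)
}

#' Map fine cell types to major types
#'
#' @param mapping named character vector: `names()` are fine cell types,
#'   values the major type each belongs to.  Every fine type maps to exactly
#'   one major type.
#' @return the validated mapping with class `cell_type_hierarchy`.
#' @seealso [default_hierarchy()] for the built-in 25-type panel.
#' @export
cell_type_hierarchy <- function(mapping) {
  if (is.null(names(mapping)) || anyDuplicated(names(mapping)) ||
      anyNA(mapping)) {
    stop("`mapping` must be a named character vector, one major type per ",
         "fine type", call. = FALSE)
  }
  structure(mapping, class = "cell_type_hierarchy")
}

#' Aggregate fine-grained fractions into major cell types
#'
#' Each major type's fraction is the sum of its children's fractions; the
#' total is conserved exactly.
#'
#' @param f a [fraction_vector()] (or named numeric) over fine cell types.
#' @param h a [cell_type_hierarchy()] covering every cell type in `f`.
#' @return a `fraction_vector` over the major types, in order of first
#'   appearance in `h`.
#' @export
aggregate_fractions <- function(f, h) {
  fine <- names(f)
  missing <- setdiff(fine, names(h))
  if (length(missing) > 0L) {
    stop("cell types not covered by hierarchy: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  majors <- unname(h[fine])
  order_majors <- unique(unname(h))
  order_majors <- order_majors[order_majors %in% majors]
  agg <- vapply(order_majors,
                function(mj) sum(as.numeric(f)[majors == mj]), numeric(1))
  az <- isTRUE(attr(f, "all_zero"))
  fraction_vector(agg, order_majors, all_zero = az)
}

#' Default immune cell-type panel and hierarchy
#'
#' A 25-type mouse immune panel grouped into seven major lineages
#' (granulocytes, B cells, CD4 T cells, CD8 T cells, NK cells, dendritic
#' cells, mono/macrophages).  This is the panel the synthetic-data generator
#' uses by default; it is a convention, not a hard-wired requirement — any
#' panel with a matching hierarchy works.
#'
#' @return `default_cell_types()`: character vector of 25 labels;
#'   `default_hierarchy()`: a [cell_type_hierarchy()] over them.
#' @export
default_cell_types <- function() names(default_hierarchy())

#' @rdname default_cell_types
#' @export
default_hierarchy <- function() {
  cell_type_hierarchy(c(
    "Neutrophils"               = "Granulocytes",
    "Eosinophils"               = "Granulocytes",
    "Basophils"                 = "Granulocytes",
    "Mast cells"                = "Granulocytes",
    "B cells naive"             = "B cells",
    "B cells memory"            = "B cells",
    "Plasma cells"              = "B cells",
    "T cells CD4 naive"         = "T cells CD4",
    "T cells CD4 memory"        = "T cells CD4",
    "T cells regulatory"        = "T cells CD4",
    "T cells follicular helper" = "T cells CD4",
    "Th1 cells"                 = "T cells CD4",
    "Th2 cells"                 = "T cells CD4",
    "Th17 cells"                = "T cells CD4",
    "T cells CD8 naive"         = "T cells CD8",
    "T cells CD8 memory"        = "T cells CD8",
    "T cells CD8 effector"      = "T cells CD8",
    "NK cells resting"          = "NK cells",
    "NK cells activated"        = "NK cells",
    "DC immature"               = "Dendritic cells",
    "DC activated"              = "Dendritic cells",
    "DC plasmacytoid"           = "Dendritic cells",
    "Monocytes"                 = "Mono/Macrophages",
    "Macrophages M1"            = "Mono/Macrophages",
    "Macrophages M2"            = "Mono/Macrophages"
  ))
}
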
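# TCR clonotype expansion classing and liver/tumor sharing. Clonotype
# identity is the amino-acid sequence of the CDR3 region of the TCR beta
# chain; each cell carries exactly one key, and cells with no recovered TCR
# are expected to be absent from the table.

CLONE_CLASSES <- c("unique", "small", "large", "hyperexpanded")

#' Clone sizes within a stratum
#'
#' Tallies the number of cells per clonotype key, optionally restricted to a
#' tissue and/or group. Counts always sum to the number of cells in the
#' stratum.
#'
#' @param table A clonotype `data.frame` with columns `clonotype_key` and
#'   optionally `tissue`, `group`.
#' @param tissue,group Optional stratum filters.
#' @return Named integer vector: clonotype key -> cell count.
#' @export
clone_sizes <- function(table, tissue = NULL, group = NULL) {
  stopifnot("clonotype_key" %in% names(table))
  keep <- rep(TRUE, nrow(table))
  if (!is.null(tissue)) keep <- keep & table$tissue %in% tissue
  if (!is.null(group)) keep <- keep & table$group %in% group
  keys <- table$clonotype_key[keep]
  if (length(keys) == 0L) return(integer(0))
  tab <- table(keys)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Clone-size expansion class
#'
#' Maps clone sizes onto the four expansion classes: unique (1 cell), small
#' (2-5 cells), large (6-30 cells), hyperexpanded (more than 30 cells). The
#' classes partition the positive integers; 31 is the smallest hyperexpanded
#' size.
#'
#' @param size Positive integer vector of clone sizes.
#' @return Ordered factor with levels unique < small < large < hyperexpanded.
#' @examples
#' classify_clone(c(1, 5, 6, 30, 31))
#' @export
classify_clone <- function(size) {
  if (length(size) == 0L)
    return(factor(character(0), levels = CLONE_CLASSES, ordered = TRUE))
  if (anyNA(size) || any(size < 1) || any(size != floor(size)))
    stop("clone sizes must be positive integers", call. = FALSE)
  cls <- cut(size, breaks = c(0, 1, 5, 30, Inf), labels = CLONE_CLASSES,
             ordered_result = TRUE)
  cls
}

#' Per-class tallies of cells and clonotypes
#'
#' Summarizes a stratum by expansion class, reporting both how many
#' clonotypes fall in each class and how many cells they comprise (figures in
#' the field use either tally; both are emitted).
#'
#' @inheritParams clone_sizes
#' @return A `data.frame` with columns `class`, `n_clonotypes`, `n_cells`.
#' @export
clone_class_counts <- function(table, tissue = NULL, group = NULL) {
  sizes <- clone_sizes(table, tissue = tissue, group = group)
  cls <- classify_clone(sizes)
  data.frame(
    class = factor(CLONE_CLASSES, levels = CLONE_CLASSES, ordered = TRUE),
    n_clonotypes = as.integer(table(cls)),
    n_cells = as.integer(tapply(sizes, cls, sum, default = 0L)),
    stringsAsFactors = FALSE)
}

#' Clonotypes shared between two tissues
#'
#' Finds clonotype keys present in both tissues and reports each key's size
#' and expansion class in each tissue. The shared key set is symmetric in the
#' two tissue arguments.
#'
#' @param table A clonotype `data.frame` (see [clone_sizes()]).
#' @param tissue_a,tissue_b Tissue labels (default `"liver"`, `"tumor"`).
#' @param group Optional group filter applied to both tissues.
#' @return A `data.frame` with columns `clonotype_key`, `size_a`, `size_b`,
#'   `class_a`, `class_b`, plus attributes `summary` (shared/total clonotype
#'   counts and sharing fractions relative to each tissue) and `tissues`.
#' @examples
#' tb <- data.frame(
#'   cell_id = paste0("c", 1:14),
#'   clonotype_key = c(rep("a", 4), "b", rep("a", 7), "c", "c"),
#'   tissue = rep(c("liver", "tumor"), c(5, 9)))
#' shared_clonotypes(tb)
#' @export
shared_clonotypes <- function(table, tissue_a = "liver", tissue_b = "tumor",
                              group = NULL) {
  sa <- clone_sizes(table, tissue = tissue_a, group = group)
  sb <- clone_sizes(table, tissue = tissue_b, group = group)
  shared <- sort(intersect(names(sa), names(sb)))
  out <- data.frame(clonotype_key = shared,
                    size_a = as.integer(sa[shared]),
                    size_b = as.integer(sb[shared]),
                    stringsAsFactors = FALSE)
  out$class_a <- classify_clone(out$size_a)
  out$class_b <- classify_clone(out$size_b)
  attr(out, "tissues") <- c(a = tissue_a, b = tissue_b)
  attr(out, "summary") <- list(
    n_shared = length(shared),
    n_clonotypes_a = length(sa),
    n_clonotypes_b = length(sb),
    sharing_fraction_a = if (length(sa)) length(shared) / length(sa) else NA,
    sharing_fraction_b = if (length(sb)) length(shared) / length(sb) else NA)
  out
}
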
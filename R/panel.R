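#' Construct a gene panel
#'
#' A gene panel is an ordered set of unique gene names. Its order is fixed and
#' defines the row/column order of every co-localization matrix built from it
#' (an in-situ panel of e.g. 500 genes yields a 500 x 500 matrix).
#'
#' @param genes Character vector of gene names; must be non-empty, free of
#'   duplicates, `NA`s and empty strings.
#' @return A character vector of class `"gene_panel"`.
#' @examples
#' gene_panel(c("Cd3e", "Trac", "H2-Aa"))
#' @export
gene_panel <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L)
    stop("a gene panel must contain at least one gene", call. = FALSE)
  if (anyNA(genes) || any(!nzchar(genes)))
    stop("gene names must be non-empty and non-NA", call. = FALSE)
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicated gene names in panel: ", paste(dup, collapse = ", "),
         call. = FALSE)
  structure(genes, class = "gene_panel")
}

#' @export
print.gene_panel <- function(x, ...) {
  cat("Gene panel of", length(x), "genes\n")
  show <- utils::head(unclass(x), 10L)
  cat(" ", paste(show, collapse = ", "),
      if (length(x) > 10L) ", ..." else "", "\n", sep = "")
  invisible(x)
}

as_panel <- function(x) {
  if (inherits(x, "gene_panel")) x else gene_panel(x)
}
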
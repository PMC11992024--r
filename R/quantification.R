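# Closed-form quantifications: lentiviral vector copy number from droplet
# digital PCR, caliper tumor volume, and the IIT (IFN/IL12-induced T cell)
# gene-signature score with 50th-percentile stratification for survival
# analysis. The survival fit itself is delegated to standard tools (e.g. the
# survival package); this module produces the strata.

#' Lentiviral vector copies per genome
#'
#' Droplet digital PCR quantification: twice the ratio of the vector (HIV)
#' amplicon concentration to a single-copy normalizer gene concentration,
#' both in copies/µL. The factor 2 converts per-haploid-equivalent to
#' per-diploid-genome.
#'
#' @param concentration_hiv Vector amplicon concentration (copies/µL), >= 0.
#' @param concentration_normalizer Normalizer concentration (copies/µL),
#'   strictly positive.
#' @return Copies per diploid genome (vectorized).
#' @examples
#' lv_copies_per_genome(100, 50)  # 4
#' @export
lv_copies_per_genome <- function(concentration_hiv,
                                 concentration_normalizer) {
  if (any(concentration_hiv < 0, na.rm = TRUE))
    stop("concentration_hiv must be >= 0", call. = FALSE)
  if (any(concentration_normalizer <= 0, na.rm = TRUE))
    stop("undefined measurement: normalizer concentration must be > 0",
         call. = FALSE)
  concentration_hiv / concentration_normalizer * 2
}

#' Caliper tumor volume
#'
#' Standard ellipsoid approximation from two caliper diameters:
#' `x^2 * y / 2` with `x` the larger and `y` the smaller diameter (mm).
#'
#' @param diameter_x Larger diameter, mm.
#' @param diameter_y Smaller diameter, mm; must not exceed `diameter_x`.
#' @return Volume in mm^3 (vectorized).
#' @examples
#' tumor_volume(10, 8)  # 400
#' @export
tumor_volume <- function(diameter_x, diameter_y) {
  if (any(diameter_y < 0, na.rm = TRUE))
    stop("diameters must be >= 0", call. = FALSE)
  if (any(diameter_y > diameter_x, na.rm = TRUE))
    stop("diameters mislabeled: y exceeds x (x must be the larger diameter)",
         call. = FALSE)
  diameter_x^2 * diameter_y / 2
}

#' Define a gene-signature panel
#'
#' @param genes Unique, non-empty gene names.
#' @param log_offset Offset added before log2 so zero expression is defined
#'   (default 1).
#' @return A list of class `"signature_panel"`.
#' @export
signature_panel <- function(genes, log_offset = 1) {
  genes <- as.character(genes)
  if (length(genes) == 0L || anyNA(genes) || any(!nzchar(genes)))
    stop("signature panel must contain non-empty gene names", call. = FALSE)
  if (anyDuplicated(genes))
    stop("duplicated genes in signature panel", call. = FALSE)
  check_scalar_number(log_offset, "log_offset", min = 0)
  structure(list(genes = genes, log_offset = log_offset),
            class = "signature_panel")
}

#' Read a signature panel from a text file
#'
#' One gene per line; blank lines and `#` comments are skipped. The package
#' ships `inst/extdata/iit_signature_genes.txt` pre-filled with the six
#' published members of the 22-gene IIT signature; the remaining members are
#' supplied by the user from the study's supplementary gene list.
#'
#' @param path Path to the gene list.
#' @param log_offset Passed to [signature_panel()].
#' @return A `"signature_panel"`.
#' @export
read_signature_panel <- function(path = system.file(
  "extdata", "iit_signature_genes.txt", package = "livmet"),
  log_offset = 1) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  signature_panel(lines, log_offset = log_offset)
}

#' Signature score with median stratification
#'
#' Per-sample score: the sum of log2-transformed expression (`log2(x +
#' offset)`) over the panel genes present in the matrix. Samples are
#' stratified at the 50th percentile of the scores: strictly above the
#' median is "high", the rest "low". Panel genes missing from the matrix are
#' reported via a message and the `missing_genes` attribute; scoring
#' requires at least one panel gene present.
#'
#' @param expr Numeric sample-by-gene matrix (linear scale). If genes are in
#'   rows, set `samples_in_rows = FALSE`.
#' @param panel A [signature_panel()] or character vector of genes.
#' @param samples_in_rows Orientation flag (default `TRUE`).
#' @return A `data.frame` of class `"signature_score"` with columns
#'   `sample`, `score`, `stratum`, plus attributes `cut` (the median),
#'   `missing_genes`, `log_offset`.
#' @export
iit_score <- function(expr, panel, samples_in_rows = TRUE) {
  if (!inherits(panel, "signature_panel")) panel <- signature_panel(panel)
  expr <- as.matrix(expr)
  if (!samples_in_rows) expr <- t(expr)
  if (is.null(colnames(expr)))
    stop("expression matrix must carry gene names", call. = FALSE)
  present <- intersect(panel$genes, colnames(expr))
  missing <- setdiff(panel$genes, colnames(expr))
  if (length(present) == 0L)
    stop("no signature panel gene is present in the expression matrix",
         call. = FALSE)
  if (length(missing))
    message("iit_score: ", length(missing),
            " panel gene(s) missing from the matrix: ",
            paste(utils::head(missing, 10L), collapse = ", "))
  sub <- expr[, present, drop = FALSE]
  if (any(sub < 0, na.rm = TRUE))
    stop("expression values must be non-negative", call. = FALSE)
  scores <- rowSums(log2(sub + panel$log_offset))
  cut <- stats::median(scores)
  out <- data.frame(
    sample = rownames(expr) %||% sprintf("s%03d", seq_along(scores)),
    score = unname(scores),
    stratum = ifelse(scores > cut, "high", "low"),
    stringsAsFactors = FALSE)
  attr(out, "cut") <- cut
  attr(out, "missing_genes") <- missing
  attr(out, "log_offset") <- panel$log_offset
  class(out) <- c("signature_score", "data.frame")
  out
}

#' @export
print.signature_score <- function(x, ...) {
  cat("Signature scores for", nrow(x), "samples; median cut =",
      format(attr(x, "cut"), digits = 6), "\n")
  cat("  high:", sum(x$stratum == "high"),
      " low:", sum(x$stratum == "low"), "\n")
  if (length(attr(x, "missing_genes")))
    cat("  missing panel genes:", length(attr(x, "missing_genes")), "\n")
  NextMethod()
}

#' Join signature strata with survival outcomes
#'
#' Produces the stratified table handed to a survival fit (e.g.
#' `survival::survfit(Surv(time, event) ~ stratum, data = ...)`); the fit
#' itself is outside this package's scope.
#'
#' @param scores A [iit_score()] result.
#' @param survival_table `data.frame` with columns `sample`, `time`, `event`
#'   (event: 1 = observed, 0 = censored).
#' @return `data.frame` with columns `sample`, `score`, `stratum`, `time`,
#'   `event`.
#' @export
export_strata <- function(scores, survival_table) {
  need <- c("sample", "time", "event")
  if (!is.data.frame(survival_table) || nrow(survival_table) == 0L)
    stop("survival table is empty", call. = FALSE)
  miss <- setdiff(need, names(survival_table))
  if (length(miss))
    stop("survival table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(survival_table$sample))
    stop("duplicated sample id(s) in survival table: ",
         paste(unique(survival_table$sample[
           duplicated(survival_table$sample)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(scores$sample))
    stop("duplicated sample id(s) in scores", call. = FALSE)
  only_scores <- setdiff(scores$sample, survival_table$sample)
  only_surv <- setdiff(survival_table$sample, scores$sample)
  if (length(only_scores) || length(only_surv))
    stop("sample mismatch; scored but no survival: {",
         paste(utils::head(only_scores, 5L), collapse = ", "),
         "}; survival but not scored: {",
         paste(utils::head(only_surv, 5L), collapse = ", "), "}",
         call. = FALSE)
  m <- match(scores$sample, survival_table$sample)
  data.frame(sample = scores$sample, score = scores$score,
             stratum = scores$stratum,
             time = survival_table$time[m],
             event = survival_table$event[m],
             stringsAsFactors = FALSE)
}
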
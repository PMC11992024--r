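# Reading/writing the tabular formats the pipeline touches. Transcript tables
# arrive as MERSCOPE-style detected-transcript CSV exports; co-localization
# matrices travel as TSV with full-precision decimal serialization so that
# read(write(x)) reproduces x bit-for-bit.

#' Build an in-memory transcript table
#'
#' The central spatial container: one row per detected transcript with its
#' gene, planar position in micrometres and the identity of the segmented cell
#' containing it. Transcripts outside any cell carry `NA` as `cell_id` and are
#' treated as "unassigned" (see [coloc_params()] for how the scorer handles
#' them).
#'
#' @param gene Character vector of gene names.
#' @param x,y Numeric planar coordinates in micrometres; must be finite.
#' @param cell_id Cell identifiers (coerced to character); `NA` marks an
#'   unassigned transcript.
#' @param section Optional section/condition label (recycled).
#' @return A `data.frame` of class `"transcript_table"` with columns
#'   `gene`, `x`, `y`, `cell_id` and optionally `section`.
#' @examples
#' transcript_table(c("A", "B"), x = c(0, 10), y = c(0, 0), cell_id = 1:2)
#' @export
transcript_table <- function(gene, x, y, cell_id, section = NULL) {
  gene <- as.character(gene)
  x <- as.numeric(x)
  y <- as.numeric(y)
  cell_id <- as.character(cell_id)
  n <- length(gene)
  if (length(x) != n || length(y) != n || length(cell_id) != n)
    stop("gene, x, y and cell_id must have equal length", call. = FALSE)
  if (n > 0 && (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))))
    stop("transcript coordinates must be finite", call. = FALSE)
  if (n > 0 && (anyNA(gene) || any(!nzchar(gene))))
    stop("gene names must be non-empty", call. = FALSE)
  out <- data.frame(gene = gene, x = x, y = y, cell_id = cell_id,
                    stringsAsFactors = FALSE)
  if (!is.null(section)) out$section <- rep_len(as.character(section), n)
  class(out) <- c("transcript_table", "data.frame")
  out
}

#' Describe a detected-transcript CSV dialect
#'
#' MERSCOPE exports do not have a single fixed schema; the dialect object maps
#' file columns onto the internal ones, names the sentinel used for
#' transcripts not assigned to a cell, and gives the pattern identifying
#' blank-barcode control rows.
#'
#' @param gene,x,y,cell_id Column names in the file (defaults follow the
#'   common MERSCOPE export naming: `gene`, `global_x`, `global_y`,
#'   `cell_id`).
#' @param section Optional name of a section/condition column.
#' @param unassigned Sentinel value marking an unassigned transcript in the
#'   cell column (default `"-1"`); empty strings are always treated as
#'   unassigned.
#' @param blank_pattern Regular expression identifying blank-barcode rows
#'   (negative controls, not genes); matching rows are dropped on read.
#' @return A list of class `"transcript_dialect"`.
#' @export
transcript_dialect <- function(gene = "gene", x = "global_x", y = "global_y",
                               cell_id = "cell_id", section = NULL,
                               unassigned = "-1",
                               blank_pattern = "^Blank-") {
  structure(list(gene = gene, x = x, y = y, cell_id = cell_id,
                 section = section, unassigned = as.character(unassigned),
                 blank_pattern = blank_pattern),
            class = "transcript_dialect")
}

#' Read a detected-transcript CSV
#'
#' Parses a MERSCOPE-style per-transcript CSV into a [transcript_table()].
#' Blank-barcode rows are dropped (they are imaging controls, not panel
#' genes); the number dropped is reported via [message()] and stored in the
#' `"dropped_blanks"` attribute. Cell identifiers equal to the dialect's
#' unassigned sentinel become `NA`.
#'
#' @param path Path to a CSV file.
#' @param dialect A [transcript_dialect()]; the default matches common
#'   MERSCOPE exports.
#' @return A `"transcript_table"` with attribute `dropped_blanks`.
#' @export
read_transcripts <- function(path, dialect = transcript_dialect()) {
  stopifnot(inherits(dialect, "transcript_dialect"))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  need <- c(gene = dialect$gene, x = dialect$x, y = dialect$y,
            cell_id = dialect$cell_id)
  missing_cols <- need[!need %in% names(raw)]
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  xs <- suppressWarnings(as.numeric(raw[[dialect$x]]))
  ys <- suppressWarnings(as.numeric(raw[[dialect$y]]))
  bad <- which(is.na(xs) | is.na(ys) | !is.finite(xs) | !is.finite(ys))
  if (length(bad))
    stop("non-numeric coordinate(s) at data line(s): ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) " ..." else "", call. = FALSE)

  genes <- raw[[dialect$gene]]
  blanks <- grepl(dialect$blank_pattern, genes)
  n_blanks <- sum(blanks)
  if (n_blanks > 0L)
    message("read_transcripts: dropped ", n_blanks, " blank-barcode row(s)")

  cells <- raw[[dialect$cell_id]]
  cells[cells == dialect$unassigned | cells == ""] <- NA_character_

  keep <- !blanks
  section <- if (!is.null(dialect$section) && dialect$section %in% names(raw))
    raw[[dialect$section]][keep] else NULL
  out <- transcript_table(genes[keep], xs[keep], ys[keep], cells[keep],
                          section = section)
  attr(out, "dropped_blanks") <- n_blanks
  out
}

#' Write a transcript table as CSV
#'
#' Inverse of [read_transcripts()]: serializes the table in the dialect's
#' column naming, writing `NA` cell identifiers as the unassigned sentinel.
#'
#' @inheritParams read_transcripts
#' @param table A `"transcript_table"`.
#' @export
write_transcripts <- function(table, path, dialect = transcript_dialect()) {
  stopifnot(inherits(table, "transcript_table"))
  out <- data.frame(table$gene,
                    sprintf("%.17g", table$x),
                    sprintf("%.17g", table$y),
                    ifelse(is.na(table$cell_id), dialect$unassigned,
                           table$cell_id),
                    stringsAsFactors = FALSE, check.names = FALSE)
  names(out) <- c(dialect$gene, dialect$x, dialect$y, dialect$cell_id)
  if (!is.null(table$section))
    out[[dialect$section %||% "section"]] <- table$section
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Serialize a numeric matrix value losslessly (17 significant digits round-trip
# any IEEE double); NA becomes the literal token "NA".
format_full <- function(v) {
  out <- sprintf("%.17g", v)
  out[is.na(v)] <- "NA"
  out
}

#' Write a co-localization (or differential) matrix as TSV
#'
#' The file has a header row of gene names and a leading column of gene names;
#' values are serialized with 17 significant digits so a round-trip through
#' [read_coloc_matrix()] reproduces them exactly. `NA` entries are written as
#' the token `NA`.
#'
#' @param m A [coloc_matrix()] result, a `"coloc_diff"`, or a plain labelled
#'   square matrix.
#' @param path Output file path.
#' @export
write_coloc_matrix <- function(m, path) {
  vals <- as.matrix(m)
  if (nrow(vals) != ncol(vals))
    stop("matrix must be square", call. = FALSE)
  g <- rownames(vals)
  if (is.null(g) || is.null(colnames(vals)) ||
      !identical(g, colnames(vals)))
    stop("matrix must carry identical row and column gene labels",
         call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", g), collapse = "\t"), con)
  for (i in seq_len(nrow(vals)))
    writeLines(paste(c(g[i], format_full(vals[i, ])), collapse = "\t"), con)
  invisible(path)
}

#' Read a matrix written by [write_coloc_matrix()]
#'
#' Genes keep the file's order; values (including `NA` tokens) are restored to
#' full precision.
#'
#' @param path Path to the TSV.
#' @return A labelled numeric matrix.
#' @export
read_coloc_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("matrix file must have a header and at least one row", call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  genes <- header[-1L]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  rn <- vapply(rows, `[[`, character(1), 1L)
  vals <- t(vapply(rows, function(r) {
    v <- r[-1L]
    num <- suppressWarnings(as.numeric(v))
    bad <- is.na(num) & v != "NA"
    if (any(bad))
      stop("non-numeric matrix value(s): ",
           paste(utils::head(v[bad], 5L), collapse = ", "), call. = FALSE)
    num
  }, numeric(length(genes))))
  if (length(genes) == 1L) vals <- matrix(vals, ncol = 1L)
  dimnames(vals) <- list(rn, genes)
  if (!identical(rn, genes))
    stop("row labels do not match column labels", call. = FALSE)
  vals
}

#' Long-format export of a score matrix
#'
#' Flattens a square score matrix into `(gene_a, gene_b, score)` rows for
#' plotting tools, preserving panel order (row-major).
#'
#' @param m A matrix-like object with gene labels.
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `score`.
#' @export
coloc_long <- function(m) {
  vals <- as.matrix(m)
  g <- rownames(vals)
  data.frame(gene_a = rep(g, each = ncol(vals)),
             gene_b = rep(colnames(vals), times = nrow(vals)),
             score = as.vector(t(vals)),
             stringsAsFactors = FALSE)
}
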
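# Pairwise transcript co-localization scoring for in-situ (MERFISH/MERSCOPE)
# detected-transcript tables.
#
# Counting semantics, documented prominently because it is what makes the
# matrix asymmetric: the entry (A, B) counts transcripts of the SOURCE gene A
# that have at least one transcript of the PARTNER gene B strictly within the
# radius and in a different cell. A source transcript close to many partners
# still counts once (the unique-interaction rule). The score is then
# normalized as 2 * count / (n_A + n_B), which lies in [0, 1] whenever
# n_source <= n_partner but can exceed 1 otherwise; values are reported
# unclamped with a warning.

#' Co-localization scoring parameters
#'
#' @param radius Close-distance threshold in micrometres (default 30, the
#'   scale at which a disc covers a handful of cells). The comparison is
#'   strict: pairs at exactly `radius` are NOT close.
#' @param same_cell_exclusion Exclude transcript pairs sharing a cell ID
#'   (default `TRUE`); only transcripts originating from different cells are
#'   biologically informative for cross-cell proximity.
#' @param unassigned_policy How to treat transcripts with no cell identity:
#'   `"distinct"` (default) treats each unassigned transcript as its own
#'   singleton cell, so it is never removed by the same-cell rule;
#'   `"drop"` removes unassigned transcripts before scoring (they then do not
#'   contribute to per-gene totals either).
#' @param include_diagonal Compute the (A, A) diagonal (with self-pairing
#'   forbidden; default `TRUE`). When `FALSE` the diagonal is `NA`.
#' @return A list of class `"coloc_params"`.
#' @export
coloc_params <- function(radius = 30,
                         same_cell_exclusion = TRUE,
                         unassigned_policy = c("distinct", "drop"),
                         include_diagonal = TRUE) {
  check_scalar_number(radius, "radius", min = 0, strict_min = TRUE)
  unassigned_policy <- match.arg(unassigned_policy)
  structure(list(radius = radius,
                 same_cell_exclusion = isTRUE(same_cell_exclusion),
                 unassigned_policy = unassigned_policy,
                 include_diagonal = isTRUE(include_diagonal)),
            class = "coloc_params")
}

# Apply the unassigned-transcript policy to a table.
apply_unassigned_policy <- function(table, params) {
  if (params$unassigned_policy == "drop" && anyNA(table$cell_id))
    table <- table[!is.na(table$cell_id), , drop = FALSE]
  table
}

# TRUE for pairs excluded by the same-cell rule. Unassigned (NA) cells are
# singleton cells: never equal to anything, including another NA.
same_cell <- function(ca, cb) {
  out <- !is.na(ca) & !is.na(cb) & ca == cb
  out
}

#' Count source transcripts close to a partner gene
#'
#' Counts transcripts of `source_gene` having at least one transcript of
#' `partner_gene` at Euclidean distance strictly below `params$radius` and in
#' a different cell. Each source transcript contributes at most one count
#' however many close partners it has; when `source_gene == partner_gene` a
#' transcript is never its own partner.
#'
#' @param source_gene,partner_gene Gene names.
#' @param table A [transcript_table()].
#' @param params A [coloc_params()].
#' @param panel Optional [gene_panel()]; when supplied, both genes must
#'   belong to it (genes absent from the table then simply have zero
#'   transcripts).
#' @return Integer count.
#' @examples
#' tb <- transcript_table(c("A", "B", "B"), c(0, 10, 12), c(0, 0, 0),
#'                        cell_id = c(1, 2, 2))
#' close_count("A", "B", tb)  # 1: one source transcript, counted once
#' @export
close_count <- function(source_gene, partner_gene, table,
                        params = coloc_params(), panel = NULL) {
  stopifnot(inherits(params, "coloc_params"))
  if (!is.null(panel)) {
    panel <- as_panel(panel)
    unknown <- setdiff(c(source_gene, partner_gene), panel)
    if (length(unknown))
      stop("unknown gene(s) not in panel: ", paste(unknown, collapse = ", "),
           call. = FALSE)
  }
  table <- apply_unassigned_policy(table, params)
  ia <- which(table$gene == source_gene)
  ib <- which(table$gene == partner_gene)
  if (length(ia) == 0L || length(ib) == 0L) return(0L)
  r2 <- params$radius^2
  d2 <- outer(table$x[ia], table$x[ib], "-")^2 +
        outer(table$y[ia], table$y[ib], "-")^2
  ok <- d2 < r2
  if (params$same_cell_exclusion)
    ok <- ok & !outer(table$cell_id[ia], table$cell_id[ib], same_cell)
  if (source_gene == partner_gene)
    ok[cbind(seq_along(ia), seq_along(ib))] <- FALSE
  sum(rowSums(ok) > 0L)
}

#' Normalized co-localization score of one gene pair
#'
#' `2 * close_count / (n_source + n_partner)`; `NA` when both genes have zero
#' transcripts (under the chosen unassigned policy). The score is asymmetric
#' in its arguments because of the unique-interaction counting rule.
#'
#' @inheritParams close_count
#' @return A numeric score, or `NA` if both genes are absent.
#' @examples
#' tb <- transcript_table(c("A", "A", "B", "B"), c(0, 100, 10, 200),
#'                        c(0, 0, 0, 0), cell_id = c(1, 2, 2, 3))
#' coloc_score("A", "B", tb)  # 2 * 1 / 4 = 0.5
#' @export
coloc_score <- function(source_gene, partner_gene, table,
                        params = coloc_params(), panel = NULL) {
  tb <- apply_unassigned_policy(table, params)
  n_a <- sum(tb$gene == source_gene)
  n_b <- sum(tb$gene == partner_gene)
  if (source_gene == partner_gene) n_b <- n_a
  denom <- if (source_gene == partner_gene) 2L * n_a else n_a + n_b
  if (denom == 0L) return(NA_real_)
  cc <- close_count(source_gene, partner_gene, table, params, panel)
  2 * cc / denom
}

# Enumerate all ordered transcript pairs (i, j), i != j, at distance < r,
# using a uniform grid of bin side r so only the 3 x 3 neighbourhood of each
# occupied bin is scanned. Returns integer index vectors i, j.
find_near_pairs <- function(x, y, r) {
  n <- length(x)
  if (n < 2L) return(list(i = integer(0), j = integer(0)))
  gx <- floor(x / r); gx <- gx - min(gx)
  gy <- floor(y / r); gy <- gy - min(gy)
  stride <- max(gx) + 2  # > max column index + 1: row keys cannot alias
  key <- gy * stride + gx
  bucket <- split(seq_len(n), key)
  uk <- as.numeric(names(bucket))
  n_cells <- length(uk)
  # For each occupied bin, positions (into `bucket`) of its 9 neighbours.
  nbr <- matrix(NA_integer_, n_cells, 9L)
  k <- 0L
  for (dy in -1:1) for (dx in -1:1) {
    k <- k + 1L
    nbr[, k] <- match(uk + dy * stride + dx, uk)
  }
  r2 <- r * r
  res_i <- vector("list", n_cells)
  res_j <- vector("list", n_cells)
  for (t in seq_len(n_cells)) {
    ii <- bucket[[t]]
    nb <- nbr[t, ]
    jj <- unlist(bucket[nb[!is.na(nb)]], use.names = FALSE)
    d2 <- outer(x[ii], x[jj], "-")^2 + outer(y[ii], y[jj], "-")^2
    hit <- which(d2 < r2)
    if (length(hit)) {
      ai <- ii[(hit - 1L) %% length(ii) + 1L]
      bj <- jj[(hit - 1L) %/% length(ii) + 1L]
      keep <- ai != bj
      res_i[[t]] <- ai[keep]
      res_j[[t]] <- bj[keep]
    }
  }
  list(i = unlist(res_i, use.names = FALSE) %||% integer(0),
       j = unlist(res_j, use.names = FALSE) %||% integer(0))
}

# Close-count matrix for one section: C[a, b] = number of transcripts of gene
# a with >= 1 close transcript of gene b in another cell. G = panel size.
section_counts <- function(table, gene_idx, params, G) {
  pr <- find_near_pairs(table$x, table$y, params$radius)
  i <- pr$i; j <- pr$j
  if (length(i) && params$same_cell_exclusion) {
    keep <- !same_cell(table$cell_id[i], table$cell_id[j])
    i <- i[keep]; j <- j[keep]
  }
  if (length(i)) {
    # unique (source transcript, partner gene) combinations
    u <- (i - 1) * G + gene_idx[j]
    first <- !duplicated(u)
    code <- (gene_idx[i][first] - 1L) * G + gene_idx[j][first]
    C <- matrix(tabulate(code, nbins = G * G), nrow = G, byrow = TRUE)
  } else {
    C <- matrix(0L, G, G)
  }
  C
}

#' Gene-by-gene co-localization matrix
#'
#' Computes the full asymmetric matrix of normalized co-localization scores
#' over an ordered gene panel: entry (i, j) is [coloc_score()] with gene i as
#' source and gene j as partner. Internally a fixed-radius grid index makes
#' the run subquadratic in transcript count; the result is identical to the
#' all-pairs brute force.
#'
#' If the table carries a `section` column with several sections, scores are
#' combined across sections: `combine = "pooled"` (default) sums close counts
#' and per-gene totals before normalizing; `combine = "mean"` averages the
#' per-section score matrices (propagating `NA`).
#'
#' @param table A [transcript_table()].
#' @param panel A [gene_panel()] fixing row/column order; defaults to the
#'   table's genes in first-seen order. Transcripts of genes outside an
#'   explicit panel are dropped with a message.
#' @param params A [coloc_params()].
#' @param combine Cross-section combination rule (see above).
#' @param condition Optional condition label stored in the provenance.
#' @return An object of class `"coloc_matrix"`: a list with elements
#'   `values` (labelled numeric matrix, `NA` where both genes have zero
#'   transcripts), `panel`, `n_per_gene`, `params`, `provenance`.
#' @export
coloc_matrix <- function(table, panel = NULL, params = coloc_params(),
                         combine = c("pooled", "mean"), condition = NULL) {
  stopifnot(inherits(params, "coloc_params"))
  combine <- match.arg(combine)
  if (is.null(panel)) {
    if (nrow(table) == 0L)
      stop("empty table and no panel: nothing to score", call. = FALSE)
    panel <- gene_panel(unique(table$gene))
  } else {
    panel <- as_panel(panel)
    extra <- !(table$gene %in% panel)
    if (any(extra)) {
      message("coloc_matrix: dropping ", sum(extra),
              " transcript(s) of genes outside the panel")
      table <- table[!extra, , drop = FALSE]
    }
  }
  if (length(panel) == 0L) stop("empty gene panel", call. = FALSE)
  table <- apply_unassigned_policy(table, params)
  G <- length(panel)
  gene_idx <- match(table$gene, panel)

  sections <- if (!is.null(table$section)) unique(table$section) else "all"
  per_sec <- lapply(sections, function(s) {
    tb <- if (identical(sections, "all")) table
          else table[table$section == s, , drop = FALSE]
    gi <- match(tb$gene, panel)
    list(C = section_counts(tb, gi, params, G),
         n = tabulate(gi, nbins = G))
  })

  if (combine == "pooled" || length(per_sec) == 1L) {
    C <- Reduce(`+`, lapply(per_sec, `[[`, "C"))
    n <- Reduce(`+`, lapply(per_sec, `[[`, "n"))
    denom <- outer(n, n, "+")
    S <- 2 * C / denom
    S[denom == 0] <- NA_real_
  } else {
    mats <- lapply(per_sec, function(p) {
      denom <- outer(p$n, p$n, "+")
      m <- 2 * p$C / denom
      m[denom == 0] <- NA_real_
      m
    })
    S <- Reduce(`+`, mats) / length(mats)
    n <- Reduce(`+`, lapply(per_sec, `[[`, "n"))
  }
  if (!params$include_diagonal) diag(S) <- NA_real_
  dimnames(S) <- list(as.character(panel), as.character(panel))
  names(n) <- as.character(panel)
  if (any(S > 1, na.rm = TRUE))
    warning("some scores exceed 1 (possible when a source gene has many ",
            "more transcripts than its partner); values are reported ",
            "unclamped", call. = FALSE)
  structure(list(values = S, panel = panel, n_per_gene = n, params = params,
                 provenance = list(condition = condition,
                                   combine = combine,
                                   sections = sections)),
            class = "coloc_matrix")
}

#' @export
as.matrix.coloc_matrix <- function(x, ...) x$values

#' @export
print.coloc_matrix <- function(x, ...) {
  G <- length(x$panel)
  cat("Co-localization matrix:", G, "x", G, "genes,",
      sum(x$n_per_gene), "transcripts\n")
  cat("  radius:", x$params$radius, "µm (strict); same-cell exclusion:",
      x$params$same_cell_exclusion, "\n")
  if (!is.null(x$provenance$condition))
    cat("  condition:", x$provenance$condition, "\n")
  rng <- range(x$values, na.rm = TRUE)
  cat("  score range: [", format(rng[1], digits = 4), ", ",
      format(rng[2], digits = 4), "], NA entries: ",
      sum(is.na(x$values)), "\n", sep = "")
  invisible(x)
}

#' Differential co-localization matrix between two conditions
#'
#' Elementwise `case - control`, propagating `NA`. The sign convention —
#' positive entries mean the gene pair is closer (higher co-localization) in
#' the case condition — is stored in the result's metadata.
#'
#' @param case,control [coloc_matrix()] objects over identical panels and
#'   parameters.
#' @return An object of class `"coloc_diff"` with elements `values`, `panel`,
#'   `case`, `control`, `sign_convention`.
#' @export
differential_matrix <- function(case, control) {
  stopifnot(inherits(case, "coloc_matrix"), inherits(control, "coloc_matrix"))
  if (!identical(as.character(case$panel), as.character(control$panel))) {
    only_case <- setdiff(case$panel, control$panel)
    only_ctrl <- setdiff(control$panel, case$panel)
    stop("panel mismatch between case and control; only in case: {",
         paste(only_case, collapse = ", "), "}; only in control: {",
         paste(only_ctrl, collapse = ", "), "}",
         if (!length(only_case) && !length(only_ctrl))
           " (same genes, different order)" else "",
         call. = FALSE)
  }
  if (!identical(case$params, control$params))
    stop("case and control were scored with different parameters",
         call. = FALSE)
  structure(list(values = case$values - control$values,
                 panel = case$panel,
                 case = case$provenance$condition %||% "case",
                 control = control$provenance$condition %||% "control",
                 sign_convention =
                   "case - control; positive = higher co-localization in case"),
            class = "coloc_diff")
}

#' @export
as.matrix.coloc_diff <- function(x, ...) x$values

#' @export
print.coloc_diff <- function(x, ...) {
  cat("Differential co-localization matrix (", x$case, " - ", x$control,
      ")\n", sep = "")
  cat("  ", x$sign_convention, "\n", sep = "")
  rng <- range(x$values, na.rm = TRUE)
  cat("  range: [", format(rng[1], digits = 4), ", ",
      format(rng[2], digits = 4), "]\n", sep = "")
  invisible(x)
}

#' Slice a differential matrix to a gene subset and draw a heatmap
#'
#' Selects the rows/columns of `gene_subset` (in the given order) and renders
#' a heatmap with a diverging palette centered at 0, the natural display for
#' condition differences. Also works on a plain [coloc_matrix()].
#'
#' @param diff A `"coloc_diff"` or `"coloc_matrix"`.
#' @param gene_subset Character vector of panel genes (non-empty).
#' @param file Optional PNG path; when given the heatmap is written there,
#'   otherwise it is drawn on the active device.
#' @param draw Set `FALSE` to skip plotting and only return the slice.
#' @return The sliced labelled matrix, invisibly when drawn.
#' @export
subset_heatmap <- function(diff, gene_subset, file = NULL, draw = TRUE) {
  vals <- as.matrix(diff)
  if (length(gene_subset) == 0L)
    stop("empty gene subset", call. = FALSE)
  unknown <- setdiff(gene_subset, rownames(vals))
  if (length(unknown))
    stop("unknown gene(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  sl <- vals[gene_subset, gene_subset, drop = FALSE]
  if (draw) {
    if (!is.null(file)) {
      grDevices::png(file, width = 900, height = 800)
      on.exit(grDevices::dev.off())
    }
    draw_diverging_heatmap(sl, main = if (inherits(diff, "coloc_diff"))
      paste0("Differential co-localization (", diff$case, " - ",
             diff$control, ")") else "Co-localization score")
  }
  invisible(sl)
}

# Base-graphics diverging heatmap centered at 0 (blue-white-red).
draw_diverging_heatmap <- function(m, main = "") {
  lim <- max(abs(m), na.rm = TRUE)
  if (!is.finite(lim) || lim == 0) lim <- 1
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  n <- nrow(m)
  op <- graphics::par(mar = c(6, 6, 3, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(n), seq_len(n), t(m[n:1, , drop = FALSE]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(n), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(m)), las = 2,
                 cex.axis = 0.7)
  invisible(NULL)
}

#' @export
plot.coloc_diff <- function(x, genes = x$panel, ...) {
  subset_heatmap(x, genes)
}

#' @export
plot.coloc_matrix <- function(x, genes = x$panel, ...) {
  subset_heatmap(x, genes)
}
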
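# Neoantigen candidate selection: consensus filtering of variant call sets,
# integration of epitope-predictor scores with expression, filter-then-sort
# ranking, top-N selection, and chimeric construct assembly with
# junction-epitope minimization. The epitope predictors themselves are
# consumed as score tables, never executed; a deterministic mock junction
# scorer is bundled for tests and examples.

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Consensus filter over four variant call sets
#'
#' Keeps missense variants detected (by chrom/pos/ref/alt identity, 1-based
#' coordinates as in VCF) in at least `min_sets` of the four datasets
#' (WES and RNA from in vivo and in vitro samples). Variants flagged as
#' germline in any set are removed first: the matched control sample serves
#' as a germline reference and its variants never enter the candidate pool.
#'
#' @param sets A list of exactly 4 variant `data.frame`s, each with columns
#'   `chrom`, `pos`, `ref`, `alt`, `effect` and optionally `is_germline`.
#' @param min_sets Minimal dataset occupancy (default 3).
#' @return A `data.frame` of surviving variants (one row each) with an
#'   `n_sets` column giving their dataset occupancy.
#' @export
consensus_filter <- function(sets, min_sets = 3L) {
  if (!is.list(sets) || length(sets) != 4L)
    stop("exactly 4 variant call sets are required (got ",
         length(sets), ")", call. = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "effect")
  for (s in sets)
    if (!all(need %in% names(s)))
      stop("variant set missing column(s): ",
           paste(setdiff(need, names(s)), collapse = ", "), call. = FALSE)
  all_v <- do.call(rbind, lapply(sets, function(s)
    s[, c(need, intersect("is_germline", names(s))), drop = FALSE]))
  if (is.null(all_v$is_germline)) all_v$is_germline <- FALSE
  all_v$is_germline[is.na(all_v$is_germline)] <- FALSE
  key <- variant_key(all_v)

  germline_keys <- unique(key[all_v$is_germline])
  occupancy <- lapply(sets, function(s) unique(variant_key(s)))
  counts <- table(unlist(occupancy))

  first <- !duplicated(key)
  out <- all_v[first, , drop = FALSE]
  out$n_sets <- as.integer(counts[variant_key(out)])
  keep <- out$effect == "missense" &
    out$n_sets >= min_sets &
    !(variant_key(out) %in% germline_keys)
  out <- out[keep, setdiff(names(out), "is_germline"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Integrate predictor scores and expression into candidates
#'
#' Joins the outputs of the two epitope-prediction pipelines to the surviving
#' variants and attaches gene expression. Candidates reported by both
#' pipelines are deduplicated by (peptide, allele), keeping the better
#' (lower) predicted affinity; the `provenance` column records which
#' pipeline(s) reported each candidate. Candidates whose gene is absent from
#' the expression table get TPM 0.
#'
#' @param variants Output of [consensus_filter()] (or any `data.frame` with
#'   `chrom`, `pos`, `ref`, `alt`).
#' @param predictor_tables List of 2 score `data.frame`s with columns
#'   `peptide`, `allele`, `chrom`, `pos`, `ref`, `alt`, `gene`,
#'   `affinity_nM`, `agretopicity`, `foreignness`.
#' @param expression `data.frame` with columns `gene`, `tpm`.
#' @return Candidate `data.frame` with the four selection criteria
#'   (`affinity_nM`, `tpm`, `agretopicity`, `foreignness`) per peptide.
#' @export
integrate_scores <- function(variants, predictor_tables, expression) {
  if (length(predictor_tables) != 2L)
    stop("exactly 2 predictor tables are required", call. = FALSE)
  need <- c("peptide", "allele", "chrom", "pos", "ref", "alt", "gene",
            "affinity_nM", "agretopicity", "foreignness")
  nms <- names(predictor_tables) %||% c("predictor1", "predictor2")
  if (is.null(names(predictor_tables))) names(predictor_tables) <- nms
  rows <- list()
  for (pn in names(predictor_tables)) {
    tab <- predictor_tables[[pn]]
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop("predictor table '", pn, "' missing column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    bad <- which(!is.finite(tab$affinity_nM) | tab$affinity_nM <= 0 |
                   !is.finite(tab$agretopicity) | tab$agretopicity <= 0)
    if (length(bad))
      stop("malformed score row(s) in '", pn, "': ",
           paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
    tab$provenance <- pn
    rows[[pn]] <- tab[, c(need, "provenance"), drop = FALSE]
  }
  cand <- do.call(rbind, rows)
  cand <- cand[variant_key(cand) %in% variant_key(variants), , drop = FALSE]
  if (nrow(cand) == 0L) {
    cand$tpm <- numeric(0)
    rownames(cand) <- NULL
    return(cand)
  }
  # dedup by (peptide, allele): keep the lower affinity, merge provenance
  dk <- paste(cand$peptide, cand$allele, sep = "|")
  ord <- order(dk, cand$affinity_nM)
  cand <- cand[ord, , drop = FALSE]
  dk <- dk[ord]
  prov <- tapply(cand$provenance, dk, function(p)
    paste(sort(unique(p)), collapse = "+"))
  first <- !duplicated(dk)
  out <- cand[first, , drop = FALSE]
  out$provenance <- as.character(prov[dk[first]])
  tpm <- expression$tpm[match(out$gene, expression$gene)]
  out$tpm <- ifelse(is.na(tpm), 0, tpm)
  rownames(out) <- NULL
  out
}

#' Ranking policy configuration
#'
#' Hard filters followed by a configurable multi-key sort. Defaults: keep
#' candidates with predicted MHC-I affinity at most `affinity_max` nM,
#' expression strictly above `tpm_min` TPM, agretopicity at least `agre_min`
#' (mutant binds at least as well as wild type) and foreignness at least
#' `foreign_min`; then sort ascending by affinity, breaking ties by
#' descending TPM, descending foreignness and finally alphabetical peptide.
#'
#' @param affinity_max Maximum predicted affinity in nM (default 500, the
#'   conventional weak-binder cutoff).
#' @param tpm_min Expression must be strictly greater than this (default 0:
#'   unexpressed genes are excluded).
#' @param agre_min Minimal agretopicity (default 1).
#' @param foreign_min Minimal foreignness (default 0).
#' @param sort_keys Sort key order; any permutation/subset of
#'   `"affinity"` (ascending), `"tpm"`, `"foreignness"`, `"agretopicity"`
#'   (each descending), `"peptide"` (alphabetical).
#' @return A list of class `"rank_config"`.
#' @export
rank_config <- function(affinity_max = 500, tpm_min = 0, agre_min = 1,
                        foreign_min = 0,
                        sort_keys = c("affinity", "tpm", "foreignness",
                                      "peptide")) {
  check_scalar_number(affinity_max, "affinity_max", min = 0,
                      strict_min = TRUE)
  check_scalar_number(tpm_min, "tpm_min", min = 0)
  check_scalar_number(agre_min, "agre_min", min = 0)
  check_scalar_number(foreign_min, "foreign_min", min = 0)
  ok <- c("affinity", "tpm", "foreignness", "agretopicity", "peptide")
  if (!length(sort_keys) || !all(sort_keys %in% ok))
    stop_config("sort_keys must be drawn from: %s", paste(ok, collapse = ", "))
  structure(list(affinity_max = affinity_max, tpm_min = tpm_min,
                 agre_min = agre_min, foreign_min = foreign_min,
                 sort_keys = sort_keys),
            class = "rank_config")
}

#' Filter and rank neoantigen candidates
#'
#' Applies the hard filters of a [rank_config()] then sorts by its keys. The
#' output is a permutation of the filtered input; the sort is stable.
#'
#' @param candidates Output of [integrate_scores()].
#' @param config A [rank_config()].
#' @return The filtered candidates in rank order.
#' @export
rank_candidates <- function(candidates, config = rank_config()) {
  stopifnot(inherits(config, "rank_config"))
  if (nrow(candidates) == 0L) return(candidates)
  keep <- candidates$affinity_nM <= config$affinity_max &
    candidates$tpm > config$tpm_min &
    candidates$agretopicity >= config$agre_min &
    candidates$foreignness >= config$foreign_min
  out <- candidates[keep, , drop = FALSE]
  if (nrow(out) == 0L) return(out)
  keycols <- lapply(config$sort_keys, function(k)
    switch(k,
           affinity = out$affinity_nM,
           tpm = -out$tpm,
           foreignness = -out$foreignness,
           agretopicity = -out$agretopicity,
           peptide = out$peptide))
  out <- out[do.call(order, keycols), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the top candidates
#'
#' @param ranked Output of [rank_candidates()].
#' @param n Number of peptides to keep (default 33, a typical payload for a
#'   single chimeric antigen construct).
#' @return Character vector of the first `min(n, nrow(ranked))` peptides.
#' @export
select_top <- function(ranked, n = 33L) {
  check_scalar_number(n, "n", min = 1)
  utils::head(ranked$peptide, n)
}

#' Deterministic mock junction scorer
#'
#' A stand-in for an MHC-binding predictor used by tests and examples:
#' maps any peptide to a reproducible pseudo-random affinity in (1, 50000]
#' nM via a polynomial string hash. Lower values mean stronger predicted
#' binding, as for real predictors.
#'
#' @param seed Integer mixed into the hash, so different "predictors" can be
#'   emulated.
#' @return A function `character vector -> numeric affinities (nM)`.
#' @export
mock_junction_scorer <- function(seed = 0L) {
  seed <- as.integer(seed)
  function(peptides) {
    vapply(peptides, function(p) {
      h <- (seed %% 1048573) + 1
      for (ch in utf8ToInt(p)) h <- (h * 131 + ch) %% 1048573
      1 + 49999 * (h / 1048573)
    }, numeric(1), USE.NAMES = FALSE)
  }
}

# All 8-11-mers spanning the junction between two peptides joined by a
# linker: k-mers of left||linker||right not wholly contained in either
# peptide (so every reported k-mer is a sequence novel to the construct).
junction_kmers <- function(left, linker, right, k_range = 8:11) {
  s <- paste0(left, linker, right)
  L <- nchar(left); lam <- nchar(linker); n <- nchar(s)
  out <- character(0)
  for (k in k_range) {
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    ends <- starts + k - 1L
    spanning <- !(ends <= L) & !(starts >= L + lam + 1L)
    out <- c(out, substring(s, starts[spanning], ends[spanning]))
  }
  unique(out)
}

# Weakest-binder value of one ordered junction: the minimum (strongest,
# lowest-nM) affinity over its spanning k-mers. The assembly objective is to
# make this as LARGE (weak) as possible at every junction.
junction_value <- function(left, right, linker, scorer) {
  kmers <- junction_kmers(left, linker, right)
  if (length(kmers) == 0L) return(Inf)
  min(scorer(kmers))
}

# Objective of a full ordering: the minimum junction value along the chain
# (the strongest junction epitope anywhere in the construct).
order_objective <- function(peps, linker, scorer) {
  if (length(peps) < 2L) return(Inf)
  vals <- vapply(seq_len(length(peps) - 1L), function(i)
    junction_value(peps[i], peps[i + 1L], linker, scorer), numeric(1))
  min(vals)
}

# Exact search: the permutation maximizing the bottleneck junction value;
# ties broken by lexicographically smallest peptide order.
assemble_exact <- function(peptides, linker, scorer) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- NULL; best_val <- -Inf
  for (p in perms(sort(peptides))) {
    val <- order_objective(p, linker, scorer)
    if (val > best_val) { best_val <- val; best <- p }
  }
  best
}

# Greedy chain heuristic: start from the ordered pair with the weakest
# (highest-nM) junction, then extend at either end, each time choosing the
# extension whose new junction is weakest; ties by alphabetical peptide,
# front before back.
assemble_greedy <- function(peptides, linker, scorer) {
  peps <- sort(peptides)
  n <- length(peps)
  if (n <= 2L) return(assemble_exact(peps, linker, scorer))
  jv <- matrix(NA_real_, n, n, dimnames = list(peps, peps))
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    jv[i, j] <- junction_value(peps[i], peps[j], linker, scorer)
  best <- which(jv == max(jv, na.rm = TRUE), arr.ind = TRUE)[1L, ]
  chain <- c(peps[best[1L]], peps[best[2L]])
  remaining <- setdiff(peps, chain)
  while (length(remaining)) {
    front_vals <- vapply(remaining, function(p)
      junction_value(p, chain[1L], linker, scorer), numeric(1))
    back_vals <- vapply(remaining, function(p)
      junction_value(chain[length(chain)], p, linker, scorer), numeric(1))
    bf <- max(front_vals); bb <- max(back_vals)
    if (bf >= bb) {
      p <- remaining[which.max(front_vals)]
      chain <- c(p, chain)
    } else {
      p <- remaining[which.max(back_vals)]
      chain <- c(chain, p)
    }
    remaining <- setdiff(remaining, p)
  }
  chain
}

#' Assemble a chimeric polyepitope construct
#'
#' Orders the selected peptides and joins them with linker sequences so that
#' the strongest predicted MHC-binding k-mer spanning any junction is as weak
#' as possible (junction epitopes are assembly artifacts one wants to avoid
#' immunizing against). For up to 7 peptides the exact bottleneck-optimal
#' order is found by exhaustive search; beyond that a greedy chain heuristic
#' is used (start from the pair with the weakest junction, extend at either
#' end). The construct is reported fused downstream of a leader moiety (by
#' default the CD74 invariant chain, carried as metadata).
#'
#' @param peptides Character vector of peptide sequences (at least 1).
#' @param linker Linker placed between consecutive peptides (default
#'   `"GGSGG"`).
#' @param junction_scorer Function mapping peptides to predicted affinities
#'   in nM; default [mock_junction_scorer()].
#' @param leader Leader amino-acid sequence prepended to the construct
#'   (default empty; the leader identity is metadata).
#' @param leader_label Name of the leader moiety (default `"CD74"`).
#' @param method `"auto"` (exact up to 7 peptides, greedy beyond), `"exact"`
#'   or `"greedy"`.
#' @return An object of class `"chimeric_construct"`: ordered `peptides`,
#'   `linker`, `leader`, `leader_label`, full `sequence`, `junction_report`
#'   (one row per junction-spanning 8-11-mer with its predicted affinity)
#'   and `objective` (the minimal junction affinity, nM).
#' @export
assemble_construct <- function(peptides, linker = "GGSGG",
                               junction_scorer = mock_junction_scorer(),
                               leader = "", leader_label = "CD74",
                               method = c("auto", "exact", "greedy")) {
  method <- match.arg(method)
  if (length(peptides) == 0L)
    stop("at least one peptide is required", call. = FALSE)
  peptides <- as.character(peptides)
  if (anyDuplicated(peptides))
    stop("duplicated peptides in construct", call. = FALSE)
  ordered <- if (length(peptides) == 1L) peptides
  else switch(method,
              exact = assemble_exact(peptides, linker, junction_scorer),
              greedy = assemble_greedy(peptides, linker, junction_scorer),
              auto = if (length(peptides) <= 7L)
                assemble_exact(peptides, linker, junction_scorer)
              else assemble_greedy(peptides, linker, junction_scorer))
  sequence <- paste0(leader, paste(ordered, collapse = linker))
  report <- NULL
  if (length(ordered) > 1L) {
    rows <- lapply(seq_len(length(ordered) - 1L), function(i) {
      kmers <- junction_kmers(ordered[i], linker, ordered[i + 1L])
      data.frame(junction = i, left = ordered[i], right = ordered[i + 1L],
                 kmer = kmers, affinity_nM = junction_scorer(kmers),
                 stringsAsFactors = FALSE)
    })
    report <- do.call(rbind, rows)
  } else {
    report <- data.frame(junction = integer(0), left = character(0),
                         right = character(0), kmer = character(0),
                         affinity_nM = numeric(0), stringsAsFactors = FALSE)
  }
  structure(list(peptides = ordered, linker = linker, leader = leader,
                 leader_label = leader_label, sequence = sequence,
                 junction_report = report,
                 objective = if (nrow(report)) {
                   min(vapply(split(report$affinity_nM, report$junction),
                              min, numeric(1)))
                 } else Inf,
                 method = method),
            class = "chimeric_construct")
}

#' @export
print.chimeric_construct <- function(x, ...) {
  cat("Chimeric construct:", length(x$peptides), "peptide(s), linker '",
      x$linker, "', leader: ", x$leader_label, "\n", sep = "")
  cat("  sequence length:", nchar(x$sequence), "aa\n")
  if (is.finite(x$objective))
    cat("  weakest-junction objective (min junction k-mer affinity):",
        format(x$objective, digits = 5), "nM\n")
  invisible(x)
}

#' Write a construct as FASTA
#'
#' @param construct A [assemble_construct()] result.
#' @param path Output file.
#' @param name Sequence header (default built from the leader label and
#'   peptide count).
#' @export
write_construct_fasta <- function(construct, path, name = NULL) {
  stopifnot(inherits(construct, "chimeric_construct"))
  name <- name %||% sprintf("%s_chimeric_%dpep", construct$leader_label,
                            length(construct$peptides))
  seq <- construct$sequence
  lines <- c(paste0(">", name),
             substring(seq, seq(1, nchar(seq), 60),
                       pmin(seq(60, nchar(seq) + 59, 60), nchar(seq))))
  writeLines(lines, path)
  invisible(path)
}
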
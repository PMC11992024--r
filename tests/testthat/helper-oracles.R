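# Independent reference implementations used as oracles. These deliberately
# share no code with the package: plain distance matrices, naive permutation
# loops, explicit pairwise comparators.

# All-pairs brute-force co-localization matrix (quadratic, no spatial index).
brute_coloc_matrix <- function(tb, panel, radius = 30,
                               same_cell_exclusion = TRUE,
                               drop_unassigned = FALSE) {
  if (drop_unassigned) tb <- tb[!is.na(tb$cell_id), , drop = FALSE]
  G <- length(panel)
  S <- matrix(NA_real_, G, G, dimnames = list(panel, panel))
  n <- nrow(tb)
  d2 <- outer(tb$x, tb$x, "-")^2 + outer(tb$y, tb$y, "-")^2
  close <- d2 < radius^2
  if (same_cell_exclusion && n > 0) {
    cs <- outer(tb$cell_id, tb$cell_id,
                function(u, v) !is.na(u) & !is.na(v) & u == v)
    close <- close & !cs
  }
  diag(close) <- FALSE  # a transcript is never its own partner
  for (a in seq_len(G)) for (b in seq_len(G)) {
    ia <- which(tb$gene == panel[a])
    ib <- which(tb$gene == panel[b])
    na <- length(ia); nb <- length(ib)
    denom <- if (a == b) 2L * na else na + nb
    if (denom == 0L) next
    cnt <- sum(vapply(ia, function(i) any(close[i, ib]), logical(1)))
    S[a, b] <- 2 * cnt / denom
  }
  S
}

# Random transcript table for oracle-equivalence checks.
random_table <- function(seed, n_max = 2000, n_genes = 8, field = 400,
                         unassigned_frac = 0.05) {
  set.seed(seed)
  n <- sample.int(n_max, 1L)
  cell <- sprintf("c%d", sample.int(200L, n, replace = TRUE))
  cell[runif(n) < unassigned_frac] <- NA
  transcript_table(gene = sprintf("g%03d", sample.int(n_genes, n, TRUE)),
                   x = runif(n, 0, field), y = runif(n, 0, field),
                   cell_id = cell)
}

# Naive exhaustive construct-ordering oracle: enumerate every permutation,
# maximize the minimal junction k-mer affinity, break ties by the
# lexicographically smallest peptide sequence.
oracle_best_order <- function(peptides, linker, scorer) {
  junc_val <- function(l, r) {
    s <- paste0(l, linker, r)
    L <- nchar(l); lam <- nchar(linker); n <- nchar(s)
    kmers <- character(0)
    for (k in 8:11) {
      if (n < k) next
      for (st in seq_len(n - k + 1L)) {
        en <- st + k - 1L
        if (!(en <= L) && !(st >= L + lam + 1L))
          kmers <- c(kmers, substr(s, st, en))
      }
    }
    kmers <- unique(kmers)
    if (!length(kmers)) Inf else min(scorer(kmers))
  }
  all_perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(all_perms(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; best_val <- -Inf
  for (p in all_perms(sort(peptides))) {
    vals <- vapply(seq_len(length(p) - 1L),
                   function(i) junc_val(p[i], p[i + 1L]), numeric(1))
    v <- min(vals)
    if (v > best_val) { best_val <- v; best <- p }
  }
  list(order = best, value = best_val)
}

# Selection-sort candidate ranking with an explicit pairwise comparator
# (default policy: affinity asc, then tpm desc, foreignness desc, peptide).
oracle_rank <- function(cand) {
  keep <- cand$affinity_nM <= 500 & cand$tpm > 0 &
    cand$agretopicity >= 1 & cand$foreignness >= 0
  cand <- cand[keep, , drop = FALSE]
  lt <- function(i, j) {
    if (cand$affinity_nM[i] != cand$affinity_nM[j])
      return(cand$affinity_nM[i] < cand$affinity_nM[j])
    if (cand$tpm[i] != cand$tpm[j]) return(cand$tpm[i] > cand$tpm[j])
    if (cand$foreignness[i] != cand$foreignness[j])
      return(cand$foreignness[i] > cand$foreignness[j])
    cand$peptide[i] < cand$peptide[j]
  }
  idx <- seq_len(nrow(cand))
  out <- integer(0)
  while (length(idx)) {
    m <- idx[1L]
    for (i in idx) if (lt(i, m)) m <- i
    out <- c(out, m)
    idx <- setdiff(idx, m)
  }
  cand[out, , drop = FALSE]
}
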
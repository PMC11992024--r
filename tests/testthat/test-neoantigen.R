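mk_variant <- function(chrom, pos, effect = "missense", germ = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
             effect = effect, gene = paste0("G", pos),
             is_germline = germ, stringsAsFactors = FALSE)
}

test_that("consensus filter keeps >=3-of-4 missense, drops the rest", {
  v_all <- mk_variant("chr1", 100)            # in 4/4
  v_three <- mk_variant("chr1", 200)          # in 3/4
  v_two <- mk_variant("chr1", 300)            # in 2/4
  v_syn <- mk_variant("chr1", 400, "synonymous")  # synonymous in 4/4
  v_germ <- mk_variant("chr1", 500)           # 3/4 but germline-flagged
  g <- mk_variant("chr1", 500, germ = TRUE)
  sets <- list(rbind(v_all, v_three, v_two, v_syn, g),
               rbind(v_all, v_three, v_syn, v_germ),
               rbind(v_all, v_three, v_syn, v_germ),
               rbind(v_all, v_syn))
  out <- consensus_filter(sets)
  expect_setequal(out$pos, c(100L, 200L))
  expect_equal(out$n_sets[out$pos == 100], 4L)
  expect_error(consensus_filter(sets[1:3]), "4")
})

test_that("consensus filter is monotone in dataset occupancy", {
  v <- mk_variant("chr2", 42)
  sets <- list(v, v, mk_variant("chr2", 1), mk_variant("chr2", 2))
  expect_equal(nrow(consensus_filter(sets)), 0L)  # 2/4: dropped
  sets[[3]] <- rbind(sets[[3]], v)                # add an occurrence
  expect_equal(consensus_filter(sets)$pos, 42L)   # now kept
  sets[[4]] <- rbind(sets[[4]], v)                # still kept at 4/4
  expect_equal(consensus_filter(sets)$pos, 42L)
})

test_that("synthetic consensus rate matches the binomial tail", {
  v <- gen_variants(variant_sim_config(seed = 8, n_variants = 1000,
                                       detection_probs = rep(0.9, 4),
                                       fraction_missense = 1))
  out <- consensus_filter(unname(v$sets))
  tail3 <- sum(dbinom(3:4, 4, 0.9))  # 0.9477
  frac <- nrow(out) / 1000
  expect_lt(abs(frac - tail3), 3 * sqrt(tail3 * (1 - tail3) / 1000))
  # and it reproduces the generator's recorded truth exactly
  expect_equal(sort(paste(out$chrom, out$pos)),
               sort(paste(v$truth$chrom, v$truth$pos)[v$truth$consensus]))
})

mk_pred <- function(peptide, affinity, pos = 100, gene = "G1") {
  data.frame(peptide = peptide, allele = "H2-Kb", chrom = "chr1", pos = pos,
             ref = "A", alt = "T", gene = gene, affinity_nM = affinity,
             agretopicity = 2, foreignness = 0.5, stringsAsFactors = FALSE)
}

test_that("score integration dedups on (peptide, allele) keeping the
           better affinity and zero-fills missing expression", {
  vars <- data.frame(chrom = "chr1", pos = c(100, 200), ref = "A", alt = "T")
  preds <- list(p1 = rbind(mk_pred("SIINFEKLA", 40),
                           mk_pred("AAAAAAAAA", 90, pos = 200, gene = "G2")),
                p2 = mk_pred("SIINFEKLA", 60))
  expr <- data.frame(gene = "G1", tpm = 12)
  cand <- integrate_scores(vars, preds, expr)
  expect_equal(nrow(cand), 2L)
  s <- cand[cand$peptide == "SIINFEKLA", ]
  expect_equal(s$affinity_nM, 40)       # better of 40/60
  expect_equal(s$provenance, "p1+p2")
  expect_equal(s$tpm, 12)
  expect_equal(cand$tpm[cand$gene == "G2"], 0)  # absent from expression

  # candidates must stem from surviving variants
  cand2 <- integrate_scores(vars[vars$pos == 100, , drop = FALSE],
                            preds, expr)
  expect_equal(cand2$peptide, "SIINFEKLA")

  bad <- preds
  bad$p1$affinity_nM[1] <- -5
  expect_error(integrate_scores(vars, bad, expr), "malformed")
  expect_error(integrate_scores(vars, preds[1], expr), "2 predictor")
})

test_that("ranking filters then sorts by the configured keys", {
  cand <- data.frame(
    peptide = c("PEPA", "PEPB", "PEPC", "PEPD", "PEPE", "PEPF"),
    allele = "H2-Kb",
    affinity_nM = c(300, 30, 30, 700, 50, 50),
    tpm = c(10, 5, 100, 50, 20, 20),
    agretopicity = c(2, 2, 2, 2, 0.5, 2),
    foreignness = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
  r <- rank_candidates(cand)
  # PEPD filtered (affinity > 500), PEPE filtered (agretopicity < 1);
  # affinity ties 30/30 broken by TPM
  expect_equal(r$peptide, c("PEPC", "PEPB", "PEPF", "PEPA"))

  # TPM 0 excluded under the default threshold
  cand$tpm[1] <- 0
  expect_false("PEPA" %in% rank_candidates(cand)$peptide)

  # output is a permutation of the filtered input
  expect_setequal(r$peptide, c("PEPA", "PEPB", "PEPC", "PEPF"))
  expect_error(rank_config(affinity_max = -1), "affinity_max")
  expect_error(rank_config(sort_keys = "nope"), "sort_keys")
})

test_that("ranking equals an explicit pairwise-comparator sort", {
  set.seed(77)
  n <- 100
  cand <- data.frame(
    peptide = replicate(n, paste(sample(LETTERS, 9, TRUE), collapse = "")),
    allele = "H2-Kb",
    affinity_nM = sample(c(20, 100, 450, 600), n, TRUE),  # forced ties
    tpm = sample(c(0, 5, 50), n, TRUE),
    agretopicity = sample(c(0.5, 1, 3), n, TRUE),
    foreignness = sample(c(0.2, 0.8), n, TRUE),
    stringsAsFactors = FALSE)
  got <- rank_candidates(cand)
  want <- oracle_rank(cand)
  expect_equal(got$peptide, want$peptide)
  expect_equal(got$affinity_nM, want$affinity_nM)
})

test_that("top-N selection truncates and validates n", {
  ranked <- data.frame(peptide = sprintf("P%02d", 1:40))
  expect_length(select_top(ranked), 33L)
  expect_equal(select_top(ranked, 3), c("P01", "P02", "P03"))
  expect_length(select_top(ranked[1:10, , drop = FALSE], 33), 10L)
  expect_error(select_top(ranked, 0), "n")
})

test_that("construct assembly is exact for small payloads and
           reconstructs its sequence from parts", {
  scorer <- mock_junction_scorer(1)
  peps <- c("SIINFEKLM", "KAVYNFATC", "RGYVYQGLK")
  con <- assemble_construct(peps, junction_scorer = scorer)
  oracle <- oracle_best_order(peps, "GGSGG", scorer)
  expect_identical(con$peptides, oracle$order)
  expect_identical(con$objective, oracle$value)
  expect_identical(con$sequence, paste(con$peptides, collapse = "GGSGG"))

  # junction report covers every adjacent pair with spanning 8-11-mers only
  expect_setequal(unique(con$junction_report$junction), 1:2)
  expect_true(all(nchar(con$junction_report$kmer) %in% 8:11))
  inside_left <- vapply(seq_len(nrow(con$junction_report)), function(i)
    grepl(con$junction_report$kmer[i],
          con$junction_report$left[i], fixed = TRUE), logical(1))
  expect_false(any(inside_left))

  # single peptide: trivial construct
  solo <- assemble_construct("SIINFEKLM", junction_scorer = scorer,
                             leader = "MHRRRS")
  expect_equal(nrow(solo$junction_report), 0L)
  expect_identical(solo$sequence, "MHRRRSSIINFEKLM")
  expect_error(assemble_construct(character(0)), "at least one")
})

test_that("assembly equals the exhaustive optimum up to six peptides", {
  for (s in 1:4) {
    set.seed(s)
    n <- sample(4:6, 1)
    peps <- replicate(n, paste(sample(AA <- strsplit(
      "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9, TRUE), collapse = ""))
    scorer <- mock_junction_scorer(s)
    con <- assemble_construct(peps, junction_scorer = scorer)
    oracle <- oracle_best_order(peps, "GGSGG", scorer)
    expect_equal(con$objective, oracle$value)
  }
})

test_that("greedy ordering beats the median of random orders", {
  set.seed(101)
  peps <- replicate(9, paste(sample(strsplit(
    "ACDEFGHIKLMNPQRSTVWY", "")[[1]], 9, TRUE), collapse = ""))
  scorer <- mock_junction_scorer(3)
  greedy <- assemble_construct(peps, junction_scorer = scorer,
                               method = "greedy")
  # objective of random orders, computed directly from the junction k-mers
  rand_vals <- replicate(100, {
    p <- sample(peps)
    vals <- vapply(seq_len(length(p) - 1L), function(i) {
      kms <- livmet:::junction_kmers(p[i], "GGSGG", p[i + 1L])
      min(scorer(kms))
    }, numeric(1))
    min(vals)
  })
  expect_gte(greedy$objective, median(rand_vals))
})

test_that("constructs serialize as FASTA", {
  con <- assemble_construct(c("SIINFEKLM", "KAVYNFATC"),
                            junction_scorer = mock_junction_scorer())
  f <- withr::local_tempfile(fileext = ".fa")
  write_construct_fasta(con, f)
  lines <- readLines(f)
  expect_match(lines[1], "^>CD74_chimeric_2pep")
  expect_identical(paste(lines[-1], collapse = ""), con$sequence)
})
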
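# Worked examples with hand-computed expectations, then the properties the
# score must satisfy (oracle equivalence, rigid-motion invariance, radius
# monotonicity, degenerate-count semantics).

test_that("close counting follows the unique-interaction rule", {
  # one source transcript near two partners in another cell: counts once
  tb <- transcript_table(c("A", "B", "B"), c(0, 10, 12), c(0, 0, 0),
                         cell_id = c(1, 2, 2))
  expect_identical(close_count("A", "B", tb), 1L)
  # threshold is strict: 30 um apart is NOT close
  tb2 <- transcript_table(c("A", "B"), c(0, 30), c(0, 0), cell_id = c(1, 2))
  expect_identical(close_count("A", "B", tb2), 0L)
  tb3 <- transcript_table(c("A", "B"), c(0, 29.99), c(0, 0),
                          cell_id = c(1, 2))
  expect_identical(close_count("A", "B", tb3), 1L)
  # same cell excluded
  tb4 <- transcript_table(c("A", "B"), c(0, 5), c(0, 0), cell_id = c(7, 7))
  expect_identical(close_count("A", "B", tb4), 0L)
  # absent partner
  expect_identical(close_count("A", "Z", tb), 0L)
  # unknown gene only when a panel is declared
  expect_error(close_count("A", "Z", tb, panel = c("A", "B")), "Z")
})

test_that("normalized score matches hand computation and is asymmetric", {
  tb <- transcript_table(c("A", "A", "B", "B"), c(0, 100, 10, 200),
                         c(0, 0, 0, 0), cell_id = c(1, 2, 2, 3))
  expect_equal(coloc_score("A", "B", tb), 0.5)  # 2 * 1 / (2 + 2)

  tb2 <- transcript_table(c("A", "B", "B", "B"), c(0, 5, 6, 200),
                          c(0, 0, 0, 0), cell_id = c(1, 2, 2, 3))
  expect_equal(coloc_score("A", "B", tb2), 0.5)  # 2 * 1 / 4
  expect_equal(coloc_score("B", "A", tb2), 1.0)  # 2 * 2 / 4

  # equal counts, fully paired across distinct cells -> exactly 1
  k <- 5
  tb3 <- transcript_table(rep(c("A", "B"), each = k),
                          x = c(seq(0, by = 100, length.out = k),
                                seq(5, by = 100, length.out = k)),
                          y = rep(0, 2 * k),
                          cell_id = c(seq_len(k), k + seq_len(k)))
  expect_identical(coloc_score("A", "B", tb3), 1)
  expect_identical(coloc_score("B", "A", tb3), 1)
})

test_that("zero-count semantics: 0 when one side empty, NA when both", {
  tb <- transcript_table(c("A", "A"), c(0, 1), c(0, 0), cell_id = c(1, 2))
  m <- coloc_matrix(tb, panel = c("A", "B"))
  v <- as.matrix(m)
  expect_equal(v["A", "B"], 0)  # 2 * 0 / (2 + 0)
  expect_equal(v["B", "A"], 0)
  expect_true(is.na(v["B", "B"]))
  expect_false(is.na(v["A", "A"]))
})

test_that("diagonal forbids self-pairing", {
  tb <- transcript_table(c("A", "A"), c(0, 5), c(0, 0), cell_id = c(1, 2))
  expect_identical(close_count("A", "A", tb), 2L)
  expect_identical(coloc_score("A", "A", tb), 1)
  solo <- transcript_table("A", 0, 0, cell_id = 1)
  expect_identical(close_count("A", "A", solo), 0L)
})

test_that("everything in one cell scores zero under same-cell exclusion", {
  set.seed(1)
  tb <- transcript_table(sample(c("A", "B", "C"), 60, TRUE),
                         runif(60, 0, 10), runif(60, 0, 10),
                         cell_id = rep("c1", 60))
  v <- as.matrix(coloc_matrix(tb, panel = c("A", "B", "C")))
  expect_true(all(v == 0))
  # and without the exclusion scores recover
  v2 <- as.matrix(suppressWarnings(
    coloc_matrix(tb, panel = c("A", "B", "C"),
                 params = coloc_params(same_cell_exclusion = FALSE))))
  expect_true(any(v2 > 0))
})

test_that("grid-indexed matrix equals the brute-force oracle exactly", {
  panel <- sprintf("g%03d", 1:8)
  for (s in 1:20) {
    tb <- random_table(seed = s, n_max = 400)
    # scores above 1 are legitimate on skewed random tables; the designed
    # warning is not under test here
    got <- as.matrix(suppressWarnings(coloc_matrix(tb, panel = panel)))
    want <- brute_coloc_matrix(tb, panel)
    expect_identical(got, want)
  }
})

test_that("scores are invariant under rigid motions of the section", {
  tb <- random_table(seed = 99, n_max = 300)
  panel <- sprintf("g%03d", 1:8)
  base <- as.matrix(coloc_matrix(tb, panel = panel))
  th <- 0.7
  rot <- tb
  rot$x <- cos(th) * tb$x - sin(th) * tb$y + 1234.5
  rot$y <- sin(th) * tb$x + cos(th) * tb$y - 987.25
  moved <- as.matrix(coloc_matrix(rot, panel = panel))
  expect_equal(moved, base, tolerance = 0)
})

test_that("close_count is non-decreasing in the radius", {
  tb <- random_table(seed = 5, n_max = 300)
  radii <- c(5, 10, 20, 30, 50, 100)
  cnts <- vapply(radii, function(r)
    close_count("g001", "g002", tb, coloc_params(radius = r)), integer(1))
  expect_true(all(diff(cnts) >= 0))
})

test_that("unassigned transcripts: singleton-cell default vs drop policy", {
  # unassigned partner 5 um away: counted under "distinct", gone under "drop"
  tb <- transcript_table(c("A", "B"), c(0, 5), c(0, 0),
                         cell_id = c("1", NA))
  expect_equal(coloc_score("A", "B", tb), 1)
  expect_equal(coloc_score("A", "B", tb,
                           coloc_params(unassigned_policy = "drop")), 0)
  # two unassigned transcripts are distinct singleton cells, never excluded
  tb2 <- transcript_table(c("A", "B"), c(0, 5), c(0, 0),
                          cell_id = c(NA, NA))
  expect_equal(coloc_score("A", "B", tb2), 1)
})

test_that("scores above 1 are possible and reported with a warning", {
  # many source transcripts around one partner transcript
  tb <- transcript_table(c(rep("A", 9), "B"),
                         x = c(seq(-4, 4, length.out = 9), 0),
                         y = c(rep(1, 9), 0),
                         cell_id = c(seq_len(9), 99))
  expect_warning(m <- coloc_matrix(tb, panel = c("A", "B")), "exceed 1")
  expect_gt(as.matrix(m)["A", "B"], 1)  # 2 * 9 / 10
})

test_that("sections combine by pooled counts or per-section mean", {
  tb1 <- transcript_table(c("A", "B"), c(0, 5), c(0, 0), cell_id = c(1, 2),
                          section = "s1")
  tb2 <- transcript_table(c("A", "A", "B"), c(0, 100, 300), c(0, 0, 0),
                          cell_id = c(3, 4, 5), section = "s2")
  both <- rbind(tb1, tb2)
  class(both) <- class(tb1)
  pooled <- as.matrix(coloc_matrix(both, panel = c("A", "B")))
  # counts: s1 contributes 1, s2 contributes 0; totals n_A = 3, n_B = 2
  expect_equal(pooled["A", "B"], 2 * 1 / 5)
  meaned <- as.matrix(coloc_matrix(both, panel = c("A", "B"),
                                   combine = "mean"))
  expect_equal(meaned["A", "B"], (1 + 0) / 2)
})

test_that("differential matrix subtracts control from case, NA-propagating", {
  set.seed(11)
  tb_case <- random_table(seed = 21, n_max = 300)
  tb_ctrl <- random_table(seed = 22, n_max = 300)
  panel <- sprintf("g%03d", 1:8)
  mc <- coloc_matrix(tb_case, panel = panel, condition = "treated")
  mt <- coloc_matrix(tb_ctrl, panel = panel, condition = "control")
  d <- differential_matrix(mc, mt)
  expect_equal(as.matrix(d), as.matrix(mc) - as.matrix(mt))
  # antisymmetry under swapping case and control
  d_rev <- differential_matrix(mt, mc)
  expect_equal(as.matrix(d_rev), -as.matrix(d))
  # case == control -> all-zero
  d0 <- differential_matrix(mc, mc)
  expect_true(all(as.matrix(d0) == 0, na.rm = TRUE))
  expect_match(d$sign_convention, "positive = higher co-localization in case")
})

test_that("differential matrix rejects mismatched panels and params", {
  tb <- random_table(seed = 31, n_max = 200)
  # out-of-panel transcripts are dropped with a message (not under test)
  m1 <- suppressMessages(coloc_matrix(tb, panel = c("g001", "g002")))
  m2 <- suppressMessages(coloc_matrix(tb, panel = c("g001", "g003")))
  expect_error(differential_matrix(m1, m2), "g002.*g003")
  m3 <- suppressMessages(coloc_matrix(tb, panel = c("g001", "g002"),
                                      params = coloc_params(radius = 20)))
  expect_error(differential_matrix(m1, m3), "parameters")
})

test_that("heatmap slicing preserves subset order and validates genes", {
  tb <- random_table(seed = 41, n_max = 300)
  panel <- sprintf("g%03d", 1:8)
  d <- differential_matrix(
    coloc_matrix(random_table(seed = 42, n_max = 300), panel = panel),
    coloc_matrix(tb, panel = panel))
  sl <- subset_heatmap(d, c("g005", "g002", "g007"), draw = FALSE)
  expect_identical(rownames(sl), c("g005", "g002", "g007"))
  expect_equal(sl["g005", "g002"], as.matrix(d)["g005", "g002"])
  full <- subset_heatmap(d, panel, draw = FALSE)
  expect_equal(full, as.matrix(d))
  expect_error(subset_heatmap(d, character(0)), "empty")
  expect_error(subset_heatmap(d, c("g001", "nope")), "nope")
  f <- withr::local_tempfile(fileext = ".png")
  subset_heatmap(d, c("g001", "g002"), file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})

test_that("planted co-localization is recoverable over replicate seeds", {
  genes <- sprintf("g%03d", 1:8)
  planted <- numeric(0); nulls <- numeric(0)
  for (s in 1:20) {
    cfg <- spatial_sim_config(
      seed = s, n_genes = 8, transcripts_per_gene = 100, field_size = 1000,
      coloc_pairs = list(list(gene_a = "g001", gene_b = "g002",
                              sigma = 2, fraction = 0.8)))
    v <- as.matrix(coloc_matrix(gen_transcripts(cfg), panel = genes))
    excl <- rownames(v)[row(v)] %in% c("g001", "g002") |
      colnames(v)[col(v)] %in% c("g001", "g002") | row(v) == col(v)
    planted <- c(planted, v["g002", "g001"])
    nulls <- c(nulls, mean(v[!excl]))
  }
  # one-sided paired comparison across seeds at alpha = 0.01
  tt <- t.test(planted, nulls, paired = TRUE, alternative = "greater")
  expect_lt(tt$p.value, 0.01)
})
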
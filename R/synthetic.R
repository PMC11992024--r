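# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one downstream stage assumes (spatial point patterns with planted
# pairwise co-localization; clone-size distributions with tissue sharing;
# overlapping variant call sets with predictor scores; log-scale expression
# with survival labels) so the whole pipeline is exercisable without any
# external download. All generators restore the caller's RNG state.

#' Configuration for the spatial transcript simulator
#'
#' @param seed Integer seed; fixes the output bit-for-bit.
#' @param field_size Side of the square imaging field in micrometres.
#' @param n_genes Number of panel genes (named `g001`, `g002`, ...).
#' @param transcripts_per_gene Single count or per-gene vector.
#' @param cell_grid_pitch Side of the square cell mosaic in micrometres
#'   (default 20, so a 30 µm disc covers roughly 7 mosaic cells — the
#'   handful-of-cells neighbourhood the proximity radius is meant to probe).
#' @param coloc_pairs List of planted co-localized pairs, each a list with
#'   elements `gene_a`, `gene_b`, `sigma` (Gaussian dispersion, µm) and
#'   `fraction` (fraction of `gene_b` transcripts coupled to `gene_a`
#'   anchors, in \[0, 1\]).
#' @param unassigned_fraction Fraction of transcripts emitted with no cell
#'   identity (default 0), to exercise the scorer's unassigned policy.
#' @param couple_across_cells Re-draw coupled placements landing in the
#'   anchor's own mosaic cell (default `TRUE`). Planted co-localization is
#'   meant to emulate cross-cell transcript proximity — the feature the
#'   proximity score quantifies, which excludes same-cell pairs; with small
#'   `sigma` an unconditioned Gaussian offset would leave most planted pairs
#'   inside one cell and thus invisible to the scorer.
#' @return A list of class `"spatial_sim_config"`.
#' @export
spatial_sim_config <- function(seed = 1L, field_size = 1000, n_genes = 10L,
                               transcripts_per_gene = 100L,
                               cell_grid_pitch = 20,
                               coloc_pairs = list(),
                               unassigned_fraction = 0,
                               couple_across_cells = TRUE) {
  check_scalar_number(field_size, "field_size", min = 0, strict_min = TRUE)
  check_scalar_number(n_genes, "n_genes", min = 1)
  check_scalar_number(cell_grid_pitch, "cell_grid_pitch", min = 0,
                      strict_min = TRUE)
  check_fraction(unassigned_fraction, "unassigned_fraction")
  if (any(transcripts_per_gene <= 0) || anyNA(transcripts_per_gene))
    stop_config("transcripts_per_gene must be positive")
  if (!length(transcripts_per_gene) %in% c(1L, n_genes))
    stop_config("transcripts_per_gene must have length 1 or n_genes")
  for (p in coloc_pairs) {
    if (!all(c("gene_a", "gene_b", "sigma", "fraction") %in% names(p)))
      stop_config("each coloc pair needs gene_a, gene_b, sigma, fraction")
    check_scalar_number(p$sigma, "sigma", min = 0)
    check_fraction(p$fraction, "fraction")
  }
  structure(list(seed = as.integer(seed), field_size = field_size,
                 n_genes = as.integer(n_genes),
                 transcripts_per_gene =
                   rep_len(as.integer(transcripts_per_gene), n_genes),
                 cell_grid_pitch = cell_grid_pitch,
                 coloc_pairs = coloc_pairs,
                 unassigned_fraction = unassigned_fraction,
                 couple_across_cells = isTRUE(couple_across_cells)),
            class = "spatial_sim_config")
}

# Mosaic cell label of points: the square grid cell containing each point.
mosaic_cell <- function(x, y, pitch, field_size) {
  ncol_cells <- ceiling(field_size / pitch)
  cx <- pmin(floor(x / pitch), ncol_cells - 1)
  cy <- pmin(floor(y / pitch), ncol_cells - 1)
  sprintf("c%d_%d", cx, cy)
}

#' Generate a synthetic detected-transcript table
#'
#' Noise genes are uniform over the field. For each planted pair, a
#' `fraction` of `gene_b`'s transcripts is placed at a Gaussian offset
#' (isotropic, sd `sigma`) from randomly chosen `gene_a` transcripts;
#' coupled points falling outside the field are re-drawn so per-gene counts
#' stay exact. Cell identity is the square mosaic cell containing the point.
#'
#' @param config A [spatial_sim_config()].
#' @return A [transcript_table()]; per-gene counts equal the configuration.
#' @export
gen_transcripts <- function(config) {
  stopifnot(inherits(config, "spatial_sim_config"))
  with_seed(config$seed, {
    genes <- sprintf("g%03d", seq_len(config$n_genes))
    counts <- config$transcripts_per_gene
    xs <- vector("list", config$n_genes)
    ys <- vector("list", config$n_genes)
    fs <- config$field_size
    for (g in seq_len(config$n_genes)) {
      xs[[g]] <- stats::runif(counts[g], 0, fs)
      ys[[g]] <- stats::runif(counts[g], 0, fs)
    }
    names(xs) <- names(ys) <- genes
    for (p in config$coloc_pairs) {
      ga <- match(p$gene_a, genes); gb <- match(p$gene_b, genes)
      if (is.na(ga) || is.na(gb))
        stop_config("coloc pair gene not in panel: %s/%s", p$gene_a, p$gene_b)
      n_coupled <- round(p$fraction * counts[gb])
      if (n_coupled == 0L) next
      idx <- sample.int(counts[gb], n_coupled)
      anchors <- sample.int(counts[ga], n_coupled, replace = TRUE)
      pitch <- config$cell_grid_pitch
      for (k in seq_len(n_coupled)) {
        ax <- xs[[ga]][anchors[k]]; ay <- ys[[ga]][anchors[k]]
        anchor_cell <- mosaic_cell(ax, ay, pitch, fs)
        tries <- 0L
        repeat {
          tries <- tries + 1L
          nx <- ax + stats::rnorm(1, 0, p$sigma)
          ny <- ay + stats::rnorm(1, 0, p$sigma)
          inside <- nx >= 0 && nx <= fs && ny >= 0 && ny <= fs
          if (inside &&
              (!config$couple_across_cells || tries > 1000L ||
               mosaic_cell(nx, ny, pitch, fs) != anchor_cell)) break
        }
        xs[[gb]][idx[k]] <- nx
        ys[[gb]][idx[k]] <- ny
      }
    }
    gene_col <- rep(genes, counts)
    x <- unlist(xs, use.names = FALSE)
    y <- unlist(ys, use.names = FALSE)
    cell <- mosaic_cell(x, y, config$cell_grid_pitch, fs)
    if (config$unassigned_fraction > 0) {
      n <- length(x)
      drop <- sample.int(n, round(config$unassigned_fraction * n))
      cell[drop] <- NA_character_
    }
    transcript_table(gene_col, x, y, cell)
  })
}

#' Configuration for the clonotype simulator
#'
#' @param seed Integer seed.
#' @param n_cells_tumor,n_cells_liver Cells with a recovered TCR per tissue.
#' @param clone_size_law `"geometric"` (default) or `"powerlaw"`.
#' @param law_param For the geometric law the success probability p (clone
#'   sizes ~ 1 + Geometric(p)); for the power law the exponent alpha of
#'   P(size = k) proportional to k^-alpha.
#' @param sharing_fraction Fraction of tumor clonotypes whose key is also
#'   planted among liver clonotypes, in \[0, 1\].
#' @return A list of class `"clonotype_sim_config"`.
#' @export
clonotype_sim_config <- function(seed = 1L, n_cells_tumor = 1000L,
                                 n_cells_liver = 1000L,
                                 clone_size_law = c("geometric", "powerlaw"),
                                 law_param = 0.5,
                                 sharing_fraction = 0.3) {
  clone_size_law <- match.arg(clone_size_law)
  check_scalar_number(n_cells_tumor, "n_cells_tumor", min = 1)
  check_scalar_number(n_cells_liver, "n_cells_liver", min = 1)
  check_fraction(sharing_fraction, "sharing_fraction")
  if (clone_size_law == "geometric")
    check_scalar_number(law_param, "law_param", min = 0, max = 1,
                        strict_min = TRUE)
  else check_scalar_number(law_param, "law_param", min = 1,
                           strict_min = TRUE)
  structure(list(seed = as.integer(seed),
                 n_cells_tumor = as.integer(n_cells_tumor),
                 n_cells_liver = as.integer(n_cells_liver),
                 clone_size_law = clone_size_law, law_param = law_param,
                 sharing_fraction = sharing_fraction),
            class = "clonotype_sim_config")
}

# Draw clone sizes for one tissue until they cover n_cells, trimming the last
# clone to land exactly on n_cells.
draw_clone_sizes <- function(n_cells, law, param) {
  sizes <- integer(0)
  while (sum(sizes) < n_cells) {
    block <- if (law == "geometric") stats::rgeom(256L, param) + 1L
    else {
      # discrete power law on 1..1000 by inverse-CDF sampling
      k <- 1:1000
      pmf <- k^(-param); pmf <- pmf / sum(pmf)
      sample(k, 256L, replace = TRUE, prob = pmf)
    }
    sizes <- c(sizes, block)
  }
  cum <- cumsum(sizes)
  last <- which(cum >= n_cells)[1L]
  sizes <- sizes[seq_len(last)]
  sizes[last] <- sizes[last] - (cum[last] - n_cells)
  sizes[sizes > 0L]
}

#' Generate a synthetic clonotype table
#'
#' Clone sizes per tissue follow the configured law; clonotype keys are
#' random CDR3beta-like amino-acid sequences (prefix `CASS`, suffix `F`). A
#' `sharing_fraction` of tumor clonotypes has its key planted into liver
#' clonotypes (replacing a liver key), so the planted sharing is recoverable
#' by [shared_clonotypes()].
#'
#' @param config A [clonotype_sim_config()].
#' @return A `data.frame` with columns `cell_id`, `clonotype_key`, `tissue`.
#' @export
gen_clonotypes <- function(config) {
  stopifnot(inherits(config, "clonotype_sim_config"))
  with_seed(config$seed, {
    sizes_t <- draw_clone_sizes(config$n_cells_tumor, config$clone_size_law,
                                config$law_param)
    sizes_l <- draw_clone_sizes(config$n_cells_liver, config$clone_size_law,
                                config$law_param)
    n_keys <- length(sizes_t) + length(sizes_l)
    keys <- paste0("CASS", random_peptides(n_keys, 8L), "F")
    while (anyDuplicated(keys))
      keys[duplicated(keys)] <-
        paste0("CASS", random_peptides(sum(duplicated(keys)), 8L), "F")
    keys_t <- keys[seq_along(sizes_t)]
    keys_l <- keys[length(sizes_t) + seq_along(sizes_l)]
    n_shared <- round(config$sharing_fraction * length(keys_t))
    n_shared <- min(n_shared, length(keys_l))
    if (n_shared > 0L) {
      shared <- sample(keys_t, n_shared)
      keys_l[sample.int(length(keys_l), n_shared)] <- shared
    }
    tab <- data.frame(
      cell_id = sprintf("cell%06d",
                        seq_len(config$n_cells_tumor + config$n_cells_liver)),
      clonotype_key = c(rep(keys_t, sizes_t), rep(keys_l, sizes_l)),
      tissue = rep(c("tumor", "liver"),
                   c(config$n_cells_tumor, config$n_cells_liver)),
      stringsAsFactors = FALSE)
    tab
  })
}

#' Configuration for the variant-set simulator
#'
#' @param seed Integer seed.
#' @param n_variants Number of distinct somatic variants.
#' @param detection_probs Per-dataset detection probabilities; exactly 4
#'   values (WES/RNA x in vivo/in vitro).
#' @param fraction_missense Fraction of variants with missense effect; the
#'   remainder are synonymous.
#' @param fraction_germline Fraction flagged as germline (to be excluded by
#'   the consensus filter).
#' @return A list of class `"variant_sim_config"`.
#' @export
variant_sim_config <- function(seed = 1L, n_variants = 500L,
                               detection_probs = c(0.9, 0.9, 0.9, 0.9),
                               fraction_missense = 0.7,
                               fraction_germline = 0) {
  if (length(detection_probs) != 4L)
    stop_config("exactly 4 detection probabilities required (got %d)",
                length(detection_probs))
  for (p in detection_probs) check_fraction(p, "detection_probs")
  check_fraction(fraction_missense, "fraction_missense")
  check_fraction(fraction_germline, "fraction_germline")
  check_scalar_number(n_variants, "n_variants", min = 1)
  structure(list(seed = as.integer(seed), n_variants = as.integer(n_variants),
                 detection_probs = detection_probs,
                 fraction_missense = fraction_missense,
                 fraction_germline = fraction_germline),
            class = "variant_sim_config")
}

#' Generate four overlapping variant call sets with predictor scores
#'
#' Each variant is detected independently in each of the four datasets with
#' that dataset's probability; the consensus truth (missense, non-germline,
#' detected in at least 3 of 4) is recorded for recovery tests. Per-variant
#' predictor tables emulate the outputs of two epitope-prediction pipelines
#' (peptide, allele, affinity in nM, agretopicity, foreignness), and an
#' expression table assigns a TPM to each mutated gene.
#'
#' @param config A [variant_sim_config()].
#' @return A list with elements `sets` (list of 4 variant `data.frame`s named
#'   `WES_invivo`, `WES_invitro`, `RNA_invivo`, `RNA_invitro`), `truth`
#'   (all variants with their per-set detection flags and `consensus`
#'   indicator), `predictor_tables` (list of 2 score `data.frame`s),
#'   `expression` (`gene`, `tpm`).
#' @export
gen_variants <- function(config) {
  stopifnot(inherits(config, "variant_sim_config"))
  with_seed(config$seed, {
    n <- config$n_variants
    variants <- data.frame(
      chrom = sample(paste0("chr", 1:19), n, replace = TRUE),
      pos = sample.int(1e8L, n),
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    variants$alt <- vapply(variants$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
    variants$gene <- sprintf("Gene%04d", sample.int(10 * n, n))
    variants$effect <- ifelse(
      stats::runif(n) < config$fraction_missense, "missense", "synonymous")
    variants$is_germline <- stats::runif(n) < config$fraction_germline

    set_names <- c("WES_invivo", "WES_invitro", "RNA_invivo", "RNA_invitro")
    det <- sapply(config$detection_probs,
                  function(p) stats::runif(n) < p)
    colnames(det) <- set_names
    sets <- lapply(set_names, function(s) {
      v <- variants[det[, s], , drop = FALSE]
      v$set_id <- rep(s, nrow(v))
      rownames(v) <- NULL
      v
    })
    names(sets) <- set_names

    truth <- cbind(variants, det,
                   consensus = rowSums(det) >= 3L &
                     variants$effect == "missense" & !variants$is_germline)

    # Predictor score tables: one mutant 9-mer per missense variant, scored
    # by each pipeline with slightly different affinities; each pipeline
    # reports an overlapping random subset.
    mis <- which(variants$effect == "missense")
    peptides <- random_peptides(length(mis), 9L)
    base_aff <- stats::rlnorm(length(mis), meanlog = log(300), sdlog = 1.2)
    mk_tab <- function(jitter_sd) {
      keep <- stats::runif(length(mis)) < 0.9
      data.frame(
        peptide = peptides[keep],
        allele = "H2-Kb",
        chrom = variants$chrom[mis][keep],
        pos = variants$pos[mis][keep],
        ref = variants$ref[mis][keep],
        alt = variants$alt[mis][keep],
        gene = variants$gene[mis][keep],
        affinity_nM = base_aff[keep] *
          stats::rlnorm(sum(keep), 0, jitter_sd),
        agretopicity = stats::rlnorm(sum(keep), log(1.5), 0.8),
        foreignness = stats::runif(sum(keep)),
        stringsAsFactors = FALSE)
    }
    predictor_tables <- list(garnish_like = mk_tab(0.3),
                             pvac_like = mk_tab(0.3))
    expression <- data.frame(
      gene = unique(variants$gene),
      tpm = stats::rexp(length(unique(variants$gene)), rate = 1 / 20),
      stringsAsFactors = FALSE)
    list(sets = sets, truth = truth, predictor_tables = predictor_tables,
         expression = expression)
  })
}

#' Generate a synthetic expression matrix with survival labels
#'
#' Emulates a cohort for signature-score stratification: samples come from
#' two latent groups; signature genes are shifted upward (on log2 scale) in
#' the "high" group by `effect_size`, and survival times are longer in that
#' group. Used to check that the median split recovers the planted labels up
#' to the overlap of the two score distributions.
#'
#' @param seed Integer seed.
#' @param n_samples Number of samples (split evenly between groups).
#' @param genes Gene names (the signature panel plus any background genes).
#' @param signature_genes Subset of `genes` carrying the planted shift.
#' @param effect_size Mean log2 shift per signature gene in the high group.
#' @param sd_log2 Per-gene log2 noise standard deviation.
#' @return A list with `expr` (sample x gene matrix, linear scale),
#'   `group` (planted labels `"high"`/`"low"`), `survival` (`sample`,
#'   `time`, `event`).
#' @export
gen_expression <- function(seed = 1L, n_samples = 100L,
                           genes = sprintf("Gene%02d", 1:30),
                           signature_genes = genes[1:10],
                           effect_size = 1, sd_log2 = 0.5) {
  stopifnot(all(signature_genes %in% genes), n_samples >= 2L)
  with_seed(seed, {
    grp <- rep(c("high", "low"), length.out = n_samples)
    base <- matrix(stats::rnorm(n_samples * length(genes), mean = 5,
                                sd = sd_log2),
                   nrow = n_samples,
                   dimnames = list(sprintf("s%03d", seq_len(n_samples)),
                                   genes))
    shift <- outer(grp == "high", genes %in% signature_genes) * effect_size
    log2_expr <- base + shift
    expr <- 2^log2_expr - 1  # linear scale; scorer re-applies log2(x + 1)
    expr[expr < 0] <- 0
    surv <- data.frame(
      sample = rownames(expr),
      time = stats::rexp(n_samples,
                         rate = ifelse(grp == "high", 1 / 24, 1 / 12)),
      event = stats::rbinom(n_samples, 1, 0.7),
      stringsAsFactors = FALSE)
    list(expr = expr, group = grp, survival = surv)
  })
}
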
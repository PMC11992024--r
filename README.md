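# livmet

Analysis toolkit for the computational readouts of liver-metastasis
immunotherapy experiments: transcript-level spatial co-localization from
MERFISH/MERSCOPE data, neoantigen candidate selection and chimeric
construct assembly, TCR clonotype expansion and tissue sharing, and the
small closed-form quantifications (vector copy number, tumor volume,
gene-signature survival strata) that tie such studies together. Every input
format has a seeded synthetic generator, so the whole pipeline runs and is
tested without any external data.

## Who this is for

Groups analyzing in-situ transcriptomics of tumor/liver tissue alongside
immunogenomic readouts (variant calls, epitope predictions, single-cell
TCR-seq), who need the bespoke scoring and selection logic between the
standard tools — not the standard tools themselves (variant calling,
clustering, survival model fitting are consumed or delegated, not
re-implemented).

## The core statistic

For a source gene $A$ and partner gene $B$ detected as transcripts with
planar positions and cell identities, the co-localization score is

$$ S(A,B) = \frac{2\,C(A,B)}{n_A + n_B}, \qquad
   C(A,B) = \#\{a \in A : \exists\, b \in B,\ \lVert a-b\rVert < r,\
   \mathrm{cell}(a) \ne \mathrm{cell}(b)\} $$

with a strict radius of $r = 30$ µm, same-cell pairs excluded, and each
source transcript counted once however many partners are near (which makes
the gene-by-gene matrix asymmetric). Scores of two conditions over the same
panel subtract into a differential matrix whose positive entries mean
"closer together in the case condition". Computation uses a fixed-radius
grid index and is exactly equal to the brute-force scan (tested), so a
500-gene panel at 100 transcripts/gene scores in about a second.

The other modules implement: a ≥3-of-4 missense consensus filter over
WES/RNA × in-vivo/in-vitro variant sets with germline exclusion; candidate
ranking on predicted affinity, TPM, agretopicity and foreignness;
polyepitope assembly minimizing the strongest junction epitope; clone-size
classes (1 / 2–5 / 6–30 / >30 cells); and the signature score
$\sum_g \log_2(\mathrm{expr}_g + 1)$ with a strict-above-median high/low
split.

## Worked example

```r
library(livmet)

# two synthetic tissue sections, one with a planted co-localized pair
cfg_case <- spatial_sim_config(seed = 11, n_genes = 8,
  transcripts_per_gene = 150, field_size = 1000,
  coloc_pairs = list(list(gene_a = "g001", gene_b = "g002",
                          sigma = 3, fraction = 0.7)))
cfg_ctrl <- spatial_sim_config(seed = 12, n_genes = 8,
  transcripts_per_gene = 150, field_size = 1000)

panel <- sprintf("g%03d", 1:8)
case <- coloc_matrix(gen_transcripts(cfg_case), panel = panel,
                     condition = "treated")
ctrl <- coloc_matrix(gen_transcripts(cfg_ctrl), panel = panel,
                     condition = "control")
case
#> Co-localization matrix: 8 x 8 genes, 1200 transcripts
#>   radius: 30 µm (strict); same-cell exclusion: TRUE
#>   condition: treated
#>   score range: [0.2067, 0.8333], NA entries: 0

d <- differential_matrix(case, ctrl)
round(as.matrix(d)[1:4, 1:4], 3)
#>        g001   g002   g003   g004
#> g001 -0.027  0.300  0.000  0.060
#> g002  0.473  0.087 -0.020 -0.047
#> g003  0.000 -0.047 -0.067 -0.013
#> g004  0.007 -0.120  0.013 -0.033
```

The planted pair stands out: the entry (g002 → g001) is +0.47 — about 47%
more of g002's transcripts have a g001 transcript within 30 µm in another
cell under treatment than in the control — while unplanted entries hover
near 0. `subset_heatmap(d, panel)` renders the diverging heatmap;
`write_coloc_matrix()` / `coloc_long()` export it.

The other modules in one breath:

```r
classify_clone(c(1, 4, 12, 55))
#> [1] unique  small  large  hyperexpanded
lv_copies_per_genome(100, 50)   # ddPCR: 2 * 100/50
#> [1] 4
tumor_volume(10, 8)             # caliper: 10^2 * 8 / 2 mm^3
#> [1] 400
```

and `consensus_filter()` → `integrate_scores()` → `rank_candidates()` →
`select_top()` → `assemble_construct()` takes four variant call sets to a
linker-joined FASTA construct (see the methods vignette,
`vignettes/livmet-methods.Rmd`, for the policies and their rationale).

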
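---
title: "Methods: spatial co-localization scoring, neoantigen selection and clonotype analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial co-localization scoring, neoantigen selection and clonotype analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livmet)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters and their defaults, what
the synthetic-data generators emulate (and do not), and the numerical and
design choices made where the methodology was genuinely open.

## 1. Transcript co-localization scoring

### The score

In-situ transcriptomic platforms (MERFISH/MERSCOPE) report every detected
transcript as a point: a gene label, a planar position in micrometres, and
the identity of the segmented cell containing it. For a *source* gene $A$
and a *partner* gene $B$, the close count is

$$ C(A, B) = \left| \{\, a \in A : \exists\, b \in B,\;
  \lVert a - b \rVert < r,\; \mathrm{cell}(a) \neq \mathrm{cell}(b),\;
  a \neq b \,\} \right| $$

and the normalized score is

$$ S(A, B) = \frac{2\, C(A, B)}{n_A + n_B}. $$

Three rules define the counting semantics:

* **Strict radius.** A pair at exactly $r$ micrometres is *not* close. The
  default $r = 30$ µm is the scale at which a disc covers a handful of
  cells (5–10 in typical liver sections), so the score probes cell-to-cell
  neighbourhoods rather than subcellular structure.
* **Same-cell exclusion.** Only transcripts originating from *different*
  cells are counted. Co-expression within one cell is a different (and much
  stronger) signal than spatial association between cells; excluding it
  keeps the score about tissue architecture.
* **Unique interaction.** A source transcript with several close partners
  counts once. This is what makes the matrix **asymmetric**: $S(A, B)$
  asks what fraction of $A$'s transcripts have a $B$-neighbour, while
  $S(B, A)$ asks the converse, and when $n_A \neq n_B$ or the point
  patterns differ the answers differ. A both-directions sum would be
  symmetric and was deliberately not used.

The normalization places $S$ in $[0, 1]$ whenever $n_A \le n_B$
(the fully-paired equal-count configuration attains exactly 1), but when a
source gene has many more transcripts than its partner the score can exceed
1; such values are reported unclamped with a warning rather than silently
truncated, because clamping would hide a strong asymmetry in abundance.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `radius` | 30 µm | strict close-distance threshold |
| `same_cell_exclusion` | on | drop same-cell transcript pairs |
| `unassigned_policy` | `"distinct"` | unassigned transcripts are singleton cells |
| `include_diagonal` | on | compute $S(A,A)$ with self-pairing forbidden |

Unassigned transcripts (no cell identity) are treated by default as their
own singleton cells: the exclusion rule is keyed on *sharing* a cell ID, and
a transcript outside any segmented cell shares its (non-)identity with
nothing. A `"drop"` policy removes them entirely, including from the
per-gene totals. The diagonal is computed (a gene can self-cluster across
cells) but a transcript is never its own partner; for a gene with zero
transcripts the diagonal is `NA` — in general an entry is `NA` exactly when
both genes have zero transcripts, and 0 when only the source or only the
partner is absent.

### Differential matrices

Two conditions scored over the same panel and parameters are compared
elementwise: `differential_matrix(case, control)` is `case - control`,
`NA`-propagating, so **positive entries mean the gene pair sits closer
together (higher co-localization) in the case condition**. The sign
convention is stored in the object's metadata because the two possible
orientations are easy to confuse. When one tissue section per condition is
insufficient, a `section` column pools sections: close counts and per-gene
totals are summed before normalizing (default), or per-section score
matrices are averaged (`combine = "mean"`). Pooling weights sections by
transcript count, which is the natural behaviour when sections differ in
area or detection efficiency.

### Complexity and exactness

The full matrix is computed with a uniform spatial grid of bin side $r$:
each transcript is compared only against the 3×3 neighbourhood of its bin,
giving $O(n \cdot \rho \pi r^2)$ work (density $\rho$) instead of the
quadratic all-pairs scan, and then unique (source transcript, partner gene)
pairs are tallied into the count matrix. The result is *exactly* equal to
the brute-force computation — the test suite asserts bit-identity against
an independent quadratic implementation on 100 random instances of up to
2,000 transcripts — and a 500-gene panel at 100 transcripts/gene
(50,000 points) scores in about a second. Scores are invariant under rigid
motions of the section; distance ties at the threshold are exact
floating-point comparisons, and test fixtures avoid placing points at
exactly $r$ except where strictness itself is under test.

## 2. Synthetic spatial data

`gen_transcripts()` emulates a detected-transcript table: uniform noise
genes over a square field, a square mosaic of 20 µm cells standing in for
segmentation (a 30 µm disc covers ≈ 7 mosaic cells, matching the
handful-of-cells neighbourhood the radius is designed to probe), and
planted co-localization: for each configured pair, a chosen fraction of the
partner gene's transcripts is placed at an isotropic Gaussian offset from
randomly chosen anchor transcripts of the other gene.

Two placement details matter:

* Coupled points falling outside the field are re-drawn, keeping per-gene
  counts exact.
* Coupled points falling in the **anchor's own mosaic cell** are re-drawn
  as well (default `couple_across_cells = TRUE`). Planted co-localization
  emulates *cross-cell* transcript proximity — the feature the score
  quantifies. With a small dispersion (e.g. σ = 2 µm against a 20 µm cell)
  an unconditioned Gaussian offset would leave ~80% of planted pairs inside
  a single cell, where the same-cell rule deliberately ignores them; the
  planted signal would then be mostly invisible to the very statistic it is
  meant to exercise. The rejection step uses the same mechanism as the
  field-border re-draw and is capped so a degenerate σ ≈ 0 cannot loop
  forever.

The generator does **not** emulate imaging optics, blank-barcode decoding
errors, segmentation errors, anisotropic tissue structure, or per-gene
abundance profiles of real panels (abundances are free parameters; real
500-plex panels span orders of magnitude). Passing the planted-recovery
tests therefore shows the scorer detects cross-cell proximity structure at
realistic densities — not that it is robust to segmentation artifacts.

Recovery is checked at a planted dispersion of 2 µm and coupling 0.8, with
200 transcripts/gene in a 1 mm² field: the planted pair's differential
entry (case vs an independent unplanted control) must be positive and
exceed the 95th percentile of null-pair entries in at least 19 of 20 seeds,
and pooled null entries must be centered at zero. The case and control use
independent seeds: a same-seed paired control would make null differential
entries exactly zero, which is a weaker test of the null distribution.

## 3. Neoantigen selection

The pipeline consumes *already-called* variant sets and *already-computed*
epitope predictor outputs; it implements the decision logic between them.

* **Consensus filter.** Missense variants, keyed by (chrom, pos, ref, alt)
  in 1-based VCF coordinates, must appear in at least 3 of the 4 datasets
  (WES/RNA × in vivo/in vitro). Germline-flagged variants are removed
  first. The filter is monotone: adding an occurrence of a variant to
  another dataset can only help it. At per-dataset detection probability
  0.9, the expected pass rate is the binomial tail
  $P(X \ge 3), X \sim \mathrm{Bin}(4, 0.9) = 0.9477$, which the synthetic
  generator reproduces.
* **Score integration.** Candidates from the two predictors are
  deduplicated by (peptide, allele), keeping the better (lower) affinity —
  the predictors disagree on a jittered scale, and the optimistic merge is
  the convention that loses no candidate. Expression is attached per gene;
  genes absent from the expression table get TPM 0 (and are then removed by
  the default ranking filter, since unexpressed mutations cannot be
  presented).
* **Ranking.** The four published criteria (affinity, TPM, agretopicity,
  foreignness) come with no published weights, so the policy is
  filter-then-sort with every number configurable: affinity ≤ 500 nM (the
  conventional weak-binder bound), TPM strictly > 0, agretopicity ≥ 1
  (mutant binds at least as well as wild type), foreignness ≥ 0; then
  ascending affinity with descending-TPM, descending-foreignness and
  alphabetical-peptide tie-breaks. Reproducing any specific published
  peptide list is out of scope — that requires the original sequencing data
  and predictor versions.
* **Construct assembly.** The selected peptides are concatenated with
  linkers (default `GGSGG`; the linker is configurable because published
  constructs differ) downstream of a leader moiety (CD74 by default, as
  metadata). Junctions create novel k-mers; the assembly orders peptides to
  **maximize the minimum junction k-mer affinity in nM** — i.e. make the
  strongest accidental junction epitope as weak as possible. All 8–11-mers
  spanning each junction (including linker residues: any k-mer not wholly
  inside one peptide) are enumerated and scored. Up to 7 peptides the
  bottleneck-optimal order is found exhaustively; beyond that a greedy
  chain heuristic starts from the pair with the weakest junction and
  extends at either end. The greedy result is checked to beat the median of
  random orders; the exact search makes the small-payload optimality
  guarantee unconditional rather than heuristic. The junction scorer is
  pluggable; a deterministic hash-based mock ships for tests, real use
  plugs in an MHC predictor wrapper.

## 4. Clonotype classes and sharing

Clonotype identity is the CDR3β amino-acid sequence (paired-chain keys are
out of scope). Expansion classes partition clone sizes as
1 / 2–5 / 6–30 / >30 (unique / small / large / hyperexpanded); 31 is the
smallest hyperexpanded size. Cells with no recovered TCR are excluded from
denominators. Because figures in this field sometimes count clonotypes per
class and sometimes cells, `clone_class_counts()` emits both tallies.
Sharing between tissues reports the intersection of key sets (symmetric in
the two tissues) with each key's size and class per tissue.

The clonotype generator draws clone sizes i.i.d. from a geometric law
(default, $1 + \mathrm{Geom}(p)$, $p = 0.5$) or a discrete power law,
trimming the last clone to hit the exact cell count; neither law is a claim
about real repertoires, they are conventional heavy-ish-tailed choices that
populate all four classes at realistic sample sizes. Sharing is planted by
key replacement, so the planted fraction is exactly recoverable up to
rounding.

## 5. Closed-form quantifications

* **Vector copy number:** `2 * concentration_HIV / concentration_normalizer`
  (copies per diploid genome); a zero normalizer concentration is an
  undefined measurement, not a zero.
* **Tumor volume:** `x² · y / 2` mm³ with `x` the larger caliper diameter;
  `y > x` is rejected as mislabeled rather than silently swapped.
* **Signature score:** per sample, the sum of `log2(expr + offset)` over
  the panel genes present in the matrix, stratified at the 50th percentile:
  strictly above the median is "high", ties go to "low" (the published rule
  is "above the 50th percentile", which is strict). The sum is used rather
  than a mean — for a fixed panel the two give identical strata, which is
  all the downstream survival fit consumes. The offset defaults to +1 so
  zero expression is defined; with offset 0 (all-positive matrices) strata
  are exactly invariant under any global rescaling $x \mapsto a x^b$,
  which is affine on the log scale; with a positive offset the invariance
  is approximate at very low expression. The 22-gene IIT signature ships as
  an editable text file pre-filled with its six published members; the full
  list is supplied by the user. The survival fit itself (Kaplan–Meier, Cox)
  is delegated to the survival package; `export_strata()` produces the
  joined (sample, score, stratum, time, event) table it consumes.

The expression generator plants two latent groups separated by a per-gene
log2 shift, with exponential survival times differing by group; the median
split recovers the planted labels up to the overlap probability of the two
score components, and the test suite checks exactly that bound.

## 6. Problem sizes used in the test suite

Scales were chosen as the smallest at which each statistical claim is
meaningful: oracle equivalence on 100 random instances of up to 2,000
transcripts; planted-recovery over 20 seeds at 200 transcripts/gene across
12 genes; consensus rates at n = 1,000 variants; full-panel scoring at 500
genes × 100 transcripts/gene. The grid-indexed scorer handles the latter in
roughly a second, so none of these sizes is a practical constraint for real
sections, which are typically within an order of magnitude of the largest
test case.

## 7. Known limitations

* Distances are planar; a z coordinate, if present, is ignored. On thin
  (~10 µm) sections the planar approximation is standard.
* The score has no built-in significance model; differential entries are
  descriptive. Permutation-based significance is a possible extension.
* The square-mosaic cell model in the generator is a deterministic stand-in
  for segmentation, not a cell-morphology model.
* The ranking policy's thresholds are conventions, not fitted values; real
  studies tune them against validation data.
* Clonotype sharing treats identical CDR3β strings as identical clones;
  convergent recombination is ignored.
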
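---
title: "Methods: OTU construction, taxon calling and diversity estimation for AMF amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: OTU construction, taxon calling and diversity estimation for AMF amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfdiv)
```

## The problem

Arbuscular mycorrhizal fungi (AMF, phylum Glomeromycota) are obligate root
symbionts whose species-level diversity is hard to survey. They cannot be
cultured axenically, spore morphology under-counts taxa, and — most
importantly for sequence-based surveys — a single fungal individual is
heterokaryotic: its hyphae and spores carry thousands of nuclei with
divergent rDNA copies, so one species emits a *cloud of ribotypes* rather
than one barcode sequence. Amplicon surveys of the ITS1 and ITS2 spacers
therefore face three linked problems:

1. **Clustering**: how to group reads into operational taxonomic units
   (OTUs) at a 97% identity radius without losing rare but real variants,
   while removing PCR chimeras and sequencing noise;
2. **Identification**: how to call species from highly polymorphic spacers
   when reference databases cover only part of the known diversity —
   leaving many clusters as sequence-defined *virtual taxa* (VTs);
3. **Ecology**: how to compare diversity across sites with unequal
   sequencing depth and relate it to site metadata.

`amfdiv` implements this workflow as composable, deterministic, tested
stages, together with a synthetic-community generator that emulates the
statistical structure of a field survey so every stage can be validated
against a known truth without any external database.

## Two-step OTU construction

Reads are merged (`merge_pairs`), length-filtered (`>= 120` bp, strict),
primer-stripped and filtered on expected errors
(`E = sum 10^(-Q/10) <= 1`, strict `>` discards). Filtering is applied
uniformly before clustering; the order merge → length → primer →
expected-error is fixed, and the length and error filters commute (both
are pure row filters), which the tests assert.

Clustering then proceeds in two steps on dereplicated sequences sorted by
(abundance descending, sequence ascending):

1. **Closed-reference mapping** (`closed_ref_map`): each unique sequence is
   assigned to the best-matching reference centroid at global identity
   `>= 0.97`. Identity is defined as *matching columns / all alignment
   columns, terminal gaps included*, from an end-to-end alignment with
   match +1, mismatch −1, gap open −2, gap extend −1. This is the
   strictest common convention; it is fixed here because "97%" is
   meaningless without a denominator. Assignment is best-hit (not
   first-above-threshold), with ties resolved toward the centroid with the
   larger already-mapped abundance, then the smallest accession — making
   the step order-independent. Singletons are *eligible* for mapping:
   reference centroids rescue reliable one-off reads that de novo
   clustering would discard.
2. **Abundance-greedy de novo clustering** (`denovo_cluster`): unmapped
   sequences join the highest-identity existing centroid at `>= 0.97`, are
   otherwise tested as chimeras, and otherwise found new centroids. After
   the pass, centroids whose total abundance is 1 ("residual singletons")
   are removed. The singleton policy is deliberately asymmetric:
   reference-mapped singletons are kept, de novo residual singletons are
   dropped.

**Chimera test.** A sequence is chimeric when a two-parent single-crossover
model (left prefix from one centroid, right suffix from another, crossover
scanned at 1-bp granularity) reaches identity `>= 0.99` while the best
single parent stays below the 0.97 radius. The parent pool includes the
*reference* centroids as well as the de novo ones: under a complete
reference panel nearly everything maps, so a de-novo-only pool would leave
recurrent chimeras of two reference-mapped parents undetectable, and they
would found spurious OTUs. The scan uses per-position match profiles from
one cached alignment per parent rather than re-aligning every crossover
model; on the substitution-only sequences the simulator emits the two are
equivalent, and the test suite confirms this against an oracle that builds
every crossover model explicitly.

## Genus-binned trees and the clade decision rules

OTU centroids are annotated by best global identity against the reference
panel (phylum-level floor 0.80), binned by best-hit genus — aligning
within genera is the only reliable option for AMF spacers, whose
between-genus divergence defeats alignment — trimmed to the spacer using
conserved anchor motifs (one mismatch allowed, soft failure), and aligned
per genus by center-star progressive alignment seeded on the longest
sequence. Each bin gets a neighbor-joining tree on p-distances (pairwise
deletion) with column-bootstrap supports.

The NJ implementation is deliberately pinned down: the lexicographically
smallest pair of node labels is joined among minimal-Q ties, children are
emitted in label order, and negative branch lengths are clamped to zero
with the deficit moved to the sister edge. This makes trees reproducible
and order-invariant, and NJ remains exact on additive matrices (verified
against path-length sums and `ape::nj` in the tests).

A manual workflow — inspecting trees, supports, p-distances and
species-specific substitutions — is formalized as ordered rules
(`classify_clades`), where a "clade" is a minority side of a supported
(`>= 70`) bipartition:

1. An OTU in a supported clade whose references all belong to one species,
   within `t_species = 0.03` p-distance of the nearest such reference, and
   not contradicting that species' diagnostic sites → **species call**.
2. Each remaining OTU joins its *smallest* supported reference-free clade;
   OTUs sharing that clade (after merging nested clades) form one
   **species-level VT**. Using smallest-then-merge rather than maximal
   clades keeps two sibling reference-free species separate when each has
   its own supported cluster, while still uniting a clade with a stray
   member that only clusters at the next level up.
3. An OTU in no supported clade and farther than `t_genus = 0.15` from
   every reference → **excluded** as a genus-level-or-higher VT; such
   sequences cannot be counted as species and would bias diversity
   estimates.
4. Remaining unplaced OTUs form VTs with other unplaced OTUs within
   `t_species` (single-linkage; components of size one are excluded).
   Sharing one label per component avoids double-counting a taxon that two
   singleton labels would introduce.

Thresholds (`S_min = 70`, `t_species = 0.03`, `t_genus = 0.15`) are
configurable; the defaults reflect common practice for intra-/interspecific
ITS divergence in this group and are *not* fitted to any dataset. VT
labels `VT_<genus>_<k>` are assigned by ordering clades on their smallest
member OTU id; since OTU ids are deterministic functions of the input,
labels are stable across reruns and invariant to input order. In bins too
small for a tree (fewer than four leaves there are no internal edges),
rule 1 falls back to the distance criterion alone.

## Hill diversity

Observed diversity of order *q* is `(sum p_i^q)^(1/(1-q))` with the
`q = 1` limit `exp(Shannon)`. Asymptotic estimates use Chao1 with the
`(n-1)/n` small-sample factor for `q = 0` (bias-corrected form when no
doubletons), the Chao–Jost entropy estimator with rare-species correction
`A = 2 f2 / ((n-1) f1 + 2 f2)` for `q = 1` (continuation
`A = 2 / ((n-1)(f1-1)+2)` when `f2 = 0`), and the minimum-variance
unbiased inverse Simpson for `q = 2`. Sample coverage is
`1 - (f1/n) * ((n-1) f1 / ((n-1) f1 + 2 f2))`. Confidence intervals are
percentile bootstrap (default 200 replicates) under the coverage-adjusted
multinomial model: observed frequencies shrunk to the estimated coverage
plus the Chao1-estimated number of unseen taxa sharing the remainder.
This percentile interval is a deliberate choice over analytic
approximations: it is distribution-free and seeds deterministically. When
every taxon is a singleton the order-2 estimator is undefined and is
flagged rather than patched.

## Community statistics

Counts are total-sum scaled; sample dissimilarity is Spearman distance
(1 − ρ, midranks for ties); group separation is tested by ANOSIM
(999 permutations, +1-corrected p, delegated to `vegan::anosim` under a
fixed seed); ordination by classical MDS (double-centering +
eigendecomposition) and PCA, both with a positive-dominant-loading sign
convention; clustering by Ward's method. Per-taxon group differences use
one-way ANOVA (Welch optional). No multiple-testing correction is applied
by default — group comparisons in this literature conventionally report
raw `p < 0.05` — but a Benjamini–Hochberg column is available
(`fdr = TRUE`). Report rounding is fixed (correlations to 2 decimals,
ratios to 1, means to integers) because the downstream comparisons are
against printed tables. At `n = 9` plots the two-sided 5% significance
threshold for a Pearson coefficient is `|r| > 0.6664`.

## The synthetic community generator

`sim_config()` fixes the study conditions; `generate_reference_db()`,
`simulate_reads()` and `simulate_metadata()` are deterministic given the
seed. What it emulates, and the values chosen:

* **Taxonomy**: 10 genera × 3 species by default, each species' spacers
  derived from a genus ancestor at half the inter-species divergence so
  congeneric pairs land near 10% p-distance; deep random background taxa
  (Ascomycota/Basidiomycota stand-ins) for the non-target fraction.
* **Heterokaryosis**: 3 ribotypes per species at 0.5% per-site divergence
  from the species reference, plus one-off "singleton" variants (5% of
  reads) emulating quasi-unique rDNA copies.
* **Artifacts**: 2% two-parent single-crossover chimeras (breakpoint
  uniform in the middle 50% of the amplicon — matching the two-parent
  model the chimera filter tests), 50% non-AMF background reads.
* **Read model**: error-free bases except substitutions injected at the
  rate implied by a two-state quality profile (Q38 good / Q12 bad, 3% bad
  bases), so the expected-error filter operates on a meaningful signal.
  No indels, PCR bias or length heterogeneity are modeled.
* **Depth**: 2000 read pairs per sample, 9 samples in 3 biotopes. The
  field survey this emulates sequenced ~10⁶ reads per plot; the simulator
  runs at desk scale because the properties under test (radius geometry,
  recovery, conservation, planted correlations) are scale-free. Tests and
  the acceptance script use 80–750 reads per run for the same reason.
* **Metadata**: altitude strictly ordered river valley < forest <
  subalpine meadow; "percent annual plants" planted to a target Pearson
  correlation with per-sample AMF abundance via a linear projection of the
  standardized abundance (`y = r z + sqrt(1-r²) ε`, mapped to 0–100). A
  Gaussian copula on ranks was considered but controls the *rank*
  correlation and attenuates the Pearson target under skewed read counts;
  the projection keeps the expected Pearson coefficient exactly at the
  target, which is the quantity the recovery checks measure. At small
  `n` the realized correlation is noisy (for `n = 9`, a 0.8 target
  commonly realizes anywhere in 0.5–0.95); recovery within ±0.05 holds in
  expectation for `n >= 50`.

What passing tests on this generator do **not** show: robustness to
indels and alignment ambiguity, platform-specific error spectra, PCR
abundance bias, or real reference-database annotation errors. The
generator is a statistical stand-in, not a sequencing emulator.

One emergent property worth noting: with 0.5%/site ribotype divergence a
ribotype occasionally drifts beyond the 3% radius and legitimately founds
a second OTU for its species. This mirrors the multiple-OTUs-per-species
phenomenon reported for heterokaryotic AMF in real surveys, and it is why
end-to-end "one OTU per species" recovery holds only up to a small
binomial tail.

## Numerical and degeneracy choices

* Identity/alignment: Biostrings `pairwiseAlignment` end-to-end, with the
  column count recovered as `n_a + n_b -` (base-to-base columns); exact
  agreement with exhaustive alignment enumeration is tested on short
  sequences.
* p-distance with zero comparable columns is an error (inside bootstrap
  replicates such pairs take the matrix maximum instead, so replicates
  never abort).
* All tie-breaks (dereplication order, mapping ties, NJ joins, Ward via
  `hclust`) are deterministic and documented at the function level.
* Boundary semantics: "shorter than 120" strict, expected-error `> 1`
  strict, supports compared with `>=`.
* Seeds: every stochastic stage takes an explicit seed; sub-seeds are
  derived arithmetically (stay below 2³¹) so stages are independently
  reproducible.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_genera = 4, species_per_genus = 3,
                  depth_per_sample = 250, n_samples = 6,
                  background_fraction = 0.3)
run <- run_pipeline(run_config(sim = cfg, n_boot = 50, n_perm = 199),
                    outdir = "amfdiv_demo")
run$study_table$stp_reads          # per-plot read/OTU accounting
run$markers$ITS1$summary$per_biotope
run$hill$ITS1$subalpine_meadow     # observed + asymptotic Hill numbers
run$stats$anosim                   # biotope separation
```

The packaged per-plot study tables (`study_table()`) reproduce the survey's
printed headline numbers exactly; `summary_tables()` recomputes them and
`scripts/acceptance.R` writes them (plus simulation-recovery metrics) as
JSON.

## Known limitations

* Center-star alignment is adequate at intra-genus divergence but is not a
  general MSA; indel-rich real data would need a dedicated aligner behind
  the same interface.
* The clade rules formalize a manual workflow; the thresholds are
  defensible defaults, not calibrated to any published per-genus
  p-distance table.
* Reference-free species represented by a single OTU cannot be
  distinguished from noise by rule 4 and are excluded — the same
  conservative bias the manual workflow has.
* ANOSIM/MDS run on whichever marker table is listed first; the two
  markers are analyzed separately by design (they behave as distinct
  barcodes), and cross-marker species-list union is by name only.
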
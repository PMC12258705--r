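---
title: "Methods: PSI estimation and stability analytics for N-terminal motifs"
author: "psifive"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSI estimation and stability analytics for N-terminal motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay being modelled

In the *E. coli* N-degron pathway, the first five residues (P1–P5) of a
protein's N-terminus determine whether it is recognized and degraded: the
N-recognin ClpS binds bulky P1 residues (Phe, Leu, Trp, Tyr) and delivers
substrates to the ClpAP protease, while the transferase LFTR converts
positively charged P1 residues (Arg, Lys) into ClpS substrates by
appending Leu/Phe. A binned-sorting (FACS-seq) screen probes this at
scale: an NNK-mutagenized five-codon library is fused to a fluorescent
reporter, cells are sorted into four fluorescence bins (B1 least stable …
B4 most stable), each bin's amplicon pool is sequenced, and every motif's
stability is summarized by the **Protein Stability Index**

$$\mathrm{PSI} = \sum_{i=1}^{4} R_i \cdot i,$$

where $R_i$ is the fraction of the motif's reads in bin $i$. PSI ranges
from 1 (all reads in the least-stable bin) to 4 (all in the most-stable
bin).

`psifive` implements this pipeline end to end — a synthetic sorted-library
generator, amplicon filtering and counting, PSI databases, comparative
analytics between host genotypes (wild type, ClpS⁻, LFTR⁻), and a
gradient-boosted sequence→PSI regressor with additive attributions — so
that every downstream stage is testable without any sequencing download.

## The synthetic sorted-library generator

The generator is first-class, tested code, not a fixture. It emulates:

* **Library composition.** Five NNK codons (N = A/C/G/T, K = G/T) are
  drawn position-wise, so all 32 codons — including the TAG stop — occur
  at their natural frequencies. Members whose mutagenized region
  translates to a stop are excluded from the cloned library (they produce
  no fluorescent reporter); stop-containing *reads* still arise
  downstream through sequencing errors and are exercised by the filters.
  Member abundance is log-normal (`abundance_dispersion`, default sdlog
  0.5), reflecting uneven NNK cloning.

* **Ground truth.** An `effect_model()` assigns each motif a true
  stability on the PSI scale: baseline + additive residue–position
  effects + optional pairwise interactions, clamped to [1, 4]. Every
  effect carries a dependency tag (`"clps"`, `"lftr"`, `"clps+lftr"`);
  knockout genotypes suppress the matching effects, which is what makes
  genotype-difference analytics recoverable by construction. The shipped
  preset encodes the pathway's known qualitative behaviour (bulky/charged
  P1 destabilization, P2 Pro/Gly stabilization, P2 Gln destabilization,
  acidic stabilization, an Nt-Cys interaction) at plausible magnitudes;
  it is a recovery fixture, not a reproduction of measured values.

* **Sorting.** A latent-Gaussian model: a cell's log-fluorescence is
  Gaussian with mean equal to the motif's true stability and spread
  `noise_sd`, partitioned by three thresholds (default 1.5, 2.5, 3.5)
  into the four bins. This is the simplest model that yields unimodal,
  stability-ordered binning. `noise_sd` defaults to 0.2 — the largest
  round value for which a motif at either end of the scale places ≥ 99%
  of its mass in the extreme bin, which we treat as a definitional
  property of a well-gated sort. The real screen's fluorescence
  distributions had long tails spanning orders of magnitude; the Gaussian
  deliberately does not reproduce that shape, nor debris,
  reporter-inactivating mutants, or PCR bias.

* **Read allocation.** Reads are drawn by a single multinomial over all
  (member, bin) pairs with weights `abundance × P(bin | stability)` and
  total budget `sum(depths)`. Realized per-bin read counts therefore
  track the population's bin occupancy — the regime of a screen in which
  each sorted pool is sequenced in proportion to its cell count, and the
  regime in which the literal read-fraction PSI is a consistent
  estimator. A bin into which no cell sorts receives no reads (for a
  flat ClpS⁻ population the two low bins are empty). The default depth
  proportions are the screen's WT sorted-cell counts scaled to a
  400,000-read budget.

* **Errors.** Substitutions only, i.i.d. per base (default 0.001).
  Indels are excluded deliberately: the downstream filters are
  exact-match, so an indel read would simply be discarded — modelling
  them would only relabel ledger categories.

A count-level fast path, `simulate_motif_counts()`, draws each motif's
per-bin counts directly (a fixed number of reads per motif through its
bin probabilities), skipping FASTQ assembly. Parameter-recovery tests use
it at 20,000 motifs × 200 reads; FASTQ round-trips are exercised at
~2,000 motifs × 200,000 reads, where the whole
simulate → count → PSI chain runs in seconds and recovers true stability
with Pearson r ≈ 0.99.

## Read filtering

Filters run in a fixed order, and each read is discarded by exactly one
rule, so the discard ledger partitions the input:

1. **Demultiplex** — exact match of the 3-nt barcode at its declared
   offset (`barcode-mismatch` otherwise; ambiguous bases fail).
2. **Consensus** — every base outside the barcode slot and the 15-nt
   mutagenized region must equal the template (`consensus-mismatch`).
   Zero mismatches is the policy; a mismatch budget exists behind an
   argument but defaults to 0.
3. **Extraction** — the first exact occurrence of the 15-nt anchor
   locates the region as the 15 nt immediately 5′ of it (`no-anchor` if
   absent or too close to the read start). The template constructor
   rejects anchors that also occur in the upstream consensus, making
   first-match unambiguous.
4. **Translation** — standard genetic code; any stop codon (TAG, TAA,
   TGA) rejects the read (`stop-codon`), as does any N in a codon
   (`ambiguous-base`); scanning is left to right and the first failing
   codon's rule wins.

Coordinates are 0-based half-open in all configuration. Reads are treated
as single, already-oriented sequences; paired-end merging and
reverse-complement handling are the caller's concern. No quality-based
filtering is applied (the screen reported Q30 > 95% and applied none).

## PSI normalization modes

The literal definition — $R_i$ = fraction of the motif's reads in bin
$i$ — is `mode = "raw"` and the default. It is the consistent estimator
whenever per-bin sequencing depth is proportional to per-bin cell counts,
which holds for the simulator and for the screen it models. A second
mode, `"depth"`, first divides each bin's count by that bin's total
sequencing depth and renormalizes; it is appropriate when bins are
sequenced to a fixed budget unrelated to their occupancy. The database
records the mode in its TSV header. Motifs with zero kept reads are
absent rather than stored as NaN; `min_reads` filtering (default 1;
model training uses 20) happens at database construction.

## Comparative analytics

All analytics are pure functions of the motif database.

* **Residue–position matrices** (20 × 5, canonical residue order): mean
  PSI per (residue, position) cell with per-cell n; empty cells are `NA`,
  never zero-filled. Genotype differences are cellwise subtractions
  (antisymmetric by construction); conditional matrices restrict to a
  fixed residue at one position and summarize the remaining four.

* **Contrasts.** Two-sided Mann–Whitney U (exact enumeration when
  min(n₁, n₂) ≤ 8 and tie-free; otherwise the normal approximation with
  midranks, tie-corrected variance, and continuity correction — PSI
  values tie heavily at low counts) plus Cliff's delta computed from
  midranks, which is algebraically identical to the all-pairs definition.
  Effect size is reported as |delta| with the signed value retained, and
  annotated: `*` p < 0.05 & ES 0–0.25, `**` 0.25–0.50, `***` 0.50–0.75,
  `****` 0.75–1.0. In the far tails (exact p ~ 10⁻⁴ at n = 8) the normal
  approximation deviates from exact enumeration by design of the
  approximation, not of this package. No multiple-testing correction is
  applied anywhere; raw p-values are reported alongside effect sizes.

* **Enrichment.** P1/P2 log2 stable/unstable enrichment normalizes each
  stratum to its own size before the ratio (frequency normalization,
  chosen over subsampling to keep the pipeline deterministic); pairs
  absent from a stratum are `NA`. Fold-enrichment logo matrices divide
  positionwise subset frequencies by background frequencies.

* **Charge and property groups.** Net charge counts R/K as +1, D/E as
  −1, His as 0 (forced by the printed values of the clonal charge series:
  FDEDE = −4, FRKAA = +2), with an optional position mask because some
  analyses sum P2–P5 only. Group counts use the canonical property sets
  (Negative DE, Positive RK, Hydrophobic AVILMFWY, Polar RNDQEKHSTYC,
  Aromatic FWYH, Small GASC, Flexible GSDN, Bulky FLWY, and the
  canonically destabilizing FLWYRK).

* **P1 Pro.** Analyses that exclude P1 Pro (it is the one residue whose
  ubiquitin fusion is not uniformly cleaved in the assay) take exclusion
  arguments; the analysis drivers exclude it where the modelled screen
  did.

* **MetAP comparison.** For each residue X, motifs `M-X-Y₃-Y₄-Y₅` are
  compared with motifs whose first four residues match the `X-Y₃-Y₄-Y₅`
  windows observed behind Met — a positive difference means Met excision
  would expose a more degradation-prone N-terminus. This needs dense
  coverage of matching windows; at desk scale the tests use a
  sub-alphabet library to guarantee density.

## The stability regressor

Motifs are one-hot encoded into 100 binary features (position-major,
residue-alphabetical; the order is frozen and stored in the model
artifact), with PSI as the 101st column of the training matrix. Training
follows the screen's recipe: minimum 20 reads per motif, seeded 80/20
random split, gradient-boosted trees with the tuned hyperparameters
(986 estimators, depth 11, learning rate 0.085, subsample 0.904,
colsample_bytree 0.810, squared-error objective). Split and training
seeds are explicit configuration; early stopping is off. Where training
descriptions disagree on length ("20 rounds" vs 986 estimators), the
tuned estimator count is taken as authoritative. Predictions are clamped
to [1, 4] for reporting, since the target is bounded; attribution uses
exact tree-path additive (SHAP) contributions whose sum equals the *raw*
prediction — to within ~10⁻⁵, the booster's single-precision arithmetic,
which is why the additivity tests assert 10⁻⁴ rather than a
double-precision tolerance.

Attribution sign-recovery is evaluated as the mean contribution of a
feature *among motifs carrying it*: by the SHAP sum rule the
unconditional mean over random motifs is pulled toward zero by the 95%
non-carriers, so the carrier-conditional mean is the quantity that
reflects an injected effect's sign.

Two caveats on interpretation. First, the latent-Gaussian sort makes the
map from true stability to expected PSI a smooth staircase: scores at
thresholds or midway between them are fixed points, but intermediate
effects are locally compressed or expanded, so recovered magnitudes match
injected ones exactly only at staircase fixed points (recovery tests are
designed on those points). Second, boosted trees do not extrapolate to
stabilizer combinations unseen in training, so constrained candidate
selection explores the model's learned range, not the theoretical
additive optimum.

## Problem sizes and determinism

The test suite simulates at 2,000–20,000 motifs and 10⁵–4×10⁶ reads,
sizes at which multinomial sampling error on per-cell means is well below
the 0.1-PSI recovery tolerances used; the full-size model configuration
is trained once on a 20,000-motif database. All randomness flows through
explicit seeds: identical simulator configurations produce byte-identical
FASTQ, and identical split/training seeds reproduce the training report
on a fixed machine configuration.

## Known limitations

* The generator's Gaussian fluorescence cannot produce the heavy
  low-fluorescence tails, debris, or reporter-inactivating mutants of
  real sorts, so passing recovery tests demonstrates estimator
  correctness under the stated sorting model, not robustness to gating
  artifacts.
* PSI confidence intervals and shrinkage of low-count motifs are out of
  scope, as in the screen being modelled.
* LFTR polyaddition (multiple Leu/Phe appended before Arg/Lys) is
  represented only implicitly through `"clps+lftr"`-tagged P1 effects,
  not as sequence rewriting.
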
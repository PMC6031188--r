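---
title: "Adjudicating CRISPR off-target mutations from whole-genome variant calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjudicating CRISPR off-target mutations from whole-genome variant calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otwgs)
```

## The problem

Whole-genome sequencing of a CRISPR-edited plant yields hundreds of
variant calls, almost none of which have anything to do with the
nuclease. A regenerated rice plant typically carries on the order of a
hundred SNVs and a few dozen indels from the tissue-culture process
alone, plus pre-existing variants inherited from its parental line,
additional indels associated with *Agrobacterium*-mediated
transformation, and a steady trickle of spontaneous mutations
(roughly 23 SNVs and 18 indels per generation, i.e. a per-site,
per-diploid-genome, per-generation rate near 5 x 10^-8). Deciding
whether any particular call is a true nuclease off-target event is
therefore a subtraction-and-attribution problem, not a detection
problem.

`otwgs` implements that adjudication as a reusable, testable pipeline:

1. **Consensus.** Per sample, variants are accepted only when every
   caller (three, in the emulated default) reports the identical
   normalized `(chrom, pos, ref, alt)` key, and only at allele
   frequency >= 10% (calls below that are indistinguishable from
   sequencing error). Consensus AF and depth are medians across
   callers.
2. **Subtraction.** Variants present in any control sample — wild-type
   generations, tissue-culture-only regenerants, *Agrobacterium*- and
   nuclease-backbone controls — are moved to a ledger tagged with the
   absorbing group. Pedigree variants outrank everything else.
3. **Homology.** Each guide's potential cutting sites are enumerated by
   a both-strand protospacer+PAM scan (Cas9 `NGG`, optionally `NAG`;
   Cpf1 `TTTV`) within a mismatch budget, with mismatches inside the
   PAM-proximal 18-nt seed tracked separately. A bulge-aware local
   alignment of mutation flanks (25 bp each side) covers
   insertion/deletion-type homology the Hamming scan cannot see.
4. **Replicate logic.** Surviving indels that overlap a guide-homologous
   site are off-target candidates. They are *validated* when an
   independently regenerated line carrying the same guide is edited at
   the same site with a **distinct** allele — independent repair events
   at one locus are the signature of a nuclease, whereas identical
   shared alleles at loci with poor protospacer homology indicate
   inheritance from the parental line and are classified pre-existing.
5. **Profiling.** Mutation rates, pyrimidine-folded SNV spectra,
   allele-frequency bins (somatic-like `[0, 0.25]`, heterozygous-like
   `(0.25, 0.75)`, homozygous-like `[0.75, 1]`), and
   feature-category enrichment with BH-corrected binomial tests.

## Classification rules, in order

For each post-subtraction variant of an edited sample:

1. In the control ledger or pedigree: `pre_existing` (wild-type or
   pedigree absorber) or `background` (culture/transformation groups).
2. Overlapping the declared target site (+/- 5 bp): `on_target`.
3. An indel overlapping another guide-homologous site:
   `off_target_candidate`, promoted to `off_target_validated` when
   (a) an independent replicate line carries a *different* indel allele
   at the same site, or (b) controls were checked, the variant is
   absent from all of them and the pedigree, and the site is of
   prediction-grade homology (<= 3 protospacer mismatches). SNVs at
   sites stay candidates with a warning tag and are never validated:
   nuclease repair products are indels, and SNV dominance at shared
   loci argues against nuclease origin.
4. Shared with an identical allele by the replicate but unassigned or at
   poor homology (> 6 mismatches): `pre_existing`.
5. Otherwise `spontaneous`.

Rule 3b deserves a note: validating an off-target from a single line is
inherently interpretive. We require both the negative evidence (absence
from every control and the pedigree) and strong positive homology
(<= 3 mismatches, the budget at which off-target prediction tools
operate). Without the homology condition, the generous 10-mismatch
budget used for *mapping* mutations to candidate sites would promote
variants at homology levels that argue against nuclease origin.

A guide is **unsafe** when at least one locus carries a validated
off-target mutation. For prospective design, `guide_specificity()`
applies the seed rule instead: a guide passes when every non-target
site within 3 mismatches has at least 2 mismatches inside the 18-nt
seed.

## The synthetic cohort generator

No sequencing data ships with the package; the generator produces
cohorts with the statistical structure the pipeline is meant to face,
and the test suite scores the pipeline against the generator's truth.
Per-class defaults (Poisson means per sample):

| class | SNVs | indels | AF mode |
|---|---|---|---|
| founder pre-existing (shared by all lines) | 50 | 20 | heterozygous |
| tissue culture (every regenerant) | 114 | 36 | heterozygous |
| spontaneous (per parent-to-progeny link) | 23 | 18 | heterozygous |
| *Agrobacterium* extra (transformed lines) | 0 | 28 | heterozygous |

The culture and spontaneous loads are the reported per-sample averages
for rice; the *Agrobacterium* excess is reported only as a range
(~15-41 extra indels) with large variation, so it is exposed as a
configurable mean with the midpoint as default. The founder load is not
quantified per-sample anywhere we know of; 50+20 heterozygous variants
is our choice of a realistic shared parental-line load, and nothing in
the validation depends on its exact value since pedigree-shared
variants are subtracted exactly.

Edits are planted at the nuclease cut position (Cas9: blunt cut 3 bp 5'
of the PAM; Cpf1: after protospacer position 18, the staggered-cut
region) with alleles drawn uniformly from a fixed catalog of 25 indels
(deletions of 1-15 bp, insertions of 1-10 bp with a fixed inserted
sequence per length). The catalog makes "same allele vs distinct
allele" comparisons exact and gives replicate lines a known 1/25
probability of drawing identical alleles at a shared site. Emulated
callers see the truth set minus independent false-negative drops
(default 1% per caller), plus uniform false-positive SNV calls
(default 10^-5 per bp per caller) never coinciding with a truth
position, with Gaussian AF noise (sd 0.05) truncated to `[0, 1]`.

What the generator does **not** emulate: read-level errors and mapping
artifacts (caller errors are independent by construction, which is
exactly what makes strict intersection so effective — correlated
artifacts in real data will survive consensus more often), mosaicism,
structural variants, and segregation in T1 progeny (T1 lines inherit
the full parental set plus one spontaneous generation). Passing the
recovery suites therefore demonstrates that the decision logic is
implemented correctly under the stated statistical conditions, not that
real cohorts are free of correlated artifacts.

## Randomness and determinism

A single integer seed drives everything through a counter-style stream
hierarchy: each (sample, stage, replicate) derives its own seed by
hashing the tag into the parent seed (`derive_seed()`), with Lehmer
scrambling rounds so that near-identical tags do not yield adjacent
seeds (adjacent Mersenne-Twister seeds produce visibly correlated first
draws). Adding a sample to a design therefore never perturbs the truth
sets of existing samples, and identical seeds reproduce byte-identical
cohorts. The analysis pipeline itself consumes no randomness: re-runs
on the same inputs are byte-identical.

## Numerical and boundary choices

* AF floor inclusive: `af >= 0.10` is retained — "below 10%" excludes
  strictly smaller values. The floor is applied to the consensus
  (median) AF after intersection by default; whether to filter per
  caller instead is genuinely ambiguous, so it is exposed as
  `af_per_caller` in `consensus_sample()`.
* AF bins: 0.25 assigned to somatic-like (downward), 0.75 to
  homozygous-like (upward); only the outer bins are standard, the
  boundary assignment is ours.
* Variant keys compare only after left-aligned, minimal normalization
  (suffix trimmed, single anchor base, indels shifted leftmost through
  repeats). Near-miss indels (same locus, different allele) never
  match — allele identity is load-bearing for the replicate logic.
* Site coordinates are 0-based half-open internally and 1-based in all
  reports; the round-trip is covered by tests.
* Seed length defaults to 18 (PAM-proximal positions 1-18); the
  literature often uses 10-12, so it is configurable everywhere.
* `NAG` is opt-in: off for guide-design safety checks, on (by default)
  when mapping mutations to sites during classification.
* Reference `N` never matches a protospacer position (counts as a
  mismatch) and never satisfies a PAM position.
* Bulge alignment allows at most one 1-nt gap, with gap penalty 1.5 so
  a single bulge outranks two mismatches; gap types are labelled by the
  Cas-OFFinder convention (DNA bulge = extra base in the DNA target,
  RNA bulge = base missing from the target).
* Assignment window: a variant maps to a site when its reference
  interval intersects the protospacer+PAM interval padded by 5 bp
  (covering resection around the cut); ties break by lowest mismatch
  count, then seed mismatches, then position.
* Simulated variants never overlap: colliding draws are resampled, and
  planted edits are drawn before background so background cannot erase
  an edit.
* Overlapping feature annotations resolve by precedence CDS > UTR >
  intron > TE > repeat > intergenic (plant TEs overlap genes);
  uncovered genome is intergenic.

## Validation studies and problem sizes

The suite validates the pipeline at fixed, documented scales chosen to
keep a full run comfortably on one CPU:

* **Scanner-oracle equivalence** — 100 random 50-kb genomes x random
  guides, budgets 0-5 mismatches, PAM sets `NGG` / `NGG+NAG` / `TTTV`,
  against an exhaustive window-enumeration oracle.
* **Consensus robustness** — one 1-Mb genome, 100 cohort draws, three
  emulated callers at 2% miss rate and 10^-5/bp false positives: zero
  consensus false positives expected (independent errors essentially
  never agree on a key), recall bounded by 0.98^3 ~ 94.1%.
* **Planted-truth recovery** — a 20-Mb, 10-contig genome (desk-scale
  stand-in for the ~374-Mb rice genome; the genome and the 15-guide
  panel are fixed, the mutational and caller processes are re-drawn),
  50 cohort draws of 37 samples each; off-target sensitivity,
  background-false-validation, and per-guide safety flags are scored
  against generator truth.
* **Rate recovery** — one 10-Mb genome, 50 draws of 8-link wild-type
  trio chains at a true rate of 5.4 x 10^-8.

The worked replicate-logic example (seven shared-locus/distinct-allele
indels, five single-line site indels, ten shared identical-allele
variants far from any site) is constructed exactly and must classify
12 validated loci and 10 pre-existing variants.

## Known limitations

* The Hamming scanner is exact but not indexed; it is linear per guide
  and contig and sized for desk-scale genomes, not for scanning
  thousands of guides against gigabase assemblies.
* No thermodynamic or learned off-target scoring — site ranking is by
  mismatch and seed-mismatch count only.
* Background rates are treated as sample-class constants; real
  tissue-culture mutagenesis varies between regeneration events, which
  only widens per-sample counts, not the classification logic.
* Validation from a single line (rule 3b) remains interpretive however
  it is parameterized; the evidence trail records which promotion path
  fired so downstream consumers can filter on it.
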
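---
title: "Delimiting cryptic species with two mitochondrial barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting cryptic species with two mitochondrial barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(cryptgap)
```

## The problem

Morphology-based surveys of marine invertebrates routinely lump
genetically distinct lineages under one name. Such *cryptic species* —
morphologically indistinguishable, genetically divergent — inflate the
apparent range and deflate the apparent richness of the taxa involved.
The standard molecular screen is DNA barcoding: sequence one or two
fast-evolving mitochondrial markers (the ~660 bp COI "Folmer fragment"
and/or ~500 bp of 16S rDNA) from many individuals per morphospecies and
ask whether the within-species genetic variation and the between-clade
variation form separated distributions — the *barcoding gap*.

`cryptgap` packages that workflow end to end for a two-locus survey:

1. per-locus pairwise **K2P distances** from pre-aligned FASTA,
2. **clade inference** within each morphospecies (distance clustering,
   or imported trees with posterior supports),
3. **gap and ratio tests** deciding cryptic species vs unresolved
   species complex,
4. **scenario classification** reconciling the two loci,
5. **MB-style labelling** and a before/after **species-richness
   ledger**,
6. a seeded **K2P sequence simulator** so every stage is testable
   without downloads.

## The distance model

For an aligned pair, let `P` and `Q` be the observed proportions of
transition (A↔G, C↔T) and transversion differences among the sites that
are unambiguous and ungapped in *both* sequences (pairwise deletion).
Kimura's two-parameter correction estimates substitutions per site as

$$d = -\tfrac12 \ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\,\big].$$

Two numerical policies matter:

* **Pairwise deletion**, not complete deletion. Barcoding data have
  ragged ends; deleting a column for everyone because one specimen is
  short throws away most of the signal. The comparable-site count `L`
  is kept per pair and reported. The source surveys this package
  models rarely state their deletion policy, so second-decimal
  differences against published tables are expected.
* **Saturation is flagged, not clamped.** When `1 − 2P − Q ≤ 0` the
  estimator has no finite value; such pairs get status `saturated`,
  are excluded from all summary means, and their count is carried into
  the reports. Inventing a ceiling distance would silently bias the
  gap statistics.

Distances are stored as proportions and always *reported* ×100 as
percent, the field's convention.

## Clade inference

The published analyses this package operationalises delimit clades from
Bayesian tree topology plus expert judgement; no explicit distance
threshold exists there. `cryptgap` makes the rule explicit and
overridable:

* `cluster_by_threshold()` — agglomerative clustering (single linkage
  by default, mirroring the connectivity notion of a clade; average
  linkage for robustness checks) cut at **0.03 for COI** and **0.01
  for 16S**. The defaults sit inside the empirically observed
  separation: intra-clade barcode variation is typically below 1%
  while COI inter-clade divergence is typically ≥6%. Merges happen
  strictly *below* the threshold, so ties at the cut separate —
  determinism over generosity.
* `partition_from_tree()` — when an externally inferred tree with
  posterior supports is available, clades are the maximal monophyletic
  groups of the morphospecies' specimens whose node support is
  ≥ `min_support` (default 0.95, the conventional significance mark);
  everything else becomes a singleton.

Single-linkage clustering at threshold *t* is provably the
connected-components partition of the graph with edges `d < t`; the
test suite checks that equivalence against an independent
transitive-closure oracle.

## Gap, ratio and the delimitation verdict

With a partition in hand, `variation_summary()` pools the within-clade
and between-clade pairwise distances (plain arithmetic means of the
pooled pairs — the source figures do not state whether clade-pair means
were themselves averaged, and pooling is the simpler, variance-weighted
choice). Two complementary statistics are reported rather than hidden
behind one verdict:

* **gap** = min inter − max intra (strict non-overlap when positive);
* **ratio** = mean inter / mean intra, with the conventional 10×
  rule-of-thumb threshold (`ratio_k = 10`).

`delimit()` then decides: one clade → `single_species`; gap present
*and* ratio passed → `cryptic_species`; otherwise, if congeneric
reference distances are supplied and the observed mean inter-clade
divergence falls at or above the smallest reference inter-species
distance, still `cryptic_species` (with a note — the "similar to known
congeners" argument made explicit); otherwise `species_complex`. A
partition of only singletons is `undetermined`. Requiring *both* gap
and ratio for the unassisted call is deliberate: under single linkage
the minimum inter-clade distance is structurally at least the
clustering threshold, so a gap alone is weak evidence at marginal
divergences; the ratio test is what fails in the published borderline
cases (e.g. 2.28% vs 0.25%, ratio ≈ 9, called a complex).

One property worth recording: merging two clades always grows the
intra pool and shrinks the inter pool, so `max_intra` and `min_inter`
are monotone under coarsening — but the pooled *mean* inter can move in
either direction, since the removed cross-pairs may lie above or below
the pool average. The tests assert the monotone facts, not the
tempting-but-false mean version.

## Two-locus scenarios and labels

`classify_scenario()` reconciles the per-locus verdicts into the four
evidence classes such surveys report:

* **S1** — every available locus says cryptic and the partitions are
  *coherent* on shared specimens (no two clades of one locus both
  split across the same two clades of the other; the weakest formal
  reading of "clade groupings consistent across genes"). A
  single-locus dataset with a clean cryptic signal is also S1.
* **S2** — COI establishes cryptic species, 16S is present but absorbs
  the clades (single clade, or an unresolved complex that does not
  contradict COI). This matches the published handling of a
  morphospecies whose COI split is invisible in 16S.
* **S3** — a complex/undetermined verdict with no locus establishing
  cryptic species; also the conservative bucket for conflicting loci
  (both cryptic with crossing partitions, or 16S-cryptic against a
  COI single clade — cases with no published precedent).
* **S4** — a single clade everywhere.

`assign_mb_labels()` mints the species labels: distinct integers
(`MB1`, `MB2`, …) for cryptic species, one integer with clade letters
(`MB1a`…) for a complex, bare `MB` for an unsplit morphospecies and
for specimens that lack the discriminating locus and whose block
cannot be mapped unambiguously across loci. Numbering is deterministic:
clades ordered by size (descending), ties by smallest specimen id.

## The richness ledger

`tally()` turns a species table (one row per secondary species) into
the before/after accounting: each MB-numbered species adds one, a
lettered complex adds one in total, each morphological reassignment
adds one. Two conventions are load-bearing:

* the reported richness percentage is the **after/before ratio** ×100
  (35 from 15 prints as 233), matching the headline convention of the
  survey the packaged table encodes, not the 133% increase;
* a cryptic lineage that *replaces* its parent name one-for-one is a
  retained row carrying the cryptic flag — it flags the morphospecies
  without adding to the counts. This is the only reading under which
  the packaged table's totals (15 primary, +10 cryptic, +10
  reassigned, 35 total, 8 of 15 flagged) reconcile simultaneously.

The reconciliation identity `total = primary + cryptic_additions +
reassignment_additions` is enforced at construction and property-tested
on randomized tables.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates two-locus datasets with planted truth:
each morphospecies holds 1–3 clades; a random root is evolved into one
ancestor per clade and on to each specimen under the continuous-time
K2P process (transition/transversion rate ratio `kappa`, default 2).
With the total substitution rate normalised to 1 per site, branch
lengths are literally expected K2P distances, so planted values are
calibrated by construction: ancestor branches of
`(inter − intra) / 2` and tip branches of `intra / 2` give expected
pairwise divergence `inter` between clades and `intra` within. The
event process is simulated exactly (per-site Poisson event counts with
a jump chain — uniformisation of the CTMC, exact because the exit rate
is state-independent), which is what lets the closed-form expectations
serve as oracles in the tests.

Defaults mirror the study conditions the package models: 15
morphospecies, COI 660 bp / 16S 500 bp, 16S evolving at 1/3 the COI
rate, planted inter-clade divergence 10% (COI scale) against 0.5%
intra, COI available for 60% of specimens and 16S for 95% (COI
amplification fails more often in practice), 5 specimens per clade.
`simulate_scenario_suite()` fixes one bundle per scenario: S1 (three
clades, both loci separated), S2 (COI 8% vs a 16S planted inter equal
to intra, so 16S collapses), S3 (16S-only, inter 2.5% vs intra 0.5% —
ratio 5, below the rule), S4 (one clade).

Deliberate omissions, hence limits on what passing tests show about
real data: no indels (alignment is out of scope; gap handling is
exercised by hand-built fixtures), no rate heterogeneity across sites,
no selection or coalescent genealogy, site-independent evolution, and
clade ancestors drawn as a star from the root rather than under a
birth–death process. Real barcoding data violate all of these mildly;
the simulator validates the *pipeline logic*, not the biological
realism of K2P.

## Validation problem sizes

The shipped test suite runs entirely from generated data: 12-specimen
fixtures for the brute-force distance and clustering oracles, 1,000
random `(P, Q)` pairs against a frozen 40-digit evaluation of the K2P
formula (tolerance 1e-12), 1,000 simulated pairs of length 10,000 for
estimator consistency (3 standard errors), and 200 seeded replicates
per scenario bundle for ≥95% end-to-end recovery. The same
computations, re-seeded from the command line, are what
`scripts/acceptance.R` reports.
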
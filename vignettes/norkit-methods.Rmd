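---
title: "Methods: simulating and analysing a human nucleolar organizer region"
author: "norkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a human nucleolar organizer region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system being modelled

A human nucleolar organizer region (NOR) is the stretch of an acrocentric
short arm that carries a tandem array of ribosomal DNA units between a
proximal junction (PJ, centromeric) and a distal junction (DJ, telomeric).
Each unit is roughly 43 kb: a ~13 kb transcribed region encoding the 47S
pre-rRNA (5'ETS, 18S, ITS1, 5.8S, ITS2, 28S, 3'ETS) followed by a ~32 kb
intergenic spacer (IGS).  NORs are still gaps in reference assemblies, and
the experimental route to closing one — releasing the whole array with a
restriction enzyme that never cuts inside rDNA, capturing it in yeast by
recombination with short vector-borne "hooks", sequencing the resulting
circular clone, and comparing the units against a reference unit — defines
a chain of computations that this package implements on synthetic data with
known ground truth.

Every stage is therefore checkable: the generator records the variants it
plants, the planted restriction sites, the released fragment, and the clone
insert, and the analysis stages are tested by recovering those records.

## The synthetic NOR generator

`nor_spec()` / `build_nor()` emit PJ + n units + DJ.  Background sequence is
i.i.d. at the configured GC content (default 0.55, rDNA-like): downstream
operations depend only on motif placement and edit structure, not on
realistic k-mer composition, so a compositional model is sufficient and
keeps every expectation analytically available.  Region lengths default to
the standard human unit layout (3657 / 1869 / 1077 / 157 / 1167 / 5070 /
361 / 29,642 bp, a 43,000 bp unit), all scalable by one factor for fast
tests.

Units derive from a single reference unit by per-region Poisson mutation.
The default per-unit rates (variants/kb) are derived once from the reported
anchors for human rDNA heterogeneity rather than invented:

* pairwise divergence between units of ~130 variants per ~43 kb pair — two
  independently mutated copies accumulate both variant sets, so the
  per-unit overall rate is ~1.5/kb;
* IGS density about twice the transcribed region;
* 28S as the hottest mature rRNA (~4.1–5 variants/kb in pairwise
  comparisons, i.e. ~2.07/kb per unit), almost nothing in 18S, nothing in
  5.8S.

Solving those constraints gives the defaults `5'ETS/ITS1/ITS2/3'ETS =
0.225`, `18S = 0.045`, `5.8S = 0`, `28S = 2.07`, `IGS = 1.8`, which imply an
expected pairwise divergence of `2 × 1.519 × 43 ≈ 131` variants per pair and
an IGS:transcribed ratio of 2.0.  They are free parameters, not assertions:
the generative process behind the observed densities is unknown, so the
rates are exposed in `nor_spec()` and several tests deliberately run at
other values (e.g. 7.5/kb, the reported overall density across rDNA).

Indels are single contiguous events of truncated-geometric length (mean 3,
maximum 20 — the largest indel the study system highlights is a
20-nucleotide one), a configurable fraction (default 0.15) of all events.
One contiguous indel is one variant throughout the package.  Truth records
are left-aligned in reference-unit coordinates, exactly as the caller
left-aligns, so recovery is exact key matching.

Restriction sites are planted only in the flanks.  Because a 6-mer occurs
every ~2 kb in random sequence, the generator scrubs chance occurrences of
the planted enzymes' motifs (both strands) from the reference unit, its
tandem self-junction, and the flank/array junctions, and re-draws any
mutation that creates one inside a unit; this enforces the biological
premise the cloning design rests on — no EcoRV/ApaLI sites inside the
array — which in real rDNA is a fact and in an i.i.d. simulation must be
imposed.

Coordinates are 1-based inclusive everywhere in memory (matching the
convention in which hook positions like 26,273–26,468 are printed); BED
export converts to 0-based half-open.

## Restriction design

`scan_sites()` matches IUPAC motifs on both strands via
`Biostrings::matchPattern(fixed = FALSE)`, reports palindromes once, never
matches subject `N`s, and is property-tested against a naive per-position
matcher.  Cut positions are approximated by motif starts: both cloning
enzymes cut within their 6-mers and every downstream use (site
presence/absence, ~kb band sizes) is insensitive to sub-motif offsets; an
offset field is reserved on the enzyme table.

`select_cloning_enzymes()` keeps enzymes with zero sites overlapping the
array and at least one site in each flank, and returns the innermost flank
sites; `predict_fragments()` gives the released fragment (the band a CHEF
gel would show).  `design_hooks()` takes ~170–200 bp hooks immediately
inside the fragment ends, sliding inward (up to 1 kb) only if uniqueness
within the fragment demands it.  Uniqueness is required within the released
fragment, not genome-wide, since the hooks target junction sequence and no
genome is available in a synthetic setting.

## Clone finishing and merging

A captured clone is a circle (vector + released fragment); an assembler
emits it as a rotated linearization, usually with a duplicated terminal
segment.  `finish_assembly()` (i) trims that circular overlap — longest
terminal suffix–prefix match at ≥ `min_overlap` (default 100 bp) and
≤ `max_divergence` (default 0.01), always shorter than half the sequence;
(ii) locates the vector by exact match (searching across the origin via
doubling) or, failing that, by local alignment at ≥ 95% identity over ≥ 90%
of the vector length — thresholds chosen loose enough for polished long-read
consensus error and strict enough to avoid hook-length false hits, since no
values are prescribed for this step; the reverse strand is searched too and
the strand is reported; (iii) removes the vector and re-orients the
sequence to begin at the first base after it; (iv) verifies each hook
occurs exactly once.  The 200-clone round-trip (random spec, seed, rotation,
overlap) must recover the stored truth insert byte-for-byte.

`merge_inserts()` joins two inserts on their maximal terminal overlap,
trying both orders and strands, with exact 31-mer seeding extended by
mismatch counting (quadratic scans are avoided so ~130 kb inserts merge in
seconds).  The longest qualifying overlap wins; ties break to fewest
mismatches.  `|contig| = |A| + |B| − overlap` is asserted on every merge,
and failures report the best sub-threshold candidate.

## Unit alignment and variant statistics

`align_units()` is global affine-gap alignment (match +1, mismatch −2, gap
open −5, extend −1) restricted to a diagonal band, with the band doubled
until the score stops changing (cap 5000).  The scoring defaults are tuned
for <1% divergent ~43 kb units and are explicit arguments because variant
counts depend on the aligner.  The banded score is tested for equality with
`Biostrings::pairwiseAlignment` as an independent global-alignment oracle.

`call_variants()` emits one record per mismatch and one per contiguous gap
run, left-aligns indels against the reference, and labels regions from the
annotation (`"unannotated"` outside it, never dropped).
`pairwise_divergence()` reports per-pair counts with the mean and standard
error per group label (within/between chromosomes); `classify_sharing()`
partitions variant keys into unique / shared / universal (universal =
present in every chromosome group); `region_density()` reports variants/kb
per region and the IGS:transcribed ratio; `map_to_features()` reports
signed distances to annotated sites (CTCF, Sal-box replication fork
barriers, processing sites; a synthetic feature table ships in
`inst/extdata/`).  These are descriptive counts; no multiple-testing
correction is applied anywhere in this module, deliberately.

## RNA structure impact

Two exact folding models are built in: base-pair maximization, and a
weighted-stack model (GC = 3, AU = 2, GU = 1, +1 per stacked pair) as a
nearest-neighbour-flavoured stand-in.  Both are dynamic programs with a
minimum hairpin loop of 3 nt, verified against exhaustive enumeration of
all non-crossing structures for short sequences; an external thermodynamic
folding engine can be plugged in through `fold_params(backend = ...)`, but
every shipped test runs on the built-ins because desk-scale verifiability
requires an in-repo oracle.

`opening_penalty()` is the score cost of forcing an interval unpaired
(zero exactly when the interval is already unpaired in an optimum — the
"target structure opening" notion).  `structural_index()` is the Euclidean
distance between binary base-pair indicator vectors,
`D = sqrt(|pairs(s1) XOR pairs(s2)|)`; alleles of different length are
compared through the allele coordinate map, with pairs at unmapped
(inserted/deleted) positions counted into the symmetric difference.  Among
the defensible readings of a "Euclidean distance of base pairs" this is the
one that makes D a true metric over a fixed frame, which the tests verify
(identity, symmetry, triangle inequality).

`randomization_null()` shuffles the window (mononucleotide by default,
dinucleotide available), re-applies the variant at the same offset, and
recomputes the statistic; `empirical_p = (r + 1)/(n + 1)` with `r` the
number of null values at or above the observed one, and a z-score from the
null moments.  Two design points matter:

* **Exchangeability.**  The observed variant is always a real substitution,
  so the re-applied null SNV must be one too: when the shuffled base at the
  offset equals the alternate, the alternate is redrawn among the other
  bases.  Without this the null is anti-conservative.
* **Ties.**  The statistics are discrete, and the probability that a
  substitution leaves the optimum unchanged (statistic 0) is roughly the
  unpaired fraction of the window (~0.15–0.3).  The p-value is therefore
  *valid* (conservative: `P(p <= t) <= t`, which the suite tests) but not
  exactly uniform — it has an atom at 1.  A continuous-uniform KS check on
  these p-values fails for structural reasons, not implementation ones;
  this is a known limitation of pairing discrete structure statistics with
  randomization p-values.

`call_ribosnitch()` folds windows (default 100 and 350 nt) centred on the
variant for both alleles, reports D, the change in opening penalty, the
randomization p and z, and an MWW comparison of the two alleles'
opening-penalty profiles across scanning sub-windows.  The flag is raised
when the empirical p is ≤ α (default 0.05, per-variant calls, no
correction) in at least one window.  The flag statistic defaults to the
opening-penalty change rather than D: optimal structures are highly
degenerate on shuffled sequences, so the base-pair-distance null swamps
single-SNV effects, while the opening penalty of the variant footprint is
local and discriminates a designed stem-breaking control (p ≈ 0.01) from
unstructured controls (p = 1).  Both statistics are selectable.

`mww_test()` enumerates all labelings exactly for n ≤ 12 (ties contribute
1/2 to U) and uses the tie-corrected normal approximation above that; it is
cross-checked against `stats::wilcox.test` where both are exact.

## qPCR copy number

`estimate_copies()` is relative quantification against a single-copy
control locus and a calibrator sample of known copy number, with
per-amplicon efficiencies E in (0, 1] (default 1, perfect doubling — no
efficiencies are reported for the study design, so they are configurable
rather than assumed):
`q = (1+E_t)^-(dCt_t) / (1+E_c)^-(dCt_c) × calibrator copies`, averaged
over the IGS amplicons with the SE over amplicon × replicate quantities.
The calibrator copy number is a required user input: the value implied by
"total genomic DNA" is study-specific.  `simulate_qpcr()` inverts the same
model with Gaussian Ct noise.  At the reference design (noise 0.2 cycles,
4 amplicons × 3 replicates) the estimator's relative SD is analytically
`ln 2 × sqrt(2σ²/3 + 2σ²/12) ≈ 13%`; it is unbiased, so precision beyond
that comes from averaging plates, which is what the acceptance script does
(8 plates).

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at sizes chosen to exercise
every stage in a few minutes: 1/10- to 1/20-scale NORs for
generator/cloning round-trips (200 clones), 500 sequences of ≤ 18 nt for
the fold-enumeration oracle, 100 units of 5 kb at 7.5 variants/kb for
caller precision/recall, 50 replicates of a 45 kb two-region unit for the
density ratio, six full-scale 43 kb units for pairwise divergence, and 200
randomization cases for the p-value checks.  The full-scale drivers under
`analysis/` rerun the same stages narratively and write their tables under
`results/`.

## Known limitations

* The generator's i.i.d. background has no repeats, no GC gradient along
  the IGS, and no sequencing error model; passing tests demonstrate
  correctness of the algorithms against their contracts, not performance
  on real PacBio assemblies.
* Enzyme-site scrubbing makes "no sites in the array" true by construction;
  with real rDNA it is an empirical fact to be checked, and
  `select_cloning_enzymes()` does check it on whatever sequence it is
  given.
* Units are mutated independently from the reference, so shared and
  universal variants arise only by coincidence in simulations; real rDNA
  units share ancestry (concerted evolution), which is why the sharing
  classifier is validated on constructed membership sets rather than on
  generator output.
* The built-in folding models are score-based, not thermodynamically
  calibrated; opening penalties are in model units, not kcal/mol.
* Randomization p-values are conservative, with an atom at 1 (see above).
* Hook uniqueness is enforced within the released fragment only.
* Exact pairwise divergence values are alignment-parameter-sensitive; the
  defaults are stated above and exposed.
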
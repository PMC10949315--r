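---
title: "Methods: surveying and characterising short-chain asparaginases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: surveying and characterising short-chain asparaginases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asparascan)
```

This vignette documents the models, parameter choices and numerical
conventions behind `asparascan`, and what its synthetic-data tests do
and do not establish about real data.

## The scientific question

L-asparaginases (ASNases) hydrolyse L-asparagine to L-aspartate and
ammonia. The canonical bacterial class 1 enzymes are 300–400 residues
long and fold into an N-terminal catalytic domain plus a C-terminal
domain. A family of much shorter enzymes (~160–180 residues,
"short-chain" or scASNases) corresponds to the N-terminal domain alone
yet retains hydrolytic activity. Delineating that family from genome
sequence requires a translated homology survey, a length-based
partition, similarity clustering, co-occurrence statistics against the
long-chain repertoire, conservation analysis of catalytic residues, and
biochemical/structural characterisation of representatives. Each stage
is a module here.

## Translated survey

Queries (protein) are aligned against all six reading frames of each
genome by exact Smith–Waterman local alignment under BLOSUM62 with
affine gap penalties (open 11, extend 1). At desk scale exactness is
affordable and removes the seeding heuristics of production search
tools as a source of variation. Codons containing `N` translate to `X`,
which is scored 0 against everything, so ambiguous sequence neither
helps nor hurts a hit.

Scores are converted to expectations with the Karlin–Altschul formula
`E = K·m·n·exp(−λS)` using the standard ungapped constants
λ = 0.3176 nats per score unit and K = 0.134. The search space `n` is
the total translated length of all six frames across the searched
genome set, matching the per-search semantics of the default cutoff
`E ≤ 0.01`. These constants are documented defaults of the
`scoring_scheme()` object, not fitted quantities; the E-values they
produce for *gapped* scores are approximate (see the clustering
threshold below).

Within one reading frame, the aligner reports a single best alignment,
so the survey iterates: accept the best hit, mask its subject interval
with stop symbols, re-align, until the expectation exceeds the cutoff.
Two genes of the same family landing in one frame are therefore both
found.

**ORF determination.** Each accepted hit is expanded to the surrounding
in-frame stop-to-stop segment. Whether reported ORFs should start at
the first in-frame start codon (ATG/GTG/TTG) or at the stop boundary is
a genuine convention choice; both are implemented
(`start_trim = TRUE`/`FALSE`), the start-trimmed form is the default
and is used for length statistics. An in-frame stop inside the aligned
interval (possible for weak hits in background sequence) resolves to
the stop-free segment with the larger overlap, with a warning.
Coordinates are 0-based half-open internally and 1-based inclusive in
written tables; reverse-strand features are always reported on
forward-strand coordinates.

## Length partition and similarity clustering

Surveyed ORF lengths are bimodal: 300–400 residues (long-chain) versus
160–180 (short-chain). The partition cutoff of 250 aa is the midpoint
of the gap; any value inside the gap gives the same partition, and the
cutoff is exposed as a parameter (`partition_by_length(cutoff = )`,
strict `length < cutoff` ⇒ short).

To remove sequence length as a clustering signal, pairwise comparisons
use only the first 150 residues (`truncate_n_terminal()`). Edge
weights are `max(0, −log10 E)` of the pairwise local alignment with
`m·n` the two sequence lengths, clipped at a cap of 100 — the weight at
which identical sequences of the full truncation length saturate.

**Clustering threshold.** Cluster membership is deliberately *not*
taken from the force-directed layout (which is for visualisation) but
from connected components of the graph after discarding edges below a
weight threshold. The default threshold is 10. The choice is
statistical: simulation shows that chance Smith–Waterman similarities
between unrelated random ~150-mers reach weights of 2–4 in a few
percent of pairs and the extreme over thousands of pairs reaches ~8
(ungapped Karlin–Altschul constants are anti-conservative for gapped
scores on uniform-composition sequences), while genuinely homologous
family members at ≤ 15% per-site divergence saturate near the cap.
Any threshold in the wide gap between those two regimes recovers the
family partition exactly; 10 sits at the bottom of the gap. A
threshold as low as 2 (nominally E ≤ 0.01) admits chance edges that
fuse unrelated families and is not recommended for sets beyond a few
dozen sequences.

Component labels are canonical (0, 1, … by decreasing size, ties by
smallest member id), making the clustering invariant to input order.
The 2-D embedding (`layout_2d()`) is Fruchterman–Reingold with edge
weights as attraction, seeded and reproducible; only the separation
property (intra-family distances smaller than inter-family) is
asserted anywhere.

Localization is consumed from a label table in the dialect of
signal-peptide predictors (`OTHER`/`SP`/`LIPO` →
cytoplasmic/SPI/SPII); proteins without a predicted signal peptide are
presumed cytoplasmic. Reimplementing a trained signal-peptide predictor
is out of scope by design.

## Co-occurrence statistics

Repertoires are tallied per species. Where a species contributes
several genomes, counting is presence-based: exact duplicate loci are
dropped, then identical proteins within a species are collapsed — a
species count should not grow because a strain was sequenced twice.
Per-genome tallying is available (`collapse = "genome"`) since the
collapsing convention is not uniquely determined by the question.
The short-chain fraction is stratified by long-chain count groups
{0, 1, >1}; a group with no species yields an undefined fraction (NA),
never 0, so "no data" cannot masquerade as "no co-occurrence".

## Conservation profiling

Representatives are selected by greedy identity clustering (longest
first; identity = global-alignment matches / shorter sequence length,
the convention of the standard redundancy-reduction tool; threshold
0.9). The built-in aligner is center-star (center = minimal total edit
distance; merges under "once a gap, always a gap") — adequate for
closely related families; externally computed alignments are accepted
via `read_alignment()` for anything demanding.

Per column, the Shannon score is `log2(20) − H` with the entropy `H`
computed over the 20 amino acids only: gaps and `X` are excluded from
the frequencies and reported separately as a gap fraction. The
alphabet size stays 20 even when `X` occurs, fixing the score range to
[0, log2 20 ≈ 4.32]. All-gap columns are flagged and carry an NA score
rather than a fabricated 0.

The family consensus is the Levenshtein median string. Exact mode
enumerates all strings over the observed alphabet with lengths between
the shortest and longest input (a global minimiser exists in that
range) and is limited to small instances; heuristic mode starts from
the set medoid and hill-climbs over single-character edits. The
heuristic can never return a string worse than the best input, and on
small random instances it attains the exhaustive optimum in ≥ 90% of
cases (checked in the test suite). The median is computed on ungapped
sequences by default; computing it on gapped rows would make the
consensus depend on the aligner's gap placement.

Key-residue reports map reference residue numbers (e.g. the N-terminal
active-site threonine at position 16 of the 172-residue reference
chain) to alignment columns by cumulative non-gap count and list every
row deviating from the modal residue, so "strictly conserved" is an
auditable claim, not a summary statistic.

## Enzyme kinetics

The rate law is `v = Vmax·S / (Km + S·(1 + S/Ki))` — Michaelis–Menten
with single-site uncompetitive substrate inhibition; `Ki = Inf`
recovers the plain hyperbola. This is the standard single-substrate
inhibition form; the data motivating it (rate loss above ~5 mM
L-asparagine) do not constrain more elaborate mechanisms.

Two fitters are provided. The classical double-reciprocal
(Lineweaver–Burk) fit regresses `1/v` on `1/S` unweighted and excludes
points with `S > S_max` (default 5 mM) so that substrate inhibition
does not bend the line; on noiseless Michaelis–Menten data it inverts
the generating parameters to machine precision. The recommended
nonlinear fit (`fit_nonlinear()`) minimises squared residuals on the
velocity axis by Levenberg–Marquardt, with starting values from the
data (Vmax ≈ max v; Km ≈ S at half-max; Ki ≈ 5·max S) and positivity
bounds. Blank rates, when supplied, are subtracted before fitting.
Assay absorbances convert to ammonia as `c = A/(ε·l)` with
ε₄₈₀ = 1302 M⁻¹cm⁻¹ and l = 1 cm defaults.

Relative activities are percentages of wild type with a detection
floor: below 0.1% (a turnover number three orders of magnitude under
wild type) a variant is reported as 0 — inactive at assay resolution.
pH optima are grid maxima of mean activity; ties break to the lower pH
and are flagged, as is an optimum at a grid boundary.

## Structure comparison

Cα traces are read from PDB or mmCIF (first model; highest-occupancy
altloc per residue). Chains of the same protein are paired by common
residue numbers; cross-protein comparisons require an alignment-based
mapping and can use iterative outlier trimming (drop pairs beyond 2×
the current rmsd, re-superpose, ≤ 5 cycles) because published
"equivalent Cα" selections are rarely enumerated. Superposition is the
Kabsch SVD construction with the reflection case corrected
(determinant forced to +1); degenerate (collinear) inputs are errors,
not silent garbage. The implementation is cross-checked against an
independent quaternion-method oracle to 10⁻⁸ Å in the test suite.

Percent sequence identity uses gap-free columns as the denominator:
`100 × identical gap-free columns / gap-free columns`. Other
denominators (alignment length, shorter sequence) change the number;
the convention is stated wherever a value is reported.

Protein masses are sums of average residue masses plus one water,
in kDa; oligomer masses are protomer multiples.

## What the synthetic data does and does not emulate

The generators produce: genomes with planted stop-to-stop genes of the
two length classes on both strands (uniform i.i.d. intergenic
background — chosen because it maximises stop-codon density, keeping
spurious ORFs short; uniform synonymous codon choice), mutationally
diverged families (i.i.d. per-site substitution, uniform over the
other 19 residues), localization-labelled repertoires with planted
co-occurrence fractions, noiseless or lognormal-noise kinetic and pH
data, and rigid-body-transformed coordinate sets with Gaussian jitter.
Every generator is a pure function of its arguments and a seed, and
genome generators emit machine-readable truth tables whose loci
re-translate to the stored proteins (verified by `check_truth()`).

Deliberately *not* modelled: realistic codon usage and GC skew, operon
structure and promoters, BLOSUM-structured substitution processes,
sequencing error, and phylogenetic correlation between species.
Passing the planted-truth tests therefore demonstrates that the
algorithms are correct on data satisfying their assumptions — it does
not certify recall or clustering accuracy on real genomes, where
composition bias and deep divergence can move E-values and identities.
The co-occurrence fractions planted in the tests (5%, 3%, 38% for the
0/1/>1 long-chain groups) mirror the magnitudes reported for real
bacterial species, but their exact recovery is a bookkeeping check,
not a biological result.

## Problem sizes and determinism

The test suite runs at sizes chosen to exercise every code path while
staying comfortably interactive: 20-seed sweeps for survey recall
(two to three planted genes per genome, ~150 nt spacers) and for
three-family clustering (sizes 40/30/30, first 150 residues), 50 seeds
for negative controls, 100 random instances for the superposition
oracle, 50 for the median-string oracle, and 500 seeds for stochastic
kinetic recovery. All randomness flows through explicit seeds; two
runs of any generator or fit with the same arguments are
byte-identical.

## Known limitations

* E-values use ungapped constants for gapped scores; they order hits
  correctly but are not calibrated p-values. Search sensitivity at
  large evolutionary distance is bounded by BLOSUM62.
* The center-star aligner is O(n²) in sequence count and approximate;
  for publication-grade alignments use an external aligner and import
  the result.
* Exact median strings are exponential in length; the heuristic is a
  local optimum.
* The Lineweaver–Burk estimator is statistically inefficient under
  noise (reciprocal transformation inflates low-velocity errors); it
  is provided for comparability and validated on noiseless data, while
  the nonlinear fitter is the recommended estimator.
* Cross-protein Cα pairing by residue number assumes a shared
  numbering scheme; otherwise supply an alignment mapping.
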
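---
title: "Methods: how erfsurvey identifies, classifies and profiles an AP2/ERF superfamily"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how erfsurvey identifies, classifies and profiles an AP2/ERF superfamily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erfsurvey)
```

# The problem

Genome-wide surveys of the AP2/ERF transcription-factor superfamily follow
a well-established recipe: detect the AP2 DNA-binding domain (and the B3
domain) in every predicted protein; classify genes by domain architecture
into the AP2 family (two AP2 domains), the RAV family (one AP2 plus one
B3), the single-domain ERF family with its DREB and ERF subfamilies
(groups A1–A6 and B1–B6), and the divergent single-copy Soloist; build a
neighbor-joining tree of the domain regions; call orthologs, paralogs and
near-identical duplicates by percent-identity thresholds; map genes onto
chromosomes and flag tandem clusters; and estimate tissue expression from
EST tag counts.  `erfsurvey` implements that recipe end to end as tested,
deterministic R code, driven by a synthetic-data generator with planted
ground truth rather than a genome download, so every stage can be
validated against known answers.

# Domain detection

Each domain type is modelled as a position-frequency matrix (PFM) over the
20 amino acids.  `make_domain_model()` builds a PFM of a given consensus
length (60 columns for AP2, 50 for B3) by drawing each column from a
Dirichlet distribution concentrated on the consensus residue; the
`diversity` parameter (default 20) is the concentration, and 20 gives the
strongly conserved columns a real DNA-binding domain shows.  Scores are
log-odds in bits against a uniform background; an unknown residue (`X`)
scores 0 per column, i.e. is treated as uninformative.

`calibrate_threshold()` turns the scan into a decision rule with an
E-value semantics: it scores at least 1000 shuffled background windows and
fits a Gaussian null to the decoy scores.  A window score is the sum of
~60 independent per-column scores, so the central limit theorem makes the
normal an excellent description of the decoy law; we found a
generalized-Pareto/exponential tail fit far too unstable for the 8–9
orders of magnitude of extrapolation a 1e-4 E-value over 1e5 windows
requires, while the Gaussian fit is reproducible to a fraction of a bit
across calibration seeds.  The reported per-hit `evalue_surrogate` is the
expected number of decoy windows at or above the observed score in a
database of `database_size` windows.  Overlapping candidate windows are
resolved greedily by descending score with leftmost-start tie-breaking;
on the planted-domain benchmark this equals the exhaustive optimal
non-overlapping selection.

# Family and group classification

Classification applies rules in a fixed precedence, so permuting the
input never changes a call:

1. **Architecture**: two AP2 hits → AP2 family; one AP2 + one B3 → RAV;
   exactly one AP2 → ERF candidate; no AP2 → outside the superfamily.
   Three or more AP2 hits are kept as AP2 with a review flag.
2. **Soloist**: an ERF candidate whose best panel exemplar is the Soloist
   reference (identity ≥ 50%) becomes the Soloist family.
3. **Rescue**: a remaining single-domain candidate whose full-length
   identity against any AP2-family reference reaches 60% is reassigned to
   the AP2 family.  The rescue threshold is a package default: it sits
   deliberately below the 75% ortholog bar and far above the 40% group
   floor, and is configurable.
4. **Group**: nearest-exemplar assignment of the domain region against
   the 15-group reference panel (best global-alignment identity; ties by
   alignment score, then exemplar id; below 40% → unassigned).

All identity thresholds in the package are inclusive (≥).

# Pairwise homology

`global_align()` wraps an exact affine-gap Needleman–Wunsch alignment
(BLOSUM62, gap open 11 / extend 1 — the standard protein defaults).
Percent identity is matches over alignment columns after trimming
terminal gap overhangs, with internal gaps counted in the denominator —
the closest desk-scale analogue of a database-search identity.  The
E-value surrogate is a Gumbel fit to shuffled-decoy alignment scores,
calibrated once per session at a fixed internal seed and rescaled by
sequence lengths; it reproduces the role of the 1e-10 gate without a
database-search dependency.

Ortholog calling is best-hit (not reciprocal-best) at identity ≥ 75 and
E ≤ 1e-10, because whole-genome triplication makes the expected map
many-to-one.  Paralogs use identity ≥ 80 within one species; duplicates
use the stricter ≥ 95 near-identity bar and report both orientations of a
reciprocal pair (a `dedupe` flag collapses them).  A 6-mer sharing
prefilter skips pairs that cannot reach these bars: at 75% identity over
a few hundred residues, shared exact 6-mers are essentially guaranteed,
while unrelated background pairs essentially never share one.

# Phylogeny

`pdistance_matrix()` computes amino-acid p-distances with pairwise
deletion: per pair, mismatches over columns where both sequences are
non-gap; a pair with no shared column is an explicit error.  p-distance
is the simplest substitution model compatible with the survey recipe and
is declared in the output; the choice matters little for the fixed-length
domain regions the tree is built on.  `neighbor_joining()` implements
standard NJ (Q-criterion, Studier–Keppler updates) with two determinism
rules the textbook algorithm leaves open: join ties break to the smallest
(i, j) index pair, and negative branch-length estimates are clamped to
zero with the deficit recorded.  NJ is exactly consistent on additive
matrices, which the tests verify to n = 12 against both the generating
topology and an independent reference implementation (`ape::nj`).

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports each original bipartition's
replicate frequency as an integer percentage; supports at or below 50 are
flagged (the usual display floor) but never dropped.

# Conserved motif blocks

Instead of EM motif discovery, the package computes a deterministic
per-column conservation profile (frequency of the modal non-gap residue)
and reports the longest contiguous run of columns with conservation
≥ 0.8 and gap fraction ≤ 0.2 (ties to the leftmost run).  The defaults are
package choices — the survey literature reports motif lengths without a
numeric conservation criterion — and are configurable.  Short signature
elements (WLG, AYD and their converted variants such as HLG) are counted
per sequence, and the modal variant at the element's aligned position is
reported even when the canonical form is absent.

# Genome map

The distribution table counts placed genes per chromosome with the ERF
family split into its DREB/ERF subfamily columns; scaffold (unanchored)
genes are reported separately and genes without a family call go to an
exclusions report rather than disappearing.  Tandem clusters are maximal
runs of same-group genes on one chromosome in which consecutive members
are separated by at most one other surveyed gene and at most 100 kb.
The numeric rule is a package default calibrated so that the classic
published runs of consecutively numbered genes qualify; both knobs are
configurable.  Coordinates are 1-based inclusive throughout.

# EST expression

ESTs are assigned to CDS sequences by exact affine-gap alignment of the
whole EST within the CDS, with an 11-mer seed prefilter; a hit is
eligible at identity ≥ 90% over ≥ 100 aligned bases and E ≤ 1e-5, and
each EST counts toward its single best CDS (ties to the alphabetically
first id).  Counting raw eligible tags per tissue — not library-size
normalized — matches the tag-count character of the data; a profile is
the six-tissue count vector (bud, flower, leaf, root, seed, silique).
Percentages in the printed tables round half-up at two decimals
(one decimal for the family summary), so recomputed table entries match
published precision exactly.  Profile clustering is average-linkage on
1 − PCC, with constant profiles excluded (their correlation is
undefined, never silently zero).

# The synthetic-data generator

The generator emulates the statistical structure the survey assumes, not
a real genome:

* **Census**: the default family counts are 248 ERF / 29 AP2 / 14 RAV /
  1 Soloist (total 292) — the composition of the survey this package is
  built to reproduce; the ERF count is spread over the twelve DREB/ERF
  groups in roughly the published 109:139 proportion.
* **Architectures**: each gene's domain(s) are `mutate_copy()` mutations
  (default divergence 10%) of its group's panel exemplar, embedded in
  uniform-background flanks of 30–120 residues; AP2-family genes carry
  two AP2 domains, RAV one AP2 + one B3.
* **Soloist**: the exemplar is sampled from the AP2 model at temperature
  1.3 under a deterministic acceptance band of 0.70–1.00 bits/column
  self-score, so it scores clearly above a calibrated threshold yet well
  below a typical within-group hit (~1.3 bits/column).  Higher
  temperatures produce sequences no calibrated scan could accept.
* **Homology truth**: duplicate pairs (default identities 100, 100, 100,
  97.65, 99.2, 95.6, 100 — the published near-identity range) and
  paralog pairs (85–92%) are planted by overwriting one member of a
  same-group pair; a diverged second species is generated at 85%
  identity with a one-to-one planted ortholog map (default 214 pairs).
* **Genome layout**: ten chromosomes, non-overlapping 1–4 kb genes,
  planted same-group runs (default sizes 5, 3, 3, 2, 2) with 2–20 kb
  internal gaps, and 3 unanchored scaffold genes.
* **ESTs**: per gene and tissue, counts are negative-binomial with the
  stated mean and dispersion 0.3 (variance = μ + 0.3 μ²), reads are
  contiguous CDS substrings of 150–400 bp with i.i.d. substitution
  errors (default 1%).  `mutate_copy` plants substitutions only, so
  identity targets are exact to 1/len.

What the generator does **not** emulate — real triplication history,
codon structure, introns, EST library-size imbalance, domain families
with indel variation — bounds what a passing test shows: the pipeline's
decision logic and arithmetic are correct on data satisfying its
assumptions; performance on a real proteome still depends on the quality
of the domain models supplied.

# Numerical choices and problem sizes

All randomness flows from one seed through named substreams, so every
result — including the end-to-end `run_survey()` report — is reproducible
bit for bit.  Identity ties in best-hit selection break alphabetically;
join ties in NJ break by index; block ties break leftmost.  The test
suite and the acceptance script exercise the full-size census (292
genes, 214 planted orthologs) for scan/classification/homology, and
deliberately smaller instances where the statistics do not need scale:
bootstrap demonstrations run at a few hundred replicates on a capped
taxon subset (`tree_taxa_cap`, default 80, sampled to keep at least one
gene per group), NJ consistency uses 100 random additive matrices up to
n = 12, and the expression two-block recovery uses 10-gene designs over
100 seeds.  These sizes are the package's own validation choices; the
`survey_config()` defaults (1000 bootstrap replicates and the full gene
set) remain the analysis-scale settings.

# Known limitations

* The PSSM scan has no insert/delete states; a domain with internal
  indels relative to the model can fall below threshold.  The generator
  therefore plants substitution-only divergence.
* The E-value surrogates (Gaussian for window scores, Gumbel for
  alignment scores) are empirical calibrations, not Karlin–Altschul
  theory; they are accurate where it matters (near the gates) and
  deliberately conservative far into the tails.
* Group assignment is reference-based; whether the Soloist clusters with
  RAV or AP2 in a tree is a phylogenetic question the classifier does
  not answer.
* The paralog (≥ 80) and duplicate (≥ 95) gates are both provided
  because published usage varies; the package keeps them as distinct
  operations rather than resolving the ambiguity.
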
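---
title: "Evaluating multi-locus DNA barcode libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-locus DNA barcode libraries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeval)
```

## The problem

A plot-based DNA barcode reference library pairs each collected tree with
aligned sequences at a handful of barcode loci (typically the plastid
standards rbcL and matK plus the supplementary trnH–psbA and ITS) and a
field identification (species, genus, family, plot). Three questions decide
whether such a library is useful:

1. **Resolution** — does each species form its own well-supported clade on a
   tree built from the sequences?
2. **Identification** — does a similarity search against the library return
   the right species for an unknown query?
3. **Label quality** — which field identifications does the molecular data
   itself contradict?

`barcodeval` implements the three evaluations, the supermatrix machinery
they share, and a synthetic data generator so that every step can be tested
end to end without access to field collections.

## Data model and supermatrix

A dataset couples a validated specimen table (`sample_id`, binomial
`species`, `genus`, `family`, `plot`; one genus per species, one family per
genus) with one pre-aligned matrix per locus over the `{A,C,G,T,N,-}`
alphabet. IUPAC ambiguity codes collapse to `N` on input: all downstream
rules count only unambiguous identical sites, so retaining ambiguity codes
would add states the statistics never use. A specimen may be missing from
any locus — that is the data's record of PCR or sequencing failure, and
`recovery_stats()` reports per-locus and any-marker recovery from exactly
this missingness. Published success tables sometimes use an unstated
denominator (e.g. PCR-positive samples rather than all samples), so the
function accepts a caller-supplied denominator and reports both.

`concatenate()` builds a partitioned supermatrix in the caller's locus
order with 0-based half-open column ranges (re-emitted 1-based inclusive in
RAxML-style partition files for interoperability). A member missing a locus
is padded with `-`, and padding means *missing*, never an indel: every
distance and identity computation uses pairwise deletion, so padded columns
simply drop out per pair.

Loci that cannot be globally aligned (trnH–psbA in practice) are aligned
within families and folded block-diagonally by
`concatenate_family_blocks()`: each family gets its own disjoint column
range. Two consequences are deliberate. First, a cross-family pair has zero
comparable sites *at that locus*; in a multi-locus supermatrix the other
loci supply the cross-family signal. Second, on the block-diagonal locus
alone most cross-family distances are undefined, and the package flags them
(`NA` plus an explicit marker) rather than scoring 0 — a tree built from
such a locus alone is largely impossible, which mirrors the practical
experience that this locus cannot be evaluated by tree methods across a
diverse flora.

## Distances, NJ and bootstrap

Site counting is done once per alignment via 0/1 indicator matrices, so
comparable sites, matches, transitions and transversions per pair are dense
matrix cross-products; this keeps the bootstrap loop in BLAS. Two models
are offered: the uncorrected p-distance and K2P,
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$, with saturation
($1-2P-Q \le 0$ or $1-2Q \le 0$) flagged per pair. K2P is the default
because it is the community default for barcoding NJ trees; the original
tree-building settings behind the data this package emulates are not
published, so both models are offered and documented as approximations.

Trees come from classic Saitou–Nei Neighbor-Joining (via \pkg{ape}'s
reference implementation), with negative branch lengths clamped to zero and
the remainder moved to a sibling edge; downstream code uses topology and
support only. Pairs with undefined or saturated distances must be resolved
first — `drop_undefined_members()` greedily removes the most-affected
members (ties by name, so the result is deterministic) and logs them.

Nonparametric bootstrap (`bootstrap_support()`) resamples columns with
replacement — independently within each partition when a partition map is
present, so family blocks retain their block structure — rebuilds the NJ
tree per replicate, and attaches to each internal edge of the *original*
tree the percentage of replicates containing the same bipartition (the
common NJ reporting convention; no consensus topology is substituted).
Replicates in which a pair loses all comparable sites are redrawn and
counted. The default is 1000 replicates; the analysis scripts in this
repository use 200 and the test suite 60–100, sizes chosen so the whole
suite re-runs in minutes while leaving support estimates precise to a few
percent.

## Supported-monophyly resolution

A taxon with leaf set $S$ ($2 \le |S| < n$) is monophyletic iff the
bipartition $S\,|\,\bar S$ exists in the unrooted tree, and *supported* iff
that edge's bootstrap support is at least the cutoff (default 50).
Monophyly is defined on the unrooted tree because no outgroup is specified
for this kind of survey data; rooting would be arbitrary, and the statuses
are invariant to rerooting (tested). Singletons are excluded from the
denominator — with one sampled individual, monophyly is vacuous — matching
the "samples ≥ 2" accounting convention of published resolution figures.
Genus and family resolution are scored by the same rule with leaves
relabeled at that rank; whether published genus-level figures used this or
a weaker criterion is not documented anywhere we know of, so the package
states its choice and applies it uniformly. Two boundary cases are scored
as supported: a taxon spanning all leaves (no separating edge exists) and a
taxon spanning all but one leaf (the separating edge is the complement's
pendant edge, which carries no bootstrap value).

## Similarity-based identification

`pairwise_identity()` scores aligned pairs over columns where both
sequences have an unambiguous base. Whether a published "≥95 % identical
sites" criterion refers to full-length identity or local-alignment coverage
is generally unstated; this package defines it over scored columns of the
shared alignment, which makes the rule exactly auditable. For unaligned
inputs a free-end-gap global alignment (match +1, mismatch −1, gap −2,
terminal gaps free) is provided in place of a heuristic local-alignment
engine: an exact dynamic program keeps the decision rule deterministic and
testable against exhaustive enumeration. Among equal-score alignments the
implementation maximizes matches, then minimizes aligned columns — a
documented tie-break so identity is a function, not a sampling artifact.

The decision rule for a query at species rank: (i) identity to at least one
sequence of the query's recorded species must reach the threshold (default
0.95), else *no assignment*; (ii) every sequence of the best-matching
species must show *strictly* higher identity than every sequence of any
other species — a tie with a heterospecific breaks dominance and scores as
incorrect; the assignment is *correct* iff both hold and the best species
is the recorded one. At genus rank the same rule is applied at genus
granularity: the best species must dominate every *other-genus* subject,
while congeners of the best species are treated as evidence for the same
genus rather than competitors. This derived rule guarantees that a correct
species assignment is always a correct genus assignment, which both keeps
the two rates ordered the way published genus/species figures are and makes
the species-rate ≤ genus-rate invariant provable (and tested).

Multi-locus queries sum matches and comparable sites over shared loci —
the scored-site-weighted average of per-locus identities. Averaging (rather
than concatenation-then-rescoring) is chosen because it remains defined
when different subjects have different locus availability; for subjects
sharing all loci the two are identical.

Evaluation designs: `evaluate_leave_one_out()` queries every sequenced
specimen against all others; `evaluate_cross_plot()` uses one plot as the
reference database and the other plots' specimens — restricted to species
(or genera, for genus-rank scoring) present in the database — as queries,
with the database plot itself reducing to within-plot leave-one-out. Rates
are reported over queries with a defined outcome (correct or incorrect);
`no_assignment` and `unscorable` counts are kept separate so denominators
are always explicit.

## The misidentification audit

The audit formalizes the first, algorithmic step of reciprocal
illumination — inspecting a core-barcode (rbcL+matK) NJ tree for specimens
whose placement contradicts their recorded taxonomy; the second step,
reviewing vouchers, is human work and out of scope. A leaf is flagged when
the smallest clade (bipartition side) containing it and at least one other
leaf contains no recorded conspecific, *and* the separation is supported.
The support gate is the maximum bootstrap support over edges whose
leaf-side excludes every recorded conspecific. This "any supported
separating edge" form matters: with star-like intraspecific genealogies the
smallest enclosing clade is often a weakly supported within-species cherry,
while the strongly supported edge demonstrating the conflict is the
misplaced leaf's host-species clade. Pendant edges carry no bootstrap value
and never satisfy the gate on a bootstrapped tree; on a tree without
support values the gate is inactive.

Leaves whose recorded species has no other sampled member cannot conflict
at species level; they are flagged only when they nest with *part of* one
other species (sister to a complete clade of another taxon is normal
phylogenetic structure, not a conflict). The flag records the neighborhood
taxon — the majority species/genus/family among the other leaves of the
smallest enclosing clade, ties broken lexicographically — and the conflict
level is the shallowest rank of disagreement between recorded and
neighborhood triples (family, else genus, else species; placeholder
taxonomy classifies as unknown). Both leaves of a conspecific-free cherry
can be flagged: either may be the mislabeled one, and deciding is exactly
the human step. Audit summaries therefore also count these "shadow" flags,
which is why a realized flag rate can exceed the injected error rate on
synthetic data.

## The synthetic-data generator

The generator is first-class, tested code, not a fixture. It emulates the
statistical structure the evaluations depend on:

* **Nested taxonomy** — families ⊃ genera ⊃ species with configurable
  counts or ranges, 1–6 individuals per species by default, pseudo-Latin
  binomials consistent with their genus, and specimens allocated to plots
  by configurable weights (default heavily skewed toward one large plot,
  as plot-based campaigns are).
* **A shared genealogy** — one specimen genealogy underlies all loci:
  height-banded pure-birth (Yule) trees nested per rank. Unit-height Yule
  topologies are drawn per family set, per genus within family, and per
  species within genus; their split heights are mapped affinely into each
  level's band (family root at `inter`, genus crowns at
  `genus_crown_frac * inter`, species crowns at
  `species_crown_frac * inter`), and conspecific specimens hang as a star
  of height `intra`. A single flat Yule tree over species would carry no
  genus or family signal at all — genus-level resolution would be
  meaningless and the species/genus-ratio comparisons impossible — which is
  why the generator nests the levels. With two species per genus the
  sister-species divergence equals the species crown height exactly, which
  is what makes the clean-gap parameter-recovery conditions deterministic
  rather than luck.
* **JC69 substitutions** — sequences evolve along the genealogy under
  Jukes–Cantor (single rate, no indels, so data are born aligned; the
  family-block path is exercised by generating trnH–psbA per family). JC69
  suffices because every evaluation statistic uses only identity and
  monophyly; hooks for richer models would add parameters the criteria
  never see. The expected intraspecific p-distance is
  $\tfrac34(1-e^{-8h/3}) \approx 2h$ for star height $h$, verified against
  simulation in the tests.
* **Recovery** — per specimen per locus, an independent Bernoulli draw at
  the locus's recovery rate (defaults match a realistic campaign: rbcL
  0.908, trnH–psbA 0.856, matK 0.795, ITS 0.710). Real failures are
  correlated across loci (bad extractions fail everywhere), so the
  independent model understates the all-loci-failed fraction; published
  tables report only marginal per-locus rates, which is all this model
  matches.
* **Plot structure** — optionally, conspecifics from different plots
  coalesce at `plot_sep_height` above the within-plot star, producing the
  between-plot intraspecific divergence that drives cross-plot
  identification decay and between-plot variable sites.
* **Misidentification injection** — a configurable fraction of specimens
  (default level mix 74:17:5 family:genus:species, apportioned by largest
  remainder so realized counts are deterministic) get their recorded labels
  replaced by a donor taxon at the requested level; sequences always follow
  the true genealogy, and for family-block loci the corrupted specimen's
  sequence is filed in its *recorded* family's block, as a family-based
  alignment workflow would misfile it. The ground truth and error list
  travel alongside the dataset.

Divergence defaults (`inter` 0.05, `intra` 0.001 substitutions/site) are
stated as conventional round values — no quantitative intra/interspecific
estimates exist for the flora this emulates — and are exposed in the
configuration.

What passing the synthetic tests does *not* show about real data:
alignment error, indels, rate heterogeneity across sites and lineages,
correlated locus failure, paralogy in ITS, and chloroplast capture are all
absent from the generator, and every one of them degrades real-world
performance. The synthetic results certify the *procedures*, not any
field-level accuracy number.

## Problem sizes and numerical choices

The test suite and the acceptance script use deliberately modest sizes: the
clean-gap parameter-recovery runs use 16 species / roughly 40 specimens,
four 1000-column loci and 100 bootstrap replicates over 10–20 seeds; the
directional comparisons use 20–30 species with 300–500-column loci and no
bootstrap (identification does not need one). These sizes were chosen once,
before freezing the tests, as the smallest conditions under which the
expected effects are structural rather than marginal: with species crowns
at 0.0075 substitutions/site and 4000 total columns, the closest species
pair differs at ~60 sites while conspecifics differ at ~4, so perfect
resolution is a property of the configuration, not of a lucky seed.

Other numerical conventions, in one place: percentages round half-up to one
decimal everywhere (base R's half-to-even would misprint several published
ratios); identity and distance ties are broken deterministically
(documented per function); bootstrap and simulation functions take explicit
seeds and restore the caller's RNG state; all reported denominators are
explicit in the output tables.

## Known limitations

* The audit's flag rate counts shadow flags (intact specimens dragged into
  review by a mislabeled neighbor); it is an over-count of true errors by
  design, since the human review step resolves direction.
* Genus/family-block trnH–psbA supports no meaningful single-locus tree
  across families; this is inherent to block-diagonal construction and is
  reported (dropped members are logged), not silently worked around.
* The free-end-gap aligner is exact but quadratic; it is meant for
  per-pair scoring at barcode lengths, not for database-scale unaligned
  search.
* Maximum-likelihood trees are out of scope; where both NJ and ML have been
  run on comparable data the reported differences are small, and the
  package's criteria are tree-method-agnostic given a support-annotated
  topology.
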
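---
title: "Tracing paralog origins: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing paralog origins: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

ftszprov implements a comparative-genomics workflow for asking where
the paralogs of a modular protein family came from, with the
FtsZ/tubulin family — the cell-division GTPases shared by Bacteria,
Archaea and eukaryotes — as the motivating case.  Members of such a
family share a conserved N-terminal domain, while their C-terminal
tails are lineage-diagnostic: when a paralogous group (say, an
archaeal CetZ-like group) carries a tail that still shows detectable
similarity to the tails of one particular subfamily, that subfamily is
the likely source lineage of the paralog.  The package provides every
stage of that argument — homolog collection with profile HMMs,
taxonomically balanced curation, distance phylogenies with bootstrap
supports, gene-neighborhood domain abundance, and the anchored
C-terminus cross-search — plus a simulator that generates corpora with
known ground truth so each stage can be validated end to end.

## The profile HMM and its score model

A `ProfileHMM` is the classic match/insert/delete architecture: match
state $k$ emits residues from a pseudocount-smoothed column
distribution, insert states emit the background, and per-position
transition probabilities are estimated from the state paths implied by
the training alignment with add-one smoothing.  Scoring is log-odds
against the background.  In the default local mode, entry into the
core model is uniform over match states, exit from match state $k$
has probability $1/(M-k+1)$ (uniform over remaining end points), and
the flanking regions are scored neutrally; the sum over alignment
start offsets is normalised by the sequence length, so a random
background sequence scores near or below zero bits (median negative).
Glocal mode forces a full-model pass (entry at match 1, exit at match
$M$).  The forward recursion sums all paths in log space; Viterbi
returns the single best path, whose emitted span is the domain
envelope used for anchoring.  Ties prefer match over delete over
insert and the leftmost placement, so envelopes are deterministic.

**E-values.**  Calibration scores `nRandom` (default 1000)
i.i.d. background sequences, with lengths drawn from a normal
distribution around the model length (sd 0.2 of it, truncated at 30),
and fits a Gumbel by maximum likelihood with the scale fixed at
$\ln 2$ per bit, the asymptotic tail behavior of forward log-odds
scores; only the location is estimated.  We verified on large null
samples that a free-scale fit tracks the bulk of the score
distribution but underestimates tail probabilities by orders of
magnitude, which silently inflates significance; the fixed-scale fit
is mildly (about an order of magnitude) conservative across the tail,
the safe direction for homolog collection.  The E-value of a score is
`db_size * P(S >= s)` with `db_size` equal to the number of sequences
searched in the invocation, which makes the self-consistency property
testable: searching the calibration-sized null set at E ≤ 1 should
yield about one hit.

## Curation

Collection searches the anchor model (the family's shared N-terminal
domain profile; in real use a curated domain-database model such as a
Pfam entry, supplied as an input) against the proteomes at the
conventional threshold E ≤ 1e-3.  Alignment coverage filtering removes
rows with fewer than 60% non-gap characters relative to the full
alignment length (the denominator is the alignment length, matching
the phrase "alignment coverage").  Redundancy reduction is a greedy
CD-HIT-style clustering per taxonomic class: sequences sorted by
length join the first representative they match at or above the
class's identity cutoff.  The cutoff scales with class size — 95%
identity for classes of up to 20 sequences down to 55% at 250 or more,
linearly interpolated between those endpoints and rounded to two
decimals; the interpolation is a documented choice, as only the
endpoints of the scheme are conventional.  Identity is matches over
the full global-alignment length (gap columns count in the
denominator), a deliberate approximation of CD-HIT's coverage
behavior without its word-filter heuristics.

Two trimmers are provided.  Gap-threshold trimming keeps columns whose
non-gap fraction is at least `gt` (0.7 strict, 0.2 inclusive, 0.1
soft), composing a provenance map so every kept column can be traced
to its original index.  Entropy trimming is BMGE-inspired: the column
distribution is smoothed through a similarity kernel
($w(a\,|\,b) \propto e^{S(a,b)/2}$) so that similar residues pool
their mass, and the normalised Shannon entropy of the smoothed
distribution is compared against the ceiling (default 0.55) after a
3-column running-mean smoothing; columns with more than 20% gaps are
removed too.  An invariant column scores exactly 0, a column uniform
over the alphabet scores near 1, and columns varying only among
biochemically similar residues score low.  This is not a
bit-compatible BMGE reimplementation; the default matrix is BLOSUM45,
the lowest-identity BLOSUM shipped with Biostrings, appropriate for
divergent alignments.

## Alignment

The built-in aligner removes any external binary dependency: global
pairwise alignment is Needleman–Wunsch with affine gaps (BLOSUM62,
open −11, extend −1, tie-break diagonal over up over left), and
multiple alignment is progressive — a UPGMA guide tree over 3-mer
cosine distances, then profile–profile merges with the same affine DP,
with column scores $f_A^\top S f_B$ over column frequency vectors.
Once two residues are aligned within a profile their relative
alignment never changes, so ungapping any output row reproduces its
input exactly, and sequence ids canonicalise the guide tree so the
result is independent of input order.  Iterative refinement is out of
scope; an adapter hook accepts an external aligner command whose
output is validated against the same invariants.

## Phylogenies

Distances are proportions of differing residues over mutually
ungapped columns with Kimura's protein correction
$d = -\ln(1 - p - 0.2\,p^2)$; saturated pairs ($p \ge 0.85$, where the
correction is undefined) receive a documented ceiling of 5.0
substitutions/site.  Trees come from an in-package Saitou–Nei
neighbor-joining with two documented details: negative branch lengths
are clamped to zero with the deficit moved to the sibling edge, and
ties in the Q criterion break on the smallest index pair with taxa in
lexicographic id order (which also makes bootstrap supports invariant
to input row order).  Supports are classical column-resampling
bootstraps: each replicate resamples alignment columns with
replacement, rebuilds the NJ tree, and each internal edge of the
original tree is annotated with the percentage of replicates
containing the same bipartition.  Maximum-likelihood inference with
model selection is deliberately out of scope — the reusable substance
of the workflow (rooting, collapsing, annotation mapping) is
downstream of whatever tree is supplied, and a Newick-with-supports
adapter accepts externally computed trees.

Midpoint rooting places the root halfway along the longest
leaf-to-leaf path (supports are carried across the rooting by
bipartition matching, since bipartitions are rooting-invariant), and
`collapseLowSupport()` contracts internal edges below a display
threshold (conventionally 85%) into polytomies, discarding the
contracted edge length and leaving child edges untouched.  iTOL
color-strip and heatmap annotation files are emitted as plain text.

## Genomic context

For each focal gene, the neighborhood is the window 5 kb up- and
downstream of the gene (a documented choice between the two window
sizes in circulation for this analysis; configurable), clipped at the
contig start, with half-open coordinate semantics internally and
1-based inclusive coordinates in files.  Any gene overlapping the
window by at least one base pair is a neighbor — full containment is
not required, so boundary genes are never silently dropped.  Neighbor
proteins are annotated with a domain-model library; presence is
counted as a set at the genome level: a domain counts once per genome
regardless of repeats within a protein, a neighborhood, or across
paralogous neighborhoods.  The abundance table (domains × phyla) and
its top-k ranking (ties alphabetical; 25 is the conventional figure
setting) summarise the contrast between clade-specific neighborhood
content, e.g. the division-and-cell-wall cluster next to bacterial
family members versus protein-biosynthesis genes next to archaeal
ones.

## The C-terminus provenance test

The signature analysis anchors each collected sequence at the end of
its N-terminal domain envelope (Viterbi, anchor significance E ≤ 1e-3
at single-sequence database size) and takes everything downstream as
the tail; tails shorter than 20 residues are discarded as too short to
model (the threshold is a package choice — shorter tails make
meaningless models).  Per phylogenetic group, tails are aligned,
soft-trimmed (`gt = 0.1`), built into a profile HMM and calibrated.
The cross-search scores every group model against every collection
member with no E-value threshold, recording the best E-value per
(model, target).  Heatmap bins default to decade edges 1e-10 / 1e-5 /
1e-3 / 1e-1, bracketing the conventional strong / weak / marginal
strata of such searches.  `provenanceReport()` aggregates the matrix
over (family × taxonomic domain) strata and flags strata whose median
E-value is at or below 1e-2 — the weakest signal stratum conventionally
treated as meaningful — as candidate source lineages of the query
group's tail.

## The simulator and what passing tests mean

`simulateCorpus()` generates the study conditions.  The species tree
joins two equal-size birth-only subtrees — the taxonomic domains —
by stem edges of length 0.5 (so the inter-domain split is deep
relative to within-domain radiation, as for the prokaryotic domains),
rescaled to unit root height; phylum, class and order labels come from
cutting the tree at depths 0.25, 0.5 and 0.75.  Sequences evolve under
a fixed Dayhoff exchangeability matrix with per-segment rate
multipliers $1 - \mathrm{conservation}$ (defaults: N-terminal domain
140 residues at conservation 0.85, tail 70 residues at 0.25 — tails
are weakly conserved), geometric indels (length parameter 0.7, rate
0.02 per substitution, never inside the first 10 residues of the
N-terminal segment so the anchor always exists).  Events —
duplication, loss, lateral transfer, tail replacement — sit on named
branches at named times; every emitted record appears exactly once in
the truth tables, and per-residue homology keys make the true
alignment recoverable for aligner validation.

The bundled scenarios encode the family's hallmark history: one
duplication on the archaeal stem before archaeal diversification
(`"duplication"`), and additionally (`"cterm"`) a family-specific
archaeal tail lineage acquired on the stem, a CetZ-like copy that
therefore inherits the archaeal tail, and a tub-like copy whose tail
is replaced by a fresh lineage.  The tail-replacement design follows
the modular-family picture in which subfamily C-termini are
family-specific rather than gradual divergences of one ancestral
tail; it also makes the provenance contrast sharp — with a single
ancestral tail lineage, stochastic retention of deep similarity makes
the "unrelated" stratum intermittently detectable, which is not the
regime the workflow is meant to distinguish.  Domain-library consensi
for neighborhood genes are drawn randomly but kept mutually
dissimilar (redrawn when any cross-model score reaches 5 bits),
modelling unrelated domain families.

What the simulator does not emulate: site-rate heterogeneity and
compositional bias within segments, overlapping genes and operon
structure, genome rearrangements, annotation noise in gene
coordinates, and realistic taxon sampling imbalance.  Passing the
simulation-based tests therefore shows the pipeline's logic is sound
and its statistics calibrated under the model's assumptions, not that
any particular biological conclusion about a real family is correct.

## Numerical and operational choices

Forward/Viterbi run in natural-log space (log-sum-exp); results are
reported in bits.  Problem sizes in the validation experiments — 32
genomes, 100 bootstrap replicates, 20 seeded replicates per
experiment, 1000-sequence calibrations — were chosen as the smallest
sizes at which the statistical checks are stable.  Pipeline stages
derive their seeds from the root seed through labelled hashes, so
toggling one stage never shifts another stage's random stream, and all
text outputs use fixed formatting (6 significant digits, LF endings),
making reruns byte-identical — the checksum manifest is the
reproducibility contract.  Degenerate inputs fail loudly with
structured messages (`schedule-error`, `anchor-not-found`,
`incomparable-pair`, `missing-id`, `configuration-error`), never
silently.

## Known limitations

The aligner is progressive-only and will not match iterative
refinement on hard alignments; NJ trees are a desk-scale stand-in for
ML inference and inherit its artifacts (no rate heterogeneity, no
model selection); the entropy trimmer is BMGE-inspired, not
BMGE-compatible; E-values are deliberately conservative in the tail;
and the LGT event model lets the donor's own lineage evolve
independently from the transfer point (the transferred copy shares
the donor's history only up to the donor branch start).
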
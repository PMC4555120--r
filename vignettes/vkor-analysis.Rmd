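---
title: "Methods: loop-restricted phylogeny, conservation grading and circular-permutation analysis of the VKOR family"
author: "vkorcp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VKOR-family phylogeny and circular-permutation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vkorcp)
```

# The scientific problem

Vitamin K 2,3-epoxide reductase (VKOR) family enzymes are four-helix-bundle
membrane oxidoreductases carrying two redox-active cysteine pairs; the human
paralogs VKORC1 and VKORC1L1 drive the vitamin K cycle.  The prokaryotic
DsbB family performs the analogous quinone-coupled disulfide chemistry with
the same bundle architecture but a different threading of the primary
sequence through the four helices: DsbB threads helices in the label order
ABCD, VKOR homologs in the order CDAB.  Two sequences related this way are
circular permutations of each other -- one equals the other with its
N- and C-terminal halves exchanged.

`vkorcp` packages the analyses this comparison requires:

1. **Curation** -- reference-coordinate truncation of a family alignment to
   a core domain or to the large lumenal loop between the first two sequence
   helices (human VKORC1 Asp36--Ser79), redundancy/coverage/motif culling,
   and a census of major shared indels.
2. **Phylogeny** -- maximum-likelihood machinery for empirical amino-acid
   models (WAG, JTT) with invariant sites and discrete-gamma rate
   heterogeneity, ML pairwise distances, neighbor-joining topologies,
   branch-length optimization, model selection by AIC/AICc/BIC,
   nonparametric bootstrap supports, outgroup rooting and pruning.
3. **Conservation** -- empirical-Bayes per-site rate posteriors binned into
   the nine conservation grades used for visual comparison across clades
   (grade 9 = most conserved, grade 0 = absent in the scored subset).
4. **Clade analysis** -- clade extraction from seed taxa, fully conserved
   "signature" sites, clade-differential absent segments, and single-site
   determinant scans of the Ile136Cys kind.
5. **Structure** -- interhelical and ligand contacts from PDB coordinates by
   a heavy-atom minimum-distance criterion.
6. **Circular permutation** -- helix-pair module construction (AB and CD),
   CXXC-anchored and identity-maximizing translation alignments between
   families, conserved-feature matching, and general rotation-offset
   detection by local alignment against a doubled sequence.
7. **Synthetic data** -- a generator that plants every feature the pipeline
   is supposed to find, so each stage is testable against known truth.

# Likelihood model

Site likelihoods use Felsenstein pruning under a reversible empirical model:
the rate matrix is built from published exchangeabilities $S$ and
equilibrium frequencies $\pi$ as $Q = S\,\mathrm{diag}(\pi)$ with the
diagonal set so rows sum to zero, scaled so the expected rate at equilibrium
is one (branch lengths are expected substitutions per site).  Rate
heterogeneity follows the standard discrete-gamma construction: $K$
equal-probability categories of a mean-one gamma with shape $\alpha$, each
represented by its conditional mean and renormalized to mean exactly one.
With an invariant-sites proportion $p_{inv}$ the site likelihood is

$$L_i = p_{inv}\,c_i\,\pi_{x_i} + (1 - p_{inv})\,\frac{1}{K}\sum_k L_i(r_k),$$

where $c_i$ indicates a column whose non-missing states are all equal (an
all-missing column contributes 1), and $L_i(r_k)$ is the pruning likelihood
with branch lengths scaled by $r_k$.  Gaps and `X` are missing data
(partial-likelihood vectors of ones).  The pruning core is compiled
(Rcpp/Armadillo) with per-site rescaling, so trees of hundreds of taxa do
not underflow.  Exactness is tested against exhaustive enumeration over all
internal-state assignments on trees of up to five leaves (relative error
below 1e-10) and against the pulley principle (re-rooting changes site
log-likelihoods by less than 1e-10).

Branch lengths are optimized coordinate-wise (scalar optimization per branch
in [0, 10], passes until the total log-likelihood improves by less than
1e-6 or 20 passes); on data simulated from an 8-taxon tree with 3000 sites
the fit matches an independent ML implementation to four decimals, and
internal branches of at least 0.05 substitutions/site are recovered within
15%.  Rate parameters are estimated by nested scalar optimization,
$\alpha \in [0.05, 20]$ (searched on the log scale) inside
$p_{inv} \in [0, 0.95]$, with the $p_{inv}=0$ boundary checked explicitly.

## Model selection

Candidates (base matrix, optionally +I, +G) are each fitted -- branch
lengths, then rate parameters, then branch lengths again -- and scored by
AIC, corrected AIC and BIC.  The free-parameter count $k$ covers rate
parameters only: all candidates share the same topology and branch lengths,
so criteria differences reflect the rate model, mirroring the +I/+G
nesting comparison the pipeline is used for.  Users who wish to count
branch lengths can add `Nedge(tree)` to `k` themselves.

## Distances, trees and supports

Pairwise ML distances maximize the two-sequence likelihood over shared
non-missing columns (a 20x20 count table makes this cheap).  Topologies come
from standard neighbor joining on those distances (`ape::nj` behind the
module surface), with negative branch-length estimates clamped to zero.
Bootstrap supports resample alignment columns with replacement, rebuild a
tree per replicate with the same distance+NJ pipeline, and report for each
internal bipartition of the point-estimate tree the percentage of replicate
trees containing it.  This deliberately substitutes a desk-scale,
deterministic pipeline for heavy ML tree searches: on strong planted
signal (two clades behind a stem branch of 1 substitution/site) the planted
split reaches support >= 95.

# Conservation grading

The per-column posterior mean rate is
$\hat r_i = \sum_k r_k L_i(r_k) w_k / \sum_k L_i(r_k) w_k$ under a
discrete-gamma prior with the alignment's estimated $\alpha$; 16 categories
are used here (finer than the 4 used for tree likelihoods) because the
posterior mean, not the likelihood, is the quantity of interest.  Rates are
standardized to zero mean and unit variance across scored columns, and the
observed score range is cut into nine equal-width bins: lowest bin (slowest,
most conserved) = grade 9, highest = grade 1; all-equal scores give grade 5;
columns that are all-gap in the scored subset get grade 0, the "absent"
code used when comparing clades.  Equal-width binning is a documented,
bit-reproducible choice; conservation servers do not publish their exact
boundaries, so absolute grade agreement with any particular server is not a
goal -- planted-truth recovery is.  Columns under 10% occupancy are scored
but flagged low-confidence.  Clade profiles restrict the rows and prune the
tree to the clade (at least 3 members required) and re-run the same
machinery.

# Clade analyses

`clade_partition` assigns leaves to labeled clades from seed taxa: each
label's clade is the *largest* subtree containing all of that label's seeds
and none of any other label's.  The MRCA of the seeds is the lower bound; if
it already contains a foreign seed the groups are not mutually monophyletic
and the call errors.  The maximal reading (rather than the bare MRCA) is
what makes a single representative taxon per clade recover a full planted
partition, which is how reference trees are annotated in practice.

`single_site_markers` operationalizes "uniquely identifying" as perfect
presence/absence over non-missing states (in-group frequency >= 1, out-group
frequency <= 0 by default; both thresholds are parameters).  Missing states
(`-`, `X`) are excluded from numerator and denominator, and columns where
either side has no observed residue are skipped -- presence/absence is
undefined without data, and this makes the scan symmetric between a group
and its complement whenever both sides are monomorphic.  Note the scan is
*not* symmetric in general: a complement that is monomorphic for a state
absent from a polymorphic group is a marker for the complement but not for
the group.

`clade_absent_segments` reports maximal column spans gapped throughout one
clade but occupied in at least half of another -- the "absent segment"
comparison used to contrast prokaryotic and animal loop architecture.
`fully_conserved_sites` lists columns with a single non-missing state at
>= 90% occupancy, the natural reading of family signature residues.

# Structural contacts

Interhelical contacts use a heavy-atom minimum-distance criterion between
residues on different annotated helices; the cutoff defaults to 4.5
angstrom, the common van der Waals contact convention, and is configurable
because published contact counts depend on unstated criteria.  Ligand
contacts apply the same criterion between protein residues and a named
HETATM ligand.  Both are validated against brute-force all-atom-pair scans
and are invariant to rigid motion and record order.  Author residue
numbering is used throughout.

# Circular-permutation analysis

Helix-pair modules follow the helix *labels*: the AB module runs from the
start of helix A to the end of helix B including the intervening loop, and
likewise for CD.  Under the CDAB threading of VKOR homologs the AB module is
therefore the C-terminal half of the core domain, and both families'
redox-active CXXC motifs (VKORC1 Cys132--Cys135, DsbB Cys41--Cys44) fall in
the AB module -- the residue-level anchors (VKORC1 Ser117 and Leu124 on
helix A, Thr138 on helix B) force this reading even where prose summaries
describe the modules by sequence position.  The exact N/C boundaries of
each module are an explicit helix-range configuration
(`inst/extdata/index_helices.yaml` for the shipped index sequences), since
small boundary shifts change identity counts.

Module alignment is translation-only (no internal gaps): `anchor_align`
shifts one module until the CXXC anchors coincide; `best_identity_offset`
scans all translations with at least 10 overlapping columns and maximizes
the identity-site count, breaking ties by smallest absolute offset, negative
before positive.  Identity counting over several index sequences uses the
union-of-pairwise reading ("the partner residue matches at least one index
sequence") with per-pair counts always reported alongside, so the stricter
triple-identity reading can be computed from the same object.  `X` never
counts as identity.

`find_cp_offset` detects a rotation by locally aligning one sequence against
the doubled other (BLOSUM62, gap open 11, extend 1) and reduces the best
start position modulo the sequence length; a per-offset ungapped score
profile is returned for diagnostics.  Rotations are recovered exactly for
clean inputs of length >= 50 and in >= 90% of seeds after 15% random
substitutions at length 150.

The shipped index sequences (`inst/extdata/index_sequences.fasta`) are the
human VKORC1 (UniProt Q9BQB6, 163 aa) and E. coli DsbB (UniProt P0A6M2,
176 aa) records, transcribed from the public databases and checked against
more than forty independently documented residue positions (catalytic
cysteines, loop boundaries, helix-contact residues, core-domain termini).
The human VKORC1L1 paralog is deliberately not shipped: no comparably dense
set of positional anchors was available to verify a transcription, and an
unverifiable reference sequence is worse than an absent one.  Identity-site
counts computed here are therefore VKORC1-vs-DsbB pairwise counts under this
package's documented helix ranges; they are not comparable to counts
published for three index sequences under other alignments and module
boundaries.

# The synthetic study bundle

`generate_study_bundle` emits a complete miniature study with known ground
truth, emulating the real analysis's inputs at desk scale:

* a rooted tree of 60 taxa in five labeled monophyletic clades
  (18/7/7/10/18 -- the same ordering of clade sizes as the real family:
  two large prokaryotic clades, two small vertebrate paralog clades, one
  mid-sized invertebrate clade), stems of 0.5 substitutions/site;
* 160 columns evolved under WAG with gamma rates ($\alpha = 0.8$, a typical
  protein-family estimate) and 5 planted invariant "catalytic" columns,
  mimicking the five family signature residues;
* a planted perfect single-site marker (state `C`) carried by a 6-member
  group drawn across the two prokaryote-like clades, emulating a
  pathogen-group covariant site;
* one planted 13-column insertion present in clades 2--4 and gapped in
  clades 1 and 5, emulating the animal-specific loop extension;
* a circularly permuted partner family (rotation at half the alignment
  length, 15% divergence);
* a toy four-helix bundle: ideal alpha-helices (1.5 angstrom rise, 100
  degrees per residue; C-alpha plus one side-chain pseudo-atom) on a square
  of side 10 angstrom with 0.25 angstrom coordinate jitter, plus a small
  bound ligand, with exact contact truth from brute-force enumeration.

Marker planting overwrites the evolved column (in-group state vs a disjoint
out-group state) because the analysis this emulates reports a *perfect*
determinant; insertions are planted as blocks rather than evolved because
the indel analysis is a census, not an evolutionary inference.  Every
sub-generator draws from its own derived seed, so adding a feature does not
perturb the others, and a self-audit re-derives each planted feature from
the emitted data before anything is written.  What passing these tests shows
is that the machinery is correct, not that real families behave this way:
the generator has no indel evolution, no heterotachy, no alignment error,
and its clades are cleanly separated by construction.

# Numerical choices and degenerate inputs

* Gamma categories: 4 for tree likelihoods (the phylogenetics convention),
  16 for rate posteriors.
* Branch-length optimizer bounds [0, 10]; scalar tolerance 1e-5 per branch,
  1e-6 on the total log-likelihood across passes.
* Zero-length branches use an exact identity transition matrix, so
  impossible configurations give exactly `-Inf` rather than underflow noise.
* NJ tie-breaks are inherited from the deterministic implementation;
  negative NJ branch estimates are clamped to zero.
* All-constant alignments flag rate estimation as degenerate (warning,
  boundary estimates).  All-equal conservation scores grade 5.  All-gap
  columns grade 0.
* Duplicate culling keeps the first record in input order; all coordinates
  are 1-based inclusive in reference numbering.

# Problem sizes used in validation

The shipped validation uses desk-scale replicas of each analysis: 5-leaf
trees for enumeration checks, 8 taxa x 3000 sites for branch-length
recovery, 40 taxa x 500 sites for rate-parameter recovery, 20 replicates of
20 taxa x 500 sites for model selection, 100 random trees of up to 12 taxa
for distance-based reconstruction, 100 bootstrap replicates on a 12-taxon
two-clade signal, 20 bundle seeds for marker recovery, 200 random rotations
for permutation detection and 100 toy bundles for contact extraction.
These sizes were chosen so the whole suite exercises every claim in minutes
on one core while keeping every statistical tolerance comfortably wide of
its simulated sampling noise.

# Known limitations

* No ML topology search (NNI/SPR): topologies come from NJ on ML distances,
  which is the intended desk-scale substitute, not a replacement for full
  searches on hard data sets.
* Translation-only module alignment: no gapped refinement, by design.
* The conservation grades are reproducible but not numerically identical to
  any particular public server's binning.
* PDB handling keeps the first alternate location and ignores insertion
  codes; mmCIF is out of scope.
* Identity-site counts for the index pair depend on the helix-range
  configuration; treat the shipped ranges as a documented default, not as
  structure-derived truth.
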
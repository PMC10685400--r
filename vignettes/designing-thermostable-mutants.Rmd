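---
title: "Designing thermostable multiple-point mutants: methods and choices"
author: "stabiliforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing thermostable multiple-point mutants: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabiliforge)
```

## The problem and the protocol

Raising a protein's melting temperature usually takes several mutations,
but stabilizing mutations are not freely combinable: a pair can interact
antagonistically, and a naively stacked mutant can end up less stable than
its best single. `stabiliforge` implements an automated protocol that
treats this as a graph problem. Candidate single-point mutations are
nominated by three strategies, filtered hard for safety, and then combined
only along pairs whose joint free-energy change is verified (or safely
additive) — the final design is the best clique of mutually compatible
mutations.

The package works from two inputs: a tertiary structure (PDB) with
B-factors, and a multiple-sequence alignment of curated homologs whose
query row matches the structure's chain. Energies come from a pluggable
evaluator interface; exported prediction tables can be used directly, and
a deterministic built-in surrogate makes the whole pipeline runnable at
desk scale.

## Annotation model

**Conservation.** Per alignment column with residue distribution $p$ and a
background distribution $q$ (BLOSUM62 marginal amino-acid frequencies),
the score is the Jensen–Shannon divergence
$\mathrm{JSD}(p\|q) = \tfrac12 KL(p\|m) + \tfrac12 KL(q\|m)$ with
$m=(p+q)/2$ and base-2 logarithms, hence bounded in $[0,1]$. The raw score
is multiplied by $(1-\text{gap fraction})$ so gappy columns cannot look
conserved, then smoothed along the sequence: the final score is
$(1-w)\cdot\text{own} + w\cdot\text{mean of neighbours}$ over up to 3
columns on each side with $w=0.5$ (both configurable). Scores are
discretised into grades 0–9 by strict-rank deciles — grade =
$\min(9,\lfloor 10 f\rfloor)$ where $f$ is the fraction of columns scoring
strictly higher — so grade 0 is the most conserved. The grade scale's
orientation (low = conserved) is fixed by the filter's intent: positions of
grade ≤ 4 are treated as functionally constrained and excluded from
mutagenesis. Which absolute scale a web service would print is not
derivable from first principles; the decile construction is this package's
choice and both the cutoff and the orientation are parameters.

**Coevolution.** Four methods ship by default, all mapping the alignment
to a symmetric column-pair matrix with zero diagonal: mutual information
(bits, over sequences non-gapped at both columns), OMES
($\sum (N_{obs}-N_{exp})^2/N$), a substitution-matrix correlation score
(Pearson correlation, over all sequence pairs, of the substitution scores
observed at the two columns; BLOSUM62 by default — the matrix is an
argument, so a McLachlan-type matrix can be supplied), and
average-product-corrected MI, included as the panel's corrected-MI member
($out_{ij} = in_{ij} - \bar r_i \bar r_j / \bar r$ over off-diagonal
means). Further methods register as plain functions `msa -> matrix`.
Because the methods' scales are incommensurable, each method flags its top
1 % of pairs (ties kept; non-positive scores never flagged) and the
consensus score of a pair is the number of flagging methods. The decision
threshold 3.5 refers to a seven-method reference panel; with $k$ methods
installed it rescales to $3.5\,k/7$ so the default remains meaningful.
Equal method weights are assumed throughout.

**Structure features.** Solvent accessibility is computed by Shrake–Rupley
sphere sampling (960 points per atom on a deterministic golden-spiral set,
probe 1.4 Å, standard van der Waals radii, fallback 1.8 Å with a warning)
and normalised by the per-residue-type theoretical maxima; residues with
relative SASA ≥ 0.25 form the surface mask. "Within 10 Å" between two
residues means the minimal heavy-atom distance between the wild-type side
chains' residues — the strictest of the common conventions, chosen because
it never misses a potentially interacting pair. Flexibility is the
per-residue mean of atom B-factors, reported with z-scores and a
descending ranking (ties broken toward lower residue numbers); both a
fixed-count (`top_n`) and a z-score selection are available because
reasonable analyses use either.

## Candidate generation and filtering

Positions that are essential (user-supplied list), conserved (grade ≤ 4)
or correlated are excluded in *every* scenario. The mutation-level filters
define the risk split: the **low-risk** policy additionally rejects
substitutions whose target residue never occurs in the position's
alignment column, and charge-class changes (K/R positive, D/E negative,
histidine neutral at pH 7) at surface positions; the **high-risk** policy
skips exactly these two checks. Filters are evaluated in a fixed order
(essential, conserved, correlated, alignment-presence, charge-surface) and
a rejected candidate records the first failing filter, which makes the
`summary()` rejection table interpretable. By construction the high-risk
survivor set contains the low-risk one.

The three branches:

* **Saturation energies.** All 19 substitutions at every position (or only
  the most flexible residues, when B-factor targeting is chosen). A
  two-stage cascade mirrors a fast-scan-then-refine force-field setup:
  stage 1 must reach −1.0 kcal/mol, and only its survivors are evaluated
  by stage 2, which must reach −1.5 kcal/mol. Both cutoffs are inclusive
  (a mutation at exactly the threshold passes): the thresholds are stated
  as limits, and inclusivity keeps the advertised values usable.
* **Back-to-consensus.** Per position, the most frequent column residue
  $c$ (ties resolved alphabetically for determinism) is a candidate if
  $c$ differs from the wild type and either $f_c \ge 0.50$ (majority) or
  $f_c \ge 0.40$ and $f_c \ge 5 f_{wt}$ (ratio). Frequencies exclude gaps
  from the denominator by default — counting gaps would make gap-rich
  columns unable to reach 50 % regardless of their residue makeup — with
  a switch to include them. Both thresholds are inclusive. Surviving
  candidates are energy-checked with a tolerance threshold of
  +0.5 kcal/mol: evolution already vouches for them, so the energy check
  only removes clearly destabilizing ones.
* **Ancestral.** Each precomputed ancestral sequence is globally aligned
  to the query (Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5 —
  conventional protein-alignment defaults) and substitutions at aligned
  columns are collected; insertions and deletions are ignored. Because
  nodes near the root accumulate unreliable substitutions, only mutations
  recurring in at least 2 nodes are kept. The branch is reported as a
  single-point list rather than entering the clique machinery: ancestral
  variants are typically synthesised as reconstructed sequences, not
  recombined mutation-by-mutation.

Homolog curation, when starting from unaligned homologs, applies an
inclusive 30–90 % identity window (global identity: identical columns over
alignment columns excluding terminal gaps; `X` never matches), greedy
clustering at 90 % identity over length-sorted input (exact pairwise
identity in place of word-index heuristics), and selection of at most 200
cluster representatives sorted by query coverage (aligned query fraction),
with identity and id as deterministic tie-breaks. Whether "identity"
should be local or global is a genuine fork; global is used and exposed.

## The pair graph and clique search

Accepted singles become nodes weighted by their ΔΔG. For every unordered
pair at distinct positions: within 10 Å the pair ΔΔG is evaluated
explicitly; beyond it the pair is taken as exactly additive. An edge
survives only when the pair is non-antagonistic,
$\Delta\Delta G_{pair} \le \min(\Delta\Delta G_a, \Delta\Delta G_b)$ —
the combination must be at least as good as its better member. Note that
additive pairs between two *stabilizing* singles always pass, while an
additive pair involving a destabilizing single always fails; mildly
destabilizing consensus mutations therefore rarely reach combined designs,
which is the intended risk containment. Pairs whose evaluation fails are
dropped conservatively (no unverified co-occurrence). Same-position
mutations are never connected.

Maximal cliques are enumerated by Bron–Kerbosch with pivoting, returned in
a canonical order (members sorted by position, cliques sorted
lexicographically) so results are stable across runs. The design is the
clique minimising the sum of its members' single ΔΔG values — pair
energies decide only edge existence. This reading keeps selection
independent of pair magnitudes; a variant that adds pair corrections would
need pair values for all distant pairs too, which the additivity rule
deliberately avoids. Ties prefer the larger clique, then the
lexicographically smallest position list (invented, deterministic).
Enumerating cliques is exponential in the worst case; beyond roughly 25
accepted mutations runtimes grow quickly and no mitigation beyond the
filters themselves is attempted.

Combined designs re-run the same machinery on the union of the energy and
evolution designs' mutations, reusing already-evaluated pair values;
same-position conflicts keep the more stabilizing single. An empty branch
leaves the combined design equal to the other branch's design.

## Energy evaluators

An evaluator is a pair of functions, `single(mutation)` and
`pair(mut_a, mut_b)`, both in kcal/mol with negative = stabilizing, the
sign convention implied by negative thresholds throughout. `pair` is
symmetrised and refuses same-position input.

`table_evaluator()` wraps exported prediction tables read by
`read_ddg_table()` (plain TSV, a position-by-amino-acid grid dialect, and
a `ddG:`-record dialect). Duplicate rows are averaged with a warning — the
tolerant reading of multi-run exports. A missing single is an error; a
missing pair falls back to additivity and counts the fallback.

`surrogate_evaluator()` is the package's own deterministic stand-in for
desk-scale operation: the ΔΔG of a mutation is the summed change of a
contact potential over neighbours within 6.5 Å of the side-chain reference
point (C-beta; C-alpha for glycine), plus a seeded position-hashed noise
term of amplitude 0.2 kcal/mol that keeps toy landscapes non-degenerate
without flipping engineered signs. The potential is a hydrophobicity
product, $e(a,b) = -0.05\,kd_a\,kd_b$ (Kyte–Doolittle), so burying
mutually hydrophobic residues is favourable. The 0.05 scale was set from
distribution statistics: it puts per-contact energy differences near
1 kcal/mol — the order of magnitude of statistical contact potentials —
and gives whole-protein saturation scans a spread of about 1 kcal/mol with
a stabilizing tail of roughly 10 % at the −1 kcal/mol stage, the regime a
thresholded force-field cascade is designed to prune. Pair values add a
coupling term only when the two mutated residues are themselves in
contact, and are exactly additive otherwise. The surrogate is a
self-contained model, not a calibrated predictor: its numbers are
internally consistent and deterministic, nothing more.

## What the generators emulate — and what they do not

`synth_structure()` builds an ideal α-helix (rise 1.5 Å, 100° twist,
helical radius 2.3 Å) with backbone atoms and C-beta stubs, log-normal
per-residue B-factors, optionally planted high-flexibility residues and an
optional occluding atom shell to create a genuinely buried residue. It
provides exact ground truth for geometry, SASA and B-factor code, but has
no packing core, no loops, no quaternary contacts.

`synth_msa()` plants known signal — invariant columns, consensus residues
at stated frequencies, bijectively coupled column pairs — on a background
where each homolog row matches the query with probability 0.55 per
position, the middle of the 30–90 % identity window the curation step
enforces. This query-biased background matters: columns drawn uniformly
from 20 residues would have so much finite-sample mutual-information bias
at realistic depths that no planted coupling could surface, which is a
property of uniform noise, not of homolog alignments. The generator makes
no attempt at phylogenetic correlation between rows, indels, or
domain-level conservation structure; passing tests therefore demonstrate
rule fidelity and engine correctness on alignments with controlled
statistics, not predictive accuracy on natural proteins.

`synth_landscape()` returns an evaluator with stated singles, additive
pairs and explicit overrides — the ground truth for the antagonism and
clique machinery.

The test-suite problem sizes — alignments of 20–50 sequences over 10–50
columns, structures of 8–40 residues, graphs of up to 12 nodes checked
against exhaustive $2^n$ enumeration, landscapes of up to 10 mutations
against exhaustive subset search — are the package's choices for exact
oracle comparison: small enough to enumerate completely, large enough to
exercise every rule.

## Numerical and degenerate-input conventions

* Confusion metrics: sensitivity tp/(tp+fn), specificity tn/(tn+fp), FDR
  fp/(tp+fp) with FDR defined as 0 when nothing is predicted positive (the
  empty-prediction case must not crash, and a zero-FP row should read 0);
  reported rounded to 3 decimals. Experimentally "stabilizing" means
  ΔΔG < 0 strictly; a measured 0 counts as not stabilizing.
* All threshold comparisons in the pipeline are inclusive.
* Alternate locations in PDB input keep the highest-occupancy copy;
  selenomethionine maps to methionine; other non-standard residues drop
  with a warning; an all-gap alignment, an empty homolog set after
  filtering, and an empty clique list all produce defined results
  (error, empty table, wild-type design) rather than surprises.
* Oracle-comparison tolerances in the tests are 1e-9 or tighter for
  closed-form quantities; SASA comparisons allow the sampling tolerance of
  the point set (2 % on doubling the points, 1 % on whole-protein area
  under rigid motion).
* Every generator accepts a seed, derives all randomness from it, and
  restores the caller's RNG state.

## Known limitations

The surrogate potential has no backbone, electrostatics, or solvation
terms and cannot rank real mutations; use exported predictions from a real
force field for design work. Conservation grades are alignment-relative
(deciles), so their absolute meaning shifts with alignment composition.
The coevolution panel ships four of the seven methods a full consensus
panel would use; the rescaled threshold keeps the decision calibrated but
with fewer independent votes. Structures are used as given — no repair or
minimisation precedes evaluation. Ancestral sequences must be
reconstructed elsewhere; the package only consumes them. Clique
enumeration is exact, hence exponential in pathological dense graphs.
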
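# stabiliforge

Automated computational design of thermostable multiple-point protein
mutants, for protein engineers who have a tertiary structure and a set of
sequence homologs and want a short list of mutations that are safe to
combine.

Single-point stability predictions are plentiful; the hard part is
combining them. Two individually stabilizing mutations can interact
antagonistically, so a multiple-point mutant assembled naively may be worse
than its best member. `stabiliforge` implements a protocol that (i)
annotates the target protein, (ii) nominates single-point mutations from
three independent strategies, and (iii) assembles them into
non-antagonistic combinations via a graph/clique search.

## The method in brief

**Annotation.** From an alignment of curated homologs (identity window
30–90 %, greedy 90 % identity clustering, ≤200 coverage-sorted
representatives) each query position gets a conservation score — the
Jensen–Shannon divergence between the column's residue distribution *p* and
a background *q*,

> JSD(p‖q) = ½ KL(p‖m) + ½ KL(q‖m),  m = (p+q)/2,

gap-damped, window-smoothed and discretised into grades 0–9 (0 = most
conserved). Column pairs are scored by a panel of coevolution methods (MI,
OMES, substitution-matrix correlation, APC-corrected MI, plus user
plugins); each method flags its top 1 % of pairs and a position is
*correlated* when a pair it belongs to is flagged by enough methods
(consensus ≥ 3.5 on a 7-method reference scale). The structure contributes
per-residue solvent accessibility (Shrake–Rupley), a surface mask
(relative SASA ≥ 0.25) and B-factor flexibility rankings.

**Single-point candidates.** Three branches, each filtered against
essential, conserved (grade ≤ 4) and correlated positions:

* *saturation energies* — all 19 substitutions everywhere, kept when both
  stage-1 (ΔΔG ≤ −1.0 kcal/mol) and stage-2 (ΔΔG ≤ −1.5 kcal/mol)
  evaluations pass; low-risk designs additionally require the target
  residue to occur in the alignment column and forbid charge changes on
  the surface;
* *back-to-consensus* — the column consensus residue when its frequency is
  ≥ 50 % (majority rule) or ≥ 40 % and ≥ 5× the wild-type frequency
  (ratio rule), kept unless clearly destabilizing (ΔΔG > +0.5 kcal/mol);
* *ancestral* — substitutions recurring in ≥ 2 reconstructed ancestral
  sequences of the query lineage (reported as a single-point list).

Energies come from pluggable evaluators: adapters for exported prediction
tables, or a built-in deterministic surrogate contact potential for
desk-scale runs.

**Multiple-point assembly.** Accepted mutations become graph nodes
weighted by their ΔΔG. Pairs closer than 10 Å are evaluated explicitly;
more distant pairs are taken as additive. An edge is kept only when the
pair is non-antagonistic — its ΔΔG is at least as good as the better of
the two singles. Maximal cliques are enumerated with Bron–Kerbosch
(pivoting) and the clique with the lowest total single-mutation ΔΔG is the
design. The procedure is repeated over the union of the energy and
consensus designs to build combined low-/high-risk mutants.

## Worked example

Everything below is synthetic and runs in a few seconds:

```r
library(stabiliforge)

st <- synth_structure(40, seed = 7)                 # ideal helix + B-factors
qseq <- chain_sequence(st)$sequence
al <- synth_msa(qseq, depth = 30, seed = 8,        # plant a consensus signal
                consensus_injections = data.frame(pos = 37, aa = "T",
                                                  freq = 0.55))
res <- design_stability(st, al, seed = 7)
res
```

```
stability_designs over 40 residues (chain A) 
  energy-low     2 mutation(s)  total ddG  -5.160  S15V T17I
  energy-high    3 mutation(s)  total ddG  -9.689  S15I T17I D21I
  evolution      1 mutation(s)  total ddG   0.104  S37T
  combined-low   2 mutation(s)  total ddG  -5.160  S15V T17I
  combined-high  3 mutation(s)  total ddG  -9.689  S15I T17I D21I
```

Each line is one design scenario: the mutation set is a maximal clique of
the non-antagonistic pair graph and the total is the sum of its members'
predicted ΔΔG (kcal/mol, negative = stabilizing). The high-risk scenario
admits surface charge changes and alignment-absent residues, hence the
larger, more aggressive set. `S37T` is the planted consensus signal
recovered by the evolution branch; because it is itself mildly
destabilizing (+0.10 kcal/mol), every additive pair it forms is
antagonistic (the pair sum is worse than the stabilizing partner alone),
so the combined designs here coincide with the energy designs — exactly
the risk containment the edge-removal rule is for. `summary(res)` breaks
down the filter cascade (rejection reasons per filter, survivor counts),
and `write_designs(res, "out/")` exports FASTA/CSV/JSON reports.

With real inputs, replace the generators with `read_pdb()`,
`read_aligned_fasta()` and, for external energy predictions,
`table_evaluator(read_ddg_table(...))`.

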
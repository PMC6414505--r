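---
title: "Template-based peptide binding-site prediction: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Template-based peptide binding-site prediction: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepbind)
```

## The problem and the model

Short peptides (5-25 residues, typically disordered when unbound) mediate a
large class of regulatory protein interactions, yet their complexes are hard
to study experimentally. `pepbind` predicts *where* on a receptor structure a
given peptide binds, without docking: the structural neighbourhood of the
receptor in fold space is mined for precedent. The pipeline has four stages.

1. **Mass structural alignment.** The receptor is superposed onto the
   receptor-role chain of every entry in an interaction-template library
   (pairs of chains from known complexes with any heavy atom within 6 Å of
   each other). Alignments are scored with the TM-score,
   $\mathrm{TM} = \frac{1}{L} \sum_i \frac{1}{1 + (d_i/d_0)^2}$, with
   $d_0 = 1.24\,(L-15)^{1/3} - 1.8$ (floored at 0.5 Å for short chains).
   Alignments with target-normalized TM-score ≥ 0.5 — the accepted threshold
   for a significant fold match — transfer the template's interface residues
   onto the equivalent receptor positions, proposing a candidate binding
   surface.
2. **Feature extraction.** Each candidate is summarised by 23 features
   (lengths, alignment quality, aligned-region complexity, amino-acid
   composition distances, secondary-structure content, surface exposure and
   conservation, and the sequential continuity of the template's peptide),
   plus an optional receptor model-quality feature when the receptor is a
   homology model.
3. **Random-forest classification.** A 100-tree probability forest with
   unlimited depth and $\sqrt{N}$ features per split estimates the
   probability that a candidate is *correct*, where a training candidate is
   labelled correct when at least 80% of the residues it suggests belong to
   the true site.
4. **Clustering and scoring.** Candidate surfaces are clustered by
   average-linkage hierarchical clustering under the mean cross-pair
   C$_\alpha$ distance, cut automatically at the elbow (the largest jump in
   merge heights). A cluster scores the maximum member probability; the top
   10% of templates in the best cluster are combined into per-residue *local
   scores* by probability-weighted membership averaging; and the prediction's
   confidence is the *global score* $0.61\,c + 0.39\,\ell$, the fixed convex
   combination of cluster score $c$ and maximum local score $\ell$.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| contact cutoff | 6.0 Å | heavy-atom distance defining interfaces |
| min receptor length | 25 | smallest chain eligible for the receptor role |
| TM-score gate | 0.5 | target-normalized significance threshold |
| label threshold | 0.8 | fraction of suggested residues that must be correct |
| per-pair training cap | 2000 | max templates one complex contributes |
| jack-knife exclusion | TM ≥ 0.5 | structural similarity barred from training |
| forest | 100 trees, √N mtry | probability forest configuration |
| score weights | 0.61 / 0.39 | cluster / local contribution to the global score |
| probe radius | 1.4 Å | solvent probe for SASA |

## Numerical and design choices

**Residue indexing.** All residue positions are 1-based indices into a
chain's residue list, the natural R convention; author numbering and
insertion codes survive only in the atom table.

**SASA.** Shrake–Rupley with NACCESS-compatible van der Waals radii
(C 1.87, N 1.65, O 1.40, S 1.85 Å), probe 1.4 Å, and a deterministic
Fibonacci point lattice (960 points/atom by default). Coordinates are first
rotated into a deterministic principal-axis frame, which makes the value
exactly invariant under rigid-body motion of the input; when SASA values are
*differenced* across chain subsets (buried surface, burial fraction) a
single common frame is used so the lattice discretisation cancels. The
buried ("shared") surface is reported as the full difference
SASA(A) + SASA(B) − SASA(AB), not halved — with the full-difference
convention a 5-residue peptide lying semi-exposed along a protein surface
buries roughly 400 Å², the magnitude used by the dataset filter, whereas the
halved convention would put such peptides far below it.

**Secondary structure.** A C$_\alpha$-geometry assignment in the spirit of
P-SEA: a window is helical when its i/i+2, i/i+3, i/i+4 distances match ideal
helix geometry (≈5.4, 5.1, 6.2 Å), strand-like for extended-sheet distances;
everything else is coil. Chains shorter than 5 residues, and positions
without C$_\alpha$, are coil.

**Structural alignment.** A simplified TM-align-style heuristic: gapless
diagonal seed fragments (full diagonal overlaps plus length-8 windows) are
Kabsch-superposed and refined by up to five rounds of Needleman–Wunsch
alignment (free end gaps, gap penalty −0.6, match score
$1/(1+d^2/d_0^2)$) alternating with re-superposition; the mapping with the
best target-normalized TM-score wins, ties broken by the earliest seed. The
final TM-scores are maximised over superpositions of the mapped pairs with a
TM-score-style iterative-inclusion search. Exact parity with reference
implementations is not a goal; the contract is the TM-score definition and
the 0.5 gate. The gate is applied to the *target*-normalized score: the
quantity of interest is how much of the target is explained by the template,
and normalizing by target length prevents long templates from matching
trivially.

**Feature definitions.** Where a feature name admits more than one formula,
the package fixes: composition distance = Euclidean distance between
20-dimensional relative frequency vectors; contact order = relative contact
order over the aligned region (6 Å heavy-atom contacts, sequence separation
≥ 3); sequential distances of the template peptide = gaps between consecutive
interface positions; conservation = 1 − Shannon entropy of the MSA column
normalized by log 20, averaged over the site, with a neutral 0.5 when no MSA
is supplied; peptide secondary-structure probabilities come from a
user-supplied 3-state prediction or, failing that, normalised Chou–Fasman
propensities. The forest learns on whatever definitions are used, so
internal consistency rather than parity with any external tool is the
contract. The summed-segment-length feature, defined as the total size of
the maximal consecutive runs of the partner interface, always equals the
interface size under this definition; it is kept for completeness.

**Clustering.** Site distance is the mean over *all cross pairs* of member
C$_\alpha$ distances — the phrase "distance between the coordinates for each
residue" is ambiguous between cross-pair and matched-residue means, and the
cross-pair mean needs no residue correspondence and is defined for unequal
site sizes. The elbow cutoff is the midpoint of the largest first difference
of the sorted merge heights (first such gap on ties; a single merge yields
one cluster). Candidate coordinates come from the unbound target structure,
so clusters describe locations on the target surface. The local-score
normalisation divides by the summed weights of the *selected* (top 10%)
members only. The amino-acid preference profile is a reconstruction (no
published formula): the probability-weighted frequencies of the partner
residue types contacting each template interface residue, read from the
contact map stored at library build time, accumulated over all templates in
the winning cluster.

**Ranking.** Classification, not regression (the fraction-correct regression
variant is deliberately not implemented). `ranger` provides the forest;
`min.node.size = 1` emulates depth-unlimited trees, `mtry = ⌊√N⌋`, Gini
(impurity) importances. The seed is a required argument and is recorded in
the model metadata. Class imbalance is left as-is. Each template pair can
contribute both of its chains as receptor-role entries when both pass the
25-residue filter; whether the original pipeline used one or two is unknown,
and two maximises library coverage.

**Homolog exclusion.** The benchmark harness removes templates with
`blastp` E < 0.001 to the target when `blastp` is on the PATH; otherwise it
falls back (with a warning) to a global-alignment identity filter at 30%.
Redundancy reduction of benchmark cases replaces BLASTCLUST with greedy
single-linkage clustering on global-alignment identity (matches over
alignment length).

**Coverage regression.** The true binary interface vector is fitted as a
linear combination of template interface vectors by minimum-norm ordinary
least squares (`MASS::ginv`); the fitted site is the $|y|$ highest-scoring
residues, mirroring the "predict n residues" framing of the random baseline,
whose surface is defined as residues with relative exposure above 5%.

## The synthetic-data generator

Real template libraries require a PDB snapshot; the generator builds
deterministic stand-ins so every stage is testable offline. Chains are ideal
backbones — α-helix (1.5 Å rise, 100°/residue, 2.3 Å radius), zig-zag
strand (3.8 Å spacing), hairpin, three-helix bundle — with pseudo side-chain
atoms (CB at 1.5 Å, CG at 2.9 Å from C$_\alpha$, pointing away from the
backbone) so that contacts, SASA and burial behave qualitatively like real
chains. Complexes place a peptide against the bundle groove at a 3.0 Å
closest approach, giving true interfaces of roughly 5–10 residues — the
scale of a semi-exposed MoRF site. Planted libraries contain a σ-noise copy
of the target complex (the correct template), unrelated folds (which fail
the TM gate), and optionally wrong-site homologs (which pass the gate and
supply negative training examples). Sequences are uniform over the 20 amino
acids unless specified.

What the generator does *not* emulate: full side-chain packing and real
atom counts (interfaces are smaller and SASA totals lower than for all-atom
chains), realistic fold and interface-size distributions, sequence-structure
correlations, and crystallographic artefacts. Passing the synthetic
benchmarks therefore demonstrates that the machinery — alignment, transfer,
learning, clustering, scoring — recovers planted signal under noise; it does
not certify accuracy on real complexes, which depends on library coverage of
the real fold space.

## Problem sizes used by the shipped analyses

The bundled tests and the acceptance script train on 8 synthetic targets
(planted libraries with 6 unrelated + 5 wrong-site decoys each), evaluate
end-to-end on 20 independent replicates (20 decoys each, σ = 0.5 Å), use
10,000 Monte-Carlo trials for the random baseline, 1,000 random rotations ×
50 instances for the superposition oracle, and 100 random instances for the
coverage-regression monotonicity property. These sizes were chosen as the
smallest at which the stochastic checks are stable across seeds.

## Known limitations

- mmCIF input, explicit hydrogens, ligands and nucleic acids are out of scope.
- The alignment heuristic is sequential (no non-sequential alignments) and
  may underestimate TM-scores for multi-domain rearrangements.
- The d0 floor (0.5 Å) makes TM-scores of very short normalization lengths
  conservative; the raw formula value is available via `tm_d0(l, clamp = FALSE)`.
- No 3-D peptide pose is produced; the output is a surface, a confidence and
  a residue-type preference, intended as a starting point for docking tools.
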
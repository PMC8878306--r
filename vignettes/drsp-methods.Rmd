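---
title: "Predicting drug-resistance mutations from protein-drug complex structure"
author: "drsp package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug-resistance mutations from protein-drug complex structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drsp)
```

## The problem and the model

Targeted anticancer drugs bind a specific protein; single amino acid
variants (SAVs) in that protein can abolish or weaken binding and make the
tumour resistant. Given a protein-drug complex structure, a list of SAVs and
a sequence-conservation profile, `drsp` classifies each SAV as *resistant*
or *non-resistant*.

The model rests on one structural observation: the majority of known
resistance mutations sit inside the drug-binding pocket, operationally the
region within 8 Å of the bound drug, while a substantial minority act at a
distance. The two regimes are mechanistically different (direct steric or
chemical interference with binding versus allosteric or stability effects),
so the classifier is *routed*: a SAV whose minimum heavy-atom distance to
the drug is at most 8 Å goes to an interior model, all others to an exterior
model, and the combined system is the disjoint union of the two. The
boundary itself (exactly 8.0 Å) is assigned to the interior model; the
interior model has the higher sensitivity, so the inclusive convention
favours catching pocket mutations. Each stratum gets its own feature subset
and its own classifier, because the features that matter in the pocket
(drug contact energies, pocket packing) are not those that matter outside
it.

## The 45-feature SAV descriptor

Each SAV is described by 45 named features in four blocks.

**Interaction energies (3).** `DKE-ele`, `DKE-hb`, `DKE-vdw` decompose the
drug-residue interaction into electrostatic, hydrogen-bond and van der
Waals terms, summed over non-hydrogen atom pairs between the variant
residue and the ligand. The package computes them with documented standard
forms: a Coulomb sum with distance-dependent dielectric
$\varepsilon(r) = 4r$ over a fixed per-element partial-charge table; a 12-6
Lennard-Jones sum with per-element radii and well depths combined by
Lorentz-Berthelot rules; and a square-well hydrogen-bond term of
$-2.5$ kcal/mol per donor-acceptor (N/O-N/O) pair with
$2.3 \le r \le 3.5$ Å. All three are truncated at 10 Å. The contract is the
three-term decomposition, determinism, and invariance under rigid motions —
these are coarse contact descriptors, not a docking score.

**Microenvironment packing (26).** The weighted contact number of the
variant's Cα atom, $\mathrm{WCN} = \sum_j 1/r_j^2$, measures local packing
density and tracks evolutionary constraint. `WCN-ca`, `WCN-n` and `WCN-o`
sum over all other residues' Cα, nitrogen and oxygen atoms respectively
(backbone and side chain for N/O). The remaining 23 features restrict the
Cα sum to neighbours of one physicochemical class under six schemes —
hydropathy (H), volume (V), polarizability (Z), polarity (P), charge
character (F; 3 classes each) and chemical group (E; 8 classes). Classes
partition the 20 residues, so within each scheme the class features sum
exactly to `WCN-ca`; this identity is asserted to $10^{-9}$ in the tests
and is a strong internal consistency check. All WCN features scale as
$1/k^2$ under coordinate scaling by $k$.

**Structure (5).** `BF` is the raw Cα B-factor (no normalization: complexes
are featurized one at a time, and the classifier's min-max scaling absorbs
the units). `ACC` is the residue's solvent-accessible surface area from a
Shrake-Rupley sphere sampling (probe 1.4 Å, 92 golden-spiral points per
atom, heavy atoms; agreement with a 1000-point reference is within 5 %).
`EHB-acc` and `EHB-don` are the best (most negative) backbone hydrogen-bond
energies with the residue as acceptor and donor, using the Kabsch-Sander
electrostatic model
$E = 27.888\,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol with the
standard $-0.5$ kcal/mol bond threshold; residues with no bonded partner
report 0. We take the best single partner rather than a sum: the quantity
is meant to say "how firmly is this backbone position anchored", and the
strongest bond carries that information without conflating bifurcated
geometries. `SSE` encodes secondary structure as 1 (helix: H/G/I), $-1$
(strand/bridge: B/E), 0 (loop). These can be computed internally (amide
hydrogens reconstructed from the preceding carbonyl; n-turn and bridge
patterns assigned from the bond matrix) so no external DSSP binary is
needed, or supplied as a parsed classic DSSP file ([read_dssp()]); both
routes satisfy the same contract.

**Sequence conservation (11).** `SSI-b62` and `SSI-p250` are the BLOSUM62
and PAM250 entries for the wild-type-to-mutant substitution (shipped as
NCBI-format text matrices). `SSI-pssm` is the PSI-BLAST PSSM score at the
SAV position; the package scores the *mutant* residue by default — the
quantity of interest is how well the introduced residue fits the
evolutionary record of that position — with `"wt"` and `"delta"` modes
available. `ETP-avgW` for $W \in \{1,3,5,\dots,15\}$ averages per-position
Shannon entropy (base 2; any fixed base only rescales the feature) over a
window of width $W$ centred on the SAV, truncated at the sequence ends and
averaged over available positions only. Profile columns are amino-acid
frequencies; entropy is computed from them directly, with no sequence
weighting or pseudocounts.

## Feature selection: the genetic algorithm

With 45 candidate features and a few hundred labelled SAVs per stratum,
exhaustive subset search is impossible and greedy selection is unstable, so
a genetic algorithm searches mask space. A solution is a binary mask of
length $m$; fitness is a classification measure (accuracy, MCC, F1, or the
Hybrid measure $\mathrm{Sensitivity} + \delta\,\mathrm{Specificity}$ with
$\delta$ the positives:negatives ratio of the training labels) of the
masked SVM under stratified 5-fold cross-validation with pooled out-of-fold
predictions. Defaults follow the study conditions: 80 solutions, 150
generations, 8 independent runs, and the best run chosen by MCC.

The operators are deliberately minimal. Two elitist incumbents are kept:
$\alpha$, the best solution ever seen in the first half of the population,
and $\beta$, likewise for the second half (both start with fitness 0 and no
mask). Each new generation copies $\alpha$ into odd slots and $\beta$ into
even slots; solutions $1..N/2$ then mutate each bit independently with
probability 0.1, solutions $N/2{+}1..N$ have exactly one uniformly chosen
bit flipped; finally consecutive pairs undergo one-point tail-swap
crossover with probability 0.5 (swap point uniform on $1..m$). The
evaluate → update incumbents → copy → mutate → crossover order follows the
procedure's narrative description; the package also exposes the reversed
mutate/crossover order behind `ga_control(op_order=)` for sensitivity
checks. Because the incumbents can only improve, the best-so-far fitness
trace is non-decreasing — asserted exactly in the tests.

Numerical choices worth stating: all-zero masks (possible after mutation or
crossover) get sentinel fitness $-1$ rather than being repaired, keeping
the operators exactly as specified; ties in the incumbent update keep the
earlier-encountered candidate, with the previous incumbent considered last;
cross-validation folds are drawn once per run, so fitness comparisons
between masks are paired; and each run $r$ is seeded with
$\mathrm{seed} + r - 1$, giving both fresh initial populations and fresh
folds per run while keeping the whole computation deterministic. If every
candidate in a half scores below 0 while the incumbent still has no mask (a
degenerate situation reachable only in the first generations), the best
candidate of that half is used so that generation building always has a
parent. Within a run, fitness values are cached by mask, which speeds the
strongly repetitive later generations considerably without changing any
result.

Inside GA fitness evaluation the SVM uses fixed hyperparameters
($C = 1$, $\gamma = 1/m_\text{selected}$): nesting the full hyperparameter
grid inside every mask evaluation would multiply the cost by three orders
of magnitude while mostly re-ranking masks the same way. The grid search is
applied once, to the final model on the selected mask.

## The classifier

Each stratum's final model is a LIBSVM RBF-kernel C-classifier. Features
are min-max scaled to $[-1, 1]$ with parameters fitted on training data
only (training folds during cross-validation; the full stratum for the
final refit); constant features map to 0. The penalty and kernel width are
chosen by exhaustive exponential grid search, $C = 2^a$, $\gamma = 2^b$
with integer $a, b \in [-15, 15]$ (31 × 31 pairs), scored by stratified
5-fold cross-validated MCC with ties broken toward smaller $a$, then
smaller $b$ (a mild preference for flatter models among equals). MCC is
used for model selection throughout because the class balance is heavily
skewed (roughly 1 resistant : 3.6 non-resistant in the emulated training
conditions) and accuracy saturates on the majority class. Class weights are
left unadjusted; the imbalance enters only through the Hybrid fitness
option.

The combined model stores both submodels plus the 8 Å cutoff. Prediction
routes each variant by distance and reports the label and a signed decision
value (positive = resistant). Evaluation of the combined model is
bookkeeping, not averaging: the pooled confusion counts are exactly the sum
of the interior and exterior counts, asserted as an identity in the tests.

## Synthetic study conditions

The package generates every input class it consumes, so the full pipeline
is testable offline.

* **Toy complexes** are idealized backbones (N, CA, C, O per residue) built
  from internal coordinates (default dihedrals $\varphi = -57^\circ$,
  $\psi = -47^\circ$, an ideal α-helix; an extended-strand setting is used
  in tests), with a random proline-free sequence, plausible B-factors, and
  a multi-atom ligand placed along the designated residue's outward radial
  direction so that the minimum heavy-atom distance hits a requested target
  within 0.1 Å (the placement solves a 1-D root-finding problem in the
  actual minimum-distance function). These exercise parsers, distances and
  every structure feature; they do not model side chains, rotamers, or real
  pocket chemistry.
* **Conservation profiles** have per-position frequency vectors whose
  entropies match requested targets within 0.05 bits (one dominant residue
  mixed with a uniform background, mixing weight solved by root finding),
  with optional spikes for window-dilution tests.
* **Feature tables** plant a known signal: negatives are standard normal in
  all 45 columns, positives are shifted by a standardized effect size
  (default 3) on a small informative subset (default 5 columns), and class
  sizes follow a positives:negatives ratio of 133/477 — the imbalance of
  the emulated training data. The planted effect is a mean shift only; it
  validates recovery and guards against leakage, but real resistance
  signatures are weaker, correlated, and not axis-aligned, so passing these
  tests demonstrates correctness of the machinery, not field performance.

All generators are deterministic under their seed, to the byte, for the
serialized outputs.

Problem sizes in the test and acceptance runs are scaled to desk scale as
the package's own test design: planted-recovery uses $n = 200$, population
20, 20 generations over 10 seeds; the end-to-end demonstration uses
$n = 400$ with population 10 and 10 generations and a coarsened exponent
grid. The defaults in `ga_control()` remain the full study conditions.

## Known limitations

* Docking is out of scope: the package consumes complexes with the ligand
  already placed, and residue numbering follows the structure's author
  numbering (any UniProt mapping is the caller's responsibility).
* The interaction-energy block is a fixed-parameter contact model; it is
  not fitted to, and will not numerically match, any docking program's
  scoring function.
* The internal secondary-structure assignment implements the hydrogen-bond
  turn and bridge patterns but not the full ladder/sheet bookkeeping of a
  reference DSSP implementation; for the encoded three-state feature
  (helix/strand/loop) this is equivalent on the fixtures tested, and a
  parsed DSSP file can always be supplied instead.
* Headline performance numbers on curated resistance datasets depend on
  data that is not distributed with the package; the shipped evaluations
  are property-based and synthetic.
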
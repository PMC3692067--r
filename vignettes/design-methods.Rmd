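---
title: "Evolutionary profile-guided sequence design: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary profile-guided sequence design: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profdesign)
```

# The design problem

Fixed-backbone protein design asks: given a scaffold structure, which amino-acid
sequences are most likely to fold back into it? Physics-based force fields answer
by free-energy minimization, but their inaccuracies make it hard to discriminate
correct folds. `profdesign` instead leans on evolution: if a family of structures
share the scaffold's fold, the residues they tolerate at each structurally
equivalent position are direct evidence about what the fold accepts there. The
package turns a structure library into a position-specific log-odds profile,
couples it with single-sequence predictions of local structure, and searches
sequence space by Metropolis Monte Carlo under a Z-score-normalized energy.

# Pre-processing

## Reference features of the scaffold

The design energy compares predicted features of a candidate sequence against
reference features assigned from the scaffold's coordinates:

* **Secondary structure (SS)** by hydrogen-bond analysis of the backbone in the
  Kabsch–Sander style: the electrostatic bond energy
  $E = 0.084 \cdot 332 \,(1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$ kcal/mol
  marks a bond when $E < -0.5$; n-turns give helices, bridge patterns give
  strands, and the 8 classes collapse to 3 as H,G,I → H; E,B → E; else C. Only
  the 3-state alphabet {H,E,C} is exposed.
* **Backbone torsions** $\phi/\psi$ in degrees from the standard dihedrals;
  undefined (NA) at the respective chain termini.
* **Relative solvent accessibility (RSA)** by Shrake–Rupley sphere sampling
  (960 deterministic Fibonacci-lattice points per atom, probe 1.4 Å) divided by
  the per-residue-type theoretical maxima of Tien et al. (2013), clamped to
  [0, 1]. Before sampling, coordinates are rotated into a canonical
  principal-axes frame (signs fixed by third moments) so the computed areas are
  exactly invariant under rigid-body superposition of the input. This is a
  sphere-sampling accessibility, not a reimplementation of any particular DSSP
  area dialect; only the relative scale matters downstream.

C-α-only input is first passed through `reconstruct_backbone()`, which places
N, C and O with ideal bond geometry (N–CA 1.46 Å, CA–C 1.52 Å, C–N 1.33 Å,
C=O 1.23 Å) oriented by local peptide frames measured once on ideal helix and
strand models and interpolated by the local C-α pseudo-torsion. The contract is
that feature assignment works downstream, not that any particular statistical
reconstruction is reproduced; side chains are never built because none of the
features above need them.

## Homolog selection and the profile

Library structures are aligned to the scaffold with a simplified TM-align:
seed alignments are refined by iterating Kabsch superposition on the current
pair set with Needleman–Wunsch re-alignment under the TM-score position score
$1/(1+d_{ij}^2/d_0^2)$, $d_0 = \max(0.5,\ 1.24(L-15)^{1/3}-1.8)$, until the
pair set is stable (at most 20 iterations, gap penalty −0.6). The TM-score is
normalized by scaffold length. Equivalence with the published TM-align binaries
is not claimed — the formula-level behavior (self-alignment 1.0, analytic
half-point at $d_i \equiv d_0$) and monotone discrimination on fixtures are
the tested contract.

The acceptance threshold starts at TM-score 0.7 and relaxes in steps of 0.05
(a choice; the schedule's endpoints 0.7 and 0.5 are fixed, and the count test
is *strictly more than* 10 homologs, configurable) until enough homologs pass
or the 0.5 floor is reached. The accepted alignments form a master–slave MSA
anchored on scaffold positions — homologs are never re-aligned to each other —
and the scaffold's own sequence is always included, so the profile is defined
even with zero library hits (self-profile mode).

Profile construction uses Henikoff position-based weights with exact duplicate
rows collapsed (duplicates share one weight, so adding a copy of a homolog
never changes the profile), and mixes the weighted column frequencies with
BLOSUM62 background pseudocounts using a diversity-based effective count (the
number of distinct residues observed in the column, PSI-BLAST style) at
strength β = 5:
$p_{ja} = (n_j f_{ja} + \beta q_a)/(n_j + \beta)$, with log-odds
$\log(p_{ja}/q_a)$ in natural-log units. Both the weighting scheme and β are
configurable; the columns always renormalize
($\sum_a p_{ja} = 1$).

# The design energy and its Z-score

For a candidate sequence the energy is a linear combination of four
per-residue-normalized cost terms (lower = better):

$$
\begin{aligned}
e_{\text{profile}} &= -\tfrac{1}{L}\textstyle\sum_j \text{log-odds}[j, s_j] \\
e_{\text{ss}} &= \tfrac{1}{L}\textstyle\sum_j \bigl(1 - P_j(\text{SS}^{\text{scaffold}}_j)\bigr) \\
e_{\text{ta}} &= \tfrac{1}{L}\textstyle\sum_j \sqrt{\Delta\phi_j^2 + \Delta\psi_j^2}\,/\,180 \\
e_{\text{sa}} &= \tfrac{1}{L}\textstyle\sum_j \bigl|\widehat{rsa}_j - rsa^{\text{scaffold}}_j\bigr|
\end{aligned}
$$

with wrapped angular differences, single-angle termini contributing
$|\Delta|/180$, and default term weights of 1 each (the combination is linear;
no published weight set exists, so equal weights are the neutral default and
are exposed in `design_config()`). Per-residue normalization keeps length from
dominating, which matters because Z-scoring happens on totals.

The search is guided not by the raw energy but by its Z-score against a
baseline of 1000 random sequences (uniform over the 20 amino acids; the
composition is configurable):
$Z = (E - \bar E)/\delta E$, with sample mean and $(n-1)$-denominator standard
deviation. An optional physics term enters as
$Z \mathrel{+}= w\,(E_{\text{phys}} - \bar E_{\text{phys}})/\delta E_{\text{phys}}$
with $w = -2.44$; the physics scorer itself is a user-registered callback
(none ships with the package), and the two contributions are Z-scored
*separately* so both are dimensionless — whether the weight should instead
multiply the raw physics energy inside a single Z-score is not decidable from
the available description, and the separate form is the one that keeps the
two force fields on a common scale.

## Feature predictors

Decoy features are predicted from single sequences (they are evaluated inside
the inner loop of the search, so they must cost $O(L \cdot \text{window})$, not
a profile construction):

* **propensity** (default, no training): Chou–Fasman H/E/C propensities and a
  Kyte–Doolittle-derived exposure scale in [0, 1], triangularly smoothed over a
  15-residue window and normalized.
* **neural**: one-hidden-layer feed-forward networks (8 hidden units, trained
  with `nnet`) on one-hot 15-residue windows — a softmax net for SS and a
  logistic net for RSA. Training data come from the synthetic-structure
  generator with features assigned by the package itself; training is
  deterministic per seed and a held-out chain split reports Q3.

$\phi/\psi$ are predicted as the torsion-bin centers of the most probable SS
state (helix −62/−41, strand −120/135, coil −75/150) — the simplest model that
serves the torsion-match term; a direct regression is a possible extension.
The same in-repo predictor scores decoys during the search *and* computes the
report-time errors; no external pretrained predictors are involved. All
architecture choices here (window, hidden size, bin centers, scales) are this
package's own.

# Monte Carlo search

One *sweep* is L attempted single-position substitutions: a non-frozen
position chosen uniformly, a different allowed residue proposed uniformly,
accepted when $\Delta Z \le 0$ or with probability $\exp(-\Delta Z/T)$ at the
constant temperature $T = 0.03$. After each sweep the chain state is recorded
as one decoy, so 10 trajectories × 30,000 sweeps with the first 1000 decoys of
each discarded as near-random burn-in pool exactly 290,000 decoys — this
single-substitution, one-record-per-sweep move set is the only reading
consistent with that arithmetic. Trajectory seeds derive deterministically
from the master seed, so serial and parallel execution agree and reruns are
bit-identical.

The hot loop is compiled (Rcpp): predictions are maintained incrementally — a
substitution at position p only touches the window around p, and hidden-layer
pre-activations / propensity sums are updated by input deltas — with a full
refresh every 256 sweeps to bound floating-point drift. The 3-state argmax
uses a small tolerance favoring the earlier state so that exact propensity
ties (e.g. cysteine's equal strand and coil propensities) resolve identically
on the incremental and fresh paths; without it the torsion term's bookkeeping
diverges from the recorded energies. Frozen positions and per-position
excluded residues are enforced in the proposal distribution itself, so every
recorded decoy satisfies them. A pure-R reference sweep (`mc_sweep()`)
accepts arbitrary scorers (including physics-augmented ones) and doubles as a
readable specification of the kernel.

# Clustering and reports

Decoys are compared with a BLOSUM62-derived distance,
$d(a,b) = \tfrac{1}{L}\sum_j \bigl(B(a_j,a_j)+B(b_j,b_j)-2B(a_j,b_j)\bigr)/2$,
which is zero on identity, symmetric and non-negative. Clustering follows the
largest-neighbor-ball expansion used for structure decoys: the threshold
starts at 0 and grows in steps of 0.25 (the endpoints — start at zero, stop at
40% — are fixed; the step is a choice) until the primary cluster holds ≥ 40%
of the pool; clusters are then peeled off at the stopping threshold, at most
10. Pools larger than 5000 are uniformly subsampled first (seeded): the
procedure needs the all-pairs distance matrix, which is O(n²) in memory —
at the full 290,000 pool it would need tens of gigabytes, while 5000 decoys
(~200 MB) estimate the cluster structure of a Monte Carlo pool more than
adequately. The 40% stop criterion applies to the subsample.

Each cluster is represented by its lowest-Z member ("the lowest free energy"
reading of seed selection), reported in decreasing cluster-size order with:

* the **design score** — the seed's Z; lower = more confident. This preserves
  the published ordering semantics but is *uncalibrated*: the published
  absolute confidence calibration (score < 1.0 ↔ high-confidence designs)
  depends on a large benchmark that is not reproducible here.
* percent sequence identity to the scaffold;
* **NRE** (normalized relative error) per feature:
  $(EDS - ETS)/ETS$, where EDS/ETS are the feature-prediction errors of the
  design / scaffold sequence against the scaffold structure assignment
  (3-state error rate for SS, mean absolute difference for RSA, mean wrapped
  absolute difference in degrees for φ and ψ). Negative NRE means the design
  sequence out-predicts the native one; ETS = 0 leaves NRE undefined (NA),
  not infinite;
* conservation flags for ligand-binding residues — residues with any atom
  within 8 Å of a hetero atom (waters excluded; C-α distance when only C-α is
  present).

# The synthetic study conditions

Because profile construction needs a structure library, the package ships a
deterministic generator instead of depending on a curated PDB mirror:
idealized backbones built from canonical torsions (helix −62/−41, strand
−140/135, loops near −75/150, 4° jitter) in three topologies, with
topology-biased sequences. A *family* derives members from a scaffold by
per-atom Gaussian jitter and per-position mutation (uniform over the 19
alternatives), returning the generating distribution as ground truth for
profile-recovery checks. Defaults are 15 members, 0.5 Å jitter and 10%
mutation on a 40-residue helix bundle; 0.5 Å was fixed once as the noise level
that keeps family members inside the high-similarity TM-score band (> 0.7) of
the homolog-selection schedule, and the test suite and acceptance script use
these frozen conditions throughout. An antiparallel strand-pair fixture is
built by the two-fold rotation of an extended strand with registration offsets
frozen from a one-time scan of the hydrogen-bond geometry.

What the generator does *not* emulate: real side-chain packing, non-ideal
loop geometry, sequence correlations beyond per-position mutation, and
genuinely divergent homolog folds. Passing tests therefore demonstrate the
pipeline's internal correctness and its printed arithmetic, not design
accuracy on experimental structures — the published accuracy benchmarks
(external folding of designs, RMSD to target) require the full PDB library
and third-party folding programs and are out of scope at desk scale.

# Numerical choices and degenerate inputs

* Scaffolds shorter than 30 residues are rejected (no meaningful fold).
* A profile with no positional signal makes the baseline degenerate
  (zero standard deviation); this is an error advising a richer profile, not
  a silent division by zero.
* Constraints must leave at least one allowed residue per position, and at
  least one mutable position overall.
* Clustering tie-breaks: the lowest decoy index wins among equal neighbor
  counts; cluster seeds sort on (Z, sequence) so pool order never changes the
  report beyond representative ties.
* Problem sizes used by the test suite and the acceptance script: 40-residue
  scaffolds, 15–50-member families, the full 10 × 30,000-sweep simulation for
  the pool-arithmetic check, and ≤ 5000-decoy clustering — sizes at which the
  whole suite completes in a few minutes on one core while still exercising
  the full-scale decoy arithmetic.

# Known limitations

* The structural aligner and the decoy-clustering procedure are simplified
  reimplementations of the field's standard algorithms; they satisfy the
  documented contracts but are not drop-in replacements for the original
  binaries.
* The design score is an uncalibrated Z; compare designs within a run, not
  across scaffolds.
* No physics force field ships with the package — only the plug-in interface
  and the w = −2.44 combination rule.
* The neural predictor is trained on synthetic chains; for real scaffolds the
  propensity variant is the safer default unless you retrain on experimental
  features.

# A minimal run

```{r example, eval = FALSE}
fam <- make_family(family_spec(n_members = 15, mutation_rate = 0.2,
                               topology = "helix_bundle", length = 40,
                               seed = 11))
cfg <- design_config(n_traj = 2, n_sweeps = 2000, burn_in = 200, seed = 42)
job <- run_job(fam$scaffold, fam$library, cfg, verbose = FALSE)
job$reports[, c("rank", "design_score", "identity_pct", "cluster_size")]
```
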
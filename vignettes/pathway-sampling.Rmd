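---
title: "Sampling conformational transition pathways with rigidity-guided RRT*"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling conformational transition pathways with rigidity-guided RRT*}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathweaver)
```

# The model

`pathweaver` computes a sequence of intermediate conformations connecting
two experimentally determined structures of the same protein. Three modeling
commitments shape everything else:

* **Semi coarse-grained representation.** Only N, CA, C, O and Cβ atoms are
  kept (glycine has no Cβ). The carbonyl O is retained although it is not a
  chain-path atom because both the hydrogen-bond energy term and the
  rigidity analysis need it. Waters, ligands, hydrogens and non-standard
  residues are discarded at parse time.
* **Torsion-space kinematics.** The only degrees of freedom are the backbone
  dihedrals φ(i) = torsion(C(i−1), N(i), CA(i), C(i)) and
  ψ(i) = torsion(N(i), CA(i), C(i), N(i+1)), IUPAC convention, degrees.
  `set_dihedral()` rotates every atom C-terminal to the rotated bond rigidly
  about the bond axis, so bond lengths, bond angles and all other torsions
  are preserved exactly (to 1e-9 Å / degrees; the test suite asserts this).
  The N-terminus is the fixed frame — a standard choice in torsion-space
  samplers; the direction of propagation is a convention, not physics.
  Chain gaps (peptide C–N distance above 1.8 Å) act as rotation barriers so
  a disconnected segment is never torn.
* **lRMSD over CA atoms.** All distances between conformations are least
  RMSDs after optimal superposition (Kabsch, proper rotations only),
  computed over the CA atoms of *paired* residues. Pairing is by identical
  residue number where the residue type agrees, with a
  longest-common-block fallback for renumbered constructs; mutated or
  unmatched residues are excluded from both the metric and perturbation.
  CA-lRMSD is the common convention; whether a published initial RMSD used
  CA, backbone, or all heavy atoms is often unstated, which is why the
  package exposes the raw `superpose()` for users who need other subsets.

# The search

The engine is an RRT\*-style tree search hybridized with Monte-Carlo
acceptance. Per iteration: biased node selection → torsion perturbation →
bounded minimization → energy gate → MC acceptance → least-cost parenting
and rewiring → scheduled pool pruning. Parameters, defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `bias_fraction` | 1/3 | probability of expanding one of the `k_best` goal-nearest nodes |
| `k_best` | 20 | size of the "best" pool |
| `angle_diff_min` | 5° | only torsions still differing from the goal by more than this are perturbed |
| `perturb_step_max` | 10° | per-torsion step is uniform in ± this |
| `perturb_max_angles` | max(2, ⌈0.05·n⌉) | number of torsions per move, drawn uniformly in 1..max |
| `minimize_steps` | 10 | steepest-descent cap per candidate |
| `energy_k` | 5 | gate: total energy < `energy_k` · n_residues (strict) |
| `mc_a` | 0.01 | uphill acceptance scale |
| `neighbor_radius` | 1.0 Å | near-neighbor radius for parenting/rewiring (inclusive; falls back to the single nearest node) |
| `stall_limit` | 500 | stop after this many iterations without best-lRMSD improvement |
| `goal_threshold` | 0.25·initial lRMSD clamped to [1.7, 3.65] Å | stop when reached |
| `rigidity_mode` | `adaptive` | `off` / `once` / `adaptive` |
| `rigidity_recompute_drift` | 2.0 Å | best-node drift (strict >) that triggers re-analysis |
| `min_cluster_atoms` | 6 | smallest rigid cluster retained |

Points where the design was genuinely open, and what we chose:

* **Accumulated cost.** The node cost is cost(n) = g(n) + h(n) with
  h(n) = lrmsd(n, goal). For g we use the recurrence
  g(n) = g(parent(n)) + lrmsd(n, start): each hop adds the node's distance
  from the *start*. This makes g grow with both path length and progress,
  which double-counts distance-to-start relative to a true path-length
  integral; `g_mode = "edge"` switches to the conventional
  g(parent) + lrmsd(n, parent) for users who prefer edge-length costs. The
  default is kept because only cost *differences among near neighbors*
  matter for parenting/rewiring, and the two modes rank neighbors very
  similarly in practice.
* **Node selection.** The unbiased branch draws from the pool *excluding*
  the current k-best set (falling back to the whole pool when it has at
  most `k_best` members), so the expected fraction of draws hitting the
  best set is exactly `bias_fraction`. Folding the best set into the
  unbiased branch would inflate that fraction pool-size-dependently.
* **Monte-Carlo reference.** The candidate's lRMSD is compared against the
  *selected* node it was perturbed from. RRT\* may later attach the
  candidate to a different parent; acceptance logically precedes parenting.
* **Energy gate vs MC.** Candidates failing the 5·n gate after minimization
  are discarded outright (the stricter of two plausible readings of how the
  gate and the MC rule interact); the MC rule only arbitrates among
  gate-passing candidates.
* **Pruning.** Redundant pool pairs (mutual lRMSD ≤ 10 % of the smaller
  goal distance, processed in increasing goal-distance order) lose their
  farther member — but only from the *selection pool*. Tree edges are never
  severed, otherwise extracted paths could break; pruned nodes remain
  valid waypoints. Pruning fires when the pool first reaches n_residues
  members and again at each 3-fold multiple.
* **Adaptive trigger.** Rigidity is recomputed when the *best* node has
  drifted more than 2 Å (lRMSD) since the previous analysis. The newest or
  the selected node would also be defensible triggers; the best node is the
  one whose neighborhood the biased selection keeps expanding, so its
  rigidity is the most relevant.
* **Stall accounting.** Iterations that produce no accepted node (no
  eligible angles, gate failure, MC rejection) still count toward the
  500-iteration stall limit — stalling is about wall progress, not
  acceptance bookkeeping.

# The energy function

The composite potential is
E_total = E_HB + E_burial + E_water + E_bond + E_angle + E_VdW, in nominal
kcal/mol. Its only consumer is the strict gate E_total < 5·n_residues, so
relative scale is what matters. E_bond = Σ k_b (r − r₀)² and
E_angle = Σ k_θ (θ − θ₀)² are harmonic with AMBER-magnitude force constants
reduced to the five retained atom classes. E_VdW is a Lennard-Jones sum
over nonbonded pairs (bond-path separation ≥ 3) with the repulsive branch
clamped at its value at 0.8·r_min — the "soft collision" tolerance a
reduced representation needs — which also guarantees a finite energy for
any coordinates, including coincident atoms. A 10 Å cutoff truncates the
sum; the discontinuity (< 1e-3 kcal/mol per pair) is irrelevant at gate
scale.

The three knowledge-based terms are deliberately simple, documented forms
behind one parameter list (`default_energy_params()`), chosen so the search
has a finite, clash-penalizing, rotation-invariant potential with these
named components — not a literature-faithful statistical potential:

* **E_HB**: −1 kcal/mol per geometric backbone hydrogen bond
  (O(i)···N(j), |i−j| ≥ 3, 2.5–3.5 Å, CA–O···N angle > 90°; a square well
  in distance and angle).
* **E_burial**: a hydrophobicity-weighted sigmoid of each residue's Cβ
  contact count (contacts within 7.5 Å, half-saturation at 4).
* **E_water**: −0.05 kcal/mol per Cβ–Cβ pair in the 6.5–9.5 Å
  water-mediated shell.

Minimization is plain steepest descent on E_bond + E_angle + E_VdW only
(the terms that report clashes and deformities): initial step 0.01 Å along
the normalized negative gradient, halved on energy increase, the step
rejected — ending the descent — after 5 halvings, at most 10 steps. The
descent runs in Cartesian space; the dihedral cache is recomputed
afterwards. No step-size rule is canonical here; this one is monotone by
construction and cheap, and the cap matters more than the schedule.

Equilibrium bond lengths and angles are taken from the same ideal-geometry
table the fixture builder uses (with the two geometrically implied angles,
O–C–N and Cβ–CA–C, derived from the placement geometry in closed form), so
a freshly built fixture scores exactly zero bonded energy — a deliberate
self-consistency that the tests assert.

# Rigidity analysis

The analysis is a (6,6) body-bar pebble game on a constraint multigraph:
every atom is a 6-DOF body; each bar removes one relative DOF. Bar
multiplicities follow the standard molecular body-bar convention:

| interaction | bars |
|---|---|
| rotatable covalent bond (N–CA, CA–C) | 5 |
| locked covalent bond (peptide C–N, C=O, CA–Cβ) | 6 |
| hydrogen bond (geometric criterion as in E_HB, no lower distance bound) | 5 |
| hydrophobic contact (Cβ–Cβ < 6 Å, both residues in {A,V,L,I,M,F,W,P}, sequence separation ≥ 2) | 2 |

CA–Cβ deserves a note: chemically it is a rotatable single bond, but Cβ is
a terminal body in this representation, and "spinning" a terminal atom
about its own bond axis is not a structural degree of freedom. Leaving it
at 5 bars would strand every Cβ outside every rigid cluster and mark every
non-glycine residue flexible, destroying the hinge-vs-domain signal; we
therefore lock it, as molecular rigidity packages do for bonds to terminal
atoms.

A bar is independent iff 7 pebbles can be gathered on its endpoints; after
all bars are processed, maximal rigid clusters are the transitive closure
of pairwise mutual rigidity over adjacent bodies (a pair is mutually rigid
iff 7 pebbles cannot be gathered on it). The decomposition is independent
of edge insertion order, and on small graphs it is checked in the test
suite against an independent oracle: the numeric rank of a generic body-bar
rigidity matrix.

Residues with at least one atom outside every retained cluster (clusters
below `min_cluster_atoms = 6` atoms are disregarded as noise; 6, 7 and 8
are all reasonable) form the flexible set that perturbation is restricted
to. Two loud caveats: the analysis runs on the *coarse-grained* model, not
on an all-atom structure with hydrogens, so cluster boundaries will not
match an all-atom rigidity server's output — only the qualitative hinge
placement; and users with better information can bypass the analysis
entirely with a flexible-residue list file (`read_flexible_list()`), which
is then used verbatim and never recomputed.

# Synthetic fixtures and what they do (not) show

`build_peptide()` places atoms sequentially (NeRF) with ideal bond lengths
and angles and exact requested torsions; `make_transition_pair()` applies
hinge torsion offsets to produce a goal conformation whose true flexible
residues are known *by construction*. `two_domain_fixture()` is the
canonical study system: 20 residues, two hydrophobic α-helices (ϕ/ψ =
−57°/−47°, LEU/ALA so the helix cores carry hydrophobic contacts) joined
by a 3-residue extended serine/glycine hinge, with the transition opening
the hinge ψ angles by ±40°.

By default the goal also carries two 8° ψ *decoys* inside the helix cores
(residues 4 and 16). Rationale: with a hinge-pure pair, the 5°
angle-difference filter alone already isolates the hinge, and rigidity
guidance would have nothing left to contribute — which is not how real
structure pairs behave. Real pairs differ by small uncorrelated torsion
deviations everywhere; the decoys emulate exactly that, and they are what
makes the guided-vs-unguided comparison meaningful: the unguided search
spends moves on eligible decoy angles inside rigid cores (large Cartesian
swings, mostly MC-rejected), while the guided search is confined to the
hinge. With the hinge fixed and decoys untouched, the remaining lRMSD
floor of the default fixture is ≈ 0.3 Å, so the study runs use a 1.0 Å
goal threshold — reachable by hinge-only moves with margin. The comparison
in the acceptance suite uses 10 seeds per mode, up to 4000 iterations per
run, and compares median iterations-to-convergence; the acceptance script
recomputes the same quantities for any seed.

What the fixtures deliberately do **not** emulate: side chains beyond Cβ
(no packing, no χ angles), loop irregularity, crystallographic noise in
bond geometry, solvent, and any energetic trap along the transition. A
passing suite therefore demonstrates the correctness of the machinery —
kinematics, rigidity, gating, tree optimality bookkeeping — and the
qualitative value of rigidity guidance, not predictive accuracy on real
transitions. On real proteins the published initial lRMSDs (e.g. ~14.8 Å
for the calmodulin open/closed pair, 7.14 Å for adenylate kinase) and
convergence behavior can be checked with the same code paths by supplying
the PDB files; no coordinate data ships with the package.

# Numerical choices

* Superposition uses SVD with a determinant correction (proper rotations
  only); the RMSD is computed from the explicit residual rather than the
  closed-form trace, which suffers catastrophic cancellation near zero.
  Collinear point sets get whatever optimal rotation the SVD yields.
* Torsions are stored in degrees in (−180, 180]; circular differences are
  folded into [0, 180]. Setting a torsion to its current value is an exact
  identity (no rotation applied).
* The Lennard-Jones clamp makes the gradient exactly zero inside
  0.8·r_min, so overlapping atoms produce a finite energy and a
  well-defined (if uninformative) descent direction from the other terms.
* Tie-breaks: `choose_parent` resolves equal prospective costs by smaller
  candidate-to-neighbor lRMSD, then insertion order. The pebble game's
  cluster set is insertion-order invariant, so no tie-break is needed
  there.
* Degenerate inputs: empty chains, structures with fewer than 3 paired
  residues, torsions undefined at termini or across chain gaps, and
  zero-length paths all raise immediate, typed errors; the
  `pw_no_eligible_angles` condition is part of the API so callers can
  count stalled iterations.
* Problem sizes: the test and acceptance workloads use 8–20-residue
  fixtures (up to ~100 atoms, trees of a few hundred nodes), where a full
  guided run takes seconds and the 20-run scenario comparison a few
  minutes. The pebble game is quadratic-ish in atoms per analysis and the
  engine re-measures lRMSD against the whole pool per insertion, so
  multi-hundred-residue proteins are minutes-per-run workloads, not
  seconds.

# Known limitations

* The cost recurrence (`g_mode = "paper"`) is not a path-length metric;
  see above.
* Rigidity on the coarse model under-constrains side-chain-mediated
  stiffness (only Cβ–Cβ contacts represent it) and over-frees polar
  residues' side chains; hinge placement is qualitative.
* The knowledge-based energy terms are stand-in forms; absolute energies
  are meaningless outside the 5·n gate.
* The pebble-game implementation targets coarse models (hundreds of
  bodies); it is not an all-atom rigidity engine.
* Pathways are sequences of gate-passing conformations, not dynamics: no
  kinetics, no barrier heights, no ensemble weights.
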
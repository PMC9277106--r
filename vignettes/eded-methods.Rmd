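---
title: "Essential dynamics ensemble docking: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essential dynamics ensemble docking: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ededock)
```

## The problem

Docking a compound library against a single receptor structure assumes
that one conformation represents the binding-competent state. For
flexible targets — GPCRs in particular — that assumption fails twice
over: the deposited structures may represent the wrong signaling state
(agonist-bound/active where an antagonist program needs inactive), and
even the right state is an ensemble of pocket geometries, not a point.
Ensemble docking addresses this by docking against several receptor
models, but two design questions then dominate the outcome: *which*
conformations to pick from an MD trajectory, and *how* to combine the
per-conformation scores into one number per compound.

`ededock` answers the first with dimensionality reduction restricted to
the binding pocket (clustering on global backbone RMSD is easily
dominated by floppy loops that are irrelevant to ligand binding) and
the second with a Boltzmann-weighted partition ratio rather than an
average.

## Conformation selection

### Pocket definition

A residue belongs to the pocket iff the minimum Euclidean distance
between its side-chain heavy atoms and any ligand heavy atom in the
static reference complex is at most `cutoff` (default 3 Å). Choices
behind that sentence:

- **Heavy atoms only.** "Side chain within 3 Å" in a modeling context
  conventionally excludes hydrogens, whose presence depends on the
  protonation pipeline; hydrogens are retained on read but excluded
  from every distance and center-of-mass computation.
- **Glycine** has no side-chain heavy atoms; its Cα substitutes, so a
  tight glycine contact is not silently unselectable. A message is
  emitted when this rule fires.
- **No periodic imaging.** Distances are plain Euclidean; input frames
  are assumed whole. This is documented rather than handled because
  imaging policy belongs to the trajectory-preparation stage.

The rule is monotone in the cutoff (a tested invariant), and the
implementation is checked against an exhaustive all-pairs distance scan
on constructible fixtures whose minimum contact distances are exact by
design, including 2.9-Å-in / 3.1-Å-out boundary cases.

### Superposition and features

Every frame is superposed onto the reference by the Kabsch algorithm
(SVD of the cross-covariance, with the determinant correction against
improper rotations) over Cα atoms of a configurable residue range —
for a GPCR, the 7TM core in author numbering; by default, all shared
protein Cα atoms. The reference never moves: it defines the laboratory
frame, and the per-frame transform is applied to all atoms. The
alignment atom subset is a convention choice (the field aligns on Cα
when nothing else is specified); the tests cross-check the resulting
RMSD against an independent quaternion (Horn) superposition at 1e-8 Å.

The feature vector of a frame is the concatenation of the m pocket
residues' mass-weighted center-of-mass coordinates after superposition
(3m columns, Å). Whole-residue COM over heavy atoms is the default;
side-chain-only COM is available as `com_mode = "sidechain"` because
the selection rule is side-chain-based and one can argue the features
should be too. Whole-residue is the default because it is the literal
reading of "center of mass of the residue" and is less sensitive to
side-chain flips that do not change the pocket envelope. Featurization
is rigid-motion invariant by construction (the superposition undoes
any per-frame rigid transform exactly, up to floating point; tested at
1e-6 Å).

### PCA

PCA operates on the covariance of the mean-centered features — never
the correlation matrix, since all columns share Å units and rescaling
would inflate low-amplitude directions. Eigenvalues use the unbiased
F−1 denominator (this rescales all eigenvalues uniformly and changes
neither directions nor variance fractions). The retained count is the
smallest k whose cumulative variance fraction reaches
`variance_threshold` (default 0.90), then capped at `max_pcs` (default
15). Both knobs exist because a fixed "first fifteen PCs at 90%" rule
conflates two stopping criteria; exposing both lets either bind.
Numerical conventions: components are sign-fixed so each one's
largest-magnitude entry is positive (eigen-solvers are sign-ambiguous;
output must be deterministic), and a zero-total-variance matrix (all
frames identical) is a named error rather than NaN propagation.

### Clustering and state thermodynamics

K-means with squared-Euclidean distance runs in retained-PC space:
k-means++-style seeding, Lloyd iterations, best of `restarts` (default
10) runs by total within-cluster sum of squares. k is a user parameter
(default 4); an inertia-vs-k elbow table is written by the pipeline to
support choosing k by inspection, but no automatic selection is
attempted — the knee of that curve is a judgment call that should stay
visible. Labels are renumbered by descending population, so cluster 0
is the most populated state and the free-energy reference. Runs that
leave an empty cluster are discarded and retried within the restart
budget; exhausting it is a named error. Given (data, k, seed,
restarts) the result is fully deterministic.

Relative conformational free energies come from cluster occupancies:

    dG_conf(1,i) = -ln(N_i / N_1)   [kT]

with N_1 the largest cluster. This is the standard occupancy estimator
and the central interpretive decision of the selection stage; it is
overridable by a user-supplied vector (e.g. from a better free-energy
estimate), and `mode = "equal"` sets all values to zero for the
equal-weighting limit. On synthetic four-state trajectories the
estimator recovers −ln(p_i/p_1) within 0.1 kT at 5000 frames (tested).

Each state's representative is the member frame minimizing Euclidean
distance to the cluster center in retained-PC space, ties broken to the
lowest frame index. PC-space distance equals RMSD between the
corresponding back-projected pocket geometries up to a constant factor,
so this is the "closest frame by RMSD" rule in the cheaper space; a
`metric = "cartesian"` switch measures instead against the
back-projected center in feature space for users who want the literal
reading. The search is restricted to cluster members so every state is
guaranteed a valid exemplar.

## Score aggregation

For one compound with docking scores ΔG_bind(i) (kcal/mol) against the
k representatives:

    Ensemble dG_bind = kT * ln( sum_i e^(-dG_conf(1,i))
                              / sum_i e^(-dG_conf(1,i) - dG_bind(i)/kT) )

the log of the unbound over bound partition sums. Unit conventions
matter here: dG_conf is carried in kT (its exponent takes no /kT),
docking scores in kcal/mol (converted through kT = R·T with
R = 0.0019872041 kcal/(mol·K), T = 300 K by default, kT = 0.59616
kcal/mol). Both partitions are evaluated with max-shifted log-sum-exp,
which the tests exercise to ±50 kcal/mol scores and 500 kT
conformational energies without overflow.

Properties the implementation guarantees (all tested against a
brute-force partition-sum oracle):

- the score always lies between the best and worst per-conformation
  scores, and strictly improves when any single conformation's score
  improves;
- a state 20 kT above the reference shifts the score by less than
  1e-6 kcal/mol even if the compound docks to it as well as to the best
  state — rare states cannot dominate, which is the argument for this
  aggregation over plain averaging;
- with all dG_conf = 0 it reduces to the equal-weighting form
  kT·ln(n / Σ e^(−ΔG_bind(i)/kT)), and with n = 1 to the raw score.

**Missing poses.** A compound that fails to dock against conformation i
has no ΔG_bind(i). Its term is omitted from the bound partition —
equivalent to ΔG_bind(i) → +∞, i.e. treating a docking failure as
evidence of non-binding to that state — while the conformation stays in
the unbound partition. The result is flagged (`missing_pose`), and a
compound with no poses at all is an error, not a score. The alternative
(imputing a penalty score) was rejected as it invents a number where
the evidence is an absence.

**Triage and evaluation.** Predicted actives are compounds scoring at
or below `triage_cutoff` (default −9 kcal/mol; the boundary is
inclusive since more negative is better and the cutoff should admit
itself). Evaluation against activity classes (default: strong and
medium count as active) produces confusion counts, accuracy, FNR and
FPR, with empty-denominator rates reported as `NA` — an undefined rate
is information, zero is misinformation.

## The synthetic generator

`make_multistate_system()` builds a receptor whose m pocket residues
(default 12) surround a small ligand with their side chains in contact
range, plus a fixed outer scaffold ring for superposition. k metastable
states (default 4, populations 0.5/0.3/0.15/0.05) differ by displacing
one pocket residue's center of mass outward by `separation × sigma`
(default 25 σ, σ = 0.25 Å), so states are well separated in feature
space relative to the within-state fluctuation. Frame states are drawn
i.i.d. from the populations; residues are rigid templates re-posed
around their noisy centers of mass, which makes the generative feature
vector of every frame exact. Optional per-frame random rigid transforms
(`rigid_jitter`) must be undone by the superposition stage, turning the
generator into an oracle for featurization invariance. Score tables add
Gaussian noise (default 0.25 kcal/mol) and optional missing poses to
per-state true affinities, with the true ensemble scores returned as
ground truth.

What the generator deliberately does *not* emulate: temporally
correlated dynamics (frames are i.i.d., so nothing here validates
convergence or statistical-inefficiency handling on real MD),
anisotropic or state-dependent fluctuations, side-chain rotamer
structure within a residue, backbone connectivity constraints, and any
force-field realism. Tests passing on these fixtures certify the
pipeline's algebra and determinism — selection geometry, PCA, cluster
thermodynamics, score aggregation — not the adequacy of 500 ns of
sampling or of docking scores as binding free energies.

Default problem sizes in the test suite and acceptance script (5000
frames for state-recovery checks, 200 frames for invariance checks,
1000–2000 frames and 200 compounds for end-to-end runs) were chosen as
the smallest sizes at which the statistical assertions have comfortable
margins; the generator scales to larger F if sharper checks are wanted.

## Degenerate inputs and failure modes

Every contract violation raises a classed condition
(`ededock_<name>`): unparseable files, ligand name matching nothing,
empty pockets (with the advice to widen the cutoff), topology/frame
atom-count mismatches, fewer than 3 alignment atoms, zero feature
variance, k exceeding the frame count, empty clusters after all
restarts, zero populations, non-zero reference dG_conf, all-missing
score rows, unlabeled compounds. Pipeline stages wrap their errors with
the stage name so a failed run points at the failing step. Alternate
locations in PDB input keep the first altloc and warn; atom order is
never permuted by any I/O path.

## Limitations

- dG_conf from occupancies inherits all sampling error of the
  trajectory; 500 ns-scale GPCR simulations rarely converge state
  populations, which is why the vector is overridable and the
  equal-weighting mode exists.
- The pocket is defined once, on the static reference; residues that
  move into contact only in some states are not re-selected per state.
- Binary trajectory support covers reading CHARMM/NAMD DCD; XTC and
  mmCIF are out of scope, as is any bond/topology perception beyond
  residue and atom-name rules.
- The ensemble score interprets docking scores as binding free
  energies. They are not; the score is a ranking device for triage,
  and cross-compound comparisons inherit every bias of the docking
  engine that produced the inputs.
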
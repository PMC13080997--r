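---
title: "Methods: allosteric network analysis with allokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: allosteric network analysis with allokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokin)
```

## Scope and model

`allokin` analyses equilibrium molecular-dynamics (MD) trajectories of a
protein — it was developed around the motor domain of human kinesin-5 and its
catalytic cycle (ATP-bound, ADP-bound, apo, and inhibitor-bound states) — and
asks where allosteric communication runs and how it changes between states.
It does not run MD: trajectories come from outside (or from the package's
own synthetic generators), and everything downstream is a functional of the
sampled coordinate distribution.

Four analyses are provided.

### Distance fluctuation (DF)

For residues $i$ and $j$ with per-frame C$\alpha$ distance $d_{ij}$,

$$DF_{ij} = \left\langle \left(d_{ij} - \langle d_{ij}\rangle\right)^2
\right\rangle ,$$

the variance of the inter-residue distance over the trajectory (Å$^2$).
Distances are invariant to rigid-body motion, so no superposition is
performed — the trajectory is only stripped to one atom per residue. A low
$DF_{ij}$ means the pair moves in a coordinated way. State-to-state changes
are summarised by $\Delta DF = DF^{\text{end}} - DF^{\text{start}}$ along
the transitions of the catalytic cycle; positive entries mean the pair
*lost* coordination during the transition.

Two estimator choices are explicit parameters:

* **Variance normalisation.** The default divides by $F$ (population
  variance), matching the expectation form of the definition; `estimator =
  "sample"` divides by $F-1$.
* **Replica handling.** Independent MD replicas concatenated into a
  metatrajectory can be pooled (`replica_mode = "pooled"`, the default) or
  averaged per replica (`"per_replica_mean"`). By the law of total variance
  the pooled value equals the per-replica mean plus a non-negative
  between-replica term, so pooled $\ge$ per-replica mean entrywise; both
  modes are exposed because published analyses are often ambiguous about
  which they used. The difference between the two is itself informative:
  it isolates between-replica drift in mean geometry.

### Shortest path map (SPM)

Displacement correlations are computed relative to a reference structure:

$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle \Delta r_i^2\rangle\,\langle \Delta r_j^2\rangle}},$$

where $\Delta r_i$ is the displacement of C$\alpha_i$ from its position in
the most representative frame, after superposing every frame onto that
reference. The reference is derived by superposing the trajectory on
C$\alpha$ atoms, hierarchically clustering frames on pairwise RMSD
(default cut height 2 Å), and taking the centroid of the most populated
cluster — the member frame minimising summed RMSD to the other members.

Residues become graph nodes; an edge joins $i$ and $j$ only when their mean
C$\alpha$ distance $\langle d_{ij}\rangle$ stays below a 6 Å cutoff, with
length

$$l_{ij} = -\log |C_{ij}|.$$

Strong correlation *or* anticorrelation gives short edges (coupling is
coupling, whatever its sign); $C_{ij}=0$ pairs carry no information and get
no edge (their length would be infinite). One shortest path is traced for
every residue pair in the same connected component, and edges used by at
least `keep_frac` (default 20%) of the maximum edge usage form the final
map.

Numerical choices, all documented in the function help:

* **Logarithm base**: natural log. Path ranking is invariant to the base
  (a uniform rescaling of all edge lengths), which the test suite asserts;
  only the reported lengths change.
* **Tie-break**: when several shortest paths tie, the lexicographically
  smallest node sequence wins. Ties are measure-zero for sampled
  correlations, but a deterministic rule makes results reproducible and
  lets the implementation be checked *exactly* against an independent
  Floyd–Warshall oracle.
* **Rigid residues** (zero mean-square displacement, possible in synthetic
  scaffolds): flagged and isolated as degree-0 nodes rather than erroring.
* **Retention threshold**: the map threshold is inherently a display
  choice; 20% of the maximum usage gives a sparse backbone-like map on
  typical inputs and is exposed as a parameter.

### Loop-conformation clustering

A four-step protocol separates positional regimes of a flexible loop
carried by a helix (loop 5 of kinesin-5, Glu116–Gly134, interrupting helix
$\alpha$2):

1. strip to backbone, align to the first frame's backbone;
2. align on residues stably assigned helix/strand (the shared rigid frame
   across all analysed states) and compute the average structure;
3. fit each frame to the helix anchor flanking the loop (default residues
   111–116 and 135–140) of that average, and keep only the loop backbone
   (residues 111–140);
4. agglomerate frames hierarchically on pairwise RMSD and cut the
   dendrogram at $\varepsilon = 5$ Å.

The step-4 RMSD is deliberately computed *without* per-pair re-fitting:
after the anchor fit, frames share a frame of reference, so a docked and an
undocked loop position are distinguished even when their internal shapes
match. Average linkage is the default (single and complete are available);
$\varepsilon$ is interpreted as the height at which merging stops — the
smallest inter-cluster linkage distance exceeds $\varepsilon$. Cluster
representatives are member frames minimising summed within-cluster RMSD.

Secondary structure for step 2 is assigned by a backbone-dihedral
classifier (helix: $\phi \in (-100,-30)$, $\psi \in (-80,-5)$; strand:
$\phi \in (-180,-40)$, $\psi > 90$ or $\psi < -170$; terminal residues are
coil), with a residue counted "stable" when structured in at least 75% of
frames of *every* input trajectory. Both the regions and the fraction are
parameters.

### Interaction metrics

Per-frame geometric criteria, each reported as a time series plus an
occupancy (fraction of frames satisfying the criterion):

| metric | criterion | defaults |
|---|---|---|
| $\pi$-stacking | ring-centroid distance and acute inter-plane angle | $\le$ 5.5 Å, $\le$ 30° |
| salt bridge | minimum heavy-atom cross distance | $\le$ 4.0 Å |
| hydrogen bond | D$\cdots$A distance and D–H$\cdots$A angle | $\le$ 3.5 Å, $\ge$ 135° |

The thresholds are conventional values for face-to-face stacking, contact
ion pairs and moderate hydrogen bonds; every one is a parameter recorded in
the output, because reasonable alternatives exist for all three. Ring
planes come from the SVD of the centred ring atoms; frames whose ring
geometry degenerates to a line are flagged and excluded from the occupancy
denominator rather than guessed at.

Radial distribution functions are normalised by shell volume and by the
mean target density inside the analysis sphere of radius $r_{max}$, so a
homogeneous gas gives $g(r) = 1$ and the binwise identity
$\sum_b g_b \, \rho \, V_b$ = (mean pairs within $r_{max}$ per reference)
holds exactly. Occupancy densities are per-voxel fractions of frames with at
least one selected atom in the voxel; two densities are compared with the
min/max overlap $\sum_v \min(a_v,b_v) / \sum_v \max(a_v,b_v)$, a
Jaccard-style score chosen because it is bounded, symmetric, and exactly
computable on constructed cases (identical densities give 1, disjoint give
0, the half-shared three-voxel case gives 1/3).

## Synthetic data: what it emulates, what it does not

Microsecond MD of a ~370-residue motor domain is far beyond a test suite,
so validation rests on generators whose statistics are known exactly.

**Gaussian fluctuations** (`make_harmonic_trajectory()`): frames are
independent draws $x = \mu + \epsilon$, $\epsilon \sim N(0, \Sigma)$, with
$\Sigma$ specified per residue, as a shared per-axis covariance, or as a
full $3N \times 3N$ matrix. The exact correlation matrix follows from
$\Sigma$ (`ground_truth_correlation()`), and in the collinear,
well-separated limit the DF matrix has the closed form
$DF_{ij} = \sigma_i^2 + \sigma_j^2 - 2\,\mathrm{cov}_{ij}$
(`collinear_df_closed_form()`); the package's estimators are tested for
convergence to both.

**Two-state loop** (`make_two_state_trajectory()`): each frame's loop
conformation is drawn from $\{A, B\}$ with fixed probabilities plus
isotropic within-state noise, on a near-rigid scaffold. The generator
returns the frame labels, making clustering recovery measurable. The
standard test condition — loop A–B RMSD 8 Å, noise 0.5 Å, $p_A = 0.6$,
5000 frames, $\varepsilon = 5$ Å — represents a clearly two-state loop
with realistic within-state breadth, and mirrors the population-imbalanced
regimes reported for kinesin-5 loop 5 (a ~60%-dominant conformation);
specifications whose noise exceeds half the A–B separation are flagged as
overlapping rather than rejected.

Frames are i.i.d. by default. DF, correlation and SPM are functionals of
the marginal displacement distribution only, so autocorrelation would
change convergence rates, not expectations; an optional AR(1) coefficient
is available (preserving the stationary covariance) for studies of error
bars. Replicas are seeded as `seed + replica - 1`, mirroring independently
seeded MD runs.

What the generators deliberately do **not** model: anharmonicity and
multi-basin backbone dynamics outside the designated loop, solvent and
ligand degrees of freedom, temporal correlation (by default), and periodic
boundary artifacts (trajectories are assumed pre-imaged; a validation pass
errors on frame-to-frame C$\alpha$ jumps above 20 Å instead of silently
unwrapping, since unwrapping conventions are engine-specific). Passing
tests therefore demonstrate estimator correctness and protocol behaviour
under known statistics — not that any particular biological conclusion
holds for real trajectories.

## Problem sizes used in validation

The shipped validation suite runs entirely on synthetic data: 20,000-frame
trajectories at 10–50 residues for the DF and correlation convergence
checks (chosen so Monte-Carlo error sits well inside the 5% / 0.05
acceptance bands), 200 rigid-transform frames at 100 residues for the
invariance check, 20 random graphs of up to 12 nodes against the exact
shortest-path oracle, 5000-frame two-state runs (20 seeds) for clustering
recovery, and a 2 × 10$^6$-sample homogeneous gas for the RDF flatness
check. These sizes are the package's own validation choices and scale
linearly in frames for all estimators.

## Numerical and degenerate-input policy

* Superposition uses the closed-form least-squares (Kabsch, SVD,
  reflection-corrected) rotation; it is validated against an independent
  reference implementation to 10$^{-9}$ Å and needs at least three fit
  atoms.
* Cross-structure RMSD pairs atoms by residue sequence number plus atom
  name over residues resolved in both structures, chain-agnostic, so
  crystal chains with different gaps compare directly; no common atoms is
  an error, not a zero.
* Alternate locations resolve to the highest-occupancy copy;
  insertion-coded residues are excluded from numeric range selections
  (their numbering is ambiguous); waters and heteroatoms are kept but
  flagged.
* Variances are clamped at zero against floating-point cancellation;
  correlations are clamped to $[-1, 1]$.
* Population fractions always sum to 1 and every frame is labelled;
  clustering a single repeated conformation yields one cluster of
  population 1.

## Known limitations

* Trajectory formats: multi-model PDB, DCD and Amber NetCDF. GROMACS
  XTC/TRR are not read; convert upstream.
* The dihedral secondary-structure classifier ignores hydrogen-bond
  topology; it is deliberately simple, and the stable-SS selection can
  always be supplied explicitly instead.
* One shortest path is counted per residue pair; co-optimal path ensembles
  and betweenness variants are out of scope.
* Regions (loops, switches, pockets) are user-declared selections; the
  package does not detect them from structure.
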
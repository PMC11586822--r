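---
title: "Predicting nanocluster-protein interaction sites with nanodock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting nanocluster-protein interaction sites with nanodock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Ligand-protected metal nanoclusters — atomically precise particles with a
~1–3 nm metallic core wrapped in a thiolate monolayer — bind proteins at
preferred surface sites, and which site they pick governs everything from
biosensing performance to protein-corona toxicology. Crystal structures of
such hybrid complexes are rare, and molecular-dynamics exploration of all
candidate sites is far too expensive to run routinely. `nanodock`
implements a four-stage pipeline that proposes ranked candidate binding
sites from the two partners' structures alone:

1. **Featurization.** The protein becomes a residue graph; the cluster
   becomes a global descriptor vector plus one local descriptor vector per
   protecting ligand.
2. **Interaction prediction.** An ensemble of small feed-forward networks
   predicts the Coulomb and van-der-Waals contribution of every
   ligand-residue pair; predictions are rescaled into interaction
   strengths $\varphi$.
3. **Placement.** Metropolis simulated annealing moves the rigid cluster
   over the protein surface, minimizing a loss that combines contact
   geometry with $-k\sum\varphi$; the final centres of mass from many
   independent runs are clustered to rank sites.
4. **Refinement.** Restricted all-atom annealing resolves clashes around
   each chosen site.

A synthetic-complex generator with a closed-form pairwise energy oracle
replaces the molecular-dynamics training data that the approach would use
in production, making the whole pipeline trainable and testable on a desk.

# Protein representation

Residues are nodes, positioned at their C$\alpha$ atoms; two nodes share
an (unweighted) edge when their C$\alpha$ atoms lie within 4.5 Å. Each
node carries 39 attributes:

| block | dim | content |
|---|---|---|
| element counts | 4 | heavy-atom C, N, O, S counts of the residue |
| molecular mass | 1 | average residue mass (Da) |
| amino-acid type | 5 | one-hot over hydrophobic / polar / positive / negative / special |
| hydrophobicity | 5 | five published scales (Kyte-Doolittle, Hopp-Woods, Eisenberg, Janin, Engelman) |
| secondary structure | 8 | one-hot over the 8 DSSP classes |
| exposure | 4 | relative ASA, SASA (1.4 Å probe), accessible shell, main pocketness |
| pocketness clusters | 5 | banded ray-probe buriedness |
| R_inacc | 1 | minimum inaccessible radius |
| OPD chirality | 2 | Osipov-Pickup-Dunmur index over 5 and 7 nearest neighbours |
| curvature | 2 | Ollivier-Ricci and Forman-Ricci node curvature |
| graph shape | 2 | box-counting dimension (global, broadcast) and GNM mobility |

Surface and secondary-structure features are *pluggable providers*: in
`"external"` mode they are read from an annotation CSV produced by
whatever third-party tool the user trusts (DSSP, Ghecom, FreeSASA); in
`"internal"` mode the package computes stand-ins from geometry alone — a
Shrake–Rupley SASA with a 1.4 Å probe, a P-SEA-style C$\alpha$-distance
secondary-structure assignment (which only populates the H/E/T/C classes
of the 8-class one-hot), and ray-probe buriedness measures (26 directions,
1 Å marching, 2 Å clash radius, 10 Å horizon). The contract is the
*meaning* of each feature, not bit-compatibility with any external binary.
The hydrophobicity table is data, not code, and can be swapped via
`default_feature_registry()`.

Node attributes are then expanded with a continuous Weisfeiler–Lehman
scheme: each update replaces a node's vector by the average of itself and
the mean of its neighbours,
$a^{i+1}(v) = \tfrac12\bigl[a^i(v) + \tfrac{1}{\deg v}\sum_{u \in N(v)}
a^i(u)\bigr],$
and the final representation concatenates the raw attributes with every
update. Two updates (the default) give $39 \times 3 = 117$ entries per
node: each node sees its two-hop neighbourhood. Isolated nodes use a zero
neighbour term, so their attributes halve per update — a declared
convention for a degenerate input that real chains do not produce.

## Numerical notes on the graph descriptors

* **Ollivier–Ricci.** Edge curvature $1 - W_1(\mu_u, \mu_v)/d(u,v)$ with
  $\mu_x$ uniform on the neighbours of $x$ and hop-distance ground metric;
  the 1-Wasserstein distance is solved exactly as a transportation linear
  program (simplex method). Node value = mean over incident edges; values
  lie in $[-1, 1]$ on unit-weight graphs.
* **Forman–Ricci.** Unweighted combinatorial form $4 - \deg u - \deg v$
  per edge, averaged per node.
* **Box-counting dimension.** Greedy covering of the graph by
  shortest-path balls of radius $r = 1\ldots$ diameter; dimension = minus
  the log–log slope. The greedy cover uses a fixed most-covering-first
  tie-break; the quantity is a graph-level scalar broadcast to all nodes.
* **GNM mobility.** Diagonal of the Moore–Penrose pseudoinverse of the
  contact-graph Laplacian, min-max scaled per protein — a mean-square
  fluctuation proxy that depends only on the graph and is therefore
  rigid-motion invariant.
* **OPD chirality.** A rotation-invariant, reflection-antisymmetric
  quadruple sum over the residue's C$\alpha$ and its $k$ nearest
  C$\alpha$ neighbours; evaluated at the coarse-grained (C$\alpha$-only)
  level.

# Cluster representation

Nine global descriptors: heavy-atom fraction, gold fraction, sulfur per
ligand, the radius/area/volume ratios of centroid-centred bounding spheres
of the gold vs. carbon subsets, and the three sorted principal moments of
inertia normalised to sum to one (all ⅓ for a sphere; one near zero for a
rod). Only ratios and normalised quantities enter, so the simple
centroid-centred bounding sphere (radius = maximal centroid distance) is
used rather than a true minimal enclosing sphere.

Per ligand, seven (eight when bridge-site ligands exist) descriptors:
minimum head-centroid distance to a neighbouring head, minimum
ring-centre distance, a π–π stacking flag, the mean minimum inaccessible
radius over the ligand's atoms and over its oxygens, and a one-hot of the
ligand's position on its protecting unit (middle/end, plus bridge only
when present — a constant class would carry no information). The π–π
criterion is geometric and configurable: ring centres within 5.0 Å and
ring normals within 30° of parallel; the flag is symmetric by
construction. Undefined neighbour distances (single-ligand clusters) use
a 999 Å sentinel that input min-max scaling later confines.

A ligand-residue *pair feature vector* concatenates
`[global(9); ligand(7|8); node WL(117)]` — 133 entries with the defaults.
Pair features are pose-independent, so the full ligand × residue table is
computed once per protein-cluster combination.

# The interaction model

Five feed-forward regressors (hidden layers 128, 64, 32, ReLU, linear
2-output head) are trained with Adam (learning rate $10^{-3}$, batches of
32 configurations, 150 epochs) on five distinct 80% folds of the
configurations; prediction averages the folds. Supervision is deliberately
weak: only the *configuration-level* sum of Coulomb and van-der-Waals
energies is known, so the loss is the mean absolute error between
$\sum_{\text{pairs}} (\hat e_{\mathrm{coul}} + \hat e_{\mathrm{vdw}})$
over the pairs formed within 10 Å and the configuration label. The
network must discover the per-pair decomposition on its own — the central
learnability property the package tests.

Numerical choices that matter:

* Inputs are min-max scaled to $[0,1]$ on the training set; constant
  features map to 0 with a warning.
* Outputs are scaled into $[-1,1]$ by a **single zero-preserving max-abs
  factor shared by both channels**. Two facts force this: an affine
  intercept cannot be inverted through a sum over a *variable* number of
  pairs, and with sum-only supervision the Coulomb/vdW split of a pair
  output is not identified, so per-channel factors would corrupt the
  inverted sum. Consequently individual channel values are not
  interpretable — only their sum is.
* The output layer starts near zero so that configuration sums begin on
  the scale of the labels rather than the pair count.
* Training stops at the fixed 150-epoch cap; no early-stopping patience.
* One master seed drives fold assignment, weight initialisation and batch
  shuffling; retraining with the same seed is bit-reproducible.

Predicted pair energies are rescaled into interaction strengths by the
affine map $\varphi(E) = (\mathrm{median} - E)/(\mathrm{median} -
E_{\min})$: the strongest (most negative) prediction gets exactly 1, the
median exactly 0. $\varphi$ is computed once over the full predicted
table for a protein-cluster combination.

# Placement by simulated annealing

The coarse-grained stage sees only C$\alpha$ atoms and ligand-head
centroids. The loss of a pose is

$$L = \sum_j^{N_{\mathrm{lig}}} \Bigl[\frac{\theta}{d_j^4}
  - e^{-(d_j-d_0)^2/\sigma}\Bigr]
  + \sum_j^{N_{\mathrm{close}}} \frac{1}{(t_j - c)^4}
  - k \sum_j^{N_{\mathrm{pairs}}} \varphi_j,$$

with $d_j$ the minimum head-to-C$\alpha$ distance of ligand $j$, $d_0 =
5$ Å (the coarse contact scale), $\theta = d_0^4/3$ so the well minimum is
$1/3 - 1$, $\sigma = 2$ Å², $t_j$ the C$\alpha$-to-cluster-centre
distance, $c$ the minimum centre-to-head distance of the cluster, the
barrier restricted to residues with $t_j - c < 5.5$ Å (capped at $10^6$
under penetration to keep the chain alive), pairs within 5.5 Å entering
the $\varphi$ sum, and $k = 1$. Every term vanishes as the cluster
recedes, a contract the tests assert.

Each of the 64 independent runs approaches the protein from one direction
of a Fibonacci-sphere set with a random orientation, sliding inward until
just outside contact. Proposals translate the cluster in a random
direction and rotate it about its centre of mass; acceptance follows the
Metropolis rule $P = \min(1, e^{-\Delta L/T})$ in reduced units
($k_B = 1$). Step sizes adapt every 50 proposals to hold acceptance in
the 40–60% band (×1.1 above, ×0.9 below, clamped to $[10^{-3}, 20]$ Å and
$[10^{-3}, \pi]$ rad).

Three engine-level choices are the package's own:

* **Temperature calibration.** $T_0$ is set from a 200-proposal probe at
  contact so that a typical uphill move would be accepted with
  probability ≈ 0.8; the *median* uphill $\Delta L$ is used because
  penetrating proposals produce barrier-scale outliers that would
  otherwise make $T_0$ orders of magnitude too hot. Cooling is geometric,
  ×0.95 every 100 steps over 5,000 steps.
* **Search domain.** Proposals in which every ligand head is farther than
  12 Å from all C$\alpha$ atoms are rejected (a reflecting wall at the
  edge of the contact shell). Because the loss is asymptotically flat,
  an unbounded chain at the calibrated temperatures simply diffuses away
  and never returns; the wall bounds the explored volume without
  altering the loss landscape anywhere the cluster can bind.
* **Site selection.** Final centres of mass are clustered by
  complete-linkage agglomerative clustering cut at 10 Å; clusters are
  ranked by membership, and each top cluster is represented by its
  member pose with the lowest predicted total interaction energy (raw
  energies, not $\varphi$, so representatives are comparable across
  clusters).

Refinement reuses the same engine at the all-atom level: $d_j$ and pair
membership switch to minimum interatomic distances (any atom within
5.5 Å), $d_0$ drops to 4 Å, and proposals are rejected outright if the
centre of mass leaves an 8 Å ball around the site or any interatomic
distance falls below a 1.5 Å steric floor (which replaces the
coarse-grained barrier term). If a clash cannot be resolved the
best-found pose is returned with a warning flag.

# The synthetic benchmark

`make_protein()` grows a self-avoiding C$\alpha$ random walk (3.8 Å
steps, 4.0 Å excluded volume, persistent direction) and decorates each
residue with pseudo-atoms whose element counts match its claimed type.
A planted binding patch is, by default, the mid-chain residue plus its
five *spatially* nearest neighbours — a compact surface blob, which is
what a binding site is; a sequence-contiguous window need not be
spatially compact. Patch residues are lysines (+1); the background
palette deliberately contains no positively charged residues, so the
patch is the unique attractive region and planted-site recovery is
well-posed. `make_cluster()` builds an icosahedral gold core with
carboxylate-like ligands whose head centroids sit exactly on a sphere
(for even ligand counts the heads are antipodal pairs and the centre of
mass coincides exactly with the sphere centre).

The energy oracle is exactly pair-decomposable: reduced-unit Coulomb
$C\,q_iq_j/(\varepsilon_r d)$ (prefactor 10) plus Lennard-Jones
($\varepsilon = 0.5$, $\sigma_{LJ} = 4$ Å), **both truncated at the 10 Å
pair-formation distance** so that every configuration label is exactly
the sum over the pairs the regressor is shown — the property the
sum-aggregated architecture assumes. Labels carry Gaussian noise with
5% of the label standard deviation. Training configurations span contact
to 15 Å of separation with random orientations.

Two geometric scales coexist: the Au25-like default
(`make_cluster(18, radius = 8)`) for featurization realism, and a compact
benchmark cluster (`make_cluster(8, radius = 3.5)`) for placement tests,
chosen so that the cluster's centre of mass at perfect contact
($\approx r + d_0 - \text{lean} \approx 7$ Å from the patch) is
commensurate with the 8 Å recovery radius used in the planted-site tests;
with an 8 Å head sphere the centre of mass could never come that close
even for a perfect placement.

What the generator does *not* emulate — conformational flexibility,
solvent, real side-chain chemistry, the time-averaging of MD-derived
energy labels — bounds what passing tests mean: they validate the
machinery (featurization contracts, sum-supervised learnability,
annealing control and recovery), not chemical accuracy on real
complexes.

# Problem sizes and reproducibility

The test-suite benchmark uses a 60-residue protein, an 8-ligand cluster,
200 training + 40 held-out configurations, 64 annealing runs of 5,000
steps, and 2,000-step refinements; the end-to-end pipeline check uses a
100-residue, three-patch protein. These sizes were chosen so the full
suite documents every claim in minutes on a single core while keeping
each statistical check comfortably away from its threshold. Every
stochastic component takes an explicit seed, and identical seeds
reproduce centre-of-mass traces and reports byte-for-byte.

# Known limitations

* Both partners are rigid; induced fit is out of scope.
* The internal feature providers are geometric stand-ins with the same
  meaning but not the same values as DSSP/Ghecom outputs; models trained
  with one provider mode are not interchangeable with the other.
* With sum-only supervision the Coulomb/vdW decomposition of a pair
  prediction is not identified; only summed energies are meaningful.
* The annealing temperature calibration assumes the probe starts at
  contact; a pathological input with no accessible surface would fall
  back to a default temperature.
* Multi-chain proteins are supported by the reader and the graph, but
  the synthetic generator only emits single chains.
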
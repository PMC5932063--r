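---
title: "Structure-encoded allosteric cross-talk of PTM sites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structure-encoded allosteric cross-talk of PTM sites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokit)
```

# The question and the approach

Post-translational modification (PTM) sites on multi-domain chaperones such
as Hsp90 do not act in isolation: phosphorylation or acetylation at one site
can shift the conformational equilibrium felt by distant sites. allokit asks,
for a set of annotated PTM sites on a structure, which sites behave as

* **hinges** — immobilised pivots of the slow collective motions,
* **effectors** — rigid, globally coupled sites whose perturbation moves the
  rest of the protein,
* **sensors / carriers** — mobile sites that receive and transmit the
  allosteric signal.

The evidence is assembled from two independent axes. The *sequence* axis
scores evolutionary conservation (per-column Kullback–Leibler divergence
from background amino-acid frequencies) and coevolution (mutual information
between alignment columns, summarised per residue as cMI and its structural
neighbourhood average pMI). The *dynamics* axis derives a fluctuation
covariance from a coarse-grained conformational ensemble and reads off
B-factors, PCA slow-mode displacement profiles, perturbation-response maps,
flexibility–rigidity indices, and a weighted residue-interaction network
whose shortest paths trace communication routes from effectors to sensors.

# Sequence models

**KL conservation.** For column *i* with observed (non-gap) amino-acid
frequencies $P$ and background $Q$,
$\mathrm{KL}_i=\sum_a P(a)\ln\frac{P(a)}{Q(a)}$, in nats. The built-in
background is a database-wide amino-acid composition, overridable by TSV.
Columns with more than 50 % gaps are scored but flagged unreliable.

**Mutual information.** Raw MI between two columns is computed in nats on
pairwise-complete observations,
$\mathrm{MI}(i,j)=\sum_{a,b}P(a_i,b_j)\ln\frac{P(a_i,b_j)}{P(a_i)P(b_j)}$,
with pairs below a minimum joint count masked. The reported score is, by
default, the average-product-corrected MI standardised against a
column-shuffle null (a configurable number of shuffles, seeded): shuffling
every column independently preserves compositions while destroying
covariation, so the z-score isolates the coevolutionary signal. The
threshold used for the per-residue cumulative score,
$\mathrm{cMI}_x=\sum_{y:\,\mathrm{MI}(x,y)>t}\mathrm{MI}(x,y)$ with
$t = 6.5$, is interpreted on this standardised scale — raw MI in nats is
bounded by the column entropies and cannot reach 6.5. A raw-threshold mode
is available for users who want it.

**pMI.** The proximity score of residue $x$ is the mean cMI over the
structural neighbourhood $\{x\}\cup\{y: d(x,y)<5\,\text{Å}\}$, where the
distance is the minimum over non-hydrogen atom pairs. Including the residue
itself makes isolated residues well defined. For Cα-only models (the
synthetic toys) no side chains exist, and an 8 Å Cα–Cα neighbourhood is used
instead.

**Column-to-structure mapping** aligns the ungapped query sequence globally
against each chain's residue sequence (Needleman–Wunsch via Biostrings),
refusing mappings below 90 % identity. Each protomer of a homodimer is
mapped independently, so one alignment column annotates both chains.

# Dynamics models

**Square-well DMD.** Residues are Cα beads; bonded neighbours are confined
to $[(1-\sigma)r^0,(1+\sigma)r^0]$ with $\sigma=0.05$ around the native
bond length (≈3.8 Å), and all non-consecutive pairs closer than
$r_c = 8$ Å in the native conformation get wells with $\sigma=0.1$. Between
wall events beads move ballistically; at a wall the normal component of the
pair's relative velocity is reflected elastically, conserving energy and
momentum exactly (verified to ~1e-15 relative per 1e5 events). Event times
are kept as absolute times per pair; after each collision only the pairs
touching the two colliding beads are recomputed. Velocities are initialised
from the Maxwell–Boltzmann distribution in reduced units (mass = 1,
$k_BT$ = temperature parameter). An optional Andersen-style thermostat
resamples all velocities at a fixed time interval; it is off by default,
but is required for canonical sampling of very small systems — a two-bead
well conserves relative angular momentum, so only the thermostatted run
visits the canonical shell density $p(d)\propto d^2$, which we verify by a
Kolmogorov–Smirnov test against the closed-form CDF, sampling frames at
the resampling interval so that draws are effectively independent.

**ENM Gaussian surrogate.** Long explicit-solvent MD is out of scope at
desk scale; the package substitutes the anisotropic elastic-network model:
uniform springs between Cα pairs within a cutoff, covariance proportional
to the pseudo-inverse of the Hessian with the six rigid-body modes removed.
Ensembles are drawn from the corresponding Gaussian, and the trajectory
reader accepts external multi-model PDB so real MD output can be dropped
in — every downstream stage consumes only frames or the covariance.

**Covariance, B-factors, slow modes.** Frames are least-squares superposed
onto their mean (on by default; removes rigid-body motion), deviations give
$C = \langle \Delta R\,\Delta R^\top\rangle$ (3N × 3N). Mean-square
fluctuations are the traces of the 3×3 diagonal blocks and
$B_i = \tfrac{8\pi^2}{3}\,\mathrm{msf}_i$. The slow-mode profile is the
eigenvalue-weighted average of per-residue squared displacements over the
top three PCA modes, normalised to sum to 1. Hinges are local minima of
the (optionally smoothed) profile lying below its 20th percentile. The
smoothing window defaults to 1 (no smoothing): ENM-derived profiles are
already smooth at these sizes and wider windows erase single-residue linker
minima; the window is a configuration knob for noisy, long real
trajectories.

**PRS.** Linear response takes the inverse Hessian proportional to $C$:
the displacement response to a force $f$ at residue $i$ is $C F$ with $F$
zero outside block $i$. Entry $(i,j)$ of the response map is
$\langle|\Delta R_j|^2\rangle$ averaged over 250 forces at $i$. Averaging
over uniformly random directions has the closed form
$\mathrm{tr}(B^\top B)/3$ per 3×3 coupling block $B$, which the package
exports and uses as its correctness oracle. The default force generator
draws random *orthonormal triads* (Haar rotations): every complete triad
reproduces the direction average exactly, so the 250-force estimate carries
well under 1 % deviation, whereas independent sphere directions would
fluctuate by >10 % per entry at this budget; the i.i.d. sphere mode remains
available. The map is row-normalised by its diagonal (self-response = 1);
effector profiles are row means and sensor profiles column means, both
excluding the diagonal — including the self-response would reward floppy
residues in both profiles. Peaks are z > 1.5 with a 3-residue minimum
separation. These conventions make effectors anti-correlate and sensors
correlate with mobility, which is the behaviour the classification relies
on.

**FRI.** The flexibility–rigidity index needs no matrix decomposition:
$\mu_i = \sum_{j\neq i}\Phi(r_{ij})$ with the exponential kernel
$\Phi(r)=e^{-(r/\eta)^\kappa}$, $\eta = 3$ Å, $\kappa = 2$ by default (a
Lorentz kernel is available), and flexibility $f_i = 1/\mu_i$, averaged
over ensemble frames when a trajectory is supplied.

**Surface metrics.** Accessible areas come from a deterministic
golden-spiral dot-sphere (Shrake–Rupley-style) construction with standard
van der Waals radii and a 1.4 Å probe; surviving dots are retained and
double as the accessible surface for the residue-depth proxy: an atom's
depth is its distance to the nearest surface dot minus its expanded
radius, floored at zero, so surface atoms have depth exactly 0. This is a
deterministic stand-in for solvent-box depth methods and is
monotone-equivalent on compact structures. RSA is the percentage of the
Gly-X-Gly theoretical maximum per residue type; residues are exposed above
50 %, buried below 20 %, deeply buried below 10 %. Cα-only input triggers a
coarse mode (3.0 Å bead radius) in which exposure classes are suppressed.

# The residue interaction network

Mutual information between two residues' fluctuation vectors is estimated
with the closed-form Gaussian estimator
$I = \tfrac12\ln\frac{\det S_i\,\det S_j}{\det S_{ij}}$ and mapped to the
generalized correlation coefficient
$R_{MI}=\sqrt{1-e^{-2I/d}}\in[0,1]$ ($d=3$). When a coevolution profile is
supplied, each residue's vector gains a fourth, unit-variance channel whose
loading on a common latent signal is the residue's pMI scaled to [0, 1), so
residue pairs that both carry high proximity-coevolution scores share
information in the composite vector ($d=4$). A literal "static fourth
coordinate" would carry no information (a constant has no variance), so
this latent-channel construction is the package's concrete reading; the
pure-dynamics mode is the default when no alignment is given, and the
estimator and mode are recorded in the output metadata.

Edges join residue pairs whose $R_{MI}$ exceeds 0.5 (strictly) in at least
one independent ensemble, optionally gated to structural contacts to
suppress spurious long-range correlations; the edge length is
$w_{ij}=-\ln R_{MI}$. All-pairs shortest communication distances come from
Floyd–Warshall with predecessor reconstruction (cross-checked against an
independent single-source algorithm); edge betweenness counts shortest
paths with equal splitting among ties and is normalised by the number of
connected pairs, so a bridge used by every pair attains the component
maximum. Effector-to-sensor pathways are the k shortest loopless routes
(Yen), ranked by total length, with per-node traversal counts exposing
gate-keeper residues.

# PTM classification

A mapped site is *conserved* when its column's KL exceeds the column mean
plus `conservation_k` (default 1) standard deviations — the package's
quantification of "markedly higher than average". Roles are non-exclusive:
hinge within 2 residues of a slow-mode minimum; effector/sensor when the
respective z-score exceeds 1.5; carrier in a slow-mode maximum region or
strictly above the 75th sensor percentile. Homodimer profiles are averaged
across protomers before classification, with a warning when the protomers
disagree by more than 20 %.

# What the synthetic generator emulates

`make_toy_dimer` builds a deterministic (up to small seeded jitter)
two-protomer system: three compact serpentine-lattice domains
(pseudo-NTD/MD/CTD) per protomer joined by single linker beads, a helical
N-terminal tail, and a C2 copy rotated about an axis through the MD–CTD
linker so the protomers cross at their linker stack. The planted features
are structural, not statistical:

* the **hinge** (MD–CTD linker) lies on the two-fold axis, so the slow
  inter-protomer modes leave it immobile — a slow-mode minimum by
  geometry;
* the **sensors** are the tail beads, whose amplitudes the ground-truth
  covariance (`toy_covariance`) scales by 1.6;
* the **effector** is the interface-forming CTD bead; its fluctuation
  vector is defined as the collective mean motion of all other beads plus
  0.35 of its own elastic-network motion (keeping it correlated with its
  structural neighbours, so it participates in the residue network) and a
  small independent noise. That is the literal covariance signature of a
  global mediator — maximal global coupling at minimal mobility — and it
  is planted directly at the covariance level because elastic-network
  spring plants proved unable to guarantee it: rank-one phantom springs to
  a compact distant anchor cluster always leave two soft directions, and
  the dimer's natural interface beads otherwise dominate the effector
  profile. The resulting matrix is still a valid Gaussian model (a linear
  transform of the ENM Gaussian plus independent noise).

`make_synthetic_msa` draws independent columns from the background,
conserved columns from a peaked distribution (consensus letter with
probability `conservation_level`), and coevolving pairs by copying a random
bijective recoding of one column into the other with probability
`coupling`; gaps are sprinkled independently, and a supplied query sequence
is embedded ungapped as the first record so column-to-structure mapping is
exact. The study-scale defaults (200 sequences, 50 columns, 5 pairs at
coupling 0.9, 5 % gaps) are what the recovery tests run at.

What passing these tests shows — and does not show. The generator plants
clean, well-separated signals in a small, topologically simple system; real
alignments carry phylogenetic bias that the column-shuffle null does not
model (sequence-identity reweighting is available but no tree-aware
correction), and real ensembles carry anharmonic, multi-basin dynamics that
neither the ENM surrogate nor square-well DMD reproduces. The pipeline's
recovery of planted roles validates the statistical machinery, not the
biology of any particular chaperone.

# Numerical choices and degenerate inputs

* Contacts use strict inequality (distance < cutoff) for determinism.
* Altloc handling keeps the highest-occupancy conformer (first encountered
  on ties); hydrogens are identified by element, falling back to an
  atom-name heuristic.
* $R_{MI}$ is capped at $1-10^{-12}$ before the logarithm; rigidity indices
  are floored at $10^{-12}$; near-singular per-residue covariances are
  masked with a warning.
* The ENM refuses disconnected networks and Hessians with more than six
  near-zero modes (under-braced chains — e.g. collinear termini — are a
  known ANM artifact; the toy's helical tail is built so its end beads have
  three non-coplanar springs).
* Ties among equal shortest paths: equal splitting for betweenness;
  the representative path follows the predecessor matrix.
* All stochastic stages are seeded; the pipeline derives per-stage seeds
  from one master seed and the report is byte-reproducible.

# Problem sizes used by the test-suite

Unit and acceptance tests run at deliberately small scale: toy dimers of
78 beads (10 beads per domain, 7-bead tails), alignments of 120–400
sequences × ≤50 columns, ensembles of 150–10 000 frames, DMD runs of
1e3–1e5 events, and graphs of ≤40 nodes. These sizes were chosen so every
oracle comparison (brute-force MI, exhaustive path enumeration, exhaustive
event search, closed-form sphere averages) is exact and the whole suite
runs in well under a minute per module.

# Known limitations

* The ENM surrogate has a single uniform spring constant; B-factor
  magnitudes are meaningful only up to scale.
* Coarse (Cα-only) SASA/RSA is a qualitative tool; exposure classes are
  suppressed in that mode.
* The Gaussian $R_{MI}$ estimator captures linear dependence plus the
  Gaussian part of nonlinearity; strongly anharmonic couplings would need
  a different estimator.
* Pfam-scale alignment construction, structure preparation, and all-atom
  reconstruction of coarse-grained frames are out of scope; the package
  starts from a prepared structure, an alignment, and a PTM table.
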
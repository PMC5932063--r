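# allokit

Structure-encoded analysis of allosteric cross-talk between
post-translational modification (PTM) sites in multi-domain proteins, built
for the Hsp90-style setting: a homodimeric chaperone whose phosphorylation
and acetylation sites sit at hinges, rigid "effector" hubs, and mobile
"sensor" regions of the collective dynamics.

## Who this is for

Computational structural biologists who have (a) a structure (PDB), (b) a
multiple sequence alignment of the protein family (FASTA/Stockholm), and
(c) a table of annotated PTM sites, and who want a reproducible,
desk-scale pipeline that classifies each site's role in allosteric
communication. Every stage is also usable on its own.

## What it computes

**Sequence axis.** Per-column Kullback–Leibler conservation
`KL_i = Σ_a P(a) ln(P(a)/Q(a))`; pairwise mutual information
`MI(i,j) = Σ P(a_i,b_j) ln[P(a_i,b_j)/(P(a_i)P(b_j))]` (nats,
APC-corrected and z-scored against a column-shuffle null); the per-residue
cumulative score `cMI_x = Σ_{MI>6.5} MI(x,y)` and its structural
neighbourhood average `pMI` (heavy-atom contacts within 5 Å).

**Dynamics axis.** Conformational ensembles from event-driven square-well
discrete molecular dynamics on Cα beads (wells `(1±σ)r⁰`, σ = 0.05 bonded /
0.1 non-bonded, cutoff 8 Å) or from an elastic-network Gaussian surrogate;
the 3N×3N fluctuation covariance `C = ⟨ΔR ΔRᵀ⟩`; B-factors
`B_i = (8π²/3)·msf_i`; slow-mode displacement profiles (top 3 PCA modes,
eigenvalue-weighted); perturbation response scanning `ΔR = C·F` with 250
random forces per residue, diagonal-normalised, with effector (row-mean)
and sensor (column-mean) profiles; flexibility–rigidity indices
`μ_i = Σ exp(-(r/η)^κ)`; solvent accessibility, exposure classes
(50 %/20 %/10 %), and residue depth.

**Integration.** A residue interaction network with edge lengths
`w_ij = −ln R_MI` (generalized correlation `R_MI = √(1−e^(−2I/d))`, edges
where `R_MI > 0.5` in at least one independent ensemble), Floyd–Warshall
shortest communication paths, edge betweenness, k-shortest
effector→sensor pathways, and finally per-site role assignment: hinge /
effector / sensor / carrier, plus a conserved-site flag
(KL > mean + 1 SD).

A synthetic-data module generates toy dimers, alignments, and ensembles
with planted, recoverable ground truth, so the entire pipeline is testable
offline.

## Worked example

```r
library(allokit)
res <- run_full_pipeline(output_dir = "out", seed = 7)
res$report$table[, c("resnum", "planted", "effector_z", "sensor_z",
                     "conserved", "roles")]
```

```
  resnum    planted effector_z sensor_z conserved                  roles
1     29      hinge     0.6272  -0.5076      TRUE                  hinge
2     30   effector     5.8001  -0.5858      TRUE hinge,effector,carrier
3      1     sensor    -0.4962   4.4801     FALSE         sensor,carrier
4     27 background    -0.0431  -0.4527     FALSE                   none
5     32 background    -0.3150  -0.0434     FALSE          hinge,carrier
6      9 background    -0.3248  -0.4117     FALSE                  hinge
7     22 background    -0.2282  -0.2786     FALSE                carrier
8     19 background    -0.4086   0.2198     FALSE                carrier
```

The toy dimer plants a hinge at the MD–CTD linker (residue 29), a globally
coupled rigid effector next to the dimer interface (residue 30), and a
floppy sensor tail (residues 1–7). The report shows each planted site
recovered: the hinge site lies at a slow-mode minimum, the effector site
carries an effector z-score of 5.8 (the top profile peak), and the tail
site a sensor z-score of 4.5; both structurally planted sites sit on
planted conserved alignment columns. Communication pathways run from the
effector hub through the linker and N-terminal domain into the sensor
tail:

```
res$pathways$paths[1, ]
#   source target rank total_weight                          path
# 1     30      1    1     1.763325 30-29-22-20-18-11-12-13-5-4-1
```

Stage artifacts (structure, PTM table, network edge list, trajectory,
report.tsv/report.json, resolved config.yaml) are written under `out/`.
A thin command-line wrapper lives at `inst/cli/allokit.R`
(`Rscript allokit.R run --out out --seed 7`).

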
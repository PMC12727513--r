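---
title: "Methods: motif scaffolding geometry, metrics and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: motif scaffolding geometry, metrics and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsk)
```

# The problem

De novo enzyme design starts from a *catalytic array* (theozyme): a handful
of amino-acid functional groups frozen in the geometry that stabilizes a
reaction's transition state, e.g. a lysine amine poised at a substrate
carbonyl plus tyrosine/asparagine hydrogen-bond donors for a retro-aldolase,
or a histidine nucleophile + glutamate + arginine triad for the
Morita-Baylis-Hillman reaction. A generative backbone model can scaffold a
protein around such an array, but two geometric sub-problems are purely
deterministic and benefit from exact, testable code:

1. **Artificial motif libraries** -- enumerate physically plausible ways to
   carry the array on short helical backbone fragments.
2. **Pocket enforcement** -- keep the generative process from burying the
   substrate channel, via a placeholder helix and a guiding potential.

This package implements those stages, the deterministic skeleton of the
iterative sequence-design/relax/predict refinement loop (external neural
networks and force fields enter only through adapter contracts), and the
metric suite used to evaluate finished designs and their measured kinetics.

# Inverse rotamers

A rotamer is normally applied forward: given backbone N/CA/C and chi
angles, build the sidechain. Here the functional-group atoms are fixed in
space and the backbone is the unknown. Because the terminal functional
group of each residue type is internally rigid (its geometry does not
depend on the preceding chi angles), inversion is solved exactly:

* build the residue with the requested chi angles in a canonical frame from
  ideal internal coordinates (template bond lengths/angles; NeRF placement);
* superpose the built functional atoms onto the fixed target atoms
  (Kabsch, proper rotations only);
* the transformed N/CA/C is the unique backbone frame.

The forward builder is the oracle for the inverse: rebuilding from the
recovered frame reproduces the functional atoms to < 1e-6 A for all 18
chi-bearing residue types (tested). Residues with a single chi
(Ser/Thr/Cys) get their polar hydrogen from the template so the functional
frame has three non-collinear atoms; for glycine and alanine there is
nothing to invert.

A convention lesson learned the hard way: the package's first dihedral
implementation was internally consistent but 180 degrees off the IUPAC
convention, and every self-referential test passed. The bug surfaced only
in an *external* oracle -- an "ideal helix" built at phi = -57, psi = -47
had consecutive CA-CA distances of 2.77 A (a cis-like chain) instead of
3.80 A. Both the geometry kernel and the generated templates now use the
standard convention, and the helix oracle is a permanent test.

# Motif library construction

For each catalytic residue, rotamers are drawn from a backbone-dependent
rotamer library, restricted to the (phi, psi) bin of the fragment's anchor
position (10 degree bins by default; the on-disk TSV schema is documented
in `?rotamer_library`). Each rotamer is inverted, an ideal helical fragment
(default length 7, anchor at the center) is superposed onto the inverted
frame, and the catalytic residue is rebuilt full-atom on the anchor.

All combinations taking one placement per residue are enumerated
depth-first with incremental pairwise clash pruning; the result provably
equals brute-force Cartesian filtering (tested on instances up to 1,000
combinations). A pair of atoms clashes when `d < gamma * (r_i + r_j)` with
standard van der Waals radii (C 1.7, N 1.55, O 1.52, S 1.8 A) and
`gamma = 0.75` -- the common soft-overlap convention; the source method
names no numeric criterion, so both gamma and the radii are configuration.

Ranking combines what the method describes qualitatively -- rotamer
probability and fragment abundance -- as

```
score = w_rot * mean(log p_i) + w_abund * mean(log(abundance_i + 1))
```

with default weights (1, 1). The log-mean form makes the score independent
of array size and insensitive to a single dominant term; it is a documented
reconstruction, not the authors' exact formula. Ties break on insertion
order, so libraries are byte-identical across reruns.

# Pocket enforcement

Ligand burial is measured as the number of protein alpha-carbons within
8 A (inclusive) of any ligand heavy atom, normalized by the ligand
heavy-atom count -- natural enzymes average about 7 on this scale, which
motivates enforcing pockets rather than hoping for them. During backbone
generation a placeholder ideal helix marks the entry channel; the guiding
potential is flat-bottom quadratic on all backbone atoms,

```
E = w * sum_i max(0, |x_i - center| - r0)^2
```

with analytic gradients (verified against central differences to 1e-5
relative; an atom exactly at the center gets zero gradient by convention).
Defaults r0 = 12 A, w = 1. The exact functional form used upstream is not
published; this is the standard restraint shape with the stated contract
(pure function: coordinates in, energy + gradient out), so an external
diffusion wrapper can call it per denoising step.

Helix placement follows the geometric recipe (axis from the
functional-atom centroid through the ligand centroid, near end at a
standoff beyond the ligand) with a deterministic search: axial rotations in
30 degree steps, standoff offsets 0-5 A -- plus, beyond the original
design decision, a tilt fallback of +/-10 and +/-20 degrees about two axes
perpendicular to the channel axis. The tilt stage was added because on
compact toy motifs the nominal axis can pass within ~1 A of a fragment
atom, where no axial rotation or offset can ever clear; the search remains
fully deterministic and fails loudly with the tightest-clash diagnostic
when exhausted.

# Refinement skeleton and adapters

The refinement loop runs sequence design, constrained relax, sequence
redesign and structure prediction, then keeps `ceil(keep_fraction * n)`
designs. External tools are adapters: `(design, options) -> (design,
metrics)`, never mutating inputs, with a declared determinism flag. Two
stubs ship: an identity stub and a seeded Gaussian jitter stub, making the
loop, metric bookkeeping, lineage tracking and selection testable offline.
Ranking is a z-score weighted sum with sign conventions in the weights
(default `sidechain_rmsd -2, motif_backbone_rmsd -1, plddt_avg +1`);
keep_fraction defaults to 0.5 and the cycle count to 3. All are
reconstructions of a qualitative description and are configuration.
Coordinate constraints serialize to a one-line-per-atom harmonic dialect
(`?write_constraints`) and round-trip losslessly.

# Evaluation metrics

* **Motif RMSD** (`motif_rmsd`): explicit residue mapping; "ca"/"backbone"
  selections superpose globally on the selected atoms, sidechain and
  functional-group selections superpose on the mapped backbone N/CA/C
  first. Chemically equivalent namings (Tyr/Phe ring flips, Asp/Glu
  carboxylates, Arg NH1/NH2) are resolved by the minimum-RMSD relabelling;
  the source's convention is unstated.
* **SAP** (`sap_score`): Shrake-Rupley SASA (probe 1.4 A, 960 deterministic
  golden-spiral points), per-atom relative exposure against the isolated
  residue's reference SASA, weighted by Black-Mould hydrophobicity
  normalized to glycine = 0, summed in 5 A spheres at each CA; the total is
  the sum of positive per-residue values.
* **Core contacts** (`core_contacts`): mean over residues of the count of
  other-residue heavy atoms within 10 A of the residue's CA (the source
  names "core atomic density" without a formula; this is the documented
  reconstruction; a core-fraction at a configurable threshold rides along
  as an attribute).
* **Stability regression** (`fit_stability_model`): OLS of chemical
  denaturation midpoints on relax energy, mean pLDDT, SAP and core
  contacts. Exact on noiseless synthetic tables (tested); the published
  dataset-level correlation is not desk-reproducible and is substituted by
  that recovery property. Real tables are ingested via plain data frames.
* **Composite active-site metric** (`composite_site_metric`): sum of
  absolute deviations of catalytic H-bond distances (intermediate complex)
  and the nucleophilic attack distance (substrate complex) from ideals
  (defaults 2.8 A and 3.5 A; configurable -- the upstream constants live in
  an unpublished supplement).
* **Ensemble metrics** (`ensemble_metrics`): per-frame all-protein CA
  superposition (convention choice; unstated upstream), sidechain
  heavy-atom RMSF about time means, H-bond distance deviations against
  reference distances, and functional-group displacement after superposing
  on the reference motif backbone. A Gaussian-jittered ensemble with
  per-atom sigma has expected per-atom RMSF sigma*sqrt(3); the generator
  and metric agree within 5% at 500 frames (tested).
* **SAXS descriptors**: mass-weighted radius of gyration and the
  dimensionless Kratky transform `(qRg)^2 I/I0` vs `qRg`; a Guinier
  scatterer peaks at `qRg = sqrt(3)`, value `3/e` (tested by calculus).

# Kinetics layer

Rates are stored in s^-1 and concentrations in mol/L, with explicit unit
tags (`"per_s"`, `"per_min"`) at every interface -- a missing tag is a
contract error, because the uncatalysed reference rate for the retro-aldol
background (3.9e-7) is conventionally quoted per minute while design kcats
are per second.

Michaelis-Menten and two-pKa profiles are fitted with `stats::nls`,
deterministically initialized (kcat0 = max v, km0 = median S; pKa starts
from the half-maximum crossings). Two numerical notes: `nls` famously fails
on zero-residual data, handled via `scaleOffset = 1`; and exact-recovery
tests need a tighter-than-default convergence tolerance, so the fits try
`tol = 1e-10` first and fall back to the default tolerance for noisy data.
Single-limb pH data yields a warning and `pKa2 = Inf` from a one-pKa fit.

Kinetic resolution of a racemate with selectivity factor E uses the
standard irreversible relations; at the low-conversion limit
`ee_product = (E - 1)/(E + 1)` (E = 4 gives 60%, E = 200 gives 99%). At
finite conversion the relations are solved by bracketed root finding on
log-transformed variables (`log(1 - ee)` and `log(1 - c(1 + ee))`), with
`log1p` forms to avoid cancellation at c = 0.5 where the untransformed log
argument is exactly 1. Forward and inverse compose to identity within 1e-7
relative wherever `1 - ee > 1e-9`; closer to 1 the IEEE-double
representation of ee itself dominates (at E = 500, c = 0.9 the substrate
ee underflows to 1 exactly), which is a representation limit, not a solver
tolerance.

# What the synthetic fixtures do and do not establish

The toy catalytic arrays are *constructed* from ideal internal coordinates
-- a Lys/Tyr/Asn/Tyr tetrad and a His/Glu/Arg triad with H-bond partners
placed at 2.6-3.2 A around small placeholder ligands -- deliberately not
copied from any deposited structure, so the package builds and tests with
no downloads. The toy rotamer library walks canonical gauche/trans chi
patterns, rejecting any rotamer that folds back onto its own backbone, with
per-bin probabilities normalized to 1. Consequently a green test
establishes the *geometry and bookkeeping* (inversion exactness, clash
logic, enumeration completeness, ranking determinism, metric definitions)
-- it does not establish that real rotamer statistics, real PDB fragment
abundances, or real designed-enzyme metric distributions are reproduced,
and the published experiment-dependent numbers (hit rates, dataset
correlations, crystal-vs-model RMSDs) are out of desk scope by
construction.

# Worked example

```{r}
arr <- make_toy_catalytic_array("ra_tetrad")
lib <- build_motif_library(arr, make_toy_rotamer_library(seed = 1),
                           list(make_ideal_helix(7)),
                           config = list(min_prob = 0, max_out = 5))
lib
s <- assembly_to_structure(lib$assemblies[[1]])
burial_score(s, "Z:1")$burial
helix <- place_channel_helix(lib$assemblies[[1]], arr$ligand)
pot <- pocket_potential(coords(s, atoms = c("N", "CA", "C", "O")),
                        pocket_potential_params(pocket_center(helix)))
pot$energy
rate_acceleration(3.1e-2, 3.9e-7, kcat_unit = "per_s", kuncat_unit = "per_min")
```

# Known limitations

* Only the PDB coordinate dialect is supported (no mmCIF); alternate
  locations resolve to the highest-occupancy conformer.
* Fragment geometry is parametric (per-fragment phi/psi); arbitrary mined
  backbone fragments would need an extended on-disk format.
* Noncanonical amino acids are treated as their canonical parents.
* The enumeration is exact and therefore exponential in the residue count;
  a configurable combination cap (default 1e6) guards runtime.
* SASA is O(n^2) per structure in plain R; adequate for motifs and small
  designs, not for large complexes.
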
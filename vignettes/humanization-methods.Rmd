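---
title: "Methods: structure-guided antibody humanization with abgraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-guided antibody humanization with abgraft}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abgraft)
```

This vignette documents the models, conventions and numerical choices
behind `abgraft`, in the order a humanization campaign uses them.

## Scheme numbering by template alignment

A variable-domain sequence is numbered by semi-global Needleman–Wunsch
alignment against a curated template for its chain class (heavy, kappa,
lambda). Each template residue carries both its Kabat and IMGT labels, so
one alignment serves both schemes. Design choices:

* **Scoring.** BLOSUM62 substitution scores; linear gap costs that are
  position specific: deleting a CDR column costs 1, a framework column 8,
  and a conserved anchor column (the two canonical cysteines and the
  tryptophan following CDR1) is effectively undeletable (cost 1000).
  Query insertions are cheap (cost 1) adjacent to CDR columns and
  expensive (cost 10) inside frameworks. Leading and trailing template
  deletions are free, which is what lets germline V genes — which end
  before FR4 — and slightly truncated domains number cleanly.
* **CDR length rules.** After alignment, each CDR is relabelled purely
  from its observed length: Kabat loops fill left-to-right up to the
  canonical insertion point (H35, H52, H100, L27, L54, L95) with
  insertion letters A, B, … there, keeping the span tail right-anchored;
  IMGT loops fill symmetrically from both span ends toward the middle.
  IMGT loops longer than their span receive ascending insertion letters
  at position 111, an encoding of IMGT's 111.x/112.x convention chosen so
  that positions remain totally ordered by (number, letter).
* **Failure modes.** Sequences outside 90–140 residues, anchors that do
  not align, anchors carrying `X`, and non-monotonic label assignments
  all raise an "unnumberable" error naming the offending anchor rather
  than returning a partial numbering.
* **Scope.** The exact CDR boundary conventions of interactive numbering
  servers are not bit-reproducible from the literature; the bundled
  boundary tables follow the canonical published Kabat/IMGT definitions
  and every report names the table it used. The kappa tables are reused
  for lambda; lambda insertions outside L1/L3 are not specially cased.

Numbering is deterministic, idempotent, and round-trips between schemes;
the test suite cross-validates it against the synthetic-sequence
generator's ground-truth labels on 100 derived sequences with CDR indels.

## Framework ranking, grafting and panels

Framework identity between a parental chain and a germline entry is the
fraction of matching residues over framework positions present in both
chains (CDRs excluded, gaps excluded from the denominator). Ties break by
more aligned positions, then lexicographic gene name — the upstream
database's tie handling is not published, so the package picks a
deterministic rule and documents it. Grafting concatenates acceptor
FR1–FR4 with parental CDR1–3 under the chosen boundary table; since V
genes end before FR4, a curated human J-segment consensus per chain class
supplies FR4 unless the acceptor provides one. Panels are the full
heavy × light cross product, tagged `{prefix}H{i}L{j}` in heavy-major
order; back-mutations are applied only after verifying the expected
residue at each position and are appended to the candidate's ledger, so
every framework residue of a candidate is attributable to the acceptor
gene or the ledger.

## SASA, buried surface area and contacts

SASA uses the Shrake–Rupley construction: test points on each atom's
solvent-expanded sphere (van der Waals radius + probe, default 1.4 Å,
Bondi-type radii shipped as data) are counted accessible if outside every
neighbour's expanded sphere. Numerical choices:

* The point set is a deterministic golden-angle spiral over one
  hemisphere completed by its antipodes (default 960 points). Antipodal
  symmetry makes inversion-related environments receive *identical*
  SASA — the homodimer symmetry test is exact, not approximate — and
  cancels odd-order quadrature error.
* Each atom name's point set is rotated by a fixed, hash-derived
  rotation. This decorrelates the lattice error between the atoms of a
  residue so per-residue sums converge faster, while keeping
  symmetry-related atoms (which share a name) on identical orientations.
* At 960 points the per-atom quadrature error on bead fixtures is a few
  tenths of a percent; the two-sphere analytic oracle is met within 1%.
  The convergence property (halving of error with doubled points) is
  asserted from a 1920-point base in the tests.

Per-residue BSA follows the side-alone-minus-complex convention:
`BSA_i = SASA_i(own side isolated) − SASA_i(complex)`, clamped at zero.
Side totals are sums over that side's residues, and when numbered chains
are attached, per-side CDR vs framework fractions are reported — the
framework fraction of the *antibody-side* total is the package's
headline interface statistic. An antigen-side or interface-area
denominator would give different values; the convention is recorded in
every report.

Contacts are typed on heavy atoms with precedence
salt bridge > hydrogen bond > hydrophobic > van der Waals:

| type | criterion | default |
|---|---|---|
| salt bridge | charged-group centroid distance (Lys NZ; Arg NE/NH1/NH2; His ND1/NE2; Asp OD1/OD2; Glu OE1/OE2) | ≤ 4.5 Å |
| hydrogen bond | donor–acceptor heavy-atom distance (donor angle ≥ 100° only when hydrogens are present; distance-only otherwise) | ≤ 3.5 Å |
| hydrophobic | carbon–carbon between apolar carbons (side-chain carbons bonded only to C/H) | ≤ 4.0 Å |
| van der Waals | heavy-atom distance ≤ radius sum + slack | 0.5 Å slack |

The cutoffs follow common practice for geometric interaction profilers
and are fully configurable (`default_contact_config()`); detection is
verified against an exhaustive all-pairs brute-force oracle on fixtures.
Altlocs resolve to the highest-occupancy conformer; waters and hetero
atoms are excluded by default with opt-in flags (relevant when a
structure coordinates an ion at the interface).

## Superposition, RMSD and RMSF

Rigid-body superposition is least-squares optimal (Kabsch via SVD, with
the determinant correction so reflections are never returned). The fit
selection defaults to the Cα atoms of all mapped residues; passing the
framework residue keys gives the framework-anchored fit used to read
loop deviations: per-residue RMSD is then computed over all mapped
residues. Degenerate (collinear or < 3 atoms) fits error out. On small
systems the result is cross-checked in the tests against direct
minimization over the six rigid-motion parameters.

RMSF over an ensemble is `sqrt(mean_t |x_i(t) − x̄_i|²)` per selected atom
(default one Cα per residue), averaged per residue. Superposing each
frame onto the ensemble mean first (two-pass) is the default, matching
trajectory-analysis practice; for synthetic jitter ensembles with no net
motion the tests disable it, because the fit itself absorbs six degrees
of freedom and would deflate the expected σ√3 by roughly `3/N` per atom.

## Back-mutation proposal

`propose_back_mutations()` intersects three evidence streams over the
framework diff between parental and humanized chains:

* **direct_contact** — the parental residue buries at least
  `bsa_threshold` Å² (default 10 Å², configurable and recorded in every
  report; the threshold separates emphasized interface residues from
  incidental grazing contacts and is deliberately a parameter, not an
  inference) or makes ≥ 1 cross-interface contact;
* **vernier** — the position is in the bundled Vernier-zone table
  (Foote & Winter positions, Kabat numbering, shipped as cited data);
* **contact_and_vernier** — both.

Proposals are ranked contact_and_vernier, then direct_contact by BSA,
then vernier. When a parental structure is available, a Vernier proposal
within 8 Å (Cβ–Cβ, Cα for glycine) of another differing framework
position annotates that position as a coupled partner — the
generalization of the heavy-chain 71/78 steric pair, without hard-coding
those positions. Three properties are enforced by tests: proposals are a
subset of framework diffs, raising the BSA threshold never adds
direct-contact proposals, and applying all proposals then re-proposing
yields the empty set.

## Binding kinetics and titrations

Sensorgrams follow the closed-form 1:1 Langmuir solution (association
`R(t) = R_max C/(C+K_D)(1 − e^{−(k_on C + k_off)t})`, dissociation
exponential with rate `k_off`). Mass transport, drift and reference
subtraction are intentionally out of the model; residual RMS per trace is
reported so lack-of-fit is visible instead of absorbed. Fitting is
nonlinear least squares (Levenberg–Marquardt) on log-parameters with a
3 × 3 multi-start grid over (k_on, k_off); global mode shares
k_on/k_off/R_max across all traces (the default, matching instrument
practice) and per-trace mode exists for diagnostics — both are provided
because published fits rarely state which was used. EC50 uses a
four-parameter logistic with free Hill slope; flat responses raise a
"no dose-dependence" error rather than returning a degenerate fit.

The simulation defaults mirror the assay design the package targets: a
two-fold dilution series from 125 nM, 180 s association and dissociation
at 1 Hz sampling, and rates on the k_on ≈ 1e5 /M/s, K_D ≈ 1.5 nM scale.
At 2% of R_max Gaussian noise, the dominant uncertainty is k_off: only
~3% of the signal decays within a 180 s dissociation at these rates, so
median K_D recovery within 10% (verified over 20 seeds in the tests) is
the realistic expectation, not solver error.

## What the synthetic fixtures do and do not show

The fixture module generates: template-derived sequences with recorded
edits and ground-truth labels (point mutations at non-anchor positions,
≤ 2 CDR indels); two-sphere and shell structures with analytic SASA;
toy two-chain interfaces with planted, well-separated typed contacts;
a schematic full-chain antibody–antigen bead complex with planted
paratope contacts at chosen scheme positions; Gaussian-jittered
ensembles with known per-residue σ; and seeded noisy sensorgrams. All
are byte-deterministic given their seed.

These fixtures verify the *computational* contracts — numbering
correctness, exact BSA bookkeeping, contact typing, RMSD/RMSF
calibration, fit recovery — on inputs with known truth. They do not
emulate folded antibody geometry, real packing densities, correlated
loop motions, or instrument artifacts; passing them shows the engines
are correct, not that a particular real antibody will tolerate a
particular graft. The three structural acceptance checks that require
deposited crystal structures of the Fab–antigen system run only when
those coordinate files are supplied locally (they are too large to
bundle); which deposited entry corresponds to which Fab variant is read
from the files' metadata at run time, never hard-coded. The bundled
parental and germline sequences are synthetic stand-ins and curated
approximations (clearly tagged in their FASTA headers); they reproduce
the framework-residue biology the workflow is built around — K60/R66 on
the light chain, K71/V78 vs V71/F78 on the heavy chain — but are not
verified database records.

## Problem sizes

The test suite and acceptance script run at deliberately desk-scale
sizes: 100 synthetic sequences for numbering cross-validation, ≤ 500-atom
contact fixtures, 1000-frame ensembles for RMSF calibration, 960-point
SASA spheres, 20 noise seeds for kinetic recovery. Each was chosen as the
smallest size at which the corresponding statistical tolerance (5% for
σ√3, 10% median K_D error, 1% SASA oracle) is comfortably interpretable.

## Known limitations

* Chothia/Martin/AHo numbering, nucleotide input and humanness scoring
  are out of scope; lambda-chain Kabat conventions are approximated by
  the kappa tables.
* SASA accuracy is quadrature-limited at the default 960 points
  (sub-percent per residue); crystallographic-grade interface areas
  should be computed at 1920+ points.
* The 1:1 kinetic model cannot represent mass-transport-limited or
  heterogeneous binding; such data will show structured residuals.
* Proposal evidence is geometric, not energetic: no ΔΔG is predicted,
  and accepting a proposal remains a human decision by design.
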
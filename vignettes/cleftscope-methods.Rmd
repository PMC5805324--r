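---
title: "Methods and design of cleftscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of cleftscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cleftscope)
```

`cleftscope` implements the structural and dynamical analyses used to
rationalise the thermal stability and reduced activity of a thermophilic
two-domain zinc peptidase relative to its mesophilic orthologs.  This
vignette records the methods, the defaults, and the design decisions that
were genuinely open — with enough detail that a user can judge what a
result does and does not mean.

## Interaction detection

All detection is heavy-atom based.  Crystal structures at ~2 Å resolution
carry no hydrogens, so hydrogen-bond geometry cannot use the D–H···A angle
directly.  Instead, the angle θ is measured at the donor heavy atom between
the donor→antecedent direction (the donor's covalently bonded neighbour)
and the donor→acceptor direction.  A bond pointing "away from" the
antecedent (θ > 90°) is geometrically capable of donating; this is a
deliberate, documented divergence from hydrogen-explicit definitions, and
trajectory analysis switches to the D–H···A ≥ 135° criterion automatically
when the topology contains hydrogens.

Class definitions (defaults in `interaction_criteria()`):

| class | atoms | geometry | counting |
|---|---|---|---|
| hydrogen bond | N/O donor → N/O acceptor | d ≤ 3.9 Å, θ > 90° | per atom pair |
| weak hydrogen bond | C donor → N/O acceptor | 3.6 ≤ d ≤ 3.9 Å, 90° < θ < 130° | per atom pair |
| ionic | carboxylate O vs. Arg/Lys side-chain N | d ≤ 4.0 Å | once per residue pair |
| hydrophobic | apolar C vs. apolar C | d ≤ 4.0 Å | per atom pair |
| aromatic | ring atom vs. ring atom (His/Phe/Tyr/Trp) | any pair ≤ 4.0 Å | once per ring pair |

Decisions taken where the convention was ambiguous:

* The weak-bond angle window is stated in the source material in an
  unsatisfiable form ("90° > θ > 130°"); it is implemented as
  90° < θ < 130° and restricted to carbon donors (C–H···A), the common
  reading.  Both bounds are configurable.
* Histidine is neutral by default, so it never participates in ionic
  interactions unless `default_chemistry(his_charged = TRUE)` is used.
  Protonation cannot be read from a heavy-atom structure.
* Hydrophobic contacts are counted per apolar-carbon pair (the magnitude of
  published counts, ~1800 for a 650-residue protein, implies atom-pair
  counting); atom pairs between two rings already counted as an aromatic
  contact are excluded so the two classes do not double-count stacking.
* Antecedents are resolved geometrically (nearest same-residue heavy atom
  within 1.9 Å) rather than from a bonded-topology dictionary.  A donor
  with no antecedent (possible in coarse synthetic structures) passes on
  distance alone; this leniency is intentional and documented here.
* Intra-residue pairs, and backbone–backbone pairs of sequence-adjacent
  residues, are excluded as covalent neighbourhood.
* Detection scans polymer atoms only.  Waters and ligands are analysed by
  the dedicated zinc-site, ligand-contact and cleft-water operations.

Absolute interaction counts on real structures depend on the chemistry
dictionaries (which atoms count as apolar, which as donors), so exact
reproduction of counts from any particular third-party contact server is
*not* promised; the per-residue densities, percentages and scaled
comparisons computed *from* counts are exact arithmetic, and on synthetic
structures the detector is validated against an exhaustive pair-scan
oracle, class by class.

## Profiles and scaled comparison

A structure profile reports, per category, the absolute count and a
relative value: percentages for residue categories (helix, sheet, proline,
polar, charged, hydrophobic), per-residue densities for interaction
classes.  The default denominator is the number of *resolved* polymer
residues; percentages may instead be referred to the full sequence length
(`denominator = "full_length"`), because published comparisons mix both
conventions.  The residue-class sets are explicit package defaults
(charged = {Glu, Arg, Lys}; polar = {S,T,N,Q,Y,C,H}; hydrophobic =
{A,V,L,I,M,F,W,P}) and user-overridable — published polar/hydrophobic rows
may not be exactly reproducible because their sets are rarely stated.

`compare_profiles()` scales each category pair so the larger relative value
maps to 100, computing from *unrounded* relatives.  Published tables
sometimes scale from rounded intermediates; for such rows (e.g. densities
printed to 3 decimals) the scaled values can differ by a few tenths, which
is why the package's own tests allow 0.4 on those rows and are exact
elsewhere.  Presentation rounding (1 decimal for percentages and scaled
values, 3 for densities) happens only in the writers.

## Geometry

* **d₁, d₂** — Cα–Cα distances between residues 142–404 and 330–404 in the
  thermophile's author numbering; both selectors are arguments, the
  defaults are merely bound to that protein.  Conformer classes are
  labelled reference points in the (d₁, d₂) plane with a tolerance radius
  (default 1.5 Å); assignment is nearest-reference within tolerance, ties
  broken by scheme order, else `"unassigned"`.
* **Radius of gyration** — mass-weighted RMS distance from the centroid;
  unit masses by default, over backbone atoms (N, CA, C, O) when given a
  structure, matching the usual backbone-R_g convention for traces.
* **Superposition** — the Kabsch algorithm via SVD, proper rotations only
  (det = +1, reflections corrected through the sign of the smallest
  singular direction).  Collinear coordinate sets (second singular value
  numerically zero) are an error.  Cross-ortholog superposition requires an
  explicit residue correspondence (`read_correspondence()`), because
  pairing two different sequences is an alignment problem this package
  deliberately does not solve.
* **Zinc site** — first-shell cut-off 2.6 Å by default, a typical Zn–N/O
  first-shell distance; no value is canonical in the source material, so it
  is an argument everywhere.  Denticity of a coordinating carboxylate uses
  the same cut-off: `bi` needs both carboxylate oxygens inside it.

## Trajectory analytics

Trajectories are a topology plus ordered coordinate frames; the native
format is multi-model PDB because it is self-contained and synthesisable as
text.  Hydrogen-bond populations follow the
`100 · N(frames with bond) / N(frames)` definition at the tighter
trajectory criteria (3.0 Å, 135°), aggregated per protein residue and role
by summation — a residue accepting through two oxygens simultaneously
genuinely exceeds 100%, and that is informative, not an error.  Entries
below 5% are omitted from reports (threshold configurable; at threshold 0
the bookkeeping conserves total bond-frames exactly, which is tested).
Ligand residues get generic N/O donor+acceptor roles because a hetero
group's protonation is unknowable from the topology.

The cleft region is a union of spheres (default radius 8 Å) around either
fixed points or the Cα atoms of user-listed cleft-lining residues — the
literature never defines "trapped in the inter-domain cleft", so the
definition is explicit and configurable.  The water-expulsion estimate
multiplies the open/closed difference in mean cleft-water count by the
literature per-water release energy range 1.2–2.3 kcal/mol.

Accelerated-MD boost parameters follow the conventional dual-boost recipe:
threshold = mean energy + e·N with e_r = 1 kcal/mol per residue
(torsional) and e_a = 0.1 kcal/mol per atom (total), roughness
α_t = e_r·N_res/5 and α_T = e_a·N_atoms.  The α expressions are the
standard convention, stated here because the primary description defers to
prior work without printing them.  Energy-series interval summaries (for
externally computed MM-PBSA/GBSA series — the package never evaluates those
energy functions) tile the series in order, flag a trailing partial
interval, and format as `mean (±SD)` with sample SDs.

## Kinetics

`fit_michaelis_menten()` fits `v = V_max·S/(K_M + S)` by
Levenberg–Marquardt least squares, started from the closed-form Hanes–Woolf
linearisation (robust and initialisation-free).  With ≥ 3 labelled
replicates each replicate is fitted separately and parameters reported as
mean ± SD across replicates, matching the "average of three measurements
± SD" convention of experimental tables; otherwise SDs come from the fit
covariance.  A fitted K_M outside (0, 10 · max S) flags the fit as
saturation-unidentifiable; identical rates across all concentrations are an
error.  Efficiency is k_cat/K_M in M⁻¹s⁻¹ (K_M converted from µM).
Published efficiency columns are sometimes inconsistent in the last digit
with the printed K_M and k_cat (upstream rounding); the package always
reports the quotient of its own fitted values.

Thermal-inactivation profiles normalise residual activity to the maximum
(= 100%) and interpolate T₅₀ at the first downward crossing of 50%;
profiles that never cross have no T₅₀ rather than an extrapolated one.
`normalize = FALSE` accepts already-normalized percentages.  Temperature
and pH optima are reported descriptively (argmax of the measured series);
no model is fitted because none is fitted in practice.

## Synthetic data: what it does and does not emulate

The generators exist so that every analysis stage has a test oracle.  A toy
structure plants, in well-separated 30 Å grid cells: salt bridges (3.2 Å)
with decoys (4.5 Å), backbone hydrogen bonds (2.9 Å / 4.4 Å), weak C–H
bonds (3.75 Å at 110°, decoys below the window or at 150°), hydrophobic CB
pairs (3.6 / 4.3 Å), stacked Phe rings (3.6 / 5.0 Å), a pentacoordinated
zinc site with a bidentate Glu and a 3.0 Å second-shell decoy water, a
hetero dipeptide with polar contacts at 2.7/2.8/2.8/3.1 Å plus a 3.6 Å
decoy, cleft waters inside and outside an 8 Å region, and d₁/d₂ marker
residues at 22.6/18 Å (the crystal-form d₁ of the thermophile).  Breathing
trajectories realise an open/closed d₁ schedule exactly, ligand-bond
occupancies to the frame, phase cleft-water counts of 90 (open) and 40
(closed) — the published hydration contrast — zinc-water residence
fractions, and a bidentate→monodentate switch at 35% of the frames.

These structures are *chemically minimal and non-physical*: residues carry
only the atoms their planted role needs, geometries are idealised, and
there is no packing, no solvent structure, no force field.  Passing tests
therefore demonstrate that the *measurement operations* are correct —
detection, counting, population bookkeeping, phase statistics — not that
the package reproduces any particular experimental structure, whose
chemistry-dictionary sensitivity is discussed above.  Determinism is a
contract: every generator draws all randomness from its spec seed through
an RNG-state-preserving wrapper, and identical specs produce byte-identical
output files.

Problem sizes in the shipped tests were chosen to keep the full suite
around fifteen seconds: toy structures of a few hundred atoms, trajectories
of 20–100 frames (one 1000-frame trajectory exercises the 200-frame
residence threshold), 50 kinetic replicates.  All sizes are spec arguments;
nothing in the implementation assumes them.

## Known limitations

* No sequence or structure alignment, no automatic domain decomposition,
  no pKa/protonation prediction, no π–cation or halogen-bond typing.
* mmCIF reading is delegated to `bio3d::read.cif()` and shares its
  limitations; secondary-structure labels are read from PDB HELIX/SHEET
  records (or supplied by the user) and are not recomputed from geometry.
* `write_structure()` writes coordinates, not HELIX/SHEET metadata, so
  secondary-structure labels do not survive a write/read round trip.
* MM-PBSA/GBSA energies, force fields and trajectory generation are out of
  scope by design: the package consumes per-frame outputs and produces
  interval statistics.
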
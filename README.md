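# cleftscope

Structural and dynamical analysis of two-domain zinc peptidases in R.

Thermophilic enzymes buy their heat tolerance with structure: more
secondary-structure content, more prolines, and above all a denser network
of non-covalent interactions than their mesophilic orthologs — often at the
price of a more rigid, less adaptable active site and reduced activity.
`cleftscope` packages the analyses used to make that argument quantitative
for a two-domain zinc exopeptidase (dipeptidyl peptidase III, MEROPS family
M49), and is applicable to any protein with an inter-domain cleft:

* **Interaction profiling** — hydrogen bonds (donor–acceptor distance
  ≤ 3.9 Å, donor angle θ > 90°), weak C–H hydrogen bonds (3.6–3.9 Å,
  90° < θ < 130°), ionic interactions, hydrophobic and aromatic contacts
  (≤ 4 Å), absolute counts and per-residue densities, and scaled
  cross-structure comparison tables in which the larger relative value of a
  category maps to 100.
* **Conformation geometry** — inter-domain Cα–Cα distance coordinates
  (d₁, d₂) for open/closed conformer classification, backbone radius of
  gyration, Kabsch superposition RMSD, ligand polar contacts, and the zinc
  coordination sphere with per-carboxylate denticity (mono-/bidentate).
* **Trajectory analytics** over multi-model PDB trajectories —
  hydrogen-bond populations (`H_pop = 100 · N(frames with bond) / N(frames)`,
  summed per residue so values above 100% are meaningful), zinc-coordination
  dynamics, water residence, cleft-water counting, the water-expulsion
  energy estimate `ΔN · [1.2, 2.3]` kcal/mol, accelerated-MD dual-boost
  parameters, and interval summaries of externally computed MM-PBSA/GBSA
  energy series.
* **Kinetics** — Michaelis–Menten fitting (`v = V_max·S / (K_M + S)`,
  Levenberg–Marquardt from a Hanes–Woolf start), catalytic-efficiency
  ratios, relative-activity tables, and thermal-inactivation profiles with
  interpolated T₅₀.
* **Synthetic data** — seeded generators for toy structures, breathing
  (open/closed) trajectories and kinetic datasets, each with a ground-truth
  manifest, so every stage of the pipeline is testable without downloading
  anything.

## Worked example

Comparing a mesophilic and a thermophilic ortholog from their interaction
counts (647 and 524 resolved residues respectively):

```r
library(cleftscope)

meso <- structure_profile_from_counts(
  c(helix = 374, sheet = 86, hbond = 741, weak_hbond = 502, ionic = 94,
    aromatic = 127), n_resolved = 647, name = "BtDPP3")
thermo <- structure_profile_from_counts(
  c(helix = 332, sheet = 82, hbond = 606, weak_hbond = 431, ionic = 92,
    aromatic = 113), n_resolved = 524, name = "CaDPP3")
compare_profiles(meso, thermo)
#> Structural factors comparison: BtDPP3 vs CaDPP3
#>    category abs1   rel1 abs2   rel2 scaled1 scaled2
#>       helix  374 57.810  332 63.360    91.2     100
#>       sheet   86 13.290   82 15.650    84.9     100
#>       hbond  741  1.145  606  1.156    99.0     100
#>  weak_hbond  502  0.776  431  0.823    94.3     100
#>       ionic   94  0.145   92  0.176    82.7     100
#>    aromatic  127  0.196  113  0.216    91.0     100
```

Every scaled pair reads "per cent of the denser structure": the
thermophile wins every interaction category despite being 123 residues
smaller — the structural signature of thermostability.

Fitting synthetic replicate kinetics generated at the thermophile's
published parameters (K_M = 35.2 µM, k_cat = 3.07 s⁻¹, 5% noise):

```r
kd <- make_kinetic_dataset(kinetic_spec(noise_sd = 0.05, n_replicates = 3,
                                        seed = 11))
fit_michaelis_menten(kd$data, enzyme_conc = 0.01)
#> Michaelis-Menten fit (3 replicates, SD across replicates)
#>   KM    = 39.1 +- 2.4 uM
#>   kcat  = 3.147 +- 0.053 1/s  (Vmax = 0.03147, [E] = 0.01 uM)
#>   kcat/KM = 8.049e+04 1/(M s)
```

A synthetic toy structure carries a fully planted zinc site:

```r
toy <- make_toy_structure(toy_structure_spec())
zinc_site(toy$structure)
#> <zinc_site> A:901 - CN 5 at cutoff 2.6 A
#>    res res_name atom element distance
#>  A:144      GLU  OE1       O 2.000000
#>  A:138      HIS  NE2       N 2.100000
#>  A:140      HIS  NE2       N 2.150000
#>  A:910      HOH    O       O 2.200000
#>  A:144      GLU  OE2       O 2.300543
#> denticity: A:144 = bi
```

— the pentacoordinated zinc (two His Nε, a bidentate Glu carboxylate, one
water) characteristic of the family's active site.

See `vignettes/cleftscope-methods.Rmd` for the full account of the methods,
defaults and their rationale.

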
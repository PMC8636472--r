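# quadstruct

Topology, stability and dynamics of DNA G-quadruplexes (GQs) formed by the
`(G4C2)n` hexanucleotide repeat expansion of *C9orf72* — the most common
genetic mutation in ALS/FTD.  The repeat's coding strand folds into
antiparallel (GQ-AP) or parallel (GQ-P) four-stranded structures whose
balance shifts with the molecular crowding environment, and whose CpG
cytosines can carry 5-methylcytosine in patients.  `quadstruct` packages the
computations used to characterise these structures, for spectroscopists and
modellers working on repeat-expansion nucleic acids:

* **CD spectral analysis** — Savitzky–Golay smoothing, rule-based topology
  calls from the canonical signatures (GQ-AP: +295/−260 nm; GQ-P:
  +260/−240 nm), and constrained linear unmixing
  `S(λ) = x·AP(λ) + y·P(λ)` with `x + y = 1`, solved in closed form
  (`x* = Σ(S−P)(A−P) / Σ(A−P)²`).
* **Thermal melts** — four-parameter Boltzmann sigmoid
  `S(T) = S_low + (S_high − S_low)/(1 + exp((T − Tm)/w))` fitted to 295 nm
  melt curves, replicate averaging, and Student unpaired two-tailed
  comparison of melting temperatures.
* **Structure models** — PDB read/write, residue deletion, base mutation on
  the glycosidic frame, 3′ extension, strand joining, CpG 5-methylcytosine
  editing (`5CM`, methyl at C5 in the base plane), Hoogsteen tetrad
  detection (cyclic N1→O6 / N2→N7 contacts ≤ 3.5 Å), inter-tetrad K⁺
  placement, and deterministic idealized GQ builders.
* **Trajectory statistics** — Kabsch superposition, per-residue RMSD/RMSF,
  and per-tetrad buckle displacement (mean base-plane/tetrad-plane angle)
  with quartile summaries, from multi-model PDB trajectories.
* **Synthetic data** — seeded generators for basis spectra, crowding
  titrations, melt replicates, and rigid-tetrad/mobile-loop trajectories,
  so every analysis can be validated by parameter recovery.

## Worked example

```r
library(quadstruct)

## the repeat oligo and its CpG sites
s <- expand_repeat("GGGGCC", 3, "GGGG", name = "C9-22mer")
as.character(s)
#> "GGGGCCGGGGCCGGGGCCGGGG"
find_cpg_sites(s)        # 0-based positions of the three CpG cytosines
#> [1]  5 11 17

## a synthetic PEG-crowding titration, decomposed against the basis
b <- gen_basis_spectra()
series <- gen_titration_series(b, c(1, 0.6, 0.3, 0.05), noise_sd = 0.02, seed = 1)
titration_fractions(series, b)
#>      condition      x        y residual_ss
#> 1 frac_ap=1.00 0.9993 0.000668      0.0326
#> 2 frac_ap=0.60 0.6078 0.392187      0.0342
#> 3 frac_ap=0.30 0.3004 0.699604      0.0435
#> 4 frac_ap=0.05 0.0498 0.950167      0.0388
```

The recovered AP fraction `x` tracks the generator truth within noise and
`x + y = 1` holds exactly — the crowding titration's AP→P transition in
miniature.

```r
## melt-curve fit at the methylated-oligo midpoint
curves <- gen_melt_curve(tm = 84.3, noise_sd = 0.01, seed = 1, n_reps = 3)
fit_melt_curve(average_replicates(curves))
#> <melt_fit> Tm = 84.33 C, width = 3.02 C, plateaus [-0.00425, 1]

## idealized antiparallel model of the 22-mer and its tetrads
gq <- build_ideal_gq(s, "antiparallel")
detect_tetrads(gq)
#> <gq_tetrads> 4 tetrad(s)
#>   [0] residues A1-A10-A13-A22, mean H-bond 2.90 A
#>   [1] residues A2-A9-A14-A21, mean H-bond 2.90 A
#>   [2] residues A3-A8-A15-A20, mean H-bond 2.90 A
#>   [3] residues A4-A7-A16-A19, mean H-bond 2.90 A

## rigid-core / mobile-loop trajectory: loops dominate the fluctuations
traj <- gen_gq_trajectory(gq, sigma_tetrad = 0.2, sigma_loop = 1.0,
                          n_frames = 200, seed = 1)
aggregate(rmsf_A ~ resid, per_residue_rmsf(traj), mean)
#>   resid rmsf_A
#> 1    DC  1.728
#> 2    DG  0.345
```

The fitted `Tm` reproduces the generator midpoint within the replicate
noise; the four stacked tetrads each close a Hoogsteen cycle at 2.9 Å; and
the cytosine loop residues fluctuate ~5× more than the tetrad guanines,
the signature that tetrads rigidify the fold.

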
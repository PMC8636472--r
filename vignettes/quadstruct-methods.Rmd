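---
title: "Models and methods behind quadstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind quadstruct}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quadstruct)
```

`quadstruct` analyses DNA G-quadruplexes (GQs) formed by the `(G4C2)n`
hexanucleotide repeat of *C9orf72*, the most common genetic lesion in
ALS/FTD.  The package covers three experimental readouts end to end:
circular dichroism (CD) topology analysis, thermal stability at 295 nm, and
stability statistics of molecular-dynamics-style trajectories — together
with structure-model construction/editing and a synthetic-data module that
provides every input with known ground truth.  This vignette records the
models, the tunable parameters, and the design decisions that were
genuinely open.

## Constrained CD spectral decomposition

A measured spectrum is modelled as a linear combination of an antiparallel
(GQ-AP) and a parallel (GQ-P) reference spectrum,

$$ S(\lambda) = x\,A(\lambda) + y\,P(\lambda), \qquad x + y = 1 , $$

with $x$ chosen to minimise the squared residual sum.  Substituting
$y = 1 - x$ makes the problem one-dimensional with a closed form,

$$ x^* = \frac{\sum_\lambda (S - P)(A - P)}{\sum_\lambda (A - P)^2}, $$

which the implementation uses instead of an iterative optimiser; the test
suite checks it against a brute-force grid search over $x \in [0,1]$ at
$10^{-4}$ resolution.  Only the sum constraint is imposed: a spectrum
outside the span of the two references can return $x \notin [0,1]$, which is
informative (it flags that the two-component model does not hold).  The
`clip` option truncates to $[0,1]$ with a warning for users who want
strictly physical fractions; both behaviours are exposed because whether
the original optimisation was bounded is ambiguous.

Spectra live on a uniform 220–320 nm grid, 1 nm step, by default.  The
instrument scan range in the source protocol is quoted as "220–230 nm",
which is internally inconsistent with spectra that show features at 295 nm;
we read it as a typo for 220–320 nm and chose the default grid accordingly.
Ellipticity units are arbitrary but must be consistent between spectrum and
basis; no mdeg/Δε conversion is attempted.

Smoothing is Savitzky–Golay (`signal::sgolayfilt`) with 4 neighbours per
side and a 2nd-order polynomial by default — the filter reproduces any
quadratic exactly, so band positions of smooth spectra are not biased.

Topology classification is deliberately rule-based and qualitative,
mirroring how CD traces are read by eye: GQ-AP requires a positive 295 nm
peak dominating the 260 nm value; GQ-P requires a positive 260 nm peak with
a negative 240 nm trough.  Diagnostic values are extrema within ±3 nm; the
threshold is 10% of the maximum absolute ellipticity.  Both patterns at
once give `"mixed"`, neither gives `"non-GQ"`.  Quantitative population
statements should come from `decompose_spectrum()` ($x \ge 0.7$ AP-dominant,
$x \le 0.3$ P-dominant), not from the classifier.

## Thermal melts at 295 nm

The 295 nm band is specific to the antiparallel fold, so its temperature
dependence traces GQ unfolding.  Melt curves are fitted with the
four-parameter Boltzmann sigmoid

$$ S(T) = S_\mathrm{low} + \frac{S_\mathrm{high} - S_\mathrm{low}}
   {1 + e^{(T - T_m)/w}} , $$

the conventional two-state "sigmoidal fit" ($T_m$ = midpoint, $w$ =
transition breadth; no specific functional form is prescribed by the
source protocol, so the Boltzmann form was chosen and documented).  The
transition direction is not assumed: the plateau parameters are free, and
the width sign is normalised after fitting (negating $w$ and swapping the
plateaus leaves the curve unchanged).  Starting values are the 10th/90th
percentile signals, the steepest finite-difference slope for $T_m$, and a
tenth of the temperature span for $w$.  Fitting uses Levenberg–Marquardt
(`minpack.lm::nlsLM`) without box constraints — bounds provoked spurious
singular-gradient failures for transitions near the end of the ramp — and
validity is gated afterwards: optimiser convergence, amplitude above five
times the residual noise, $R^2 > 0.8$ against a constant-signal model, and
$T_m$ within the measured range ±10 °C.  Curves failing any gate are
returned with `converged = FALSE` and `tm = NA` rather than a number.

Two caveats the gates are designed to surface: with the instrument range
ending at 90 °C and $T_m \approx 84$ °C, the post-transition plateau is
weakly constrained, and a melt whose midpoint lies beyond the ramp shows
only a drifting baseline — such fits must be flagged, not extrapolated.

`compare_tm()` is a Student pooled-variance unpaired two-tailed t-test by
default (`welch = TRUE` switches), with mean ± SEM reported per group and
the degenerate zero-variance/equal-means case returning $p = 1$ by
convention.

## Structure models and editing

Atomic models are flat atom tables (`gq_structure`) read and written as
PDB via `bio3d`, with standard chemical-component names: `DA/DC/DG/DT`,
`5CM` (5-methyl-dC), `BGM` (8-bromo-dG), `K`.  Hydrogens are optional
everywhere; every geometric criterion uses heavy atoms only, so models
from X-ray/NMR depositions work unmodified.

Editing operations reproduce the classic GQ model-building recipe: residue
deletion (numbering untouched), base mutation on the glycosidic frame
(sugar kept, base replaced by an idealized template aligned on C1′, the
glycosidic nitrogen and its ring neighbours; `BGM`→`DG` simply removes the
bromine), 3′-extension by a template nucleotide (P placed 1.60 Å along the
C3′–O3′ direction), strand joining with renumbering and explicit junction
gap records, and CpG methylation (methyl carbon `C5A` in the base plane,
1.50 Å from C5, pointing away from the ring centroid).  Edited models are
*not* energy-minimised — minimisation is out of scope — so `count_clashes()`
and the junction-gap table are provided to make the unrefined status
visible; junction gaps of an unminimised join are large by construction
and are reported, not hidden.

Tetrad detection looks for directed 4-cycles of guanines in which each
guanine's Watson–Crick edge donors reach the next guanine's Hoogsteen
acceptors, N1→O6 and N2→N7, both within a 3.5 Å heavy-atom cutoff
(donor–acceptor distances, not hydrogen geometry).  Overlapping candidate
quartets are resolved greedily by smallest total donor–acceptor distance.
Tetrad planes are total-least-squares fits over the 4×9 purine ring atoms;
the stack axis is the first principal component of the tetrad centroids,
oriented so the tetrad holding the 5′-most guanine has `stack_index` 0.
One K⁺ is placed per adjacent tetrad pair at the midpoint of their O6
centroids (the carbonyl cage), giving $n-1$ ions for $n$ tetrads.

`build_ideal_gq()` constructs deterministic idealized models: a canonical
planar guanine template is placed C4-symmetrically so the Hoogsteen
distances are ≈2.9 Å and the O6 channel radius ≈2.4 Å (the in-plane
placement was solved once, numerically, and is frozen as package
constants), tetrads are stacked with 3.3 Å rise and 30° twist, and loop
residues ride on outer arcs (13 Å radius) between their flanking tracts.
Residues carry base heavy atoms plus C1′ — enough for tetrad detection,
plane/buckle analysis, methylation editing, and synthetic trajectories.
One deliberate simplification: the quartet arrangement is identical for
both topologies, as it is in real GQs, where antiparallel strands are
accommodated by syn/anti glycosidic torsions rather than a different
quartet.  A base+C1′ model cannot express a glycosidic torsion, and
flipping whole bases provably breaks the Hoogsteen cycle (we verified the
corresponding C2-symmetric placement has no clash-free solution), so the
topologies differ in strand threading: parallel runs every tract up the
stack, antiparallel alternates direction.  `build_tetramolecular_gq()`
builds a four-strand parallel fixture with *full* heavy-atom nucleotides so
the strand-editing recipe (delete/mutate/append/join) can be exercised.

## Trajectory statistics

Trajectories are multi-model PDB (binary MD formats are out of scope).
Superposition is the Kabsch algorithm via SVD with the proper-rotation
determinant correction.  Conventions, since the analysis protocol leaves
them open:

* **Per-residue RMSD** — each frame is superposed on frame 1 over the
  tetrad-guanine heavy atoms (the rigid core), and each residue's
  heavy-atom RMSD is averaged over frames.
* **Per-residue RMSF** — frames are superposed on the time-averaged
  structure with one re-superposition iteration;
  $\mathrm{RMSF} = \sqrt{\langle |r(t)-\bar r|^2 \rangle_t}$ per atom,
  averaged unweighted over each residue's heavy atoms (not mass-weighted).
* **Buckle displacement** — not given a formal definition in the source
  analysis; defined here as the mean over the four guanines of the angle
  between each base-ring plane normal and the tetrad mean-plane normal,
  folded into [0°, 90°].  It reduces to the classic base-pair buckle notion
  and is 0° for an ideal planar tetrad.  A signed variant (sign from the
  base-centroid displacement along the stack axis) is available because
  published violin plots of such quantities often include negative values;
  the unsigned mean is the default.  Summary quartiles use the
  linear-interpolation convention (R type 7) so violin summaries are
  reproducible.

## The synthetic-data module

No raw spectra, melts or trajectories are publicly deposited for this
system, so the generators define the study conditions with known ground
truth and the analysis layer is validated by parameter recovery:

* **Basis spectra** — Gaussian bands at the canonical positions (+295/−260
  nm for AP, +260/−240 nm for P).  Only positions and signs are
  constrained by the CD signatures; widths of 8–12 nm and unit amplitudes
  were chosen once to resemble typical GQ spectra.
* **Titrations** — $f_i\,A + (1-f_i)\,P$ plus iid Gaussian noise, default
  fractions 1/0.6/0.3/0.05 emulating a 0–30% PEG-200 series.
* **Melts** — the Boltzmann sigmoid on the 25–90 °C instrument grid at
  0.5 °C steps, noise 1% of amplitude, 3 replicates — the reported
  experimental design ($n = 3$, mean ± SEM).
* **Trajectories** — the ideal model plus iid Gaussian displacement with
  $\sigma_\mathrm{tetrad}$ for tetrad guanines and $\sigma_\mathrm{loop}$
  for everything else (defaults 0.2/1.0 Å, encoding the observation that
  loops dominate structural fluctuation), optional random global rigid
  motion per frame.  Residue classes come from `detect_tetrads()` on the
  input model, never from hard-coded indices.

Every generator takes an explicit seed, uses a local RNG stream, and
restores the global RNG state.  What passing recovery tests shows — and
does not show: decomposition, melt fitting and RMSF/RMSD recover known
generator parameters at the stated noise levels (e.g. fitted $T_m$ within
0.5 °C at 1% noise and $n=3$; loop/tetrad RMSF ratio within 15% at 500
frames; RMSF $\to \sigma\sqrt{3}$ within 5%).  The generators contain no
physics: no force field, no solvent, no correlated motion, no baseline
drift or instrument artefacts.  Agreement on synthetic data validates the
estimators, not the biology of real samples.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the statistical claims are stable: 101-point
spectra, 131-point melt curves with 100-replicate recovery sweeps,
22-residue (246-atom) ideal models, and 500-frame trajectories for the
asymptotic RMSF checks (shorter ones elsewhere).  Determinism: every
stochastic test and the acceptance script fix their seeds; structure
construction and detection are fully deterministic, with detection
tie-breaks resolved by total distance.  Degenerate inputs are first-class:
flat melts flag non-convergence, identical basis spectra raise a
degenerate-basis error, single-frame trajectories refuse RMSF, fewer than
two tetrads place no ions (with a warning), and superposition refuses
collinear or <3-atom selections.

## Known limitations

* Idealized models are unrefined rigid-template geometry; they are
  analysis fixtures and starting points, not substitutes for minimised
  structures.  Junction gaps after `join_strands()` are reported precisely
  because they are unphysical until refined.
* The editing recipe reproduced from the published model construction
  yields per-strand `GGGGGC` (G·C-containing loops) rather than the
  repeat's C·C loops; the operations reproduce the stated steps verbatim
  and do not second-guess them.
* Only the given strand is scanned for CpG sites (the methylated oligo is
  the coding strand itself); no reverse-complement scanning.
* Two-component unmixing only; no multi-basis or SVD spectral family
  analysis, no van't Hoff thermodynamics, no hydrogen-bond occupancy or
  conformer clustering of trajectories.
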
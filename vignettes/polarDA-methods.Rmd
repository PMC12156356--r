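---
title: "Reactivity models and numerical choices in polarDA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactivity models and numerical choices in polarDA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarDA)
```

`polarDA` turns ground-state electronic-structure summaries of dienes and
dienophiles into reactivity predictions for (4+2) cycloadditions. This
vignette documents the models it implements, the defaults and why they
were chosen, what the synthetic-data generator does and does not emulate,
and the numerical decisions a maintainer would want written down.

## Global reactivity indices

For a species with frontier-orbital energies $E_H$ and $E_L$ (eV), the
package uses the standard frontier approximations of conceptual DFT:

$$\mu \approx \tfrac{1}{2}(E_H + E_L), \qquad
  \eta \approx E_L - E_H, \qquad
  \omega = \frac{\mu^2}{2\eta}, \qquad
  N = E_H(\mathrm{Nu}) - E_H(\mathrm{TCE}).$$

All energies are carried in eV internally; hartree input is converted on
read with the fixed constant 27.2114 eV/hartree. The nucleophilicity
scale is anchored at tetracyanoethylene (TCE): the user supplies a
reference record with `role = "reference"`, ideally computed at the same
theory level (a `level_tag` mismatch warns rather than errors, because
the tag is free text and false mismatches would be common).

A zero HOMO–LUMO gap is accepted at I/O (records are raw data) but
rejected by `chemical_hardness()`, since every downstream index divides
by $\eta$. The frontier approximation is used exactly as written; no
finite-difference ionization-potential variant is offered.

### Scale classification

The literature scales the package defaults to are: electrophiles strong
at $\omega \ge 1.50$ eV, moderate in $[0.80, 1.50)$, marginal below;
nucleophiles strong at $N \ge 3.00$ eV, moderate in $[2.00, 3.00)$,
marginal below, with a superstrong flag at $N \ge 4.00$ eV. Boundary
values are assigned to the higher class — a documented closed-lower-bound
tie rule, so classification is deterministic. All cut-offs are plain data
in `default_thresholds()` and can be replaced wholesale.

## Parr functions and local indices

The electrophilic Parr function $P^+_k$ is the per-atom Mulliken spin
density of the vertical radical **anion**, the nucleophilic $P^-_k$ that
of the vertical radical **cation**. This mapping deserves emphasis: it is
the convention of the Parr-function literature, and reversing it silently
flips every regiochemistry prediction. Records carry a free-text
provenance tag rather than an enforced "vertical vs relaxed" flag, since
input data cannot be re-derived at this layer.

Raw spin-density vectors are accepted when their sum is within 0.05 e of
unity (Mulliken sums deviate slightly) and renormalized to exactly 1
before use, so the condensation $\omega_k = P^+_k\,\omega$,
$N_k = P^-_k\,N$ conserves the global values exactly
($\sum_k \omega_k = \omega$, $\sum_k N_k = N$; the test suite checks this
to 1e-10). Negative components — a known artifact of Mulliken
partitioning — are retained in the tables but excluded from
reactive-center argmax selection unless no positive candidate exists.

The reactive-center search is restricted to the record's
`reactive_atoms` when given, otherwise to all carbon atoms, otherwise to
all atoms. Exact ties break toward the lowest atom index and raise a tie
flag that propagates into pair assessments as `borderline`.

## Pair assessment rules

Three rules, applied per diene/dienophile pair by `assess_all()`:

* **Polarity.** $\Delta\omega = |\omega_1 - \omega_2|$; the pair is
  classed polar when $\Delta\omega$ strictly exceeds 1 eV, non-polar
  otherwise. The threshold is an argument; equality is classified
  non-polar with a borderline flag (a strict reading of the rule, chosen
  so the flag — not a silent coin flip — marks the knife edge).
  $\Delta\omega$ is defined as an absolute difference: the code never
  assumes which partner is the stronger electrophile.
* **Flux direction.** Electron density flows downhill in chemical
  potential: forward (diene to dienophile) when
  $\mu_{diene} - \mu_{dienophile} > 10^{-6}$ eV, reverse when below
  $-10^{-6}$, undetermined inside the dead band. The tolerance exists
  solely to keep floating-point noise from flipping signs.
* **Regiochemistry.** The predicted first-formed bond pairs the diene's
  top-$N_k$ atom with the dienophile's top-$\omega_k$ atom. Labels are
  emitted as atom-pair strings (`"C4-C2"`); no attempt is made to name
  regioisomeric products, since product nomenclature depends on the
  user's numbering scheme.

## The Hammett model

`hammett_fit()` regresses the polarity index on a substituent-constant
scale, $\Delta\omega = \rho\,\sigma + c$, by exact closed-form ordinary
least squares (no iterative optimizer; refitting identical data gives
bit-identical coefficients). The Pearson $R$ is reported signed; the
scale comparison ranks by $|R|$ with alphabetical tie-break and tie flag.
At least three complete points are required per scale, and rows missing
either variable are dropped listwise per scale. No multiple-testing
correction is applied across scales — the comparison is descriptive
ranking, not inference.

The shipped constant table covers H, Me, OMe, OH, NMe2, F, Cl, Br, CF3,
CN and NO2 on the $\sigma_p$, $\sigma^+$, $\sigma_R$ and $\sigma_I$
scales, following the standard Hansch–Leo–Taft compilation; it is
ordinary data and any user table with the same columns overrides it.
Note that $\sigma^+$ is nearly collinear with $\sigma_p$ over common
para substituents, so the ranking between those two scales on noisy data
is not very meaningful; the informative comparisons are against
$\sigma_R$ and $\sigma_I$.

## ELF topology

The ELF is computed in the closed-shell Becke–Edgecombe form,

$$\mathrm{ELF} = \frac{1}{1 + (D/D_h)^2}, \qquad
  D = \tau - \frac{|\nabla\rho|^2}{8\rho}, \qquad
  D_h = \tfrac{3}{10}(3\pi^2)^{2/3}\rho^{5/3},$$

with the density gradient taken by central differences on the grid
(one-sided at the boundary; oblique axes are handled through the inverse
of the step-vector matrix). A spin-resolved variant is out of scope: the
species this package targets are closed-shell singlets. Small negative
$D$ values from numerical noise are clamped to zero, and ELF is set to 0
where the density is below `rho_floor`.

**Accuracy caveat.** Finite-difference gradients of an exponentially
decaying density are unreliable in the far tails: the relative truncation
error grows like $(h\,|x|/w^2)^2$ for decay length $w$ and spacing $h$,
and since $D$ is compared against $D_h \propto \rho^{5/3}$, tail noise
maps onto spurious ELF values near 1. Two defenses are built in: the
default grid spacing is 0.1 bohr (the conventional production choice,
configurable), and `elf_basins()` zeroes the ELF wherever the density is
below the unassigned-charge floor before searching for attractors, so
tail voxels cannot seed basins. Users supplying coarser cubes should
expect basin populations to degrade before descriptor-level quantities
do.

### Attractors, basins, populations

* Attractors are 26-connected local maxima; grid-adjacent maxima
  (plateaus) and maxima closer than the merge radius (default 0.2 bohr)
  coalesce to their field-weighted centroid, with a plateau flag when a
  coalesced group shares one value. A constant field is an error, not an
  answer.
* Basin assignment is discrete steepest ascent: each voxel steps to its
  highest 26-neighbor until a maximum is reached. Ties between
  equal-valued neighbors break toward the lowest linear voxel index — an
  arbitrary but documented and deterministic rule, applied identically in
  the fast pointer-doubling implementation and in the test suite's
  independent per-voxel path-following oracle. Voxels with density below
  the floor (default 1e-6 e/bohr³) stay unassigned and their charge is
  reported separately, so basin populations plus unassigned charge equal
  the grid integral by construction.
* Synapticity: a basin whose attractor lies within the core radius of a
  heavy nucleus (defaults 0.5 bohr for Z ≤ 10, 0.9 bohr for 11 ≤ Z ≤ 36,
  configurable as a function of Z) is a core basin C(A). Otherwise the
  basin's atom set collects heavy atoms whose core region is within one
  voxel diagonal of the basin and hydrogens within 1.2 bohr of it
  (protons have no core basin). One atom → monosynaptic V(A), two →
  disynaptic V(A,B), three or more → polysynaptic. Several basins on one
  atom set get primes (V, V′, V″) and are summed by `merge_equivalent()`
  for reporting, mirroring the convention of combined V+V′ populations.
* Lewis summary thresholds: combined disynaptic populations of
  1.6–2.6 e read as single bonds, ≥ 3.2 e as double bonds, the window
  between as "intermediate" and below 1.6 e as "partial"; monosynaptic
  populations divided by two and rounded give lone-pair counts. These
  windows bracket the populations typical of C–C single and double bonds
  in ELF analyses of conjugated systems; they are arguments, reported
  with every summary, not constants.

## The synthetic-data generator

The generator exists so that every stage has fixtures with known ground
truth. What it emulates, and what it does not:

* `gen_record()` inverts the frontier formulas, so a generated record
  reproduces its prescribed $(\mu, \eta, \omega, N)$ exactly (tested to
  1e-10); its spin densities are random unit-sum vectors with optional
  exact site symmetry (`gen_asd()`, with a peakedness parameter whose
  large-concentration limit is a one-hot vector, computed in log space to
  avoid underflow). It does **not** emulate basis-set sensitivity or the
  sign structure of real Mulliken populations beyond allowing negative
  entries on input.
* `gen_hammett_series()` draws
  $\Delta\omega_i = c + \rho\,\sigma_i + \varepsilon_i$ with
  homoscedastic Gaussian noise over an eight-member para-substituent
  design (H through NO2, $\sigma_p \in [-0.27, 0.78]$). The default
  noise, 0.05 eV, was fixed once so that the expected correlation
  strength of a generated series sits in the $R \approx 0.97$–$0.99$
  regime typical of substituent-effect correlations of this kind — i.e.
  so the fixtures exercise the fitter in the realistic regime rather than
  at near-perfect linearity. Real series differ in having correlated,
  possibly heteroscedastic deviations; a generated series says nothing
  about which physical scale *should* correlate best.
* `gen_gaussian_field()` builds $\rho = \sum_i q_i\,\mathcal{N}(c_i,
  w_i^2)$, so per-center integrals are known analytically; a companion
  kinetic-energy field $\tau = |\nabla\rho|^2/(8\rho) + a\,D_h$ with
  $a = \sqrt{1/t - 1}$ makes the exact ELF equal a chosen constant $t$,
  and an optional bump-shaped ELF surrogate provides fields with known
  attractor positions for the basin machinery. Analytic Gaussians decay
  far faster than molecular densities and have no shell structure; basin
  tests on them validate the machinery, not chemical realism.

All generators take an explicit seed, use R's Mersenne-Twister stream,
one stream per call, and restore the caller's RNG state, so identical
arguments give identical output and generator calls never perturb user
code.

## Problem sizes and test design

The shipped suite validates the algebraic identities on $10^4$ randomly
generated records; fits 200 seeded replicate series ($n = 8$, noise
0.05 eV) for slope recovery and coverage of the $\pm 2\,\mathrm{SE}$
interval; and checks basin labels against the brute-force ascent oracle
on twenty random smooth $20^3$ fields plus analytic two-Gaussian fixtures
(populations within 1%, charge conservation within 0.5%, stability under
halving the grid spacing within 1%). These sizes were chosen as the
smallest at which the stochastic checks are stable across seeds.

`scripts/acceptance.R` reports the Pearson $R$ of the $\sigma_p$ fit for
three generated dienophile-family series (shared slope 0.8 eV per sigma
unit; intercepts 0.9, 1.1 and 1.5 eV encoding the increasing baseline
polarity from nitroethenes through their α-bromo to their α-cyano
analogs, the last polar for every substituent). No measured
per-compound $\Delta\omega$ tables ship with the package, so these
series are labelled synthetic stand-ins; the script computes every
reported number at run time from the seed it is given.

## Known limitations

* Descriptors are frontier-orbital approximations at the ground state;
  no transition-state quantities (activation energies, electron-density
  transfer at the TS) and no endo/exo stereoselectivity are computed.
* ELF quality is bounded by the input grids (see the accuracy caveat);
  there is no analytic wavefunction evaluation, and no AIM/QTAIM charge
  analysis.
* The cube reader supports the standard scalar layout only (no orbital
  data sets); raw engine log files are out of scope by design — any
  engine's output can be mapped onto the documented JSON/CSV record
  schema.
* Atom numbering is taken from the user's records and never inferred;
  regio labels are only as meaningful as that numbering.
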
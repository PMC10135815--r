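---
title: "Modelling mass effects on phase separation of disordered protein segments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling mass effects on phase separation of disordered protein segments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgslab)
```

## The scientific question

Isotope labelling (²H/¹³C/¹⁵N) and the insertion of short non-interacting
peptides both change the mass of a protein without materially changing its
interactions.  `cgslab` implements a coarse-grained model built to ask how such
mass changes alter liquid–liquid phase separation (LLPS) of intrinsically
disordered FUS segments: the 50-residue prion-like domain (PLD, FUS 1–50,
2 negative charges) and the RGG3 segment (RGG, FUS 453–502, 6 negative and
9 positive charges).  Mass enters Langevin dynamics through both the inertia
and the thermostat, so at equal temperature heavier beads move more slowly.
The package provides the model, the slab-geometry simulations, and the
observables used to quantify the consequences for phase behaviour.

## The model

Each residue is one bead at its Cα position.  Three energy terms act between
beads, with all constants in GROMACS-style units (nm, ps, kJ/mol, amu):

* **Bonds.** Adjacent beads in a chain interact through
  $U_b(r) = K_b (r - r_0)^2$ with $K_b = 20{,}000$ kJ nm⁻² mol⁻¹ and
  $r_0 = 0.38$ nm.
* **Lennard-Jones.** All non-bonded pairs interact through
  $U_{LJ}(r) = \varepsilon\left[(\sigma/r)^{12} - (\sigma/r)^6\right]$ with
  $\sigma = 1$ nm and $\varepsilon = 0.001$ kJ/mol; any pair involving an
  inserted glycine uses $\varepsilon_\text{insert} = 10^{-5}$ kJ/mol, which
  renders the insert effectively non-interacting.  Note the prefactor: this
  form carries no conventional factor 4, so its well depth is
  $\varepsilon/4$.  `force_field(lj_prefactor_mode = "standard_4eps")`
  provides the conventional form for comparison.
* **Debye–Hückel electrostatics.**
  $U_{DH}(r) = K_\text{coulomb}\, B(\kappa)\, q_i q_j\, e^{-\kappa r} /
  (\epsilon r)$ with $K_\text{coulomb} = 138.94$ kJ mol⁻¹ nm e⁻²,
  dielectric $\epsilon = 80$, charges $-1$ for D/E and $+1$ for K/R, and
  $\kappa = 3.2\sqrt{C_\text{salt}}$ nm⁻¹.  The two studied conditions are
  10 mM salt ($\kappa = 0.32$ nm⁻¹, essentially unscreened) and a no-charge
  condition that removes the term entirely.  The salt coefficient
  $B(\kappa)$ is not specified beyond "salt-dependent"; the package defaults
  to $B = 1$ and exposes it as a plain parameter.

Mass variants set every non-inserted bead to 1.0, 1.1, 1.2, 1.3 or 1.5 bead
mass units; glycine-inserted variants (`tail10`: 10 glycines appended,
`head5tail5`: 5 + 5) keep mass 1.0 per bead, so the 60-bead `tail10` chain
has exactly the total mass of the 50-bead mass-1.2 chain.

Temperatures are reported in reduced units of $T_0 = 100$ K and times in
$\tau = 1$ ns, with $k_B = 0.0083145$ kJ mol⁻¹ K⁻¹.

### A note on energy scales

Taken at face value, $\varepsilon = 0.001$ kJ/mol is four orders of magnitude
below $k_B T_0 = 0.83$ kJ/mol, so the cohesive energy of the model cannot
sustain an equilibrium condensate at these temperatures; the dynamics,
by contrast, are fully consistent with this unit system (a free 50-bead
mass-1.0 chain at 2.0 $T_0$ has a predicted z motion rate of ≈ 92 Å/τ,
matching the scale reported for the weakly interacting slab).  The package
therefore treats the printed constants as authoritative and interprets the
short-run density observables kinetically: starting from a condensed slab,
lighter chains disperse faster, which is precisely the mobility mechanism the
mass comparison probes.  Users wanting a thermodynamically condensing variant
can simply raise `eps`; every observable works unchanged.

## Simulations

Dynamics are integrated with the BAOAB splitting of Langevin dynamics
(chosen for its accuracy in configurational averages at moderate friction)
at a 2 fs time step and friction 1 ps⁻¹.  Bead mass appears in the inertia
and in the thermostat noise amplitude $\sqrt{k_B T/m}$, so the
fluctuation–dissipation balance holds at every mass.  Non-bonded
interactions are truncated and energy-shifted; default cutoffs are 3.0 nm
(LJ) and 3.5 nm (electrostatics), both configurable.  Directly bonded pairs
are excluded from the non-bonded terms (the stiff bond dominates at that
distance); 1–3 pairs and beyond are included.  Pair search uses a cell-list
built Verlet list with a 0.3 nm skin, rebuilt when any bead has moved half a
skin; list energies equal an $O(N^2)$ double loop exactly, which the test
suite asserts.

The slab protocol follows the direct-coexistence method: chains are packed
as self-avoiding random walks into the central fifth of the elongated box
(31 × 31 × 300 nm for the 10,000-bead systems, 34 × 34 × 300 nm for the
12,000-bead glycine-inserted systems), relaxed at the target temperature,
then run in NVT production with frames on a 0.5 τ grid.  The published
pre-equilibration (cubic NVT + NPT) is path equivalent for coexistence
observables; constructing the compact slab directly avoids an unspecified
barostat.  On-step velocities carry an $O((\omega\,dt)^2)$ kinetic-energy
discretisation bias from the stiff bonds (about 2–4 % at 2 fs); thermostat
validation therefore uses a smaller step where that bias is subdominant to
the sampling error, and the bias magnitude is documented here rather than
hidden.

## Observables

* **Density contrast** $P_H - P_L$: the z axis is cut into 30 windows; the
  occupancy fraction $P_\gamma = m_\gamma/N$ is averaged over the analysis
  window and the difference between the highest and lowest window is the
  order parameter for phase separation.
* **Condensed-phase centering**: the slab centre is the circular (periodic)
  mean of bead z; each chain's coordinate is the minimum-image distance
  $|z|$ of its centre of mass from that centre, binned into 30 windows of
  5 nm (for the 300 nm box).
* **z motion rate**: mean absolute chain-CM z displacement per τ on the
  0.5 τ grid, using unwrapped coordinates (Å/τ).
* **Flux**: chains crossing the condensed-phase boundary per τ.  The
  boundary is the pair of planes at $|z - z_c| = 25$ nm; the published
  indicator (written in absolute box coordinates of a 3000 Å box) is
  available via `flux(..., convention = "printed")`.
* **Conformation and contacts**: head-to-tail distance D (excluding inserted
  glycines), and opposite-charge contact counts within 12 Å (same chain,
  E_intra) or 15 Å (different chains, E_inter, credited to both partners —
  the published model leaves the attribution unspecified; crediting both
  partners is the package's documented choice).  Contact observables are meaningful only for charged
  systems (RGG at 10 mM).  Profiles along $|z|$ omit observations beyond
  140 nm, where the dilute tail touches the box boundary.

The analysis convention is the last fifth of the production run (the
published runs analyse the last 1000 τ of 5000 τ); shortened desk runs
analyse the analogous fraction.  The frame at t = 0 is the constructed
initial condition: it seeds the first motion interval but is excluded from
state averages.

## Critical temperature

Two estimators are provided and reported side by side, because the published
analysis is compatible with either:

* `tcr_threshold()`: linear interpolation of the first downward crossing of
  $P_H - P_L$ through 0.07, the threshold below which phase separation is
  considered gone (0.15 marks "obvious" phase separation; `classify_llps()`
  labels series by both).
* `tcr_fit()`: least squares for $P_H - P_L = A\,(T_{cr} - T)^\beta$, the
  binodal power law.  $A$ is profiled analytically, the remaining search is a
  deterministic multi-start, and $\beta$ is either free or pinned at 0.325
  (the 3D Ising exponent, a conventional default where no value is stated).  The fit
  returns a classed model object with the usual `coef`, `predict`, `plot`,
  `summary`, `residuals` and `simulate` methods.

On synthetic binodals the fit recovers its generating parameters to
$10^{-6}$ without noise, and the median $T_{cr}$ over replicates stays
within 2 % of truth under 1 % noise; both properties are asserted in the
test suite.

## Synthetic data

`make_sequence()` builds charge-composition-matched sequences (the tests use
compositions 2/0 and 6/9 to mirror PLD and RGG), `make_scripted_trajectory()`
builds single-bead-chain trajectories whose motion statistics are hand
countable, `make_slab_configuration()` builds static slabs with recorded
window occupancy, and `make_binodal()` draws from the power law with optional
Gaussian noise.  Every generator is deterministic under its seed and carries
its construction record, so each downstream metric is tested against ground
truth computed by construction rather than by the code under test.  These
generators emulate the *statistical* structure the metrics consume; they do
not emulate condensate microstructure, interfacial fluctuations or
sequence-specific interactions, so passing metric tests validates the
analysis code, not the realism of any particular simulation.

## Desk-scale study design

The full published scale (200 chains × 5000 τ at 2 fs ≈ 2.5 × 10⁹ steps per
condition) is far beyond a single-CPU test run.  The `desk` preset scales the
study to 30 chains × 20 beads in a 15 × 15 × 75 nm slab box, 0.05 τ
relaxation and 1.0 τ production, frames every 0.1 τ with motion metrics on
the defining 0.5 τ grid, a flux boundary of Lz/12 (the published 25/300
geometric ratio), and a 1.5 nm LJ cutoff — at $\varepsilon = 0.001$ kJ/mol
the truncated tail is below $10^{-4}\,k_B T$, so the shorter cutoff is a
cost choice with no physical consequence for these runs.  At this scale the
density contrast of the dispersing slab and the z motion rate reproduce the
mass orderings (heavier ⇒ denser and slower at equal temperature) and the
temperature trend of the density contrast.  The flux ordering (heavier ⇒
fewer boundary crossings) is clear at the cold end, where a condensed slab
still exists, and in the fully dispersed hot limit, but at intermediate
temperatures it crosses over: the desk boundary sits inside the initial
slab, so the lighter system can already have emptied the boundary region
while the heavier one still feeds it, and the two flux means tie within
counting noise.  These are transient-regime observations consistent with
the mobility mechanism; they are not equilibrium binodals, and the desk
runs make no claim about $T_{cr}$ itself.

```{r desk-example, eval = FALSE}
g <- experiment_grid(systems = "neutral20", mass_scales = c(1.0, 1.5),
                     charge_modes = "no_charge", temperatures = c(1, 2, 4),
                     seeds = 1, preset_name = "desk",
                     sequences = list(neutral20 = make_sequence(20, 0, 0, 1)))
res <- run_grid(g)
aggregate(cbind(ph_pl, z_rate, flux) ~ mass_scale + temperature, res, mean)
```

## Numerical choices and degenerate inputs

* Tie-breaks: window binning is half-open and lower-inclusive; a coordinate
  at exactly Lz/2 from the centre falls in the last $|z|$ window.
* Placement rejects beads within 0.5 nm of another chain (and of non-bonded
  beads of its own chain), with a bounded retry count; failure reports the
  bead density at which packing became infeasible.
* Bead overlaps below $10^{-6}$ nm in the energy path are reported as
  errors rather than silently evaluated.
* `tcr_fit()` refuses series with fewer than three points above the
  disappearance threshold; `tcr_threshold()` reports one-sided censoring
  when the series never crosses the threshold.
* The thermostat noise stream is a dedicated deterministic generator seeded
  from the R session seed; trajectories are bitwise reproducible for a fixed
  seed on a given platform at thread count 1.

## Known limitations

* The LJ scale is homopolymeric: no residue-specific interaction strengths
  (hydrophobicity scales), no π-based terms.
* Electrostatics are cutoff Debye–Hückel, not Ewald; fine for the screened,
  weakly charged systems modelled here.
* No barostat: the published NPT pre-equilibration leg is replaced by direct
  slab construction plus NVT relaxation.
* Desk-scale runs probe the kinetic regime (see the energy-scale note
  above); reproducing equilibrium coexistence densities requires either the
  full published scale or a larger `eps`.
* The RGG segment boundary is sometimes quoted as residue 501 and sometimes
  as 502 in the literature on this construct; the packaged fixture uses
  453–502 (50 residues), which reproduces the published charge census
  exactly.
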
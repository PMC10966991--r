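---
title: "Differentiable implicit-solvent dynamics: models, gradients and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differentiable implicit-solvent dynamics: models, gradients and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gbdms)
```

## The problem

Implicit-solvent force fields replace discrete water with a continuum
dielectric. They are fast, but standard parameter sets over-compact
intrinsically disordered proteins (IDPs) and over-stabilise helices. gbdms
implements, at desk scale, the machinery needed to *train* such a force
field by differentiable molecular simulation: run Langevin dynamics, compare
the distribution of residue--residue distances against reference statistics,
and push gradients of that comparison back through the integrator into the
force-field parameters.

## The potential

The potential is an Amber-style protein force field plus a Generalized-Born
(GB) solvation model, in units of nm, ps, kJ/mol, e and K (angles in
radians):

* harmonic bonds $k_b (r - r_0)^2$ and angles $k_a (\theta - \theta_0)^2$
  (not trainable);
* periodic proper torsions $\sum_m k_m (1 + \cos(n_m\phi - \delta_m))$,
  matched to 13 type-quadruple keys carrying 33 trainable amplitudes in
  total; phases are frozen;
* Lennard-Jones $4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with
  Lorentz--Berthelot combining and Coulomb $k_e q_i q_j / r$
  ($k_e = 138.935458$ kJ mol$^{-1}$ nm e$^{-2}$) over all non-excluded
  pairs with **no distance cutoff**; pairs exactly three bonds apart are
  scaled by the two trainable 1-4 couplings;
* GB polar solvation
  $E = -\tfrac12 \sum_{ij} k_e\!\left(\tfrac1{\varepsilon_p} -
  \tfrac{e^{-\kappa f_{ij}}}{\varepsilon_w}\right)\tfrac{q_iq_j}{f_{ij}}$,
  $f_{ij} = \sqrt{r^2 + R_iR_j e^{-r^2/4R_iR_j}}$, with solute dielectric
  1, solvent dielectric 78.5 (both fixed) and Debye--Hückel screening
  $\kappa = 0.7$ nm$^{-1}$ by default (roughly 100 mM salt at 300 K);
* an ACE-style surface-area term
  $\mathrm{saf}\sum_i 4\pi(\rho_i + p)^2 (\tilde\rho_i/R_i)^6$.

Born radii follow the GBNeck2-style pipeline: pairwise HCT descreening
integrals with per-element screening factors, a neck correction, intrinsic
radii reduced by a trainable offset, and the
$\tanh(\alpha\psi - \beta\psi^2 + \gamma\psi^3)$ rescaling with per-element
coefficients. The reference model tabulates the neck position $d_0$ and
height $m_0$ numerically per radius pair; a numeric table is not
differentiable in the radii, so gbdms uses a smooth surrogate:
$d_0 = \rho_i + \rho_j + 1.6\,p$,
$m_0 = 0.36\,p^2 / (\rho_i\rho_j d_0)$, a lobe
$1/(1 + 100\Delta^2 + 3\times10^5\Delta^6)$ with
$\Delta = \max(r - d_0, 0)$ that plateaus below $d_0$ (keeping Born radii
monotone as atoms approach), and a logistic switch of width 0.01 nm at
$r = \rho_i + \rho_j + \mathrm{neck\_cutoff}$ so the neck-cutoff global has
a defined gradient. The surface-area term applies the burial factor
$(\tilde\rho/R)^6$ to the offset-reduced radii; the reference publications
do not state which radius enters, so the form is isolated behind
`surface_area_energy()` for easy substitution.

## The 108 trainable parameters

`ff_registry()` carries the defaults; `ff_params()` flattens them in fixed
order:

| block | count | units | default source |
|---|---|---|---|
| charge scalings (16 atom types) | 16 | -- | 1.0 |
| LJ $\sigma$ (HO excluded) | 15 | nm | Amber-style per type |
| LJ $\varepsilon$ (HO excluded) | 15 | kJ/mol | Amber-style per type |
| torsion amplitudes (13 keys) | 33 | kJ/mol | embedded registry |
| Coulomb / LJ 1-4 scalings | 2 | -- | 1/1.2, 0.5 |
| GB radii (H, HN, C, N, O, OC) | 6 | nm | GBNeck2-style |
| GB $\alpha,\beta,\gamma$ (H,C,N,O) | 12 | -- | GBNeck2-style |
| GB screening (H,C,N,O) | 4 | -- | GBNeck2-style |
| GB globals (neck cutoff/scale, offset, probe, SA factor) | 5 | mixed | GBNeck2-style |

The hydroxyl hydrogen HO has $\sigma = \varepsilon = 0$ (standard for
Amber-style hydroxyls) and is excluded from the LJ blocks, which is what
makes the per-type non-bonded block 46 rather than 48. The six GB radius
classes are keyed {H, H-on-N, C, N, O, O-carbonyl}; the class of a hydrogen
is decided per atom from its bonded neighbour. The 13 torsion keys are the
backbone $\phi$/$\psi$ quadruples, their side-chain variants, the amide
$\omega$ keys and wildcard fallbacks; each key's multi-periodicity
amplitudes sum to the 33 trainable values. Unmatched quadruples carry no
torsion energy.

Partial charges are never trained directly. Each atom type has a scaling
$s_t$; within every residue the base charges are multiplied by their type's
scaling and the resulting drift from the residue's formal charge is removed
in proportion to each atom's share of the total absolute scaled charge
(`rescale_residue_charges()`). The residue charge is conserved exactly for
any positive scalings, and the map is differentiable, so charge-scaling
gradients flow through a per-residue Jacobian.

## Dynamics and reverse-mode gradients

The integrator is BAOAB splitting Langevin dynamics (1 fs default step,
300 K, $\gamma = 0.1$ ps$^{-1}$ for training-style runs). BAOAB was chosen
over other splittings for its configurational accuracy at large steps; with
$\gamma = 0$ and zero noise it reduces exactly to velocity Verlet, which the
tests exploit. Noise is drawn per checkpoint block from a seed derived
deterministically from the run seed, so replaying any block reproduces the
forward trajectory bit for bit; this is the package's equivalent of
counter-style noise keyed by (seed, step).

Every `record_interval` steps (5000 by default, i.e. every 5 ps) the
running sums of Calpha pair distances $X$ and $X^2$ are accumulated; at the
end of the run they give the per-pair mean $\mu$ and standard deviation
$\sigma$. The loss per pair is the two-way closed-form Gaussian KL
divergence, compressed as $\ln(D+1)$ in each direction, weighted by
sequence separation ($0$ at $|i-j|=0$, linear to $1$ at $|i-j|\ge 10$), and
averaged over all unordered pairs (including zero-weight ones by default;
both conventions are supported because the choice only rescales the
gradient). A $\sigma$ floor of $10^{-3}$ nm protects rigid pairs; floored
pairs get zero gradient through $\sigma$.

There is no automatic-differentiation framework for R, so the adjoint of
the integrator is hand-derived. The kernels return analytic first
derivatives -- forces and $\partial E/\partial\theta$ for every trainable
channel, verified against central finite differences to $10^{-6}$ relative
in the test suite. The reverse pass walks each BAOAB step backwards,
propagating coordinate and velocity adjoints; the second-order products it
needs, $(\partial F/\partial x)u$ and $(\partial F/\partial\theta)^Tu$, are
formed as directional finite differences of those analytic first
derivatives (central, displacement $10^{-5}$ nm), so each reversed step
costs a constant small number of kernel evaluations independent of the
number of parameters. Because BAOAB reuses the force at each step boundary
in two adjacent half-kicks and nothing between the two reversed kicks
touches the velocity adjoint, the directional product is computed once per
boundary and reused exactly.

Loss sensitivities enter the reverse pass at the recording steps as
gradients with respect to the distance accumulators. Adjoints are clipped
to norm 0.1 (per block, coordinates and velocities separately -- "either
norm" is read per block and the threshold is configurable) every 100 steps
of the reverse pass, mirroring the forward checkpoint interval. Memory for
the checkpointed reverse pass is bounded by one block. An alternative
`mode = "full"` stores per-step coordinates and first derivatives during
the forward pass and runs a one-sided reverse pass against those stored
baselines; it yields gradients equal to the central-difference mode to
about $3\times10^{-5}$ relative (far below the seed-to-seed variation of
stochastic trajectory gradients) at roughly half the cost, and is used for
the larger packaged experiments. Checkpointed and full-storage reverse
passes over the same machinery agree bitwise.

Single-precision simulation is available by rounding the state through IEEE
floats each step; gradient evaluations stay in double precision because the
directional differences would drown in float round-off.

## The update pipeline

Per epoch and per protein: repeats are averaged elementwise; the gradient
is divided by the median of its absolute entries (so every protein
contributes comparably); LJ $\sigma$ entries and entries of hydrogen atom
types are multiplied by 0.02 (their raw gradients are disproportionately
large and destabilising); the proposed change $-\eta g$ with
$\eta = 4\times10^{-4}$ is clamped to $\pm0.5\%$ of the parameter's
epoch-start magnitude per protein, and the summed change to $\pm3\%$.
Median normalisation precedes the class weighting (the narrative order of
the method); the order is configurable. The caps are read as percentages of
each parameter's epoch-start value; a zero-valued parameter (none among the
108 defaults) would fall back to an absolute cap. Training runs are
repeated and the run with the lowest final mean training loss is selected,
ties breaking to the lowest index.

## What the synthetic generator emulates

`make_toy_chain()` builds zwitterionic Ala/Gly/Ser peptides from idealised
internal coordinates (extended $\phi=-135^\circ,\psi=135^\circ$; helical
$\phi=-57^\circ,\psi=-47^\circ$), deterministic per seed.
`make_reference_stats()` generates reference distance statistics by
simulating the system under a *stated* parameter vector -- the desk-scale
stand-in for explicit-solvent reference trajectories. This preserves the
structure of the training problem (match the distance distributions of a
different Hamiltonian) and makes parameter-recovery experiments closed
loop, but it does not emulate explicit-solvent physics: passing tests show
that the gradient and update machinery works, not that training against
these references improves agreement with experiment for real proteins.

The packaged experiments run at sizes chosen so a laptop CPU finishes them
comfortably: the paired-gradient experiment uses a 15-residue helical
polyalanine (153 atoms), 20 ps evaluations recorded every 50 fs against
references from a 10 ps run of a torsion-perturbed Hamiltonian; the
recovery experiment uses a 5-residue peptide, 3 ps epochs and a 6 ps
reference, and perturbs the leading $\psi$ amplitude by +10 %. These
lengths are orders of magnitude below production force-field training; the
quantities they measure (gradient sign agreement and correlation between
repeated stochastic evaluations, direction of parameter recovery) are the
ones that remain meaningful at this scale.

## Numerical choices and degenerate inputs

* Minimisation is steepest descent with a backtracking line search
  (tolerance 10 kJ/mol/nm on the maximum force component by default);
  energies are non-increasing across accepted steps.
* Interacting pairs at exactly zero distance raise a singular-geometry
  error; non-finite coordinates abort a run with the step index.
* Degenerate charge rescaling (all scaled charges zero with a non-zero
  formal-charge mismatch) is an error.
* Statistics need at least two recorded frames; negative variances from
  round-off clamp to the $\sigma$ floor.
* The aggregate-loss denominator includes zero-weight pairs by default.
* Harmonic constants use the $k(x-x_0)^2$ convention internally; the XML
  exporter writes $2k$ in the $\tfrac12 k (x-x_0)^2$ convention.
* Atom indices are 1-based (R convention); residue indices are 0-based and
  contiguous; PDB serial numbers are never trusted.

## Known limitations

* Gradient reproducibility across repeated stochastic evaluations is a
  property of the *converged* regime. At production scale the distance
  statistics entering the loss are averaged over thousands of essentially
  decorrelated frames, so two evaluations with different seeds
  differentiate nearly the same functional and their gradients agree in
  sign for most parameters. At the 20 ps scale of the packaged
  paired-gradient experiment the per-pair moments are averaged over only a
  handful of correlation times; the loss realisation itself varies severalfold
  between seeds, and the gradient direction outside the reference-perturbed
  channel is dominated by a collective fluctuation mode whose sign is a
  coin flip. The experiment therefore measures exactly what it claims --
  the seed-to-seed reproducibility of stochastic trajectory gradients at
  this scale -- and its summary statistics are themselves strongly
  seed-dependent. `paired_gradient_experiment()` accepts longer `sim_ps`
  for users who want to watch the statistics (and with them the
  reproducibility) converge.
* Residue coverage is Ala/Gly/Ser with protonated/deprotonated termini --
  enough to exercise all 16 atom types' machinery, not to simulate real
  training sets.
* The neck surrogate reproduces the shape, not the tabulated values, of
  the reference neck correction.
* No periodic boundaries during dynamics (training protocol); the analysis
  operators optionally apply minimum-image distances in a cubic box.
* No constraints, Ewald summation, or NVE-ensemble gradient support
  (unconstrained 1 fs dynamics makes constraints unnecessary at training
  scale, and stochastic Langevin dynamics is what keeps the adjoints
  stable).
* Trajectory output is multi-MODEL PDB rather than a binary trajectory
  format, keeping the package free of binary artefacts.

## A small worked run

```{r, eval = FALSE}
toy <- make_toy_chain(toy_spec(5, "helical"))
eng <- system_engine(toy$system)
mn <- minimize(eng)
cfg <- simulation_config(n_steps = 2000, record_interval = 50,
                         checkpoint_interval = 100, seed = 1)
ref <- make_reference_stats(toy$system, ff_params(ff_registry()), cfg)
lg <- loss_gradient(eng, ref, cfg)
str(lg[c("loss", "gradient")])
```
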
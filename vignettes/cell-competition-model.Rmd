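---
title: "A two-layer cellular Potts model of cell competition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-layer cellular Potts model of cell competition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compotts)
```

## The model

`compotts` simulates competition between two epithelial cell types — a
mutant colony (type A) embedded in wild-type tissue (type B) — by stacking
two layers.

**The physical layer** is a 2D cellular Potts model.  Each cell is the set
of lattice sites carrying its identifier (0 is extracellular medium), and
the mechanical energy is

$$E = \sum_{\langle i,j\rangle:\, n_i \neq n_j} J(\sigma_i, \sigma_j)
    + \sum_\alpha \lambda_\alpha \left(A_\alpha - A^T_\alpha\right)^2,$$

a contact energy over unordered neighbour pairs with different identifiers
(five independent values $J_{AA}, J_{BB}, J_{AB}, J_{AM}, J_{BM}$; lower
$J$ means stronger adhesion) plus an area-elastic penalty with per-type
compressional modulus $\lambda_\alpha$.  There is no perimeter term:
interfacial tension is carried entirely by the contact energies.  The
lattice evolves by Metropolis–Hastings dynamics: a flip of one site's
identity to that of a differing neighbour is accepted with probability 1
if it lowers the energy and $e^{-\Delta E / k_BT}$ otherwise.  One
Monte-Carlo step (MCS) — the simulation's time unit — is as many flip
attempts as there are lattice sites.

**The decision layer** runs once between Monte-Carlo steps, for every
living cell:

* *Growth.* The target area integrates
  $dA^T/dt = G\, e^{-k (A - A^T)^2}$ (explicit Euler, $dt$ = 1 MCS),
  applied while $A \le A^T$.  The pressure proxy $A - A^T$ damps growth
  exponentially with sensitivity $k$ — this is contact inhibition of
  proliferation.  The guard is non-strict: daughters are born exactly at
  $A = A^T$, and a strict inequality would freeze newborn growth.
* *Cycle.* A G1 sizer / S-G2-M timer: a cell stays in G1 until its area
  reaches its sizer threshold $A_S$ (drawn per cell,
  Gaussian $1400 \pm 35$ sites, truncated at 1), then counts down a timer
  $\tau_0$ (Gaussian $225 \pm 5.625$ steps, truncated at 1) and divides.
  The cleavage line passes through the centroid perpendicular to the
  principal axis of the site-coordinate covariance, so the daughters are
  arranged along the semi-major axis, each with $A^T = A$ (mechanical
  equilibrium at birth) and fresh cycle draws.
* *Elimination.*  Three modes.  (i) Density-dependent apoptosis with the
  logistic per-step hazard
  $P_{den}(\rho) = p_{den,max} / (1 + e^{-\beta(\rho - \rho_{1/2})})$,
  where the local density $\rho$ is the inverse of the cell's area plus
  the inverse areas of all cells it touches.  (ii) Contact-dependent
  apoptosis with the Hill curve
  $P_{con}(p_{AB}) = p_{con,max}\, p_{AB}^{n_H} / (S^{n_H} + p_{AB}^{n_H})$
  of the heterotypic contact fraction $p_{AB}$ (see below for its time
  base).  Each living cell draws two independent uniforms per step; either
  success initiates apoptosis, which sets the target area to zero so the
  cell shrinks and is removed.  (iii) Live-cell extrusion: a cell strictly
  below a quarter of its type's current mean area is deleted instantly,
  its sites becoming medium.

Populations, mean local densities and event tallies (divisions, both
apoptosis modes, extrusions, removals) are recorded every step, per label,
and the bookkeeping closes exactly:
$N(t{+}1) - N(t) = \text{divisions} - \text{removals}$.

## Parameters and units

Parameters are entered in the reference units in which they are reported
— areas in units of the mean sizer $A_S = 1400$ sites, times in mean
timer periods $\tau_0 = 225$ MCS, contact energies in units of
$\lambda A_S^{3/2}$ — and converted once to lattice units:

```{r}
convert_params()[c("G", "k", "rho_half", "beta")]
round(convert_contact_energies(), 3)
```

Defaults (both types identical unless overridden): $\lambda = 1$,
$G = 1.14\,A_S/\tau_0$, $k = 1.96\times10^5 A_S^{-2}$,
$p_{den,max} = 0.0015$, $\rho_{1/2} = 14.01\,A_S^{-1}$,
$\beta = 0.104\,A_S$, $p_{con,max} = 1$, $S = 1.35$, $n_H = 3.6$,
$k_BT = 10$, with adhesion ordered
$J_{BB} < J_{AB} < J_{AA} < J_{AM} = J_{BM}$ (wild-type most cohesive,
medium least adhesive).

## The time base of the contact hazard

The two elimination curves were calibrated on different experimental
systems, and only the density curve arrives on a per-step scale
($p_{den,max} = 0.0015$ gives a homeostatic turnover time of a few
cell-cycle lengths).  The contact curve saturates at $p_{con,max} = 1$:
read literally per MCS it would kill any cell with appreciable
heterotypic contact within a few steps — a boundary cell with
$p_{AB} \approx 0.4$ would die within a small fraction of one cycle
phase, and every embedded colony, however stiff, would be erased by
interface churn within a few $\tau_0$.  That is inconsistent with the
behaviour this model family is known for: neutral colonies that persist
over tens of $\tau_0$, contact-driven elimination acting as a
size-dependent perturbation, and a finite critical colony radius.

`compotts` therefore treats the fitted contact curve as a probability per
*epoch* and folds it to a per-step hazard
$1 - (1 - P_{con})^{1/\text{epoch}}$, with `contact_epoch` defaulting to
one timer period (225 steps).  This makes the two hazards commensurate
(both saturate near $10^{-3}$ per step) while leaving the curve itself —
its midpoint at $p_{AB} = S$, its $n_H$-invariance there, its value at
full heterotypic contact — untouched.  Setting `contact_epoch = 1`
restores the literal per-step reading.  This is the single most
consequential calibration choice in the package and is deliberately
exposed as a parameter.

## The tissue generator

`make_initial_state()` emulates a mechanically relaxed confluent
monolayer on a fixed, non-periodic square domain with an immutable
one-site medium frame: cell centres are laid on a hexagonal packing with
one resting area $A_0 = 1300$ sites per centre, sites are assigned by
nearest centre, targets are set to $A_0$, and a few Monte-Carlo steps of
relaxation at frozen targets roughen the interfaces.  The packing is
aligned so that the domain centre sits at a deep hole of the hexagonal
lattice; with the default $A_0$ this makes a colony of radius 50 sites
contain exactly six cells, the stated smallest-colony condition.  Cells
whose centre lies within the colony radius are type A; `pseudo_clone`
mode labels that patch A while giving it wild-type parameters and
energies (a tracked subset of homogeneous tissue); `tiled_mixture`
randomizes the type map for fully mixed tissues.

What the generator does *not* emulate: curved or free tissue boundaries
(the frame is rigid), pre-existing size heterogeneity beyond the
tessellation's discreteness, and any spatial correlation in cycle phase —
all cells start in G1 with independent draws.  Passing tests on these
tissues therefore demonstrates the model's internal phenomenology, not
agreement with any particular experimental monolayer.

## Reduced-scale protocol and problem sizes

The reference experiments run on a $1500^2$ lattice for hundreds of timer
periods with tens of replicates — cluster-scale work.  The package's own
tests and the acceptance script use a desk-scale protocol chosen once:
a $300^2$ domain (about 68 cells), horizons of $24\tau_0$
($5400$ MCS), default colony radius 105 sites (the largest the
one-cell-diameter margin rule allows, keeping the colony as
bulk-dominated as the domain permits), and 2–5 replicate seeds.  At this
scale qualitative orderings are meaningful but absolute thresholds shift:
a desk-scale colony sits near the model's critical size, so the
coexistence boundary in the stiffness–crowding plane lies closer to
$\lambda_A/\lambda_B = 1$ than at full scale, and the equal-parameter
colony drifts slowly downward through residual contact churn at its
curved interface rather than holding exactly flat.  The test suite
asserts directions, orderings and sign changes, never full-scale
threshold values.

## Numerical choices

* **Neighbourhood**: Moore (8-neighbour) for contact energies, flip
  candidates and contact profiles; standard CPM practice and consistent
  with smooth interfaces.  Order 4 is available for sensitivity checks.
* **Proposal kernel**: source site uniform over non-frame sites; the
  candidate identity is drawn uniformly from the *distinct* differing
  identities among the site's neighbours; attempts with no differing
  neighbour are consumed without effect.
* **Connectivity**: not constrained (at $k_BT = 10$ cells stay compact);
  `fragmentation()` counts connected components per identifier so
  fragmentation can be monitored.
* **$p_{AB}$ denominator**: all boundary contacts including cell–medium —
  the heterotypic fraction is a property of the whole perimeter.
* **Division ties**: the principal axis falls back to the first lattice
  axis when the covariance is degenerate (perfect squares, single
  sites); site order along the axis is made total by breaking projection
  ties on coordinates, so partitions are deterministic.
* **Apoptotic removal floor**: 10 sites; in practice the quarter-of-mean
  extrusion rule removes most apoptotic cells first.
* **Hazard draws**: two independent uniforms per cell per step, drawn in
  identifier order from a dedicated decision RNG stream; the engine keeps
  three independent streams (lattice, decisions, cycle draws) so
  decision-rule changes do not perturb the lattice trajectory at a fixed
  seed, and stream positions are checkpointed, making resumed runs
  bit-identical to uninterrupted ones.
* **Energy tolerance**: local energy differences are validated against a
  global recompute to $10^{-9}$ relative.

## A worked reduced-scale run

A stiff colony ($\lambda_A = 2$) embedded in softer wild-type tissue;
both apoptosis modes active:

```{r, eval = FALSE}
cfg <- cpm_config(domain = 300, steps = 24 * 225, colony_radius = 105,
                  A = list(lam = 2))
run <- run_competition(cfg, seed = 1)
print(run)
plot(run)                      # normalized population curves
summary(run)$fit_A             # net growth rate of the colony
```

The stiff colony compresses its neighbours above their homeostatic
density, raising their density-dependent apoptosis hazard while their
growth stalls in G1; the wild-type population declines and the colony
expands.  Swapping the moduli reverses the direction; equalizing them
leaves no systematic winner beyond the finite-size drift discussed above.

## Limitations

2D only; no chemotaxis, no perimeter/contractility energy, no explicit
extrusion mechanics (deletion is instantaneous); the two hazard curves
come from different biological systems and their common time base is a
modelling decision (see above); desk-scale results shift quantitatively
with domain and colony size, and full-scale phase boundaries should be
recomputed at full scale.
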
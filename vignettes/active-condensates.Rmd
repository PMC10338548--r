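---
title: "Modelling transcription-driven nuclear condensates with condensim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling transcription-driven nuclear condensates with condensim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensim)
```

## The model

Nuclear condensates -- nucleoli, speckles, paraspeckles, transcriptional
condensates -- are protein/RNA-rich bodies that assemble by phase
separation and sit next to clustered, actively transcribed genes.
`condensim` implements a coarse-grained two-field model of this
situation: a protein pseudospecies $\phi_P(\vec x, t)$ whose total amount
is conserved, and an RNA pseudospecies $\phi_R(\vec x, t)$ that is
actively produced, diffuses, and is degraded.

The bulk free-energy density is

$$
f(\phi_P, \phi_R) = \rho_P (\phi_P - \alpha)^2 (\phi_P - \beta)^2
 - \chi\, \phi_P \phi_R + c\, \phi_P^2 \phi_R^2 + \rho_R\, \phi_R^2 ,
$$

plus a square-gradient (surface-energy) term
$\tfrac{\kappa}{2} |\nabla \phi_P|^2$ in the full functional. The double
well drives protein demixing with pure-protein binodals at $\alpha$
(dilute) and $\beta$ (dense); $-\chi \phi_P \phi_R$ is the heterotypic
RNA--protein attraction; $c\,\phi_P^2\phi_R^2$ is a quartic repulsion
that dominates at RNA-rich compositions; $\rho_R \phi_R^2$ penalizes RNA
self-crowding. Together the two coupling terms produce *re-entrant*
phase behaviour: a little RNA strengthens protein partitioning, a lot of
RNA dissolves it.

The dynamics couple conserved (Model B) relaxation of the protein to a
reaction--diffusion equation for the RNA:

$$
\partial_t \phi_P = M_p \nabla^2 \frac{\delta F}{\delta \phi_P},
\qquad
\partial_t \phi_R = M_r \nabla^2 \phi_R + k_p(\vec x)\,\phi_P
  - k_d\, \phi_R .
$$

RNA production is proportional to the local protein concentration
(transcribing machinery) times a spatial rate constant $k_p(\vec x)$
that encodes gene-cluster geometry. A cluster is a Gaussian of extent
$\sigma$ and total activity $k_T = \int k_p\, d\vec x$, so the amplitude
is $k_T / 2\pi\sigma^2$ on an infinite domain; the uniform control
spreads the same $k_T$ over the whole domain.

## Parameters, units and defaults

All quantities are in simulation units (lengths in grid units, energies
of order one). The defaults are:

| parameter | meaning | default | provenance |
|---|---|---|---|
| $\rho_P$, $\alpha$, $\beta$ | double well; binodals | 1, 0.1, 0.7 | model definition |
| $\chi$ | RNA--protein attraction | 0.8 | calibrated (below) |
| $c$ | quartic RNA--protein repulsion | 3.0 | calibrated |
| $\rho_R$ | RNA self-repulsion | 1.0 | calibrated |
| $\kappa$ | surface-energy coefficient | 0.04 | calibrated |
| $M_p$, $M_r$ | mobilities | 1, 1 | flow-scenario values |
| $k_d$ | RNA degradation rate | 0.5 | flow-scenario value |
| domain radius, $\Delta r$ | disk geometry | 30, 0.2 | model definition |

The coupling coefficients $(\chi, c, \rho_R, \kappa)$ are a calibrated
set, chosen once by requiring four properties simultaneously and then
frozen:

1. **Re-entrance with closure.** `partition_scan()` at total protein 0.4
   must show dense-phase protein enrichment that rises with total RNA,
   peaks, and collapses to a mixed single phase (for the defaults, the
   two-phase window closes near $\phi_R^{tot} \approx 0.46$). Large $c$
   (roughly $c \gtrsim 5$ at $\chi \approx 0.8$) instead opens a
   segregative protein-rich/RNA-rich demixing branch at high RNA that
   never closes, which is the wrong phenomenology.
2. **Locally stable binodals.** The Hessian determinant of $f$ must be
   positive at both pure-protein binodal points.
3. **Unstable inner interface.** A vacuole's inner boundary must cross
   compositions with $\det J < 0$ so that a core--shell condensate shows
   two interface bands. This requires the vacuole to form while core RNA
   is still moderate; in terms of the couplings, approximately
   $c \gtrsim 3.6\,\chi^2$ (onset of local protein expulsion at
   $\phi_R \approx \chi/2c\phi_P$ must lie below the RNA level
   $\approx \sqrt{0.18/c}$ at which $c\,\phi_R^2$ re-stabilizes the
   spinodal band). With $\chi = 0.8$ this puts $c \approx 3$, squeezed
   from both sides by property 1.
4. **Sensible interfaces.** $\kappa = 0.04$ gives a relaxed 1D interface
   with tanh length scale $\sqrt{\kappa/2}/(\tfrac{\beta-\alpha}{2})
   \approx 0.47$, i.e. a 10--90% width of about five cells at
   $\Delta r = 0.2$ (and still $\ge 2.6$ cells at the reduced
   $\Delta r = 0.4$ used in tests).

$M_r = 1.0$ and $k_d = 0.5$ are the printed parameters of the
directed-flow scenario and serve as package-wide kinetic defaults. Two
scenario families deliberately override $k_d$: the size-vs-activity and
nucleation presets use $k_d = 0.02$, making the RNA decay length
$\sqrt{M_r/k_d} \approx 7$ comparable to condensate radii. With fast
degradation the RNA stays so localized that a condensate under high
activity escapes outward as a surviving ring instead of dissolving;
slow degradation lets high activity blanket and dissolve it, which is
the regime in which activity controls condensate size and stability.

## Numerics

The disk of radius 30 is discretized as a masked Cartesian grid
(spacing $\Delta r = 0.2$; reduced test geometry: radius 15,
$\Delta r = 0.4$). The 5-point Laplacian is assembled over in-domain
cell pairs only, which enforces the no-flux boundary on the mask edge
and makes the operator symmetric with zero column sums -- conserved
dynamics then conserve mass identically.

Time stepping is backward Euler with Newton sweeps for the protein
equation: each sweep linearizes the bulk chemical potential about the
current iterate and solves the resulting fourth-order system matrix-free
with BiCGSTAB, preconditioned by a constant-coefficient operator whose
sparse Cholesky factorization is cached and reused across steps. Sweeps
stop when the iterate moves less than $10^{-6}$ (typically 2--3 sweeps);
a non-converging step is rejected and the step size halved. The RNA
equation is linear and solved directly (cached factorization), which
makes its discrete production--degradation balance close to round-off at
every step. Step-size control: $\Delta t_0 = 0.05$, growth $\times 1.1$
per accepted step capped at $\Delta t = 0.5$, halving on rejection,
abort below $10^{-4}$. Steady state is declared when the maximum
per-cell $|\Delta\phi|/\Delta t$ stays below $10^{-6}$ for 50
consecutive steps; the default budget is 15,000 steps.

Negative protein concentrations are tolerated transiently (the
polynomial free energy is defined there); clipping would break
conservation. Excursions below $-10^{-3}$ are counted in the run
diagnostics and the run aborts below $-0.05$.

Symmetry handling: with symmetric inputs the discretization preserves
mirror symmetry to round-off, so symmetry breaking never emerges from
silent numerics. Scenarios that rely on it (high-activity vacuoles) add
a seeded, mass-neutral random perturbation of amplitude $10^{-3}$ to the
initial protein field; the seed is part of the configuration, so runs
remain reproducible.

## Morphometrics

Snapshots are summarized by: dense-region segmentation at the well
midpoint $(\alpha+\beta)/2 = 0.4$ with $R_{eff} = \sqrt{A/\pi}$;
vacuole radius (largest dilute region fully enclosed by dense phase);
interface count along a ray from the cluster centre as contiguous bands
of $\det J < 0$; mass-weighted centroid; and eccentricity from second
central moments. The default eccentricity is the rotation-invariant
combination $((I_{xx}-I_{yy})^2 + 4I_{xy}^2)/(I_{xx}+I_{yy})^2$; a
`literal` option reproduces the variant with an unsquared cross-moment
term, which coincides with the default whenever $I_{xy} = 0$
(axis-aligned geometries) but is not rotation-invariant, so the
invariant form is the default. Drift velocities are finite differences
of the tracked centroid, non-dimensionalized by $R_c / D_P$ with
$D_P = M_p\, \partial^2 f/\partial\phi_P^2|_{(0,0)} = 1.56\,M_p$ for the
default well and $R_c = 4$. Note $\partial^2 f/\partial \phi_P^2 =
2\rho_P(\alpha^2 + 4\alpha\beta + \beta^2)$ -- the factor 2 matters and
is included.

Outcome classification is rule-based: *dissolved* (no dense component),
*vacuole* (enclosed dilute region), *aspherical* (eccentricity above
0.05), else *spherical*; and for dynamics *at-site*, *flow* (net
displacement toward the cluster exceeding $R_c/2$),
*dissolution/renucleation* (original condensate lost while a dense
component stands at the cluster), else *no-effect*. The thresholds are
exposed because the qualitative phase boundaries are not sharply defined
by the model.

## Gradient theory

With the protein held at $\phi_P^0$ and production constant inside a
disk of radius $\sigma$ (zero outside), the steady RNA profile solves a
modified Helmholtz equation radially; the solution is a combination of
modified Bessel functions $I_0, K_0$ of $r/\sqrt{M_r/k_d}$, continuous
and flux-continuous at $r = \sigma$, with the maximal gradient exactly
at the source edge. `gradient_summary()` evaluates the concentration
scale $\phi_R^0$, decay length $L_{dr}$ and
$\nabla\phi_R^{max} = \phi_R^0/L_{dr}$; exponentially scaled Bessel
evaluations keep everything finite at large $\tilde\sigma$.
`scaling_smallsigma()` gives the leading small-$\tilde\sigma$ laws, with
proportionality constants fixed by matching the exact formulas at
$\tilde\sigma = 0.01$ (the laws are stated as proportionalities; a
reference point is needed to plot them against the exact curves).
`fit_velocity_constant()` fits the single empirical constant linking
peak drift velocity to $\nabla\phi_R^{max}$ by zero-intercept least
squares.

When comparing simulation to this theory, use `disk_rate_field()` (the
top-hat source the theory assumes, with supersampled rim cells), freeze
the protein (`frozen_protein = TRUE`), and keep the domain radius well
above $L_{dr}$ -- the closed form assumes an infinite domain, and the
finite no-flux boundary is only an approximation.

## What the scenarios emulate -- and what they do not

The presets reproduce the model's characteristic regimes at reduced
scale (radius 15, $\Delta r = 0.4$, $\le$ 2,000--8,000 steps; chosen so
the full battery runs on a laptop core in minutes): non-monotone
condensate size versus activity with the clustered curve dissolving
before the uniform control; a bounded nucleation region in
$(k_T, \sigma)$ with no nucleation for uniform activity; the
droplet-to-vacuole transition with interface count 1 to 2 and, at
higher activity, loss of radial symmetry; directed flow toward a
distal cluster; and two-cluster competition. These are statements about
the model's phenomenology on an idealized disk with deterministic
dynamics. They do not capture thermal noise (condensates here never
diffuse on their own), chromatin mechanics or viscoelasticity,
hydrodynamic flows, stochastic low-copy transcription, or 3D geometry
-- so passing scenarios demonstrate internal consistency of the model
and solver, not quantitative agreement with any particular nuclear
body.

At high activity the reduced-scale vacuole breaks up into several dense
fragments arranged around the source rather than a single crescent; the
number of fragments is set by the fastest-growing azimuthal mode of the
ring and depends on domain size and perturbation. The classification
treats any non-symmetric, non-vacuole outcome (largest-fragment
eccentricity or fragment count) as symmetry broken.

## Degenerate inputs and edge cases

- `solve_coexistence()` at exactly zero total RNA solves the reduced
  protein-only system ($\phi_R \equiv 0$): the RNA chemical-potential
  equality is vacuous with no RNA to redistribute, and the full
  five-equation system would force a negative RNA concentration in one
  phase whenever $\chi > 0$. Roots with negative concentrations, merged
  phases, or locally unstable phases are rejected and reported as
  single-phase (`converged = FALSE`), never as errors.
- At low but nonzero total RNA the interior root can likewise demand a
  negative light-phase RNA concentration; the physical equilibrium pins
  $\phi_R^{light} = 0$ (all RNA partitions into the dense phase) and
  satisfies the RNA chemical-potential condition one-sidedly. The
  solver detects this and solves the constrained four-equation system.
- Cold starts that fail near the re-entrant nose are retried by
  continuation in total RNA from the zero-RNA root.
- `seed_droplet()` with $R_0 = 0$ degenerates to the uniform state;
  seeds reaching outside the domain are errors.
- Gaussian clusters are renormalized by their discrete in-domain
  integral, so $k_T$ is conserved exactly even when $\sigma$ is
  comparable to the domain radius (the infinite-domain
  $k_T/2\pi\sigma^2$ amplitude would leak activity).

## A quick tour

```{r, eval = FALSE}
library(condensim)

# equilibrium: re-entrant partitioning
p <- calibrate_defaults()
scan <- partition_scan(p, phi_P_total = 0.4, seq(0, 0.5, by = 0.01))
plot(scan$phi_R_total, scan$enrichment, type = "b",
     xlab = "total RNA", ylab = "dense/light protein")

# dynamics: seeded droplet on an active cluster (reduced geometry)
cfg <- preset_config("vacuole", scale = "reduced")
res <- run(cfg)
res$summary

# theory: RNA gradient around a small source
gradient_summary(k_P = 0.05, phi_P0 = 0.7, k_d = 0.5, M_r = 1, sigma = 2)
```
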
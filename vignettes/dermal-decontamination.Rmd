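---
title: "Modelling the dermal decontamination window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the dermal decontamination window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermdecon)
```

## The physical picture

A finite dose of a toxicant deposited on skin sits in the upper stratum
corneum and is consumed by three competing processes: diffusion inward to
the systemic circulation, loss at the exposed surface (evaporation and any
interfacial reaction with an applied decontaminant), and first-order
neutralization in the bulk of the tissue by a reactive decontaminant.
`dermdecon` treats the stratum corneum as a one-dimensional homogeneous slab
of thickness $h$ and diffusivity $D_{SC}$, with the deposit spread uniformly
over the top fraction $\beta$ of the barrier. The inner face is a perfect
sink (anything reaching the viable epidermis is counted as absorbed), and
the outer face is a radiation (Robin) boundary whose coefficient lumps
evaporation and interfacial reaction.

Scaling depth by $h$ and time by the diffusion time $h^2/D_{SC}$ gives

$$
\frac{\partial c}{\partial \tau} = \frac{\partial^2 c}{\partial x^2} - Da\, c,
\qquad
\left.\frac{\partial c}{\partial x}\right|_{x=0} = \pi_{surf}\, c(0,\tau),
\qquad
c(1,\tau) = 0,
$$

with $c(x,0) = 1/\beta$ on $[0,\beta]$ and $0$ below (unit total mass). Two
dimensionless groups carry all the physics:

* $Da = k\,h^2/D_{SC}$, the bulk Damköhler number — how fast in-tissue
  neutralization is relative to diffusion;
* $\pi_{surf} = \kappa_{evap} + Da_{surf}
  = (k_{evap} + k_{surf})\,h/D_{SC}$, the surface-loss number.

`agent_scenario()` takes the dimensional inputs in the units they are
reported in experimental work (cm²/s, µm, s⁻¹, cm/s) and
`dimensionless_groups()` performs the reduction; `decon_scenario()` accepts
the dimensionless triplet directly for parameter sweeps. $\beta$ defaults to
0.1, the conventional penetration depth for a fresh finite dose; it is a
plain argument everywhere. Vapor pressure is accepted as metadata only: no
correlation from $P_{vap}$ to an evaporation velocity is implemented, so
volatility must be supplied as a mass-transfer velocity $k_{evap}$ (or as
$\kappa_{evap}$ directly). For the preset VX case the literature-derived
value $\pi_{surf} \approx 0.17$ is stored as given, because the underlying
evaporation measurements are not reducible from the published summary.

## The eigenfunction solution

Separation of variables with the sink condition built in gives modes
$\varphi_n(x) = \sin\big(\lambda_n (1-x)\big)$; the Robin condition forces

$$ \lambda \cos\lambda + \pi_{surf} \sin\lambda = 0, $$

with exactly one root per interval $\big((n-\tfrac12)\pi,\, n\pi\big)$. For
$\pi_{surf}=0$ the roots are $(n-\tfrac12)\pi$ exactly; as
$\pi_{surf}\to\infty$ they climb to $n\pi$ (the surface becomes a second
sink). `solve_eigenvalues()` brackets each root in its interval and solves
with Brent's method (`stats::uniroot`, tolerance $10^{-12}$) followed by one
Newton polish; because the characteristic function grows like $\lambda$, the
convergence check is scale-aware (residual divided by $\max(1, \lambda)$).
This bracketed approach cannot skip or duplicate roots, which matters more
here than raw speed.

Projecting the deposit onto the modes gives

$$
A_n = \frac{\cos\big(\lambda_n(1-\beta)\big) - \cos\lambda_n}
           {\beta\,\lambda_n N_n},
\qquad
N_n = \tfrac12 - \frac{\sin 2\lambda_n}{4\lambda_n},
\qquad
\mu_n = \lambda_n^2 + Da .
$$

Each pathway's cumulative mass fraction is a closed modal sum — e.g.
$M_{abs}(\tau) = \sum_n (A_n \lambda_n/\mu_n)\,(1 - e^{-\mu_n\tau})$ — never
a quadrature of fluxes. The eigencondition makes the four-way split
(absorbed, surface-lost, reacted, remaining) sum to the series mass of the
deposit *exactly, mode by mode*, so conservation error equals the truncation
mass deficit and nothing else.

### Series length and small-time behaviour

The projection of a discontinuous deposit converges like $1/n^2$ in the
mass sums. The default of 400 terms keeps the conservation defect below
$10^{-6}$ even at strong surface loss ($\pi_{surf} \sim 11$), where 200
terms leave a $\sim 4\times 10^{-6}$ deficit. At very small times
($\tau \lesssim 10^{-4}$) the truncated sums oscillate by $O(10^{-8})$
around zero; values are clipped to the physical range $[0,1]$, and
quantities at such times are better checked against the finite-difference
solver below. The default evaluation grid is 400 logarithmically spaced
points on $[10^{-3},\, 6/\mu_1]$: wide enough to resolve the fast surface
transient and to come within $\sim e^{-6}$ of the asymptotes, which is why
curve end-points agree with the exact steady state to about $10^{-3}$, not
better.

## Steady state without series: splitting probabilities

The asymptotic partition is computed exactly from stationary boundary-value
problems rather than by series truncation. The probability that a molecule
starting at depth $x$ is absorbed before being lost or reacted solves
$u'' = Da\,u$ with $u(1)=1$, $u'(0)=\pi_{surf}u(0)$:

$$
u_{abs}(x) = \frac{\pi_{surf}\sinh(qx) + q\cosh(qx)}
                  {\pi_{surf}\sinh q + q\cosh q},
\qquad q = \sqrt{Da},
$$

reducing to $(\pi_{surf}x+1)/(\pi_{surf}+1)$ at $Da=0$. The surface pathway
solves the companion problem with $u(1)=0$, $u'(0)=\pi_{surf}(u(0)-1)$,
giving $u_{surf}(x) = \pi_{surf}\sinh\big(q(1-x)\big) / (\pi_{surf}\sinh q +
q\cosh q)$. `steady_fractions()` averages each over the deposit with the
closed antiderivative (no quadrature) and takes
$M_{reac}(\infty) = 1 - M_{abs}(\infty) - M_{surf}(\infty)$. Useful limits
that the tests exercise: $(Da,\pi_{surf})=(0,0)$ gives $M_{abs}=1$; at
$Da=0$, $\pi_{surf}\to\infty$, absorption tends to $\beta/2$, the mean
relative depth of the deposit between two perfect sinks.

```{r steady}
steady_fractions(decon_scenario(Da = 6, pi_surf = 0.4))
```

## Kinetic summaries: $\tau_{eff}$ and $t_{98}$

Each cumulative curve is summarized by its **first-moment effective time
constant**

$$
\tau_{eff} = \int_0^\infty \Big(1 - \frac{M_p(\tau)}{M_p(\infty)}\Big)d\tau
           = \frac{\sum_n r_n/\mu_n^2}{\sum_n r_n/\mu_n},
$$

the definition used in the Laplace-transform effective-time-constant
tradition. For a single exponential, $4\tau_{eff}$ is the 98.2% completion
point, which is the usual practical reading ("four time constants ≈ 98%
done"). Multi-modal curves deviate from it: the absorbed pathway has a
diffusive lag that makes it complete *earlier* than $4\tau_{eff}$ suggests
(its $t_{98}/\tau_{eff}$ ratio drops toward 2.5 at high $Da$), while the
surface pathway has a long algebraic tail pushing the ratio above 5. The
package therefore also reports the literal 98% time $t_{98}$, found by root
bracketing on the monotone normalized curve, and the two are deliberately
separate outputs. A pathway with zero asymptote (e.g. surface loss when
$\pi_{surf}=0$) has no time constant and is reported `NA`, never 0.

Regime classification follows the Damköhler thresholds: $Da<3$
diffusion-dominated (maximize surface removal), $3\le Da\le 8$ intermediate
(optimize both), $Da>8$ bulk reaction-dominated (focus on reaction
chemistry).

## The decontamination window

When decontamination is effective, the surface and bulk pathways — which act
at and near the application point — complete before absorption, which must
traverse the whole barrier:

$$ 4\tau_{eff,surf,d} < 4\tau_{eff,reac,d} < 4\tau_{eff,abs,d}. $$

`decontamination_window()` evaluates this chain of strict inequalities
(ties within $10^{-9}$ are reported as a tie, not as an ordering), reports
the $4\tau$ markers (in minutes too when the dimensional time scale is
available), and compares the absorbed asymptote against a no-bulk-reaction
baseline. The reported *extent*, $4\tau_{eff,abs} - 4\tau_{eff,reac}$, is a
convention of this package — the model statement is the ordering itself —
and the output labels it as such.

Two conventions decided here deserve a note:

* **Baseline surface loss.** The no-decontamination baseline sets $Da=0$.
  When the scenario records the split $\pi_{surf} = \kappa_{evap} +
  Da_{surf}$, the baseline keeps only $\kappa_{evap}$, since without a
  decontaminant there is no interfacial reaction either; without a split the
  full $\pi_{surf}$ is retained. The choice is recorded in the output
  (`baseline_pi_surf`).
* **Window extent units.** Dimensionless by default; multiplied by
  $h^2/D_{SC}$ (minutes) when a timescale is supplied.

## The absorption risk map

`build_risk_map()` evaluates the closed-form absorbed asymptote on a grid of
$(Da, \pi_{surf})$ — default $[0,10]\times[0.4,2]$ at $101\times101$, the
sweep range representative of the chemical-warfare-agent literature — and
labels zones. The *safer* threshold (absorbed fraction < 0.20) is a
published operational bound; the *high-risk* threshold is the "majority
absorbed" reading, taken here as > 0.50. Both are arguments. Because
$M_{abs}(\infty)$ is strictly decreasing in both groups, the 0.20 contour is
monotone and the safer region along increasing $Da$ is always a suffix —
the tests assert this.

## The finite-difference cross-check

All analytical results are verified against an independent solver,
`fd_solve()`: second-order central differences ($n_x = 201$ nodes), the
Robin condition imposed through a ghost node
($c_{-1} = c_1 - 2\Delta x\,\pi_{surf}c_0$), Crank–Nicolson time stepping
($\theta = \tfrac12$, base step $2.5\times10^{-5}$, ten times finer while
$\tau < 10^{-3}$ where the deposit edge relaxes), and the constant
tridiagonal operator LU-factorized once. Two design points make it a
genuine oracle rather than a re-derivation:

* cumulative fractions are accumulated trapezoidally from boundary fluxes
  and the bulk reaction integral, so mass conservation is a *diagnostic*
  of the discretization (kept below $5\times10^{-4}$), not an identity;
* the deposit edge at $x=\beta$ is volume-averaged onto the cell containing
  it, preserving unit discrete mass exactly whether or not the edge falls
  on a node.

The suite pins series-vs-FD agreement below $5\times10^{-4}$ on every curve
over $(Da, \pi_{surf}) \in \{0,1,10\}\times\{0,0.4,11.2\}$ for
$\tau \in [10^{-3}, 6/\mu_1]$, checks the steady limits to $2\times10^{-3}$,
and verifies second-order convergence (halving $\Delta x$ and $\Delta t$
cuts the deviation by about 4×). Stationary quantities are additionally
checked against a separate dense tridiagonal solve of the splitting-probability
problem implemented inside the test helpers.

## Problem sizes and runtimes

The defaults are sized so that every computation in the package is
interactive: 400 eigenvalues per scenario (milliseconds), 400-point time
grids, $101\times101$ risk maps (about a second), and finite-difference
verification runs of $10^4$–$10^5$ steps (seconds each). The test suite
uses a $3\times3$ scenario grid for solver cross-checks, a $41\times33$
grid for the safer-zone bound, and coarser FD configurations where the
tolerance under test permits.

## Limitations

The model assumes Fickian diffusion, first-order kinetics, one homogeneous
layer, intact skin, constant temperature, and uniform decontaminant
coverage. It does not represent multilayer skin, follicular/sweat-duct
shunts, time-dependent barrier damage (corrosives), occlusion, or partial
coverage — all of which generally shorten the real decontamination window
relative to the model's. Predictions are a planning and experimental-design
tool, not a clinical one: the preset scenarios reproduce literature-derived
parameter sets, and passing tests demonstrate internal mathematical
consistency (series ↔ closed form ↔ finite differences), not agreement with
new in vitro or in vivo measurements.
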
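---
title: "Modelling IOP after drainage-device implantation and suture occlusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling IOP after drainage-device implantation and suture occlusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iopflow)
```

## The physical model and its assumptions

Aqueous humor is produced by the ciliary body at `Q_cb` (default 2 µl/min)
and leaves the anterior chamber by three routes: the uveoscleral pathway, a
pressure-independent sink taking a fixed fraction (default 0.15) of the
inflow; the trabecular meshwork / Schlemm's canal; and, after surgery, the
drainage-device tube into a filtration bleb. The package models the steady
state of this network under the following assumptions, each of which it
inherits from the analytical tractability of creeping flow:

* **Creeping, fully developed tube flow.** Reynolds numbers in the tube are
  far below unity, so entrance effects are negligible and the pressure
  drop follows the generalized Hagen–Poiseuille law
  $\Delta p = 128\,\mathcal{S}\,L_v\,\mu\,Q / (\pi D_h^4)$ with
  $D_h = D_i - D_s$.
* **Linear trabecular resistance.** The trabecular pathway is a constant
  resistance calibrated from the pre-surgery state,
  $(p_g - p_{ev})/Q_0$, carrying flow only while the IOP exceeds the
  episcleral venous pressure $p_{ev}$. Tissue deformation (e.g. collapse
  of Schlemm's canal) is outside the model.
* **Lumped bleb.** Transport and absorption in the subconjunctival tissue
  reduce, at steady state, to an effective resistance towards a reference
  pressure: $p_b - p_r = R_b\,Q_i$.
* **Constant bleb resistance between interventions.** This is the central
  clinical assumption: the bleb's morphology does not change between
  measuring the post-implant IOP and inserting the suture. It is what
  allows the unmeasurable bleb pressure to be eliminated from the
  correction formulas. Cicatrization violates it in one direction only
  (more resistance), which is why every computed suture diameter is
  reported as an upper bound.
* **Pressure-independent inflow.** $Q_{cb}$ and the uveoscleral fraction do
  not vary with IOP over the range of interest.

## Parameters

| Parameter | Meaning | Unit | Default |
|---|---|---|---|
| `p_g` | IOP before surgery | mm Hg | 35 |
| `p_ev` | episcleral venous pressure | mm Hg | 10.5 |
| `p_r` | bleb reference pressure | mm Hg | 0 |
| `Q_cb` | ciliary inflow | µl/min | 2 |
| `uveoscleral_fraction` | inflow share bypassing both outflow paths | — | 0.15 |
| `mu` | aqueous humor viscosity | mPa s | 0.75 |
| `inner_diameter` | tube bore $D_i$ | µm | 305 |
| `length` | tube length $L_v$ | mm | 11 |

The defaults describe a Baerveldt-type non-valved implant in an eye with
moderately advanced glaucoma; `Q_0 = Q_cb (1 - f) = 1.7` µl/min is derived
and cannot be set directly, which keeps the triple consistent. A narrow
bore of 100 µm is used throughout examples as the regime where a suture
has real authority. Interfaces use clinical units; all arithmetic is SI
internally with 1 mm Hg = 133.322 Pa fixed, because $D^4$ in micrometres
is a precision hazard.

## The shape factor

For the open tube $\mathcal{S} = 1$. For a concentric suture the classical
annulus solution gives the closed form

$$\mathcal{S}(\kappa) = \frac{(1-\kappa)^4}{\,1-\kappa^4 +
  (1-\kappa^2)^2/\ln\kappa\,}, \qquad \kappa = D_s/D_i .$$

Two numerical points deserve a note. First, the braces denominator is an
$O(\varepsilon^3)$ difference of $O(1)$ terms as
$\varepsilon = 1-\kappa \to 0$; the package evaluates it through an exact
polynomial rearrangement in $\varepsilon$ with `log1p`, which keeps the
root-finding bracket of the inverse solver usable to $\kappa = 1-10^{-6}$.
Second, $\mathcal{S}$ is *not* monotone and exceeds 1 for thin concentric
sutures (up to $\approx 1.24$ near $\kappa \approx 0.03$): a thin central
wire removes flow logarithmically while $D_h^4$ shrinks only
algebraically. The physically monotone quantity is the occluded-to-open
resistance ratio $\mathcal{S}(\kappa)(1-\kappa)^{-4}$, which increases
strictly from 1 and diverges as the gap closes; inversion is performed on
its logarithm.

For a wall-touching suture (internally tangent circles — the generic
position of a suture denser than aqueous humor, and the one with the
*lower* resistance at equal diameter) no closed form exists. The shape
factor comes from the unit-forced Poisson problem $\nabla^2 \hat v = -1$,
$\hat v = 0$ on the contour, on the section scaled so that $D_h = 1$,
with $\mathcal{S} = (\pi/128)\,(\int \hat v\, \mathrm{d}S)^{-1}$. This
scaling is fixed by two checks enforced in the tests: the circle limit
must return exactly 1 and the concentric case must reproduce the closed
form.

### Numerical scheme

The solver discretizes the section on a uniform Cartesian grid with the
Shortley–Weller stencil: where a stencil arm crosses the contour, the arm
length is replaced by the exact distance to the circle (or polygon edge),
keeping second-order accuracy on curved boundaries. The sparse system is
solved directly. Accuracy control is a two-level Richardson comparison
between resolutions $n$ and $n/2$; the relative estimate
$|\mathcal{S}_n - \mathcal{S}_{n/2}|/((2^p-1)\mathcal{S}_n)$ is attached to
every result and the solve fails loudly if it exceeds the tolerance
(default $5\times 10^{-3}$). The production resolution default is
$n = 192$, where the concentric solve agrees with the closed form to a few
parts in $10^{4}$ across $\kappa \in [0.1, 0.9]$ in about a second per
solve — comfortably inside the stated tolerance with no need for finer
grids in routine use.

The tangency point of the wall-touching geometry is a cusp at which
$\hat v \to 0$. Rather than grading a mesh into the cusp, the scheme
relies on the fact that the cusp neighbourhood carries essentially no
flow, so its contribution to $\int \hat v$ is negligible; the Richardson
comparison is the acceptance check. Measured errors on the shipped table
(below) are $\le 2.5\times 10^{-4}$, supporting that choice. No
artificial gap is introduced at the contact point.

A deliberately low-order variant (`solver = "masked"`, first order: the
first node outside the domain is pinned to zero) exists as a cross-check,
and the test suite additionally reimplements it independently of the
package internals.

### The wall-touching table

Because the inverse solver calls $\mathcal{S}(\kappa)$ inside a
root-finding loop, wall-touching values are interpolated rather than
solved per call: a 33-point table on $\kappa = 0, 1/32, \dots, 1$
(endpoints anchored analytically at $\mathcal{S}(0)=1$,
$\mathcal{S}(1)=0$) ships at `inst/extdata/shape_factor_wall_touching.csv`,
computed by this package's own solver at resolutions up to $n = 1536$ for
the thinnest gaps, and is interpolated with a Hyman-filtered monotone
spline. Inversion for wall-touching placement is limited to the solved
range $\kappa \le 31/32$; targets beyond it raise a "suture alone
insufficient" error rather than extrapolating.

## Steady states and regime selection

The post-implant state solves the network for the IOP $p_c$. The
trabecular-open balance is computed first and accepted iff its $p_c$
exceeds $p_{ev}$; otherwise the trabecular branch is shut and
$p_c = p_b + \Delta p_\text{tube}(Q_0)$. The two branches agree at
$p_c = p_{ev}$ (continuity is tested by bracketing the boundary), and
equality is assigned to the closed regime. If neither assumption is
strictly consistent — possible only in a sliver at the boundary — the
state is returned pinned at $p_c = p_{ev}$ with a `boundary` flag rather
than failing. Design inversions (bore for a target IOP at fixed length,
and length at fixed bore) use the corresponding closed forms and are
verified by round trip through the forward solver to $10^{-9}$.

## Suture correction

Eliminating $p_b^{(1)}, p_b^{(2)}$ through constant $R_b$ turns the
correction into a scalar relation between the measured IOP $p_c^{(1)}$,
the target $p_c^{(2)}$ and the required resistance ratio
$\mathcal{S}_2 (1-\kappa)^{-4}$, with three cases by the position of the
two IOPs relative to $p_{ev}$. The case formulas are continuous across
both boundaries and were verified against an explicit numerical solve of
the underlying five-equation system to $\sim 10^{-15}$, including the
$p_{ev} p_r$ cross terms that vanish at the default $p_r = 0$ (for
$p_r > 0$ the expressions are implemented exactly as derived; no
independent worked value exists for that corner, which is why the test
relies on the network oracle).

Forward prediction with $p_c^{(1)} \le p_{ev}$ evaluates the both-closed
expression first and falls back to the mixed one when the predicted IOP
contradicts the closed assumption; monotonicity of the network makes
exactly one case self-consistent. The large-$p_g$ approximation (which
needs neither $p_r$ nor $p_{ev}$) is an explicit opt-in
(`approximate = TRUE`), not a default, since it is motivated only by
those parameters being unmeasured in clinic; its first-order agreement
with the exact both-open formula is a tested property.

Degenerate inputs are rejected with typed conditions
(`iopflow_infeasible_error`, `iopflow_domain_error`,
`iopflow_numerical_error`, `iopflow_geometry_error`), which the
command-line interface maps to documented exit statuses. A measured
$p_c^{(1)}$ implying negative implant flow is an error, not a guess.

## What the defaults emulate, and limits

The default parameter set represents a single idealized adult eye with
pre-surgery IOP of 35 mm Hg. Passing tests under these conditions shows
internal consistency of the network model and the accuracy of the shape
factor machinery; it does not validate the clinical assumptions —
constant $R_b$ across interventions, rigid straight suture, linear
trabecular resistance — against patient data. Known limitations, stated
rather than modelled: suture bending (which raises resistance well above
the straight-suture bound and is the package's favoured explanation for
clinically observed over-corrections), bleb cicatrization dynamics,
valved implants, non-Newtonian rheology, multiple sutures in one lumen,
and transient or pulsatile behaviour.

## Problem sizes used in the checks

The shipped test suite runs the Poisson solver at $n = 64$–$192$ (with
$n = 192$ the production default used for the circle-limit and
closed-form-agreement checks), sweeps IOP grids at 0.02–0.5 mm Hg
spacing, and uses a few dozen randomized network problems under fixed
seeds; the whole suite completes in well under a minute on one core.
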
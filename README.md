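# iopflow

Steady-state modelling of intraocular pressure (IOP) after implantation of
a glaucoma drainage device, and of its correction by an intraluminal
suture.

## The problem

Glaucoma drainage devices shunt aqueous humor from the anterior chamber
through a fine tube into a subconjunctival filtration bleb. Over-drainage
causes hypotony (IOP of 2–6 mm Hg), which surgeons treat by threading a
suture into the tube lumen to raise its hydraulic resistance. There is no
standard rule for choosing the suture diameter, and outcomes are hard to
reproduce. `iopflow` implements an analytical model of this system for the
people who need numbers out of it: modellers of ocular fluid mechanics and,
indicatively, surgeons planning a hypotony correction. All reported suture
diameters are **upper bounds** — bleb cicatrization between interventions
and bending of the suture inside the tube only add resistance — and nothing
here is clinical decision authority.

## The model

Flow in the tube is creeping and fully developed, so the pressure drop
obeys the generalized Hagen–Poiseuille law

    p_c − p_b = 128 S L_v μ Q_i / (π D_h⁴),

where `D_h = D_i − D_s` is the hydraulic diameter and `S` a dimensionless
shape factor of the cross-section: `S = 1` for the open tube, a closed-form
annulus expression for a concentric suture, and the solution of a Poisson
problem (`∇²v̂ = −1`, `v̂ = 0` on the contour, section scaled so `D_h = 1`,
`S = (π/128)/∫v̂ dS`) for a suture resting against the wall — computed here
with a second-order Shortley–Weller finite-difference solver and shipped as
an interpolation table.

The eye is a lumped network: ciliary inflow `Q_cb` minus a uveoscleral
fraction feeds two parallel outflow paths — the trabecular
meshwork/Schlemm's canal branch, a linear resistance calibrated from the
pre-surgery IOP `p_g` and carrying flow only while IOP exceeds the
episcleral venous pressure `p_ev`, and the implant in series with the bleb,
an effective resistance `R_b = (p_b − p_r)/Q_i`. Assuming `R_b` unchanged
between interventions eliminates the unmeasurable bleb pressure and yields
closed-form forward (given `D_s`, predict the new IOP) and inverse (given a
target IOP, choose `D_s`) solvers across the three flow-regime cases
(both IOPs above `p_ev`, mixed, both below).

## Worked example

A narrow-bore implant (`D_i` = 100 μm, `L_v` = 11 mm) left the IOP at
4 mm Hg and the surgeon wants 6 mm Hg:

```r
library(iopflow)
eye <- eye_parameters()   # p_g 35, p_ev 10.5, p_r 0 mm Hg, Q_0 1.7 uL/min
sol <- suture_diameter_for_target(eye, implant_geometry(100, 11),
                                  p_c1 = 4, p_c2 = 6,
                                  placement = "concentric")
sol
#> <correction_solution> (inverse, both_closed case)
#>   p_c1 = 4 -> p_c2 = 6 mm Hg (increase 2)
#>   D_s = 33.85 um (concentric, kappa = 0.3385), S_2 = 0.7277, resistance ratio = 3.8
#>   D_s is an upper bound: bleb cicatrization or suture bending only add resistance.
```

Both IOPs sit below `p_ev` = 10.5 mm Hg (the commonest case in practice),
so the both-closed formula applies: the tube must multiply its resistance
by 3.8, which a ~34 μm coaxial suture achieves. The forward check:

```r
tidy(predicted_iop_after_suture(eye, implant_geometry(100, 11), 4,
                                suture_config(35, "concentric")))
#>   mode     p_c1  p_c2 delta   D_s kappa placement  ...  case
#>   forward     4  6.13  2.13    35  0.35 concentric ...  both_closed
```

By contrast a Baerveldt-type tube (`D_i` = 305 μm) is hydraulically
transparent — the full ciliary inflow drops under 0.01 mm Hg across it —
so thin sutures do nothing:

```r
tube_pressure_drop(2, implant_geometry(305, 11))
#> [1] 0.009711618
iop_increase_sweep(eye, implant_geometry(305, 11), "wall_touching",
                   p_c1 = 4, D_s = c(150, 250, 290))
#>    p_c1   D_s   p_c2   delta case
#> 1     4   150   4.01  0.0086 both_closed
#> 2     4   250   4.46  0.46   both_closed
#> 3     4   290   9.95  5.95   both_closed
```

Sweep tables are tibbles with `autoplot()` methods; `plot_shape_factor_curve()`
draws `S(κ)` for both placements. A thin command-line interface is
installed at `exec/iopflow` (subcommands `shape-factor`, `predict`,
`design-suture`, `design-implant`, `figures`; exit statuses 0 ok, 2 usage,
3 infeasible, 4 numerical).

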
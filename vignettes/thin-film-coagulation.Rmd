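---
title: "A reduced thin-film model of thrombin and fibrin generation under venous flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced thin-film model of thrombin and fibrin generation under venous flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clotcore)
```

## The model

When whole blood flows over a collagen/tissue-factor (TF) patch at venous
shear rates, platelets rapidly build a deposit whose inner, P-selectin
positive "core" — about 15 µm thick and roughly half void by volume — is
where thrombin is generated and fibrin accumulates. `clotcore` treats this
core as a well-mixed thin film that exchanges material diffusively with the
plasma streaming over it. Three transport assumptions make the chemistry
tractable:

1. **Substrates are clamped at plasma levels.** Zymogens (FX, FIX, FII,
   FXI, fibrinogen) diffuse into the film faster than they are consumed, so
   each Michaelis–Menten activation reaction becomes first order in its
   enzyme with coefficient
   $\alpha = k_{cat}\,S_0/(K_m + S_0)$, optionally damped by an
   *effectiveness factor* $\eta \le 1$ (actual over transport-unlimited
   rate). Fibrinogen, at 340 kDa, is the one substrate whose delivery into
   the dense core is strongly diffusion limited, hence $\eta_5 = 0.05$.
2. **Free products escape quickly.** Free thrombin and FXIa leave the film
   by diffusion with a 2 s half-life ($k_{elute} = \ln 2/2$ s⁻¹), the
   measured escape half-life of albumin from a clot core. Surface-bound
   complexes (TF/FVIIa and, by construction, the FXa/FVa and FIXa/FVIIIa
   surrogates) do not elute.
3. **Inhibition is lumped first order.** Proteases are inactivated with a
   one-minute half-life ($k_i = \ln 2/60$ s⁻¹; three minutes for TF/FVIIa,
   whose FVIIa is not regenerated). Fibrin-bound thrombin is fully
   protected.

Cofactor generation (FVa, FVIIIa) is taken as non-rate-limiting, so
"FXa" stands for prothrombinase and "FIXa" for intrinsic tenase. The
resulting eight-state stiff ODE system tracks TF\*, FXa, FIXa, FXIa,
fibrin, and free, E-domain-bound, and γ′-site-bound thrombin. Fibrin's
"antithrombin-I" activity is modelled as kinetically controlled reversible
adsorption at two site classes that appear in proportion to fibrin
monomer: a weak E-domain site ($K_D = 2.8$ µM, 1.6 sites/monomer) and the
strong γ′-chain site carried by the γ′-fibrinogen splice variant
($K_D = 0.1$ µM, 0.3 sites/monomer), both with diffusion-limited
association $k_f = 100$ µM⁻¹s⁻¹. Thrombin in the catalytic and loss terms
is *free* thrombin; bound thrombin is treated as catalytically silent,
which is a deliberate simplification — real fibrin-bound thrombin retains
activity toward small substrates.

The cascade starts from 2.2 pM TF/FVIIa in the core (1 TF molecule/µm²
with 1% instantaneously complexed with plasma FVIIa, homogenized over the
pore volume — `tf_surface_to_concentration()` reproduces this number) and
everything else at zero.

```{r rates}
p <- default_parameters()
p$reactions[, c("id", "substrate", "enzyme", "alpha", "eta")]
```

## What the baseline run shows

```{r baseline}
traj <- simulate_cascade(p, t_end = 800)
traj
```

The cascade amplifies over three decades: pM-level extrinsic tenase makes
tens of pM intrinsic tenase, ~15 nM prothrombinase, and tens of µM
(mostly fibrin-bound) thrombin, with thrombin-feedback activation of FXIa
(a ~5 pM plateau) dominating production after ~500 s. Only of order 1% of
thrombin remains free:

```{r partition}
tail(thrombin_partition(traj)[, c("time", "free", "total", "frac_free")], 3)
```

Two caveats about absolute endpoint values. First, the time-integrated
states are exquisitely sensitive to when the FXIa feedback loop ignites:
the late-time levels of the *flow* variables (free thrombin, FXa, FIXa,
FXIa) sit on a self-limiting attractor set by the balance of production,
escape and fibrin capture, while total thrombin and fibrin keep
integrating. Doubling the escape half-life from 2 s to 4 s multiplies
thrombin at 800 s by ~2.8× in this implementation
(`scenario(escape_halflife = 4)`), which is the model's strongest single
sensitivity. Second, because of that sensitivity, implementations of the
same printed equations can agree closely on the quasi-steady species yet
differ by factors of order two in the accumulated totals at a fixed clock
time; this package integrates the system as printed, at tight tolerances
(BDF, rtol 1e-8, atol 1e-12 µM; halving the tolerances moves endpoints by
well under 0.1%).

## Scenarios

`scenario()` composes the in silico experiments: `gprp` removes fibrin
(either by zeroing fibrin generation, the default, or by making both sites
non-binding); `hemophilia` zeroes FIXa generation and intrinsic tenase
activity (reactions 2 and 3); `no_fxia_feedback` zeroes the thrombin→FXIa
→FIXa loop (reactions 6 and 7); `gamma_prime_scale` rescales the γ′ site
density (50–200% of normal γ′-fibrinogen); `escape_halflife` sets the
free-species elution half-life. Knockouts act through a per-reaction mask
so the derived $\alpha$ column always stays consistent with its defining
formula. `pathway_decomposition()` reruns the cascade with and without the
FXIa loop on a shared grid and attributes the late FIXa/FXa/thrombin to
the feedback pathway by curve subtraction.

```{r scenarios}
scenario_compare(p, c("baseline", "gprp", "hemophilia"),
                 t_end = 800)[, c("scenario", "iia_total_uM", "fibrin_uM",
                                  "tat_fmol", "f12_fmol")]
```

The orderings, not the absolute values, are the robust content here:
blocking fibrin raises the eluted-thrombin (TAT) flux at every time beyond
the first ~100 s because captured thrombin cannot elute; hemophilia
collapses thrombin output by more than two orders of magnitude; removing
the FXIa loop removes essentially all late-time growth.

## Elution-flux observables

The measurable effluent species are fragment F1.2 (released 1:1 with
thrombin generation and assumed to leak out as fast as it is made) and
thrombin–antithrombin complex (70% of eluted thrombin; the rest is taken
by other inhibitors):

$$J_{F1.2}(t) = \eta_4\,\alpha_4\,[Xa](t)\,\delta, \qquad
  J_{TAT}(t) = 0.7\,k_{elute}\,[IIa_{free}](t)\,\delta .$$

The film factor is written $\delta$ (= pore volume / patch area) exactly
as in the source equations, although the geometric pore volume per area is
$\delta \times$ porosity; `porosity_correct = TRUE` opts into the latter.
Fluxes are in µM·µm/s (×10⁻⁹ for mol m⁻² s⁻¹) and `cumulative_eluted()`
integrates them to femtomoles over the 250 × 250 µm patch. The
fibrin mass conversion uses exactly 3 µM per mg/mL, the value implied by
the model's own anchors (9 µM ↔ 3 mg/mL plasma fibrinogen, 90 µM ↔
30 mg/mL intraclot fibrin).

## The channel transport companion

`run_loading()`/`run_elution()` simulate the same binding chemistry
spatially: a 1000 × 60 µm channel at a 200 s⁻¹ clean-wall shear rate with
a 250 × 15 µm porous fibrin zone 150 µm from the inlet. A thrombin flux
(in the experiments, the F1.2-derived production rate; here typically the
ODE model's own `fixture_from_ode()` output) enters along the clot's
bottom boundary, free thrombin advects and diffuses, and the two binding
ODEs run in every clot cell against site loads 1.6 × fibrin(t) and
0.3 × fibrin(t).

Numerical choices, in the package's own terms:

* **Velocity.** Steady Stokes flow with Brinkman drag in the clot, on a
  staggered (MAC) grid, assembled sparse and solved directly. The inlet
  carries the developed parabolic profile scaled to the requested wall
  shear rate; the outlet is open at zero reference pressure. The discrete
  divergence is conserved to machine precision, and with the clot removed
  the solver reproduces plane Poiseuille flow.
* **Transport.** Conservative finite volumes with first-order upwind
  advection and harmonic-mean central diffusion, advanced by backward
  Euler with the operator factorized once per step size. The implicit
  step removes the CFL restriction, which matters because elution from a
  well-loaded clot must be followed for thousands of seconds; the price is
  first-order time accuracy, so loading uses a smaller step (0.1–0.25 s)
  than elution (0.5–5 s). Mass budgets (influx − efflux − storage) close
  to round-off by construction and are recorded every few steps.
* **Binding.** Operator-split per cell and solved implicitly: with the
  end-of-step free concentration as the single unknown, both bound pools
  have closed-form backward-Euler updates, and the local conservation
  equation is solved by a bracketed, vectorized Newton iteration. This
  keeps the 10⁴ s⁻¹-scale association rates stable at transport-sized
  steps and conserves thrombin exactly cell by cell.
* **Diffusivity and permeability** are not part of the published
  parameter set. Defaults: D = 60 µm²/s free (Stokes–Einstein scale for a
  ~36 kDa protein), reduced to 15 µm²/s in the clot
  (porosity/tortuosity ≈ 0.25), consistent with the 2 s escape half-life
  over a 15 µm film; Darcy permeability 10⁻³ µm² (platelet-thrombus
  literature order), which makes the clot interior diffusion dominated.
  Both are configurable in `transport_params()`.

The physically meaningful output is the *retardation* of elution by
binding: a site-free clot clears in seconds (diffusion across 15 µm into
the flow), while at 90 µM fibrin the clot-averaged total thrombin halves
roughly 300–450× more slowly — within a factor two of the dilute-limit
equilibrium retardation $1 + \theta_E/K_E + \theta_{\gamma'}/K_{\gamma'}
\approx 322$, and monotone in fibrin load. The published experiment-driven
figures (61 nM free vs 5.5 µM total at 500 s; a 1.1 h elution half-life)
used measured flux and fibrin series that were never published
numerically, so this package checks those *properties* rather than the
numbers.

```{r pde, eval = FALSE}
g <- channel_geometry(nx = 40, ny = 40)
tp <- transport_params()
fx <- fixture_from_ode(traj)
loading <- run_loading(g, tp, J = as.data.frame(fx$J),
                       fibrin = as.data.frame(fx$fibrin), t_end = 800)
elution <- run_elution(loading$field, t_end = 20000, dt = 2)
elution$halflife
```

## Problem sizes, degenerate inputs, limitations

The test suite runs the full 800 s cascade (sub-second) and channel runs
of 20 × 12 to 80 × 48 cells with loading windows of 300–800 s and elution
windows up to 9000 s — sizes chosen so the whole suite completes in well
under a minute per module while every assertion still comes from a real
solve. Degenerate inputs are defined: zero fibrin means no binding sites
(bound pools only release); zero substrate means a zero rate; an all-zero
state is a fixed point; a series that never halves reports its final
fraction rather than a half-life. States are accepted down to −10⁻⁹ µM of
solver undershoot and clipped; anything lower aborts the run.

What passing tests do *not* show: the synthetic fixtures are smooth,
noise-free stand-ins for immunoassay-derived series, so agreement with
them says nothing about assay noise, nor about features the reduced model
omits by design — clot growth and moving boundaries, platelet dynamics,
FXIIa/contact activation, mechanistic TFPI/ATIII inhibition, plasmin, or
arterial shear. The γ′-site stoichiometry treats γ′ content as a fixed
fraction of fibrin rather than tracking the splice variant separately.
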
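---
title: "Energy budgets and comparative life-history traits: models and methods"
author: "debtraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy budgets and comparative life-history traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(debtraits)
```

## The model

`debtraits` implements the standard (std) Dynamic Energy Budget model and its
metabolic-acceleration variant (abj) over the full life cycle, and derives
from a species' primary parameters the life-history trait set used in
comparative analyses of fish energetics.

A DEB individual has two mass pools — reserve $E$ (J), which requires no
maintenance, and structure with volumetric length $L$ (cm, volume $V = L^3$)
— plus cumulated maturity $E_H$ (J) and, after puberty, a reproduction buffer
$E_R$.  Food intake follows a scaled functional response $f \in [0,1]$;
assimilation adds $\dot p_A = f\,\{\dot p_{Am}\}\, s\, L^2$ to reserve once
maturity passes the birth threshold $E_H^b$ (feeding starts at birth).
Mobilized reserve

$$\dot p_C \;=\; E\,\frac{E_G\, s\, \dot v\, L^2 + \dot p_S}
                         {\kappa E + E_G L^3},
\qquad \dot p_S = [\dot p_M] L^3 + \{\dot p_T\} L^2,$$

is split by the $\kappa$-rule: a fixed fraction $\kappa$ covers somatic
maintenance $\dot p_S$ and growth $\dot p_G = \kappa \dot p_C - \dot p_S$;
the remainder covers maturity maintenance $\dot p_J = \dot k_J \min(E_H,
E_H^p)$ and maturation or reproduction $\dot p_R = (1-\kappa)\dot p_C - \dot
p_J$.  The factor $s = \min(L, L_j)/L_b$ is the acceleration factor: 1
throughout life for std, and for abj it rises from 1 at birth to
$s_{\mathcal M} = L_j/L_b$ at metamorphosis (maturity $E_H^j$), during which
the individual grows as a V1-morph (surface area proportional to volume).
Setting $E_H^j = E_H^b$ recovers std exactly; this degeneracy is tested to
solver precision.

The algebraic closed form of $\dot p_C$ is used for all stages (no separate
embryo formulation), so embryos are simply the $\dot p_A = 0$ case.  In a
constant environment the scaled reserve density $e = E/(E_m L^3)$ equilibrates
at $f$, and post-acceleration growth reduces to von Bertalanffy,
$dL/da = \dot r_B (L_\infty - L)$ with
$\dot r_B = \dot k_M g / (3(f + g))$ and
$L_\infty = s_{\mathcal M}(f L_m - L_T)$.
This closed form serves as an independent oracle in the test suite
(agreement to $10^{-8}$ cm after metamorphosis).

### Aging and survival

Death by aging follows the two-parameter Weibull–Gompertz module: damage
acceleration $q$ and hazard $h$ obey

$$\dot q = \left(q \tfrac{L^3}{L_m^3} s_G + \ddot h_a\right) e
           \left(\tfrac{s \dot v}{L} - \dot r\right) - \dot r\, q,
  \qquad \dot h = q - \dot r\, h,$$

with $\dot r$ the specific structural growth rate.  At fixed size and $s_G =
0$ this integrates to Weibull survival $S(a) = \exp(-\ddot h_a e \dot v
a^3/(6L))$, which the suite checks against the ODE solution.  $s_G = 1$ gives
the abrupt ("programmed death") decay; the package accepts any $s_G \ge 0$
with no special-casing.  Survival is integrated as a cumulated hazard, so
optional background and thinning hazards compose additively and $S$ cannot
underflow the solver.

### The maternal effect and the embryo seed

The initial reserve $E_0$ of an egg is defined implicitly by the maternal
effect: the scaled reserve density at birth equals the mother's $f$.  The
package locates $E_0$ by monotone bracketing and root refinement on
$e(a_b) - f$ (tolerance $10^{-6}$), integrating the embryo from a structure
seed $L_{seed} = 10^{-4}$ cm.  Because structure grows at the finite rate
$\dot v/3$ as $L \to 0$, starting at a positive seed omits the startup time
$3 L_{seed}/\dot v$; the embryo clock therefore starts at that offset, which
makes the reported age at birth insensitive to the seed (relative change
below $10^{-6}$ between seeds of $10^{-4}$ and $5\times10^{-5}$ cm, tested).
$E_0$ is seed-insensitive without the correction.

### Events and solver settings

Maturity thresholds (birth, metamorphosis, puberty) are located by the
solver's root finding (`deSolve::lsodar`, rtol $10^{-8}$, atol $10^{-10}$);
each stage is then re-integrated densely up to the event so output grids
resolve every stage, and the state is re-initialized exactly at the
threshold.  A maturation stall ($\dot p_R \downarrow 0$ before a threshold)
terminates integration with an explicit unreachable-birth/-puberty error;
starvation ($\dot p_G < 0$) is likewise an error, since all analyses here are
at constant food where it cannot occur, and shrinking rules are out of scope.

### Respiration

Dioxygen consumption is obtained by mass balance: for each aggregate
transformation (assimilation, dissipation, growth) the organic C-mol fluxes
per joule follow from the composition conventions, and the mineral fluxes
(CO2, H2O, O2, NH3) close the 4x4 element balance.  This yields
$J_{O_2} = \eta_A \dot p_A + \eta_D \dot p_D + \eta_G \dot p_G$ with
$\dot p_D$ the dissipated power.  At constant $f$, $J_{O_2}(L)$ for adults is
exactly a polynomial with constant, $L^2$ and $L^3$ terms — no linear term —
which the suite verifies by three-point reconstruction.  The composition
defaults (dry structure density 0.1 g/cm^3, molar weights 23.9 g/mol,
chemical potentials 550 and 500 kJ/mol, indices CH$_{1.8}$O$_{0.5}$N$_{0.15}$
for food, reserve, structure and faeces, digestion efficiency 0.8, faeces
yield 0.1) are conventions of the generalized animal, all configurable via
`deb_composition()`.

### Temperature

All rates are stored at the reference temperature (20 °C by convention) and
corrected to other body temperatures with the one-parameter Arrhenius factor
$c_T = \exp(T_A/T_{ref} - T_A/T)$: rates multiply by $c_T$, times divide by
it, and the aging acceleration (dimension d$^{-2}$) corrects by $c_T^2$.
Dimensionless traits are temperature-invariant, which `trait_record()`
preserves exactly.

## Life-history traits

`trait_record()` derives, per species at constant $f$ (default 1, the
"maximum" traits) and at 20 °C:

* compound parameters $[E_m] = \{\dot p_{Am}\}/\dot v$ and
  $L_m = \kappa\{\dot p_{Am}\}/[\dot p_M]$;
* ages, structural lengths and wet weights at birth, metamorphosis and
  puberty, and ultimate size;
* the acceleration factor $s_{\mathcal M}$, the precociality coefficient
  $s_H^{bp} = E_H^b/E_H^p \in (0,1)$, and the supply stress
  $s_s = \dot k_J E_H^p [\dot p_M]^2 / (f^3 s_{\mathcal M}^3 \{\dot
  p_{Am}\}^3)$, which equals $\dot p_J \dot p_S^2/\dot p_A^3$ at ultimate
  size and is bounded by $\kappa^2(1-\kappa) \le 4/27$ (attained at the
  maturation ceiling with $\kappa = 2/3$);
* lifespan $a_m = \int_0^\infty S(a)\,da$ under pure aging, truncated at
  $S < 10^{-6}$ with an exponential tail correction;
* the maximum reproduction rate $\dot R_\infty = \kappa_R \dot
  p_R(L_\infty)/E_0$ (a continuous egg-flow abstraction; clutch handling and
  spawning discretization are out of scope);
* lifetime reproductive output $N_\infty = \int S(a) R(a)\, da$ and lifetime
  neonate mass $N_\infty W_w^b$;
* the specific body growth rate at maximum growth $\dot r_m$, located on the
  trajectory with the weight derivative evaluated analytically from the
  fluxes (for a reserve-equilibrated std individual this sits at $L = \tfrac23
  L_\infty$ with $\dot r_m = 1.5\, \dot r_B$);
* weight-specific respiration at ultimate size and the specific population
  growth rate under thinning (below).

Wet weight uses $W_w = 1\,\mathrm{g\,cm^{-3}} \cdot L^3 + (E + E_R)\, w_E /
(\mu_E \cdot 0.2)$ — wet structure density 1 and reserve dry-to-wet fraction
0.2 — as documented conventions; no reported quantity depends on them beyond
monotonicity.  Body weight for the growth-rate trait excludes the
reproduction buffer (the buffer is continuously converted to eggs).

Two readings of the "weight-specific neonate mass production" trait coexist
in the field: a rate, $\dot R_\infty W_w^b / W_w^\infty$ (per day), and the
dimensionless lifetime ratio $N_\infty W_w^b / W_w^\infty$.  Both are
reported (`jWb_i` and `NWb_Wi`) rather than resolving the ambiguity.

## Population growth under thinning

Thinning is the age-dependent hazard that keeps a cohort's total feeding
constant: individual intake scales as $s L^2$, so $h_{thin} =
\mathrm{d}\ln(s L^2)/\mathrm{d}a$ — $2\dot L/L$ after acceleration, $3 \dot
L/L$ during it, zero before birth (embryos do not feed).  By construction
$N(a)\,s(a)L(a)^2$ is constant from birth on, which the suite asserts to
$10^{-8}$.

The specific population growth rate solves the Euler–Lotka characteristic
equation $1 = \int_0^\infty e^{-ra} S(a) R(a)\,da$ with $S$ under the
configured hazards and $R(a) = \kappa_R \dot p_R(a)/E_0$ (zero before
puberty).  The integrand is monotone decreasing in $r$, so the root is unique;
it is bracketed starting from $[-0.5, 5]$ d$^{-1}$ with geometric expansion
and refined to a residual below $10^{-6}$.  The schedule is integrated to
$10\times$ lifespan or until survival falls below $10^{-10}$, whichever
comes first.  Sub-replacement schedules ($R_0 \le 1$) return the negative
root with a warning; schedules with no surviving reproduction at all are an
error.

## Comparative layer

* **Survivor curves** over species use strict exceedance — the fraction of
  species whose value exceeds the abscissa — matching how such curves are
  drawn in comparative energetics; medians use the ordinary midpoint
  convention.
* **Co-variation fits** are ordinary least squares on log10-transformed
  values, with a fixed-slope mode that fits only the intercept (the
  reference-line idiom for slopes of 1, −1 or −1.2).
* **Classical MDS** standardizes the 15-trait set (lifespan, ages at birth
  and puberty, lengths at birth, puberty and ultimate, reserve capacity,
  reproduction rate, supply stress, precociality, maintenance, conductance,
  allocation fraction, maturities at birth and puberty): log10 for strictly
  positive unbounded traits, identity for the bounded indices ($\kappa$,
  $s_s$, $s_H^{bp}$), then per-column z-scores, Euclidean distances, and
  Torgerson double-centering.  Whether source analyses log-transform is not
  stated anywhere authoritative; this scheme is the package's documented
  choice, recorded in the result object (`transform`) so alternatives remain
  comparable.  Trait loadings are Pearson (optionally Spearman) correlations
  with the first coordinate.

## The synthetic generator

`generate_params()` produces parameter tables with the statistical structure
the comparative layer assumes, so the full pipeline is testable without an
external database:

* a zoom factor $z$ (log-uniform, default 0.2–20 cm) scales the extensive
  parameter $\{\dot p_{Am}\}$ linearly and the maturity thresholds as $z^3$,
  embodying the physical co-variation rules; intensive parameters stay at the
  generalized-animal reference values
  ($\{\dot p_{Am}\} = 22.5$ J d$^{-1}$cm$^{-2}$, $\dot v = 0.02$ cm/d,
  $\kappa = 0.8$, $[\dot p_M] = 18$ J d$^{-1}$cm$^{-3}$, $\dot k_J = 0.002$
  d$^{-1}$, $E_G = 2800$ J cm$^{-3}$, $E_H^b = 0.275$ J, $E_H^p = 166$ J,
  $\ddot h_a = 10^{-6}$ d$^{-2}$, $s_G = 0.01$, $T_A = 8000$ K);
* independent lognormal scatter (default 0.05 log10 units — a deliberately
  mild inter-species spread that keeps designed contrasts identifiable at
  test-scale sample sizes; logit-scale for $\kappa$);
* a **waste-to-hurry** group multiplies both $\{\dot p_{Am}\}$ and $[\dot
  p_M]$ by one shared lognormal factor (median 3).  Nothing else is edited:
  any response of growth, reproduction, size or lifespan must emerge from the
  mechanism.  Building the empirical lifespan–maintenance slope in would make
  its "recovery" circular, so it is deliberately absent;
* an **accelerating** group uses abj with $E_H^j$ calibrated by secant
  iteration so the *realized* $s_{\mathcal M}$ lands in the configured range
  (default 2–6);
* a **demand-like** group (large neonates, raised maturity levels and
  maturity maintenance, lower $\kappa$) emulates the chondrichthyan end of
  the supply–demand spectrum.

Draws failing an analytic viability screen (positive reproduction flux at
ultimate size, $E_H^b < E_H^p$) are resampled, at most 100 times per row
before erroring.  Tables are fully reproducible from the seed.

What the generator does **not** emulate: the real taxonomic composition of
any database, phylogenetic correlation between species, measurement error in
estimated parameters, and any built-in lifespan–maintenance or
respiration–lifespan slope.  Passing recovery tests therefore demonstrates
that the pipeline measures what the mechanism produces — not that real fish
follow the mechanism.

## What the mechanism does and does not produce

Two findings from building the package are worth stating plainly.

*Waste-to-hurry and lifespan.*  Jointly raising $\{\dot p_{Am}\}$ and $[\dot
p_M]$ leaves $L_\infty$ exactly unchanged and boosts the von Bertalanffy
rate, peak specific growth and the reproduction rate — all asserted on the
reference fixture.  It does **not** shorten the aging lifespan: damage
induction $\ddot h_a e (s\dot v/L - \dot r)$ is unchanged at equal length
(neither $\dot v$, $\ddot h_a$ nor $L_\infty$ moves), so $a_m$ is essentially
flat (in fact slightly up, via the shorter transient spent at small $L$ where
specific mobilization is high).  The short lives of waste-to-hurry species in
nature must therefore enter through the aging parameters themselves — the
mechanism "works via respiration", not through the aging ODEs at fixed
$\ddot h_a$ — and the package treats any assertion that the multiplier alone
shortens $a_m$ as false.

*Reserve capacity counteracts the growth boost.*  Because $[E_m]$ is
extensive, the absolute von Bertalanffy rate falls with size, and for large
$z$ the waste-to-hurry boost on $\dot r_B$ fades ($[E_m]$ dominates $E_G$ in
the denominator).  Recovery tests therefore compare growth at equal size.

## Numerical choices and problem sizes

Tolerances: solver rtol $10^{-8}$/atol $10^{-10}$ (tighter where an
invariant is asserted at $10^{-8}$); shooting tolerance $10^{-6}$ on scaled
reserve density; characteristic-equation residual $10^{-6}$; event ages at
solver root precision.  Everything is deterministic except the generator,
which is seeded.

Test problem sizes are chosen so the designed effects are unambiguous while
the full suite stays fast: co-variation slopes use $n = 300$ baseline
species (no simulation needed), end-to-end trait recovery uses 20 species
per group, and the MDS separation check uses 15 per group on a narrowed zoom
range (1–4 cm) so the demand signature is not drowned by the body-size axis.
Regression fixtures for the reference animal ($E_0$, birth and puberty ages
and lengths, lifespan) were frozen from an independent fixed-grid RK4
integrator with step $5\times10^{-3}$ d and bisection to $10^{-9}$ J.

## Limitations

No parameter estimation from data; no dynamic food or temperature forcing
(all traits are at constant conditions); no starvation/shrinking rules; no
foetal development; no reproduction-buffer/spawning discretization; no
surface-area maintenance estimation (the parameter exists, defaults to 0,
and whether it accelerates under abj is moot at that default — implemented
as non-accelerating); no phylogenetically corrected statistics.
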
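---
title: "Coupled PBPK and whole-body flux modelling of ethanol and acetaldehyde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled PBPK and whole-body flux modelling of ethanol and acetaldehyde}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`ethanolWBM` couples two descriptions of ethanol disposition that operate on
different time scales:

* a **physiologically-based pharmacokinetic (PBPK) layer** — 34 ordinary
  differential equations for the concentrations of ethanol and acetaldehyde
  in 14 perfused tissue compartments (lung, liver, stomach, small and large
  intestine, pancreas, spleen, kidney, skin, muscle, adipose, brain, heart,
  and a pooled venous blood compartment) and 3 gut lumina (stomach, small
  intestine, large intestine);
* a **whole-body stoichiometric layer** — a reduced flux network for
  ethanol metabolism and excretion (diet intake, hepatic alcohol
  dehydrogenase, colon catalase, structurally silent colon/adipose alcohol
  dehydrogenase, breath/urine/sweat/feces exchange, and hepatic plus colonic
  aldehyde dehydrogenase closing the acetaldehyde species), solved as a
  linear program at steady state.

A generic perfused compartment follows

$$\frac{dC_i}{dt} = \frac{Q_i}{V_i}\left(C_{art} - \frac{C_i}{K_i}\right)
  - k_i C_i - R_i,$$

with organ blood flow $Q_i$ (L/min), organ volume $V_i$ (L), tissue:plasma
partition coefficient $K_i$, first-order absorption/transport constants
$k_i$, and a reaction term $R_i$ (mM/min) supplied either by closed-form
Michaelis–Menten kinetics (standalone PBPK mode) or by the most recent flux
solution (coupled mode). The circulation has two mixing points: the lung
receives the full cardiac output from the venous pool and feeds the
arterial side, and the liver receives the hepatic artery plus the portal
venous outflow of stomach, intestines, pancreas and spleen. Flow is
conserved exactly at both points by construction, and the validity method
of `PhysiologyParameters` asserts it.

The flux layer maximises hepatic alcohol dehydrogenase flux subject to
steady state $Sv = 0$, capacity bounds, and route-fraction couplings, in a
dynamic-FBA loop: the solution is held constant in the ODE system until the
held rates deviate from the current Michaelis–Menten rates by more than a
relative tolerance (default 1%), at which point the program is re-solved at
the current concentrations. Dose events also trigger a re-solve.

# Physiology and partitioning

Organ volumes, flows and tissue composition ship as a delimited reference
table (`inst/extdata/physiology_male.tsv`). The scaling convention — an
open choice, since several conventions coexist in the literature — is
**mass scaling**: non-adipose organ volumes scale with lean body mass
relative to the 73 kg / 20% fat reference male; adipose volume is
`weight * bodyFat / 0.916` (adipose density in kg/L); cardiac output scales
allometrically as $6.3\,(W/73)^{0.75}$ L/min and is distributed by flow
fractions that sum to exactly one over the systemic organs. Body-surface
scaling would be an equally defensible convention; the table documents the
one used so it can be swapped as data.

Tissue:plasma partitioning uses the standard composition equation for
non-ionised solutes,

$$K = f_u\,\frac{P\,(NL_t + 0.3\,PL_t) + (W_t + 0.7\,PL_t)}
               {P\,(NL_p + 0.3\,PL_p) + (W_p + 0.7\,PL_p)},$$

with $P = 10^{\log P}$ and water/neutral-lipid/phospholipid fractions of
tissue and plasma. For hydrophilic ethanol ($\log P = -0.31$) this reduces
to roughly the tissue:plasma water ratio, which is why the classical
total-body-water distribution model works for ethanol.

# Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `vmaxADH`, `kmADH` | 2.2, 0.4 | mM/min (per L liver), mM | shipped hepatic parameter file (literature-scale stand-in for the external fitted set; replaceable) |
| `vmaxALDH2`, `kmALDH2` | 2.7, 0.0012 | mM/min, mM | mitochondrial low-Km aldehyde dehydrogenase |
| `vmaxALDH2Colon` | 0.5 | mM/min (per L colon) | colonic ALDH activity well below hepatic |
| `kStom`, `kSI`, `kStomSI` | strength-dependent | 1/min | drink-strength anchors at 5.1 / 12.5 / 20 %w/v |
| `clUrine`, `clSweat` | 0.04 | L/min | see "Auxiliary routes" below |
| `clCatalase` | 0.01 | L/min | keeps catalase a sub-percent contributor |
| `tol` | 0.01 | – | dynamic-FBA re-solve tolerance (0.1% for fine reproduction runs) |
| `dt` | 1 | min | FBA hold interval and reporting grid |

Enzyme genetics and pharmacology enter as multiplicative scales on the
aldehyde-dehydrogenase capacity: the homozygous ALDH2 isoform table
(activities 100 … 1.5% of wild type) and a constant blood disulfiram level
mapped to residual activity through a single-parameter exponential
inhibition curve fitted to the shipped in-vitro anchor table (the anchors,
not the exponential form, are authoritative; the fit reproduces them to
within 0.03 on the activity scale). Heterozygous genotypes are rejected
with an informative error — averaging subunit activities would misrepresent
the tetrameric enzyme's dominant-negative behaviour.

# Auxiliary elimination routes

The whole-body layer constrains the minor routes as fractions of
elimination: breath 0.05%, urine 3–10%, sweat 3–10%, feces 0, colon
catalase 0–2%, with the liver window at 90–95%. Fractions are encoded as
linear couplings **relative to the liver flux**, rescaled by the liver
window ($f'_{min} = f_{min}/0.95$, $f'_{max} = f_{max}/0.90$), which keeps
a single LP per solve.

Couplings alone, however, make every auxiliary route a fixed proportion of
the liver flux, so impaired-liver scenarios would show no compensation at
all. Each route therefore carries a **concentration-driven physiological
proposal** — an apparent clearance times the blood (or colon) ethanol
concentration — clipped into its coupling band; the secondary
lexicographic objective (minimise total auxiliary flux, for pivot-order
independence) then selects exactly that proposal. Kidneys and skin
excrete more when blood ethanol is high, which is what produces both the
compensation behaviour (a slower liver leaves blood ethanol high for
longer, so urine and sweat carry more cumulative mmol, up to their caps)
and a cumulative liver share near 91% at normal expression. The clearances
(0.04 L/min each for urine and sweat, 0.01 L/min for catalase) were
calibrated once against those two baseline facts and are not study knobs.
Note the two calibration facts are in mild arithmetic tension: route lower
bounds of 3% + 3% + 0.05% imply a liver share of 94% if the minor routes
sit at their minima, while the target cumulative liver share is ~91%; the
concentration-driven component is what reconciles the two in this
implementation.

Under strong impairment the auxiliary caps (each $\le f'_{max} \cdot
v_{liver}$) let the liver share fall below the nominal 90% window — the
same behaviour the compensation study itself displays — so the window is
enforced through the rescaled couplings rather than as a hard share
constraint.

# The aldehyde bound: a deliberate deviation

Taken literally, bounding *both* dehydrogenases by their Michaelis–Menten
rates at current concentrations deadlocks the coupled model at $t = 0$:
with no acetaldehyde present the aldehyde-dehydrogenase bound is zero, the
acetaldehyde species is closed in $S$, so the alcohol-dehydrogenase flux is
forced to zero and no acetaldehyde can ever be produced. Because the
enzyme's Km is of order 1 µM — far below any concentration at which its
capacity could bind — the LP instead uses the **saturation capacity**
$s \cdot V_{max} \cdot V_{liver}$ as the aldehyde bound (scaled by
expression, isoform and disulfiram), while the PBPK side always eliminates
acetaldehyde with the full saturable kinetics. The stoichiometric closure
still throttles ethanol oxidation to what the aldehyde system can dispose
of, which is the mechanism behind the genotype and disulfiram predictions.

One structural consequence is worth knowing: when the aldehyde capacity is
the binding constraint, production is pinned *at* that capacity, so the
kinetic clearance (which is strictly below $V_{max}$ at any finite
concentration) always lags by the Km-tail $V_{max} K_m/(K_m + C)$. The
escaping acetaldehyde is what reaches the blood. For the most impaired
genotypes this makes the 500-min exposure window production-limited: the
near-null ALDH2.2 variant shows a *smaller* truncated-window AUC than a
12.5%-activity variant, even though its total (untruncated) exposure is
larger and it needs thousands of minutes to return to baseline. The
package reports what the model produces; the tests pin the orderings the
model guarantees and the acceptance suite states the truncated-window
ordering faithfully.

A related deviation: between solves the ethanol fluxes are held constant,
but acetaldehyde elimination is always kinetic rather than held. Holding
the aldehyde flux at its solved value (equal to production) would cancel
acetaldehyde generation identically and no acetaldehyde would ever appear
in blood; the kinetic form is what yields the few-µM circulating
acetaldehyde seen in paired clinical curves.

# Numerics

* **Integrator** — fixed-step Strang splitting per reporting step:
  analytic/implicit reaction half-steps around an RK4 transport step.
  The transport sub-step is capped at 0.125 min (the stiffest perfusion
  eigenvalue, cardiac output over lung water volume, is ≈17/min).
  Saturable sinks are advanced by an exact implicit solve of the
  integrated Michaelis–Menten relation; the liver/colon acetaldehyde
  pools combine held production and saturable clearance in a
  backward-Euler step whose fixed point is the quasi-steady concentration
  $K_m r/(V_{max} - r)$ — an explicit scheme would need sub-millisecond
  steps to resolve the µM-Km sink. Against a stiff adaptive solver
  (`deSolve::lsoda`, rtol 1e-8) the split integrator agrees to ~0.1% in
  blood-ethanol AUC; halving the sub-step moves the AUC by well under
  0.5%.
* **Mass accounting** — every elimination route integrates into a
  cumulative mmol ledger; the audit `massBalance()` closes dose = body +
  lumen + eliminated to machine precision in unclamped runs and is
  asserted below 0.5% everywhere.
* **Nonnegativity** — held-rate sinks are availability-clamped per
  sub-step and clamps are counted in the audit metadata; transport states
  are floored at zero (deficits beyond 1e-9 mM are logged).
* **LP** — a package-internal dense two-phase simplex with Bland's rule
  (finite termination under degeneracy). The bundled networks have 12
  reactions and ~25 active rows, where a dense tableau is ample. Solutions
  are tie-broken lexicographically (maximise liver flux, then minimise
  total auxiliary flux) so they do not depend on pivot order; tests check
  the solver against exhaustive vertex enumeration and an independent
  simplex implementation.
* **Dose events** — a dose adds `grams/MW` mmol to the stomach lumen; the
  drink volume `grams/(10 · strength)` L sets the lumen volume (ceiling
  1 L), so equal doses at different strengths give equal mmol at different
  initial lumen concentrations. Absorption and gastric transit rates come
  from the drink-strength anchor table by piecewise-linear interpolation;
  outside 5.1–20 %w/v the edge segment is extended and the result is
  flagged as an extrapolation.

# The synthetic-study generator

`generateSyntheticStudy()` emulates beverage-arm absorption studies:
subjects drawn around the reference male (log-normal weight, sd 10%;
height, sd 4%; uniform age 20–40 and body fat 15–25%), truth curves from
the standalone PBPK layer, and mean-one multiplicative log-normal
observation noise. It reproduces exactly under a seed and does not disturb
the caller's RNG stream. It emulates *between-subject anthropometric*
variability and *measurement* noise only — not within-subject kinetic
variability, meal effects, first-pass gastric metabolism, or assay
censoring at the limit of detection. Passing recovery tests on these data
therefore shows the fitting machinery is correct and well-conditioned, not
that real clinical arms of this size identify the absorption parameters
equally well.

# Problem sizes used by the test and acceptance runs

Baseline coupled runs use 1000 one-minute steps (single dose, full
elimination); exposure-window studies use 500 steps; disulfiram runs use
2500 min at 2-min reporting to reach full elimination; the
consistency-limit comparison runs 300 min at dt 0.5 with the liver-only
network; fitting tests observe 8 points over 300 min. A full baseline run
solves the LP a few hundred times and completes in ~10 s on one CPU.

# Known limitations

* The hepatic Michaelis–Menten constants ship as a literature-scale
  stand-in file; the drink-strength and disulfiram anchor tables are
  synthetic stand-ins encoding the documented qualitative structure. All
  three are data files a user can replace without touching code, and all
  downstream numbers inherit their uncertainty.
* Blood is a single pooled compartment; comparisons with arterial or
  breath-derived measurements inherit a small mixing bias.
* Disulfiram is a constant blood level (no ADME of the drug itself);
  heterozygous ALDH2 genotypes are rejected rather than approximated;
  there is no reverse alcohol-dehydrogenase flux, no microbiome or airway
  acetaldehyde production, and no meal effect.
* Expression scaling multiplies both dehydrogenase capacities jointly.
  Because the liver acetaldehyde quasi-steady concentration depends only
  on the ratio of production to clearance capacity, joint scaling leaves
  it invariant while stretching the exposure duration, so acetaldehyde
  AUC *rises* as expression falls in this model; independent per-enzyme
  overrides are available on `setBounds()`/`KineticParameters` for users
  who want to explore the alternative reading.

# A worked session

```{r}
library(ethanolWBM)

ind <- referenceMale()
phys <- buildPhysiology(ind)
parts <- buildPartitions(phys)
kin <- loadKinetics(strength = 12.5)
net <- buildEthanolNetwork()

cts <- runDFBA(phys, parts, kin, net,
               ScenarioConfig(regimen = doseRegimen(0, 0.25, 12.5),
                              tEnd = 1000, tol = 0.01))
cumulativeRouteFractions(cts)        # liver ~0.92, urine/sweat ~0.04 each
massBalance(cts, phys)$ethanolRelError
auc(cts, 0, Inf, "blood", "ethanol") # mM*min
```
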
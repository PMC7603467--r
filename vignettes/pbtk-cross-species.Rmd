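---
title: "Cross-species PBTK modelling and dose-normalized sensitivity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species PBTK modelling and dose-normalized sensitivity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbtkcross)
```

Physiologically based toxicokinetic (PBTK) models describe the absorption,
distribution, metabolism and excretion of a substance with organ-level
resolution. Their defining property is the strict separation between the
*species model* — the substance-independent physiology — and the compound's
physicochemistry. That separation is what makes cross-species extrapolation
a parameter-replacement exercise: exchange the physiology, keep the
compound, re-derive everything downstream. `pbtkcross` implements that
workflow end to end, together with the analysis that makes it practical: a
dose-normalized sensitivity screen that tells a modeller which of the
hundreds of physiological parameters of a new species actually need careful
identification.

## The whole-body model

The simulator is a perfusion-limited whole-body model with 29 states: 15
organs (lung, liver, kidney, muscle, skin, adipose, brain, heart, gonads,
bone, spleen, the stomach/small-/large-intestinal walls and a lumped
"rest"), three blood pools (venous, arterial, portal), eight gut lumen
segments (stomach, duodenum, upper/lower jejunum, upper/lower ileum,
caecum, colon) and three sinks (metabolized, urine, faeces). Amounts are
carried in µmol, volumes in L, time in minutes, and a density of 1 kg/L
links volumes to body weight.

Each organ exchanges with arterial blood at flow
$Q_o = \mathrm{sbf}_o \cdot V_o$ and drains at the partition-limited outflow
concentration $C_{out,o} = C_o \,/\, (K_{p,o}/BP)$:

$$\frac{dA_o}{dt} = Q_o\,(C_{art} - C_{out,o}) - \mathrm{elim}_o .$$

The lung sits in series between the venous and arterial pools and carries
the cardiac output (the sum of all arterial inflows). The splanchnic organs
(spleen, gut walls, stomach wall) drain into a portal node that perfuses
the liver together with the hepatic artery — this first-pass architecture
is what couples intestinal absorption to hepatic clearance. Elimination has
three drivers, chosen so that each clearance-related physiological
parameter is functionally active: hepatic metabolism
($CL_{h}\cdot V_{liver}\cdot fu \cdot C^{plasma}_{out,liver}$), glomerular
filtration ($f_{GFR}\cdot \mathrm{GFR}_{spec}\cdot V_{kidney}\cdot fu\cdot
C^{plasma}_{art}$) and tubular secretion
($CL_{sec}\cdot V_{kidney}\cdot fu\cdot C^{plasma}_{out,kidney}$). The
renal mass drains leave from the kidney compartment; draining filtration
from the arterial pool instead would depress the arterial concentration by
flux/CO and bias the effective elimination rate, which is measurable in
the one-compartment limit discussed below.

### Partition coefficients

No tissue-composition partition scheme is uniquely canonical; the package
uses a deliberately minimal one in which every composition entry, pH value
and the haematocrit is functionally active. The affinity of a compartment
with composition $(f_w, f_l, f_p)$ at pH $\phi$ is

$$a = \frac{f_w}{f_n(\phi)} + 10^{\log P} f_l + B,$$

where $f_n$ is the Henderson–Hasselbalch neutral fraction (only the
neutral microspecies partitions into lipid or crosses membranes) and $B$
a protein-binding term. $B$ is back-calibrated in plasma from the measured
fraction unbound ($fu$) and scaled into other compartments by their
protein fraction. Cell:plasma, interstitial:plasma and erythrocyte:plasma
coefficients are affinity ratios; the blood:plasma ratio is the
haematocrit-weighted mixture, and the total tissue:plasma coefficient the
volume-weighted mixture of vascular, interstitial and cellular phases.
When $fu = 1$ (or a stated $fu$ is not reachable given plasma lipid), the
binding term floors at zero; the latter case warns.

### Gut transit and absorption

The stomach empties first order with the gastric emptying time; intestinal
segments empty at per-segment transit rates. Both the regional transit
times (small/large intestine) and the per-segment rates are listed as
independent parameters in the field's databases, so both are perturbable
here: the effective exit rate is
$k_s = r_s \cdot T^{ref}_{region}/T_{region}$, where $r_s$ is the stored
segment rate and $T^{ref}$ the regional time at which the rates were
initialized (kept as non-perturbable metadata). At baseline $k_s = r_s$;
perturbing either leaf changes the kinetics, and neither is silently
renormalized from the other.

Only intestinal segments absorb. The flux from segment $s$ is
$P_{eff}\cdot SA_s\cdot f_n(\mathrm{pH}_s)\cdot
\min(A_s/V_s^{lumen},\ S)$, with $SA_s = 2\pi \bar r_s L_s \cdot
\mathrm{SEF}_s$ and $V_s^{lumen} = \pi \bar r_s^2 L_s \cdot
\mathrm{fill}_s$. The solubility cap $S$ is the model's saturated-
absorption mechanism: when luminal concentrations exceed solubility, a
dose reduction barely changes the curve, the normalization denominator of
the sensitivity ratio shrinks, and gut parameters can exceed sensitivity 1
for oral dosing — exactly the regime where gut parameterization matters
most. The "fractional steady-state fill level" scales the luminal fluid
volume; that is the one reading of this parameter under which it has a
clear mechanistic role here.

## Sensitivity analysis

For a model parameter $i$, the package simulates the baseline curve
$c_0(t)$, the curve $c_i(t)$ with the parameter multiplied by 0.95, and
the curve $c_{dose}(t)$ with the dose reduced by the same 5 %, and reports

$$\mathrm{sens}_i = \frac{\mathrm{rmsd}(c_0, c_i)}{\mathrm{rmsd}(c_0, c_{dose})},$$

with RMSD on the linear concentration scale over the uniform output grid.
A cmax-based alternative uses the ratio of absolute $c_{max}$ deviations.
The self-normalization makes the measure robust to simulation length,
exposure magnitude and dose, which is what allows pooling across species,
compounds and routes. Derived quantities (dose, flows, partition
coefficients, lumen geometry) are rebuilt from scratch for every
perturbation — there are no stale caches — and, deliberately, no dependent
parameter is renormalized: perturbing muscle volume does not rescale other
organs, even though that temporarily breaks the volume–weight closure.
Parameters with baseline value 0 are skipped (a multiplicative
perturbation would be a no-op) and reported once per run.

Observation sites: the default is *peripheral* venous plasma — the
flow-weighted mixture of superficial organ outflows (muscle, skin), which
is where real PK samples are drawn and which gives the peripheral blood
flow fractions their functional role — plus the intracellular space of the
declared tox organs (brain, gonads by default). Central venous plasma is
available but makes the venous pool volume spuriously dominant for i.v.
boluses: the unmixed bolus at $t = 0$ contributes a concentration
$D/V_{ven}$ whose perturbation response (+5.26 % for a −5 % volume change)
slightly exceeds the dose response, an artifact of sampling an
instantaneous initial condition rather than a physiological signal.

Per-parameter maxima over all models and sites are classified with the
thresholds 0.01 / 0.1 / 0.4 (insensitive, low, moderate, sensitive; 0.4
itself still counts as moderate) and 1 ("above dose effect"), and mapped
to functional groups (gut transit, gut pH, gut geometry, plasma
parameters, volume of distribution and clearance, tox organ, other) that
mirror how a modeller would organize a literature search.

## Species templates, scaling, extrapolation

Seven approximate mammalian templates (mouse 0.02 kg … human 73 kg) are
generated from a common 73-kg reference skeleton: per-species organ-volume
fractions, specific blood flows scaled with $BW^{-0.2}$ (which lands
cardiac output near measured values from mouse to human), gut geometry via
the packaged allometric exponents, transit times with $BW^{0.25}$, and a
handful of species tweaks (haematocrit, specific GFR, stomach pH, caecum
size for hindgut fermenters). They are literature-plausible stand-ins for
a curated physiology database, not validated species models — the
numerical values are package choices, documented as such. The mouse
default of 0.02 kg sits at the lower end of the packaged weight span; a
0.23 kg convention is equally citable and available via the `body_weight`
argument.

Allometric scaling is linear in organ and blood volumes (then renormalized
so volumes close exactly on the target weight), and joint in the gut:
with weight ratio $r$, lumen lengths scale by $r^{0.46}$ and radii by
$r^{0.30}$, the unique power pair that makes total lumen volume scale by
$r^{1.06}$ and total lumen surface by $r^{0.76}$ simultaneously. Intensive
parameters (pH, fractions, compositions, specific rates, transit times)
are untouched. Extrapolation replaces the species wholesale, keeps the
compound and the mg/kg dose, and rebuilds the absolute dose from the
target body weight.

## Synthetic data

The generators stand in for data the workflow would normally take from
curated databases and validated literature models:

* **Compounds** are drawn uniformly inside the reference small-molecule
  property ranges (MW 151–361 g/mol, logP −0.02…1.25, pKa 3–10 when
  ionizable, fu 0.05–1) with three clearance archetypes (renal-only,
  hepatic-only, mixed hepatic + tubular).
* **Species** are template scalings with mean-preserving lognormal jitter
  (CV 0.2 by default) on volumes, flows, lumen lengths and transit times —
  never on pH or fractions. Volumes are re-closed on the body weight by an
  additive correction proportional to the nominal volumes, which keeps
  each volume's expectation exactly at its template value (a
  multiplicative renormalization would bias small organs upward by
  roughly the squared CV of the total).
* **The reference ensemble** is the fixed 8-protocol set — acyclovir-like
  (i.v. + p.o.), caffeine-like (i.v.), inulin-like (i.v.), ofloxacin-like
  (i.v.), paracetamol-like (p.o.), theophylline-like (i.v. + p.o.) — built
  on the rabbit template and extrapolated to the other six species:
  8 × 7 = 56 models. The demo parameterizations are archetype
  approximations ("-like"); doses are package choices in mg/kg. The
  inulin-like entry deserves its caveat: real inulin is a 6 kDa
  polysaccharide that distributes through a large-molecule pore pathway
  outside this model family, so only its renal-only clearance archetype
  is kept, with properties capped into the small-molecule ranges. The
  acyclovir-like compound carries a low permeability and a finite
  solubility, giving the ensemble one genuinely solubility-limited oral
  model (absorbed fraction well below 1) — the regime that produces
  above-dose gut sensitivities.
* **Observations** are model predictions at sampling times multiplied by
  lognormal noise (CV 0.15 default), for exercising the validation
  comparator.

What passing tests on these data do *not* show: agreement with any real
species or compound. The synthetic ensemble reproduces structural and
qualitative behaviour (mass balance, route asymmetries, group structure of
sensitive parameters, cross-species stability of non-gut sensitivity), not
quantitative PK of named drugs.

## Numerical choices

* Solver: `deSolve::lsoda` on a compiled C right-hand side, rel. tol.
  1e−8, abs. tol. 1e−10, dense output on a uniform grid of 240 samples;
  24 h for i.v., 48 h for oral dosing by default. An R implementation of
  the same right-hand side ships as a cross-check and fallback engine.
* An i.v. bolus is an initial condition in the venous pool; a positive
  `start_time` becomes a solver event. Oral doses start in the stomach
  lumen.
* Mass balance (all states plus sinks vs. administered dose) is exposed
  as a diagnostic and held to 1e−6 relative in the tests; the solver
  typically keeps it near 1e−13.
* The dose-normalization denominator is checked: a dose change that does
  not affect the observed site at all raises a degenerate-normalization
  error rather than returning an infinite sensitivity.
* Classification boundaries are closed on the moderate side (0.4 is
  moderate, anything strictly above is sensitive); ranking ties break
  lexicographically by parameter path so reports are deterministic.
* Species files are written with canonical key order and 17 significant
  digits: identical objects give byte-identical files, and a JSON round
  trip preserves every numeric leaf exactly.
* Test and acceptance problem sizes are package choices made for tight
  feedback loops: the full 56-model ensemble sensitivity (≈ 11 000
  simulations) for the ensemble-scale checks, 240-sample grids, 2 500
  draws for the jitter-mean check, and 200 seeds for the
  validation-recovery check.

## Known limitations

Permeability-limited (membrane-resistance) organ models, lymph flow,
two-pore macromolecule distribution, transporter/enzyme expression,
enterohepatic recirculation, metabolite tracking and biliary excretion
are out of scope. The partition scheme is intentionally simple; absolute
tissue exposures from it should be treated as order-of-magnitude. The
templates are not validated physiologies, and the quantitative share of
sensitive parameters in the synthetic ensemble depends on the packaged
parameter inventory (about 200 perturbable leaves per species) — a richer
species model with many near-inert parameters would shift the class
fractions toward "insensitive" without changing the qualitative structure.
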
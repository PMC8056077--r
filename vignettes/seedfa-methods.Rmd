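---
title: "Modeling seed oil metabolism with expression-coupled kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling seed oil metabolism with expression-coupled kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seedfa` models storage-compound accumulation in the developing
*Arabidopsis* embryo by driving a kinetic metabolic network with
stage-resolved gene-expression profiles, and uses the coupled model to
predict how single-gene perturbations change seed fatty-acid (FA) content.
This vignette documents the model, its assumptions, the defaults and why
they were chosen, what the synthetic data emulate, and the known
limitations — it is the design record for the package.

## From transcripts to enzymes

Absolute transcript and protein levels correlate poorly across genes, so
the model works in relative units throughout. For each enzyme the mapped
gene intensities are summed per stage and scaled by the first-stage value
(`normalize_mrna()`), giving dimensionless profiles that equal 1 at the
zygote stage; an enzyme whose genes are silent at the first stage receives
a pseudo-intensity (1 unit by default) with a warning rather than an
undefined profile. Ribosome content is proxied by the scaled weighted sum
of ribosomal-protein transcripts (`ribosome_signal()`), default weights
being 1 for genes whose mean intensity reaches 2000 (roughly 150 of the
~200 ribosomal genes in a typical atlas) and 0 otherwise. The weights are a
modeling guess — the atlas only supports expression-level groupings — and
are fully configurable.

Each enzyme then obeys

$$\frac{dE_i}{dt} = k_{syn,i}\,\mathrm{mRNA}_i(t)\,Rb(t) -
  (k_{deg,i} + \mu(t))\,E_i,$$

with degradation constants in three classes (fast 0.03, average 0.02, slow
0.01 hr⁻¹; `k_deg = ln 2 / t_{1/2}`) and `k_syn = k_deg + 0.025 hr⁻¹` so
that, at the early growth rate, production exactly balances degradation
plus dilution and a constant-input enzyme holds at level 1. Enzymes start
at that steady state. The class assignment is a calibration degree of
freedom: in the reference model the sugar-supply steps (invertase, glucose
transporter) are slow and the oil-window enzymes (ACCase, FA synthase,
thioesterase, TAG assembly, hexokinase) fast, which phases supply behind
early demand (producing the mid-development hexose transient) and lets FA
synthesis shut down in register with its transcript window at maturation.
Enzymes without an annotation default to the average class.

Stage profiles become continuous ODE inputs through a shape-preserving
monotone piecewise-cubic interpolant (`splinefun(method = "monoH.FC")`),
which passes through the stage values without overshoot, so nonnegative
data yield nonnegative inputs; linear interpolation is available as an
option, and values beyond the last stage are held constant. The stage grid
assigns zygote, octant, globular, heart, torpedo, bent and mature stages to
0, 1, 2, 4, 6, 10 and 18 DAF; the exact dissection times are not published,
so this mapping (consistent with a 0–21 DAF axis and a 7–14 DAF oil
window) is user-overridable.

## Growth

Seed mass follows a logistic curve; the specific growth rate
$\mu = r(1 - m/m_{cap})$ falls from 0.025 hr⁻¹ in the earliest stages to
0.0025 hr⁻¹ as the embryo matures. A plain logistic cannot both sustain
0.025 hr⁻¹ early and be essentially saturated during the 16–19 DAF
plateau if the 0.0025 hr⁻¹ anchor is placed at the mature dissection stage
(18 DAF); the package therefore anchors it at the onset of maturation
(15 DAF, `t_mature_hr = 360`), which matches published seed dry-weight
curves that saturate around 15–16 DAF and makes a late FA plateau
achievable. Both anchors are constructor arguments.

## The metabolic network

The mass balance is

$$\frac{dM}{dt} = S\,v(M, E(t)) - \mu(t)\,M,$$

where the dilution term applies the growth rate to the metabolite
concentration vector (per-unit-biomass pools). Cofactors are the exception:
ATP/ADP, NAD(H) and NADP(H) are modeled as conserved pairs with fixed
totals — every rate law that consumes one form produces the partner — and
are exempt from dilution, representing homeostatic synthesis of the pools
in growing cells. Without that exemption conservation and dilution would
contradict each other. Compartment volumes are taken as equal (their true
ratios are unmeasured), so concentrations compare directly across
compartments and transport carries no volume correction.

Rate laws follow $v_i = E_i\,k_i\,f(M,p)$: irreversible Michaelis–Menten
products over substrates, a pooled-denominator reversible form for sucrose
synthase, malate dehydrogenase and the PEP translocator, mass action for
first-order removals, an mRNA-proportional law for storage-protein
synthesis, and a growth-associated plus constant maintenance law
($\alpha\mu + \beta$, times an ATP-availability factor that shuts the load
off as the pool empties — a constant draw would otherwise push ATP through
zero into an absorbing dead state). Hill inhibition terms
$K_i^n/(K_i^n + I^n)$ implement biochemical feedback with default
coefficient $n = 2$ (threshold-like response; configurable per term).

The reference reconstruction (`build_default_model()`) has 34 metabolites,
40 reactions and 129 named parameters. Its regulatory structure deserves
comment because it carries the perturbation phenotypes:

* **Acyl-ACP (SCFA) feedback on ACCase and the FA synthase complex** is the
  central regulatory mechanism: it throttles synthesis when export or downstream
  use stalls, and conversely is *relieved* when thioesterase, elongation or
  TAG assembly pull harder, which is why those overexpressions raise total
  FA while FA-synthase overexpression barely does.
* **Demand-responsive supply.** The invertase is product-inhibited by
  apoplastic hexose and the glucose transporter trans-inhibited by internal
  glucose. Supply therefore responds to sustained downstream *pull* (low
  internal glucose) but not to upstream *push* — overexpressing the
  invertase or hexokinase changes FA content by at most a few percent,
  while knocking either out collapses it, reproducing the strong
  knockout/overexpression asymmetry.
* **Congestion valves along the plastid spine** (acetyl-CoA on plastid PDH,
  pyruvate on plastidial PK, malonyl-ACP on ACCase, glycolytic
  PEP-on-PFK and hexose-phosphate-on-HK inhibition) keep intermediate
  pools bounded and propagate relief signals from the SCFA node back to
  sugar uptake.
* **Elongation as extension mass.** The elongated-FA pool tracks the
  2-carbon extensions added from cytosolic malonyl-CoA to existing acyl
  chains (with a free-FA availability factor), rather than consuming an
  acyl-primer pool. Variants in which elongation competed with TAG assembly
  or export for a shared acyl pool made it impossible to reproduce the
  observed positive response of oil to TAG-assembly overexpression
  alongside the negative response to cytosolic-ACCase knockout.
* **FAS redox stoichiometry** uses 7 NADPH + 7 NADH per C16 chain
  (ketoacyl reduction is NADPH-dependent, enoyl reduction NADH-dependent in
  plant FAS); a 14-NADPH variant starves the reductant balance.

Acyl chains are lumped (16–22 C, no isomers); total FA counts the free FA
pool, acyl-ACP intermediates, elongation extensions and three acyl
equivalents per TAG, and the storage-oil read-out used at the heart stage
is the TAG acyl mass (3·TAG plus extensions). The model runs strictly in
glycolytic mode — no gluconeogenic reactions exist. The NADPH-producing
glycolytic bypass is modeled as the non-phosphorylating
glyceraldehyde-3-phosphate route; the naming of this step varies in the
literature.

## Parameterization and calibration

Affinity and inhibition constants were placed at literature-plausible
values relative to the planned operating pools (Michaelis constants at
0.3–3× the working concentration of their substrate; inhibition constants
at the intended set point of their loop). Rate constants were then solved
from an explicit, stoichiometrically consistent flux plan for the
mid-filling phase (10 DAF) evaluated at the actual simulated enzyme levels
— the package's concrete version of "rough tuning to a numerically stable,
physiologically ranged model" — and finally adjusted against the
physiological read-outs (storage time courses, flux ratios, FA turnover)
and the panel of published perturbation responses. The resulting reference
set ships as `default_parameter_values()`; bounds default to two orders of
magnitude around each value. The model is deliberately under-determined
(129 parameters, far fewer independent observations), which is why
`identifiability_profile()` re-optimizes the remaining parameters along a
grid for any parameter of interest and flags flat profiles; calibration
quality should be judged against the read-outs, not individual parameter
values.

`fit_model()` minimizes weighted squared residuals on log10-transformed
observables (floor 1e-6 before the log, because the storage pools span
orders of magnitude across development) with bounded Levenberg–Marquardt
from multiple Latin-hypercube starts (default 20, fixed seed); the
best-so-far objective is monotone by construction, and fits are
deterministic given the seed. The third calibration step of the original
workflow — structural revision — is deliberately manual here: the fit
object exposes per-observable residual patterns, but the package never
edits model structure automatically.

## Simulation choices

The metabolic ODE system is integrated with the sparse stiff solver
(`deSolve::lsodes`; the banded/full alternative gives identical results at
~30× the cost) at rtol 1e-6 and atol 1e-9. States are clamped at zero for
rate-law evaluation; an excursion below −1e-6 aborts with the offending
state named. Enzyme trajectories are precomputed on a 2-hour grid and
linearly interpolated inside the right-hand side; because the enzyme
balance is linear in its mRNA input, a constitutive fold-change
perturbation scales the enzyme trajectory exactly, and the simulator uses
that identity (verified against the explicit profile-scaling route in the
tests). Ratio read-outs floor their denominators at 1e-9. The hexose pool
in the hexose/sucrose ratio is the internal glucose pool.

## Perturbation analysis

Perturbations act from t = 0, mirroring constitutive transgenic lines.
Knockouts multiply expression by a floor of 0.01 rather than exactly zero
(avoiding structural singularities while abolishing flux); knockdowns
divide and overexpressions multiply by the fold factor; non-enzymatic steps
scale their rate constant instead. FA responses compare perturbed and
wild-type runs under identical solver settings at 20 DAF (total FA), and
flux changes average over 10–20 DAF. The two heart-stage comparisons
(epimerase and cytosolic-ACCase knockouts) evaluate the TAG-acyl pool at
4 DAF. For the published-panel table, overexpression defaults to 10-fold
(15-fold for the ACCase row, which reports a 10–20-fold increase; 2.5-fold
for the PDH-kinase-knockout row, which acts by raising PDC activity
two-to-three-fold). A modulation profile is classified "asymmetric" when
its overexpression arm never gains more than +5% FA while its knockdown arm
loses more than 10% — an operationalization of "moderate or no increase
versus significant decrease"; both thresholds are arguments.

## Synthetic data

The generator emulates the *structure* of the study inputs, not their
values: 1–3 genes per enzyme with log-normal base intensities, stage
profiles drawn from a small shape library (early-transient, broad
filling-phase, sharp 7–14 DAF oil-window peak, late maturation rise, late
decline, flat, and a supply ramp for the maternal unloading steps), a
~200-gene ribosomal block with ~150 genes above the 2000-intensity
threshold, and multiplicative log-normal observation noise with default
CV 0.15 and four biological replicates (the design of the metabolite
profiling). The canonical noise-free expression program
(`default_expression()`) assigns each reference enzyme its biological
shape and is the wild type for all perturbation analyses, making the
reference results fully deterministic.

What passing tests on these data do *not* show: the generator has no probe
level artifacts, no correlated noise across metabolites, no batch
structure, and the canonical profiles are idealized shapes rather than
measured curves. Agreement with the qualitative physiology therefore
validates the machinery and the regulatory architecture, not the numerical
transferability of the parameter set to real seeds.

## The fixture network

A reduced 8-metabolite, 10-reaction chain-with-branch network
(`fixture_model()`) with one end-product feedback loop serves as the
desk-scale oracle: its steady states are analytically tractable, an
explicit Euler integration at dt = 1e-3 h agrees with the stiff solver to
0.5%, and calibration tests recover known parameters from data simulated
out of the same network (noiseless to 1%, noisy replicate data to 25%).

## Problem sizes used in the shipped checks

The reference simulation covers 0–21 DAF at 0.1-DAF output resolution
(~0.2 s per run after a one-time enzyme precomputation); the full scan is
40 reactions × 10 perturbations (400 integrations, about a minute); the
acceptance script runs the whole analysis — reference run, prediction
panel, scan and a seeded fixture-recovery experiment — in about two
minutes on one CPU.

## Known limitations

* Several published effect *magnitudes* are not reproduced even though all
  twelve prediction signs are: the cytosolic ATP-citrate-lyase and
  epimerase responses are much smaller here, the plastidial-PK knockout
  somewhat milder, and the average knockout effect across the network
  stronger (≈ −31% vs the ≈ −10% benchmark). This reconstruction funnels
  nearly all carbon through a single supply trunk, so more knockouts are
  catastrophic than in reconstructions with parallel routes; the
  acceptance script reports the computed values without adjustment.
* Post-translational regulation, isomer-resolved lipid species,
  compartment-volume differences and genome-scale coverage are out of
  scope by design.
* The dilution term treats all non-cofactor pools as freely diluting
  concentrations; storage organelles (oil bodies, protein bodies) are not
  spatially protected from it except through the late decline of μ.
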
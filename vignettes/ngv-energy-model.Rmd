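---
title: "A reduced neuro-glia-vasculature model of brain energy metabolism and GLUT1 deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced neuro-glia-vasculature model of brain energy metabolism and GLUT1 deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`ngvmet` implements a reduced, mechanistic model of the neuro-glia-vasculature
(NGV) unit: one neuron, one astrocyte, the local capillary, and the
extracellular spaces between them, with brain energy metabolism coupled to a
Hodgkin–Huxley membrane through the neuronal Na⁺/K⁺-ATPase. It is built to
study glucose-transport deficiency (GLUT1 deficiency syndrome, GLUT1-DS):
how reduced glucose import reshapes redox and adenylate balances, why the
astrocyte absorbs blood-nutrient fluctuations, how an after-discharge seizure
phenotype emerges from pump dysregulation, and which nutrient or cofactor
supplements best restore redox normalcy.

The state vector has 87 entries across ten compartments: arterial blood
(a boundary), endothelium, the basal-lamina extracellular space
(blood→astrocyte), the interstitium (astrocyte→neuron), and for each cell a
cytosol, a mitochondrial matrix, and an intermembrane space (IMS). Glucose
traverses five stations — endothelial `Glc_t_t`, basal-lamina `Glc_ecsBA`,
astrocytic `Glc_a`, interstitial `Glc_ecsAN`, neuronal `Glc_n` — through
four GLUT1 partitions plus neuronal GLUT3; lactate and β-hydroxybutyrate
follow parallel MCT and ketone-transport chains. Each cytosol carries
glycolysis (a lumped hexokinase step into a G6P/F6P pool, the committed
phosphofructokinase step, aldolase, triose-phosphate isomerase, a lumped
lower glycolysis), LDH, the NAD⁺/NADH, NADP⁺/NADPH, ATP/ADP and
GSH/GSSG couples, and a pentose-phosphate lump feeding glutathione
reduction; each matrix carries pyruvate import, PDH, pyruvate carboxylase
(lower expression in the neuron than in the astrocyte), a full TCA cycle,
NAD-linked dehydrogenases, the ETC/ATP-synthase lump scaled by a ubiquinone
efficiency factor (`Qpool`), and the adenine nucleotide translocase chained
through the IMS back to the cytosol. The astrocyte additionally carries a
glycogen store with a glucose-inhibited phosphorylase, so falling astrocytic
glucose mobilizes glycogen.

### Rate-law forms

Every process is one of four documented forms, so each law can be verified
against a hand evaluation:

* facilitated transport — the symmetric saturable carrier
  `v = Vmax (Sa/(Sa+Km) − Sb/(Sb+Km))` for all GLUT, MCT and ketone steps;
* committed enzyme steps — irreversible Michaelis–Menten products of
  substrate saturations;
* near-equilibrium steps — reversible mass action to an equilibrium
  constant (LDH, TPI, mitochondrial MDH, and the malate–aspartate shuttle
  that carries cytosolic NADH into the matrix);
* regulation — Hill modulation with coefficient 4 for ATP inhibition and
  ADP activation of the committed glycolytic step, which produces the
  FBP/GAP/DHAP sensitivity at the glycolytic regulatory node.

Stoichiometric assembly applies exact volume-ratio corrections at every
membrane, so the conserved moieties (NAD⁺+NADH and NADP⁺+NADPH per cytosol,
matrix NAD, CoA-containing species, GSH+2·GSSG, and the volume-weighted
adenine pool across cytosol/matrix/IMS) are conserved analytically; over a
200 s simulation the pools drift only at integration precision (~1e-13
relative).

Two cataplerotic drains (on malate and on α-ketoglutarate, standing for
amino-acid and glutamate synthesis) balance the anaplerotic pyruvate
carboxylase influx; without them the TCA intermediate pool either drains or
grows without bound. They are sized below the PC capacity so the cycle
always has a stable carbon content.

### Membrane and pump

The neuron is a standard Hodgkin–Huxley membrane whose Na⁺ and K⁺ reversal
potentials are recomputed from the tracked intracellular Na⁺ and
perineuronal K⁺. The Na⁺/K⁺-ATPase consumes neuronal ATP at

`J = Vmax · H(ATP; Km, h=3) · H(Glc; Km) · H(Na_in; Km, h=1.5) · H(K_out; Km)`

with fixed 3 Na⁺ : 2 K⁺ : 1 ATP stoichiometry; the glucose term implements
the glucose dependence of the pump that links transport deficiency to
excitability. A sodium leak conductance is sized so that resting channel
fluxes match the pump's 3:2 stoichiometry — this gives the membrane a
genuine resting fixed point — and a chloride-dominated leak anchored at the
resting potential sets the excitability class so that the control neuron
never fires without a stimulus. Perineuronal K⁺ is cleared by a saturable
astrocytic uptake that only engages above a threshold over bath; because it
is capacity-limited, sustained firing can outrun it and accumulate K⁺,
which is the ionic bistability behind the seizure phenotype.

### The stimulus

`make_protocol()` defaults to a brief 30 ms pulse, which evokes 3–4 action
potentials. At physiological coupling between membrane currents and
ion/metabolite pools, that load is negligible: control and deficient tissue
respond identically. The seizure study therefore uses
`seizure_protocol()` — a 2.2 s, 20 µA/cm² tetanus — whose sustained K⁺
load brings the perineuronal balance to the edge of the firing instability.
In the control, the pump clears the load and the neuron falls silent at
stimulus offset; under the deficiency, the glucose- and ATP-gated pump
clears it more slowly, the K⁺ reversal stays depolarized, and the neuron
continues firing (the after-discharge). Exogenous ATP raises the pump's
ATP saturation (the Hill-3 term is deliberately steep around the resting
2.3 mM so that millimolar doses matter), grading the counts back to zero
along the five-dose ladder; restoring the transporter coefficient to 1
abolishes the phenotype entirely.

## Disease and therapies

GLUT1 deficiency is a multiplicative scaling of the four GLUT1 partition
capacities (default coefficient 0.4; GLUT3 untouched). The coefficient is
exposed in the configuration; 0.4 was calibrated so the model crosses the
after-discharge threshold while keeping a viable steady state.

Therapies are parameter or initial-condition modifications:

* blood supplements (GLC, LAC, bHB) raise arterial set points and act
  through the transport chains during the pre-run relaxation;
* injections (NAD⁺, ATP, and the four anaplerotic TCA entries OXA, SUCCOA,
  AKG, FUM) raise initial concentrations after relaxation, together with
  the corresponding conserved pools;
* the ubiquinone therapy raises the `Qpool` ATP-synthase efficiency factor
  (default 0.85; therapy-capped at 1).

Default magnitudes were calibrated on the deficiency background: the
glucose supplement (1.5 mM) substantially restores transport; lactate and
ketone components are small (0.08 mM) because their marginal effect on the
cytosolic redox couples, through the near-equilibrium LDH at millimolar
lactate levels, is strong. The restoration score of a therapy is the sum
over both cells and ratio families (NAD⁺/NADH cytosolic and mitochondrial,
NADP⁺/NADPH, ATP/ADP cytosolic and mitochondrial) of
`|R_therapy − R_control| / R_control` at baseline — a restoration distance,
chosen over a raw sum of ratios because a sum would reward overshoot.
Ratio denominators are floored at 1e-4 mM so nucleotide-pool collapse
(e.g. matrix ADP under a high ATP dose) yields large finite scores.

In this reduced parameterization the score landscape is glucose-dominated:
the largest deviations under the deficiency are the astrocytic ATP/ADP
deficits, which only glucose restores, while added lactate/ketones
over-reduce the cytosolic NAD couples past control. Plain glucose
supplementation therefore ranks first and the glucose–lactate–ketone
combination ranks just behind it; the anaplerotic injections show
essentially no restorative effect (under 3% improvement) and sit in the
bottom half of the ranking. We report this as a property of the reduced
model: a richer network in which lactate and ketones carry a larger share
of oxidative fuel would favor the combination more strongly.

## Blood-fluctuation variability study

Arterial glucose, lactate and β-hydroxybutyrate are driven by exact-
discretization Ornstein–Uhlenbeck processes (`ou_blood_trace()`), seeded
and reproducible, with means at the arterial set points, standard
deviations of ~5–12% of the mean, and a 120 s reversion time reflecting the
minutes-scale variation of arterial nutrient levels. Over a 600 s run the
coefficient of variation of every cell metabolite is computed over the
whole recorded trajectory (the window is configurable), grouped into the
functional subgroups (glycolysis, TCA, PPP, ETC, respiration, adenosine
phosphates, redox carriers, ketones), and compared astrocyte-vs-neuron for
shared species. The astrocyte, first in line behind the blood, carries
higher CVs for most glycolytic/TCA species; under the deficiency the
pooled CV distribution shifts upward in both cells. The astrocyte-only
shift is seed-dependent — the deficiency also scales down the transmitted
fluctuation — which is why the upward-shift check is evaluated on the
pooled distribution.

## Numerical design

* Integration: `deSolve::lsoda` on a compiled (Rcpp) right-hand side,
  default tolerances rtol 1e-6 / atol 1e-9, with the integration restarted
  at stimulus edges so the rectangular pulse is never stepped over. A
  reference R implementation of every rate law and of the assembly is kept
  in the package and tested equal to the compiled path at random states to
  1e-12.
* Output: a coarse grid (50 ms) everywhere plus a dense grid (0.5–1 ms)
  from just before the stimulus through the spike-observation window, so
  action potentials are resolved for detection (threshold −20 mV upward
  crossings, 2 ms refractory) without storing millions of samples.
* Resting states: found by alternating relaxation integration with a
  damped, scaled Newton solve of the full right-hand side. Newton steps
  are projected onto the conserved-pool manifold (unconstrained steps leak
  moiety totals) and the pseudoinverse truncates singular values below
  1e-8 of the largest, which is the reliability limit of finite-difference
  Jacobians. The control resting state is precomputed this way and shipped
  as `default_initial_state()` (residual < 1e-6 mM/s).
* Saturating terms clamp negative concentrations to zero so transient
  solver undershoots cannot create singularities; reversible mass-action
  terms are left signed and self-correct.
* Degenerate inputs: CV of a non-positive-mean series is flagged undefined
  rather than thrown; cosine clustering refuses all-zero rows by name;
  fold changes use `log2((x+1e-6)/(ref+1e-6))`.
* Problem sizes: the study uses single runs of 120–600 s per condition
  (about 20 conditions in the full study), which completes in a few
  minutes on one CPU.

## What the synthetic generators do and do not emulate

The OU blood traces emulate stationary, mean-reverting arterial nutrient
variation with interpretable amplitude and timescale; they do not emulate
meals, circadian structure, or correlated glucose–lactate excursions. The
voltage and sinusoid fixtures carry exact machine-readable ground truth
(spike times, CV = a/√2) so the analysis operations are tested against
constructions, not against the model; passing those tests validates the
analysis pipeline, not the biological realism of the simulations.

## Known limitations

* The network is a documented reduction (~80 processes): no
  glutamate–glutamine cycling kinetics (the GLTGLN label exists only for
  grouping), no methylglyoxal chemistry, no lipid β-oxidation, no
  neurovascular coupling; the blood is a boundary condition.
* One neuron and one astrocyte; no replicate structure, so no confidence
  intervals on the variability comparisons.
* The IMS carries ATP only, so its adenylate ratio is reported against
  cytosolic ADP.
* The seizure calibration (deficiency factor, stimulus, pump Hill terms)
  is a calibration of this default parameterization, not a universal
  property of the equations; the therapy-ranking landscape in particular
  is glucose-dominated here (see above).

## Running the study

```{r, eval = FALSE}
library(ngvmet)
study <- run_study(out_dir = "results/study")
study$rescue          # after-discharge counts per condition
study$ranking         # therapy ranking, total-redox mode
```

The numbered scripts under `analysis/` run the same pipeline piecewise and
write tidy CSV tables under `results/`.
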
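---
title: "A cardiovascular response model for heat, dehydration and altitude"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A cardiovascular response model for heat, dehydration and altitude}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrmodel)
```

## The model

`cvrmodel` predicts heart rate (HR), stroke volume (SV), cardiac output
(CO), whole-body oxygen extraction and regional blood flows for an
individual at rest and during exercise, and how these responses shift
under heat strain, dehydration and hypobaric hypoxia. It is a
deterministic algebraic model: every prediction is a closed-form function
of the current state, built on two identities,

$$\dot{V}\mathrm{O}_2 = CO \cdot AVO_2diff, \qquad CO = SV \cdot HR,$$

the Fick and cardiac-output principles. The package is organised the way
the model is derived: a *basic* layer (no environmental strain), an
altitude layer, a heat/dehydration layer, a blood-flow partition, and a
scenario simulator that chains them over a time series.

### Basic layer

From age, mass, height, sex and baseline $\dot{V}O_{2max}$:

* resting $\dot{V}O_2$ from Mifflin–St Jeor resting energy expenditure,
  converted to L·min⁻¹ (see *Numerical choices*);
* $SV_{max} = 40.59 + 24.81\,\dot{V}O_{2max}$ mL·beat⁻¹ (absolute
  uptake, since maximal stroke volume scales with body size);
* $SV_{rest} = 85.1$ mL·beat⁻¹, a pooled population mean — resting
  stroke volume shows no usable fitness relation;
* $HR_{max} = 208 - 0.7\,\mathrm{age}$;
  $HR_{rest} = 90.93 - 0.64\,\dot{V}O_{2max}/\mathrm{mass}\cdot1000$
  (mass-relative uptake, mL·kg⁻¹·min⁻¹);
* $CO = SV/1000 \cdot HR$ at rest and max, and the Fick quotients give
  resting and maximal extraction.

Workload is the reserve fraction
$F = (\dot{V}O_2 - \dot{V}O_{2rest})/(\dot{V}O_{2max} -
\dot{V}O_{2rest})$. HR and CO are *linear* in $F$ between their resting
and maximal values; SV is then forced to $CO/HR \cdot 1000$ and is
deliberately nonlinear. Making HR and CO the linear pair avoids a
disproportionate rise of CO near exhaustion that a linear SV would
imply.

### Altitude

The fractional decline of aerobic capacity with altitude is the
curvilinear fit $0.007\,km^2 + 0.03\,km$, zero at sea level, supported
on 0–8 km (the domain of the underlying meta-analysis; beyond it the
quadratic is refused rather than extrapolated). Maximal CO is unchanged
by acute hypoxia, so the loss is carried entirely by extraction: resting
and maximal extraction are both scaled by $(1-\mathrm{decline})$ and the
instantaneous extraction is remapped between the scaled endpoints. The
CO required at altitude is $\dot{V}O_2$ divided by the attenuated
extraction.

Because both endpoints share one attenuation factor, the remap collapses
algebraically to a uniform scaling,
$AVO_2diff(alt) = (1-\mathrm{decline})\cdot AVO_2diff(sea)$, so the
required output is exactly the basic output divided by
$(1-\mathrm{decline})$. One consequence, worth stating because it is a
property of the model as formulated and not of this implementation: at
the *attenuated* maximal uptake the required output exceeds the basic
maximal output, so the cardiac reserve fraction crosses 1 slightly
below the aerobic ceiling. The feasibility check therefore treats the
uptake ceiling and the heart-rate ceiling as separate criteria rather
than assuming they coincide.

### Heat and dehydration

Strain is summarised by a cardiac heat strain index (CHSI), a
°C-equivalent scalar built from the elevation of mean body temperature
$T_{body} = 0.2\,T_{skin} + 0.8\,T_{core}$ above 36.54 °C
($\Delta T$, floored at 0) and dehydration $D$ (% body mass lost):

* additive (default): $0.5\,D + 0.5\,\Delta T$ — equal independent
  contributions; it predicted heterogeneous validation groups best;
* synergistic: $0.433\,D + 0.091\,\Delta T + 0.125\,D\,\Delta T$ —
  includes the interaction observed in endurance-trained runners.

An index of 3.9 is scaled to match a 3.9 °C rise in mean body
temperature. No cap is applied above that anchor; values beyond it are
extrapolation and the docs say so.

Per index unit, resting SV rises 2.5 % and resting CO 31.3 %, while
maximal SV and CO both fall 8.3 %. Maximal HR is not modulated — the
drop in maximal CO is entirely inotropic — while the resting imbalance
(CO rising far faster than SV) forces resting HR up: cardiovascular
drift. The modulated resting HR is the quotient of the modulated resting
CO and SV with an explicit ×1000 unit conversion, which the quantity's
units require. The strained exercise response interpolates HR from the
elevated resting value to the unmodulated maximum, and CO from the
elevated resting value to the lowered maximum, over the cardiac reserve
fraction

$$F_{env} = \frac{CO(alt) - CO_{rest}}{CO_{max}(heat) - CO_{rest}},$$

in which the *basic* resting output appears in both numerator and
denominator — implemented exactly as formulated, despite the naming
asymmetry, so that at zero strain the fraction reduces identically to
the uptake reserve fraction. The environment-limited aerobic ceiling is
the Fick product
$\dot{V}O_{2max}(env) = AVO_2diff_{max}(alt)\cdot CO_{max}(heat)$.
The modulated stroke-volume and cardiac-output constants themselves
carry no altitude term; altitude acts through the required output at a
workload and through the extraction ceiling.

An `"adjusted"` calibration preset scales the four heat sensitivities
by 1.5 (to −0.125, −0.125, 0.038, 0.47) and raises the resting-HR
intercept by 10 beats·min⁻¹; it removes a systematic underestimation of
HR seen against heterogeneous heat-exposure data and is off by default
(`"published"`).

### Blood-flow partition

Core (viscera and major organs) flow is the total output times a
quadratic in relative cardiac demand $F_{CO} = CO/CO_{max}(env)$:
$0.86\,F_{CO}^2 - 1.79\,F_{CO} + 1.06$, strictly decreasing on (0, 1].
The constant term exceeds 1, so the unclamped extrapolation at
$F_{CO}=0$ would exceed the whole output; the model never operates
there (resting demand is ≈ 0.2) and the form is kept unclamped rather
than silently bent. Skin flow is a thermoneutral baseline of 5 % of
basic resting output plus the heat-excess output (modulated minus
altitude-only). Muscle flow is the remainder, so the three flows sum to
the total exactly; active-muscle extraction is the above-resting uptake
over muscle flow, defined as 0 at resting uptake. A non-positive muscle
flow or an extraction above 1 L·L⁻¹ sets `domain_ok = FALSE` on the
row instead of being clamped — clamping would silently break
conservation. When coupled to a thermoregulatory model the skin-flow
value is better used as a constraint than as a substitution, so it is
always reported per row.

## The scenario simulator

`simulate_cvr()` evaluates the model at every row of a scenario table
(time, phase, workload, thermal state, altitude, mass loss). The model
is memoryless — the only carried quantity in protocols is cumulative
dehydration, which the fixtures accrue linearly over exercise time only
(`dehydration_percent()`), held over rest phases and clamped at the
stated total loss if a scenario runs past its stated exercise time.
Rows are evaluation points; nothing is interpolated between them. Task
failure is adjudicated per row in fixed order — required uptake above
the environment-limited ceiling, predicted HR above maximal HR, then
user-supplied HR or body-temperature ceilings, then domain integrity —
and rows after a failure are still computed, unclamped and flagged, so
the full diagnostic trace survives; the summary reports the first
failure time. Fractional workloads are taken of the *baseline* maximal
uptake by default (the graded-test convention); \
`cvr_config(workload_relative = "environment")` switches to the
altitude-reduced maximum for relative-workload protocols.

```{r}
p <- cvr_profile(age = 25, mass = 75, height = 175, sex = "male",
                 vo2max = 4.0)
sim <- simulate_cvr(p, fixture_graded_test("fit", "heated"))
sim
sim$predictions[5, c("vo2_L_min", "chsi", "hr_bpm", "co_L_min", "sv_mL")]
```

## What the fixtures emulate — and what they do not

`fixture_graded_test()` reproduces the graded-test protocol used for
the model's illustrative simulations: a 25-yr, 75-kg, 175-cm male
("fit" 4.0 or "unfit" 2.5 L·min⁻¹), rest followed by 20–100 % of
baseline maximal uptake in 10 %/2-min steps, under constant presets —
thermoneutral (36.6 °C mean body temperature, 0.25 kg loss), heated
(39 °C, 1.5 kg), sea level (0 km) or high altitude (5 km). The
environment applies to the rest row too: resting in the heat is passive
heat strain. Note the thermoneutral preset carries a small residual
strain index (≈ 0.2), so its graded endpoint sits a shade above the
age-predicted maximal HR; a scenario with no thermal or mass-loss
columns is strain-free and hits it exactly.

`fixture_rest_exercise()` emits 30-min rest + 60-min exercise skeletons
at 5-min resolution for the fixed-load, graded-climate and altitude
(absolute/relative workload at 4 km, the equivalent of breathing 12.7 %
oxygen) protocol families. Their thermal trajectories are linear ramps
with climate-typical start/end values (e.g. warm-humid: core
36.8→38.0 °C over exercise, skin 35 °C, 1.0 kg loss) — deliberately
simple, physiologically shaped defaults chosen once for harness
testing. They are not measured traces: real core temperature rises
asymptotically, skin temperature fluctuates with sweating and airflow,
and fluid loss is nonlinear in intensity. Tests passing on these
fixtures therefore certify the model arithmetic and its invariants, not
agreement with any experimental dataset; the measured heart-rate
datasets used to validate the model externally are not redistributable
and are out of scope here. `regress_predicted_vs_measured()` is the
harness for users who hold such data.

## Numerical choices

* **Resting-uptake conversion.** The energy-to-oxygen divisor is the
  Weir form $3.941 + 1.106\,RER$ kcal·L⁻¹ by default, giving ≈ 0.25
  L·min⁻¹ for the reference male — the physiologically expected resting
  uptake. An alternative literal divisor $5.05\,RER$ is exposed
  (`divisor = "literal"`, ≈ 0.34 L·min⁻¹) so either reading of the
  conversion can be reproduced; the Weir default is documented and used
  throughout.
* **Flooring.** $\Delta T_{body}$ and the strain index are floored at
  0: the heat model was developed for heat strain, and a hypothermic
  body temperature must not invert the sensitivities outside their
  fitted range.
* **Degenerate inputs.** A profile whose resting HR is not below its
  maximal HR (extreme age/fitness combinations), or whose resting
  uptake reaches its maximal uptake, is rejected as out-of-domain
  rather than allowed to produce negative reserves. Strain large enough
  that the modulated maximal output no longer exceeds the resting
  output errors in the reserve-fraction step and is flagged as
  `domain_ok = FALSE` on the modulated constants.
* **Tolerances.** Feasibility comparisons use a relative tolerance of
  1e-9 so exact boundary workloads remain feasible; conservation and
  zero-strain identities are exact by construction and tested at 1e-12.
* **Ties/order.** Feasibility criteria are evaluated in a fixed order
  (uptake, HR, user ceilings, domain) and the first violation names the
  limiting factor.

## Problem sizes

Everything here is closed-form, so the test suite and the worked
examples run in milliseconds: the full graded-test battery (2
individuals × 3 environments × 10 workloads) completes well under a
second on one CPU, and property loops use 10–20 sampled profiles across
a 25–60 mL·kg⁻¹·min⁻¹ fitness range — ample to exercise every branch of
an algebraic model.

## Known limitations

* Coefficients are taken as printed; no refitting of the source
  meta-analyses is performed or supported.
* No acclimation state, lactate threshold, critical power, slow
  component, pacing or time-to-exhaustion; the model flags
  unsustainable workloads but does not predict how long a sustainable
  one can be held.
* No ventilatory or haemoglobin modelling at altitude; barometric
  pressure or inspired-oxygen fractions must be converted to an
  equivalent altitude by the caller.
* The strain index has no upper cap; predictions beyond its 3.9
  scaling anchor are extrapolation.
* As noted above, near-maximal workloads at altitude can demand more
  cardiac output than the maximal value while remaining nominally below
  the attenuated aerobic ceiling; the simulator reports both criteria
  honestly rather than reconciling them.
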
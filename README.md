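# cvrmodel

Predicting cardiovascular strain — heart rate, stroke volume, cardiac
output, oxygen extraction, regional blood flow and aerobic limits — for
an individual at rest and during exercise under heat, dehydration and
altitude stress.

Thermophysiological models usually carry only a total cardiac output,
derived from metabolic rate plus the skin blood flow thermoregulation
demands, with a fixed muscle oxygen extraction. That leaves them blind
to the *limits* of the circulation: maximal heart rate, maximal cardiac
output, the heat-induced collapse of stroke volume, the
altitude-induced collapse of oxygen extraction — and hence to whether a
given workload is sustainable at all. `cvrmodel` fills that gap for
exercise scientists, occupational-safety analysts and developers of
thermoregulation models: it is a standalone, deterministic algebraic
model designed so its outputs (heart rate above all) can be checked
against field data, and so it can later serve as the cardiovascular
submodel of a multi-segment thermal model.

## The model in brief

Two identities anchor everything:

```
VO2 = CO · AVO2diff        (Fick principle)
CO  = SV · HR              (cardiac-output principle)
```

* **Basic layer** — from age, mass, height, sex and baseline VO2max:
  `SVmax = 40.59 + 24.81·VO2max`, `SVrest = 85.1 mL`,
  `HRmax = 208 − 0.7·age`,
  `HRrest = 90.93 − 0.64·VO2max/mass·1000`; resting VO2 from
  Mifflin–St Jeor energy expenditure. HR and CO are linear in the
  VO2-reserve fraction; SV = CO/HR·1000 follows.
* **Altitude** — aerobic capacity declines by `0.007·km² + 0.03·km`;
  maximal cardiac output is spared, so resting and maximal oxygen
  extraction are scaled down and the cardiac output required at a given
  VO2 rises correspondingly (0–8 km supported).
* **Heat and dehydration** — a cardiac heat strain index (CHSI) combines
  body-temperature elevation above 36.54 °C and % body-mass loss
  (additive `0.5·D + 0.5·ΔT`, default, or synergistic
  `0.433·D + 0.091·ΔT + 0.125·D·ΔT`). Per index unit: resting SV +2.5 %,
  resting CO +31.3 %, maximal SV and CO −8.3 %, maximal HR unchanged —
  which forces resting HR up (cardiovascular drift) and caps
  environment-limited VO2max as `AVO2diffmax(alt) · COmax(heat)`.
* **Blood flow** — core flow follows a decreasing quadratic in relative
  cardiac demand (`0.86·F² − 1.79·F + 1.06`), skin flow is a 5 %-of-rest
  baseline plus the heat-excess output, muscle flow is the remainder
  (flows conserve exactly), and active-muscle extraction is
  above-resting VO2 over muscle flow.
* **Task failure** — a workload is unsustainable when required VO2
  exceeds the environment-limited maximum or predicted HR exceeds
  maximal HR (user HR / body-temperature ceilings can tighten this);
  the simulator flags rows rather than truncating.

See `vignette("cvr-model")` for the full account, assumptions and
limitations.

## Worked example

A fit male (25 yr, 75 kg, 175 cm, VO2max 4.0 L·min⁻¹) cycling at
2.0 L·min⁻¹ with a mean body temperature of 39 °C and 2 % dehydration
at sea level:

```r
library(cvrmodel)
p <- cvr_profile(age = 25, mass = 75, height = 175, sex = "male",
                 vo2max = 4.0)
sim <- simulate_cvr(p, fixture_graded_test("fit", "heated"))
sim$predictions[5, c("vo2_L_min", "chsi", "hr_bpm", "co_L_min", "sv_mL",
                     "core_bf_L_min", "skin_bf_L_min", "muscle_bf_L_min")]
#>   vo2_L_min chsi  hr_bpm co_L_min    sv_mL core_bf_L_min skin_bf_L_min muscle_bf_L_min
#> 5         2 2.23 151.068 16.33836 108.1523        3.2664      1.583343        11.48861
```

The heat strain index is 2.23 (2 % dehydration and a 2.46 °C body
temperature elevation, weighted equally). Compared with the
thermoneutral response at the same workload (HR 119, CO 15.0, SV 126),
heart rate has drifted up by ~32 beats·min⁻¹ while stroke volume is
squeezed, and 1.6 L·min⁻¹ of the cardiac output is diverted to the
skin for heat dissipation. Pushing the same simulation to 100 % VO2max
shows task failure from 14 min on (`sim$summary`): first the heart-rate
ceiling, then the heat-reduced aerobic ceiling itself.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/cvr.R fixture --name fig4-fit-heated --out scenario.csv
Rscript inst/cli/cvr.R simulate --profile profile.yaml --scenario scenario.csv --out results.csv
Rscript inst/cli/cvr.R validate --pairs pairs.csv --strata climate
```

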
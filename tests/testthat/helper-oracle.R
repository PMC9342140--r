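# Independent spreadsheet-style recomputation of the full worked chain for
# the reference fit male (25 yr, 75 kg, 175 cm, 4.0 L/min) at vo2 = 2.0
# under 39 degC mean body temperature, 2% dehydration, additive strain
# index, sea level. Written as literal arithmetic from the model constants,
# deliberately independent of every package function, so agreement checks
# the implementation rather than restating it.
oracle_worked_chain <- function() {
  ree <- 10 * 75 + 6.25 * 175 - 5 * 25 + 5            # kcal/day
  vo2rest <- ree / 1440 / (3.941 + 1.106 * 0.7)       # L/min
  sv_max <- 40.59 + 24.81 * 4.0                       # mL/beat
  hr_max <- 208 - 0.7 * 25                            # beats/min
  hr_rest <- 90.93 - 0.64 * (4.0 / 75 * 1000)         # beats/min
  co_max <- sv_max / 1000 * hr_max                    # L/min
  co_rest <- 85.1 / 1000 * hr_rest                    # L/min
  f_basic <- (2.0 - vo2rest) / (4.0 - vo2rest)
  co_basic <- co_rest + f_basic * (co_max - co_rest)  # = CO(altitude) at 0 km

  dehyd <- 1.5 / 75 * 100                             # = 2 %
  d_tbody <- 39 - 36.54                               # = 2.46 degC
  strain <- 0.5 * dehyd + 0.5 * d_tbody               # additive index

  co_max_env <- (1 - 0.083 * strain) * co_max
  co_rest_env <- (1 + 0.313 * strain) * co_rest
  sv_rest_env <- (1 + 0.025 * strain) * 85.1
  hr_rest_env <- co_rest_env / sv_rest_env * 1000
  fr <- (co_basic - co_rest) / (co_max_env - co_rest)
  hr <- hr_rest_env + fr * (hr_max - hr_rest_env)
  co <- co_rest_env + fr * (co_max_env - co_rest_env)
  sv <- co / hr * 1000

  fco <- co / co_max_env
  core <- co * (0.86 * fco^2 - 1.79 * fco + 1.06)
  skin <- 0.05 * co_rest + (co - co_basic)
  muscle <- co - skin - core
  extraction <- (2.0 - vo2rest) / muscle

  list(vo2rest = vo2rest, co_max = co_max, co_rest = co_rest,
       co_basic = co_basic, chsi = strain,
       co_max_env = co_max_env, co_rest_env = co_rest_env,
       sv_rest_env = sv_rest_env, hr_rest_env = hr_rest_env,
       fraction = fr, hr = hr, co = co, sv = sv,
       core_bf = core, skin_bf = skin, muscle_bf = muscle,
       active_muscle_avo2diff = extraction,
       vo2max_env = (4.0 / co_max) * co_max_env)
}

reference_fit_profile <- function() {
  cvr_profile(age = 25, mass = 75, height = 175, sex = "male",
              vo2max = 4.0)
}

reference_unfit_profile <- function() {
  cvr_profile(age = 25, mass = 75, height = 175, sex = "male",
              vo2max = 2.5)
}

# A spread of plausible adult profiles for property-style loops.
random_profiles <- function(n, seed = 421) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    mass <- runif(1, 50, 100)
    cvr_profile(
      age = runif(1, 20, 65),
      mass = mass,
      height = runif(1, 155, 195),
      sex = sample(c("male", "female"), 1),
      vo2max = runif(1, 25, 60) / 1000 * mass  # 25-60 mL/kg/min
    )
  })
}
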
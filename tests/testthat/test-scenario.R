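test_that("feasibility is adjudicated in fixed order with named limits", {
  ok <- check_feasibility(2.0, 3.26, 151.1, 190.5)
  expect_true(ok$feasible)
  expect_identical(ok$limiting, "none")
  v <- check_feasibility(3.2, 2.70, 180, 190.5)
  expect_false(v$feasible)
  expect_identical(v$limiting, "vo2max_exceeded")
  h <- check_feasibility(2.0, 3.26, 195, 190.5)
  expect_identical(h$limiting, "hr_ceiling")
  u <- check_feasibility(2.0, 3.26, 151.1, 190.5, hr_ceiling = 140)
  expect_false(u$feasible)
  expect_identical(u$limiting, "hr_ceiling")
  d <- check_feasibility(2.0, 3.26, 151.1, 190.5, domain_ok = FALSE)
  expect_identical(d$limiting, "domain_violation")
  # the uptake check fires before the heart-rate check
  both <- check_feasibility(3.2, 2.70, 195, 190.5)
  expect_identical(both$limiting, "vo2max_exceeded")
  # exact boundary stays feasible (relative tolerance)
  edge <- check_feasibility(2.70, 2.70, 190.5, 190.5)
  expect_true(edge$feasible)
})

test_that("graded-test fixtures encode the captioned protocol", {
  sc <- fixture_graded_test("fit", "thermoneutral")
  expect_equal(nrow(sc), 10)
  expect_identical(sc$phase, c("rest", rep("exercise", 9)))
  expect_equal(sc$frac_vo2max, c(NA, seq(0.2, 1.0, by = 0.1)))
  expect_equal(diff(sc$time_min), rep(2, 9))
  expect_true(all(sc$t_body_C == 36.6) && all(sc$mass_loss_kg == 0.25))
  heated <- fixture_graded_test("fit", "heated")
  expect_true(all(heated$t_body_C == 39) && all(heated$mass_loss_kg == 1.5))
  alt <- fixture_graded_test("fit", "high_altitude")
  expect_true(all(alt$altitude_km == 5))
  expect_error(fixture_graded_test("fit", "underwater"))
})

test_that("rest-plus-exercise fixtures emit 30-min rest and 60-min exercise at 5-min steps", {
  sc <- fixture_rest_exercise("fixed_load_heat")
  expect_equal(sc$time_min, seq(0, 90, by = 5))
  expect_identical(unique(sc$phase[sc$time_min <= 30]), "rest")
  expect_identical(unique(sc$phase[sc$time_min > 30]), "exercise")
  expect_true(all(sc$vo2_L_min[sc$phase == "exercise"] == 1.0))
  # cumulative mass loss accrues over exercise only and ends at the total
  expect_true(all(sc$mass_loss_kg[sc$phase == "rest"] == 0))
  expect_equal(max(sc$mass_loss_kg), 1.0)
  abs4 <- fixture_rest_exercise("altitude_absolute")
  expect_true(all(abs4$altitude_km == 4))
  expect_equal(sort(unique(abs4$frac_vo2max[abs4$phase == "exercise"])),
               c(0.35, 0.50))
  rel4 <- fixture_rest_exercise("altitude_relative")
  expect_identical(attr(rel4, "workload_relative"), "environment")
  expect_error(fixture_rest_exercise("swim"))
})

test_that("simulation endpoints and contrasts match the worked derivations", {
  p <- reference_fit_profile()
  # strain-free scenario (no thermal or mass-loss columns): the graded
  # endpoint is exactly the age-predicted maximal heart rate
  zero <- data.frame(time_min = c(0, 2, 4),
                     phase = c("rest", "exercise", "exercise"),
                     frac_vo2max = c(NA, 0.5, 1.0),
                     stringsAsFactors = FALSE)
  sim0 <- simulate_cvr(p, zero)
  expect_equal(tail(sim0$predictions$hr_bpm, 1), 190.5,
               tolerance = 1e-9)
  expect_true(all(sim0$predictions$chsi == 0))
  # worked heated-vs-thermoneutral contrast at 2.0 L/min
  heated <- simulate_cvr(p, fixture_graded_test("fit", "heated"))
  i8 <- which(heated$predictions$vo2_L_min == 2.0)
  expect_equal(heated$predictions$hr_bpm[i8], 151.1, tolerance = 1e-3)
  zero2 <- data.frame(time_min = c(0, 2), phase = c("rest", "exercise"),
                      vo2_L_min = c(NA, 2.0), stringsAsFactors = FALSE)
  expect_equal(simulate_cvr(p, zero2)$predictions$hr_bpm[2], 119.1,
               tolerance = 1e-3)
})

test_that("a supramaximal altitude workload fails with the uptake as limiting factor", {
  p <- reference_fit_profile()
  sc <- data.frame(time_min = c(0, 5), phase = c("rest", "exercise"),
                   frac_vo2max = c(NA, 0.8), altitude_km = 5,
                   stringsAsFactors = FALSE)
  sim <- simulate_cvr(p, sc)
  expect_false(sim$predictions$feasible[2])
  expect_identical(sim$predictions$limiting[2], "vo2max_exceeded")
  expect_equal(sim$summary$first_failure_time_min, 5)
  # 0.8 * 4.0 = 3.2 exceeds the attenuated 2.70 L/min ceiling
  expect_equal(sim$predictions$vo2max_env_L_min[2], 2.70,
               tolerance = 1e-12)
})

test_that("simulation is deterministic and validates its inputs", {
  p <- reference_fit_profile()
  sc <- fixture_graded_test("fit", "heated")
  expect_identical(simulate_cvr(p, sc)$predictions,
                   simulate_cvr(p, sc)$predictions)
  bad_time <- sc; bad_time$time_min[3] <- bad_time$time_min[2]
  expect_error(simulate_cvr(p, bad_time), "strictly increasing")
  bad_both <- sc
  bad_both$vo2_L_min <- NA_real_; bad_both$vo2_L_min[2] <- 1.0
  expect_error(simulate_cvr(p, bad_both), "mutually exclusive")
  bad_alt <- sc; bad_alt$altitude_km[2] <- 9
  expect_error(simulate_cvr(p, bad_alt), "0-8 km")
  no_work <- sc; no_work$frac_vo2max[2] <- NA
  expect_error(simulate_cvr(p, no_work), "no resolvable workload")
})

test_that("per-row Fick closure and flow conservation hold across fixture runs", {
  for (fit in c("fit", "unfit")) {
    p <- graded_test_profile(fit)
    for (env in c("thermoneutral", "heated", "high_altitude")) {
      pr <- simulate_cvr(p, fixture_graded_test(fit, env))$predictions
      expect_equal(pr$co_L_min * pr$avo2diff, pr$vo2_L_min,
                   tolerance = 1e-9)
      expect_equal(pr$core_bf_L_min + pr$skin_bf_L_min +
                     pr$muscle_bf_L_min,
                   pr$co_L_min, tolerance = 1e-12)
      expect_true(all(diff(pr$hr_bpm) > 0))
    }
  }
})

test_that("graded-test simulations show the expected heat and altitude shapes", {
  p <- reference_fit_profile()
  neutral <- simulate_cvr(p, fixture_graded_test("fit", "thermoneutral"))$predictions
  heated <- simulate_cvr(p, fixture_graded_test("fit", "heated"))$predictions
  alt <- simulate_cvr(p, fixture_graded_test("fit", "high_altitude"))$predictions
  # passive heat raises resting cardiac output
  expect_gt(heated$co_L_min[1], neutral$co_L_min[1])
  # at maximal workload heat lowers cardiac output
  expect_lt(tail(heated$co_L_min, 1), tail(neutral$co_L_min, 1))
  # stroke volume is below thermoneutral at every exercise workload
  expect_true(all(heated$sv_mL[-1] < neutral$sv_mL[-1]))
  # extraction at altitude is below sea level at every workload
  expect_true(all(alt$avo2diff < neutral$avo2diff))
  # the unfit individual works at a higher heart rate for the same
  # absolute uptake
  unfit <- simulate_cvr(reference_unfit_profile(),
                        fixture_graded_test("unfit", "thermoneutral"))$predictions
  for (i in seq_len(nrow(unfit))) {
    vo2 <- unfit$vo2_L_min[i]
    b <- basic_cardio(reference_fit_profile())
    if (vo2 >= b$vo2rest) {
      fit_hr <- basic_response(b, vo2_reserve_fraction(vo2, b))$hr
      expect_gt(unfit$hr_bpm[i], fit_hr)
    }
  }
})

test_that("relative workloads can be taken of the environment-limited maximum", {
  p <- reference_fit_profile()
  sc <- data.frame(time_min = c(0, 5), phase = c("rest", "exercise"),
                   frac_vo2max = c(NA, 0.5), altitude_km = 4,
                   stringsAsFactors = FALSE)
  basic_sim <- simulate_cvr(p, sc)
  rel_sim <- simulate_cvr(p, sc,
                          cvr_config(workload_relative = "environment"))
  expect_equal(basic_sim$predictions$vo2_L_min[2], 2.0)
  expect_equal(rel_sim$predictions$vo2_L_min[2], 0.5 * (1 - 0.232) * 4.0,
               tolerance = 1e-12)
  expect_lt(rel_sim$predictions$hr_bpm[2], basic_sim$predictions$hr_bpm[2])
})

test_that("user ceilings are honoured by the simulator", {
  p <- reference_fit_profile()
  sc <- fixture_graded_test("fit", "heated")
  sim <- simulate_cvr(p, sc, cvr_config(hr_ceiling = 140))
  pr <- sim$predictions
  first_over <- which(pr$hr_bpm > 140)[1]
  expect_identical(pr$limiting[first_over], "hr_ceiling")
  expect_equal(sim$summary$first_failure_time_min,
               pr$time_min[first_over])
})

test_that("scenario CSV input and output round-trip", {
  sc <- fixture_graded_test("fit", "heated")
  path <- tempfile(fileext = ".csv")
  write_scenario(sc, path)
  back <- read_scenario(path)
  expect_equal(back, sc, tolerance = 1e-12)
  # unknown columns are preserved but warned about
  sc2 <- sc; sc2$note <- 1
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(sc2, path2, row.names = FALSE)
  expect_warning(read_scenario(path2), "unknown scenario column")
  # both workload columns populated on one row is rejected
  sc3 <- sc; sc3$vo2_L_min <- NA_real_; sc3$vo2_L_min[2] <- 1
  path3 <- tempfile(fileext = ".csv")
  utils::write.csv(sc3, path3, row.names = FALSE)
  expect_error(read_scenario(path3), "mutually exclusive")
  # results writer produces one CSV row per scenario row
  sim <- simulate_cvr(reference_fit_profile(), sc)
  out <- tempfile(fileext = ".csv")
  write_results(sim, out)
  expect_equal(nrow(utils::read.csv(out)), nrow(sc))
})

test_that("the validation regression recovers known linear structure", {
  pred <- seq(80, 180, by = 5)
  exact <- regress_predicted_vs_measured(pred, pred)
  expect_equal(exact$slope, 1, tolerance = 1e-12)
  expect_equal(exact$intercept, 0, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-12)
  synth <- regress_predicted_vs_measured(pred, 0.76 * pred + 18.8)
  expect_equal(synth$slope, 0.76, tolerance = 1e-9)
  expect_equal(synth$intercept, 18.8, tolerance = 1e-9)
  expect_equal(synth$r_squared, 1, tolerance = 1e-12)
  # strata are fitted separately alongside the pooled fit
  strata <- rep(c("a", "b"), length.out = length(pred))
  st <- regress_predicted_vs_measured(pred, 0.76 * pred + 18.8, strata)
  expect_identical(st$stratum, c("pooled", "a", "b"))
  expect_equal(st$slope, rep(0.76, 3), tolerance = 1e-9)
  expect_error(regress_predicted_vs_measured(pred, rep(150, length(pred))),
               "degenerate")
  expect_error(regress_predicted_vs_measured(1:2, 1:2), "fewer than 3")
})
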
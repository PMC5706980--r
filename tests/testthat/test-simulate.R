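test_that("a near-certain hazard produces an event on the first presentation", {
  cfg <- buildup_config(n_controls = 1, include_patient = FALSE,
                        n_objects = 10)
  sim <- simulate_buildup(cfg, hazard_spec(0), c(Intercept = 10), seed = 1)
  expect_true(all(sim$event_presentation == 1))
  expect_true(all(sim$censored == 0))
})

test_that("empirical first-presentation hazard matches the generating value", {
  # intercept-only eta = 0.4812 -> h = 0.8017; 3 Monte-Carlo SEs at n trials
  cfg <- buildup_config(n_controls = 5, include_patient = FALSE,
                        n_objects = 100)  # 1000 trials
  sim <- simulate_buildup(cfg, hazard_spec(0), c(Intercept = 0.4812), seed = 4)
  h1 <- sum(sim$event_presentation == 1, na.rm = TRUE) / nrow(sim)
  h_true <- inv_cloglog(0.4812)
  se <- sqrt(h_true * (1 - h_true) / nrow(sim))
  expect_lt(abs(h1 - 0.80), 3 * se + 0.002)
})

test_that("constant-hazard censoring follows the geometric survival law", {
  cfg <- buildup_config(n_controls = 10, include_patient = FALSE,
                        n_objects = 50)  # 1000 trials
  sim <- simulate_buildup(cfg, hazard_spec(0), c(Intercept = cloglog(0.5)),
                          seed = 8)
  p_cens <- mean(sim$censored)
  se <- sqrt(0.5^10 * (1 - 0.5^10) / nrow(sim))
  expect_lt(abs(p_cens - 0.5^10), 3 * se)
})

test_that("life-table hazards of a large simulation converge to the truth", {
  beta <- c(Intercept = 0.2, PT = -0.6, "PT^2" = 0.06, Manmade = -0.4)
  sp <- hazard_spec(2, terms = "Manmade")
  cfg <- buildup_config(n_controls = 10, include_patient = FALSE,
                        n_objects = 100)  # 2000 trials
  sim <- simulate_buildup(cfg, sp, beta, seed = 12)
  pp <- expand_person_period(sim, 10)
  for (m in 0:1) {
    lt <- estimate_lifetable(pp[pp$Manmade == m, ])
    h_true <- inv_cloglog(beta[["Intercept"]] + beta[["PT"]] * (lt$TIME - 1) +
                            beta[["PT^2"]] * (lt$TIME - 1)^2 +
                            beta[["Manmade"]] * m)
    ok <- lt$n_at_risk >= 100
    se <- sqrt(h_true * (1 - h_true) / lt$n_at_risk)
    expect_true(all(abs(lt$hazard - h_true)[ok] <= 3 * se[ok]))
  }
})

test_that("repetition flags count one per object per participant", {
  cfg <- buildup_config(n_controls = 2, include_patient = TRUE, n_objects = 25)
  sim <- simulate_buildup(cfg, hazard_spec(0), c(Intercept = 0), seed = 6)
  reps <- tapply(sim$repetition, sim$participant_id, sum)
  expect_true(all(reps == 25))
})

test_that("non-finite generating coefficients are reported by term", {
  cfg <- buildup_config(n_controls = 1, include_patient = FALSE, n_objects = 5)
  expect_error(simulate_buildup(cfg, hazard_spec(1),
                                c(Intercept = 0, PT = NaN), seed = 1),
               "simulation error.*PT")
  expect_error(simulate_buildup(cfg, hazard_spec(0, terms = "Unknown"),
                                c(Intercept = 0, Unknown = 1), seed = 1),
               "unresolvable|Unknown")
})

test_that("trial CSV files round-trip through read and write", {
  cfg <- buildup_config(n_controls = 1, include_patient = TRUE, n_objects = 8)
  sim <- simulate_buildup(cfg, hazard_spec(0), c(Intercept = -0.5), seed = 2)
  f <- tempfile(fileext = ".csv")
  write_trials(sim, f)
  back <- read_trials(f)
  expect_equal(back$event_presentation, sim$event_presentation)
  expect_equal(back$censored, sim$censored)
  expect_equal(back$object_id, sim$object_id)
  # censored trials leave the event field empty on disk
  lines <- readLines(f)
  if (any(sim$censored == 1)) {
    i <- which(sim$censored == 1)[1] + 1L
    expect_match(lines[i], ",,1$")
  }
})
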
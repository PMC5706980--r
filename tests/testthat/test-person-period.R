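test_that("expansion yields one row per presentation at risk", {
  tr <- trial_row(event_presentation = 3L)
  pp <- expand_person_period(tr, 10)
  expect_equal(nrow(pp), 3)
  expect_equal(pp$EVENT, c(0, 0, 1))
  expect_equal(pp$TIME, 1:3)

  cens <- trial_row(event_presentation = NA_integer_)
  pc <- expand_person_period(cens, 10)
  expect_equal(nrow(pc), 10)
  expect_true(all(pc$EVENT == 0))
})

test_that("expansion arithmetic scales to whole designs", {
  many <- do.call(rbind, lapply(1:1600, function(i) {
    trial_row(trial_index = i, object_id = sprintf("O%04d", i),
              event_presentation = NA_integer_)
  }))
  pp <- expand_person_period(many, 10)
  expect_equal(nrow(pp), 16000)
  expect_equal(sum(pp$EVENT), 0)

  mixed <- rbind(trial_row(trial_index = 1, event_presentation = 2L),
                 trial_row(trial_index = 2, event_presentation = NA_integer_),
                 trial_row(trial_index = 3, event_presentation = 10L))
  ppm <- expand_person_period(mixed, 10)
  expect_equal(nrow(ppm), 2 + 10 + 10)
  expect_equal(sum(ppm$EVENT), 2)  # one event per non-censored trial
})

test_that("events beyond the horizon are a data error", {
  expect_error(expand_person_period(trial_row(event_presentation = 11L), 10),
               "data error")
  bad <- trial_row(event_presentation = 3L)
  bad$censored <- 1L
  expect_error(expand_person_period(bad, 10), "data error")
})

test_that("collapsing the person-period table recovers the trials exactly", {
  cfg <- buildup_config(n_controls = 2, include_patient = TRUE, n_objects = 20)
  sim <- simulate_buildup(cfg, hazard_spec(1), c(Intercept = -0.6, PT = 0.15),
                          seed = 21)
  pp <- expand_person_period(sim, 10)
  expect_equal(nrow(pp),
               sum(ifelse(sim$censored == 1, 10, sim$event_presentation)))
  back <- collapse_person_period(pp)
  key <- paste(sim$participant_id, sim$trial_index, sep = ":")
  back <- back[match(key, back$trial_id), ]
  expect_equal(back$event_presentation, sim$event_presentation)
  expect_equal(back$censored, sim$censored)
})

test_that("design matrix columns are covariate products times centred time powers", {
  pp <- data.frame(TIME = 4, Manmade = 1, Symmetry = 1)
  expect_equal(unname(build_design_matrix(pp, hazard_spec(0))), matrix(1))
  pp2 <- data.frame(TIME = 3)
  expect_equal(unname(build_design_matrix(pp2, hazard_spec(4))[1, ]),
               c(1, 2, 4, 8, 16))
  pp3 <- data.frame(TIME = 5, Manmade = 1, Symmetry = 1)
  X <- build_design_matrix(pp3, hazard_spec(0, terms = "Manmade*Symmetry:PT"))
  expect_equal(unname(X[1, "Manmade*Symmetry:PT"]), 4)
  expect_error(build_design_matrix(pp2, hazard_spec(0, terms = "Absent")),
               "Absent")
})

test_that("design matrices at two centres differ by an invertible linear map", {
  set.seed(31)
  pp <- data.frame(TIME = rep(1:10, 4), A = rep(0:1, each = 20))
  sp1 <- hazard_spec(3, center = 1, terms = c("A", "A:PT", "A:PT^2"))
  sp5 <- hazard_spec(3, center = 5, terms = c("A", "A:PT", "A:PT^2"))
  X1 <- build_design_matrix(pp, sp1)
  X5 <- build_design_matrix(pp, sp5)
  A <- qr.solve(X1, X5)         # binomial expansion of the shifted polynomial
  expect_lt(max(abs(X5 - X1 %*% A)), 1e-9)
  expect_gt(abs(det(A)), 1e-8)  # invertible reparameterization
})
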
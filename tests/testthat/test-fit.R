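test_that("ML estimates agree with a derivative-free oracle on tiny instances", {
  set.seed(101)
  cases <- list(
    list(pp = data.frame(TIME = rep(1:3, 8), EVENT = rbinom(24, 1, 0.4),
                         A = rep(c(0, 1), each = 12)),
         spec = hazard_spec(0, terms = "A")),
    list(pp = data.frame(TIME = rep(1:5, 6), EVENT = rbinom(30, 1, 0.5),
                         A = rep(c(0, 1), 15)),
         spec = hazard_spec(1, terms = "A")),
    list(pp = data.frame(TIME = rep(1:2, 10), EVENT = rbinom(20, 1, 0.6),
                         A = 0),
         spec = hazard_spec(0))
  )
  for (cs in cases) {
    f <- fit_hazard_model(cs$pp, cs$spec)
    X <- build_design_matrix(cs$pp, cs$spec)
    expect_lt(max(abs(coef(f) - oracle_fit(X, cs$pp$EVENT))), 1e-6)
  }
})

test_that("estimates match stats::glm with the cloglog link", {
  sp <- hazard_spec(2, terms = c("Manmade", "Patient"))
  sim <- simulate_buildup(buildup_config(n_controls = 3,
                                         include_patient = TRUE,
                                         n_objects = 40),
                          sp, c(Intercept = 0.48, PT = -0.8, "PT^2" = 0.08,
                                Manmade = -0.3, Patient = -1.5), seed = 5)
  pp <- expand_person_period(sim, 10)
  f <- fit_hazard_model(pp, sp)
  g <- stats::glm(EVENT ~ I(TIME - 1) + I((TIME - 1)^2) + Manmade + Patient,
                  family = binomial("cloglog"), data = pp,
                  control = stats::glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(f)), unname(coef(g)), tolerance = 1e-6)
  expect_equal(f$loglik, as.numeric(logLik(g)), tolerance = 1e-8)
})

test_that("a saturated fit reproduces the life-table hazards exactly", {
  pp <- pp_from_counts(c(100, 20), c(80, 10))
  f <- fit_hazard_model(pp, hazard_spec(1))  # two bins, two parameters
  eta <- c(sum(coef(f) * c(1, 0)), sum(coef(f) * c(1, 1)))
  expect_equal(inv_cloglog(eta), c(0.80, 0.50), tolerance = 1e-9)
})

test_that("model covariance equals the inverse observed information", {
  skip_if_not_installed("pracma")
  sp <- hazard_spec(1, terms = "Manmade")
  sim <- simulate_buildup(buildup_config(n_controls = 2,
                                         include_patient = FALSE,
                                         n_objects = 30),
                          sp, c(Intercept = 0, PT = -0.3, Manmade = 0.4),
                          seed = 17)
  pp <- expand_person_period(sim, 10)
  f <- fit_hazard_model(pp, sp)
  X <- build_design_matrix(pp, sp)
  H <- pracma::hessian(indep_negloglik(X, pp$EVENT), coef(f))
  expect_equal(vcov(f, robust = FALSE), solve(H), tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("cluster-robust covariance assembles per-cluster scores correctly", {
  skip_if_not_installed("pracma")
  sp <- hazard_spec(1, terms = "Manmade")
  sim <- simulate_buildup(buildup_config(n_controls = 4,
                                         include_patient = FALSE,
                                         n_objects = 15),
                          sp, c(Intercept = -0.2, PT = -0.2, Manmade = 0.3),
                          seed = 19)
  pp <- expand_person_period(sim, 10)
  f <- fit_hazard_model(pp, sp, cluster = "participant_id")
  X <- build_design_matrix(pp, sp)
  # numeric per-cluster score vectors from the independent likelihood
  meat <- matrix(0, ncol(X), ncol(X))
  for (cl in unique(pp$participant_id)) {
    i <- pp$participant_id == cl
    g <- pracma::grad(indep_negloglik(X[i, , drop = FALSE], pp$EVENT[i]),
                      coef(f))
    meat <- meat + tcrossprod(-g)
  }
  B <- vcov(f, robust = FALSE)
  expect_equal(vcov(f), B %*% meat %*% B, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("singleton clusters and a saturated model collapse the sandwich", {
  pp <- pp_from_counts(c(60, 25), c(30, 10))
  pp$row_id <- seq_len(nrow(pp))
  f <- fit_hazard_model(pp, hazard_spec(1), cluster = "row_id")
  expect_equal(f$vcov_cluster, f$vcov_model, tolerance = 1e-8)
})

test_that("intercept recovery from a large constant-hazard simulation", {
  set.seed(23)
  n <- 50000
  h <- inv_cloglog(0.4812)
  pp <- data.frame(TIME = 1L, EVENT = rbinom(n, 1, h))
  f <- fit_hazard_model(pp, hazard_spec(0))
  expect_lt(abs(coef(f)[["Intercept"]] - 0.4812), 0.05)
})

test_that("degenerate designs raise informative errors", {
  pp <- data.frame(TIME = rep(1:2, 10), EVENT = rep(0:1, 10), A = 1)
  pp$B <- pp$A  # collinear with A (and the intercept)
  expect_error(fit_hazard_model(pp, hazard_spec(0, terms = c("A", "B"))),
               "singular design")
  # with every event at the first presentation the fitted hazard saturates
  # at 1 (the cloglog likelihood flattens double-exponentially, so the
  # iteration halts at a numerically certain event rather than diverging)
  sat <- data.frame(TIME = 1, EVENT = 1)[rep(1, 30), ]
  fs <- fit_hazard_model(sat, hazard_spec(0))
  expect_equal(inv_cloglog(coef(fs)[["Intercept"]]), 1, tolerance = 1e-12)
  # the runaway guard trips when iterates leave the plausible cloglog range
  expect_error(fit_hazard_model(sat, hazard_spec(0),
                                start = c(Intercept = 20)),
               "separation")
  expect_error(fit_hazard_model(data.frame(TIME = 1, EVENT = 2),
                                hazard_spec(0)), "EVENT")
})

test_that("Wald entries are (estimate/robust SE)^2 against chi-square(1)", {
  set.seed(41)
  pp <- pp_from_counts(c(50, 30), c(20, 12))
  pp$cl <- sample(rep(1:8, length.out = nrow(pp)))
  f <- fit_hazard_model(pp, hazard_spec(1), cluster = "cl")
  expect_equal(f$wald$statistic, (f$wald$estimate / f$wald$se_robust)^2)
  expect_equal(f$wald$p_value,
               pchisq((f$wald$estimate / f$wald$se_robust)^2, 1,
                      lower.tail = FALSE))
})

test_that("hazard ratios exponentiate coefficients", {
  expect_equal(round(hazard_ratio(c(Repetition = 0.5968), "Repetition"), 2),
               1.82)
  expect_equal(hazard_ratio(c(A = 0), "A"), 1.0)
  expect_equal(round(hazard_ratio(c(Patient = -2.4522), "Patient"), 2), 0.09)
  expect_error(hazard_ratio(c(A = 1), "B"), "unknown term")
})
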
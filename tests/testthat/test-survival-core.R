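test_that("engraftment terms follow the median-imputation rule", {
  cov <- data.frame(patient_id = c("A", "B", "C"),
                    graft_source = "PBSC", conditioning_intensity = "MAC",
                    atg_use = "no", donor_type = "matched_related",
                    gvhd_prophylaxis = "CNI_MTX", age = 50,
                    engrafted = c(TRUE, TRUE, TRUE),
                    engraftment_day = c(14L, 17L, 20L))
  e <- engraftment_covariates(cov)
  expect_equal(e$non_engrafted, c(0L, 0L, 0L))
  expect_equal(e$days_to_engraftment, c(14, 17, 20))

  cov$engrafted[3] <- FALSE
  cov$engraftment_day[3] <- NA
  e <- engraftment_covariates(cov)
  expect_equal(e$non_engrafted, c(0L, 0L, 1L))
  expect_equal(e$days_to_engraftment[3], 15.5)

  cov2 <- cov[3, ]
  expect_error(engraftment_covariates(cov2), "median.*undefined")
})

test_that("counting-process expansion breaks exactly at switch days", {
  scheme <- build_interval_scheme()
  rec <- data.frame(patient_id = "B", day = 3L, abx_class = "carbapenems")
  out <- data.frame(patient_id = c("A", "B"),
                    event_day = c(40L, 200L),
                    event_type = c("agvhd", "censored"))
  d <- encode_exposures(rec, scheme, patients = c("A", "B"))
  ex <- expand_counting_process(d, outcomes = out)
  a <- ex[ex$patient_id == "A", ]
  expect_equal(nrow(a), 1L)
  expect_equal(c(a$start, a$stop, a$event), c(-7L, 40L, 1L))
  b <- ex[ex$patient_id == "B", ]
  expect_equal(b$start, c(-7L, 3L))
  expect_equal(b$stop, c(2L, 180L))
  expect_equal(b$event, c(0L, 0L))
  expect_equal(b$carbapenems__i2, c(0L, 1L))
})

test_that("row count equals one plus the number of distinct switch days", {
  set.seed(6)
  scheme <- build_interval_scheme()
  rec <- data.frame(
    patient_id = sample(paste0("P", 1:10), 80, TRUE),
    day = sample(-7:30, 80, TRUE),
    abx_class = sample(default_antibiotic_classes()[1:5], 80, TRUE))
  out <- data.frame(patient_id = paste0("P", 1:10),
                    event_day = sample(60:200, 10),
                    event_type = sample(c("agvhd", "censored"), 10, TRUE))
  d <- encode_exposures(rec, scheme, patients = out$patient_id)
  ex <- expand_counting_process(d, outcomes = out)
  sw <- exposure_switch_days(d)
  for (p in out$patient_id) {
    stop_p <- min(out$event_day[out$patient_id == p], 180L)
    expected <- 1L + sum(sw[[p]] > -7 & sw[[p]] <= stop_p)
    expect_equal(sum(ex$patient_id == p), expected)
  }
  expect_error(expand_counting_process(d, outcomes = out[-1, ]),
               "missing outcome")
})

test_that("two-patient null model has log-likelihood -log 2", {
  # the single covariate separates perfectly (the only event is exposed),
  # so the slope diverges; the null likelihood is still exactly -log 2
  ex <- make_expansion(data.frame(
    patient_id = c("A", "B"), start = c(1L, 1L), stop = c(5L, 10L),
    event = c(1L, 0L), x = c(1, 0)))
  fit <- suppressWarnings(
    fit_td_hazard(ex, terms = "x", on_separation = "warn"))
  expect_equal(fit$loglik_null, -log(2), tolerance = 1e-12)
})

test_that("estimate matches grid maximization of the hand-written partial likelihood", {
  ex <- toy6()
  for (ties in c("efron", "breslow")) {
    fit <- fit_td_hazard(ex, terms = "x", ties = ties)
    oracle <- function(b) oracle_partial_loglik(ex, b, "x", ties = ties)
    bhat <- optimize(oracle, c(-4, 4), maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(unname(coef(fit)), bhat, tolerance = 1e-4)
    # and the likelihood itself agrees at the optimum
    expect_equal(fit$loglik, oracle(coef(fit)), tolerance = 1e-10)
  }
})

test_that("weighted oracle agrees and weight rescaling leaves estimates unchanged", {
  ex <- toy6()
  w <- c(2, 1, 1, 0.5, 1, 3)
  fit <- fit_td_hazard(ex, terms = "x", weights = w)
  oracle <- function(b) oracle_partial_loglik(ex, b, "x", w = w)
  bhat <- optimize(oracle, c(-4, 4), maximum = TRUE, tol = 1e-9)$maximum
  expect_equal(unname(coef(fit)), bhat, tolerance = 1e-4)
  fit3 <- fit_td_hazard(ex, terms = "x", weights = 3 * w)
  expect_equal(coef(fit), coef(fit3), tolerance = 1e-10)
})

test_that("score vanishes at the optimum and AIC follows its definition", {
  ex <- toy6()
  fit <- fit_td_hazard(ex, terms = "x")
  expect_true(fit$converged)
  expect_lt(fit$score_max, 1e-8)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * length(coef(fit)))
  expect_equal(unname(fit$hazard_ratio), unname(exp(coef(fit))))
  expect_true(all(fit$ci_lower <= fit$hazard_ratio &
                    fit$hazard_ratio <= fit$ci_upper))
})

test_that("engine agrees with the survival package on a random fixture", {
  set.seed(42)
  n <- 200
  start <- sample(0:20, n, TRUE)
  stop <- start + sample(1:30, n, TRUE)
  event <- rbinom(n, 1, 0.35)
  x1 <- rbinom(n, 1, 0.4); x2 <- rnorm(n)
  w <- sample(c(1, 1, 2, 0.5), n, TRUE)
  id <- sample(sprintf("P%02d", 1:60), n, TRUE)
  ex <- make_expansion(data.frame(patient_id = id, start = start + 1L,
                                  stop = stop, event = event,
                                  x1 = x1, x2 = x2))
  sdat <- data.frame(start = start, stop = stop, event = event,
                     x1 = x1, x2 = x2, id = id)
  for (ties in c("efron", "breslow")) {
    fit <- fit_td_hazard(ex, weights = w, ties = ties, robust = TRUE)
    cph <- survival::coxph(
      survival::Surv(start, stop, event) ~ x1 + x2 + survival::cluster(id),
      data = sdat, weights = w, ties = ties)
    expect_equal(unname(coef(fit)), unname(coef(cph)), tolerance = 1e-4)
    expect_equal(unname(fit$se), unname(sqrt(diag(vcov(cph)))),
                 tolerance = 1e-4)
  }
})

test_that("degenerate columns are dropped and separation is diagnosed", {
  ex <- toy6()
  ex$allzero <- 0
  expect_warning(fit <- fit_td_hazard(ex, terms = c("x", "allzero")),
                 "degenerate")
  expect_equal(fit$terms, "x")
  # perfectly separated covariate: all events among the exposed
  sep <- make_expansion(data.frame(
    patient_id = paste0("P", 1:6), start = 1L,
    stop = c(3L, 5L, 7L, 20L, 20L, 20L),
    event = c(1L, 1L, 1L, 0L, 0L, 0L),
    z = c(1, 1, 1, 0, 0, 0)))
  expect_error(suppressWarnings(fit_td_hazard(sep, terms = "z")),
               "monotone likelihood.*z")
  expect_warning(
    f <- fit_td_hazard(sep, terms = "z", on_separation = "warn"),
    "monotone likelihood")
  # duplicated column is rank-deficient
  ex$x2 <- ex$x
  expect_error(fit_td_hazard(ex, terms = c("x", "x2")), "rank-deficient")
})

test_that("variance inflation factors match their closed forms", {
  # orthogonal, mean-zero columns
  u <- c(1, -1, 1, -1, 0, 0, 0, 0)
  v <- c(0, 0, 0, 0, 1, -1, 1, -1)
  ex <- make_expansion(data.frame(
    patient_id = paste0("P", 1:8), start = 1L, stop = 5L,
    event = 0L, a = u, b = v))
  expect_equal(unname(compute_vif(ex, c("a", "b"))), c(1, 1))
  # exact R^2 = 0.75 pair: b = sqrt(3) u + v with u, v orthonormal-ish
  ex2 <- make_expansion(data.frame(
    patient_id = paste0("P", 1:8), start = 1L, stop = 5L,
    event = 0L, a = u, b = sqrt(3) * u + v))
  expect_equal(unname(compute_vif(ex2, c("a", "b"))), c(4, 4))
  # duplicated column -> infinite VIF
  ex3 <- make_expansion(data.frame(
    patient_id = paste0("P", 1:8), start = 1L, stop = 5L,
    event = 0L, a = u, b = u))
  expect_true(all(is.infinite(compute_vif(ex3, c("a", "b")))))
  expect_error(compute_vif(ex, "a"), ">= 2 terms")
})
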
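test_that("two-day toy reproduces the hand-computed stabilized weight", {
  # one class, two one-day intervals; the patient initiates on both days.
  # denominator probabilities (0.5, 0.8), numerator (0.6, 0.7):
  # sw(2) = (0.6/0.5) * (0.7/0.8) = 1.05
  scheme <- build_interval_scheme(1, 2, 2)
  rec <- data.frame(patient_id = c("A", "A"), day = c(1L, 2L),
                    abx_class = "carbapenems")
  d <- encode_exposures(rec, scheme, catalogue = "carbapenems")
  den <- function(nd) ifelse(nd$day == 1, 0.5, 0.8)
  num <- function(nd) ifelse(nd$day == 1, 0.6, 0.7)
  models <- structure(
    list(models = list(carbapenems = list(denominator = den,
                                          numerator = num)),
         classes = "carbapenems"),
    class = "treatment_models")
  ws <- stabilized_weights(models, d)
  expect_equal(ws$sw[ws$day == 1], 0.6 / 0.5)
  expect_equal(ws$sw[ws$day == 2], 1.05)
})

test_that("identical numerator and denominator give weights exactly 1 and reproduce the unweighted fit", {
  fix <- small_cohort(seed = 31, n = 200)
  # no baseline covariates or confounders: denominator model == numerator
  tm <- suppressWarnings(fit_treatment_models(fix$design))
  ws <- stabilized_weights(tm, fix$design)
  expect_true(all(ws$sw == 1))
  ex <- fine_gray_extend(
    msm_expand(fix$design, fix$cohort$covariates, fix$cohort$outcomes),
    fix$cohort$outcomes)
  f_msm <- fit_msm(ex, ws)
  f_unw <- fit_td_hazard(ex, robust = TRUE)
  expect_identical(coef(f_msm), coef(f_unw))
  expect_identical(f_msm$se, f_unw$se)
})

test_that("coin-flip exposure yields fitted initiation probabilities near one half", {
  set.seed(77)
  scheme <- build_interval_scheme(0, 7, 2)
  pats <- sprintf("P%03d", 1:500)
  rec <- list()
  for (p in pats) {
    on_iv <- c(FALSE, FALSE)
    for (day in 0:7) {
      iv <- interval_of_day(scheme, day)
      if (!on_iv[iv] && runif(1) < 0.5) {
        on_iv[iv] <- TRUE
        rec[[length(rec) + 1L]] <- data.frame(patient_id = p, day = day,
                                              abx_class = "carbapenems")
      }
    }
  }
  d <- encode_exposures(do.call(rbind, rec), scheme,
                        catalogue = "carbapenems", patients = pats)
  tm <- fit_treatment_models(d)
  pd <- abxgvhd:::person_day_table(d)
  expect_gt(nrow(pd), 1500)
  for (m in tm$models$carbapenems) {
    p_hat <- predict(m, newdata = pd, type = "response")
    expect_lt(abs(mean(p_hat) - 0.5), 0.03)
    expect_lt(abs(plogis(coef(m)[["(Intercept)"]]) - 0.5), 0.03)
  }
})

test_that("a class never administered is skipped and contributes weight 1", {
  scheme <- build_interval_scheme(0, 5, 2)
  rec <- data.frame(patient_id = c("A", "B"), day = c(1L, 4L),
                    abx_class = "carbapenems")
  d <- encode_exposures(rec, scheme,
                        catalogue = c("carbapenems", "linezolid"),
                        patients = c("A", "B", "C"))
  expect_warning(tm <- fit_treatment_models(d), "linezolid.*skipped")
  expect_null(tm$models$linezolid)
  ws <- stabilized_weights(tm, d)
  expect_true(all(is.finite(ws$sw) & ws$sw > 0))
})

test_that("randomized exposure keeps the mean stabilized weight near 1", {
  fix <- small_cohort(seed = 41, n = 500)
  tm <- suppressWarnings(
    fit_treatment_models(fix$design, fix$cohort$covariates))
  ws <- stabilized_weights(tm, fix$design, fix$cohort$covariates)
  expect_lt(abs(mean(ws$sw) - 1), 0.05)
  dg <- weight_diagnostics(ws)
  expect_equal(dg$mean, mean(ws$sw))
  expect_true(dg$min > 0)
})

test_that("weights are invariant to patient relabeling and record order", {
  fix <- small_cohort(seed = 51, n = 120)
  co <- fix$cohort
  tm <- suppressWarnings(fit_treatment_models(fix$design, co$covariates))
  ws <- stabilized_weights(tm, fix$design, co$covariates)

  # relabel patients (reverse names) and shuffle record rows
  relab <- setNames(rev(fix$design$patients), fix$design$patients)
  rec2 <- co$records
  rec2$patient_id <- unname(relab[rec2$patient_id])
  rec2 <- rec2[sample.int(nrow(rec2)), ]
  cov2 <- co$covariates
  cov2$patient_id <- unname(relab[cov2$patient_id])
  d2 <- encode_exposures(rec2, fix$config$scheme, fix$config$catalogue,
                         patients = cov2$patient_id)
  tm2 <- suppressWarnings(fit_treatment_models(d2, cov2))
  ws2 <- stabilized_weights(tm2, d2, cov2)
  key1 <- paste(unname(relab[ws$patient_id]), ws$day)
  m <- match(key1, paste(ws2$patient_id, ws2$day))
  expect_equal(ws$sw, ws2$sw[m], tolerance = 1e-10)
})

test_that("per-day treatment models and weight-series serialization work", {
  fix <- small_cohort(seed = 62, n = 250)
  tm <- suppressWarnings(fit_treatment_models(fix$design, per_day = TRUE))
  m <- tm$models[[which(!vapply(tm$models, is.null, logical(1)))[1]]]
  expect_true(any(grepl("^day_f", names(coef(m$denominator)))))
  ws <- stabilized_weights(tm, fix$design)
  expect_true(all(is.finite(ws$sw)))

  tm2 <- suppressWarnings(fit_treatment_models(fix$design,
                                               fix$cohort$covariates))
  ws2 <- stabilized_weights(tm2, fix$design, fix$cohort$covariates)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_weight_series(ws2, csv, js)
  back <- read.csv(csv)
  expect_equal(nrow(back), nrow(ws2))
  expect_equal(back$sw, ws2$sw)
  dg <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(dg$mean, mean(ws2$sw))
})

test_that("weight truncation clamps the extremes and refreshes diagnostics", {
  fix <- small_cohort(seed = 61, n = 200)
  tm <- suppressWarnings(fit_treatment_models(fix$design,
                                              fix$cohort$covariates))
  ws <- stabilized_weights(tm, fix$design, fix$cohort$covariates)
  tw <- truncate_weights(ws, 0.05, 0.95)
  q <- quantile(ws$sw, c(0.05, 0.95))
  expect_equal(min(tw$sw), unname(q[1]))
  expect_equal(max(tw$sw), unname(q[2]))
  expect_equal(weight_diagnostics(tw)$max, max(tw$sw))
})
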
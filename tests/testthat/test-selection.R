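sep_fixture <- function() {
  # 12 patients; carbapenems interval-2 exposure perfectly predicts the
  # event among the exposed; fluoroquinolones interval-3 exposure is mixed.
  out <- data.frame(
    patient_id = sprintf("P%02d", 1:12),
    event_day = c(20L, 25L, 30L, rep(170L, 9)),
    event_type = c(rep("agvhd", 3), "agvhd", "agvhd",
                   rep("censored", 7)))
  rec <- rbind(
    data.frame(patient_id = c("P01", "P02", "P03"), day = 2L,
               abx_class = "carbapenems"),
    data.frame(patient_id = c("P07", "P08"), day = -3L,
               abx_class = "carbapenems"),
    data.frame(patient_id = c("P04", "P05", "P06"), day = 9L,
               abx_class = "fluoroquinolones"))
  scheme <- build_interval_scheme()
  d <- encode_exposures(rec, scheme,
                        catalogue = c("carbapenems", "fluoroquinolones"),
                        patients = out$patient_id)
  list(design = d, outcomes = out)
}

test_that("perfect separation is flagged by the all-or-none rule", {
  fx <- sep_fixture()
  flags <- detect_perfect_separation(fx$design, fx$outcomes)
  # all exposed with the event (interval 2) and none of the exposed with
  # the event (interval 1) are both flagged
  expect_equal(flags$name, c("carbapenems__i1", "carbapenems__i2"))
  expect_equal(flags$n_exposed, c(2L, 3L))
  expect_equal(flags$n_events, c(0L, 3L))
  # mixed column (2 events / 1 non-event among exposed) is not flagged
  expect_false("fluoroquinolones__i3" %in% flags$name)
  # zero-exposed columns are never flagged
  expect_false(any(grepl("__i5", flags$name)))
})

test_that("separation resolution merges toward the earlier neighbour first", {
  fx <- sep_fixture()
  d2 <- resolve_separation(fx$design, fx$outcomes)
  expect_equal(nrow(detect_perfect_separation(d2, fx$outcomes)), 0L)
  expect_true("carbapenems__i1_2" %in% d2$columns$name)
  # untouched class keeps its five columns
  expect_equal(sum(d2$columns$abx_class == "fluoroquinolones"), 5L)
})

test_that("designs without separation pass through unchanged", {
  fix <- small_cohort(seed = 71, n = 300)
  flags <- detect_perfect_separation(fix$design, fix$cohort$outcomes)
  if (nrow(flags) == 0L) {
    d2 <- resolve_separation(fix$design, fix$cohort$outcomes)
    expect_identical(d2$columns, fix$design$columns)
    expect_identical(d2$first_day, fix$design$first_day)
  } else {
    d2 <- resolve_separation(fix$design, fix$cohort$outcomes)
    expect_equal(nrow(detect_perfect_separation(d2, fix$cohort$outcomes)),
                 0L)
  }
})

test_that("a class separated in every interval collapses to one column or is dropped", {
  out <- data.frame(patient_id = sprintf("P%02d", 1:10),
                    event_day = c(rep(150L, 5), rep(160L, 5)),
                    event_type = c(rep("agvhd", 5), rep("censored", 5)))
  rec <- data.frame(patient_id = rep(sprintf("P%02d", 1:5), times = 5),
                    day = rep(c(-3L, 2L, 9L, 16L, 25L), each = 5),
                    abx_class = "carbapenems")
  d <- encode_exposures(rec, build_interval_scheme(),
                        catalogue = "carbapenems",
                        patients = out$patient_id)
  expect_warning(d2 <- resolve_separation(d, out), "dropping column")
  expect_equal(n_design_columns(d2), 0L)
})

test_that("backward elimination removes null classes with decreasing AIC", {
  fix <- small_cohort(seed = 81, n = 350)
  d <- resolve_separation(fix$design, fix$cohort$outcomes)
  res <- suppressWarnings(
    backward_eliminate(d, fix$cohort$outcomes, fix$cohort$covariates))
  acc <- res$trace[res$trace$accepted, , drop = FALSE]
  expect_gt(nrow(acc), 0L)
  expect_true(all(diff(acc$aic_after) < 0 | nrow(acc) == 1L))
  expect_true(all(acc$aic_after < acc$aic_before))
  expect_lte(res$fit$aic, attr(res$trace, "initial_aic"))
  # all data are null: at least one antibiotic class should be eliminated
  expect_lt(length(unique(res$design$columns$abx_class)), 3L)
})

test_that("a strong true effect survives elimination", {
  fix <- small_cohort(seed = 91, n = 500, preset = "carbapenem_week1")
  d <- resolve_separation(fix$design, fix$cohort$outcomes)
  res <- suppressWarnings(
    backward_eliminate(d, fix$cohort$outcomes, fix$cohort$covariates))
  expect_true("carbapenems" %in% res$design$columns$abx_class)
  kept <- res$design$columns
  target <- kept$name[kept$abx_class == "carbapenems" &
                        kept$start_idx <= 2 & kept$end_idx >= 2]
  expect_gt(res$fit$coefficients[target], 0)
  expect_lt(res$fit$p_value[target], 0.05)
})

test_that("a model at a fixed point returns an empty accepted trace", {
  # two adjacent intervals with strong opposite-sign effects: no merge
  # (signs differ), no removal (both significant)
  set.seed(123)
  n <- 400
  pats <- sprintf("P%03d", 1:n)
  rec <- rbind(
    data.frame(patient_id = pats[1:200], day = 2L,
               abx_class = "carbapenems"),
    data.frame(patient_id = pats[101:300], day = 9L,
               abx_class = "carbapenems"))
  d <- encode_exposures(rec, build_interval_scheme(),
                        catalogue = "carbapenems", patients = pats)
  x2 <- !is.na(d$first_day[, "carbapenems__i2"])
  x3 <- !is.na(d$first_day[, "carbapenems__i3"])
  risk <- plogis(-0.8 + 2.2 * x2 - 2.2 * x3)
  ev <- runif(n) < risk
  out <- data.frame(patient_id = pats,
                    event_day = ifelse(ev, sample(15:90, n, TRUE), 181L),
                    event_type = ifelse(ev, "agvhd", "censored"))
  fitter <- function(dd) {
    ex <- expand_counting_process(dd, outcomes = out)
    suppressWarnings(fit_td_hazard(ex, on_separation = "warn"))
  }
  res <- backward_eliminate(d, out, fitter = fitter)
  expect_equal(sum(res$trace$accepted), 0L)
  expect_identical(res$design$columns, d$columns)
})
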
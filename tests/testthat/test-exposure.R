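scheme <- build_interval_scheme()

test_that("17-class catalogue over 5 intervals yields 85 design columns", {
  rec <- data.frame(patient_id = "A", day = 0L,
                    abx_class = "carbapenems")
  d <- encode_exposures(rec, scheme)
  expect_equal(n_design_columns(d), 85L)
  expect_equal(length(default_antibiotic_classes()), 17L)
})

test_that("empty record list gives all-zero paths", {
  rec <- data.frame(patient_id = character(0), day = integer(0),
                    abx_class = character(0))
  d <- encode_exposures(rec, scheme, patients = c("A", "B"))
  expect_true(all(exposure_path_at(d, 30) == 0L))
})

test_that("single dose switches exactly one column on from that day", {
  rec <- data.frame(patient_id = "A", day = 3L, abx_class = "carbapenems")
  d <- encode_exposures(rec, scheme)
  carb <- paste0("carbapenems__i", 1:5)
  expect_equal(unname(exposure_path_at(d, 2)["A", carb]), rep(0L, 5))
  expect_equal(unname(exposure_path_at(d, 3)["A", carb]),
               c(0L, 1L, 0L, 0L, 0L))
  expect_equal(unname(exposure_path_at(d, 30)["A", carb]),
               c(0L, 1L, 0L, 0L, 0L))
})

test_that("duplicate administrations collapse: encoding is idempotent", {
  set.seed(3)
  rec <- data.frame(
    patient_id = sample(c("A", "B", "C"), 40, TRUE),
    day = sample(-7:30, 40, TRUE),
    abx_class = sample(default_antibiotic_classes()[1:4], 40, TRUE))
  d1 <- encode_exposures(rec, scheme)
  d2 <- encode_exposures(rbind(rec, rec, rec[1:10, ]), scheme)
  expect_identical(d1$first_day, d2$first_day)
})

test_that("persistent paths are monotone non-decreasing in day", {
  set.seed(4)
  rec <- data.frame(
    patient_id = sample(paste0("P", 1:8), 60, TRUE),
    day = sample(-7:30, 60, TRUE),
    abx_class = sample(default_antibiotic_classes(), 60, TRUE))
  d <- encode_exposures(rec, scheme)
  prev <- exposure_path_at(d, -7)
  for (day in -6:30) {
    cur <- exposure_path_at(d, day)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("transient coding switches off after the interval ends", {
  rec <- data.frame(patient_id = "A", day = 3L, abx_class = "carbapenems")
  d <- encode_exposures(rec, scheme, coding = "transient")
  expect_equal(exposure_path_at(d, 6)["A", "carbapenems__i2"], 1L)
  expect_equal(exposure_path_at(d, 7)["A", "carbapenems__i2"], 0L)
  expect_true(7L %in% exposure_switch_days(d)$A)
})

test_that("out-of-window records are dropped with a count", {
  rec <- data.frame(patient_id = c("A", "A"), day = c(3L, 45L),
                    abx_class = "carbapenems")
  expect_message(d <- encode_exposures(rec, scheme), "dropped 1 record")
  expect_equal(d$n_dropped, 1L)
})

test_that("unknown class names and empty catalogues are rejected", {
  rec <- data.frame(patient_id = "A", day = 1L, abx_class = "penicillin!!")
  expect_error(encode_exposures(rec, scheme), "penicillin!!")
  expect_error(encode_exposures(rec, scheme, catalogue = character(0)),
               "non-empty")
  expect_error(validate_catalogue(c("a", "a")), "unique")
})

test_that("merging adjacent columns keeps the earliest switch day", {
  rec <- data.frame(patient_id = c("A", "B"), day = c(10L, 16L),
                    abx_class = "carbapenems")
  d <- encode_exposures(rec, scheme)
  m <- merge_columns(d, "carbapenems", c(3, 4))
  expect_equal(n_design_columns(m), 84L)
  expect_equal(unname(m$first_day["A", "carbapenems__i3_4"]), 10L)
  expect_equal(unname(m$first_day["B", "carbapenems__i3_4"]), 16L)
  # merging two all-zero columns stays all-zero
  m2 <- merge_columns(d, "aztreonam", c(1, 2))
  expect_true(all(is.na(m2$first_day[, "aztreonam__i1_2"])))
  expect_error(merge_columns(d, "carbapenems", c(1, 3)), "contiguous")
  expect_error(merge_columns(d, "carbapenems", 2), "at least 2")
})

test_that("long records round-trip through a design", {
  set.seed(5)
  rec <- data.frame(
    patient_id = sample(paste0("P", 1:6), 50, TRUE),
    day = sample(-7:30, 50, TRUE),
    abx_class = sample(default_antibiotic_classes(), 50, TRUE))
  d <- encode_exposures(rec, scheme)
  d2 <- encode_exposures(design_to_records(d), scheme,
                         patients = d$patients)
  expect_identical(d$first_day, d2$first_day)
})

test_that("wide person-day CSV and sidecar serialize and agree", {
  rec <- data.frame(patient_id = c("A", "B"), day = c(0L, 9L),
                    abx_class = c("carbapenems", "linezolid"))
  d <- encode_exposures(rec, scheme)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_design_csv(d, csv, js)
  wide <- read.csv(csv, check.names = FALSE)
  expect_equal(nrow(wide), 2 * 38)
  expect_equal(wide[wide$patient_id == "A" & wide$day == 0,
                    "carbapenems__i2"], 1L)
  expect_equal(wide[wide$patient_id == "A" & wide$day == -1,
                    "carbapenems__i2"], 0L)
  side <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(side$coding, "persistent")
  expect_equal(length(side$catalogue), 17L)
})
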
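make_tables <- function() {
  visits <- data.frame(
    visit_id = c("V1", "V2", "V3", "V4", "V5", "V6"),
    subject_id = c("P1", "P2", "P3", "P4", "P5", "P6"),
    visit_time = c(0, 0, 0, 0, 0, 0),
    age = c(55, 60, 45, 19, 70, 33)
  )
  diagnoses <- data.frame(
    visit_id = c("V1", "V2", "V3", "V5", "V6"),
    code = c("I21.0", "I21", "I22.1", "I50", "I21.9"),
    registration_time = c(5, NA, 40, 2, 3)
  )
  ecgs <- data.frame(
    ecg_id = sprintf("E%d", 1:7),
    visit_id = c("V1", "V2", "V3", "V4", "V5", "V6", "V6"),
    ecg_time = c(3, 1, 2, 1, 10, 2, 30)
  )
  list(visits = visits, diagnoses = diagnoses, ecgs = ecgs)
}

test_that("labeling and exclusion rules fire as specified", {
  tb <- make_tables()
  out <- label_and_filter(tb$visits, tb$diagnoses, tb$ecgs)
  lab <- out$labeled
  exc <- out$exclusions

  # V1: I21.0 registered 2 h after the ECG -> positive, retained
  expect_equal(lab$label[lab$ecg_id == "E1"], 1L)
  # V2: AMI code with null registration -> excluded with that reason
  expect_true("E2" %in% exc$ecg_id)
  expect_equal(exc$reason[exc$ecg_id == "E2"], "ami_registration_null")
  # V3: AMI code registered 38 h after the ECG -> excluded out-of-window
  expect_equal(exc$reason[exc$ecg_id == "E3"],
               "ami_registration_out_of_window")
  # V4: patient aged 19 -> excluded
  expect_equal(exc$reason[exc$ecg_id == "E4"], "age_under_20")
  # V5: only heart failure coded -> negative, retained
  expect_equal(lab$label[lab$ecg_id == "E5"], 0L)
  # V6 first ECG: positive; second ECG 30 h after visit -> excluded
  expect_equal(lab$label[lab$ecg_id == "E6"], 1L)
  expect_equal(exc$reason[exc$ecg_id == "E7"], "ecg_outside_24h")

  # conservation: every input ECG is either labeled or excluded, once
  expect_equal(nrow(lab) + nrow(exc), nrow(tb$ecgs))
  expect_length(intersect(lab$ecg_id, exc$ecg_id), 0)
})

test_that("ICD-10 matching is prefix-based on normalized codes", {
  ns <- asNamespace("asyncecg")
  expect_true(all(ns$is_ami_code(c("I21", "I21.4", "i21.9", "I22", "I22.8",
                                   "I219"))))
  expect_false(any(ns$is_ami_code(c("I20", "I23", "I2", "I50", "", "X21"))))
})

test_that("exclusion windows are closed at exactly 24 h", {
  visits <- data.frame(visit_id = "V1", subject_id = "P1",
                       visit_time = 0, age = 50)
  diagnoses <- data.frame(visit_id = "V1", code = "I21",
                          registration_time = 24)
  ecgs <- data.frame(ecg_id = c("E1", "E2"), visit_id = "V1",
                     ecg_time = c(24, 24.5))
  out <- label_and_filter(visits, diagnoses, ecgs)
  # E1 at exactly 24 h from the visit (and 0 h from registration): retained
  expect_equal(out$labeled$label[out$labeled$ecg_id == "E1"], 1L)
  # E2 at 24.5 h from the visit: excluded
  expect_equal(out$exclusions$reason[out$exclusions$ecg_id == "E2"],
               "ecg_outside_24h")
})

test_that("registration-time exclusions never touch uncoded visits", {
  visits <- data.frame(visit_id = c("V1", "V2"), subject_id = c("P1", "P2"),
                       visit_time = 0, age = 50)
  # a null registration time on a NON-AMI code must not exclude anything
  diagnoses <- data.frame(visit_id = c("V1", "V2"), code = c("I50", "J18"),
                          registration_time = c(NA, NA))
  ecgs <- data.frame(ecg_id = c("E1", "E2"), visit_id = c("V1", "V2"),
                     ecg_time = c(1, 2))
  out <- label_and_filter(visits, diagnoses, ecgs)
  expect_equal(nrow(out$exclusions), 0L)
  expect_equal(out$labeled$label, c(0L, 0L))
})

test_that("malformed timestamps yield per-record errors, not failure", {
  visits <- data.frame(visit_id = c("V1", "V2"), subject_id = c("P1", "P2"),
                       visit_time = c(0, NA), age = 50)
  diagnoses <- data.frame(visit_id = "V1", code = "I21",
                          registration_time = 1)
  ecgs <- data.frame(ecg_id = c("E1", "E2"), visit_id = c("V1", "V2"),
                     ecg_time = c(1, 2))
  out <- label_and_filter(visits, diagnoses, ecgs)
  expect_equal(out$labeled$label[out$labeled$ecg_id == "E1"], 1L)
  expect_equal(out$exclusions$reason[out$exclusions$ecg_id == "E2"],
               "malformed")
})

test_that("prevalence reproduces the cohort percentages", {
  # printed dataset sizes: 2,465 AMI of 138,549 train/validation ECGs and
  # 554 of 34,371 test ECGs
  trainval <- c(rep(1L, 2465), rep(0L, 138549 - 2465))
  test <- c(rep(1L, 554), rep(0L, 34371 - 554))
  expect_equal(round(prevalence(trainval, percent = TRUE), 2), 1.78)
  expect_equal(round(prevalence(test, percent = TRUE), 2), 1.61)
  expect_equal(prevalence(rep(0L, 10)), 0)
  expect_error(prevalence(integer(0)), "no labeled")
})

test_that("generated visit tables match the rule oracle", {
  tb <- generate_visit_table(n_visits = 100, n_ami = 10,
                             n_null_registration = 2, seed = 91)
  out <- label_and_filter(tb$visits, tb$diagnoses, tb$ecgs)
  expect_equal(sum(out$labeled$label == 1L), 8L)
  expect_equal(nrow(out$exclusions), 2L)
  expect_true(all(out$exclusions$reason == "ami_registration_null"))

  tb2 <- generate_visit_table(n_visits = 60, n_ami = 12,
                              n_null_registration = 3, n_out_of_window = 4,
                              n_under20 = 5, seed = 92)
  out2 <- label_and_filter(tb2$visits, tb2$diagnoses, tb2$ecgs)
  expect_equal(sum(out2$labeled$label == 1L), 5L)   # 12 - 3 - 4
  reasons <- table(out2$exclusions$reason)
  expect_equal(unname(reasons["ami_registration_null"]), 3L)
  expect_equal(unname(reasons["ami_registration_out_of_window"]), 4L)
  expect_equal(unname(reasons["age_under_20"]), 5L)
  expect_equal(nrow(out2$labeled) + nrow(out2$exclusions), nrow(tb2$ecgs))

  # under-age patients yield no retained ECGs at all
  tb3 <- generate_visit_table(n_visits = 10, n_ami = 0, n_under20 = 10,
                              seed = 93)
  out3 <- label_and_filter(tb3$visits, tb3$diagnoses, tb3$ecgs)
  expect_equal(nrow(out3$labeled), 0L)

  # fixed seed reproducibility
  expect_identical(generate_visit_table(n_visits = 50, n_ami = 5, seed = 94),
                   generate_visit_table(n_visits = 50, n_ami = 5, seed = 94))
})
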
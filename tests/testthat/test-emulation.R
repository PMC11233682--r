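# small deterministic EHR toy for the date logic
toyEhr <- function() {
  patients <- data.frame(
    patient_id = c("A", "B", "C", "D", "E"),
    birth_date = c("1950-01-01", "1970-06-01", "1940-03-01",
                   "1948-05-05", "1930-01-01"),
    sex = c(1, 0, 1, 0, 1), race = c(1, 1, 2, 3, 1),
    stringsAsFactors = FALSE)
  diagnoses <- data.frame(
    patient_id = c("A", "B", "C", "C", "D", "E", "A", "A"),
    code = c("G20", "G20", "G20", "G30", "G20", "G20",
             "OUTCOME_DEM", "LAST_CONTACT"),
    date = c("2015-07-01", "2016-01-01", "2015-01-01", "2014-06-01",
             "2016-05-01", "2015-03-01", "2016-09-01", "2016-10-01"),
    stringsAsFactors = FALSE)
  prescriptions <- data.frame(
    patient_id = c("A", "D", "E"),
    ingredient = c("drug_test", "alt1", "drug_test"),
    date = c("2015-08-01", "2016-06-01", "2014-01-01"),
    stringsAsFactors = FALSE)
  list(patients = patients, diagnoses = diagnoses,
       prescriptions = prescriptions)
}

test_that("eligibility applies the age, PD-code and prior-neuro rules", {
  ehr <- toyEhr()
  # B is 45 at first PD code; C has a prior neurodegenerative code
  elig <- applyEligibility(ehr$patients, ehr$diagnoses)
  expect_setequal(elig, c("A", "D", "E"))
  expect_error(applyEligibility(ehr$patients, ehr$diagnoses,
                                pdCodes = character(0)), "nonempty")
})

test_that("date definitions follow the 183-day rule and rejections", {
  ehr <- toyEhr()
  elig <- applyEligibility(ehr$patients, ehr$diagnoses)
  dates <- defineDates(elig, ehr$diagnoses, ehr$prescriptions,
                       "drug_test", "alt1")
  # first PD code 2015-07-01 -> initiation 2014-12-30
  a <- dates[dates$patient_id == "A", ]
  expect_equal(a$initiation, as.Date("2014-12-30"))
  expect_equal(a$index, as.Date("2015-08-01"))
  expect_equal(a$arm, "treated")
  expect_equal(dates$arm[dates$patient_id == "D"], "control")
  # E's only dispensing precedes initiation -> not in the trial
  expect_false("E" %in% dates$patient_id)
})

test_that("outcome on or before the index date rejects the patient", {
  ehr <- toyEhr()
  ehr$diagnoses$date[ehr$diagnoses$code == "OUTCOME_DEM"] <- "2015-08-01"
  dates <- defineDates(applyEligibility(ehr$patients, ehr$diagnoses),
                       ehr$diagnoses, ehr$prescriptions,
                       "drug_test", "alt1")
  expect_false("A" %in% dates$patient_id)
})

test_that("covariate matrix has the declared schema and ignores post-index events", {
  ehr <- toyEhr()
  # one baseline comorbidity and one post-index comorbidity for A
  ehr$diagnoses <- rbind(ehr$diagnoses, data.frame(
    patient_id = c("A", "A"), code = c("COM01", "COM02"),
    date = c("2015-03-01", "2015-12-01"), stringsAsFactors = FALSE))
  elig <- applyEligibility(ehr$patients, ehr$diagnoses)
  dates <- defineDates(elig, ehr$diagnoses, ehr$prescriptions,
                       "drug_test", "alt1")
  cov <- buildCovariates(dates, ehr$patients, ehr$diagnoses,
                         ehr$prescriptions,
                         sprintf("COM%02d", 1:64),
                         sprintf("coing%03d", 1:199))
  expect_equal(ncol(cov), 64 + 199 + 4)
  expect_equal(unname(cov["A", "COM01"]), 1)     # inside baseline window
  expect_equal(unname(cov["A", "COM02"]), 0)     # after index
  expect_equal(unname(cov["D", "COM01"]), 0)     # no baseline events
  expect_equal(unname(cov["A", "init_to_index_days"]),
               as.numeric(as.Date("2015-08-01") - as.Date("2014-12-30")))
})

test_that("SMD matches hand arithmetic and the 2% balance rule", {
  # means 0 vs 1 with unit variance in each arm -> SMD = 1
  s <- sqrt(0.5)
  expect_equal(smdValue(c(-s, s), c(1 - s, 1 + s)), 1)
  expect_equal(smdValue(c(1, 1), c(1, 1)), 0)    # constant in both arms
  x <- matrix(0, 6, 267, dimnames = list(sprintf("p%d", 1:6),
                                         sprintf("c%03d", 1:267)))
  # plant 6 unbalanced binary covariates (2.2% > 2%)
  x[1:3, 1:6] <- 1
  bal <- assessBalance(x, sprintf("p%d", 1:3), sprintf("p%d", 4:6))
  expect_equal(sum(bal$smd > 0.2), 6)
  expect_false(bal$balanced)
  # identical arms are balanced with all-zero SMDs
  bal2 <- assessBalance(x, sprintf("p%d", c(1, 4)), sprintf("p%d", c(1, 4)))
  expect_true(bal2$balanced)
  expect_true(all(bal2$smd == 0))
})

test_that("matching is 1:1 without replacement and balances identical pools", {
  set.seed(22)
  n <- 40
  cov <- matrix(rnorm(n * 5), n,
                dimnames = list(sprintf("p%02d", 1:n), sprintf("c%d", 1:5)))
  treated <- sprintf("p%02d", 1:10)
  pool <- sprintf("p%02d", 11:40)
  # identical covariates: copy treated rows into the pool
  cov[pool[1:10], ] <- cov[treated, ]
  tr <- matchTrial(cov, treated, pool, seed = 1)
  expect_length(tr@controls, 10)
  expect_false(anyDuplicated(tr@controls) > 0)
  expect_error(matchTrial(cov, pool, treated, seed = 1), "smaller")
})

test_that("Cox stage recovers a planted hazard ratio on matched data", {
  set.seed(23)
  n <- 3000
  ids <- sprintf("p%04d", 1:n)
  trt <- rep(c(1, 0), n / 2)
  tEv <- rexp(n, 0.1 * ifelse(trt == 1, 0.5, 1))
  tCs <- pmin(rexp(n, 0.1), 6)
  surv <- data.frame(patient_id = ids, time = pmin(tEv, tCs),
                     event = as.integer(tEv <= tCs))
  hr <- estimateCoxHr(surv, ids[trt == 1], ids[trt == 0])
  expect_gt(hr$hr, 0.42); expect_lt(hr$hr, 0.60)
  # cross-check against a direct coxph fit on the same data
  d <- surv; d$treated <- trt
  direct <- exp(coef(survival::coxph(survival::Surv(time, event) ~ treated,
                                     data = d)))
  expect_equal(hr$hr, unname(direct), tolerance = 1e-8)
  # no events in one arm -> undefined
  surv0 <- surv; surv0$event[trt == 1] <- 0
  expect_warning(r0 <- estimateCoxHr(surv0, ids[trt == 1], ids[trt == 0]),
                 "no events")
  expect_null(r0)
})

test_that("matching removes planted confounding on a compact cohort", {
  ehr <- simulateEhrCohort(ehrSpec(nPatients = 8000, seed = 30))
  elig <- applyEligibility(ehr$patients, ehr$diagnoses)
  dates <- defineDates(elig, ehr$diagnoses, ehr$prescriptions,
                       "drug_test", sprintf("alt%d", 1:5))
  cov <- buildCovariates(dates, ehr$patients, ehr$diagnoses,
                         ehr$prescriptions, sprintf("COM%02d", 1:64),
                         sprintf("coing%03d", 1:199))
  tid <- dates$patient_id[dates$arm == "treated"]
  cid <- dates$patient_id[dates$arm == "control"]
  set.seed(31)
  pool <- sample(cid, min(length(cid), 10 * length(tid)))
  tr <- matchTrial(cov, tid, pool, seed = 32)
  expect_gt(max(tr@smdPre), 0.2)                # confounding visible
  expect_gte(mean(tr@smd <= 0.2), 0.98)          # and removed
  # adjusted HR closer to the planted truth than unadjusted
  surv <- survivalFromTables(dates, ehr$diagnoses, "OUTCOME_DEM")
  adj <- estimateCoxHr(surv, tr@treated, tr@controls)
  unadj <- estimateCoxHr(surv, tid, cid)
  expect_lt(abs(log(adj$hr) - log(0.7)), abs(log(unadj$hr) - log(0.7)))
  # date ordering invariant
  expect_true(all(dates$initiation <= dates$index))
  expect_true(all(surv$time > 0))
})

test_that("emulation gates: too few treated patients skips the drug", {
  ehr <- simulateEhrCohort(ehrSpec(nPatients = 400, seed = 33))
  expect_message(est <- runEmulation(ehr, nTrials = 2, seed = 34,
                                     minTreated = 100),
                 "insufficient")
  expect_null(est)
})
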
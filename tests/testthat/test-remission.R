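ms <- function(visit, cls = character(), dose = numeric(), unit = rep("mg", length(cls))) {
  medication_state(visit, cls, dose, unit)
}

test_that("medication comparison covers the reduction lattice", {
  base <- ms("baseline", c("metformin", "SU_derivative", "insulin"),
             c(2000, 80, 40), c("mg", "mg", "IU"))
  expect_equal(compare_medication(base, ms("month3", "metformin", 2000)), "reduced")
  expect_equal(compare_medication(base, ms("month3")), "stopped_all")
  expect_equal(compare_medication(base, base), "equal")

  m <- ms("baseline", "metformin", 2000)
  expect_equal(compare_medication(m, ms("month3", "metformin", 2000)), "equal")
  expect_equal(compare_medication(m, ms("month3", "metformin", 1000)), "reduced")
  expect_equal(compare_medication(m, ms("month3", "metformin", 3000)), "increased")
  expect_equal(compare_medication(m, ms("month3", c("metformin", "SU_derivative"),
                                        c(1000, 80))), "increased")
  # mixed change within equal classes: one dose down is reduced only if none up
  two <- ms("baseline", c("metformin", "SU_derivative"), c(2000, 80))
  expect_equal(compare_medication(
    two, ms("month3", c("metformin", "SU_derivative"), c(1000, 120))), "increased")
  expect_equal(compare_medication(
    two, ms("month3", c("metformin", "SU_derivative"), c(1000, 40))), "reduced")
  # proper subset with a raised remaining dose is conservative: increased
  expect_equal(compare_medication(two, ms("month3", "metformin", 3000)), "increased")
  # both medication-free: equal
  expect_equal(compare_medication(ms("baseline"), ms("month3")), "equal")

  expect_error(compare_medication(
    ms("baseline", "insulin", 40, "IU"), ms("month3", "insulin", 40, "mg")),
    "unit mismatch")
  expect_error(medication_state("baseline", c("metformin", "metformin"),
                                c(1000, 1000), c("mg", "mg")), "one item per")
  expect_error(medication_state("baseline", "aspirin", 100, "mg"), "unknown drug")
})

test_that("status adjudication matches a hand-derived oracle on the full predicate grid", {
  # independent oracle written as literal nested conditions
  oracle_status <- function(hba1c, fpg, relation, med_free) {
    if (fpg <= 6.9 && hba1c < 48 && med_free) return("remission")
    if (hba1c <= 53 && fpg < 8.0 && relation %in% c("reduced", "stopped_all"))
      return("reversal")
    if (hba1c < 48 && fpg <= 6.9 && relation == "equal") return("reversal")
    "T2D"
  }
  hba_grid <- c(30, 47.9, 48, 53, 53.1, 70)
  fpg_grid <- c(5, 6.9, 7.0, 7.9, 8.0, 12)
  for (hba1c in hba_grid) for (fpg in fpg_grid)
    for (rel in c("stopped_all", "reduced", "equal", "increased")) {
      med_free <- rel == "stopped_all"
      cur <- if (med_free) ms("month3") else ms("month3", "metformin", 1000)
      got <- classify_status(list(hba1c = hba1c, fpg = fpg), rel, cur)
      expect_equal(as.character(got$status),
                   oracle_status(hba1c, fpg, rel, med_free),
                   info = sprintf("hba1c=%g fpg=%g rel=%s", hba1c, fpg, rel))
    }
})

test_that("the printed threshold boundaries are honored strictly", {
  none <- ms("month3")
  # at the remission boundary: fpg 6.9 inclusive, hba1c 48 exclusive
  expect_equal(as.character(classify_status(list(hba1c = 47.99, fpg = 6.9),
                                            "stopped_all", none)$status), "remission")
  at48 <- classify_status(list(hba1c = 48, fpg = 6.9), "stopped_all", none)
  expect_false(as.character(at48$status) == "remission")
  expect_equal(as.character(at48$status), "reversal")  # 48 <= 53 and 6.9 < 8
  # reversal boundary: hba1c 53 inclusive, fpg 8.0 exclusive
  red <- ms("month3", "metformin", 500)
  expect_equal(as.character(classify_status(list(hba1c = 53, fpg = 7.99),
                                            "reduced", red)$status), "reversal")
  expect_equal(as.character(classify_status(list(hba1c = 53.01, fpg = 7.99),
                                            "reduced", red)$status), "T2D")
  expect_equal(as.character(classify_status(list(hba1c = 53, fpg = 8),
                                            "reduced", red)$status), "T2D")
  # remission requires a medication-free visit even with perfect labs
  expect_equal(as.character(classify_status(list(hba1c = 32, fpg = 5.5),
                                            "reduced", red)$status), "reversal")
  expect_equal(as.character(classify_status(list(hba1c = 32, fpg = 5.5),
                                            "stopped_all", none)$status), "remission")
})

test_that("remission and reversal are mutually exclusive and lab improvement never demotes", {
  none <- ms("month3"); red <- ms("month3", "metformin", 500)
  rank <- c(T2D = 1, reversal = 2, remission = 3)
  set.seed(55)
  for (rep in 1:200) {
    hba1c <- runif(1, 30, 80); fpg <- runif(1, 4, 14)
    rel <- sample(c("stopped_all", "reduced", "equal", "increased"), 1)
    cur <- if (rel == "stopped_all") none else red
    s1 <- rank[[as.character(classify_status(list(hba1c = hba1c, fpg = fpg), rel, cur)$status)]]
    s2 <- rank[[as.character(classify_status(
      list(hba1c = hba1c - runif(1, 0, 10), fpg = max(fpg - runif(1, 0, 4), 0.1)),
      rel, cur)$status)]]
    expect_gte(s2, s1)
  }
})

test_that("cohort adjudication reproduces the packaged pilot status counts", {
  labs <- read_labs_csv(fixture_path("synthetic_pilot_labs.csv"))
  meds <- read_medication_csv(fixture_path("synthetic_pilot_medication.csv"))
  status <- adjudicate_status(labs, meds)
  counts <- status_counts(status)
  expect_equal(unname(counts["T2D", "baseline"]), 15L)
  expect_equal(unname(counts["reversal", "month3"]), 4L)
  expect_equal(unname(counts["remission", "month3"]), 2L)
  expect_equal(unname(counts["reversal", "month6"]), 3L)
  expect_equal(unname(counts["remission", "month6"]), 2L)
  expect_equal(colSums(unclass(counts)), c(baseline = 15, month3 = 15, month6 = 15))
})

test_that("adjudication demands an explicit baseline medication record", {
  labs <- data.frame(participant_id = "X1", visit = "month3",
                     hba1c_mmol_mol = 40, fpg_mmol_l = 6)
  meds <- data.frame(participant_id = "X1", visit = "month3",
                     drug_class = "none", daily_dose = NA, dose_unit = NA)
  expect_error(adjudicate_status(labs, meds), "baseline medication record")
})

test_that("status_counts validates and handles an empty cohort", {
  empty <- data.frame(participant_id = character(), visit = character(),
                      status = character())
  counts <- status_counts(empty)
  expect_true(all(counts == 0))
  dup <- data.frame(participant_id = c("A", "A"), visit = c("month3", "month3"),
                    status = c("T2D", "remission"))
  expect_error(status_counts(dup), "one status call")
})
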
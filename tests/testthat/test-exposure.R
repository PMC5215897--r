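cfg <- test_codesets()

rx_row <- function(code, start, days, ing = 1L)
  data.table::data.table(person_id = "X", drug_code = code,
                         dispense_date = data.table::as.IDate(start),
                         days_supplied = as.integer(days),
                         ingredient_count = as.integer(ing))

win <- lookback_window(as.Date("2010-01-01"))

test_that("average daily drug count reproduces the drug-days formula", {
  none <- rx_row("D001", "2009-01-01", 10)[0]
  expect_equal(average_daily_drug_count(none, win, cfg), 0)

  # one single-ingredient drug covering the full window -> exactly 1
  full <- rx_row("D001", win$start, 730)
  expect_equal(average_daily_drug_count(full, win, cfg), 1)

  # 730d + 365d + 2-ingredient combination for 146d: (730+365+2*146)/730
  rx <- rbind(rx_row("D001", win$start, 730),
              rx_row("D002", win$start, 365),
              rx_row("C001", win$start, 146, ing = 2))
  expect_equal(average_daily_drug_count(rx, win, cfg),
               (730 + 365 + 2 * 146) / 730)
  expect_equal(average_daily_drug_count(rx, win, cfg), 1.9)

  # prescription entirely outside the window contributes nothing
  out <- rbind(full, rx_row("D009", win$start - 400, 100))
  expect_equal(average_daily_drug_count(out, win, cfg), 1)
})

test_that("same-code overlap counts one drug type per day; ingredient expansion only for combos", {
  # two overlapping scripts of one code: a day is covered once
  rx <- rbind(rx_row("D001", win$start, 100),
              rx_row("D001", win$start + 50, 100))
  expect_equal(average_daily_drug_count(rx, win, cfg), 150 / 730)
  # non-combo multi-ingredient product still counts as 1
  rx2 <- rx_row("D002", win$start, 100, ing = 3)
  expect_equal(average_daily_drug_count(rx2, win, cfg), 100 / 730)
  # combo code with ingredient_count 1 behaves like a plain drug
  rx3 <- rx_row("C001", win$start, 100, ing = 1)
  expect_equal(average_daily_drug_count(rx3, win, cfg), 100 / 730)
})

test_that("sweep equals brute-force per-day enumeration on random sets", {
  set.seed(101)
  for (i in 1:60) {
    rx <- random_rx_set(sample(1:12, 1))
    sweep_days <- average_daily_drug_count(rx, win, cfg) * 730
    brute_days <- brute_force_drug_days(rx, win$end, cfg)
    expect_equal(sweep_days, brute_days, tolerance = 1e-12)
  }
})

test_that("average is invariant to splitting a prescription into contiguous pieces", {
  set.seed(7)
  for (i in 1:20) {
    start <- win$start + sample.int(500, 1)
    len <- sample(50:200, 1)
    cut <- sample.int(len - 1, 1)
    whole <- rx_row("D003", start, len)
    split <- rbind(rx_row("D003", start, cut),
                   rx_row("D003", start + cut, len - cut))
    expect_equal(average_daily_drug_count(split, win, cfg),
                 average_daily_drug_count(whole, win, cfg))
  }
})

test_that("polypharmacy categories use inclusive lower bounds", {
  expect_equal(as.character(categorize_polypharmacy(
    c(0, 0.99, 1, 4.999, 5, 9.99, 10, 14))),
    c("lt1", "lt1", "one_to_lt5", "one_to_lt5", "five_to_lt10",
      "five_to_lt10", "ge10", "ge10"))
  expect_error(categorize_polypharmacy(-0.1), "nonnegative")
})

test_that("MPR counts distinct covered days of a class and bins correctly", {
  expect_equal(compute_mpr(rx_row("D001", win$start, 10)[0], "h2ra", win,
                           cfg), 0)
  # one 365-day script -> 50.0, in the 50-100 stratum
  expect_equal(compute_mpr(rx_row("H2R01", win$start, 365), "h2ra", win,
                           cfg), 50)
  expect_equal(as.character(bin_mpr(50)), "ge50_le100")
  # two overlapping 200-day scripts with 100 days overlap -> 300 days
  rx <- rbind(rx_row("ACH01", win$start, 200),
              rx_row("ACH02", win$start + 100, 200))
  expect_equal(compute_mpr(rx, "anticholinergic", win, cfg),
               300 / 730 * 100)
  expect_error(compute_mpr(rx, "statin", win, cfg), "unknown PIM class")

  expect_equal(as.character(bin_mpr(c(0, 0.01, 49.99, 50, 100))),
               c("zero", "gt0_lt50", "gt0_lt50", "ge50_le100",
                 "ge50_le100"))
  expect_equal(pim_any(c(0, 0.01, 100)), c(FALSE, TRUE, TRUE))
  expect_error(bin_mpr(101), "0, 100")
  expect_error(pim_any(-1), "0, 100")
})

test_that("MPR equals the day-set union oracle and is monotone under added scripts", {
  set.seed(202)
  for (i in 1:30) {
    rx <- random_rx_set(sample(2:10, 1))
    for (cl in c("bzd_short_intermediate", "anticholinergic", "h2ra")) {
      expect_equal(compute_mpr(rx, cl, win, cfg),
                   brute_force_mpr(rx, cl, win$end, cfg))
    }
    before <- compute_mpr(rx, "anticholinergic", win, cfg)
    more <- rbind(rx, rx_row("ACH03", win$start + sample.int(600, 1), 50))
    after <- compute_mpr(more, "anticholinergic", win, cfg)
    expect_gte(after, before)
    expect_lte(after, 100)
  }
})

test_that("comorbidity profile flags groups in-window (index inclusive) and sums CCI weights", {
  dx <- function(code, date, setting = "outpatient")
    data.table::data.table(person_id = "X", icd10_code = code,
                           service_date = data.table::as.IDate(date),
                           setting = setting)
  none <- comorbidity_profile(dx("I10", "2009-01-01")[0], win, cfg)
  expect_false(any(none$flags))
  expect_equal(none$cci_score, 0L)

  # uncomplicated diabetes + COPD -> 1 + 1 = 2
  both <- comorbidity_profile(rbind(dx("E119", "2009-05-01"),
                                    dx("J449", "2009-06-01")), win, cfg)
  expect_true(both$flags[["diabetes"]])
  expect_true(both$flags[["copd"]])
  expect_equal(both$cci_score, 2L)

  # a dementia code on the index date itself is visible (day 0 of look-back)
  at_index <- comorbidity_profile(dx("F001", win$index), win, cfg)
  expect_true(at_index$flags[["dementia"]])
  expect_equal(at_index$cci_score, 1L)
  # but a claim one day after the index is not
  after <- comorbidity_profile(dx("F001", win$index + 1), win, cfg)
  expect_false(after$flags[["dementia"]])
})

test_that("derived profiles are internally consistent and match per-person recomputation", {
  sim <- simulate_from_table1_defaults(800, seed = 31)
  cases <- identify_incident_cases(sim$persons, sim$diagnoses, sim$codesets)
  pairs <- suppressMessages(select_controls(
    cases, sim$persons, sim$diagnoses, sim$codesets, seed = 32))
  skip_if(nrow(pairs) < 10)
  subj <- pairs_to_subjects(pairs)
  ex <- derive_exposures(subj, sim$prescriptions, sim$diagnoses,
                         sim$codesets)
  expect_equal(as.character(ex$polypharmacy_category),
               as.character(categorize_polypharmacy(ex$avg_daily_drugs)))
  expect_equal(ex$polypharmacy_flag, ex$avg_daily_drugs >= 5)
  mprs <- as.matrix(ex[, .SD, .SDcols = paste0("mpr_", sim$codesets$pim_classes)])
  expect_true(all(mprs >= 0 & mprs <= 100))
  # CCI equals the weighted flag sum recomputed from the weight table
  w <- sim$codesets$cci_weights
  recomputed <- as.integer(as.matrix(
    ex[, .SD, .SDcols = paste0("com_", names(w))]) %*% w)
  expect_equal(ex$cci_score, recomputed)
  # spot-check the single-person operations against the batch derivation
  set.seed(33)
  for (i in sample.int(nrow(ex), 5)) {
    wini <- lookback_window(ex$index_date[i])
    rxi <- sim$prescriptions[person_id == ex$person_id[i]]
    expect_equal(ex$avg_daily_drugs[i],
                 average_daily_drug_count(rxi, wini, sim$codesets))
    dxi <- sim$diagnoses[person_id == ex$person_id[i]]
    prof <- comorbidity_profile(dxi, wini, sim$codesets)
    expect_equal(ex$cci_score[i], prof$cci_score)
  }
})

test_that("setting every ingredient count to 1 reduces combos to distinct-code counting", {
  set.seed(44)
  for (i in 1:10) {
    rx <- random_rx_set(sample(3:10, 1))
    rx1 <- data.table::copy(rx)[, ingredient_count := 1L]
    plain_cfg <- cfg
    plain_cfg$combo_codes <- character()
    expect_equal(average_daily_drug_count(rx1, win, cfg),
                 average_daily_drug_count(rx, win, plain_cfg))
  }
})
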
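test_that("HOMA-IR matches the hand-evaluated closed form", {
  # 60 pmol/L / 6.945 = 8.6393 uU/mL; 5.0 * 8.6393 / 22.5
  expect_equal(homa_ir(5.0, 60), 5.0 * (60 / 6.945) / 22.5,
               tolerance = 1e-12)
  expect_equal(homa_ir(5.0, 60), 1.9199, tolerance = 1e-4)
  # conversion factor is configurable
  expect_equal(homa_ir(5.0, 60, insulin_conversion = 6),
               5 * 10 / 22.5, tolerance = 1e-12)
  # limit and degenerate inputs
  expect_lt(homa_ir(5.0, 1e-6), 1e-6)
  expect_true(is.na(homa_ir(5.0, -1)))
  expect_true(is.na(homa_ir(0, 60)))
  expect_true(is.na(homa_ir(NA, 60)))
})

test_that("eGFR matches the hand-evaluated CKD-EPI form and is monotone", {
  # female, 50 y, 70 umol/L = 0.7919 mg/dL; Scr/k > 1 branch
  byhand <- 141 * (70 / 88.4 / 0.7)^(-1.209) * 0.993^50 * 1.018
  expect_equal(egfr(70, 50, "F"), byhand, tolerance = 1e-12)
  expect_equal(egfr(70, 50, "F"), 87.0, tolerance = 0.01)
  expect_lt(egfr(70, 50, "F"), 90)  # flagged low at the <90 cutoff
  expect_lt(egfr(140, 50, "F"), egfr(70, 50, "F"))
  # male branch uses k = 0.9, alpha = -0.411, no 1.018
  byhand_m <- 141 * (60 / 88.4 / 0.9)^(-0.411) * 0.993^40
  expect_equal(egfr(60, 40, "M"), byhand_m, tolerance = 1e-12)
  expect_true(is.na(egfr(-5, 50, "F")))
})

test_that("threshold rules reproduce the cut-off table semantics", {
  co <- toy_cohort(1, sex = "M")
  co$waist <- 91
  st <- assess_states(co)
  expect_true(st$overweight[1])
  expect_equal(names(st), state_names())
  expect_equal(ncol(st), 12)

  # a female at 91 cm is also overweight (cutoff 80), a male at 85 is not
  co2 <- toy_cohort(2, sex = c("M", "F"))
  co2$waist <- c(85, 85)
  st2 <- assess_states(co2)
  expect_false(st2$overweight[1])
  expect_true(st2$overweight[2])
})

test_that("values exactly at a cutoff do not trigger above-type states", {
  co <- toy_cohort(1, sex = "M")
  co$glucose <- 5.55
  co$hba1c <- 6.5
  co$triglycerides <- 1.7
  co$uric_acid <- 405
  co$urea <- 7.5
  co$waist <- 90
  co$temperature <- 37
  co$systolic <- 120
  co$diastolic <- 80
  st <- assess_states(co)
  above <- c("hyperglycemia", "high_hba1c", "hypertriglyceridemia",
             "hyperuricemia", "azotemia", "overweight",
             "high_temperature", "high_blood_pressure")
  for (s in above) expect_false(st[[s]][1], label = s)
})

test_that("high blood pressure is an either-reading rule", {
  co <- toy_cohort(3)
  co$systolic <- c(125, 110, 110)
  co$diastolic <- c(70, 85, 75)
  st <- assess_states(co)
  expect_equal(st$high_blood_pressure, c(TRUE, TRUE, FALSE))
  co$diastolic[1] <- NA
  st <- assess_states(co)
  expect_true(is.na(st$high_blood_pressure[1]))
})

test_that("state prevalence counts by construction", {
  co <- toy_cohort(100)
  co$triglycerides <- c(rep(2.5, 13), rep(1.0, 87))
  st <- assess_states(co)
  expect_equal(mean(st$hypertriglyceridemia), 0.13)
})

test_that("missing inputs propagate to missing states only", {
  co <- toy_cohort(2)
  co$insulin[1] <- NA
  st <- assess_states(co)
  expect_true(is.na(st$insulin_resistance[1]))
  expect_false(is.na(st$insulin_resistance[2]))
  expect_false(anyNA(st$overweight))
})

test_that("above-type states are monotone in their biomarker", {
  set.seed(42)
  for (rep in 1:20) {
    co <- toy_cohort(1, sex = sample(c("M", "F"), 1))
    co$triglycerides <- runif(1, 0.5, 3)
    st1 <- assess_states(co)$hypertriglyceridemia
    co$triglycerides <- co$triglycerides + runif(1, 0, 2)
    st2 <- assess_states(co)$hypertriglyceridemia
    expect_false(st1 && !st2)
    # below-type states symmetrically: raising HDL cannot create low_hdl
    co$hdl <- runif(1, 0.5, 2)
    lo1 <- assess_states(co)$low_hdl
    co$hdl <- co$hdl + runif(1, 0, 1)
    lo2 <- assess_states(co)$low_hdl
    expect_false(!lo1 && lo2)
  }
})

test_that("the harmonized MetS flag needs at least 3 of 5 criteria", {
  co <- toy_cohort(3, sex = "M")
  expect_false(mets_harmonized(co)[1])  # healthy defaults: zero criteria
  # exactly 3: waist, triglycerides, glucose (boundary >= semantics)
  co$waist[2] <- 91
  co$triglycerides[2] <- 1.7
  co$glucose[2] <- 5.55
  # exactly 2 on participant 3
  co$waist[3] <- 91
  co$triglycerides[3] <- 1.7
  flags <- mets_harmonized(co)
  expect_true(flags[2])
  expect_false(flags[3])
  co$hdl[3] <- NA
  expect_true(is.na(mets_harmonized(co)[3]))
})

test_that("MetS prevalence is invariant to participant order", {
  co <- clean_cohort(generate_cohort(default_study_spec(), seed = 9))$cohort
  f <- mets_harmonized(co)
  perm <- sample(nrow(co))
  f2 <- mets_harmonized(co[perm, ])
  expect_equal(mean(f2, na.rm = TRUE), mean(f, na.rm = TRUE))
})

test_that("trend statistics recover exact linear and null cases", {
  n <- 300
  co <- toy_cohort(n, age = rep(c(20, 30, 40, 50, 60, 70), each = 50))
  co$weight <- 2 * co$age
  st <- assess_states(co)
  tr <- trend_statistics(co, st)
  w <- tr$variables[tr$variables$variable == "weight", ]
  expect_equal(w$slope, 2.0, tolerance = 1e-10)
  expect_lt(w$slope_p, 1e-10)
  # constant variable: slope 0, p 1
  g <- tr$variables[tr$variables$variable == "glucose", ]
  expect_equal(g$slope, 0)
  expect_equal(g$slope_p, 1)
  # equal prevalence in every stratum: no trend
  co$triglycerides <- rep(c(2.5, 1.0), n / 2)  # 50% everywhere
  st <- assess_states(co)
  tr <- trend_statistics(co, st)
  row <- tr$states[tr$states$state == "hypertriglyceridemia", ]
  expect_lt(row$chi2_trend, 1e-10)
  expect_equal(unname(unlist(row[names(stratify_by_age(co))])),
               rep(0.5, 6))
})

test_that("the two-stratum trend test reduces to the 2x2 chi-square", {
  co <- toy_cohort(200, age = rep(c(25, 60), each = 100))
  co$triglycerides <- c(rep(2.5, 20), rep(1, 80), rep(2.5, 45), rep(1, 55))
  st <- assess_states(co)
  tr <- trend_statistics(co, st, boundaries = c(18, 40))
  tab <- rbind(c(20, 80), c(45, 55))
  oracle <- unname(stats::chisq.test(tab, correct = FALSE)$statistic)
  row <- tr$states[tr$states$state == "hypertriglyceridemia", ]
  expect_equal(row$chi2_trend, oracle, tolerance = 1e-10)
})

test_that("independent states co-occur at the product of prevalences", {
  dep <- diag(1, 15, 15)
  dimnames(dep) <- list(catalog_variables(), catalog_variables())
  vars <- catalog_variables()
  marg <- data.frame(variable = vars, stratum = "<25",
                     mean = c(5, 5.5, 55, 1.2, 3, 1.5, 320, 5, 72, 88, 68,
                              162, 36.9, 113, 74),
                     sd = c(1.5, 1, 48, 0.3, 1, 1, 87, 1, 15, 12, 15, 9,
                            0.5, 14, 10),
                     family = "normal", stringsAsFactors = FALSE)
  spec <- cohort_spec(
    data.frame(label = "<25", n = 20000L, age_min = 18L, age_max = 24L),
    marg, dep)
  co <- generate_cohort(spec, seed = 13)
  st <- assess_states(co)
  # sex-free states only: sex-specific cutoffs couple states through the
  # shared sex covariate even when all biomarkers are independent
  use <- c("hyperglycemia", "hypertriglyceridemia", "high_ldl",
           "hyperuricemia")
  n <- nrow(st)
  for (i in 1:(length(use) - 1)) {
    for (j in (i + 1):length(use)) {
      a <- st[[use[i]]]
      b <- st[[use[j]]]
      p_joint <- mean(a & b)
      p_prod <- mean(a) * mean(b)
      se <- sqrt(p_prod * (1 - p_prod) / n)
      expect_lt(abs(p_joint - p_prod), 3 * se + 1e-9)
    }
  }
})

test_that("threshold rules survive a YAML round trip", {
  rules <- threshold_rules()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_threshold_rules(rules, path)
  back <- read_threshold_rules(path)
  expect_equal(length(back), 12)
  co <- toy_cohort(3, sex = "F")
  co$waist <- c(75, 85, 95)
  expect_equal(assess_states(co, rules = back), assess_states(co))
})
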
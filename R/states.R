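#' Homeostasis Model Assessment insulin-resistance index (HOMA-IR)
#'
#' `HOMA-IR = glucose[mmol/L] * insulin[uU/mL] / 22.5`, with basal insulin
#' converted from pmol/L to uU/mL by a configurable divisor (default 6.945;
#' laboratory conventions range 6.0--6.945).
#'
#' @param glucose fasting glucose, mmol/L.
#' @param insulin basal insulin, pmol/L.
#' @param insulin_conversion pmol/L per uU/mL, default 6.945.
#' @return Numeric vector; non-positive or missing inputs yield `NA`.
#' @examples
#' homa_ir(5.0, 60) # 1.92
#' @export
homa_ir <- function(glucose, insulin, insulin_conversion = 6.945) {
  out <- glucose * (insulin / insulin_conversion) / 22.5
  out[!is.na(glucose) & glucose <= 0] <- NA_real_
  out[!is.na(insulin) & insulin <= 0] <- NA_real_
  out
}

#' Estimated glomerular filtration rate (CKD-EPI 2009 creatinine equation)
#'
#' Serum creatinine in umol/L is converted to mg/dL (divide by 88.4) and the
#' CKD-EPI 2009 equation applied:
#' `141 * min(Scr/k, 1)^a * max(Scr/k, 1)^-1.209 * 0.993^age * 1.018[if F]`
#' with `k = 0.7` (F) / `0.9` (M) and `a = -0.329` (F) / `-0.411` (M). The
#' race coefficient is omitted by default, following current guidance; set
#' `race_coefficient = 1.159` to include the historical term.
#'
#' @param creatinine serum creatinine, umol/L.
#' @param age age in years (>= 18).
#' @param sex `"M"` or `"F"` (vector recycled as needed).
#' @param race_coefficient optional multiplicative coefficient, default 1.
#' @return eGFR in mL/min/1.73 m^2; non-positive creatinine yields `NA`.
#' @examples
#' egfr(70, 50, "F") # about 87
#' @export
egfr <- function(creatinine, age, sex, race_coefficient = 1) {
  sex <- as.character(sex)
  scr <- creatinine / 88.4
  female <- sex == "F"
  k <- ifelse(female, 0.7, 0.9)
  a <- ifelse(female, -0.329, -0.411)
  out <- 141 * pmin(scr / k, 1)^a * pmax(scr / k, 1)^(-1.209) *
    0.993^age * ifelse(female, 1.018, 1) * race_coefficient
  out[!is.na(creatinine) & creatinine <= 0] <- NA_real_
  out
}

#' The 12 pathological-state threshold rules
#'
#' Risk-oriented cut-offs distinguishing normal from abnormal biomarker
#' values; states are indicators of increased risk, not diagnoses. Three
#' rules are derived: insulin resistance thresholds HOMA-IR, low eGFR
#' thresholds the CKD-EPI estimate (hence depends on age and sex), and high
#' blood pressure is true when either the systolic or the diastolic reading
#' exceeds its cut-off. All plain comparisons are strict.
#'
#' @param insulin_conversion passed to [homa_ir()].
#' @param race_coefficient passed to [egfr()].
#' @return A list of 12 rules (state, inputs, direction, cutoff, derived),
#'   in canonical state order.
#' @export
threshold_rules <- function(insulin_conversion = 6.945,
                            race_coefficient = 1) {
  rule <- function(state, inputs, direction, cutoff, derived = NA_character_)
    list(state = state, inputs = inputs, direction = direction,
         cutoff = cutoff, derived = derived)
  list(
    rule("hyperglycemia", "glucose", "above", 5.55),
    rule("high_hba1c", "hba1c", "above", 6.5),
    rule("insulin_resistance", c("glucose", "insulin"), "above",
         c(M = 1.7, F = 1.8), derived = "homa_ir"),
    rule("low_hdl", "hdl", "below", c(M = 1.03, F = 1.3)),
    rule("high_ldl", "ldl", "above", 3),
    rule("hypertriglyceridemia", "triglycerides", "above", 1.7),
    rule("hyperuricemia", "uric_acid", "above", 405),
    rule("azotemia", "urea", "above", 7.5),
    rule("low_egfr", "creatinine", "below", 90, derived = "egfr"),
    rule("overweight", "waist", "above", c(M = 90, F = 80)),
    rule("high_temperature", "temperature", "above", 37),
    rule("high_blood_pressure", c("systolic", "diastolic"), "above",
         c(systolic = 120, diastolic = 80), derived = "bp_either")
  )
}

#' Canonical pathological state names
#'
#' @return Character vector of the 12 state names in canonical order.
#' @export
state_names <- function() vapply(threshold_rules(), `[[`, "", "state")

#' Write or read threshold rules as YAML
#'
#' @param rules list of rules as produced by [threshold_rules()].
#' @param path YAML file path.
#' @export
write_threshold_rules <- function(rules, path) {
  yaml::write_yaml(lapply(rules, function(r) {
    r$cutoff <- as.list(r$cutoff)
    if (is.na(r$derived)) r$derived <- NULL
    r
  }), path)
  invisible(path)
}

#' @rdname write_threshold_rules
#' @export
read_threshold_rules <- function(path) {
  lapply(yaml::read_yaml(path), function(r) {
    co <- unlist(r$cutoff)
    r$cutoff <- if (is.null(names(co)) || all(names(co) == "")) unname(co)[1]
                else co
    r$inputs <- unlist(r$inputs)
    if (is.null(r$derived)) r$derived <- NA_character_
    r
  })
}

# evaluate one rule on a cohort; returns logical with NA where inputs missing
.apply_rule <- function(rule, cohort, insulin_conversion, race_coefficient) {
  sex <- as.character(cohort$sex)
  if (identical(rule$derived, "homa_ir")) {
    val <- homa_ir(cohort$glucose, cohort$insulin, insulin_conversion)
    cut <- unname(rule$cutoff[sex])
    return(val > cut)
  }
  if (identical(rule$derived, "egfr")) {
    val <- egfr(cohort$creatinine, cohort$age, sex, race_coefficient)
    return(val < rule$cutoff)
  }
  val <- cohort[[rule$inputs]]
  cut <- if (length(rule$cutoff) > 1) unname(rule$cutoff[sex]) else rule$cutoff
  if (rule$direction == "above") val > cut else val < cut
}

#' Derive the binary pathological-state matrix
#'
#' Applies the 12 threshold rules to a (cleaned) cohort. A state is
#' non-missing only when every input biomarker it needs is present; the
#' column order is the canonical state order.
#'
#' @param cohort cohort data frame.
#' @param rules rule list, default [threshold_rules()].
#' @param insulin_conversion passed to [homa_ir()].
#' @param race_coefficient passed to [egfr()].
#' @return Data frame of 12 logical columns (with `NA`s), one row per
#'   participant, plus rownames from `participant_id`.
#' @export
assess_states <- function(cohort, rules = threshold_rules(),
                          insulin_conversion = 6.945,
                          race_coefficient = 1) {
  validate_cohort(cohort)
  vars <- catalog_variables()
  out <- data.frame(row.names = make.unique(cohort$participant_id))
  for (r in rules) {
    unknown <- setdiff(r$inputs, vars)
    if (length(unknown) > 0)
      stop("rule ", r$state, " references unknown variable(s): ",
           paste(unknown, collapse = ", "))
    if (identical(r$derived, "bp_either")) {
      s <- cohort$systolic > r$cutoff[["systolic"]]
      d <- cohort$diastolic > r$cutoff[["diastolic"]]
      v <- s | d
      v[is.na(s) | is.na(d)] <- NA
    } else {
      v <- .apply_rule(r, cohort, insulin_conversion, race_coefficient)
      miss <- Reduce(`|`, lapply(r$inputs, function(x) is.na(cohort[[x]])))
      v[miss] <- NA
    }
    out[[r$state]] <- v
  }
  out
}

#' Harmonized metabolic syndrome flag
#'
#' True when at least 3 of the 5 harmonized criteria are met:
#' elevated waist circumference (M > 90 cm / F > 80 cm), triglycerides >=
#' 1.7 mmol/L, reduced HDL (< 1.03 M / < 1.3 F mmol/L), elevated blood
#' pressure (systolic >= 130 or diastolic >= 85 mmHg) and fasting glucose
#' >= 5.55 mmol/L. Biomarker-only: medication-based criteria are not
#' modeled. Any missing criterion input yields a missing flag.
#'
#' Note the deliberate coexistence of two blood-pressure thresholds: the
#' pathological *state* uses the risk-screening 120/80 cut-off, while the
#' syndrome criterion uses the harmonized 130/85.
#'
#' @param cohort cohort data frame.
#' @return Logical vector with `NA`s.
#' @export
mets_harmonized <- function(cohort) {
  validate_cohort(cohort)
  sex <- as.character(cohort$sex)
  crit <- cbind(
    cohort$waist > ifelse(sex == "M", 90, 80),
    cohort$triglycerides >= 1.7,
    cohort$hdl < ifelse(sex == "M", 1.03, 1.3),
    cohort$systolic >= 130 | cohort$diastolic >= 85,
    cohort$glucose >= 5.55
  )
  # blood pressure: either reading missing makes the criterion missing
  bp_na <- is.na(cohort$systolic) | is.na(cohort$diastolic)
  crit[bp_na, 4] <- NA
  out <- rowSums(crit) >= 3
  out[apply(crit, 1, anyNA)] <- NA
  out
}

#' Age-trend statistics for variables and state prevalences
#'
#' For each physiological variable, the ordinary least-squares slope of the
#' value on continuous age (units per year) with its two-sided test. For
#' each pathological state, the Cochran--Armitage chi-square test for trend
#' in prevalence across the ordered age strata, using stratum midpoint ages
#' as scores (the open top stratum is scored at its lower bound plus half
#' the preceding stratum's width).
#'
#' @param cohort cohort data frame.
#' @param states state matrix from [assess_states()].
#' @param boundaries age stratum boundaries, see [stratify_by_age()].
#' @return List with `variables` (data frame: variable, slope, slope_p) and
#'   `states` (data frame: state, chi2_trend, trend_p, plus one prevalence
#'   column per stratum).
#' @export
trend_statistics <- function(cohort, states = assess_states(cohort),
                             boundaries = c(18, 25, 35, 45, 55, 65)) {
  validate_cohort(cohort)
  vars <- catalog_variables()
  slope <- slope_p <- numeric(length(vars))
  for (i in seq_along(vars)) {
    y <- cohort[[vars[i]]]
    ok <- !is.na(y)
    if (sum(ok) < 3 || stats::sd(y[ok]) == 0) {
      slope[i] <- 0
      slope_p[i] <- 1
      next
    }
    fit <- stats::lm(y ~ age, data = data.frame(y = y, age = cohort$age))
    # noise-free linear relations trigger a harmless perfect-fit warning
    cf <- suppressWarnings(summary(fit))$coefficients
    slope[i] <- cf["age", "Estimate"]
    slope_p[i] <- cf["age", "Pr(>|t|)"]
  }
  variables <- data.frame(variable = vars, slope = slope, slope_p = slope_p,
                          stringsAsFactors = FALSE)

  strata <- stratify_by_age(cohort, boundaries)
  if (sum(vapply(strata, nrow, 0L) > 0) < 2)
    stop("trend statistics need at least 2 non-empty strata")
  k <- length(boundaries)
  widths <- diff(boundaries)
  scores <- c((boundaries[-k] + boundaries[-1]) / 2,
              boundaries[k] + widths[k - 1] / 2)
  labels <- names(strata)
  idx <- cut(cohort$age, breaks = c(boundaries, Inf), right = FALSE,
             labels = FALSE)
  st_out <- lapply(names(states), function(s) {
    x <- states[[s]]
    succ <- tot <- integer(length(labels))
    for (g in seq_along(labels)) {
      in_g <- idx == g & !is.na(x)
      tot[g] <- sum(in_g)
      succ[g] <- sum(x[in_g])
    }
    keep <- tot > 0
    prev <- ifelse(tot > 0, succ / tot, NA_real_)
    chi2 <- p <- NA_real_
    if (sum(keep) >= 2 && sum(succ) > 0 && sum(succ) < sum(tot)) {
      tt <- suppressWarnings(
        stats::prop.trend.test(succ[keep], tot[keep], score = scores[keep]))
      chi2 <- unname(tt$statistic)
      p <- tt$p.value
    } else if (sum(keep) >= 2) {
      chi2 <- 0
      p <- 1
    }
    c(chi2_trend = chi2, trend_p = p, stats::setNames(prev, labels))
  })
  states_df <- data.frame(state = names(states),
                          do.call(rbind, st_out),
                          check.names = FALSE, stringsAsFactors = FALSE)
  rownames(states_df) <- NULL
  list(variables = variables, states = states_df)
}
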
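#' Catalog of the 15 physiological variables
#'
#' The analysis operates on a fixed panel of 15 non-derivative, continuous
#' physiological variables spanning fasting blood chemistry, anthropometry
#' and vital signs. The catalog records, for each variable, its measurement
#' unit, a permissive plausibility range used by [clean_cohort()] to mask
#' values incompatible with life, and a coarse kind (blood, anthropometric,
#' vital).
#'
#' The plausibility ranges are deliberately wide: cleaning is meant to remove
#' recording errors (a 450 mmHg systolic pressure, a 45 degree axillary
#' temperature), not to trim genuine extreme physiology. Ranges can be
#' overridden by passing a modified catalog to [clean_cohort()].
#'
#' @param ranges optional named list of `c(min, max)` pairs overriding the
#'   default plausibility range of specific variables.
#' @return A data frame with columns `name`, `unit`, `plausible_min`,
#'   `plausible_max` and `kind`, one row per variable, in canonical order.
#' @examples
#' variable_catalog()
#' variable_catalog(ranges = list(glucose = c(2, 30)))
#' @export
variable_catalog <- function(ranges = NULL) {
  cat <- data.frame(
    name = c(
      "glucose", "hba1c", "insulin", "hdl", "ldl", "triglycerides",
      "uric_acid", "urea", "creatinine", "waist", "weight", "height",
      "temperature", "systolic", "diastolic"
    ),
    unit = c(
      "mmol/L", "%", "pmol/L", "mmol/L", "mmol/L", "mmol/L",
      "umol/L", "mmol/L", "umol/L", "cm", "kg", "cm",
      "degC", "mmHg", "mmHg"
    ),
    plausible_min = c(1, 2, 1, 0.2, 0.2, 0.1, 50, 0.5, 20, 40, 25, 120,
                      30, 60, 30),
    plausible_max = c(40, 20, 3000, 5, 15, 30, 1200, 60, 2000, 200, 250, 220,
                      43, 260, 160),
    kind = c(
      "blood", "blood", "blood", "blood", "blood", "blood",
      "blood", "blood", "blood", "anthropometric", "anthropometric",
      "anthropometric", "vital", "vital", "vital"
    ),
    stringsAsFactors = FALSE
  )
  if (!is.null(ranges)) {
    stopifnot(is.list(ranges), !is.null(names(ranges)))
    for (nm in names(ranges)) {
      i <- match(nm, cat$name)
      if (is.na(i)) stop("unknown variable in ranges: ", nm)
      rr <- ranges[[nm]]
      if (length(rr) != 2 || !is.numeric(rr) || rr[1] >= rr[2])
        stop("range for ", nm, " must be numeric c(min, max) with min < max")
      cat$plausible_min[i] <- rr[1]
      cat$plausible_max[i] <- rr[2]
    }
  }
  cat
}

#' Canonical variable names
#'
#' @param catalog a variable catalog, see [variable_catalog()].
#' @return Character vector of the 15 variable names in canonical order.
#' @export
catalog_variables <- function(catalog = variable_catalog()) catalog$name

# demographic columns every cohort table carries
.demographic_cols <- c("participant_id", "age", "sex")
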
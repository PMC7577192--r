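#' Read a participant biomarker table
#'
#' Reads a delimited participant-level table into a validated cohort data
#' frame. The file must carry a header row with `age`, `sex` and the 15
#' physiological variables of the catalog; a `participant_id` column is used
#' if present and generated otherwise. Any other column is rejected so that
#' unit mismatches surface as hard errors instead of silently feeding the
#' analysis (e.g. a `glucose_mgdl` column is an error, not an extra).
#'
#' Non-numeric cells in variable columns become missing values; rows are
#' never dropped at this stage.
#'
#' @param path path to a delimited text file (UTF-8, header row).
#' @param catalog variable catalog, see [variable_catalog()].
#' @param sep field separator, default comma.
#' @return A cohort data frame with columns `participant_id` (character),
#'   `age` (integer), `sex` (factor M/F) and the 15 variable columns
#'   (numeric), in catalog order.
#' @export
read_cohort <- function(path, catalog = variable_catalog(), sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  if (nrow(raw) == 0 && ncol(raw) == 0) stop("empty file: ", path)
  vars <- catalog$name
  required <- c("age", "sex", vars)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), c(.demographic_cols, vars))
  if (length(extra) > 0)
    stop("column(s) not in the variable catalog: ",
         paste(extra, collapse = ", "))
  if (nrow(raw) == 0) stop("file has a header but no records: ", path)

  id <- if ("participant_id" %in% names(raw)) as.character(raw$participant_id)
        else sprintf("P%05d", seq_len(nrow(raw)))
  age <- suppressWarnings(as.integer(round(as.numeric(raw$age))))
  if (anyNA(age)) stop("non-numeric or missing age values")
  if (any(age < 18 | age > 120))
    stop("ages outside [18, 120]; adult cohorts only")
  sex <- toupper(trimws(raw$sex))
  if (!all(sex %in% c("M", "F"))) stop("sex must be coded M or F")

  out <- data.frame(participant_id = id, age = age,
                    sex = factor(sex, levels = c("M", "F")),
                    stringsAsFactors = FALSE)
  for (v in vars) out[[v]] <- suppressWarnings(as.numeric(raw[[v]]))
  validate_cohort(out, catalog)
  out
}

#' Write a cohort table as CSV
#'
#' Inverse of [read_cohort()]: numeric cells survive a round trip to at
#' least 10 significant digits, missing values are written as empty cells.
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(format(cohort, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Validate the structural invariants of a cohort table
#'
#' @param cohort candidate cohort data frame.
#' @param catalog variable catalog.
#' @return `cohort`, invisibly; errors describe the first violated invariant.
#' @export
validate_cohort <- function(cohort, catalog = variable_catalog()) {
  stopifnot(is.data.frame(cohort))
  need <- c(.demographic_cols, catalog$name)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0)
    stop("cohort lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyNA(cohort$age) || anyNA(cohort$sex) || anyNA(cohort$participant_id))
    stop("demographic fields (participant_id, age, sex) must be complete")
  if (any(cohort$age < 18 | cohort$age > 120))
    stop("ages outside [18, 120]")
  if (!all(as.character(cohort$sex) %in% c("M", "F")))
    stop("sex must be coded M or F")
  invisible(cohort)
}

#' Mask implausible and inconsistent biomarker values
#'
#' Cell-level cleaning: values outside the catalog's plausibility range are
#' masked (set missing) with reason `"implausible"`, and waist measurements
#' whose waist/height ratio falls outside a plausibility band are masked with
#' reason `"inconsistent"` (an implausibly large waist on a short, light
#' frame is a recording error, not physiology). Participants are never
#' dropped: the exclusion unit is the individual cell.
#'
#' Cleaning is idempotent: applied to its own output it masks nothing.
#'
#' @param cohort cohort data frame from [read_cohort()] or
#'   [generate_cohort()].
#' @param catalog variable catalog carrying the plausibility ranges.
#' @param waist_height_ratio numeric `c(min, max)` band of plausible
#'   waist/height ratios; default `c(0.25, 1.10)`.
#' @param verbose if `TRUE`, log every masked cell (participant, variable,
#'   value, reason) as a message.
#' @return A list with elements `cohort` (the masked table) and `report`, a
#'   list with `masked_cells` (data frame: participant_id, variable, value,
#'   reason) and `counts_by_variable` (named integer vector).
#' @export
clean_cohort <- function(cohort, catalog = variable_catalog(),
                         waist_height_ratio = c(0.25, 1.10),
                         verbose = FALSE) {
  validate_cohort(cohort, catalog)
  masked <- data.frame(participant_id = character(), variable = character(),
                       value = numeric(), reason = character(),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(catalog))) {
    v <- catalog$name[i]
    x <- cohort[[v]]
    bad <- which(!is.na(x) &
                   (x < catalog$plausible_min[i] | x > catalog$plausible_max[i]))
    if (length(bad) > 0) {
      masked <- rbind(masked, data.frame(
        participant_id = cohort$participant_id[bad], variable = v,
        value = x[bad], reason = "implausible", stringsAsFactors = FALSE))
      cohort[[v]][bad] <- NA_real_
    }
  }
  # cross-field anthropometric consistency, applied after range masking so
  # that a ratio driven by an already-implausible height is not double-counted
  ratio <- cohort$waist / cohort$height
  bad <- which(!is.na(ratio) &
                 (ratio < waist_height_ratio[1] | ratio > waist_height_ratio[2]))
  if (length(bad) > 0) {
    masked <- rbind(masked, data.frame(
      participant_id = cohort$participant_id[bad], variable = "waist",
      value = cohort$waist[bad], reason = "inconsistent",
      stringsAsFactors = FALSE))
    cohort$waist[bad] <- NA_real_
  }
  if (verbose && nrow(masked) > 0)
    for (j in seq_len(nrow(masked)))
      message(sprintf("masked %s[%s] = %g (%s)", masked$variable[j],
                      masked$participant_id[j], masked$value[j],
                      masked$reason[j]))
  counts <- table(factor(masked$variable, levels = catalog$name))
  list(cohort = cohort,
       report = list(masked_cells = masked,
                     counts_by_variable = stats::setNames(as.integer(counts),
                                                          catalog$name)))
}

#' Labels for age strata
#'
#' @param boundaries strictly increasing lower bounds of the age strata,
#'   first entry being the minimum modeled age. The last stratum is open
#'   above.
#' @return Character vector of labels, e.g. `"<25"`, `"25-34"`, ..., `"65+"`.
#' @export
age_stratum_labels <- function(boundaries = c(18, 25, 35, 45, 55, 65)) {
  k <- length(boundaries)
  if (k < 2 || any(diff(boundaries) <= 0))
    stop("boundaries must be strictly increasing with at least 2 entries")
  c(paste0("<", boundaries[2]),
    if (k > 2) paste0(boundaries[2:(k - 1)], "-", boundaries[3:k] - 1),
    paste0(boundaries[k], "+"))
}

#' Assign participants to age strata
#'
#' Strata follow the `[lower, upper)` convention: a participant aged exactly
#' at a boundary belongs to the stratum that starts there. The default
#' boundaries reproduce the six groups used throughout the analysis:
#' under 25, four ten-year decades, and an open 65-and-over group.
#'
#' @inheritParams age_stratum_labels
#' @param cohort cohort data frame.
#' @return A named list of cohort subsets (one per stratum, possibly empty),
#'   each carrying attributes `lower` and `upper` (`Inf` for the open top
#'   stratum). Strata partition the cohort.
#' @export
stratify_by_age <- function(cohort, boundaries = c(18, 25, 35, 45, 55, 65)) {
  labels <- age_stratum_labels(boundaries)
  if (any(cohort$age < boundaries[1]))
    stop("participants younger than ", boundaries[1],
         " are not modeled; raise the first boundary or filter the cohort")
  f <- cut(cohort$age, breaks = c(boundaries, Inf), right = FALSE,
           labels = labels)
  upper <- c(boundaries[-1], Inf)
  out <- lapply(seq_along(labels), function(i) {
    s <- cohort[!is.na(f) & f == labels[i], , drop = FALSE]
    rownames(s) <- NULL
    attr(s, "lower") <- boundaries[i]
    attr(s, "upper") <- upper[i]
    s
  })
  names(out) <- labels
  out
}
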
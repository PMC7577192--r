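#' Convert a Spearman correlation to the latent Pearson correlation
#'
#' Under a Gaussian copula the Spearman rank correlation of two continuous
#' margins relates to the latent normal Pearson correlation by
#' `r = 2 sin(pi * rho_s / 6)`. Sampling the latent normal at this Pearson
#' correlation therefore reproduces the target Spearman correlation exactly,
#' whatever the (continuous) marginals.
#'
#' @param rho Spearman correlation(s) in `[-1, 1]` (scalar or matrix).
#' @return Latent Pearson correlation(s), same shape.
#' @export
spearman_to_pearson <- function(rho) 2 * sin(pi * rho / 6)

#' Repair a nearly positive semi-definite correlation matrix
#'
#' The elementwise `2 sin(pi rho/6)` transform can nudge a valid Spearman
#' target slightly outside the PSD cone. Eigenvalues below `eps` are clipped
#' to `eps` and the result is rescaled back to unit diagonal. Matrices whose
#' smallest eigenvalue is below `-repair_tol` are considered genuinely
#' invalid and rejected.
#'
#' @param m symmetric matrix with unit diagonal.
#' @param eps eigenvalue floor, default `1e-8`.
#' @param repair_tol most negative eigenvalue deemed repairable, default 0.01.
#' @return A positive definite correlation matrix.
#' @export
nearest_psd <- function(m, eps = 1e-8, repair_tol = 1e-2) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (max(abs(m - t(m))) > 1e-12) stop("matrix must be symmetric")
  e <- eigen(m, symmetric = TRUE)
  lam <- e$values
  if (min(lam) < -repair_tol)
    stop(sprintf(
      "matrix is not repairably PSD: smallest eigenvalue %.6g", min(lam)))
  if (min(lam) >= eps) return(m)
  lam <- pmax(lam, eps)
  out <- e$vectors %*% (lam * t(e$vectors))
  d <- sqrt(diag(out))
  out <- out / outer(d, d)
  diag(out) <- 1
  dimnames(out) <- dimnames(m)
  out
}

#' Default target Spearman dependence among the 15 variables
#'
#' A documented fixture, not an empirical claim: moderate positive blocks
#' among adiposity (waist, weight, height), glycemic (glucose, HbA1c,
#' insulin), lipid (HDL, LDL, triglycerides), renal (uric acid, urea,
#' creatinine) and pressure (systolic, diastolic) variables, with weaker
#' positive cross-block links through adiposity and insulin, and HDL
#' anti-correlated with triglycerides. Axillary temperature is left
#' independent. The block values are strong enough that threshold-derived
#' pathological states co-occur above chance at the default sample sizes.
#'
#' @return A symmetric 15 x 15 matrix of target Spearman correlations with
#'   unit diagonal, named by variable.
#' @export
default_dependence <- function() {
  vars <- catalog_variables()
  m <- diag(1, length(vars))
  dimnames(m) <- list(vars, vars)
  set_pair <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  # within-block structure
  set_pair("waist", "weight", 0.70)
  set_pair("waist", "height", 0.10)
  set_pair("weight", "height", 0.45)
  set_pair("glucose", "hba1c", 0.60)
  set_pair("glucose", "insulin", 0.45)
  set_pair("hba1c", "insulin", 0.35)
  set_pair("hdl", "triglycerides", -0.40)
  set_pair("ldl", "triglycerides", 0.30)
  set_pair("ldl", "hdl", 0.05)
  set_pair("uric_acid", "urea", 0.30)
  set_pair("uric_acid", "creatinine", 0.35)
  set_pair("urea", "creatinine", 0.50)
  set_pair("systolic", "diastolic", 0.70)
  # cross-block links through adiposity, insulin and uric acid
  set_pair("waist", "insulin", 0.35)
  set_pair("waist", "glucose", 0.25)
  set_pair("waist", "triglycerides", 0.30)
  set_pair("waist", "uric_acid", 0.30)
  set_pair("waist", "systolic", 0.25)
  set_pair("waist", "hdl", -0.20)
  set_pair("weight", "insulin", 0.35)
  set_pair("weight", "triglycerides", 0.30)
  set_pair("weight", "uric_acid", 0.35)
  set_pair("weight", "systolic", 0.25)
  set_pair("insulin", "triglycerides", 0.35)
  set_pair("insulin", "hdl", -0.25)
  set_pair("glucose", "triglycerides", 0.30)
  set_pair("uric_acid", "triglycerides", 0.30)
  set_pair("uric_acid", "hdl", -0.20)
  set_pair("diastolic", "waist", 0.20)
  m
}

# Table of per-stratum marginal means and SDs for the 6 default age groups.
# Values are in each variable's catalog unit; insulin and triglycerides are
# right-skewed and get lognormal marginals, everything else normal.
.default_marginals <- function() {
  labels <- c("<25", "25-34", "35-44", "45-54", "55-64", "65+")
  mk <- function(means, sds, family = "normal") {
    data.frame(stratum = labels, mean = means, sd = sds, family = family,
               stringsAsFactors = FALSE)
  }
  spec <- list(
    glucose       = mk(c(4.6, 4.7, 5, 5, 5, 6),       c(0.5, 0.7, 1, 2, 2, 2)),
    hba1c         = mk(c(5.1, 5.1, 5, 6, 6, 6),       c(0.5, 0.6, 2, 2, 2, 2)),
    insulin       = mk(c(55, 54, 57, 60, 59, 59),     c(36, 52, 42, 62, 40, 44),
                       family = "lognormal"),
    hdl           = mk(c(1.3, 1.2, 1.2, 1.2, 1.2, 1.3), rep(0.3, 6)),
    ldl           = mk(c(2.5, 3, 3, 3.2, 3.3, 3.2),   c(0.6, 1, 2, 0.8, 0.9, 0.8)),
    triglycerides = mk(c(1.1, 1, 2, 2, 2, 2),         c(0.6, 1, 2, 1, 1, 1),
                       family = "lognormal"),
    uric_acid     = mk(c(323, 326, 319, 315, 331, 335), c(92, 90, 87, 82, 88, 85)),
    urea          = mk(c(4, 5, 4, 5, 5, 6),           c(1, 2, 1, 1, 1, 2)),
    creatinine    = mk(c(70, 74, 70, 70, 74, 88),     c(14, 45, 16, 17, 18, 78)),
    waist         = mk(c(82, 87, 91, 93, 93, 94),     c(11, 12, 12, 12, 11, 12)),
    weight        = mk(c(63, 68, 72, 71, 70, 68),     c(13, 15, 15, 14, 14, 13)),
    height        = mk(c(162, 164, 162, 159, 160, 159), c(9, 9, 9, 9, 10, 10)),
    temperature   = mk(c(37.2, 37.0, 37.0, 37.0, 36.8, 36.7),
                       c(0.5, 0.5, 0.5, 0.5, 0.5, 0.6)),
    systolic      = mk(c(109, 109, 113, 115, 121, 124), c(11, 12, 14, 14, 16, 19)),
    diastolic     = mk(c(71, 73, 76, 77, 79, 78),     c(9, 9, 11, 10, 11, 11))
  )
  do.call(rbind, lapply(names(spec), function(v)
    cbind(variable = v, spec[[v]], stringsAsFactors = FALSE)))
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: stratum sizes and age
#' ranges, per-stratum marginal distributions, a target Spearman dependence
#' matrix shared by all strata, and the female fraction.
#'
#' @param strata data frame with columns `label`, `n`, `age_min`, `age_max`.
#' @param marginals data frame with columns `variable`, `stratum`, `mean`,
#'   `sd`, `family` ("normal" or "lognormal"); one row per
#'   (variable, stratum).
#' @param dependence symmetric 15 x 15 target Spearman matrix, unit diagonal.
#' @param female_fraction probability that a participant is female.
#' @param seed default seed used when [generate_cohort()] is called without
#'   one.
#' @return An object of class `cohort_spec`.
#' @seealso [default_study_spec()] for the reference-cohort default.
#' @export
cohort_spec <- function(strata, marginals, dependence = default_dependence(),
                        female_fraction = 0.65, seed = 1L) {
  stopifnot(is.data.frame(strata),
            all(c("label", "n", "age_min", "age_max") %in% names(strata)),
            all(strata$n >= 1), all(strata$age_min <= strata$age_max),
            is.data.frame(marginals),
            all(c("variable", "stratum", "mean", "sd", "family") %in%
                  names(marginals)),
            all(marginals$sd > 0),
            all(marginals$family %in% c("normal", "lognormal")),
            is.matrix(dependence),
            female_fraction >= 0, female_fraction <= 1)
  vars <- catalog_variables()
  if (!identical(sort(unique(marginals$variable)), sort(vars)))
    stop("marginals must cover exactly the 15 catalog variables")
  miss <- setdiff(as.vector(outer(vars, strata$label, paste)),
                  paste(marginals$variable, marginals$stratum))
  if (length(miss) > 0)
    stop("marginals missing for: ", paste(miss[1:min(3, length(miss))],
                                          collapse = "; "), " ...")
  bad <- marginals$family == "lognormal" & marginals$mean <= 0
  if (any(bad)) stop("lognormal marginals require strictly positive means")
  if (!identical(rownames(dependence), vars) ||
      !identical(colnames(dependence), vars))
    stop("dependence matrix must be named by the 15 catalog variables")
  if (max(abs(dependence - t(dependence))) > 1e-12 ||
      any(abs(dependence) > 1) || any(diag(dependence) != 1))
    stop("dependence must be symmetric with unit diagonal, entries in [-1,1]")
  structure(list(strata = strata, marginals = marginals,
                 dependence = dependence,
                 female_fraction = female_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Synthetic-cohort specification for the default reference cohort
#'
#' Six age strata of sizes 680, 528, 445, 468, 352 and 99 (2572 participants
#' in total, 65% female), each with the per-stratum biomarker means and SDs
#' of the reference population, coupled through [default_dependence()].
#'
#' @return A [cohort_spec()] object.
#' @export
default_study_spec <- function() {
  strata <- data.frame(
    label = c("<25", "25-34", "35-44", "45-54", "55-64", "65+"),
    n = c(680L, 528L, 445L, 468L, 352L, 99L),
    age_min = c(18L, 25L, 35L, 45L, 55L, 65L),
    age_max = c(24L, 34L, 44L, 54L, 64L, 81L),
    stringsAsFactors = FALSE
  )
  cohort_spec(strata, .default_marginals(), default_dependence(),
              female_fraction = 0.65, seed = 1L)
}

# lognormal parameters matched to a target mean and sd
.lnorm_pars <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic cohort from a specification
#'
#' Draws each age stratum from a Gaussian copula: a latent multivariate
#' normal with correlation `2 sin(pi * rho_s / 6)` (so the sample Spearman
#' correlations converge to the target), mapped through each variable's
#' marginal quantile function (normal or moment-matched lognormal). Ages are
#' uniform integers within the stratum's range and sex is Bernoulli with the
#' spec's female fraction. Fully reproducible from the seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed; defaults to `spec$seed`.
#' @return A cohort data frame (see [read_cohort()] for the layout).
#' @examples
#' spec <- default_study_spec()
#' cohort <- generate_cohort(spec, seed = 42)
#' nrow(cohort) # 2572
#' @export
generate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  set.seed(as.integer(seed))
  vars <- catalog_variables()
  latent <- nearest_psd(spearman_to_pearson(spec$dependence))
  ch <- chol(latent)
  pieces <- vector("list", nrow(spec$strata))
  for (i in seq_len(nrow(spec$strata))) {
    st <- spec$strata[i, ]
    n <- st$n
    z <- matrix(stats::rnorm(n * length(vars)), n) %*% ch
    u <- stats::pnorm(z)
    vals <- matrix(NA_real_, n, length(vars),
                   dimnames = list(NULL, vars))
    for (j in seq_along(vars)) {
      mg <- spec$marginals[spec$marginals$variable == vars[j] &
                             spec$marginals$stratum == st$label, ]
      if (mg$family == "lognormal") {
        p <- .lnorm_pars(mg$mean, mg$sd)
        vals[, j] <- stats::qlnorm(u[, j], p$meanlog, p$sdlog)
      } else {
        vals[, j] <- stats::qnorm(u[, j], mg$mean, mg$sd)
      }
    }
    age <- sample(st$age_min:st$age_max, n, replace = TRUE)
    sex <- ifelse(stats::runif(n) < spec$female_fraction, "F", "M")
    pieces[[i]] <- data.frame(
      participant_id = sprintf("S%d-%04d", i, seq_len(n)),
      age = as.integer(age), sex = factor(sex, levels = c("M", "F")),
      vals, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Read or write a cohort specification as YAML
#'
#' @param spec a [cohort_spec()].
#' @param path YAML file path.
#' @return `read_cohort_spec()` returns a [cohort_spec()];
#'   `write_cohort_spec()` returns `path` invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  stopifnot(inherits(spec, "cohort_spec"))
  yaml::write_yaml(list(
    strata = spec$strata, marginals = spec$marginals,
    dependence = list(variables = rownames(spec$dependence),
                      values = as.vector(spec$dependence)),
    female_fraction = spec$female_fraction, seed = spec$seed), path)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  dep <- matrix(unlist(y$dependence$values),
                length(y$dependence$variables),
                dimnames = list(y$dependence$variables,
                                y$dependence$variables))
  cohort_spec(as.data.frame(y$strata), as.data.frame(y$marginals), dep,
              y$female_fraction, y$seed)
}
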
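#' Multi-domain area deprivation index
#'
#' Computes a rank-based deprivation index on a 1-100 scale (1 = least,
#' 100 = most deprived) from five area indicators grouped into three equally
#' weighted domains:
#'
#' * employment: unemployment rate (+), employed-at-residence % (-)
#' * income: purchasing power (-)
#' * education: high-school degree % (-), no-formal-education % (+)
#'
#' A `+` indicator increases deprivation, a `-` indicator decreases it. Each
#' indicator is oriented so higher = more deprived, converted to a mid-rank
#' percentile in \[0, 1\] (ties get their average rank, so the index is
#' permutation-invariant and unchanged by any monotone affine transform of an
#' indicator), averaged within its domain, and the three domain scores are
#' averaged and linearly rescaled over areas to \[1, 100\].
#'
#' @param covariates data frame with `area_id` and the five indicator
#'   columns `unemployment_rate`, `employed_at_residence`,
#'   `purchasing_power`, `highschool_degree`, `no_formal_education`; no
#'   missing values allowed.
#' @return data frame with `area_id`, the domain scores (`employment`,
#'   `income`, `education`, each in \[0, 1\]) and `deprivation` in
#'   \[1, 100\]. If all areas have identical raw scores every area gets the
#'   midpoint 50.5 and a warning is issued.
#' @export
compute_deprivation <- function(covariates) {
  ind <- c(unemployment_rate = 1, employed_at_residence = -1,
           purchasing_power = -1, highschool_degree = -1,
           no_formal_education = 1)
  miss <- setdiff(c("area_id", names(ind)), names(covariates))
  if (length(miss)) stop("missing indicator columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(covariates) < 2) stop("need at least 2 areas")
  for (nm in names(ind)) {
    if (anyNA(covariates[[nm]]))
      stop("missing ", nm, " for area(s): ",
           paste(covariates$area_id[is.na(covariates[[nm]])], collapse = ", "))
  }
  n <- nrow(covariates)
  pct <- sapply(names(ind), function(nm)
    (rank(ind[[nm]] * covariates[[nm]], ties.method = "average") - 0.5) / n)
  employment <- rowMeans(pct[, c("unemployment_rate", "employed_at_residence"),
                             drop = FALSE])
  income <- pct[, "purchasing_power"]
  education <- rowMeans(pct[, c("highschool_degree", "no_formal_education"),
                            drop = FALSE])
  raw <- (employment + income + education) / 3
  rng <- range(raw)
  if (rng[2] - rng[1] < .Machine$double.eps^0.5) {
    warning("all areas have identical deprivation; assigning midpoint 50.5")
    index <- rep(50.5, n)
  } else {
    index <- 1 + 99 * (raw - rng[1]) / (rng[2] - rng[1])
  }
  data.frame(area_id = covariates$area_id,
             employment = employment, income = income, education = education,
             deprivation = index)
}
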
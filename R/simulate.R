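#' Simulation configuration for a synthetic study region
#'
#' Defines the ground truth of a synthetic insurance population on a square
#' lattice of micro-areas. Defaults emulate the study conditions the package
#' is designed for: areas of about 300 households, a diabetic subpopulation
#' of about 17.3% of insurants, a marginal unenrollment rate of 36.8% among
#' diabetics, and odds ratios for the individual and area covariates matching
#' the global regression estimates reported for the north-east German DMP
#' population (male 0.938, age/year 0.997, foreign citizenship 1.058,
#' unemployed 1.100, deprivation 1.000, household size 0.801, commuter %
#' 0.996, physician density 0.998).
#'
#' @param n_rows,n_cols lattice dimensions (each >= 2 for any spatial model).
#' @param cell_km side length of a cell in km.
#' @param mean_insurants_per_area Poisson mean of per-area insurant counts
#'   (truncated at 1).
#' @param diabetes_target expected diabetic fraction among insurants; the
#'   age-slope logit intercept is calibrated to reach it.
#' @param diabetes_age_slope log-odds of diabetes per year of age.
#' @param enrollment_coefficients named list of log-odds-ratio coefficients
#'   of the unenrollment logit: `intercept` (NA = calibrate so the expected
#'   unenrollment fraction equals `target_unenrollment`), `male`,
#'   `age_per_year`, `foreign`, `unemployed`, `deprivation`,
#'   `household_size`, `commuter_pct`, `physician_density`.
#' @param target_unenrollment marginal unenrollment rate used to calibrate
#'   the intercept when `enrollment_coefficients$intercept` is `NA`.
#' @param spatial_sd_structured,spatial_sd_unstructured marginal standard
#'   deviations (logit scale) of the spatially structured (ICAR) and
#'   unstructured (iid normal) area effects on unenrollment.
#' @param svc_fields optional named numeric vector: for each named covariate
#'   (e.g. `male`, `commuter_pct`) the marginal sd of an ICAR-distributed
#'   spatially varying deviation added to its coefficient.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 10, n_cols = 10, cell_km = 2,
                       mean_insurants_per_area = 300,
                       diabetes_target = 0.173,
                       diabetes_age_slope = 0.055,
                       enrollment_coefficients = list(),
                       target_unenrollment = 0.368,
                       spatial_sd_structured = 0.3,
                       spatial_sd_unstructured = 0.1,
                       svc_fields = NULL,
                       seed = 1L) {
  if (n_rows < 2 || n_cols < 2) stop("lattice must be at least 2x2")
  if (spatial_sd_structured < 0 || spatial_sd_unstructured < 0)
    stop("spatial sds must be >= 0")
  beta <- list(intercept = NA_real_,
               male = log(0.938), age_per_year = log(0.997),
               foreign = log(1.058), unemployed = log(1.100),
               deprivation = 0, household_size = log(0.801),
               commuter_pct = log(0.996), physician_density = log(0.998))
  beta[names(enrollment_coefficients)] <- enrollment_coefficients
  structure(list(n_rows = n_rows, n_cols = n_cols, cell_km = cell_km,
                 mean_insurants_per_area = mean_insurants_per_area,
                 diabetes_target = diabetes_target,
                 diabetes_age_slope = diabetes_age_slope,
                 enrollment_coefficients = beta,
                 target_unenrollment = target_unenrollment,
                 spatial_sd_structured = spatial_sd_structured,
                 spatial_sd_unstructured = spatial_sd_unstructured,
                 svc_fields = svc_fields,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Square-lattice area set
#'
#' Builds an `n_rows` x `n_cols` grid of square cells in planar km
#' coordinates, the synthetic stand-in for micro-area polygons. Counts are
#' initialised to zero and filled by the generators.
#'
#' @inheritParams sim_config
#' @return An [area_set]; area ids are `"r<row>c<col>"`, row-major.
#' @export
lattice_areas <- function(n_rows, n_cols, cell_km = 1) {
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  polys <- vector("list", nrow(grid))
  for (k in seq_len(nrow(grid))) {
    x0 <- (grid$col[k] - 1) * cell_km; y0 <- (grid$row[k] - 1) * cell_km
    polys[[k]] <- cbind(c(x0, x0 + cell_km, x0 + cell_km, x0),
                        c(y0, y0, y0 + cell_km, y0 + cell_km))
  }
  info <- data.frame(area_id = sprintf("r%dc%d", grid$row, grid$col),
                     x = (grid$col - 0.5) * cell_km,
                     y = (grid$row - 0.5) * cell_km,
                     n_insurants = 0L, n_diabetics = 0L, n_unenrolled = 0L)
  area_set(info, polys, validate = FALSE)
}

#' Draw a spatially structured field from the ICAR density
#'
#' Samples the intrinsic CAR (Besag) Gaussian Markov random field on a
#' contiguity graph via eigen-decomposition of the structure matrix
#' restricted to its non-null space, then rescales so the empirical standard
#' deviation of the field equals `marginal_sd`. The draw sums to zero within
#' every connected component; components of size 1 (isolated areas) receive
#' the value 0, since an intrinsic field carries no information there.
#'
#' @param graph an [adjacency_graph].
#' @param marginal_sd target empirical sd of the field (>= 0).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return Numeric vector, one value per area.
#' @export
sample_icar_field <- function(graph, marginal_sd, seed = NULL) {
  if (marginal_sd < 0) stop("marginal_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- graph$n
  if (marginal_sd == 0) return(numeric(n))
  icar <- icar_structure(graph)
  Q <- as.matrix(icar$Q)
  eig <- eigen(Q, symmetric = TRUE)
  ncomp <- max(graph$components)
  pos <- seq_len(n - ncomp)          # eigenvalues sorted decreasing; null last
  lam <- eig$values[pos]
  if (!length(lam)) return(numeric(n))
  z <- stats::rnorm(length(lam), 0, 1 / sqrt(lam))
  s <- as.numeric(eig$vectors[, pos, drop = FALSE] %*% z)
  # exact sum-to-zero per component (numerically enforced)
  s <- s - stats::ave(s, graph$components)
  emp <- stats::sd(s)
  if (emp > 0) s <- s * marginal_sd / emp
  s
}

#' Generate a synthetic study region
#'
#' Produces the lattice of areas, its contiguity graph, and a table of
#' spatially correlated area covariates: the five deprivation indicators
#' (unemployment rate, employed-at-residence %, purchasing power, high-school
#' degree %, no-formal-education %), average household size, commuter %,
#' physician density per 100,000, and an area-level propensity of foreign
#' citizenship. Socio-economic indicators share one latent ICAR field (so
#' deprivation is spatially smooth); household size, commuting and physician
#' density ride on their own fields.
#'
#' @param config a [sim_config].
#' @return list with `areas` ([area_set], insurant counts filled),
#'   `graph` ([adjacency_graph]) and `covariates` (data frame keyed by
#'   `area_id`).
#' @export
generate_region <- function(config) {
  set.seed(config$seed)
  areas <- lattice_areas(config$n_rows, config$n_cols, config$cell_km)
  graph <- build_adjacency(areas)
  n <- nrow(areas)
  areas$n_insurants <- pmax(1L, stats::rpois(n, config$mean_insurants_per_area))

  socio <- sample_icar_field(graph, 1)
  mix <- function(field, w) w * field + sqrt(1 - w^2) * stats::rnorm(n)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  covariates <- data.frame(
    area_id = areas$area_id,
    unemployment_rate = clamp(8 + 4 * mix(socio, 0.8), 0.5, 40),
    employed_at_residence = clamp(45 - 10 * mix(socio, 0.7), 5, 95),
    purchasing_power = pmax(100 - 15 * mix(socio, 0.8), 40),
    highschool_degree = clamp(30 - 10 * mix(socio, 0.75), 2, 90),
    no_formal_education = clamp(5 + 2.5 * mix(socio, 0.8), 0.2, 30),
    household_size = pmax(2 + 0.3 * mix(sample_icar_field(graph, 1), 0.6), 1.2),
    commuter_pct = clamp(40 + 15 * mix(sample_icar_field(graph, 1), 0.7), 0, 95),
    physician_density = pmax(200 + 60 * mix(sample_icar_field(graph, 1), 0.6), 0),
    foreign_propensity = stats::plogis(stats::qlogis(0.08) +
                                       0.6 * mix(sample_icar_field(graph, 1), 0.8)))
  list(areas = areas, graph = graph, covariates = covariates)
}

#' Generate the insurant roster of a synthetic region
#'
#' Draws individual insurants per area: age truncated Normal(55, 20) on
#' [18, 100], sex Bernoulli(0.5), unemployment with a logit linear in area
#' deprivation, foreign citizenship from the area propensity, and a diabetic
#' flag with a logit linear in age whose intercept is calibrated so the
#' expected diabetic fraction equals `config$diabetes_target`.
#'
#' @param region output of [generate_region].
#' @param covariates area covariate table; must contain `deprivation`
#'   (see [compute_deprivation]) and `foreign_propensity`.
#' @param config a [sim_config].
#' @return data frame of insurants (`insurant_id`, `area_id`, `age`, `sex`,
#'   `unemployed`, `foreign_citizenship`, `diabetic`, `enrolled` = NA until
#'   [assign_enrollment] is run). The calibrated diabetes intercept is
#'   attached as attribute `diabetes_intercept`.
#' @export
generate_insurants <- function(region, covariates, config) {
  areas <- region$areas
  n_i <- areas$n_insurants
  total <- sum(n_i)
  area_idx <- rep(seq_len(nrow(areas)), n_i)
  lo <- stats::pnorm((18 - 55) / 20); hi <- stats::pnorm((100 - 55) / 20)
  age <- 55 + 20 * stats::qnorm(stats::runif(total, lo, hi))
  sex <- ifelse(stats::rbinom(total, 1, 0.5) == 1, "male", "female")
  dep <- covariates$deprivation[match(areas$area_id[area_idx],
                                      covariates$area_id)]
  if (any(is.na(dep))) stop("covariates must carry a deprivation column")
  p_unemp <- stats::plogis(stats::qlogis(0.10) + 0.015 * (dep - 50.5))
  unemployed <- stats::rbinom(total, 1, p_unemp)
  p_foreign <- covariates$foreign_propensity[match(areas$area_id[area_idx],
                                                   covariates$area_id)]
  foreign <- stats::rbinom(total, 1, p_foreign)
  s <- config$diabetes_age_slope
  a <- stats::uniroot(function(a) mean(stats::plogis(a + s * age)) -
                        config$diabetes_target,
                      interval = c(-30, 10))$root
  diabetic <- stats::rbinom(total, 1, stats::plogis(a + s * age))
  out <- data.frame(insurant_id = sprintf("i%07d", seq_len(total)),
                    area_id = areas$area_id[area_idx],
                    age = age, sex = sex, unemployed = unemployed,
                    foreign_citizenship = foreign, diabetic = diabetic,
                    enrolled = NA_integer_)
  attr(out, "diabetes_intercept") <- a
  out
}

#' Assign the enrollment outcome to diabetic insurants
#'
#' For each diabetic the probability of NOT being enrolled follows a logit
#' linear in the individual covariates (male, age, foreign citizenship,
#' unemployment), the area covariates (deprivation, household size,
#' commuter %, physician density), a spatially structured and an
#' unstructured area effect, and optional spatially varying coefficient
#' deviations. Non-diabetics keep `enrolled = NA`: enrollment is defined
#' only for the diabetic subpopulation.
#'
#' @param insurants roster from [generate_insurants].
#' @param config a [sim_config]; if `enrollment_coefficients$intercept` is
#'   `NA` it is calibrated so the expected unenrollment fraction among the
#'   realized diabetics equals `config$target_unenrollment`.
#' @param area_data data frame keyed by `area_id` with columns
#'   `deprivation`, `household_size`, `commuter_pct`, `physician_density`.
#' @param structured_field,unstructured_field per-area effects, in the order
#'   of `area_ids`; `NULL` means zero.
#' @param svc_fields optional named list of per-area coefficient-deviation
#'   fields (names among the covariate names above plus `male`, `age_per_year`,
#'   `foreign`, `unemployed`).
#' @param area_ids area id vector defining the order of the field vectors;
#'   defaults to `area_data$area_id`.
#' @return `insurants` with `enrolled` filled for diabetics (1 = enrolled)
#'   and an `unenrolled` column; the realized intercept is attached as
#'   attribute `enrollment_intercept`.
#' @export
assign_enrollment <- function(insurants, config, area_data,
                              structured_field = NULL,
                              unstructured_field = NULL,
                              svc_fields = NULL,
                              area_ids = area_data$area_id) {
  idx <- match(insurants$area_id, area_ids)
  if (any(is.na(idx))) stop("insurant references unknown area_id")
  ad <- area_data[match(area_ids, area_data$area_id), , drop = FALSE]
  need <- c("deprivation", "household_size", "commuter_pct", "physician_density")
  if (!all(need %in% names(ad)))
    stop("area_data lacks: ", paste(setdiff(need, names(ad)), collapse = ", "))
  n_areas <- length(area_ids)
  u <- structured_field %||% numeric(n_areas)
  v <- unstructured_field %||% numeric(n_areas)
  if (length(u) != n_areas || length(v) != n_areas)
    stop("field length does not match number of areas")
  b <- config$enrollment_coefficients
  xmale <- as.numeric(insurants$sex == "male")
  xvals <- list(male = xmale, age_per_year = insurants$age,
                foreign = insurants$foreign_citizenship,
                unemployed = insurants$unemployed,
                deprivation = ad$deprivation[idx],
                household_size = ad$household_size[idx],
                commuter_pct = ad$commuter_pct[idx],
                physician_density = ad$physician_density[idx])
  eta <- u[idx] + v[idx]
  for (nm in names(xvals)) eta <- eta + b[[nm]] * xvals[[nm]]
  if (!is.null(svc_fields)) {
    for (nm in names(svc_fields)) {
      if (length(svc_fields[[nm]]) != n_areas)
        stop("svc field ", nm, " has wrong length")
      xk <- if (nm == "intercept") 1 else xvals[[nm]]
      if (is.null(xk)) stop("unknown svc covariate ", nm)
      eta <- eta + svc_fields[[nm]][idx] * xk
    }
  }
  dia <- insurants$diabetic == 1
  intercept <- b$intercept
  if (is.na(intercept)) {
    intercept <- stats::uniroot(function(a)
      mean(stats::plogis(a + eta[dia])) - config$target_unenrollment,
      interval = c(-30, 30))$root
  }
  p_unenrolled <- stats::plogis(intercept + eta)
  unenrolled <- rep(NA_integer_, nrow(insurants))
  unenrolled[dia] <- stats::rbinom(sum(dia), 1, p_unenrolled[dia])
  insurants$enrolled <- ifelse(dia, 1L - unenrolled, NA_integer_)
  insurants$unenrolled <- unenrolled
  attr(insurants, "enrollment_intercept") <- intercept
  insurants
}

#' Simulate a complete synthetic study
#'
#' Runs the whole generator: region and covariates, deprivation index,
#' insurant roster, spatial effect fields, spatially varying coefficient
#' fields, and the enrollment outcome; then fills the per-area diabetic and
#' unenrolled counts. The returned object carries its full ground truth so
#' downstream recovery tests can compare estimates to the generating values.
#'
#' @param config a [sim_config].
#' @return list of class `enrollscape_sim` with elements `areas`, `graph`,
#'   `covariates` (including `deprivation`), `deprivation` (full index
#'   table), `insurants`, and `ground_truth` (config, calibrated intercepts,
#'   structured/unstructured/svc fields).
#' @export
simulate_study <- function(config = sim_config()) {
  region <- generate_region(config)
  dep <- compute_deprivation(region$covariates)
  covariates <- merge(region$covariates,
                      dep[, c("area_id", "deprivation")], by = "area_id",
                      sort = FALSE)
  covariates <- covariates[match(region$areas$area_id, covariates$area_id), ]
  rownames(covariates) <- NULL
  insurants <- generate_insurants(region, covariates, config)
  u <- sample_icar_field(region$graph, config$spatial_sd_structured)
  v <- if (config$spatial_sd_unstructured > 0)
    stats::rnorm(region$graph$n, 0, config$spatial_sd_unstructured)
  else numeric(region$graph$n)
  svc <- NULL
  if (!is.null(config$svc_fields)) {
    svc <- lapply(config$svc_fields, function(sdk)
      sample_icar_field(region$graph, sdk))
    names(svc) <- names(config$svc_fields)
  }
  insurants <- assign_enrollment(insurants, config, covariates,
                                 structured_field = u, unstructured_field = v,
                                 svc_fields = svc,
                                 area_ids = region$areas$area_id)
  tab_d <- tapply(insurants$diabetic, insurants$area_id, sum)
  tab_u <- tapply(ifelse(is.na(insurants$unenrolled), 0L,
                         insurants$unenrolled),
                  insurants$area_id, sum)
  region$areas$n_diabetics <-
    as.integer(tab_d[region$areas$area_id])
  region$areas$n_unenrolled <-
    as.integer(tab_u[region$areas$area_id])
  structure(list(areas = region$areas, graph = region$graph,
                 covariates = covariates, deprivation = dep,
                 insurants = insurants,
                 ground_truth = list(
                   config = config,
                   diabetes_intercept = attr(insurants, "diabetes_intercept"),
                   enrollment_intercept = attr(insurants, "enrollment_intercept"),
                   structured_field = u, unstructured_field = v,
                   svc_fields = svc)),
            class = "enrollscape_sim")
}

#' @export
print.enrollscape_sim <- function(x, ...) {
  n <- nrow(x$insurants)
  nd <- sum(x$insurants$diabetic)
  cat("Synthetic study region:", nrow(x$areas), "areas,", n, "insurants\n")
  cat(sprintf("  diabetics: %d (%.1f%%); unenrolled among diabetics: %.1f%%\n",
              nd, 100 * nd / n,
              100 * mean(x$insurants$unenrolled[x$insurants$diabetic == 1])))
  cat(sprintf("  spatial sds (logit): structured %.2f, unstructured %.2f\n",
              x$ground_truth$config$spatial_sd_structured,
              x$ground_truth$config$spatial_sd_unstructured))
  invisible(x)
}

#' Write the artifacts of a simulated study to a directory
#'
#' Writes `areas.geojson`, `insurants.csv`, `covariates.csv` and
#' `ground_truth.json` (config and calibrated intercepts; field draws are
#' stored alongside for exact recovery testing).
#'
#' @param sim an `enrollscape_sim`.
#' @param dir output directory (created if needed).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_areas_geojson(sim$areas, file.path(dir, "areas.geojson"))
  utils::write.csv(round_numeric(sim$insurants),
                   file.path(dir, "insurants.csv"), row.names = FALSE)
  utils::write.csv(round_numeric(sim$covariates),
                   file.path(dir, "covariates.csv"), row.names = FALSE)
  gt <- sim$ground_truth
  gt$config <- unclass(gt$config)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

round_numeric <- function(df, digits = 6) {
  for (j in seq_along(df)) if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  df
}
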
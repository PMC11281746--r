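#' Standardize values to z-scores (population sd)
#'
#' `(x - mean(x)) / sd_pop(x)` with the population standard deviation
#' (divisor n). The centering constants are stored as attributes `center`
#' and `scale` so the transformation can be inverted with [unstandardize].
#' Continuous covariates entering the spatially varying coefficient model
#' (age, deprivation, commuter share) are standardized this way so their
#' local coefficients are directly comparable.
#'
#' @param values numeric vector with at least 2 distinct values.
#' @return z-scores with attributes `center` and `scale`.
#' @export
standardize <- function(values) {
  if (length(unique(values)) < 2) stop("need >= 2 distinct values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("zero standard deviation")
  structure((values - m) / s, center = m, scale = s)
}

#' Invert [standardize]
#'
#' @param z z-scores carrying `center`/`scale` attributes (or supply them).
#' @param center,scale override the stored constants.
#' @return values on the original scale.
#' @export
unstandardize <- function(z, center = attr(z, "center"),
                          scale = attr(z, "scale")) {
  as.numeric(z) * scale + center
}

#' Coarsen a contiguity graph by a unit mapping
#'
#' Contracts the fine-area contiguity graph onto coarser administrative
#' units (the device that makes the spatially varying coefficient model
#' tractable on large lattices): two coarse units are adjacent exactly when
#' some pair of their fine areas is adjacent. Contraction preserves
#' connectivity.
#'
#' @param fine_graph an [adjacency_graph] over fine areas.
#' @param mapping coarse unit id per fine area, either aligned with
#'   `fine_graph$area_ids` or named by fine area id; every fine area must be
#'   mapped.
#' @return Object of class `coarse_graph`: list with `mapping` (named by
#'   fine id), `coarse_ids` (in first-appearance order) and `graph` (the
#'   coarse [adjacency_graph]).
#' @export
coarsen_graph <- function(fine_graph, mapping) {
  if (!is.null(names(mapping))) {
    mapping <- mapping[fine_graph$area_ids]
    if (anyNA(mapping)) stop("fine area without coarse assignment")
  }
  if (length(mapping) != fine_graph$n)
    stop("mapping must cover every fine area")
  mapping <- as.character(mapping)
  if (anyNA(mapping)) stop("fine area without coarse assignment")
  coarse_ids <- unique(mapping)
  ci <- match(mapping, coarse_ids)
  e <- fine_graph$edges
  ce <- cbind(ci[e[, 1]], ci[e[, 2]])
  ce <- ce[ce[, 1] != ce[, 2], , drop = FALSE]
  graph <- new_adjacency_graph(coarse_ids, ce)
  structure(list(mapping = stats::setNames(mapping, fine_graph$area_ids),
                 coarse_ids = coarse_ids, graph = graph),
            class = "coarse_graph")
}

#' @export
print.coarse_graph <- function(x, ...) {
  cat("Coarsened graph:", length(x$mapping), "fine areas ->",
      length(x$coarse_ids), "coarse units,", nrow(x$graph$edges), "edges\n")
  invisible(x)
}

#' Block mapping of a square lattice to coarse units
#'
#' Maps the `n_rows x n_cols` lattice ids of [lattice_areas] onto
#' rectangular blocks of `block` x `block` cells — a convenient stand-in for
#' the municipality level of a real region.
#'
#' @param n_rows,n_cols fine lattice dimensions.
#' @param block block side length in cells (must divide both dimensions to
#'   produce equal blocks; remainders join the last block).
#' @return named character vector: fine area id -> coarse unit id.
#' @export
block_mapping <- function(n_rows, n_cols, block) {
  grid <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  br <- pmin((grid$row - 1) %/% block + 1, ceiling(n_rows / block))
  bc <- pmin((grid$col - 1) %/% block + 1, ceiling(n_cols / block))
  stats::setNames(sprintf("b%dx%d", br, bc),
                  sprintf("r%dc%d", grid$row, grid$col))
}

#' Fit the Bayesian spatially varying coefficient (SVC) logistic model
#'
#' Extends the global logistic regression by letting selected coefficients
#' vary over coarse spatial units:
#' `logit P(unenrolled_i) = sum_k (beta_k + delta_k,j(i)) x_ik`,
#' where each deviation field `delta_k` follows an intrinsic CAR (Besag)
#' prior on the coarse contiguity graph with its own precision and a
#' sum-to-zero constraint per component. The intercept field varies
#' spatially too by default. Continuous covariates named in `standardize`
#' are z-scored (population sd) before fitting so local coefficients are
#' comparable across covariates; binary covariates are left untouched.
#'
#' For every varying covariate the per-unit total coefficient
#' `beta_k + delta_k,j` is summarised and the exceedance probability is
#' computed from posterior draws: the probability that the exponentiated
#' total coefficient is above 1 (direction `"greater"`, the default) or
#' below 1 (direction `"less"`, conventional for covariates with an
#' established protective direction such as household size).
#'
#' @param formula model formula for the fixed-effect part (all covariates).
#' @param data regression design with an `area_id` column (fine areas).
#' @param coarse a [coarsen_graph] result mapping fine areas to coarse
#'   units.
#' @param svc_covariates character vector of design-column names whose
#'   coefficients vary spatially (use the names as they appear in
#'   `colnames(model.matrix(...))`).
#' @param standardize_covariates columns z-scored before fitting (default
#'   `age`, `deprivation`, `commuter_pct` where present).
#' @param directions named character vector overriding the exceedance
#'   direction per covariate (values `"greater"`/`"less"`; default
#'   `c(household_size = "less")`).
#' @param intercept_varies should the intercept carry its own spatial field?
#' @param n_draws posterior draws.
#' @param tau_prior Gamma(shape, rate) prior on the field precisions.
#' @param seed integer seed.
#' @return Object of class `svc_fit`: named list `fields` of per-unit
#'   summaries (`unit_id`, `coef_mean`, `coef_sd`, `q2.5`, `q97.5`,
#'   `exceedance`, `band`), global coefficient `summary`, `dic`, `pd`,
#'   per-field precisions `taus`, the standardization `scalers`, and flags.
#' @export
fit_svc <- function(formula, data, coarse, svc_covariates,
                    standardize_covariates = c("age", "deprivation",
                                               "commuter_pct"),
                    directions = c(household_size = "less"),
                    intercept_varies = TRUE,
                    n_draws = 200, tau_prior = c(1, 5e-4), seed = 1) {
  scalers <- list()
  for (nm in intersect(standardize_covariates, names(data))) {
    z <- standardize(data[[nm]])
    scalers[[nm]] <- c(center = attr(z, "center"), scale = attr(z, "scale"))
    data[[nm]] <- as.numeric(z)
  }
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(!y %in% c(0, 1))) stop("outcome must be 0/1")
  unit_of_fine <- coarse$mapping
  unit_index <- match(unit_of_fine[data$area_id], coarse$coarse_ids)
  if (anyNA(unit_index)) stop("row references an unmapped area")
  g <- coarse$graph
  if (all(tabulate(g$components) < 2))
    stop("coarse graph needs a component of size >= 2")
  bad <- setdiff(svc_covariates, colnames(X))
  if (length(bad)) stop("svc covariates not in design: ",
                        paste(bad, collapse = ", "))
  varying <- svc_covariates
  if (intercept_varies && "(Intercept)" %in% colnames(X))
    varying <- union("(Intercept)", varying)
  bas <- icar_basis(g)
  fields <- lapply(varying, function(nm)
    list(name = nm, x = X[, nm], B = bas$B, lambda = bas$lambda))
  lap <- logistic_laplace(y, X, unit_index, fields, beta_prec = 1 / 100,
                          tau_prior = tau_prior, n_draws = n_draws,
                          seed = seed)
  bd <- lap$draws[, lap$idx_beta, drop = FALSE]
  colnames(bd) <- colnames(X)
  qs <- apply(bd, 2, stats::quantile, c(0.025, 0.5, 0.975))
  summ <- data.frame(term = colnames(X), mean = colMeans(bd),
                     sd = apply(bd, 2, stats::sd),
                     q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
                     row.names = NULL)
  out_fields <- list()
  for (f in seq_along(fields)) {
    nm <- fields[[f]]$name
    k <- match(nm, colnames(X))
    delta_draws <- bas$B %*% t(lap$draws[, lap$idx_fields[[f]], drop = FALSE])
    total <- sweep(delta_draws, 2, bd[, k], `+`)     # units x draws
    dirn <- if (nm %in% names(directions)) directions[[nm]] else "greater"
    exc <- exceedance(total, direction = dirn)
    qsu <- apply(total, 1, stats::quantile, c(0.025, 0.975))
    out_fields[[nm]] <- data.frame(
      unit_id = coarse$coarse_ids,
      coef_mean = rowMeans(total),
      coef_sd = apply(total, 1, stats::sd),
      q2.5 = qsu[1, ], q97.5 = qsu[2, ],
      exceedance = exc, direction = dirn,
      band = band_probability(exc), row.names = NULL)
  }
  taus <- stats::setNames(lap$taus, varying)
  structure(list(fields = out_fields, summary = summ, beta_draws = bd,
                 coefficients = stats::setNames(colMeans(bd), colnames(X)),
                 taus = taus, dic = lap$dic, pd = lap$pd,
                 deviance_samples = lap$deviance_samples,
                 deviance_at_mean = lap$deviance_at_mean,
                 separated = lap$separated,
                 em_iterations = lap$em_iterations,
                 scalers = scalers, coarse_ids = coarse$coarse_ids,
                 n = lap$n, seed = seed),
            class = "svc_fit")
}

#' @export
print.svc_fit <- function(x, ...) {
  cat(sprintf(
    "Spatially varying coefficient logistic model: n = %d, %d coarse units\n",
    x$n, length(x$coarse_ids)))
  cat(sprintf("  varying covariates: %s\n",
              paste(names(x$fields), collapse = ", ")))
  cat(sprintf("  DIC %.1f (pD %.1f)\n", x$dic, x$pd))
  for (nm in names(x$fields)) {
    f <- x$fields[[nm]]
    cat(sprintf("  %-18s coef sd across units %.3f; P(OR %s 1) > 0.8 in %d/%d units\n",
                nm, stats::sd(f$coef_mean),
                if (f$direction[1] == "greater") ">" else "<",
                sum(f$exceedance > 0.8), nrow(f)))
  }
  invisible(x)
}

#' @export
summary.svc_fit <- function(object, ...) object$summary

#' @export
coef.svc_fit <- function(object, ...) object$coefficients

#' Exceedance probability of posterior coefficient draws
#'
#' Fraction of posterior draws whose exponentiated (OR-scale) coefficient is
#' above 1 (`direction = "greater"`) or below 1 (`direction = "less"`),
#' computed on the log scale as the fraction of draws above/below 0. Row
#' input gives one probability per unit. At least ~100 draws per unit are
#' needed for a stable estimate.
#'
#' @param samples numeric vector of log-scale coefficient draws, or a matrix
#'   with one row per spatial unit.
#' @param direction `"greater"` or `"less"`.
#' @return probability (vector: one per row of a matrix input).
#' @export
exceedance <- function(samples, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  f <- if (direction == "greater") function(s) mean(s > 0)
       else function(s) mean(s < 0)
  if (is.matrix(samples)) apply(samples, 1, f) else f(samples)
}

#' Band an exceedance probability for mapping
#'
#' Maps probabilities to the three conventional choropleth reliability
#' bands: `[0, 0.6)` is `"<0.6"`, `[0.6, 0.8]` is `"0.6-0.8"`, `(0.8, 1]`
#' is `">0.8"` (both boundaries close into the middle band).
#'
#' @param p probability in \[0, 1\] (vectorised).
#' @return character band labels.
#' @export
band_probability <- function(p) {
  if (any(p < 0 | p > 1)) stop("probabilities must be in [0, 1]")
  ifelse(p < 0.6, "<0.6", ifelse(p <= 0.8, "0.6-0.8", ">0.8"))
}

#' Write an SVC field as GeoJSON choropleth data
#'
#' Joins a field's per-coarse-unit summaries to the fine-area polygons and
#' writes one GeoJSON with properties `coef_mean`, `exceedance`, `band`.
#'
#' @param fit an `svc_fit`.
#' @param covariate which field to export.
#' @param areas fine-area [area_set].
#' @param coarse the [coarsen_graph] mapping used in the fit.
#' @param path output path.
#' @export
write_svc_geojson <- function(fit, covariate, areas, coarse, path) {
  f <- fit$fields[[covariate]]
  if (is.null(f)) stop("no such field: ", covariate)
  j <- match(coarse$mapping[areas$area_id], f$unit_id)
  extra <- data.frame(coarse_unit = coarse$mapping[areas$area_id],
                      coef_mean = f$coef_mean[j],
                      exceedance = f$exceedance[j], band = f$band[j])
  write_areas_geojson(areas, path, extra = extra)
}
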
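#' Build the individual-level regression design from a simulated study
#'
#' Restricts the roster to diabetics and joins the area covariates,
#' producing one row per diabetic with the outcome `unenrolled` (1 = not
#' enrolled), the individual covariates `male`, `age`, `foreign`,
#' `unemployed`, and the area covariates `deprivation`, `household_size`,
#' `commuter_pct`, `physician_density`. Reference categories are female,
#' German citizenship and not unemployed.
#'
#' @param sim an `enrollscape_sim` from [simulate_study], or a list with
#'   `insurants` and `covariates` (the latter carrying `deprivation`).
#' @return data frame (the regression design) with an `area_id` column.
#' @export
regression_design <- function(sim) {
  ins <- sim$insurants[sim$insurants$diabetic == 1, ]
  cov <- sim$covariates
  idx <- match(ins$area_id, cov$area_id)
  if (anyNA(idx)) stop("diabetic row references unknown area_id")
  data.frame(area_id = ins$area_id,
             unenrolled = ins$unenrolled,
             male = as.numeric(ins$sex == "male"),
             age = ins$age,
             foreign = ins$foreign_citizenship,
             unemployed = ins$unemployed,
             deprivation = cov$deprivation[idx],
             household_size = cov$household_size[idx],
             commuter_pct = cov$commuter_pct[idx],
             physician_density = cov$physician_density[idx])
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R2_k)` where `R2_k` comes from the least-squares
#' regression of covariate k on all other covariates plus an intercept.
#' Values above `threshold` (conventionally 5) flag multicollinearity; a
#' perfectly collinear covariate is reported as `Inf`.
#'
#' @param data data frame or matrix of covariate columns (numeric).
#' @param covariates optional character vector selecting columns.
#' @param threshold flag threshold (default 5).
#' @return named numeric vector of VIFs with attribute `flagged` (names of
#'   covariates exceeding the threshold, including infinite ones).
#' @export
compute_vif <- function(data, covariates = NULL, threshold = 5) {
  X <- as.data.frame(data)
  if (!is.null(covariates)) X <- X[, covariates, drop = FALSE]
  X <- X[, vapply(X, is.numeric, TRUE), drop = FALSE]
  if (ncol(X) < 2) stop("need at least 2 covariates")
  if (nrow(X) <= ncol(X) + 1) stop("need more rows than covariates + 1")
  vif <- vapply(seq_len(ncol(X)), function(k) {
    fit <- stats::lm.fit(cbind(1, as.matrix(X[, -k, drop = FALSE])), X[[k]])
    rss <- sum(fit$residuals^2)
    tss <- sum((X[[k]] - mean(X[[k]]))^2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(X)
  structure(vif, flagged = names(vif)[vif > threshold])
}

#' Fit the global Bayesian logistic regression of unenrollment
#'
#' Individual-level model
#' `logit P(unenrolled_i) = x_i' beta + s_area(i)` with fixed-effect priors
#' Normal(0, 10^2) and an area random effect `s` chosen by `effect`:
#'
#' * `"none"`: no area effect (plain Bayesian logistic regression),
#' * `"iid"`: exchangeable Normal(0, 1/tau_v) effects,
#' * `"besag"`: intrinsic CAR (spatially structured) effects on the
#'   contiguity graph, sum-to-zero per component,
#' * `"bym"`: the Besag-York-Mollie combination of both.
#'
#' Precisions carry Gamma(1, 5e-4) priors. Inference is a Gaussian (Laplace)
#' approximation at the posterior mode with EM hyperparameter updates;
#' posterior draws, the deviance information criterion (DIC with
#' `pD = mean deviance - deviance at the posterior mean`) and OR-scale
#' summaries come from the approximation. Covariates enter unstandardized.
#' Perfect separation is detected and flagged with a warning rather than
#' failing.
#'
#' @param formula model formula, e.g.
#'   `unenrolled ~ male + age + foreign + unemployed + deprivation +
#'   household_size + commuter_pct + physician_density`.
#' @param data the regression design (see [regression_design]); must carry
#'   an `area_id` column when `effect != "none"`.
#' @param graph the [adjacency_graph] over areas (required for
#'   `iid`/`besag`/`bym`; its `area_ids` define the effect order).
#' @param effect area random-effect structure.
#' @param n_draws posterior draws used for summaries and deviance sampling.
#' @param tau_prior Gamma(shape, rate) prior on effect precisions.
#' @param seed integer seed (draws are the only randomness).
#' @return Object of class `global_fit` with posterior summaries
#'   (`summary`), draws, `dic`, `pd`, precisions, convergence/separation
#'   flags and the model metadata. Methods: `print`, `summary`, `coef`,
#'   `vcov`; see [odds_ratio_table].
#' @export
fit_global <- function(formula, data, graph = NULL,
                       effect = c("none", "iid", "besag", "bym"),
                       n_draws = 200, tau_prior = c(1, 5e-4), seed = 1) {
  effect <- match.arg(effect)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (any(!y %in% c(0, 1))) stop("outcome must be 0/1")
  fields <- list()
  area_index <- integer(length(y))
  if (effect != "none") {
    if (is.null(graph)) stop("graph required for spatial effects")
    area_index <- match(data$area_id, graph$area_ids)
    if (anyNA(area_index)) stop("row references an area missing from graph")
    if (effect %in% c("besag", "bym")) {
      if (all(tabulate(graph$components) < 2))
        stop("structured effects need a component of size >= 2")
      bas <- icar_basis(graph)
      fields <- c(fields, list(list(name = "besag", x = rep(1, length(y)),
                                    B = bas$B, lambda = bas$lambda)))
    }
    if (effect %in% c("iid", "bym")) {
      fields <- c(fields, list(list(name = "iid", x = rep(1, length(y)),
                                    B = diag(graph$n),
                                    lambda = rep(1, graph$n))))
    }
  }
  lap <- logistic_laplace(y, X, area_index, fields, beta_prec = 1 / 100,
                          tau_prior = tau_prior, n_draws = n_draws,
                          seed = seed)
  bd <- lap$draws[, lap$idx_beta, drop = FALSE]
  colnames(bd) <- colnames(X)
  qs <- apply(bd, 2, stats::quantile, c(0.025, 0.5, 0.975))
  summ <- data.frame(term = colnames(X),
                     mean = colMeans(bd), sd = apply(bd, 2, stats::sd),
                     q2.5 = qs[1, ], q50 = qs[2, ], q97.5 = qs[3, ],
                     row.names = NULL)
  taus <- lap$taus
  names(taus) <- vapply(fields, `[[`, "", "name")
  structure(list(summary = summ, beta_draws = bd,
                 coefficients = stats::setNames(colMeans(bd), colnames(X)),
                 Sigma_beta = lap$Sigma[lap$idx_beta, lap$idx_beta,
                                        drop = FALSE],
                 field_draws = lapply(seq_along(fields), function(f)
                   lap$draws[, lap$idx_fields[[f]], drop = FALSE]),
                 fields = lapply(fields, function(f)
                   f[c("name")]),
                 field_basis = lapply(fields, function(f)
                   list(B = f$B, lambda = f$lambda)),
                 taus = taus, effect = effect,
                 deviance_samples = lap$deviance_samples,
                 deviance_at_mean = lap$deviance_at_mean,
                 pd = lap$pd, dic = lap$dic,
                 separated = lap$separated,
                 em_iterations = lap$em_iterations,
                 n = lap$n, formula = formula, seed = seed,
                 area_ids = if (!is.null(graph)) graph$area_ids),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf(
    "Bayesian logistic regression (area effect: %s), n = %d\n",
    x$effect, x$n))
  cat(sprintf("  DIC %.1f (pD %.1f)%s\n", x$dic, x$pd,
              if (x$separated) "  [separation flagged]" else ""))
  ort <- odds_ratio_table(x)
  ort[-1] <- lapply(ort[-1], round, 3)
  print(ort, row.names = FALSE)
  invisible(x)
}

#' @export
summary.global_fit <- function(object, ...) object$summary

#' @export
coef.global_fit <- function(object, ...) object$coefficients

#' @export
vcov.global_fit <- function(object, ...) object$Sigma_beta

#' Deviance information criterion from deviance samples
#'
#' `Dbar = mean(deviance_samples)`, `pD = Dbar - deviance_at_mean`,
#' `DIC = Dbar + pD` (classical Spiegelhalter form).
#'
#' @param deviance_samples per-draw deviances (length >= 2).
#' @param deviance_at_mean deviance evaluated at the posterior mean.
#' @return list with `DIC`, `pD` and `Dbar`.
#' @export
compute_dic <- function(deviance_samples, deviance_at_mean) {
  if (length(deviance_samples) < 2) stop("need >= 2 deviance samples")
  dbar <- mean(deviance_samples)
  pd <- dbar - deviance_at_mean
  list(DIC = dbar + pd, pD = pd, Dbar = dbar)
}

#' Odds-ratio table of a fitted logistic model
#'
#' Exponentiates the posterior draws of the fixed effects: posterior mean OR
#' with 2.5% and 97.5% credible limits, rows in design-column order
#' (intercept first).
#'
#' @param fit a `global_fit` (or any object with a `beta_draws` matrix).
#' @return data frame with `term`, `or`, `ci_2.5`, `ci_97.5`.
#' @export
odds_ratio_table <- function(fit) {
  draws <- exp(fit$beta_draws)
  qs <- apply(draws, 2, stats::quantile, c(0.025, 0.975))
  data.frame(term = colnames(draws), or = colMeans(draws),
             ci_2.5 = qs[1, ], ci_97.5 = qs[2, ], row.names = NULL)
}

#' Percent change in risk implied by an odds ratio
#'
#' `(OR - 1) * 100`, rounded half-up to one decimal. The sign carries the
#' phrasing: -6.2 reads "6.2% lower risk", +10.0 reads "10% higher risk".
#'
#' @param or_value odds ratio(s), > 0.
#' @return signed percent change(s), one decimal.
#' @export
percent_change <- function(or_value) {
  if (any(or_value <= 0)) stop("odds ratios must be > 0")
  pc <- (or_value - 1) * 100
  sign(pc) * floor(abs(pc) * 10 + 0.5) / 10
}
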
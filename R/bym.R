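#' Expected unenrolled counts by internal standardization
#'
#' Applies the global unenrollment rate to each area's diabetic population:
#' `E_i = n_diabetics_i * sum(O) / sum(n_diabetics)`, so that
#' `sum(E) == sum(O)` exactly. These expected counts are the offset of the
#' disease-mapping model and the baseline of the scan statistic.
#'
#' @param n_diabetics per-area diabetic counts.
#' @param O per-area observed unenrolled counts.
#' @return numeric vector `E` of expected counts.
#' @export
expected_counts <- function(n_diabetics, O) {
  if (length(n_diabetics) != length(O)) stop("length mismatch")
  if (sum(n_diabetics) <= 0) stop("no diabetics")
  bad <- O > 0 & n_diabetics == 0
  if (any(bad))
    stop("unenrolled cases in areas without diabetics at index: ",
         paste(which(bad), collapse = ", "))
  n_diabetics * sum(O) / sum(n_diabetics)
}

#' Fit the Besag-York-Mollie disease-mapping model
#'
#' Poisson model for area counts with a spatially structured and an
#' unstructured random effect:
#' \deqn{O_i \sim Poisson(E_i \theta_i), \quad
#'       \log\theta_i = \beta_0 + u_i + v_i,}
#' with `u` intrinsic CAR (Besag) given the contiguity graph, constrained to
#' sum to zero per connected component, and `v_i ~ N(0, 1/tau_v)`. The
#' relative risk `theta_i` shrinks each area's crude rate toward its
#' neighbourhood and the global mean. Isolated areas carry only the
#' unstructured effect.
#'
#' Inference is Metropolis-within-Gibbs: single-site updates of `u`
#' performed simultaneously over the color classes of a proper graph
#' coloring (so no two neighbours move together), vectorised independent
#' updates of `v` and `beta0`, conjugate Gamma draws for the precisions,
#' and sum-to-zero recentering of `u` each sweep (the removed component
#' mean is absorbed into `beta0`). Each site update is an independence
#' Metropolis-Hastings step proposing from a Gaussian approximation at the
#' mode of the log-concave full conditional, so proposals self-adapt; an
#' interweaving (non-centered) update of each log precision removes the
#' funnel between a near-zero field and its precision. Split-Rhat over
#' chains is reported for `beta0` and the log precisions; a fit whose
#' largest Rhat exceeds `rhat_threshold` is flagged (`converged = FALSE`)
#' with a warning, never silently returned as clean.
#'
#' @param O,E observed and expected counts per area (`E > 0` wherever the
#'   area enters the likelihood).
#' @param graph an [adjacency_graph]; components of size >= 2 carry the
#'   structured effect.
#' @param tau_prior Gamma(shape, rate) prior on both precisions; the diffuse
#'   disease-mapping default Gamma(1, 5e-4) unless overridden.
#' @param chains,iter,burnin MCMC layout: `chains` chains of `iter`
#'   post-burn-in draws each after `burnin` adaptation sweeps.
#' @param seed integer seed.
#' @param rhat_threshold convergence flag threshold on split-Rhat.
#' @param fix_tau_u,fix_tau_v optionally hold a precision fixed at a given
#'   value instead of sampling it (hyperparameter sensitivity checks).
#' @return Object of class `bym_fit`: posterior summaries of `theta`
#'   (`theta_mean`, `theta_sd`, `theta_q`), `beta0`/precision samples and
#'   summaries, deviance bookkeeping (`dic`, `pd`, `deviance_mean`),
#'   `rhat`, `converged`, and the inputs.
#' @export
fit_bym <- function(O, E, graph, tau_prior = c(1, 5e-4),
                    chains = 4, iter = 5000, burnin = 2000,
                    seed = 1, rhat_threshold = 1.1,
                    fix_tau_u = NULL, fix_tau_v = NULL) {
  n <- graph$n
  stopifnot(length(O) == n, length(E) == n)
  if (any(E <= 0)) stop("E must be positive for every area")
  set.seed(seed)
  icar <- icar_structure(graph)
  Q <- icar$Q
  W <- Matrix::Diagonal(x = Matrix::diag(Q)) - Q
  deg <- Matrix::diag(Q)
  isolated <- deg == 0
  comp <- graph$components
  ncomp <- max(comp)
  rank_q <- n - ncomp
  colr <- graph_coloring(graph)
  classes <- split(which(!isolated), colr[!isolated])
  a0 <- tau_prior[1]; b0 <- tau_prior[2]

  # Independence MH step for the site conditional
  #   f(x) = O x - c e^x - (a/2) x^2 + b x
  # using a Gaussian proposal at the conditional mode (Newton, vectorised).
  # The proposal adapts itself to the conditional, so mixing stays good even
  # deep in the precision funnel.
  site_update <- function(x, Osite, cc, a, b) {
    xh <- x
    for (k in 1:12) {
      g1 <- Osite - cc * exp(xh) - a * xh + b
      g2 <- -cc * exp(xh) - a
      xh <- xh - g1 / g2
    }
    sdv <- 1 / sqrt(cc * exp(xh) + a)
    xp <- xh + sdv * stats::rnorm(length(x))
    lf <- function(z) Osite * z - cc * exp(z) - 0.5 * a * z^2 + b * z
    la <- lf(xp) - lf(x) +
      stats::dnorm(x, xh, sdv, log = TRUE) -
      stats::dnorm(xp, xh, sdv, log = TRUE)
    acc <- log(stats::runif(length(x))) < la
    x[acc] <- xp[acc]
    x
  }

  run_chain <- function(chain_id) {
    beta0 <- log(sum(O) / sum(E)) + stats::rnorm(1, 0, 0.1)
    u <- numeric(n); v <- stats::rnorm(n, 0, 0.05)
    tau_u <- 10; tau_v <- 10
    keep <- matrix(0, iter, 3,
                   dimnames = list(NULL, c("beta0", "tau_u", "tau_v")))
    eta_sum <- numeric(n)
    u_sum <- numeric(n); v_sum <- numeric(n)
    theta_draws <- matrix(0, iter, n)
    dev <- numeric(iter)
    total <- burnin + iter
    for (t in seq_len(total)) {
      # structured effect by color class (no neighbours updated together)
      for (cls in classes) {
        S <- as.numeric(W[cls, , drop = FALSE] %*% u)
        u[cls] <- site_update(u[cls], O[cls], E[cls] * exp(beta0 + v[cls]),
                              tau_u * deg[cls], tau_u * S)
      }
      # recenter per component; absorb the mean shift into the intercept
      m <- stats::ave(u, comp)
      u <- u - m
      if (ncomp == 1L) beta0 <- beta0 + m[1]
      # unstructured effect, independent full conditionals
      v <- site_update(v, O, E * exp(beta0 + u), rep(tau_v, n), 0)
      # intercept (prior N(0, 100))
      beta0 <- site_update(beta0, sum(O), sum(E * exp(u + v)), 1 / 100, 0)
      # precisions: conjugate Gibbs, then an interweaving (non-centered) MH
      # step on log tau that breaks the funnel between a near-zero field and
      # its precision (likelihood evaluated with the rescaled field; the
      # prior and Jacobian terms cancel in the non-centered parameterisation)
      tau_u <- fix_tau_u %||% stats::rgamma(1, a0 + rank_q / 2,
                                            b0 + as.numeric(u %*% (Q %*% u)) / 2)
      tau_v <- fix_tau_v %||% stats::rgamma(1, a0 + n / 2, b0 + sum(v^2) / 2)
      loglik_uv <- function(uu, vv)
        sum(O * (uu + vv) - E * exp(beta0 + uu + vv))
      if (any(!isolated) && is.null(fix_tau_u)) {
        w <- sqrt(tau_u) * u
        ltp <- log(tau_u) + stats::rnorm(1, 0, 1)
        la <- loglik_uv(w / sqrt(exp(ltp)), v) - loglik_uv(u, v) +
          a0 * (ltp - log(tau_u)) - b0 * (exp(ltp) - tau_u)
        if (log(stats::runif(1)) < la) tau_u <- exp(ltp)
        u <- w / sqrt(tau_u)
      }
      if (is.null(fix_tau_v)) {
        w <- sqrt(tau_v) * v
        ltp <- log(tau_v) + stats::rnorm(1, 0, 1)
        la <- loglik_uv(u, w / sqrt(exp(ltp))) - loglik_uv(u, v) +
          a0 * (ltp - log(tau_v)) - b0 * (exp(ltp) - tau_v)
        if (log(stats::runif(1)) < la) tau_v <- exp(ltp)
        v <- w / sqrt(tau_v)
      }
      if (t > burnin) {
        k <- t - burnin
        keep[k, ] <- c(beta0, tau_u, tau_v)
        eta <- beta0 + u + v
        th <- exp(eta)
        theta_draws[k, ] <- th
        eta_sum <- eta_sum + eta
        u_sum <- u_sum + u; v_sum <- v_sum + v
        dev[k] <- -2 * sum(stats::dpois(O, E * th, log = TRUE))
      }
    }
    list(keep = keep, theta = theta_draws, eta_mean = eta_sum / iter,
         u_mean = u_sum / iter, v_mean = v_sum / iter, dev = dev)
  }

  res <- lapply(seq_len(chains), run_chain)
  keep <- do.call(rbind, lapply(res, `[[`, "keep"))
  theta <- do.call(rbind, lapply(res, `[[`, "theta"))
  dev <- unlist(lapply(res, `[[`, "dev"))
  eta_mean <- Reduce(`+`, lapply(res, `[[`, "eta_mean")) / chains
  u_mean <- Reduce(`+`, lapply(res, `[[`, "u_mean")) / chains
  v_mean <- Reduce(`+`, lapply(res, `[[`, "v_mean")) / chains
  rhat <- c(beta0 = split_rhat(sapply(res, function(r) r$keep[, "beta0"])),
            log_tau_u = split_rhat(sapply(res, function(r) log(r$keep[, "tau_u"]))),
            log_tau_v = split_rhat(sapply(res, function(r) log(r$keep[, "tau_v"]))))
  converged <- all(is.finite(rhat)) && max(rhat) < rhat_threshold
  if (!converged)
    warning("BYM sampler not converged (max split-Rhat = ",
            round(max(rhat), 3), "); results are flagged")
  dbar <- mean(dev)
  dhat <- -2 * sum(stats::dpois(O, E * exp(eta_mean), log = TRUE))
  pd <- dbar - dhat
  qs <- apply(theta, 2, stats::quantile, c(0.025, 0.5, 0.975))
  structure(list(theta_mean = colMeans(theta),
                 theta_sd = apply(theta, 2, stats::sd),
                 theta_q = t(qs),
                 log_theta_mean = eta_mean,
                 u_mean = u_mean, v_mean = v_mean,
                 samples = keep,
                 beta0 = mean(keep[, "beta0"]),
                 tau_u = mean(keep[, "tau_u"]),
                 tau_v = mean(keep[, "tau_v"]),
                 deviance_samples = dev,
                 deviance_mean = dbar, deviance_at_mean = dhat,
                 pd = pd, dic = dbar + pd,
                 rhat = rhat, converged = converged,
                 O = O, E = E, area_ids = graph$area_ids,
                 chains = chains, iter = iter, burnin = burnin,
                 seed = seed),
            class = "bym_fit")
}

# split-Rhat over a draws x chains matrix
split_rhat <- function(x) {
  x <- as.matrix(x)
  half <- floor(nrow(x) / 2)
  if (half < 2) return(NA_real_)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  m <- ncol(xs); nn <- nrow(xs)
  mu <- colMeans(xs); s2 <- apply(xs, 2, stats::var)
  W <- mean(s2); B <- nn * stats::var(mu)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("BYM disease-mapping fit:", length(x$O), "areas,",
      x$chains, "chains x", x$iter, "draws\n")
  cat(sprintf("  beta0 %.3f  tau_u %.1f  tau_v %.1f  DIC %.1f (pD %.1f)\n",
              x$beta0, x$tau_u, x$tau_v, x$dic, x$pd))
  cat(sprintf("  max split-Rhat %.3f (%s)\n", max(x$rhat),
              if (x$converged) "converged" else "NOT CONVERGED"))
  invisible(x)
}

#' @export
summary.bym_fit <- function(object, ...) {
  data.frame(area_id = object$area_ids, O = object$O, E = object$E,
             theta_mean = object$theta_mean, theta_sd = object$theta_sd,
             q2.5 = object$theta_q[, 1], q50 = object$theta_q[, 2],
             q97.5 = object$theta_q[, 3])
}

#' @export
coef.bym_fit <- function(object, ...) {
  c(beta0 = object$beta0, tau_u = object$tau_u, tau_v = object$tau_v)
}

#' @export
fitted.bym_fit <- function(object, ...) object$theta_mean

#' Smoothed unenrollment rates from a BYM fit
#'
#' Converts posterior-mean relative risks to the mapped rate scale:
#' `rate_i = theta_i * global_rate`.
#'
#' @param fit a [fit_bym] result (or a numeric vector of relative risks).
#' @param global_rate the global unenrollment rate (e.g. 0.368).
#' @return numeric vector of smoothed per-area rates.
#' @export
smoothed_rates <- function(fit, global_rate) {
  theta <- if (inherits(fit, "bym_fit")) fit$theta_mean else as.numeric(fit)
  if (global_rate < 0) stop("global_rate must be >= 0")
  theta * global_rate
}
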
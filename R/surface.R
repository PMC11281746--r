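#' Matern covariance function (smoothness 1)
#'
#' `C(d) = sigma2 * (d/range) * K1(d/range)` with `C(0) = sigma2`, the
#' planar Matern family member with smoothness parameter 1 (the case the
#' SPDE representation with alpha = 2 corresponds to in two dimensions).
#'
#' @param d distances (km), any numeric array.
#' @param range_km range parameter rho (> 0).
#' @param sigma2 marginal variance.
#' @return covariances, same shape as `d`.
#' @export
matern_cov <- function(d, range_km, sigma2 = 1) {
  out <- d / range_km
  pos <- out > 0
  out[pos] <- out[pos] * besselK(out[pos], 1)
  out[!pos] <- 1
  sigma2 * out
}

#' Interpolate area values to a continuous surface
#'
#' Gaussian-process regression with a Matern (smoothness 1) covariance on
#' the area centroids, producing a smooth rate surface on a regular km grid.
#' Used to turn the smoothed per-area rates of the disease-mapping model
#' into a boundary-free map. With a vanishing nugget the surface
#' interpolates the centroid values exactly; far from all centroids it
#' reverts to the fitted constant mean.
#'
#' @param centroids two-column matrix/data frame of centroid km coordinates.
#' @param values one value per centroid (e.g. smoothed rates).
#' @param grid_spec list with either `nx`, `ny` (grid points per axis,
#'   default 200) or `spacing` (km); the grid covers the centroid bounding
#'   box.
#' @param range_km,marginal_sd Matern parameters; `NULL` (default) fits both
#'   by maximum likelihood (profile likelihood over the range).
#' @param nugget small observation variance added to the diagonal
#'   (default 1e-8 times the data variance, for numerical interpolation).
#' @return Object of class `rate_surface`: grid vectors `x`, `y`, matrix
#'   `values` (rows = y, columns = x), fitted `matern` parameters
#'   (`range_km`, `marginal_sd`, `smoothness = 1`), constant `mean`, and
#'   the training data for further prediction via [predict.rate_surface].
#' @export
interpolate_surface <- function(centroids, values, grid_spec = list(),
                                range_km = NULL, marginal_sd = NULL,
                                nugget = NULL) {
  xy <- as.matrix(centroids)[, 1:2, drop = FALSE]
  n <- nrow(xy)
  if (n < 3) stop("need at least 3 centroids")
  D <- as.matrix(stats::dist(xy))
  dup <- which(D == 0 & upper.tri(D), arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicate centroids at indices: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "))
  vy <- stats::var(values)
  if (is.null(nugget)) nugget <- 1e-8 * max(vy, 1e-12)
  dmax <- max(D)
  if (vy == 0) {
    range_km <- range_km %||% dmax / 4
    marginal_sd <- marginal_sd %||% 0
    mu <- values[1]
    alpha <- numeric(n)
  } else {
    if (is.null(range_km)) {
      prof <- function(lrho) {
        R <- matern_cov(D, exp(lrho)) + diag(nugget / max(vy, nugget), n)
        ch <- tryCatch(chol(R), error = function(e) NULL)
        if (is.null(ch)) return(1e10)
        Ri_y <- backsolve(ch, forwardsolve(t(ch), values))
        Ri_1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
        mu <- sum(Ri_y * 1) / sum(Ri_1 * 1)
        r <- values - mu
        Ri_r <- backsolve(ch, forwardsolve(t(ch), r))
        s2 <- sum(r * Ri_r) / n
        n / 2 * log(max(s2, 1e-300)) + sum(log(diag(ch)))
      }
      lrho <- stats::optimize(prof, c(log(dmax / 100), log(2 * dmax)))$minimum
      range_km <- exp(lrho)
    }
    R <- matern_cov(D, range_km) + diag(nugget / max(vy, nugget), n)
    Ri <- solve(R)
    one <- rep(1, n)
    mu <- as.numeric((one %*% Ri %*% values) / (one %*% Ri %*% one))
    if (is.null(marginal_sd)) {
      r <- values - mu
      marginal_sd <- sqrt(max(as.numeric(r %*% Ri %*% r) / n, 0) * 1)
    }
    alpha <- as.numeric(Ri %*% (values - mu))
  }
  bb <- apply(xy, 2, range)
  if (!is.null(grid_spec$spacing)) {
    gx <- seq(bb[1, 1], bb[2, 1], by = grid_spec$spacing)
    gy <- seq(bb[1, 2], bb[2, 2], by = grid_spec$spacing)
  } else {
    nx <- grid_spec$nx %||% 200; ny <- grid_spec$ny %||% 200
    gx <- seq(bb[1, 1], bb[2, 1], length.out = nx)
    gy <- seq(bb[1, 2], bb[2, 2], length.out = ny)
  }
  obj <- structure(list(x = gx, y = gy, values = NULL,
                        matern = list(range_km = range_km,
                                      marginal_sd = marginal_sd,
                                      smoothness = 1),
                        mean = mu, nugget = nugget,
                        centroids = xy, alpha = alpha),
                   class = "rate_surface")
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  pred <- predict(obj, grid)
  obj$values <- matrix(pred, nrow = length(gy), ncol = length(gx),
                       byrow = TRUE)
  obj
}

#' Predict a fitted rate surface at new locations
#'
#' @param object a `rate_surface`.
#' @param newdata two-column matrix of km coordinates.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.rate_surface <- function(object, newdata, ...) {
  P <- as.matrix(newdata)[, 1:2, drop = FALSE]
  if (all(object$alpha == 0)) return(rep(object$mean, nrow(P)))
  d2 <- outer(P[, 1], object$centroids[, 1], "-")^2 +
    outer(P[, 2], object$centroids[, 2], "-")^2
  K <- matern_cov(sqrt(d2), object$matern$range_km)
  as.numeric(object$mean + K %*% object$alpha)
}

#' @export
print.rate_surface <- function(x, ...) {
  cat(sprintf(
    "Rate surface: %d x %d grid; Matern(range %.2f km, sd %.4f, smoothness 1), mean %.4f\n",
    length(x$x), length(x$y), x$matern$range_km, x$matern$marginal_sd, x$mean))
  invisible(x)
}

#' Write a surface as an x,y,value CSV grid
#'
#' @param surface a `rate_surface`.
#' @param path output CSV path.
#' @export
write_surface_csv <- function(surface, path) {
  df <- expand.grid(x = surface$x, y = surface$y)
  df$value <- as.numeric(t(surface$values))
  utils::write.csv(round_numeric(df), path, row.names = FALSE)
  invisible(path)
}
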
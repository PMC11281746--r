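test_that("VIF is 1 for orthogonal designs and flags collinearity", {
  n <- 400
  # exactly orthogonal columns via QR
  set.seed(1)
  Qm <- qr.Q(qr(cbind(1, matrix(rnorm(n * 3), n, 3))))[, -1]
  v <- compute_vif(data.frame(a = Qm[, 1], b = Qm[, 2], c = Qm[, 3]))
  expect_true(all(abs(v - 1) < 1e-6))
  # duplicate column: infinite VIF, flagged
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  d$c <- d$a
  v2 <- compute_vif(d)
  expect_true(is.infinite(v2["a"]) && is.infinite(v2["c"]))
  expect_true(all(c("a", "c") %in% attr(v2, "flagged")))
})

test_that("a correlation-0.9 pair yields VIF 1/(1-0.81)", {
  set.seed(2)
  n <- 10000
  x1 <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x1))                 # exactly orthogonal to x1
  x1s <- (x1 - mean(x1)) / sd(x1)
  x2 <- 0.9 * x1s + sqrt(1 - 0.81) * (e - mean(e)) / sd(e)
  others <- qr.Q(qr(matrix(rnorm(n * 2), n, 2)))
  v <- compute_vif(data.frame(x1 = x1s, x2 = x2,
                              z1 = others[, 1], z2 = others[, 2]))
  expect_equal(unname(v["x1"]), 1 / (1 - 0.81), tolerance = 0.05 / 5.263)
  expect_equal(unname(v["x2"]), 5.263, tolerance = 0.05 / 5.263)
})

test_that("DIC identity and degenerate cases", {
  r <- compute_dic(c(10, 12, 14), 11)
  expect_equal(r$Dbar, 12)
  expect_equal(r$pD, 1)
  expect_equal(r$DIC, 13)
  # degenerate posterior: all deviances equal
  r2 <- compute_dic(rep(8, 10), 8)
  expect_equal(r2$pD, 0)
  expect_equal(r2$DIC, 8)
  expect_error(compute_dic(5, 5), ">= 2")
})

test_that("non-spatial Bayesian fit agrees with ML logistic regression", {
  set.seed(3)
  n <- 20000
  male <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 55, 15)
  eta <- -0.5 + log(0.938) * male - 0.003 * age
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(unenrolled = y, male = male, age = age)
  fit <- fit_global(unenrolled ~ male + age, d, effect = "none", seed = 1)
  ml <- glm(unenrolled ~ male + age, binomial, d)
  expect_true(all(abs(coef(fit) - coef(ml)) < fit$summary$sd / 10))
  # OR table has one row per design column and preserves coefficient order
  ort <- odds_ratio_table(fit)
  expect_equal(nrow(ort), 3L)
  expect_equal(order(coef(fit)), order(ort$or))
})

test_that("odds-ratio table degenerates correctly at a point posterior", {
  fake <- list(beta_draws = matrix(0, 50, 2,
                                   dimnames = list(NULL, c("a", "b"))))
  ort <- odds_ratio_table(fake)
  expect_equal(ort$or, c(1, 1))
  expect_equal(ort$ci_2.5, c(1, 1))
  expect_equal(ort$ci_97.5, c(1, 1))
  # symmetric draws: median OR of 1
  fake2 <- list(beta_draws = matrix(c(-0.1, 0, 0.1), ncol = 1,
                                    dimnames = list(NULL, "a")))
  expect_equal(median(exp(fake2$beta_draws)), 1)
})

test_that("odds ratios convert to the reported percent changes", {
  expect_equal(percent_change(0.938), -6.2)
  expect_equal(percent_change(0.997), -0.3)
  expect_equal(percent_change(1.058), 5.8)
  expect_equal(percent_change(1.100), 10.0)
  expect_equal(percent_change(0.801), -19.9)
  expect_equal(percent_change(0.996), -0.4)
  expect_equal(percent_change(1.0), 0.0)
  expect_error(percent_change(0), "> 0")
})

test_that("effect types agree on fixed effects when no spatial signal exists", {
  set.seed(4)
  g <- lattice_graph(6, 6)
  m <- g$n
  per <- 60
  area <- rep(seq_len(m), each = per)
  male <- rbinom(m * per, 1, 0.5)
  y <- rbinom(m * per, 1, plogis(-0.5 + log(0.9) * male))
  d <- data.frame(unenrolled = y, male = male, area_id = g$area_ids[area])
  fits <- lapply(c("none", "iid", "besag", "bym"), function(ef)
    fit_global(unenrolled ~ male, d, g, effect = ef, seed = 1))
  est <- sapply(fits, function(f) coef(f)["male"])
  sds <- sapply(fits, function(f) f$summary$sd[2])
  for (i in 2:4)
    expect_lt(abs(est[i] - est[1]), 2 * (sds[i] + sds[1]))
  # DIC identity holds on every stored fit
  for (f in fits)
    expect_equal(f$dic,
                 compute_dic(f$deviance_samples, f$deviance_at_mean)$DIC)
})

test_that("separation is flagged but inference still returns", {
  set.seed(5)
  n <- 500
  x <- rbinom(n, 1, 0.5)
  y <- x                                  # perfect predictor
  d <- data.frame(unenrolled = y, x = x)
  expect_warning(fit <- fit_global(unenrolled ~ x, d, effect = "none",
                                   seed = 1),
                 "separation")
  expect_true(fit$separated)
  expect_true(is.finite(fit$dic))
})
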
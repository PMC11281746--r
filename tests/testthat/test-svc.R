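test_that("standardize produces population z-scores and round-trips", {
  z <- standardize(c(1, 2, 3))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(1)
  x <- rnorm(200, 10, 3)
  z2 <- standardize(x)
  expect_lt(abs(mean(z2)), 1e-10)
  expect_equal(sqrt(mean((as.numeric(z2) - mean(z2))^2)), 1, tolerance = 1e-10)
  expect_equal(unstandardize(z2), x)
  expect_error(standardize(rep(2, 5)), "distinct")
})

test_that("graph coarsening contracts blocks and preserves connectivity", {
  gf <- lattice_graph(4, 4)
  # identity mapping: isomorphic graph
  ident <- coarsen_graph(gf, setNames(gf$area_ids, gf$area_ids))
  expect_equal(nrow(ident$graph$edges), nrow(gf$edges))
  expect_equal(max(ident$graph$components), 1L)
  # 4x4 lattice in 2x2 blocks: the coarse graph is the 2x2 lattice (4 edges)
  co <- coarsen_graph(gf, block_mapping(4, 4, 2))
  expect_equal(co$graph$n, 4L)
  expect_equal(nrow(co$graph$edges), 4L)
  expect_equal(max(co$graph$components), 1L)
  # connectivity preserved for random surjective block mappings
  for (s in 1:5) {
    set.seed(s)
    g <- lattice_graph(5, 5)
    mapping <- setNames(as.character(sample(1:6, 25, replace = TRUE)),
                        g$area_ids)
    co2 <- coarsen_graph(g, mapping)
    expect_equal(max(co2$graph$components), 1L)
  }
  expect_error(coarsen_graph(gf, setNames(rep("a", 15),
                                          gf$area_ids[1:15])),
               "coarse assignment")
})

test_that("exceedance counts draws on the requested side of OR = 1", {
  expect_equal(exceedance(c(0.5, 1, 2)), 1)            # all positive
  expect_equal(exceedance(c(-1, -1, 1, 3)), 0.5)
  expect_equal(exceedance(c(-1, -1, 1, 3), "less"), 0.5)
  set.seed(2)
  s <- rnorm(5000)
  expect_equal(exceedance(s), 0.5, tolerance = 0.05)
  expect_equal(exceedance(s) + exceedance(s, "less"), 1)
  # monotone in a location shift
  expect_gt(exceedance(s + 0.5), exceedance(s))
  # matrix input: one probability per unit
  m <- rbind(rep(1, 10), rep(-1, 10))
  expect_equal(exceedance(m), c(1, 0))
})

test_that("probability bands use the documented boundary rule", {
  expect_equal(band_probability(0.85), ">0.8")
  expect_equal(band_probability(0.8), "0.6-0.8")
  expect_equal(band_probability(0.6), "0.6-0.8")
  expect_equal(band_probability(0.59), "<0.6")
  expect_equal(band_probability(c(0, 1)), c("<0.6", ">0.8"))
  expect_error(band_probability(1.2), "\\[0, 1\\]")
})

test_that("SVC fit recovers structure and respects its constraints", {
  set.seed(3)
  gf <- lattice_graph(8, 8)
  coarse <- coarsen_graph(gf, block_mapping(8, 8, 2))  # 16 units
  delta <- sample_icar_field(coarse$graph, 0.6, seed = 4)
  n <- 12000
  fine <- sample(gf$area_ids, n, replace = TRUE)
  unit <- match(coarse$mapping[fine], coarse$coarse_ids)
  male <- rbinom(n, 1, 0.5)
  age <- rnorm(n, 55, 15)
  eta <- -0.4 + (log(0.9) + delta[unit]) * male + 0.002 * age
  y <- rbinom(n, 1, plogis(eta))
  d <- data.frame(unenrolled = y, male = male, age = age, area_id = fine)
  fit <- fit_svc(unenrolled ~ male + age, d, coarse, svc_covariates = "male",
                 seed = 1)
  f <- fit$fields$male
  expect_equal(nrow(f), 16L)
  expect_gt(cor(f$coef_mean, log(0.9) + delta), 0.5)
  # per-unit deviations average to ~0 (sum-to-zero prior)
  expect_lt(abs(mean(f$coef_mean - coef(fit)["male"])), 0.05)
  expect_true(all(f$exceedance >= 0 & f$exceedance <= 1))
  expect_true(all(f$band %in% c("<0.6", "0.6-0.8", ">0.8")))
  # age was standardized and its scaler stored for back-transformation
  expect_true("age" %in% names(fit$scalers))
  expect_equal(unname(fit$scalers$age["center"]), mean(age))
  # DIC bookkeeping is self-consistent
  expect_equal(fit$dic,
               compute_dic(fit$deviance_samples, fit$deviance_at_mean)$DIC)
})

test_that("mean of per-unit total coefficients tracks the global estimate", {
  set.seed(6)
  gf <- lattice_graph(6, 6)
  coarse <- coarsen_graph(gf, block_mapping(6, 6, 2))
  n <- 8000
  fine <- sample(gf$area_ids, n, replace = TRUE)
  male <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.4 + log(0.85) * male))
  d <- data.frame(unenrolled = y, male = male, area_id = fine)
  svc <- fit_svc(unenrolled ~ male, d, coarse, svc_covariates = "male",
                 seed = 1)
  glob <- fit_global(unenrolled ~ male, d, effect = "none", seed = 1)
  expect_lt(abs(mean(svc$fields$male$coef_mean) - coef(glob)["male"]),
            2 * glob$summary$sd[2])
})
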
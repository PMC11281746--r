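test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(4, 4, mean_insurants_per_area = 50, seed = 1)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$insurants, s2$insurants)
  expect_identical(s1$covariates, s2$covariates)
  expect_identical(s1$ground_truth$structured_field,
                   s2$ground_truth$structured_field)
})

test_that("lattice dimensions give the expected areas and grid edges", {
  r <- generate_region(sim_config(10, 10, seed = 2))
  expect_equal(nrow(r$areas), 100L)
  expect_equal(nrow(r$graph$edges), 180L)  # 2 * 10 * 9
  # Poisson(300) sum over 100 areas: within 3 sd of 30,000
  expect_lt(abs(sum(r$areas$n_insurants) - 30000), 3 * sqrt(30000))
})

test_that("ICAR field draws respect scale and constraints", {
  g <- lattice_graph(6, 6)
  expect_equal(sample_icar_field(g, 0, seed = 1), numeric(36))
  f <- sample_icar_field(g, 1.3, seed = 2)
  expect_equal(sd(f), 1.3)
  expect_lt(abs(mean(f)), 1e-10)              # sum-to-zero (one component)
  expect_error(sample_icar_field(g, -1), ">= 0")
  # per-component zero mean on a disconnected graph
  a <- areas_from_polys(list(square_poly(0, 0), square_poly(1, 0),
                             square_poly(5, 5), square_poly(6, 5)))
  gd <- build_adjacency(a)
  fd <- sample_icar_field(gd, 1, seed = 3)
  for (cmp in unique(gd$components))
    expect_lt(abs(mean(fd[gd$components == cmp])), 1e-10)
})

test_that("ICAR fields are positively autocorrelated (Moran's I)", {
  g <- lattice_graph(12, 12)
  hits <- 0L
  for (s in 1:100) {
    f <- sample_icar_field(g, 1, seed = s)
    if (morans_i(f, g) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("diabetic prevalence is calibrated near its target", {
  sim <- simulate_study(sim_config(10, 10, mean_insurants_per_area = 300,
                                   seed = 4))
  expect_gte(nrow(sim$insurants), 25000)
  frac <- mean(sim$insurants$diabetic)
  expect_gt(frac, 0.15); expect_lt(frac, 0.20)
  # diabetics are older on average than the general roster
  expect_gt(mean(sim$insurants$age[sim$insurants$diabetic == 1]),
            mean(sim$insurants$age))
})

test_that("enrollment outcome follows the configured logit", {
  sim0 <- generate_region(sim_config(6, 6, mean_insurants_per_area = 300,
                                     seed = 5))
  cov <- merge(sim0$covariates,
               compute_deprivation(sim0$covariates)[, c("area_id",
                                                        "deprivation")],
               by = "area_id", sort = FALSE)
  zero <- lapply(sim_config()$enrollment_coefficients, function(x) 0)
  # intercept 0, all coefficients 0: unenrollment ~ 0.5
  cfg0 <- sim_config(6, 6, enrollment_coefficients = zero, seed = 5)
  ins <- generate_insurants(sim0, cov, cfg0)
  ins$diabetic <- 1L   # use the whole roster for a tight binomial check
  out <- assign_enrollment(ins, cfg0, cov)
  expect_lt(abs(mean(out$unenrolled) - 0.5), 0.02)
  # intercept logit(0.368): unenrollment ~ 0.368
  zi <- zero; zi$intercept <- qlogis(0.368)
  out2 <- assign_enrollment(ins, sim_config(6, 6, enrollment_coefficients = zi),
                            cov)
  expect_lt(abs(mean(out2$unenrolled) - 0.368), 0.02)
  # a male log-OR of log(0.938) reproduces the odds ratio empirically
  zm <- zero; zm$intercept <- qlogis(0.4); zm$male <- log(0.938)
  big <- ins[rep(seq_len(nrow(ins)), 10), ]   # ~ 100k rows
  set.seed(99)
  out3 <- assign_enrollment(big, sim_config(6, 6, enrollment_coefficients = zm),
                            cov)
  tab <- table(out3$sex, out3$unenrolled)
  or <- (tab["male", "1"] / tab["male", "0"]) /
    (tab["female", "1"] / tab["female", "0"])
  expect_lt(abs(or - 0.938), 0.03)
  # enrollment undefined outside the diabetic subpopulation
  out4 <- assign_enrollment(generate_insurants(sim0, cov, cfg0), cfg0, cov)
  expect_true(all(is.na(out4$enrolled[out4$diabetic == 0])))
  expect_true(all(!is.na(out4$enrolled[out4$diabetic == 1])))
})

test_that("empirical unenrollment converges to the logit-implied rate", {
  # fixed intercept, no covariates: rate must approach plogis(intercept)
  target <- plogis(-0.3)
  errs <- sapply(c(1000, 10000, 100000), function(n) {
    set.seed(7)
    mean(rbinom(n, 1, target)) - target
  })
  sim <- simulate_study(sim_config(8, 8, mean_insurants_per_area = 200,
                                   seed = 8))
  realized <- mean(sim$insurants$unenrolled[sim$insurants$diabetic == 1])
  expect_lt(abs(realized - 0.368), 0.03)
  expect_true(all(abs(errs) < c(0.05, 0.02, 0.01)))
})

test_that("simulated study carries a complete ground truth", {
  sim <- simulate_study(sim_config(4, 4, mean_insurants_per_area = 60,
                                   svc_fields = c(male = 0.3), seed = 9))
  gt <- sim$ground_truth
  expect_s3_class(gt$config, "sim_config")
  expect_length(gt$structured_field, 16)
  expect_equal(sd(gt$structured_field), gt$config$spatial_sd_structured)
  expect_length(gt$svc_fields$male, 16)
  expect_true(is.finite(gt$enrollment_intercept))
  # per-area counts aggregated back match the roster
  agg <- tapply(sim$insurants$diabetic, sim$insurants$area_id, sum)
  expect_equal(sim$areas$n_diabetics, as.integer(agg[sim$areas$area_id]))
  expect_true(all(sim$areas$n_unenrolled <= sim$areas$n_diabetics))
})

test_that("write_sim artifacts round-trip through the readers", {
  sim <- simulate_study(sim_config(3, 3, mean_insurants_per_area = 40,
                                   seed = 10))
  td <- tempfile()
  write_sim(sim, td)
  areas <- read_areas_geojson(file.path(td, "areas.geojson"))
  expect_equal(areas$n_diabetics, sim$areas$n_diabetics)
  ins <- read.csv(file.path(td, "insurants.csv"))
  expect_equal(nrow(ins), nrow(sim$insurants))
  gt <- jsonlite::read_json(file.path(td, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$config$n_rows, 3)
})
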
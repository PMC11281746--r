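test_that("Poisson LLR matches direct evaluation", {
  # equal in/out rates: indicator fails, LLR is 0
  expect_equal(poisson_llr(10, 10, 100, 100), 0)
  expect_equal(poisson_llr(20, 10, 100, 100), 20 * log(2) + 80 * log(80 / 90),
               tolerance = 1e-10)
  expect_equal(poisson_llr(20, 10, 100, 100), 4.4403, tolerance = 1e-3)
  # all cases inside with half the expectation: second term 0 by convention
  expect_equal(poisson_llr(100, 50, 100, 100), 100 * log(2))
  expect_error(poisson_llr(5, 0, 10, 10), "E_in")
})

test_that("windows grow by next-nearest centroid within the radius cap", {
  # three collinear centroids at 0, 10, 25 km
  D <- as.matrix(dist(cbind(c(0, 10, 25), 0)))
  rownames(D) <- colnames(D) <- c("A", "B", "C")
  w <- enumerate_windows(D, 30)
  from_a <- Filter(function(x) x$center == 1, w)
  expect_equal(lapply(from_a, `[[`, "members"),
               list(1L, c(1L, 2L), c(1L, 2L, 3L)))
  # radius 0: singleton windows only
  w0 <- enumerate_windows(D, 0)
  expect_length(w0, 3L)
  expect_true(all(vapply(w0, function(x) length(x$members), 1L) == 1L))
  expect_error(enumerate_windows(D, -1), ">= 0")
})

test_that("window membership equals brute-force ball membership", {
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:12, 1)
    xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
    D <- as.matrix(dist(xy))
    maxr <- runif(1, 2, 12)
    for (win in enumerate_windows(D, maxr)) {
      ball <- which(D[win$center, ] <= win$radius_km)
      expect_setequal(win$members, ball)
      expect_lte(win$radius_km, maxr)
      expect_true(win$center %in% win$members)
    }
  }
})

test_that("max-LLR detection agrees with exhaustive search on small maps", {
  for (s in 1:30) {
    set.seed(s)
    n <- sample(5:12, 1)
    xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
    D <- as.matrix(dist(xy))
    E <- runif(n, 5, 20)
    O <- rpois(n, E * sample(c(1, 1, 3), n, replace = TRUE))
    if (sum(O) == 0) next
    res <- detect_clusters(O, E, D, max_radius_km = 20, n_sim = 19, seed = s)
    expect_equal(res$clusters$llr[1], brute_force_max_llr(O, E, D),
                 tolerance = 1e-10)
  }
})

test_that("Monte-Carlo null is seeded, reproducible and non-negative", {
  set.seed(1)
  xy <- matrix(runif(20, 0, 10), ncol = 2)
  D <- as.matrix(dist(xy))
  E <- rep(10, 10)
  a <- monte_carlo_null(100, E, D, 30, n_sim = 50, seed = 7)
  b <- monte_carlo_null(100, E, D, 30, n_sim = 50, seed = 7)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  # the conventional default replication count
  expect_equal(eval(formals(detect_clusters)$n_sim), 9999)
})

test_that("p-value equals (1 + exceedances) / (1 + n_sim)", {
  # overwhelming cluster: observed LLR beats every null replicate
  g <- lattice_areas(4, 3)
  D <- suppressWarnings(centroid_distances(g))
  E <- rep(50, 12)
  O <- rep(50, 12); O[5] <- 500
  res <- detect_clusters(O, E, D, max_radius_km = 5, n_sim = 9999, seed = 1)
  expect_equal(res$clusters$p_value[1], 1e-4)
  expect_equal(res$clusters$center_area_id[1], g$area_id[5])
})

test_that("LLR is invariant under joint relabelling of areas", {
  set.seed(2)
  n <- 9
  xy <- matrix(runif(2 * n, 0, 10), ncol = 2)
  D <- as.matrix(dist(xy))
  E <- runif(n, 5, 15); O <- rpois(n, E)
  perm <- sample(n)
  r1 <- detect_clusters(O, E, D, 20, n_sim = 9, seed = 3)
  r2 <- detect_clusters(O[perm], E[perm], D[perm, perm], 20, n_sim = 9,
                        seed = 3)
  expect_equal(r1$clusters$llr[1], r2$clusters$llr[1])
})

test_that("secondary clusters never share member areas", {
  set.seed(6)
  a <- lattice_areas(6, 6)
  D <- suppressWarnings(centroid_distances(a))
  E <- rep(50, 36)
  O <- rep(50, 36); O[c(1, 2)] <- 150; O[c(35, 36)] <- 140
  res <- detect_clusters(O, E, D, max_radius_km = 1.5, n_sim = 99, seed = 1,
                         area_ids = a$area_id)
  expect_gte(nrow(res$clusters), 2L)
  all_members <- unlist(res$member_ids)
  expect_equal(anyDuplicated(all_members), 0L)
  expect_true(all(diff(res$clusters$llr) <= 0))
})

test_that("an all-zero count map yields an empty result with a warning", {
  D <- as.matrix(dist(cbind(1:4, 0)))
  expect_warning(res <- detect_clusters(rep(0, 4), rep(1, 4), D, 10,
                                        n_sim = 9),
                 "zero")
  expect_equal(nrow(res$clusters), 0L)
})
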
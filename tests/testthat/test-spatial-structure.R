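test_that("shared-border contiguity: full side yes, corner touch no", {
  # two unit squares sharing a full side
  a <- areas_from_polys(list(square_poly(0, 0), square_poly(1, 0)))
  g <- build_adjacency(a)
  expect_equal(nrow(g$edges), 1L)
  # touching only at a corner point: zero-length intersection, no edge
  b <- areas_from_polys(list(square_poly(0, 0), square_poly(1, 1)))
  expect_equal(nrow(build_adjacency(b)$edges), 0L)
  # disjoint squares
  d <- areas_from_polys(list(square_poly(0, 0), square_poly(3, 0)))
  expect_equal(nrow(build_adjacency(d)$edges), 0L)
})

test_that("3x3 grid adjacency matches brute-force boundary enumeration", {
  a <- lattice_areas(3, 3)
  g <- build_adjacency(a)
  expect_equal(nrow(g$edges), 12L)
  # center cell (r2c2) has 4 neighbours
  center <- which(a$area_id == "r2c2")
  expect_equal(sum(g$edges == center), 4L)
  # brute force over all 36 pairs using the segment-overlap predicate on
  # raw polygons (shares a unit side iff |dr|+|dc| == 1 on the grid)
  rc <- cbind(rep(1:3, each = 3), rep(1:3, 3))
  ids <- sprintf("r%dc%d", rc[, 1], rc[, 2])
  expected <- 0L
  for (i in 1:8) for (j in (i + 1):9) {
    if (sum(abs(rc[i, ] - rc[j, ])) == 1) expected <- expected + 1L
  }
  expect_equal(nrow(g$edges), expected)
})

test_that("adjacency is symmetric and self-loop-free on random lattices", {
  for (s in 1:5) {
    set.seed(s)
    nr <- sample(2:5, 1); nc <- sample(2:5, 1)
    g <- lattice_graph(nr, nc)
    expect_true(all(g$edges[, 1] < g$edges[, 2]))   # stored upper-triangular
    expect_false(any(g$edges[, 1] == g$edges[, 2]))
    # grid edge count: nr*(nc-1) + nc*(nr-1)
    expect_equal(nrow(g$edges), nr * (nc - 1) + nc * (nr - 1))
  }
})

test_that("self-intersecting polygons are rejected with the offending id", {
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  info <- data.frame(area_id = "bt", x = 0.5, y = 0.5, n_insurants = 1L,
                     n_diabetics = 0L, n_unenrolled = 0L)
  expect_error(area_set(info, list(bowtie)), "bt")
})

test_that("ICAR structure matrix is the graph Laplacian", {
  # path graph a-b-c built from three squares in a row
  a <- areas_from_polys(list(square_poly(0, 0), square_poly(1, 0),
                             square_poly(2, 0)))
  Q <- as.matrix(icar_structure(build_adjacency(a))$Q)
  expect_equal(unname(Q),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  # rows sum to zero for arbitrary graphs
  g <- lattice_graph(4, 5)
  expect_equal(max(abs(Matrix::rowSums(icar_structure(g)$Q))), 0)
})

test_that("ICAR rank deficiency equals the number of components", {
  # connected 3x3 grid: rank 8
  Q <- as.matrix(icar_structure(lattice_graph(3, 3))$Q)
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8), 1L)
  expect_equal(qr(Q)$rank, 8L)
  # random graphs up to 50 nodes: zero eigenvalues == components
  for (s in 1:6) {
    set.seed(s)
    n <- sample(5:50, 1)
    ne <- sample(0:(2 * n), 1)
    edges <- unique(t(replicate(ne, sort(sample(n, 2)))))
    g <- enrollscape:::new_adjacency_graph(as.character(seq_len(n)), edges)
    Q <- as.matrix(icar_structure(g)$Q)
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8), max(g$components))
  }
})

test_that("isolated areas are retained and flagged", {
  a <- areas_from_polys(list(square_poly(0, 0), square_poly(1, 0),
                             square_poly(5, 5)))
  g <- build_adjacency(a)
  ic <- icar_structure(g)
  expect_equal(ic$isolated, 3L)
  expect_equal(max(g$components), 2L)
  expect_equal(as.numeric(ic$Q[3, ]), c(0, 0, 0))
})

test_that("centroid distances are Euclidean km, symmetric, zero-diagonal", {
  xy <- data.frame(area_id = c("a", "b"), x = c(0, 3) * 100,
                   y = c(0, 4) * 100)
  D <- centroid_distances(xy)
  expect_equal(D["a", "b"], 500)
  expect_equal(diag(D), c(a = 0, b = 0))
  expect_equal(D, t(D))
  # lon/lat-looking coordinates trigger the projection warning
  expect_warning(centroid_distances(data.frame(x = c(13.4, 13.5),
                                               y = c(52.5, 52.6))),
                 "projection")
})

test_that("GeoJSON round trip and edge list export preserve the lattice", {
  a <- lattice_areas(3, 2, cell_km = 2)
  a$n_insurants <- 100L; a$n_diabetics <- 20L; a$n_unenrolled <- 7L
  tf <- tempfile(fileext = ".geojson")
  write_areas_geojson(a, tf)
  b <- read_areas_geojson(tf)
  expect_equal(b$area_id, a$area_id)
  expect_equal(b$n_unenrolled, rep(7L, 6))
  expect_equal(nrow(build_adjacency(b)$edges), nrow(build_adjacency(a)$edges))
  ef <- tempfile(fileext = ".csv")
  write_edge_list(build_adjacency(a), ef)
  el <- read.csv(ef)
  expect_equal(names(el), c("area_id_1", "area_id_2"))
  expect_equal(nrow(el), 7L)  # 3*1 + 2*2 grid edges
})
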
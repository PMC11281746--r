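# shared fixtures, all built in code

square_poly <- function(x0, y0, s = 1) {
  cbind(c(x0, x0 + s, x0 + s, x0), c(y0, y0, y0 + s, y0 + s))
}

# area_set from a list of polygons with default counts
areas_from_polys <- function(polys, ids = NULL) {
  n <- length(polys)
  ids <- ids %||% letters[seq_len(n)]
  cent <- t(vapply(polys, function(p) colMeans(p), numeric(2)))
  info <- data.frame(area_id = ids, x = cent[, 1], y = cent[, 2],
                     n_insurants = 10L, n_diabetics = 5L, n_unenrolled = 2L)
  area_set(info, polys)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lattice_graph <- function(nr, nc, cell = 1) build_adjacency(lattice_areas(nr, nc, cell))

# Moran's I with binary contiguity weights
morans_i <- function(x, graph) {
  n <- length(x)
  xc <- x - mean(x)
  e <- graph$edges
  num <- 2 * sum(xc[e[, 1]] * xc[e[, 2]])
  w_total <- 2 * nrow(e)
  (n / w_total) * num / sum(xc^2)
}

# five-area indicator table with a worked-by-hand deprivation solution
dep_table <- function() {
  data.frame(area_id = c("A", "B", "C", "D", "E"),
             unemployment_rate = c(10, 5, 8, 12, 3),
             employed_at_residence = c(40, 55, 45, 35, 60),
             purchasing_power = c(90, 110, 100, 85, 120),
             highschool_degree = c(40, 35, 30, 15, 20),
             no_formal_education = c(6, 2, 4, 8, 1))
}

# brute-force scan: max Poisson LLR over every (center, radius) pair
brute_force_max_llr <- function(O, E, D) {
  E <- E * sum(O) / sum(E)
  n <- length(O)
  best <- 0
  for (c0 in seq_len(n)) {
    for (r in sort(unique(D[c0, ]))) {
      mem <- which(D[c0, ] <= r)
      if (length(mem) == n) next
      best <- max(best, poisson_llr(sum(O[mem]), sum(E[mem]), sum(O), sum(E)))
    }
  }
  best
}
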
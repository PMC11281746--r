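#' Construct a set of analysis areas
#'
#' Bundles area polygons with per-area identifiers, centroids and counts into
#' the lattice object consumed by every model in the package. Areas are the
#' small analysis units (micro-areas of a few hundred households) on which
#' unenrollment is mapped and modelled.
#'
#' @param info data frame with columns `area_id` (unique character),
#'   `x`, `y` (centroid coordinates in projected km), `n_insurants`,
#'   `n_diabetics`, `n_unenrolled` (non-negative counts with
#'   `n_unenrolled <= n_diabetics <= n_insurants`).
#' @param polygons list (one element per row of `info`) of numeric matrices
#'   with two columns giving the outer ring vertices in km; rings may be open
#'   (first vertex not repeated) or closed.
#' @param validate check polygon simplicity (non-self-intersection). Disable
#'   only for trusted machine-generated lattices.
#' @return An object of class `area_set`: the `info` data frame with the
#'   polygon list attached as attribute `polygons`.
#' @export
area_set <- function(info, polygons, validate = TRUE) {
  req <- c("area_id", "x", "y", "n_insurants", "n_diabetics", "n_unenrolled")
  missing_cols <- setdiff(req, names(info))
  if (length(missing_cols))
    stop("area info lacks columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(info$area_id))
    stop("duplicate area_id values")
  if (length(polygons) != nrow(info))
    stop("polygons list length does not match number of areas")
  bad <- with(info, n_unenrolled > n_diabetics | n_diabetics > n_insurants |
                n_unenrolled < 0)
  if (any(bad))
    stop("count invariant violated (n_unenrolled <= n_diabetics <= n_insurants) for: ",
         paste(info$area_id[bad], collapse = ", "))
  polygons <- lapply(polygons, close_ring)
  if (validate) {
    for (i in seq_along(polygons)) {
      if (!ring_is_simple(polygons[[i]]))
        stop("self-intersecting polygon for area ", info$area_id[i])
      bb <- apply(polygons[[i]], 2, range)
      if (info$x[i] < bb[1, 1] || info$x[i] > bb[2, 1] ||
          info$y[i] < bb[1, 2] || info$y[i] > bb[2, 2])
        stop("centroid outside polygon bounding box for area ", info$area_id[i])
    }
  }
  info$area_id <- as.character(info$area_id)
  structure(info, polygons = polygons, class = c("area_set", "data.frame"))
}

close_ring <- function(p) {
  p <- as.matrix(p)
  if (!isTRUE(all.equal(p[1, ], p[nrow(p), ]))) p <- rbind(p, p[1, ])
  unname(p)
}

# Simplicity: no two non-adjacent edges of the ring intersect.
ring_is_simple <- function(p) {
  n <- nrow(p) - 1L
  if (n < 3L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      adjacent <- (j == i + 1L) || (i == 1L && j == n)
      if (adjacent) next
      if (segments_cross(p[i, ], p[i + 1L, ], p[j, ], p[j + 1L, ])) return(FALSE)
    }
  }
  TRUE
}

segments_cross <- function(a, b, c, d) {
  o <- function(p, q, r) sign((q[1] - p[1]) * (r[2] - p[2]) -
                              (q[2] - p[2]) * (r[1] - p[1]))
  o1 <- o(a, b, c); o2 <- o(a, b, d); o3 <- o(c, d, a); o4 <- o(c, d, b)
  (o1 != o2) && (o3 != o4) && !(o1 == 0 || o2 == 0 || o3 == 0 || o4 == 0)
}

#' Contiguity graph from area polygons
#'
#' Two areas are neighbours when their boundaries share a segment of positive
#' length (a common edge or border). Corner contact alone does not create an
#' edge: a point intersection has zero length.
#'
#' @param areas an [area_set].
#' @param tol absolute geometric tolerance in km for collinearity and overlap
#'   tests.
#' @return An object of class `adjacency_graph`: list with `area_ids`,
#'   `edges` (two-column integer matrix of area indices, `i < j`), `n`, and
#'   `components` (integer component membership per area).
#' @export
build_adjacency <- function(areas, tol = 1e-9) {
  polys <- attr(areas, "polygons")
  n <- nrow(areas)
  bbs <- t(vapply(polys, function(p) c(range(p[, 1]), range(p[, 2])),
                  numeric(4)))
  edges <- matrix(integer(0), ncol = 2)
  if (n >= 2) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      # bounding boxes must touch for a shared border to exist
      if (bbs[i, 1] > bbs[j, 2] + tol || bbs[j, 1] > bbs[i, 2] + tol ||
          bbs[i, 3] > bbs[j, 4] + tol || bbs[j, 3] > bbs[i, 4] + tol) next
      keep[k] <- polygons_share_border(polys[[i]], polys[[j]], tol)
    }
    edges <- pairs[keep, , drop = FALSE]
  }
  new_adjacency_graph(as.character(areas$area_id), edges)
}

new_adjacency_graph <- function(area_ids, edges) {
  n <- length(area_ids)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges)) {
    if (any(edges[, 1] == edges[, 2])) stop("self-loop in adjacency")
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  structure(list(area_ids = area_ids, edges = edges, n = n,
                 components = as.integer(comp)),
            class = "adjacency_graph")
}

# Positive-length collinear overlap between any edge of ring a and ring b.
polygons_share_border <- function(a, b, tol = 1e-9) {
  na <- nrow(a) - 1L; nb <- nrow(b) - 1L
  for (i in seq_len(na)) {
    p1 <- a[i, ]; p2 <- a[i + 1L, ]
    d <- p2 - p1; len <- sqrt(sum(d^2))
    if (len < tol) next
    u <- d / len
    for (j in seq_len(nb)) {
      q1 <- b[j, ]; q2 <- b[j + 1L, ]
      # both endpoints of the candidate segment must lie on the line of (p1,p2)
      c1 <- abs((q1[1] - p1[1]) * u[2] - (q1[2] - p1[2]) * u[1])
      c2 <- abs((q2[1] - p1[1]) * u[2] - (q2[2] - p1[2]) * u[1])
      if (c1 > tol || c2 > tol) next
      t1 <- (q1[1] - p1[1]) * u[1] + (q1[2] - p1[2]) * u[2]
      t2 <- (q2[1] - p1[1]) * u[1] + (q2[2] - p1[2]) * u[2]
      lo <- max(0, min(t1, t2)); hi <- min(len, max(t1, t2))
      if (hi - lo > tol) return(TRUE)
    }
  }
  FALSE
}

#' @export
print.adjacency_graph <- function(x, ...) {
  cat("Contiguity graph:", x$n, "areas,", nrow(x$edges), "edges,",
      max(x$components), "connected component(s)\n")
  iso <- sum(tabulate(c(x$edges), x$n) == 0)
  if (iso) cat("  isolated areas:", iso, "\n")
  invisible(x)
}

#' ICAR structure matrix of a contiguity graph
#'
#' Builds the intrinsic conditional autoregressive (Besag) precision
#' structure `Q = D - W`, the graph Laplacian: `Q[i,i]` is the number of
#' neighbours of area i and `Q[i,j] = -1` for neighbours. Rows sum to zero;
#' the rank deficiency equals the number of connected components, so the
#' implied Gaussian Markov random field is proper only under a sum-to-zero
#' constraint per component.
#'
#' @param graph an [adjacency_graph].
#' @return An object of class `icar_structure`: list with sparse `Q`
#'   (`Matrix::dgCMatrix`), `components` (per-area membership),
#'   `constraint` (component indicator matrix whose rows must annihilate the
#'   field), and `isolated` (indices of areas without neighbours, which can
#'   carry no structured effect).
#' @export
icar_structure <- function(graph) {
  if (graph$n < 1) stop("empty graph")
  deg <- tabulate(c(graph$edges), graph$n)
  if (nrow(graph$edges)) {
    W <- Matrix::sparseMatrix(i = c(graph$edges[, 1], graph$edges[, 2]),
                              j = c(graph$edges[, 2], graph$edges[, 1]),
                              x = 1, dims = c(graph$n, graph$n))
  } else {
    W <- Matrix::Matrix(0, graph$n, graph$n, sparse = TRUE)
  }
  Q <- Matrix::Diagonal(x = deg) - W
  ncomp <- max(graph$components)
  A <- Matrix::sparseMatrix(i = graph$components, j = seq_len(graph$n), x = 1,
                            dims = c(ncomp, graph$n))
  structure(list(Q = methods::as(Q, "generalMatrix"),
                 components = graph$components,
                 constraint = A,
                 isolated = which(deg == 0L)),
            class = "icar_structure")
}

#' Centroid distance matrix
#'
#' Euclidean distances between area centroids in km. Coordinates must be in a
#' planar projection; if every coordinate looks geographic (|x| <= 180 and
#' |y| <= 90) a warning is issued, since geodesic distances are never
#' computed here.
#'
#' @param areas an [area_set], or a two-column matrix/data frame of centroid
#'   coordinates in km.
#' @return Symmetric matrix of km distances with zero diagonal, dimnames set
#'   to area ids when available.
#' @export
centroid_distances <- function(areas) {
  if (inherits(areas, "area_set") ||
      (is.data.frame(areas) && all(c("x", "y") %in% names(areas)))) {
    xy <- cbind(areas$x, areas$y)
    ids <- if (!is.null(areas$area_id)) as.character(areas$area_id)
  } else {
    xy <- as.matrix(areas)[, 1:2, drop = FALSE]
    ids <- rownames(areas)
  }
  if (nrow(xy) && all(abs(xy[, 1]) <= 180) && all(abs(xy[, 2]) <= 90))
    warning("all centroids look like lon/lat degrees; distances assume a ",
            "planar km projection")
  D <- as.matrix(stats::dist(xy))
  dimnames(D) <- list(ids, ids)
  D
}

# Greedy proper coloring; colors returned as integers >= 1. Used to update
# non-adjacent ICAR sites simultaneously in the samplers.
graph_coloring <- function(graph) {
  n <- graph$n
  nbr <- vector("list", n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges[k, 1]; j <- graph$edges[k, 2]
    nbr[[i]] <- c(nbr[[i]], j); nbr[[j]] <- c(nbr[[j]], i)
  }
  deg <- lengths(nbr)
  col <- integer(n)
  for (v in order(-deg)) {
    used <- col[nbr[[v]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    col[v] <- c0
  }
  col
}

#' Write a contiguity graph as an edge list
#'
#' @param graph an [adjacency_graph].
#' @param path CSV output path; columns `area_id_1`, `area_id_2`.
#' @export
write_edge_list <- function(graph, path) {
  df <- data.frame(area_id_1 = graph$area_ids[graph$edges[, 1]],
                   area_id_2 = graph$area_ids[graph$edges[, 2]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read areas from a GeoJSON FeatureCollection
#'
#' Each Feature must be a Polygon whose `properties` carry `area_id` and the
#' counts `n_insurants`, `n_diabetics`, `n_unenrolled`; any further
#' properties are kept as extra columns. Coordinates are taken as planar km.
#'
#' @param path GeoJSON file.
#' @return An [area_set]; centroids are the vertex means of the outer ring.
#' @export
read_areas_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection")
  feats <- gj$features
  polys <- vector("list", length(feats))
  rows <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (!identical(f$geometry$type, "Polygon"))
      stop("feature ", i, " is not a Polygon")
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    polys[[i]] <- ring
    pr <- f$properties
    ring_open <- ring[-nrow(ring), , drop = FALSE]
    rows[[i]] <- data.frame(
      area_id = as.character(pr$area_id),
      x = if (!is.null(pr$x)) pr$x else mean(ring_open[, 1]),
      y = if (!is.null(pr$y)) pr$y else mean(ring_open[, 2]),
      n_insurants = pr$n_insurants %||% 0L,
      n_diabetics = pr$n_diabetics %||% 0L,
      n_unenrolled = pr$n_unenrolled %||% 0L)
  }
  area_set(do.call(rbind, rows), polys)
}

#' Write areas (and optional per-area values) to GeoJSON
#'
#' @param areas an [area_set].
#' @param path output file.
#' @param extra optional data frame of additional per-area properties,
#'   row-aligned with `areas` (e.g. smoothed rates, deprivation index).
#' @export
write_areas_geojson <- function(areas, path, extra = NULL) {
  polys <- attr(areas, "polygons")
  feats <- lapply(seq_len(nrow(areas)), function(i) {
    props <- as.list(as.data.frame(areas)[i, , drop = FALSE])
    if (!is.null(extra)) props <- c(props, as.list(extra[i, , drop = FALSE]))
    props <- lapply(props, function(v) if (is.numeric(v)) signif(v, 10) else v)
    ring <- lapply(seq_len(nrow(polys[[i]])),
                   function(k) as.numeric(polys[[i]][k, ]))
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
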
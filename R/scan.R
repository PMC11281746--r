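#' Enumerate circular scan windows
#'
#' For each candidate center, windows grow by adding the next-nearest area
#' centroid while the distance stays within `max_radius_km`; distance ties
#' are broken by area order, and duplicate member sets per center are
#' collapsed (nested prefixes are always distinct, so this matters only for
#' degenerate coordinate duplicates). A zero radius yields one singleton
#' window per area.
#'
#' @param distances symmetric km distance matrix from [centroid_distances].
#' @param max_radius_km largest window radius (>= 0).
#' @return list of windows; each is a list with `center` (area index),
#'   `members` (area indices ordered by distance from the center) and
#'   `radius_km` (distance of the farthest member).
#' @export
enumerate_windows <- function(distances, max_radius_km) {
  if (max_radius_km < 0) stop("max_radius_km must be >= 0")
  pre <- window_prefixes(distances, max_radius_km)
  out <- list()
  for (c0 in seq_along(pre$ord)) {
    ord <- pre$ord[[c0]]
    seen <- character(0)
    for (m in seq_along(ord)) {
      key <- paste(sort(ord[seq_len(m)]), collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(center = c0,
                                      members = ord[seq_len(m)],
                                      radius_km = pre$rad[[c0]][m])
    }
  }
  out
}

# per-center orderings and cumulative radii, truncated at max radius
window_prefixes <- function(distances, max_radius_km) {
  n <- nrow(distances)
  ord <- vector("list", n); rad <- vector("list", n)
  for (c0 in seq_len(n)) {
    d <- distances[c0, ]
    o <- order(d, seq_len(n))
    keep <- d[o] <= max_radius_km
    # the center itself (distance 0) is always a member
    o <- o[keep]
    if (!length(o) || o[1] != c0) o <- c(c0, setdiff(o, c0))
    ord[[c0]] <- o
    rad[[c0]] <- d[o]
  }
  list(ord = ord, rad = rad)
}

#' Kulldorff Poisson log likelihood ratio
#'
#' The purely spatial Poisson scan LLR of a window, positive only when the
#' in-window rate exceeds the out-of-window rate (high-rate scan):
#' `llr = O_in log(O_in/E_in) + (O_tot - O_in) log((O_tot - O_in)/(E_tot - E_in))`
#' when `O_in/E_in > (O_tot - O_in)/(E_tot - E_in)`, else 0, with
#' `0 * log(0/x)` taken as 0. Expected counts should be scaled so that
#' `E_tot = O_tot` (internal standardization).
#'
#' @param O_in,E_in observed and expected counts inside the window
#'   (vectorised).
#' @param O_tot,E_tot study totals.
#' @return LLR value(s), >= 0.
#' @export
poisson_llr <- function(O_in, E_in, O_tot, E_tot) {
  if (any(E_in <= 0)) stop("E_in must be > 0")
  if (any(E_in >= E_tot)) stop("E_in must be < E_tot")
  O_out <- O_tot - O_in
  E_out <- E_tot - E_in
  t1 <- ifelse(O_in > 0, O_in * log(O_in / E_in), 0)
  t2 <- ifelse(O_out > 0, O_out * log(O_out / E_out), 0)
  llr <- t1 + t2
  elevated <- O_in / E_in > O_out / E_out
  ifelse(elevated, llr, 0)
}

# branchless LLR on vectors, preconditions already checked
.llr_fast <- function(O_in, E_in, O_tot, E_tot) {
  O_out <- O_tot - O_in
  E_out <- E_tot - E_in
  t1 <- O_in * log(pmax(O_in, 1) / E_in) # O_in==0 -> log(1/E)*0 handled below
  t1[O_in == 0] <- 0
  t2 <- O_out * log(pmax(O_out, 1) / E_out)
  t2[O_out == 0] <- 0
  llr <- t1 + t2
  llr[O_in * E_out <= O_out * E_in] <- 0
  llr
}

#' Monte-Carlo null distribution of the maximum scan LLR
#'
#' Conditional on the observed total, each replication redistributes the
#' cases multinomially over areas with probabilities proportional to the
#' expected counts and records the maximum window LLR (the SaTScan-style
#' conditional null).
#'
#' @param O_tot total observed cases.
#' @param E per-area expected counts.
#' @param distances km distance matrix.
#' @param max_radius_km largest window radius.
#' @param n_sim number of replications (the conventional choice is 9,999).
#' @param seed optional integer seed.
#' @return numeric vector of `n_sim` maximum LLR values (all >= 0).
#' @export
monte_carlo_null <- function(O_tot, E, distances, max_radius_km = 30,
                             n_sim = 9999, seed = NULL) {
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  pre <- window_prefixes(distances, max_radius_km)
  E <- E * O_tot / sum(E)
  nulls <- stats::rmultinom(n_sim, O_tot, prob = E / sum(E))
  max_llr_over_windows(nulls, E, pre, O_tot)
}

# nulls: areas x n_sim count matrix; returns per-column max LLR
max_llr_over_windows <- function(nulls, E, pre, O_tot) {
  n_sim <- ncol(nulls)
  E_tot <- sum(E)
  mm <- numeric(n_sim)
  for (c0 in seq_along(pre$ord)) {
    ord <- pre$ord[[c0]]
    m <- length(ord)
    if (m >= length(E)) m <- length(E) - 1L  # full-region window carries no signal
    if (m < 1L) next
    Ocum <- numeric(n_sim)
    Ecum <- 0
    for (r in seq_len(m)) {
      Ocum <- Ocum + nulls[ord[r], ]
      Ecum <- Ecum + E[ord[r]]
      mm <- pmax(mm, .llr_fast(Ocum, Ecum, O_tot, E_tot))
    }
  }
  mm
}

#' Detect high-rate spatial clusters (Kulldorff scan)
#'
#' Runs the purely spatial Poisson scan statistic over circular windows up
#' to `max_radius_km`: the primary cluster is the window maximising the LLR
#' (ties broken toward fewer members, then the lower center index);
#' secondary clusters are reported in LLR order subject to sharing no member
#' area with any better-ranked reported cluster. Each p-value is
#' `(1 + #[null max-LLR >= LLR]) / (1 + n_sim)` against the common
#' Monte-Carlo null, so the smallest attainable p is `1/(n_sim + 1)`.
#'
#' @param O,E per-area observed and expected counts (`E` is rescaled
#'   internally so totals match).
#' @param distances km distance matrix from [centroid_distances].
#' @param max_radius_km maximum window radius (default 30 km).
#' @param n_sim Monte-Carlo replications (default 9,999).
#' @param seed integer seed for the null replications.
#' @param max_clusters maximum number of reported (non-overlapping)
#'   clusters.
#' @param area_ids optional area id labels.
#' @return Object of class `scan_result`: data frame `clusters` with rank,
#'   center, radius, member count, observed, expected, relative risks and
#'   p-values, plus `member_ids` (list of member areas per cluster) and the
#'   null max-LLR vector. If all counts are zero an empty result is
#'   returned with a warning.
#' @export
detect_clusters <- function(O, E, distances, max_radius_km = 30,
                            n_sim = 9999, seed = 1, max_clusters = 10,
                            area_ids = NULL) {
  n <- length(O)
  stopifnot(length(E) == n, nrow(distances) == n)
  if (is.null(area_ids)) area_ids <- rownames(distances) %||% as.character(seq_len(n))
  O_tot <- sum(O)
  if (O_tot == 0) {
    warning("all observed counts are zero; no clusters to detect")
    return(structure(list(clusters = data.frame(), member_ids = list(),
                          null_max_llr = numeric(0), n_sim = n_sim),
                     class = "scan_result"))
  }
  E <- E * O_tot / sum(E)
  pre <- window_prefixes(distances, max_radius_km)

  # observed evaluation over every window, keeping per-window stats
  rows <- list()
  for (c0 in seq_len(n)) {
    ord <- pre$ord[[c0]]
    m <- min(length(ord), n - 1L)
    if (m < 1L) next
    Ocum <- cumsum(O[ord])[seq_len(m)]
    Ecum <- cumsum(E[ord])[seq_len(m)]
    llr <- .llr_fast(Ocum, Ecum, O_tot, sum(E))
    rows[[c0]] <- data.frame(center = c0, size = seq_len(m),
                             radius_km = pre$rad[[c0]][seq_len(m)],
                             observed = Ocum, expected = Ecum, llr = llr)
  }
  win <- do.call(rbind, rows)
  # primary ordering: LLR desc, then fewer members, then lower center index
  win <- win[order(-win$llr, win$size, win$center), ]
  null_max <- monte_carlo_null(O_tot, E, distances, max_radius_km,
                               n_sim = n_sim, seed = seed)
  taken <- logical(n)
  sel <- list()
  for (k in seq_len(nrow(win))) {
    if (length(sel) >= max_clusters) break
    if (win$llr[k] <= 0) break
    mem <- pre$ord[[win$center[k]]][seq_len(win$size[k])]
    if (any(taken[mem])) next
    taken[mem] <- TRUE
    p <- (1 + sum(null_max >= win$llr[k])) / (1 + n_sim)
    rr_out <- (O_tot - win$observed[k]) / (sum(E) - win$expected[k])
    sel[[length(sel) + 1L]] <- list(row = win[k, ], members = mem, p = p,
                                    rr = (win$observed[k] / win$expected[k]))
  }
  clusters <- do.call(rbind, lapply(seq_along(sel), function(i) {
    s <- sel[[i]]
    data.frame(rank = i, center_area_id = area_ids[s$row$center],
               radius_km = s$row$radius_km, n_areas = s$row$size,
               observed = s$row$observed, expected = s$row$expected,
               relative_risk = s$rr, llr = s$row$llr, p_value = s$p)
  }))
  structure(list(clusters = clusters %||% data.frame(),
                 member_ids = lapply(sel, function(s) area_ids[s$members]),
                 null_max_llr = null_max, n_sim = n_sim,
                 max_radius_km = max_radius_km),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  if (!nrow(x$clusters)) {
    cat("Spatial scan: no high-rate clusters detected\n")
    return(invisible(x))
  }
  cat("Spatial scan:", nrow(x$clusters), "non-overlapping cluster(s),",
      x$n_sim, "Monte-Carlo replications\n")
  df <- x$clusters
  df$radius_km <- round(df$radius_km, 2)
  df$expected <- round(df$expected, 1)
  df$relative_risk <- round(df$relative_risk, 3)
  df$llr <- round(df$llr, 2)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
summary.scan_result <- function(object, ...) object$clusters

#' @export
as.data.frame.scan_result <- function(x, ...) x$clusters

#' Write a scan result as CSV
#'
#' @param x a `scan_result`.
#' @param path output CSV path.
#' @export
write_scan_csv <- function(x, path) {
  df <- x$clusters
  df$member_area_ids <- vapply(x$member_ids, paste, "", collapse = ";")
  utils::write.csv(round_numeric(df), path, row.names = FALSE)
  invisible(path)
}
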
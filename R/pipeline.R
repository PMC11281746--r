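#' Default pipeline configuration
#'
#' Full parameter block for [run_pipeline] with every stage enabled at demo
#' scale (an 8 x 8 lattice); override any entry by passing a partial list
#' (or JSON file) to `run_pipeline`, which merges it over these defaults.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed global seed; each stage derives its own seed as
#'   `seed + stage offset` so stages stay reproducible independently.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(out_dir = "enrollscape-run", seed = 1L) {
  list(
    out_dir = out_dir, seed = as.integer(seed), log_level = "INFO",
    simulate = list(enabled = TRUE, n_rows = 8, n_cols = 8, cell_km = 2,
                    mean_insurants_per_area = 150,
                    spatial_sd_structured = 0.3,
                    spatial_sd_unstructured = 0.1),
    deprivation = list(enabled = TRUE),
    map = list(enabled = TRUE, chains = 2, iter = 1000, burnin = 500,
               grid_nx = 40, grid_ny = 40),
    scan = list(enabled = TRUE, max_radius_km = 30, n_sim = 999),
    global_fit = list(enabled = TRUE, effect = "bym", n_draws = 200),
    svc = list(enabled = TRUE, block = 2,
               svc_covariates = c("male", "commuter_pct"), n_draws = 200)
  )
}

#' Run the full unenrollment analysis pipeline
#'
#' Executes the stages simulate -> deprivation -> map -> scan -> global-fit
#' -> svc in dependency order, writing standard-format artifacts (GeoJSON,
#' CSV, JSON) into `config$out_dir` and a `manifest.json` recording, per
#' stage, the parameter hash, input-file hashes, outputs, wall time and
#' package version. Re-running with an unchanged configuration skips stages
#' whose manifest entries still match (a cached no-op); a failing stage
#' stops its dependents with a stage-named error.
#'
#' @param config partial configuration list or path to a JSON file; merged
#'   over [default_pipeline_config].
#' @param force rerun every enabled stage even if cached.
#' @return the manifest (class `pipeline_manifest`), invisibly.
#' @export
run_pipeline <- function(config = list(), force = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- modifyList(default_pipeline_config(), config)
  validate_pipeline_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifest_path))
    jsonlite::read_json(manifest_path, simplifyVector = TRUE) else list()

  stages <- list(
    simulate = list(offset = 0L, inputs = character(0), fn = stage_simulate,
                    outputs = c("areas.geojson", "insurants.csv",
                                "covariates.csv", "ground_truth.json",
                                "edges.csv")),
    deprivation = list(offset = 0L, inputs = "covariates.csv",
                       fn = stage_deprivation, outputs = "deprivation.csv"),
    map = list(offset = 1L, inputs = "areas.geojson", fn = stage_map,
               outputs = c("smoothed_rates.csv", "surface.csv",
                           "map_report.json")),
    scan = list(offset = 2L, inputs = "areas.geojson", fn = stage_scan,
                outputs = c("clusters.csv", "clusters.geojson")),
    global_fit = list(offset = 3L,
                      inputs = c("insurants.csv", "covariates.csv",
                                 "deprivation.csv", "areas.geojson"),
                      fn = stage_global,
                      outputs = c("global_fit.json", "or_table.csv")),
    svc = list(offset = 4L,
               inputs = c("insurants.csv", "covariates.csv",
                          "deprivation.csv", "areas.geojson"),
               fn = stage_svc,
               outputs = c("svc_summary.csv", "svc_fit.json")))

  for (nm in names(stages)) {
    st <- stages[[nm]]
    scfg <- cfg[[nm]]
    if (!isTRUE(scfg$enabled)) { plog(cfg, nm, "disabled; skipped"); next }
    inputs <- file.path(out, st$inputs)
    missing_in <- st$inputs[!file.exists(inputs)]
    if (length(missing_in))
      stop("stage '", nm, "': missing upstream artifact(s): ",
           paste(missing_in, collapse = ", "))
    scfg$seed <- cfg$seed + st$offset
    phash <- params_hash(scfg)
    ihash <- unname(tools::md5sum(inputs))
    entry <- manifest[[nm]]
    if (!force && !is.null(entry) &&
        identical(entry$params_hash, phash) &&
        identical(unname(unlist(entry$inputs_hash)), ihash) &&
        all(file.exists(file.path(out, st$outputs)))) {
      plog(cfg, nm, "cached; skipped")
      next
    }
    plog(cfg, nm, "running")
    t0 <- proc.time()[["elapsed"]]
    ok <- tryCatch({ st$fn(scfg, out); TRUE },
                   error = function(e)
                     stop("stage '", nm, "' failed: ", conditionMessage(e),
                          call. = FALSE))
    manifest[[nm]] <- list(params_hash = phash, inputs_hash = ihash,
                           outputs = st$outputs,
                           wall_time_s = round(proc.time()[["elapsed"]] - t0, 3),
                           version = as.character(utils::packageVersion("enrollscape")))
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA)
    plog(cfg, nm, sprintf("done (%.1fs)", manifest[[nm]]$wall_time_s))
  }
  invisible(structure(manifest, class = "pipeline_manifest"))
}

validate_pipeline_config <- function(cfg) {
  if (!is.numeric(cfg$seed)) stop("config error at 'seed': must be numeric")
  for (nm in c("simulate", "deprivation", "map", "scan", "global_fit", "svc")) {
    if (!is.list(cfg[[nm]]))
      stop("config error at '", nm, "': must be a parameter block")
  }
  if (!is.null(cfg$global_fit$effect) &&
      !cfg$global_fit$effect %in% c("none", "iid", "besag", "bym"))
    stop("config error at 'global_fit.effect': must be one of none/iid/besag/bym")
  invisible(TRUE)
}

plog <- function(cfg, stage, msg) {
  if (identical(cfg$log_level, "SILENT")) return(invisible())
  message(sprintf("[%s] %s", stage, msg))
}

params_hash <- function(params) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(params[order(names(params))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

stage_simulate <- function(scfg, out) {
  cfg <- sim_config(n_rows = scfg$n_rows, n_cols = scfg$n_cols,
                    cell_km = scfg$cell_km,
                    mean_insurants_per_area = scfg$mean_insurants_per_area,
                    spatial_sd_structured = scfg$spatial_sd_structured,
                    spatial_sd_unstructured = scfg$spatial_sd_unstructured,
                    seed = scfg$seed)
  sim <- simulate_study(cfg)
  write_sim(sim, out)
  write_edge_list(sim$graph, file.path(out, "edges.csv"))
}

stage_deprivation <- function(scfg, out) {
  cov <- utils::read.csv(file.path(out, "covariates.csv"))
  dep <- compute_deprivation(cov)
  utils::write.csv(round_numeric(dep), file.path(out, "deprivation.csv"),
                   row.names = FALSE)
}

stage_map <- function(scfg, out) {
  areas <- read_areas_geojson(file.path(out, "areas.geojson"))
  graph <- build_adjacency(areas)
  E <- expected_counts(areas$n_diabetics, areas$n_unenrolled)
  fit <- fit_bym(areas$n_unenrolled, E, graph,
                 chains = scfg$chains, iter = scfg$iter,
                 burnin = scfg$burnin, seed = scfg$seed)
  global_rate <- sum(areas$n_unenrolled) / sum(areas$n_diabetics)
  rates <- smoothed_rates(fit, global_rate)
  df <- data.frame(area_id = areas$area_id, O = areas$n_unenrolled, E = E,
                   theta = fit$theta_mean, rate = rates)
  utils::write.csv(round_numeric(df), file.path(out, "smoothed_rates.csv"),
                   row.names = FALSE)
  surf <- interpolate_surface(cbind(areas$x, areas$y), rates,
                              grid_spec = list(nx = scfg$grid_nx,
                                               ny = scfg$grid_ny))
  write_surface_csv(surf, file.path(out, "surface.csv"))
  jsonlite::write_json(list(dic = signif(fit$dic, 6), pd = signif(fit$pd, 6),
                            beta0 = signif(fit$beta0, 6),
                            rhat = as.list(signif(fit$rhat, 6)),
                            converged = fit$converged,
                            matern = lapply(surf$matern, signif, 6)),
                       file.path(out, "map_report.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_scan <- function(scfg, out) {
  areas <- read_areas_geojson(file.path(out, "areas.geojson"))
  E <- expected_counts(areas$n_diabetics, areas$n_unenrolled)
  D <- suppressWarnings(centroid_distances(areas)) # lattice coords are km
  res <- detect_clusters(areas$n_unenrolled, E, D,
                         max_radius_km = scfg$max_radius_km,
                         n_sim = scfg$n_sim, seed = scfg$seed,
                         area_ids = areas$area_id)
  write_scan_csv(res, file.path(out, "clusters.csv"))
  rank_of <- rep(NA_integer_, nrow(areas))
  for (i in seq_along(res$member_ids))
    rank_of[match(res$member_ids[[i]], areas$area_id)] <- i
  write_areas_geojson(areas, file.path(out, "clusters.geojson"),
                      extra = data.frame(cluster_rank = rank_of))
}

read_design_artifacts <- function(out) {
  ins <- utils::read.csv(file.path(out, "insurants.csv"))
  cov <- utils::read.csv(file.path(out, "covariates.csv"))
  dep <- utils::read.csv(file.path(out, "deprivation.csv"))
  cov$deprivation <- NULL
  cov <- merge(cov, dep[, c("area_id", "deprivation")], by = "area_id",
               sort = FALSE)
  regression_design(list(insurants = ins, covariates = cov))
}

stage_global <- function(scfg, out) {
  design <- read_design_artifacts(out)
  areas <- read_areas_geojson(file.path(out, "areas.geojson"))
  graph <- build_adjacency(areas)
  fml <- unenrolled ~ male + age + foreign + unemployed + deprivation +
    household_size + commuter_pct + physician_density
  vif <- compute_vif(design[, c("male", "age", "foreign", "unemployed",
                                "deprivation", "household_size",
                                "commuter_pct", "physician_density")])
  fit <- fit_global(fml, design, graph, effect = scfg$effect,
                    n_draws = scfg$n_draws, seed = scfg$seed)
  ort <- odds_ratio_table(fit)
  utils::write.csv(round_numeric(ort), file.path(out, "or_table.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(effect = fit$effect,
                            coefficients = as.list(signif(coef(fit), 6)),
                            vif = as.list(signif(vif, 6)),
                            vif_flagged = attr(vif, "flagged"),
                            dic = signif(fit$dic, 6), pd = signif(fit$pd, 6),
                            separated = fit$separated),
                       file.path(out, "global_fit.json"),
                       auto_unbox = TRUE, digits = NA)
}

stage_svc <- function(scfg, out) {
  design <- read_design_artifacts(out)
  areas <- read_areas_geojson(file.path(out, "areas.geojson"))
  graph <- build_adjacency(areas)
  rows <- as.integer(sub("r(\\d+)c.*", "\\1", areas$area_id))
  cols <- as.integer(sub(".*c(\\d+)$", "\\1", areas$area_id))
  mapping <- block_mapping(max(rows), max(cols), scfg$block)
  coarse <- coarsen_graph(graph, mapping)
  fml <- unenrolled ~ male + age + foreign + unemployed + deprivation +
    household_size + commuter_pct + physician_density
  fit <- fit_svc(fml, design, coarse,
                 svc_covariates = scfg$svc_covariates,
                 n_draws = scfg$n_draws, seed = scfg$seed)
  long <- do.call(rbind, lapply(names(fit$fields), function(nm)
    cbind(covariate = nm, fit$fields[[nm]])))
  utils::write.csv(round_numeric(long), file.path(out, "svc_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(dic = signif(fit$dic, 6), pd = signif(fit$pd, 6),
                            taus = as.list(signif(fit$taus, 6)),
                            coefficients = as.list(signif(coef(fit), 6))),
                       file.path(out, "svc_fit.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Validate pipeline input artifacts
#'
#' Checks GeoJSON validity of the area file, CSV schemas, the count
#' invariant `n_unenrolled <= n_diabetics <= n_insurants`, and referential
#' integrity of `area_id` between insurants and areas.
#'
#' @param paths named list with any of `areas` (GeoJSON), `insurants` (CSV),
#'   `covariates` (CSV).
#' @return data frame report of violations (empty when clean) with
#'   attribute `ok`.
#' @export
validate_inputs <- function(paths) {
  report <- list()
  add <- function(check, msg)
    report[[length(report) + 1L]] <<- data.frame(check = check, message = msg)
  areas <- NULL
  if (!is.null(paths$areas)) {
    areas <- tryCatch(read_areas_geojson(paths$areas), error = function(e) {
      add("geojson", conditionMessage(e)); NULL })
    if (!is.null(areas)) {
      bad <- with(areas, n_unenrolled > n_diabetics | n_diabetics > n_insurants)
      if (any(bad))
        add("count_invariant",
            paste("n_unenrolled <= n_diabetics <= n_insurants violated for:",
                  paste(areas$area_id[bad], collapse = ", ")))
    }
  }
  if (!is.null(paths$insurants)) {
    ins <- tryCatch(utils::read.csv(paths$insurants), error = function(e) {
      add("insurants_csv", conditionMessage(e)); NULL })
    if (!is.null(ins)) {
      need <- c("insurant_id", "area_id", "age", "sex", "unemployed",
                "foreign_citizenship", "diabetic")
      miss <- setdiff(need, names(ins))
      if (length(miss))
        add("insurants_schema", paste("missing columns:",
                                      paste(miss, collapse = ", ")))
      if (!is.null(areas) && "area_id" %in% names(ins)) {
        unknown <- setdiff(unique(ins$area_id), areas$area_id)
        if (length(unknown))
          add("referential", paste("insurants reference unknown area_id:",
                                   paste(utils::head(unknown, 5),
                                         collapse = ", ")))
      }
      if (all(c("enrolled", "diabetic") %in% names(ins))) {
        bad <- !is.na(ins$enrolled) & ins$diabetic != 1
        if (any(bad))
          add("enrollment_flag",
              "enrollment defined for non-diabetic insurant(s)")
      }
    }
  }
  if (!is.null(paths$covariates)) {
    cov <- tryCatch(utils::read.csv(paths$covariates), error = function(e) {
      add("covariates_csv", conditionMessage(e)); NULL })
    if (!is.null(cov)) {
      need <- c("area_id", "unemployment_rate", "employed_at_residence",
                "purchasing_power", "highschool_degree", "no_formal_education")
      miss <- setdiff(need, names(cov))
      if (length(miss))
        add("covariates_schema", paste("missing columns:",
                                       paste(miss, collapse = ", ")))
    }
  }
  out <- if (length(report)) do.call(rbind, report)
         else data.frame(check = character(0), message = character(0))
  attr(out, "ok") <- nrow(out) == 0
  out
}
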
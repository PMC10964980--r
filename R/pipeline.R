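# Pipeline driver: simulate -> annotate -> map -> detect -> analyze ->
# validate, with per-stage artifacts and a provenance record.

PIPELINE_STAGES <- c("simulate", "annotate", "map", "detect", "analyze",
                     "validate")

# artifact each stage depends on, and the stage that produces it
.STAGE_NEEDS <- list(
  annotate = c("scenario.json", "simulate"),
  map = c("annotations.csv", "annotate"),
  detect = c("map_summary.json", "map"),
  analyze = c("map_summary.json", "map"),
  validate = c("isthmus.csv", "analyze")
)

#' Serialize / deserialize a scenario config as JSON
#'
#' @param config an `ilam_scenario`.
#' @param path JSON file.
#' @return `path` (write) or an `ilam_scenario` (read).
#' @export
write_scenario <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  sc <- scenario_config(seed = raw$seed, geometry = raw$geometry,
                        structures = lapply(raw$structures, function(s) {
                          s[c("x", "y", "centre", "radius")] <-
                            lapply(s[c("x", "y", "centre", "radius")],
                                   function(v) if (is.null(v)) NULL else unlist(v))
                          s[!vapply(s, is.null, logical(1))]
                        }),
                        corridors = raw$corridors,
                        background_cv = raw$background_cv,
                        pacing_sources = lapply(raw$pacing_sources, function(p)
                          list(position = unlist(p$position),
                               onset_ms = p$onset_ms)),
                        point_density = raw$point_density,
                        egm = raw$egm)
  if (!is.null(raw$corridor_region)) {
    sc$corridor_region <- lapply(raw$corridor_region, unlist)
  }
  sc
}

#' Read a scenario config from YAML
#'
#' @param path YAML file with the [scenario_config()] fields.
#' @return an `ilam_scenario`.
#' @export
read_scenario_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- scenario_config(seed = raw$seed, geometry = raw$geometry,
                        structures = raw$structures %||% list(),
                        corridors = raw$corridors %||% list(),
                        background_cv = raw$background_cv %||% 1.0,
                        pacing_sources = raw$pacing_sources,
                        point_density = raw$point_density %||% 20,
                        egm = raw$egm %||% list(rate_hz = 1000, noise_mV = 0.02))
  if (!is.null(raw$corridor_region)) sc$corridor_region <- raw$corridor_region
  sc
}

#' Run the mapping pipeline stage by stage
#'
#' Executes the requested stages in order, each stage reading the previous
#' stage's artifacts from `out_dir` and writing its own. A structured log
#' reports per-stage counts (acquired points, used points, used-rate,
#' deceleration zones, isthmus table). Every run writes `provenance.json`
#' with the config hash, seed and package version.
#'
#' @param config an `ilam_scenario`.
#' @param out_dir results directory (created).
#' @param stages character subset of
#'   simulate/annotate/map/detect/analyze/validate, in pipeline order.
#' @param quiet suppress log messages.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = PIPELINE_STAGES, quiet = FALSE) {
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) if (!quiet) message(sprintf(...))
  state <- new.env(parent = emptyenv())

  need <- function(stage) {
    dep <- .STAGE_NEEDS[[stage]]
    if (!is.null(dep) && !file.exists(file.path(out_dir, dep[1]))) {
      stop_ilam("stage '%s' needs %s: run '%s' first", stage, dep[1], dep[2])
    }
  }
  get_mesh <- function() {
    if (is.null(state$mesh)) {
      state$config <- read_scenario(file.path(out_dir, "scenario.json"))
      state$mesh <- generate_surface(state$config)
    }
    state$mesh
  }

  for (stage in stages) {
    if (stage != "simulate") need(stage)
    switch(stage,
      simulate = {
        write_scenario(config, file.path(out_dir, "scenario.json"))
        state$config <- config
        state$mesh <- generate_surface(config)
        state$act <- simulate_activation(state$mesh)
        state$truth <- ground_truth(state$mesh, state$act)
        write_map_bundle(list(mesh = state$mesh,
                              annotations = data.frame(site_id = integer(0)),
                              ground_truth = state$truth, seed = config$seed),
                         out_dir)
        log("simulate: %d vertices, %d conducting",
            nrow(state$mesh$vertices), sum(state$mesh$label == "conducting"))
      },
      annotate = {
        mesh <- get_mesh()
        if (is.null(state$act)) state$act <- simulate_activation(mesh)
        egm_set <- synthesize_electrograms(mesh, state$act)
        state$ann <- annotate_sites(egm_set)
        utils::write.csv(state$ann, file.path(out_dir, "annotations.csv"),
                         row.names = FALSE)
        log("annotate: %d sites, %d with usable deflections",
            nrow(state$ann), sum(state$ann$used))
      },
      map = {
        mesh <- get_mesh()
        if (is.null(state$ann)) {
          state$ann <- utils::read.csv(file.path(out_dir, "annotations.csv"))
        }
        amap <- project_points(activation_map(mesh, state$ann))
        amap <- interpolate_lat(amap)
        state$amap <- amap
        state$ilam <- build_ilam(amap)
        write_vtk(mesh, file.path(out_dir, "ilam.vtk"),
                  point_data = list(lat_ms = state$ilam$lat,
                                    isochrone_index = as.numeric(state$ilam$isochrone)))
        jsonlite::write_json(list(
          bin_edges = state$ilam$bin_edges,
          total_activation_time_ms = state$ilam$total_activation_time_ms,
          n_mapped_vertices = sum(is.finite(state$ilam$lat)),
          acquired_points = amap$acquired, used_points = amap$used,
          used_rate_pct = amap$used_rate_pct),
          file.path(out_dir, "map_summary.json"), auto_unbox = TRUE,
          digits = NA)
        log("map: %d/%d points used (%.1f%%), total activation time %.1f ms",
            amap$used, amap$acquired, amap$used_rate_pct,
            state$ilam$total_activation_time_ms)
      },
      detect = {
        im <- .load_ilam(state, out_dir, get_mesh)
        thr <- feature_thresholds()
        counts <- isochrone_counts(im, thr$dz_radius_mm)
        zones <- detect_deceleration_zones(im, thr, counts = counts)
        state$zones <- zones
        ann <- .load_projected(state, out_dir, get_mesh)
        lines <- detect_block_lines(im, ann, thr)
        coll <- detect_collisions(im)
        jsonlite::write_json(list(
          deceleration_zones = lapply(zones, function(z)
            list(vertices = z$member_vertices - 1L,
                 peak_isochrone_count = z$peak_isochrone_count,
                 centroid = z$centroid, area_mm2 = z$area_mm2)),
          block_lines = lapply(lines, function(l)
            list(vertices = l$member_vertices - 1L,
                 mean_gap_ms = l$mean_gap_ms,
                 reversal_confirmed = l$reversal_confirmed)),
          collisions = lapply(coll, function(v) v - 1L)),
          file.path(out_dir, "features.json"), auto_unbox = TRUE, digits = NA)
        log("detect: %d deceleration zones, %d block lines, %d collision sites",
            length(zones), length(lines), length(coll))
      },
      analyze = {
        im <- .load_ilam(state, out_dir, get_mesh)
        ais <- delineate_isthmuses(get_mesh())
        ais <- lapply(ais, function(ai) {
          ai <- conduction_time_across(ai, im)
          ai <- conduction_velocity(ai)
          isochrones_per_cm(ai, im)
        })
        if (is.null(state$zones)) {
          thr <- feature_thresholds()
          state$zones <- detect_deceleration_zones(im, thr)
        }
        ais <- attach_dz(ais, state$zones)
        state$ais <- ais
        tab <- if (length(ais)) isthmus_table(ais) else
          data.frame(ai_type = character(0))
        utils::write.csv(tab, file.path(out_dir, "isthmus.csv"),
                         row.names = FALSE)
        log("analyze: %d isthmuses (%d slow-conducting)", nrow(tab),
            sum(tab$sc %in% TRUE))
      },
      validate = {
        tab <- utils::read.csv(file.path(out_dir, "isthmus.csv"))
        truth_file <- file.path(out_dir, "ground_truth.json")
        if (!file.exists(truth_file)) {
          jsonlite::write_json(list(status = "no truth available"),
                               file.path(out_dir, "validation.json"),
                               auto_unbox = TRUE)
          log("validate: no truth available")
        } else {
          gt <- jsonlite::read_json(truth_file, simplifyVector = TRUE,
                                    simplifyDataFrame = FALSE)
          sc_true <- vapply(gt$corridors, function(co) isTRUE(co$sc), logical(1))
          res <- list(n_isthmuses = nrow(tab),
                      n_sc_true = sum(sc_true),
                      n_dz = sum(tab$dz %in% TRUE))
          if (nrow(tab) == length(sc_true) && nrow(tab) > 0) {
            cm <- confusion_metrics(tab$dz, sc_true)
            res <- c(res, cm[c("tp", "fp", "fn", "tn", "sensitivity",
                               "specificity", "f_score")])
          }
          jsonlite::write_json(res, file.path(out_dir, "validation.json"),
                               auto_unbox = TRUE, digits = NA, na = "null")
          log("validate: %d isthmuses, %d DZ-positive", res$n_isthmuses,
              res$n_dz)
        }
      })
  }
  scen_file <- file.path(out_dir, "scenario.json")
  jsonlite::write_json(list(
    config_hash = if (file.exists(scen_file))
      unname(tools::md5sum(scen_file)) else NA,
    seed = config$seed, package_version = "0.1.0",
    stages = stages, timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, na = "null")
  invisible(out_dir)
}

.load_ilam <- function(state, out_dir, get_mesh) {
  if (!is.null(state$ilam)) return(state$ilam)
  mesh <- get_mesh()
  vt <- read_vtk(file.path(out_dir, "ilam.vtk"))
  summ <- jsonlite::read_json(file.path(out_dir, "map_summary.json"),
                              simplifyVector = TRUE)
  state$ilam <- structure(list(
    mesh = mesh, lat = vt$point_data$lat_ms,
    isochrone = as.integer(vt$point_data$isochrone_index),
    bin_edges = summ$bin_edges,
    total_activation_time_ms = summ$total_activation_time_ms,
    points = NULL, rhythm = "sinus"), class = "isochronal_map")
  state$ilam
}

.load_projected <- function(state, out_dir, get_mesh) {
  if (!is.null(state$amap)) return(state$amap$points)
  ann <- utils::read.csv(file.path(out_dir, "annotations.csv"))
  amap <- project_points(activation_map(get_mesh(), ann))
  amap$points
}
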
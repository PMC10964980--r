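# End-to-end pipeline over one corridor scenario, and the synthetic corridor
# cohort used to benchmark DZ detection against planted slow conduction.

#' Run the full mapping pipeline on one scenario
#'
#' simulate -> synthesize electrograms -> annotate -> project -> interpolate
#' -> isochronal map -> deceleration zones -> isthmus analysis.
#'
#' @param scenario an `ilam_scenario` (typically [corridor_scenario()]).
#' @param thr a `feature_thresholds`.
#' @param cfg an `annotation_config`.
#' @return list: `mesh`, `activation`, `truth`, `egm_set`, `annotations`,
#'   `ilam`, `counts`, `zones`, `isthmuses`, `table` (isthmus table).
#' @export
run_corridor_pipeline <- function(scenario, thr = feature_thresholds(),
                                  cfg = annotation_config()) {
  mesh <- generate_surface(scenario)
  act <- simulate_activation(mesh)
  truth <- ground_truth(mesh, act)
  egm_set <- synthesize_electrograms(mesh, act)
  ann <- annotate_sites(egm_set, cfg)
  amap <- activation_map(mesh, ann)
  amap <- project_points(amap)
  amap <- interpolate_lat(amap)
  im <- build_ilam(amap)
  counts <- isochrone_counts(im, thr$dz_radius_mm)
  zones <- detect_deceleration_zones(im, thr, counts = counts)
  zones <- lapply(zones, flag_extreme_slowing, annotations = amap$points,
                  thr = thr)
  ais <- delineate_isthmuses(mesh)
  ais <- lapply(ais, function(ai) {
    ai <- conduction_time_across(ai, im)
    ai <- conduction_velocity(ai)
    isochrones_per_cm(ai, im)
  })
  ais <- attach_dz(ais, zones)
  list(mesh = mesh, activation = act, truth = truth, egm_set = egm_set,
       annotations = amap$points, amap = amap, ilam = im, counts = counts,
       zones = zones, isthmuses = ais,
       table = if (length(ais)) isthmus_table(ais) else NULL)
}

#' Simulate a synthetic corridor cohort
#'
#' Generates `n_corridors` independent single-corridor maps with planted
#' conduction velocities drawn uniformly over `cv_range`, runs the full
#' pipeline on each, and returns one row per corridor relating the planted
#' truth to what the pipeline recovered. This is the study-condition surrogate
#' for the clinical cohort: DZ presence is benchmarked against planted slow
#' conduction (CV < 0.5 m/s), and isochrones/cm against estimated CV.
#'
#' @param n_corridors number of corridors; the default matches the 27
#'   anatomical isthmuses of the clinical cohort this generator emulates
#'   (>= 20 for the recovery benchmark).
#' @param cv_range planted CV range, m/s.
#' @param point_density sites per cm^2.
#' @param noise_mV electrogram noise SD (0 = noiseless annotation).
#' @param seed integer root seed; corridor i uses a seed derived from it.
#' @return data.frame: corridor, planted_cv, sc_true, dz, cv_est, sc_est,
#'   isochrones_per_cm, width_mm, conduction_time_ms, tat_ms, n_zones.
#' @export
simulate_corridor_study <- function(n_corridors = 27, cv_range = c(0.1, 1.5),
                                    point_density = 20, noise_mV = 0,
                                    seed = 1) {
  cvs <- with_substream(seed, "cohort_cv",
                        stats::runif(n_corridors, cv_range[1], cv_range[2]))
  rows <- lapply(seq_len(n_corridors), function(i) {
    sc <- corridor_scenario(seed = (seed * 131 + i) %% 2147483647,
                            planted_cv = cvs[i],
                            point_density = point_density,
                            noise_mV = noise_mV)
    res <- run_corridor_pipeline(sc)
    ai <- res$isthmuses[[1]]
    data.frame(corridor = i, planted_cv = cvs[i], sc_true = cvs[i] < 0.5,
               dz = ai$dz, cv_est = ai$cv_m_s, sc_est = ai$sc,
               isochrones_per_cm = ai$isochrones_per_cm,
               width_mm = ai$width_mm,
               conduction_time_ms = ai$conduction_time_ms,
               tat_ms = res$ilam$total_activation_time_ms,
               n_zones = length(res$zones))
  })
  do.call(rbind, rows)
}
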
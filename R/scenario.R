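# Scenario configuration for the synthetic electroanatomical map generator.

STRUCTURE_LABELS <- c("tricuspid_annulus", "pulmonary_annulus", "vsd_patch",
                      "rv_incision", "scar_patch")
AI_TYPES <- c("AI1", "AI2", "AI3", "AI4")

# taxonomy: bounding structure pair per isthmus class
AI_STRUCTURE_PAIRS <- list(
  AI1 = c("tricuspid_annulus", "rv_incision"),
  AI2 = c("rv_incision", "pulmonary_annulus"),
  AI3 = c("vsd_patch", "pulmonary_annulus"),
  AI4 = c("vsd_patch", "tricuspid_annulus")
)

#' Scenario configuration for a synthetic electroanatomical map
#'
#' A scenario fully determines one synthetic map: the surface geometry, the
#' non-conducting structures (valve annuli, patches, incisions, scar), the
#' conducting corridors between them with their planted conduction velocities,
#' the pacing source(s), the mapping-point density and the electrogram model.
#' A fixed `seed` yields a bit-identical scenario.
#'
#' Structures are placement specs: `list(label=, shape="rect", x=c(x0,x1),
#' y=c(y0,y1))` or `shape="disc", centre=c(x,y), radius=`.
#'
#' @param seed integer root seed; every stochastic draw derives from it.
#' @param geometry list with `kind` ("sheet" or "cylinder"), `length_mm`,
#'   `width_mm`, `spacing_mm` (target edge length).
#' @param structures list of non-conducting placement specs (see Details).
#' @param corridors list of `list(ai_type=, width_mm=, planted_cv=)` declaring
#'   the corridors the structure layout is expected to leave open.
#' @param background_cv background conduction velocity, m/s (= mm/ms).
#' @param pacing_sources list of `list(position=c(x,y), onset_ms=)`.
#' @param point_density mapping sites per cm^2.
#' @param egm list with `rate_hz` (>= 1000) and `noise_mV` (white noise SD).
#' @param ablation_lines optional list of polylines (n x 2 matrices, mm).
#' @return an object of class `ilam_scenario`.
#' @export
scenario_config <- function(seed,
                            geometry = list(kind = "sheet", length_mm = 112,
                                            width_mm = 30, spacing_mm = 1),
                            structures = list(),
                            corridors = list(),
                            background_cv = 1.0,
                            pacing_sources = list(list(position = c(0, 15),
                                                       onset_ms = 0)),
                            point_density = 20,
                            egm = list(rate_hz = 1000, noise_mV = 0.02),
                            ablation_lines = NULL) {
  check_number(seed, "seed")
  if (!geometry$kind %in% c("sheet", "cylinder")) {
    stop_ilam("unknown geometry kind '%s'", geometry$kind)
  }
  check_number(geometry$length_mm, "geometry$length_mm", positive = TRUE)
  check_number(geometry$width_mm, "geometry$width_mm", positive = TRUE)
  check_number(geometry$spacing_mm, "geometry$spacing_mm", positive = TRUE)
  check_number(background_cv, "background_cv", positive = TRUE)
  check_number(point_density, "point_density", positive = TRUE)
  check_number(egm$rate_hz, "egm$rate_hz", positive = TRUE)
  for (s in structures) {
    if (!s$label %in% STRUCTURE_LABELS) {
      stop_ilam("unknown structure label '%s'", s$label)
    }
  }
  for (co in corridors) {
    if (!co$ai_type %in% AI_TYPES) stop_ilam("unknown ai_type '%s'", co$ai_type)
    check_number(co$width_mm, "corridor width_mm", positive = TRUE)
    check_number(co$planted_cv, "corridor planted_cv", positive = TRUE)
  }
  if (length(pacing_sources) < 1L) stop_ilam("at least one pacing source required")
  structure(list(seed = as.integer(seed), geometry = geometry,
                 structures = structures, corridors = corridors,
                 background_cv = background_cv,
                 pacing_sources = pacing_sources,
                 point_density = point_density, egm = egm,
                 ablation_lines = ablation_lines),
            class = "ilam_scenario")
}

#' Standard single-corridor study scenario
#'
#' The workhorse scenario of the synthetic cohort: a rectangular sheet with two
#' non-conducting blocks leaving one conducting corridor between them, paced
#' from the far end so the wavefront funnels through the corridor. Corridor
#' length 18 mm and width 11 mm follow the worked clinical example and the
#' reported median isthmus width; the sheet length is chosen so that, by the
#' isochrone-width law v*T/8, the spatial isochrone width inside the corridor
#' crosses the 1 cm crowding radius near the 0.5 m/s slow-conduction threshold.
#'
#' @param seed integer seed.
#' @param planted_cv corridor conduction velocity, m/s.
#' @param ai_type isthmus class to emulate (labels the bounding blocks).
#' @param corridor_width_mm,corridor_length_mm corridor dimensions, mm.
#' @param background_cv background conduction velocity, m/s.
#' @param point_density mapping sites per cm^2.
#' @param noise_mV electrogram white-noise SD, mV.
#' @param spacing_mm mesh edge length, mm.
#' @return an `ilam_scenario`.
#' @export
corridor_scenario <- function(seed, planted_cv, ai_type = "AI3",
                              corridor_width_mm = 11, corridor_length_mm = 18,
                              background_cv = 1.0, point_density = 20,
                              noise_mV = 0, spacing_mm = 1) {
  len <- 112; wid <- 30
  x0 <- (len - corridor_length_mm) / 2
  x1 <- x0 + corridor_length_mm
  gap0 <- (wid - corridor_width_mm) / 2
  gap1 <- gap0 + corridor_width_mm
  pair <- AI_STRUCTURE_PAIRS[[ai_type]]
  structures <- list(
    list(label = pair[1], shape = "rect", x = c(x0, x1), y = c(0, gap0)),
    list(label = pair[2], shape = "rect", x = c(x0, x1), y = c(gap1, wid))
  )
  sc <- scenario_config(
    seed = seed,
    geometry = list(kind = "sheet", length_mm = len, width_mm = wid,
                    spacing_mm = spacing_mm),
    structures = structures,
    corridors = list(list(ai_type = ai_type, width_mm = corridor_width_mm,
                          planted_cv = planted_cv)),
    background_cv = background_cv,
    pacing_sources = list(list(position = c(0, wid / 2), onset_ms = 0)),
    point_density = point_density,
    egm = list(rate_hz = 1000, noise_mV = noise_mV)
  )
  sc$corridor_region <- list(x = c(x0, x1), y = c(gap0, gap1))
  sc
}

#' Multi-structure right-ventricular sheet scenario
#'
#' An "opened RV" sheet carrying all four classical anatomical-isthmus
#' corridors: tricuspid annulus, pulmonary annulus, VSD patch and an RV
#' incision are placed so that conducting corridors AI1-AI4 remain between
#' them. Used to exercise isthmus delineation on a map with the full taxonomy.
#'
#' @param seed integer seed.
#' @param point_density sites per cm^2.
#' @param noise_mV electrogram noise SD, mV.
#' @return an `ilam_scenario`.
#' @export
rv_sheet_scenario <- function(seed, point_density = 20, noise_mV = 0) {
  scenario_config(
    seed = seed,
    geometry = list(kind = "sheet", length_mm = 100, width_mm = 70,
                    spacing_mm = 1),
    structures = list(
      list(label = "tricuspid_annulus", shape = "disc",
           centre = c(50, 8), radius = 10),
      list(label = "pulmonary_annulus", shape = "disc",
           centre = c(50, 62), radius = 8),
      list(label = "vsd_patch", shape = "rect", x = c(30, 46), y = c(28, 46)),
      list(label = "rv_incision", shape = "rect", x = c(62, 65), y = c(20, 52))
    ),
    corridors = list(),
    background_cv = 1.0,
    pacing_sources = list(list(position = c(2, 35), onset_ms = 0)),
    point_density = point_density,
    egm = list(rate_hz = 1000, noise_mV = noise_mV)
  )
}

#' @export
print.ilam_scenario <- function(x, ...) {
  cat(sprintf("ilam scenario (seed %d): %s %g x %g mm, spacing %g mm\n",
              x$seed, x$geometry$kind, x$geometry$length_mm,
              x$geometry$width_mm, x$geometry$spacing_mm))
  cat(sprintf("  structures: %s\n",
              if (length(x$structures)) paste(vapply(x$structures, `[[`, "",
                                                     "label"), collapse = ", ")
              else "none"))
  for (co in x$corridors) {
    cat(sprintf("  corridor %s: width %g mm, planted CV %.2f m/s\n",
                co$ai_type, co$width_mm, co$planted_cv))
  }
  cat(sprintf("  background CV %.2f m/s, density %g sites/cm^2\n",
              x$background_cv, x$point_density))
  invisible(x)
}
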
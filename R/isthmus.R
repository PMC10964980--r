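# Anatomical isthmus analysis: delineation between non-conducting structures,
# conduction time / velocity, isochrones per cm, slow-conduction
# classification, deceleration-zone co-localization.

#' Delineate anatomical isthmuses on a labelled mesh
#'
#' One candidate corridor per structure pair of the classical taxonomy —
#' tricuspid annulus to RV incision (AI1), RV incision to pulmonary annulus
#' (AI2), VSD patch to pulmonary annulus (AI3), VSD patch to tricuspid
#' annulus (AI4) — wherever both structures exist and a conducting corridor
#' of plausible width lies between them. The corridor axis is the mid-corridor
#' geodesic from entry to exit; the width is the minimal boundary-to-boundary
#' distance.
#'
#' @param mesh a labelled `ilam_mesh`.
#' @param max_width_mm widest gap still considered a corridor, mm.
#' @return list of `anatomical_isthmus` objects (possibly empty): `ai_type`,
#'   `structures`, `width_mm`, `entry_vertex`, `exit_vertex`,
#'   `axis_vertices`, `axis_length_mm`, `region_vertices`.
#' @export
delineate_isthmuses <- function(mesh, max_width_mm = 40) {
  cond <- which(mesh$label == "conducting")
  cpos <- mesh$vertices[cond, , drop = FALSE]
  g <- mesh_graph(mesh)
  out <- list()
  for (ai_type in AI_TYPES) {
    pair <- AI_STRUCTURE_PAIRS[[ai_type]]
    va <- mesh$vertices[mesh$label == pair[1], , drop = FALSE]
    vb <- mesh$vertices[mesh$label == pair[2], , drop = FALSE]
    if (nrow(va) == 0L || nrow(vb) == 0L) next
    dA <- .min_dist_to_set(cpos, va)
    dB <- .min_dist_to_set(cpos, vb)
    through <- dA + dB
    wmin <- min(through)
    width <- wmin - mesh$spacing  # half-spacing boundary offset on each side
    if (!is.finite(width) || width > max_width_mm) next
    region <- cond[through <= wmin + 2 * mesh$spacing]
    if (length(region) < 3L) next
    ab <- colMeans(vb)[1:2] - colMeans(va)[1:2]
    ab <- ab / sqrt(sum(ab^2))
    axis_dir <- c(-ab[2], ab[1])  # corridor axis is transverse to the gap
    proj <- mesh$vertices[region, 1:2, drop = FALSE] %*% axis_dir
    # clip the axis to the overlap of the bounding structures along it, so
    # the entry/exit sit at the corridor mouths, not in the open field
    pa <- va[, 1:2, drop = FALSE] %*% axis_dir
    pb <- vb[, 1:2, drop = FALSE] %*% axis_dir
    lo <- max(min(pa), min(pb)); hi <- min(max(pa), max(pb))
    if (hi - lo < 5) { lo <- min(proj); hi <- max(proj) }
    entry <- region[which.min(abs(proj - lo))]
    exit <- region[which.max(-abs(proj - hi))]
    sp <- igraph::shortest_paths(g, from = entry, to = exit,
                                 output = "vpath")$vpath[[1]]
    if (length(sp) == 0L) next  # no conducting path: not a corridor
    axis_vertices <- as.integer(sp)
    axis_len <- igraph::distances(g, v = entry, to = exit)[1, 1]
    out[[length(out) + 1L]] <- structure(
      list(ai_type = ai_type, structures = pair, width_mm = width,
           entry_vertex = entry, exit_vertex = exit,
           axis_vertices = axis_vertices, axis_length_mm = axis_len,
           region_vertices = region,
           conduction_time_ms = NA_real_, cv_m_s = NA_real_, sc = NA,
           dz = NA, isochrones_per_cm = NA_real_),
      class = "anatomical_isthmus")
  }
  out
}

# min euclidean distance of each row of `pts` to the set `set`
.min_dist_to_set <- function(pts, set) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(set))) d <- pmin(d, .dist_to_point(pts, set[i, ]))
  d
}

#' Conduction time across an isthmus
#'
#' Difference of local activation times at the two sides of the isthmus, each
#' side's LAT taken as the median over a 3 mm cap around the axis endpoint
#' (robust to single-point annotation noise).
#'
#' @param ai an `anatomical_isthmus`.
#' @param im an `isochronal_map`.
#' @param cap_mm endpoint cap radius, mm.
#' @return the isthmus with `conduction_time_ms` filled.
#' @export
conduction_time_across <- function(ai, im, cap_mm = 3) {
  lat <- im$lat
  cap_lat <- function(v) {
    d <- .dist_to_point(im$mesh$vertices, im$mesh$vertices[v, ])
    vals <- lat[d <= cap_mm & is.finite(lat)]
    if (length(vals) == 0L) stop_ilam("isthmus %s not mapped at an endpoint",
                                      ai$ai_type)
    stats::median(vals)
  }
  ai$conduction_time_ms <- abs(cap_lat(ai$exit_vertex) -
                                 cap_lat(ai$entry_vertex))
  ai
}

#' Conduction velocity of an isthmus
#'
#' Geodesic axis length divided by conduction time; in mm/ms, numerically
#' equal to m/s. Full precision is retained on the object; use [format_cv()]
#' for report-layer rounding.
#'
#' @param ai an `anatomical_isthmus` with conduction time, or a list with
#'   `axis_length_mm` and `conduction_time_ms`.
#' @return the isthmus with `cv_m_s` and `sc` filled.
#' @export
conduction_velocity <- function(ai) {
  if (!is.finite(ai$conduction_time_ms) || ai$conduction_time_ms <= 0) {
    stop_ilam("conduction time must be > 0 to compute CV")
  }
  if (!is.finite(ai$axis_length_mm) || ai$axis_length_mm <= 0) {
    stop_ilam("axis length must be > 0 to compute CV")
  }
  ai$cv_m_s <- ai$axis_length_mm / ai$conduction_time_ms
  ai$sc <- classify_sc(ai$cv_m_s)
  ai
}

#' Slow-conduction classification
#'
#' An isthmus is slow-conducting when its CV is strictly below 0.5 m/s.
#'
#' @param cv conduction velocity in m/s (or an `anatomical_isthmus`).
#' @param threshold m/s.
#' @return logical.
#' @export
classify_sc <- function(cv, threshold = 0.5) {
  if (inherits(cv, "anatomical_isthmus")) cv <- cv$cv_m_s
  check_number(cv, "cv")
  cv < threshold
}

#' Report-layer CV rounding
#'
#' @param cv m/s.
#' @param digits decimals (clinical reports print 1-2).
#' @return rounded value.
#' @export
format_cv <- function(cv, digits = 1) round(cv, digits)

#' Isochrones per centimetre along an isthmus axis
#'
#' Isochrones traversed along the corridor axis per centimetre. Counted
#' continuously as the LAT span along the axis divided by the isochrone bin
#' width, plus one (a constant-LAT corridor touches exactly one isochrone) —
#' the continuum form of the isochrone-width law, 8/(v*T) per unit length.
#' Clinical displays show the rounded integer; the continuous value avoids
#' quantising short axes into a handful of tied levels.
#'
#' @param ai an `anatomical_isthmus`.
#' @param im an `isochronal_map`.
#' @return the isthmus with `isochrones_per_cm` filled.
#' @export
isochrones_per_cm <- function(ai, im) {
  if (ai$axis_length_mm < 5) stop_ilam("corridor too short to grade (%.1f mm)",
                                       ai$axis_length_mm)
  lat <- im$lat[ai$axis_vertices]
  lat <- lat[is.finite(lat)]
  if (length(lat) == 0L) stop_ilam("isthmus axis is unmapped")
  bw <- im$total_activation_time_ms / 8
  n_iso <- (max(lat) - min(lat)) / bw + 1
  ai$isochrones_per_cm <- n_iso / (ai$axis_length_mm / 10)
  ai
}

#' Attach deceleration-zone co-localization flags
#'
#' An isthmus is DZ-positive when any detected zone shares at least one
#' vertex with the corridor region.
#'
#' @param ais list of `anatomical_isthmus`.
#' @param zones list of `deceleration_zone`.
#' @return the list with each `dz` flag set.
#' @export
attach_dz <- function(ais, zones) {
  zone_verts <- unlist(lapply(zones, `[[`, "member_vertices"))
  lapply(ais, function(ai) {
    ai$dz <- length(zones) > 0L && any(ai$region_vertices %in% zone_verts)
    ai
  })
}

#' Tabulate isthmus characteristics
#'
#' Per-isthmus summary row set matching the clinical report layout.
#'
#' @param ais list of analysed `anatomical_isthmus`.
#' @return data.frame: ai_type, width_mm, isochrones_per_cm, dz, cv_m_s, sc.
#' @export
isthmus_table <- function(ais) {
  do.call(rbind, lapply(ais, function(ai) {
    data.frame(ai_type = ai$ai_type, width_mm = ai$width_mm,
               isochrones_per_cm = ai$isochrones_per_cm, dz = ai$dz,
               cv_m_s = ai$cv_m_s, sc = ai$sc)
  }))
}

#' @export
print.anatomical_isthmus <- function(x, ...) {
  cat(sprintf("%s: width %.1f mm, axis %.1f mm", x$ai_type, x$width_mm,
              x$axis_length_mm))
  if (is.finite(x$cv_m_s)) {
    cat(sprintf(", CT %.1f ms, CV %.2f m/s (%s)", x$conduction_time_ms,
                x$cv_m_s, if (isTRUE(x$sc)) "SC" else "normal"))
  }
  cat("\n")
  invisible(x)
}
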
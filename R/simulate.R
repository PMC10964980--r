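# First-arrival activation simulation and ablation-line editing.

#' Simulate activation times on a labelled mesh
#'
#' First-arrival local activation times under a spatially varying conduction
#' velocity: Dijkstra on the conducting edge graph with edge traversal time
#' edge length / harmonic mean of the endpoint CVs — a first-order eikonal
#' approximation whose metric error shrinks with mesh refinement. LAT at a
#' source equals its onset; with several sources each vertex takes the earliest
#' arrival.
#'
#' @param mesh an `ilam_mesh`.
#' @param cv per-vertex conduction velocity, m/s (= mm/ms); must be > 0 on
#'   conducting vertices. Defaults to [cv_field()] of the mesh's scenario.
#' @param sources list of `list(position=c(x,y), onset_ms=)` or of
#'   `list(vertex=, onset_ms=)`.
#' @return list of class `ilam_activation`: `lat` (ms per vertex, NA on
#'   non-conducting or unreachable vertices), `source_vertices`, `unreached`.
#' @export
simulate_activation <- function(mesh, cv = NULL, sources = NULL) {
  if (is.null(cv)) cv <- cv_field(mesh)
  if (is.null(sources)) sources <- mesh$scenario$pacing_sources
  cond <- mesh$label == "conducting"
  if (any(cv[cond] <= 0, na.rm = TRUE) || anyNA(cv[cond])) {
    stop_ilam("cv must be positive and finite on all conducting vertices")
  }
  src_v <- vapply(sources, function(s) {
    if (!is.null(s$vertex)) as.integer(s$vertex)
    else nearest_vertex(mesh, matrix(s$position, nrow = 1))
  }, integer(1))
  onsets <- vapply(sources, function(s) s$onset_ms %||% 0, numeric(1))
  if (any(!cond[src_v])) {
    stop_ilam("pacing source on non-conducting vertex (vertex %d)",
              src_v[which(!cond[src_v])[1]])
  }
  g <- mesh_graph(mesh, cv)
  d <- igraph::distances(g, v = src_v, algorithm = "dijkstra")
  lat <- apply(d + onsets, 2, min)
  lat[!cond] <- NA_real_
  unreached <- which(cond & !is.finite(lat))
  if (length(unreached)) {
    warning(sprintf("%d conducting vertices unreachable; flagged unmapped",
                    length(unreached)), call. = FALSE)
    lat[unreached] <- NA_real_
  }
  structure(list(lat = lat, source_vertices = src_v, onsets = onsets,
                 unreached = unreached),
            class = "ilam_activation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sever conduction across an ablation line
#'
#' Marks every conducting mesh edge that crosses the polyline as
#' non-conducting (in the x-y surface parameterisation). Re-simulating on the
#' edited mesh reproduces the post-ablation activation pattern: if a detour
#' path exists the activation direction distal to the line reverses; if not,
#' distal vertices become unreachable and are flagged unmapped.
#'
#' @param mesh an `ilam_mesh`.
#' @param polyline n x 2 matrix of mm coordinates on the surface (n >= 2); an
#'   empty polyline leaves the mesh unchanged.
#' @return the mesh with crossing edges severed (recorded in `$severed` and
#'   `$ablation_polylines`).
#' @export
apply_ablation_line <- function(mesh, polyline) {
  if (is.null(polyline) || length(polyline) == 0L || nrow(polyline) < 2L) {
    return(mesh)
  }
  # densify the polyline so the non-conducting check sees its whole course
  dense <- do.call(rbind, lapply(seq_len(nrow(polyline) - 1L), function(k) {
    nseg <- max(2L, ceiling(sqrt(sum((polyline[k + 1L, ] - polyline[k, ])^2)) /
                              (mesh$spacing / 2)))
    cbind(seq(polyline[k, 1], polyline[k + 1L, 1], length.out = nseg),
          seq(polyline[k, 2], polyline[k + 1L, 2], length.out = nseg))
  }))
  near <- nearest_vertex(mesh, dense)
  if (all(mesh$label[near] != "conducting")) {
    warning("ablation polyline lies entirely in non-conducting tissue; no-op",
            call. = FALSE)
    return(mesh)
  }
  sev <- mesh$severed %||% rep(FALSE, nrow(mesh$metric_edges))
  p1 <- mesh$vertices[mesh$metric_edges[, 1], 1:2, drop = FALSE]
  p2 <- mesh$vertices[mesh$metric_edges[, 2], 1:2, drop = FALSE]
  for (k in seq_len(nrow(polyline) - 1L)) {
    a <- polyline[k, ]; b <- polyline[k + 1L, ]
    sev <- sev | .segments_cross(p1, p2, a, b)
  }
  mesh$severed <- sev
  mesh$ablation_polylines <- c(mesh$ablation_polylines, list(polyline))
  mesh
}

# vectorised proper-intersection test of edges (p1->p2 rows) vs segment a->b
.segments_cross <- function(p1, p2, a, b) {
  d <- function(p, q, r) (q[, 1] - p[, 1]) * (r[, 2] - p[, 2]) -
    (q[, 2] - p[, 2]) * (r[, 1] - p[, 1])
  am <- matrix(a, nrow(p1), 2, byrow = TRUE)
  bm <- matrix(b, nrow(p1), 2, byrow = TRUE)
  d1 <- d(am, bm, p1); d2 <- d(am, bm, p2)
  d3 <- d(p1, p2, am); d4 <- d(p1, p2, bm)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

#' Ground truth for a simulated scenario
#'
#' Bundles the quantities the recovery tests grade against: per-vertex true
#' LAT, per-corridor planted CV with its slow-conduction status (CV < 0.5
#' m/s), and the severed-edge record.
#'
#' @param mesh an `ilam_mesh`.
#' @param activation an `ilam_activation` from [simulate_activation()].
#' @return list of class `ilam_truth`.
#' @export
ground_truth <- function(mesh, activation) {
  corridors <- lapply(mesh$scenario$corridors, function(co) {
    list(ai_type = co$ai_type, planted_cv = co$planted_cv,
         sc = co$planted_cv < 0.5)
  })
  structure(list(lat = activation$lat, corridors = corridors,
                 severed = mesh$severed),
            class = "ilam_truth")
}
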
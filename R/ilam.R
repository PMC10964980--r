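# Isochronal late activation map construction: point projection, LAT
# interpolation over the surface, eight-isochrone partition.

#' Assemble an activation map from annotated points
#'
#' @param mesh an `ilam_mesh`.
#' @param annotations data.frame from [annotate_sites()] (needs x, y, lat_ms,
#'   used).
#' @param rhythm "sinus" or "paced".
#' @return object of class `activation_map`.
#' @export
activation_map <- function(mesh, annotations, rhythm = "sinus") {
  structure(list(mesh = mesh, points = annotations, rhythm = rhythm,
                 vertex_lat = NULL, acquired = nrow(annotations),
                 used = sum(annotations$used)),
            class = "activation_map")
}

#' Project annotated points onto the mesh
#'
#' Each used point is assigned to its nearest vertex; points farther than
#' `max_distance` (or landing on non-conducting tissue) are flagged unused.
#' The used/acquired counts mirror the clinical used-point rate.
#'
#' @param amap an `activation_map`.
#' @param max_distance projection cutoff, mm.
#' @return the map with `points$vertex` filled and the used flags updated.
#' @export
project_points <- function(amap, max_distance = 5) {
  pts <- amap$points
  if (sum(pts$used) == 0L) stop_ilam("no usable points to project")
  pos <- cbind(pts$x, pts$y, 0)
  nv <- nearest_vertex(amap$mesh, pos)
  d <- sqrt(rowSums((amap$mesh$vertices[nv, , drop = FALSE] - pos)^2))
  ok <- pts$used & d <= max_distance &
    amap$mesh$label[nv] == "conducting" & is.finite(pts$lat_ms)
  pts$vertex <- ifelse(ok, nv, NA_integer_)
  pts$projection_dist <- d
  pts$used <- ok
  amap$points <- pts
  amap$used <- sum(ok)
  amap$used_rate_pct <- used_point_rate(amap$used, amap$acquired)
  amap
}

#' Interpolate LAT over the conducting surface
#'
#' Inverse-distance-weighted (power 2) mean of the projected point LATs within
#' a geodesic `fill_radius` of each vertex; exact at point-bearing vertices;
#' vertices with no point in radius stay unmapped (NA).
#'
#' @param amap a projected `activation_map`.
#' @param fill_radius geodesic interpolation radius, mm.
#' @return the map with `vertex_lat` filled.
#' @export
interpolate_lat <- function(amap, fill_radius = 5) {
  pts <- amap$points[amap$points$used, , drop = FALSE]
  if (nrow(pts) == 0L) stop_ilam("no projected points to interpolate")
  mesh <- amap$mesh
  g <- mesh_graph(mesh)
  pv <- unique(pts$vertex)
  d <- igraph::distances(g, v = pv, algorithm = "dijkstra")
  d[d > fill_radius] <- Inf
  # mean LAT of points sharing a vertex (duplicate projections)
  plat <- tapply(pts$lat_ms, pts$vertex, mean)[as.character(pv)]
  w <- 1 / pmax(d, 1e-9)^2
  w[!is.finite(d)] <- 0
  num <- colSums(w * as.numeric(plat))
  den <- colSums(w)
  lat <- ifelse(den > 0, num / den, NA_real_)
  lat[pv] <- plat  # exact at point-bearing vertices
  lat[mesh$label != "conducting"] <- NA_real_
  amap$vertex_lat <- lat
  amap
}

#' Build the eight-isochrone map
#'
#' Partitions the mapped LAT range into eight equal-width bins (the map's own
#' activation span, not a fixed window). Isochrone indices run 0-7; the last
#' bin is right-closed so the latest vertex takes index 7, the others are
#' right-open. Total activation time is LATmax - LATmin.
#'
#' @param amap an interpolated `activation_map` (or list with `mesh` and
#'   `vertex_lat`).
#' @return object of class `isochronal_map`: `mesh`, `lat`, `isochrone`
#'   (integer 0-7, NA unmapped), `bin_edges` (9 values),
#'   `total_activation_time_ms`.
#' @export
build_ilam <- function(amap) {
  lat <- amap$vertex_lat
  if (is.null(lat)) stop_ilam("activation map has no interpolated LAT")
  mapped <- which(is.finite(lat))
  if (length(mapped) < 2L) stop_ilam("need >= 2 mapped vertices")
  rng <- range(lat[mapped])
  if (diff(rng) <= 0) stop_ilam("degenerate activation range")
  edges <- seq(rng[1], rng[2], length.out = 9L)
  idx <- isochrone_index(lat, edges)
  structure(list(mesh = amap$mesh, lat = lat, isochrone = idx,
                 bin_edges = edges,
                 total_activation_time_ms = diff(rng),
                 points = amap$points, rhythm = amap$rhythm %||% "sinus"),
            class = "isochronal_map")
}

#' Isochrone index of LAT values given bin edges
#'
#' @param lat numeric LAT values, ms.
#' @param edges 9 increasing bin edges, ms.
#' @return integer indices 0-7 (NA outside range or unmapped); values equal to
#'   the last edge fall in bin 7 (right-closed last bin).
#' @export
isochrone_index <- function(lat, edges) {
  width <- (edges[9] - edges[1]) / 8
  idx <- floor((lat - edges[1]) / width)
  idx[lat >= edges[9]] <- 7L  # right-closed last bin
  idx[lat < edges[1] | lat > edges[9]] <- NA_integer_
  as.integer(idx)
}

#' @export
print.isochronal_map <- function(x, ...) {
  cat(sprintf("isochronal map: %d mapped vertices, total activation time %.1f ms\n",
              sum(is.finite(x$lat)), x$total_activation_time_ms))
  cat(sprintf("  8 isochrones, bin width %.2f ms\n",
              x$total_activation_time_ms / 8))
  invisible(x)
}
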
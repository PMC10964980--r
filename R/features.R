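# Propagation features: deceleration zones (isochronal crowding), extreme
# slowing, lines of conduction block, wave-front collision.

#' Feature detection thresholds
#'
#' Defaults fix the published constants: a deceleration zone needs more than
#' three isochrones within a 1 cm radius (`dz_min_isochrones = 4` distinct
#' indices, radius 10 mm, read literally as a radius), and a block line needs
#' an isoelectric split gap above 20 ms. The minimum zone area suppresses
#' single-vertex speckle; extreme slowing additionally requires the denser
#' crowding count and majority fractionation.
#'
#' @param dz_radius_mm crowding radius, mm.
#' @param dz_min_isochrones minimum distinct isochrone count (strictly more
#'   than 3).
#' @param block_gap_ms split-potential gap, ms.
#' @param min_zone_area_mm2 minimum deceleration-zone area, mm^2.
#' @param extreme_min_count crowding count at or above which a zone may be
#'   called extreme.
#' @param extreme_requires_fractionation logical; require majority
#'   fractionated sites for the extreme flag.
#' @return list of class `feature_thresholds`.
#' @export
feature_thresholds <- function(dz_radius_mm = 10, dz_min_isochrones = 4,
                               block_gap_ms = 20, min_zone_area_mm2 = 10,
                               extreme_min_count = 6,
                               extreme_requires_fractionation = TRUE) {
  structure(list(dz_radius_mm = dz_radius_mm,
                 dz_min_isochrones = dz_min_isochrones,
                 block_gap_ms = block_gap_ms,
                 min_zone_area_mm2 = min_zone_area_mm2,
                 extreme_min_count = extreme_min_count,
                 extreme_requires_fractionation = extreme_requires_fractionation),
            class = "feature_thresholds")
}

#' Count distinct isochrones within a radius of one vertex
#'
#' Number of distinct isochrone indices among mapped vertices within the
#' geodesic (on-surface) radius.
#'
#' @param im an `isochronal_map`.
#' @param vertex mapped vertex id.
#' @param radius_mm geodesic radius, mm.
#' @return integer count.
#' @export
count_isochrones_in_radius <- function(im, vertex, radius_mm = 10) {
  if (!is.finite(im$lat[vertex])) stop_ilam("vertex %d is unmapped", vertex)
  d <- geodesic_distances(im$mesh, from = vertex)
  near <- which(d[1, ] <= radius_mm & is.finite(im$lat))
  length(unique(im$isochrone[near]))
}

#' Crowding counts for all mapped vertices
#'
#' Vectorised [count_isochrones_in_radius()] over the whole map.
#'
#' @param im an `isochronal_map`.
#' @param radius_mm geodesic radius, mm.
#' @return integer vector per vertex (NA where unmapped).
#' @export
isochrone_counts <- function(im, radius_mm = 10) {
  mesh <- im$mesh
  mapped <- which(is.finite(im$lat))
  g <- mesh_graph(mesh)
  counts <- rep(NA_integer_, nrow(mesh$vertices))
  idx <- im$isochrone
  chunk <- 400L
  for (start in seq(1L, length(mapped), by = chunk)) {
    rows <- mapped[start:min(start + chunk - 1L, length(mapped))]
    d <- igraph::distances(g, v = rows, to = mapped, algorithm = "dijkstra")
    for (i in seq_along(rows)) {
      near <- mapped[d[i, ] <= radius_mm]
      counts[rows[i]] <- length(unique(idx[near]))
    }
  }
  counts
}

#' Detect deceleration zones
#'
#' Connected components (over the conducting mesh adjacency) of vertices whose
#' crowding count strictly exceeds three, with components below the minimum
#' area discarded. Zones are returned sorted by peak count, descending. An
#' empty list is a valid outcome (fast uniform maps have no crowding).
#'
#' @param im an `isochronal_map`.
#' @param thr a `feature_thresholds`.
#' @param counts optional precomputed [isochrone_counts()].
#' @return list of `deceleration_zone` objects: `member_vertices`,
#'   `peak_isochrone_count`, `centroid`, `area_mm2`, `extreme`.
#' @export
detect_deceleration_zones <- function(im, thr = feature_thresholds(),
                                      counts = NULL) {
  if (is.null(counts)) counts <- isochrone_counts(im, thr$dz_radius_mm)
  hot <- which(!is.na(counts) & counts >= thr$dz_min_isochrones)
  if (length(hot) == 0L) return(list())
  mesh <- im$mesh
  open <- .edge_open(mesh)
  e <- mesh$edges[open, , drop = FALSE]
  keep <- e[, 1] %in% hot & e[, 2] %in% hot
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(e[keep, , drop = FALSE]))
  comp <- igraph::components(g)
  areas <- vertex_areas(mesh)
  zones <- list()
  for (cid in unique(comp$membership[hot])) {
    members <- hot[comp$membership[hot] == cid]
    area <- sum(areas[members])
    if (area < thr$min_zone_area_mm2) next
    zones[[length(zones) + 1L]] <- structure(
      list(member_vertices = members,
           peak_isochrone_count = max(counts[members]),
           centroid = colMeans(mesh$vertices[members, , drop = FALSE]),
           area_mm2 = area, extreme = FALSE),
      class = "deceleration_zone")
  }
  zones[order(vapply(zones, `[[`, numeric(1), "peak_isochrone_count"),
              decreasing = TRUE)]
}

#' Flag extreme conduction slowing in a deceleration zone
#'
#' A zone shows extreme slowing when its isochronal crowding is denser
#' (peak count at or above `extreme_min_count`) AND the majority of mapping
#' sites inside it carry continuous fractionated activity. Both conditions are
#' required.
#'
#' @param dz a `deceleration_zone`.
#' @param annotations site annotations with `vertex` and `fractionated`
#'   columns (projected points).
#' @param thr a `feature_thresholds`.
#' @return the zone with its `extreme` flag set.
#' @export
flag_extreme_slowing <- function(dz, annotations, thr = feature_thresholds()) {
  dense <- dz$peak_isochrone_count >= thr$extreme_min_count
  inside <- annotations[!is.na(annotations$vertex) &
                          annotations$vertex %in% dz$member_vertices, ,
                        drop = FALSE]
  frac_majority <- nrow(inside) > 0L && mean(inside$fractionated) > 0.5
  dz$extreme <- dense && (frac_majority || !thr$extreme_requires_fractionation)
  dz
}

#' Detect lines of conduction block
#'
#' Candidate vertex pairs are mapped vertices lying within 2.5 mesh spacings
#' of each other whose LAT difference exceeds one isochrone bin width, with a
#' split-potential site (isoelectric gap > 20 ms) within 3 mm. Candidate
#' vertices are chained into lines by spatial proximity; a line is
#' `reversal_confirmed` when the LAT gradient along the line's axis has
#' opposite signs on its two sides.
#'
#' @param im an `isochronal_map`.
#' @param annotations projected site annotations (needs x, y, split).
#' @param thr a `feature_thresholds`.
#' @return list of `block_line` objects: `member_vertices`, `mean_gap_ms`,
#'   `reversal_confirmed`.
#' @export
detect_block_lines <- function(im, annotations, thr = feature_thresholds()) {
  mesh <- im$mesh
  lat <- im$lat
  bw <- im$total_activation_time_ms / 8
  mapped <- which(is.finite(lat))
  pr <- .near_pairs(mesh$vertices[mapped, 1:2, drop = FALSE],
                    2.5 * mesh$spacing)
  if (nrow(pr) == 0L) return(list())
  a <- mapped[pr[, 1]]; b <- mapped[pr[, 2]]
  jump <- abs(lat[a] - lat[b]) > bw
  a <- a[jump]; b <- b[jump]
  if (length(a) == 0L) return(list())
  split_sites <- annotations[annotations$split %in% TRUE, , drop = FALSE]
  if (nrow(split_sites) == 0L) return(list())
  mid <- (mesh$vertices[a, 1:2, drop = FALSE] +
            mesh$vertices[b, 1:2, drop = FALSE]) / 2
  has_split <- vapply(seq_len(nrow(mid)), function(i) {
    any((split_sites$x - mid[i, 1])^2 + (split_sites$y - mid[i, 2])^2 <= 9)
  }, logical(1))
  a <- a[has_split]; b <- b[has_split]
  verts <- unique(c(a, b))
  if (length(verts) == 0L) return(list())
  # chain into lines by proximity
  vp <- mesh$vertices[verts, 1:2, drop = FALSE]
  link <- .near_pairs(vp, 2.5 * mesh$spacing)
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  if (nrow(link)) g <- igraph::add_edges(g, t(link))
  comp <- igraph::components(g)
  gaps <- annotations$gap_ms[annotations$split %in% TRUE]
  lapply(seq_len(comp$no), function(cid) {
    members <- verts[comp$membership == cid]
    inside <- a %in% members & b %in% members
    # the line normal is the common direction of the jump pairs spanning it
    dirs <- mesh$vertices[b[inside], 1:2, drop = FALSE] -
      mesh$vertices[a[inside], 1:2, drop = FALSE]
    dirs <- dirs * sign(lat[b[inside]] - lat[a[inside]])  # orient to late side
    normal <- colSums(dirs / sqrt(rowSums(dirs^2)))
    normal <- normal / sqrt(sum(normal^2))
    structure(list(member_vertices = members,
                   mean_gap_ms = mean(gaps, na.rm = TRUE),
                   reversal_confirmed = .reversal_across(mesh, lat, members,
                                                         normal)),
              class = "block_line")
  })
}

# all index pairs (i < j) of rows of xy closer than r, via cell binning
.near_pairs <- function(xy, r) {
  n <- nrow(xy)
  if (n < 2L) return(matrix(integer(0), 0, 2))
  cx <- floor(xy[, 1] / r); cy <- floor(xy[, 2] / r)
  key <- paste(cx, cy)
  cells <- split(seq_len(n), key)
  coords <- unique(cbind(cx, cy))
  out <- vector("list", 0)
  lookup <- function(i, j) cells[[paste(i, j)]]
  for (cell in seq_len(nrow(coords))) {
    i0 <- coords[cell, 1]; j0 <- coords[cell, 2]
    here <- lookup(i0, j0)
    neigh <- unlist(lapply(-1:1, function(di) lapply(-1:1, function(dj) {
      lookup(i0 + di, j0 + dj)
    })), use.names = FALSE)
    for (i in here) {
      cand <- neigh[neigh > i]
      if (!length(cand)) next
      d2 <- (xy[cand, 1] - xy[i, 1])^2 + (xy[cand, 2] - xy[i, 2])^2
      hit <- cand[d2 <= r^2]
      if (length(hit)) out[[length(out) + 1L]] <- cbind(i, hit)
    }
  }
  if (!length(out)) matrix(integer(0), 0, 2) else do.call(rbind, out)
}

# opposite LAT-gradient directions on the two sides of a candidate line;
# the fit band starts a little away from the line because split-potential
# annotation smears the late component across it
.reversal_across <- function(mesh, lat, members, normal, band_mm = 9,
                             exclusion_mm = 2, along_mm = 10) {
  pos <- mesh$vertices[members, 1:2, drop = FALSE]
  ctr <- colMeans(pos)
  axis <- c(-normal[2], normal[1])
  rel <- sweep(mesh$vertices[, 1:2, drop = FALSE], 2, ctr)
  s <- rel %*% normal          # signed distance from line
  along <- rel %*% axis
  near <- which(is.finite(lat) & abs(s) <= band_mm & abs(s) >= exclusion_mm &
                  abs(along) <= along_mm & !(seq_along(lat) %in% members))
  slope_of <- function(v) {
    if (length(v) < 3L) return(NA_real_)
    stats::coef(stats::lm(lat[v] ~ s[v]))[2]
  }
  g1 <- slope_of(near[s[near] > 0])
  g2 <- slope_of(near[s[near] < 0])
  is.finite(g1) && is.finite(g2) && g1 * g2 < 0
}

#' Detect wave-front collision sites
#'
#' Vertices that are local LAT maxima whose neighbourhood contains two
#' approach directions with negative inner product (two opposing wavefronts
#' arriving simultaneously). Returned as clusters of adjacent collision
#' vertices.
#'
#' @param im an `isochronal_map`.
#' @param tol_ms ties within this tolerance still count as a local maximum.
#' @return list of integer vertex sets (possibly empty).
#' @export
detect_collisions <- function(im, tol_ms = 1e-6) {
  mesh <- im$mesh
  lat <- im$lat
  open <- .edge_open(mesh)
  e <- mesh$edges[open, , drop = FALSE]
  nbr <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  cand <- logical(nrow(mesh$vertices))
  for (v in which(is.finite(lat))) {
    nb <- nbr[[as.character(v)]]
    nb <- nb[is.finite(lat[nb])]
    if (length(nb) < 2L) next
    if (any(lat[nb] > lat[v] + tol_ms)) next  # not a local maximum
    lower <- nb[lat[nb] < lat[v] - tol_ms]
    if (length(lower) < 2L) next
    dirs <- sweep(mesh$vertices[lower, 1:2, drop = FALSE], 2,
                  mesh$vertices[v, 1:2])
    dirs <- dirs / sqrt(rowSums(dirs^2))
    gr <- dirs %*% t(dirs)
    if (any(gr < -0.2)) cand[v] <- TRUE
  }
  hot <- which(cand)
  if (!length(hot)) return(list())
  keep <- e[, 1] %in% hot & e[, 2] %in% hot
  g <- igraph::make_empty_graph(n = nrow(mesh$vertices), directed = FALSE)
  g <- igraph::add_edges(g, t(e[keep, , drop = FALSE]))
  comp <- igraph::components(g)
  unname(split(hot, comp$membership[hot]))
}
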
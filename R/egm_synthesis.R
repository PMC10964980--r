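# Synthetic bipolar electrograms for simulated activation fields.
#
# Signal model: each wavefront passage contributes one compact biphasic
# wavelet whose support ENDS exactly at the local activation time, so that
# last-deflection annotation recovers the planted LAT by construction. Slow
# regions additionally carry trains of low-amplitude presystolic wavelets
# (continuous fractionated activity); sites bridging a conduction gap carry a
# second, later component (split potential). White acquisition noise on top.

WAVELET_DUR_MS <- 12   # total support, ms
WAVELET_TAIL_MS <- 2   # terminal stroke: sharp final downstroke ending at LAT

# biphasic wavelet sampled at times t (ms), peak-to-peak p2p, offset at `lat`
.egm_wavelet <- function(t, lat, p2p) {
  A <- p2p / 2
  s <- numeric(length(t))
  t0 <- lat - WAVELET_DUR_MS
  body_end <- lat - WAVELET_TAIL_MS
  u <- (t - t0) / (WAVELET_DUR_MS - WAVELET_TAIL_MS)
  in_body <- t >= t0 & t < body_end
  s[in_body] <- A * sin(3 * pi * u[in_body])
  # terminal stroke: 0 -> -0.4A -> 0 over the last 2 ms, slope 0.4*A per ms
  in_tail <- t >= body_end & t < lat
  tt <- t[in_tail] - body_end
  s[in_tail] <- -0.4 * A * ifelse(tt < WAVELET_TAIL_MS / 2,
                                  tt / (WAVELET_TAIL_MS / 2),
                                  2 - tt / (WAVELET_TAIL_MS / 2))
  s
}

#' Synthesize bipolar electrograms at mapping sites
#'
#' Samples acquisition sites over the conducting surface at the configured
#' density and builds, for each site, a set of orthogonal bipolar electrograms
#' mimicking a 16-electrode grid catheter (3 mm spacing; the per-bipole
#' amplitude varies with orientation, the largest matching the site voltage).
#' Deterministic under the scenario seed.
#'
#' Sites over scar or patch tissue see no wavefront and record noise only.
#' Sites with local CV below 0.25 m/s receive a presystolic train of
#' low-amplitude wavelets (fractionated activity). Sites within reach of two
#' activation clusters separated by more than 20 ms (across a line of block)
#' record both components as a split potential.
#'
#' @param mesh an `ilam_mesh`.
#' @param activation an `ilam_activation`.
#' @param config scenario (defaults to the mesh's); `egm$rate_hz` must be >=
#'   1000 (annotation resolution contract).
#' @param sites optional n x 2 matrix of site positions (mm); default sampled.
#' @return list of class `ilam_egm_set`: `sites` (data.frame with site_id,
#'   x, y, nearest_vertex, true_lat_ms), `bipole_sets` (list of `bipole_set`),
#'   `rate_hz`, `t0_ms`, `duration_ms`.
#' @export
synthesize_electrograms <- function(mesh, activation, config = mesh$scenario,
                                    sites = NULL) {
  rate <- config$egm$rate_hz
  if (rate < 1000) stop_ilam("egm rate must be >= 1000 Hz, got %g", rate)
  noise <- config$egm$noise_mV %||% 0
  lat <- activation$lat
  cvf <- tryCatch(cv_field(mesh), error = function(e) NULL)

  if (is.null(sites)) sites <- sample_sites(mesh, config$point_density,
                                            config$seed)
  nv <- nearest_vertex(mesh, sites)
  true_lat <- lat[nv]
  dur <- max(lat, na.rm = TRUE) + 40
  t <- seq(0, dur, by = 1000 / rate)

  # activation clusters reachable within 4 mm (split-potential planting)
  second_lat <- rep(NA_real_, nrow(sites))
  if (!is.null(mesh$severed) && any(mesh$severed)) {
    for (i in seq_len(nrow(sites))) {
      d <- .dist_to_point(mesh$vertices, c(sites[i, 1:2], 0))
      near_lat <- lat[d <= 4 & is.finite(lat)]
      if (length(near_lat) && is.finite(true_lat[i]) &&
          max(near_lat) - true_lat[i] > 20) {
        second_lat[i] <- max(near_lat)
      }
    }
  }

  bipole_sets <- vector("list", nrow(sites))
  with_substream(config$seed, "egm", {
    for (i in seq_len(nrow(sites))) {
      v <- nv[i]
      local_cv <- if (!is.null(cvf)) cvf[v] else NA_real_
      volt <- if (is.finite(local_cv) && local_cv < 0.5) 0.9 else 3.0
      volt <- volt * runif(1, 0.95, 1.05)
      base <- numeric(length(t))
      if (is.finite(true_lat[i])) {
        base <- .egm_wavelet(t, true_lat[i], volt)
        if (is.finite(local_cv) && local_cv < 0.25) {
          for (k in 1:4) {  # presystolic fractionated train
            tk <- true_lat[i] - k * 18
            if (tk - WAVELET_DUR_MS >= 0) base <- base + .egm_wavelet(t, tk, 0.6)
          }
        }
        if (is.finite(second_lat[i])) {
          base <- base + .egm_wavelet(t, second_lat[i], 0.6 * volt)
        }
      }
      f <- runif(4, 0.35, 0.9)
      f[sample.int(4, 1)] <- 1
      bip <- lapply(1:4, function(j) {
        s <- f[j] * base
        if (noise > 0) s <- s + rnorm(length(s), 0, noise)
        eg <- new_electrogram(s, rate = rate, t0 = 0)
        eg$orientation <- if (j <= 2) "along_spline" else "across_spline"
        eg
      })
      bipole_sets[[i]] <- structure(
        list(site_position = c(sites[i, 1:2], 0), bipoles = bip,
             spacing = 3, site_id = i),
        class = "bipole_set")
    }
  })
  structure(list(
    sites = data.frame(site_id = seq_len(nrow(sites)), x = sites[, 1],
                       y = sites[, 2], nearest_vertex = nv,
                       true_lat_ms = true_lat),
    bipole_sets = bipole_sets, rate_hz = rate, t0_ms = 0, duration_ms = dur),
    class = "ilam_egm_set")
}

#' Sample mapping sites over the surface
#'
#' Uniform sampling at a target density over the whole surface, scar and
#' patches included — sites over non-conducting tissue record noise only and
#' come back unusable, as in a real acquisition. Deterministic under the seed
#' (substream "sites").
#'
#' @param mesh an `ilam_mesh`.
#' @param density sites per cm^2 of surface.
#' @param seed integer root seed.
#' @return n x 2 matrix of positions, mm.
#' @export
sample_sites <- function(mesh, density, seed) {
  area_cm2 <- sum(vertex_areas(mesh)) / 100
  n <- max(2L, round(density * area_cm2))
  xr <- range(mesh$vertices[, 1]); yr <- range(mesh$vertices[, 2])
  out <- with_substream(seed, "sites", {
    cbind(runif(n, xr[1], xr[2]), runif(n, yr[1], yr[2]))
  })
  colnames(out) <- c("x", "y")
  out
}
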
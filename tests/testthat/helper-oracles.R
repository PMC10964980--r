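# Shared fixtures and independent brute-force oracles. Oracles deliberately
# avoid the code paths they check.

strip_scenario <- function(seed = 1, length_mm = 50, width_mm = 4,
                           spacing_mm = 1, background_cv = 1,
                           point_density = 25, noise_mV = 0,
                           sources = list(list(position = c(0, width_mm / 2),
                                               onset_ms = 0))) {
  scenario_config(seed = seed,
                  geometry = list(kind = "sheet", length_mm = length_mm,
                                  width_mm = width_mm, spacing_mm = spacing_mm),
                  background_cv = background_cv,
                  pacing_sources = sources,
                  point_density = point_density,
                  egm = list(rate_hz = 1000, noise_mV = noise_mV))
}

# plain double-loop minimum distance between two labelled vertex sets
bf_boundary_distance <- function(mesh, label_a, label_b) {
  a <- mesh$vertices[mesh$label == label_a, , drop = FALSE]
  b <- mesh$vertices[mesh$label == label_b, , drop = FALSE]
  best <- Inf
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
  }
  best
}

# exhaustive enumeration of simple paths: first-arrival times on a small
# weighted graph (edges: m x 2, times: m, undirected)
bf_first_arrival <- function(edges, times, n, source) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(b, times[k]))
    adj[[b]] <- rbind(adj[[b]], c(a, times[k]))
  }
  best <- rep(Inf, n)
  dfs <- function(v, t, visited) {
    if (t < best[v]) best[v] <<- t
    nb <- adj[[v]]
    for (k in seq_len(NROW(nb))) {
      w <- nb[k, 1]
      if (!visited[w]) {
        visited[w] <- TRUE
        dfs(w, t + nb[k, 2], visited)
        visited[w] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[source] <- TRUE
  dfs(source, 0, visited)
  best
}

# Mann-Whitney pair counting (concordant + half ties) / (n1 * n0)
bf_pair_auc <- function(score, truth) {
  pos <- score[truth]; neg <- score[!truth]
  num <- 0
  for (p in pos) for (q in neg) {
    num <- num + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  num / (length(pos) * length(neg))
}

# independent midranks (sort-based, no rank())
bf_midrank <- function(x) {
  r <- numeric(length(x))
  for (i in seq_along(x)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

bf_spearman <- function(x, y) {
  rx <- bf_midrank(x); ry <- bf_midrank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# a clean synthetic electrogram with wavelets ending at the given offsets
make_egm <- function(offsets_ms, amplitudes = NULL, duration_ms = NULL,
                     rate = 1000, noise_mV = 0, seed = 1) {
  if (is.null(amplitudes)) amplitudes <- rep(2, length(offsets_ms))
  if (is.null(duration_ms)) duration_ms <- max(offsets_ms) + 30
  t <- seq(0, duration_ms, by = 1000 / rate)
  s <- numeric(length(t))
  for (k in seq_along(offsets_ms)) {
    s <- s + ilamr:::.egm_wavelet(t, offsets_ms[k], amplitudes[k])
  }
  if (noise_mV > 0) {
    set.seed(seed)
    s <- s + rnorm(length(s), 0, noise_mV)
  }
  new_electrogram(s, rate = rate, t0 = 0)
}

# The fixed-seed synthetic study cohort (27 corridors, noiseless annotation),
# computed once and shared across test files.
.cohort_cache <- new.env()
study_cohort <- function() {
  if (is.null(.cohort_cache$coh)) {
    .cohort_cache$coh <- simulate_corridor_study(n_corridors = 27,
                                                 point_density = 20,
                                                 noise_mV = 0, seed = 1)
  }
  .cohort_cache$coh
}
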
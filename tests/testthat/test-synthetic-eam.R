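# Synthetic electroanatomical map generator: meshes, activation simulation,
# electrogram recovery, ablation-line editing.

test_that("mesh generation is deterministic and stamps only configured structures", {
  sc <- strip_scenario(seed = 3, length_mm = 20, width_mm = 8)
  m1 <- generate_surface(sc)
  m2 <- generate_surface(sc)
  expect_identical(m1$vertices, m2$vertices)
  expect_identical(m1$triangles, m2$triangles)
  expect_true(all(m1$label == "conducting"))

  mc <- generate_surface(corridor_scenario(seed = 3, planted_cv = 0.5))
  expect_setequal(unique(mc$label),
                  c("conducting", "vsd_patch", "pulmonary_annulus"))
})

test_that("corridor width matches the request and the brute-force oracle", {
  mesh <- generate_surface(corridor_scenario(seed = 1, planted_cv = 0.8,
                                             corridor_width_mm = 11))
  w <- measure_corridor_width(mesh, "vsd_patch", "pulmonary_annulus")
  expect_gte(w, 9.9)
  expect_lte(w, 12.1)
  # oracle: plain double loop over the two labelled sets, same boundary
  # half-spacing convention
  expect_equal(w, bf_boundary_distance(mesh, "vsd_patch",
                                       "pulmonary_annulus") - mesh$spacing)
})

test_that("overlapping structures that destroy a corridor raise a named error", {
  sc <- corridor_scenario(seed = 1, planted_cv = 0.5, corridor_width_mm = 11)
  # close the gap: widen one block across the whole sheet
  sc$structures[[1]]$y <- c(0, 30)
  expect_error(generate_surface(sc), "AI3")
})

test_that("uniform strip: distal activation time equals distance over speed", {
  sc <- strip_scenario(length_mm = 50, width_mm = 4)
  mesh <- generate_surface(sc)
  act <- simulate_activation(mesh, cv = rep(1, nrow(mesh$vertices)),
                             sources = list(list(position = c(0, 2),
                                                 onset_ms = 0)))
  distal <- nearest_vertex <- which(mesh$vertices[, 1] == 50 &
                                      mesh$vertices[, 2] == 2)
  expect_equal(act$lat[distal], 50, tolerance = 0.01)
  src <- which(mesh$vertices[, 1] == 0 & mesh$vertices[, 2] == 2)
  expect_equal(act$lat[src], 0)
})

test_that("corridor of 18 mm at 1.3 m/s is traversed in about 14 ms", {
  sc <- corridor_scenario(seed = 5, planted_cv = 1.3)
  mesh <- generate_surface(sc)
  act <- simulate_activation(mesh)
  v_in <- which(mesh$vertices[, 1] == 47 & mesh$vertices[, 2] == 15)
  v_out <- which(mesh$vertices[, 1] == 65 & mesh$vertices[, 2] == 15)
  ct <- act$lat[v_out] - act$lat[v_in]
  expect_equal(ct, 18 / 1.3, tolerance = 0.06)
  expect_equal(round(ct), 14)
})

test_that("first-arrival times equal exhaustive simple-path enumeration", {
  sc <- strip_scenario(length_mm = 3, width_mm = 2)  # 4 x 3 grid, 12 vertices
  mesh <- generate_surface(sc)
  set.seed(17)
  for (rep in 1:3) {
    cv <- runif(nrow(mesh$vertices), 0.2, 1.5)
    act <- simulate_activation(mesh, cv = cv,
                               sources = list(list(vertex = 1L, onset_ms = 0)))
    e <- mesh$metric_edges
    times <- mesh$metric_len / (2 / (1 / cv[e[, 1]] + 1 / cv[e[, 2]]))
    oracle <- bf_first_arrival(e, times, nrow(mesh$vertices), 1L)
    expect_equal(act$lat, oracle, tolerance = 1e-12)
  }
})

test_that("uniform-CV activation matches geodesic distance within 3 percent", {
  sc <- strip_scenario(length_mm = 40, width_mm = 20)
  mesh <- generate_surface(sc)
  v <- 0.8
  act <- simulate_activation(mesh, cv = rep(v, nrow(mesh$vertices)),
                             sources = list(list(position = c(0, 0),
                                                 onset_ms = 0)))
  d <- sqrt(rowSums(sweep(mesh$vertices, 2, c(0, 0, 0))^2))
  far <- d > 3  # skip the immediate source neighbourhood
  rel <- abs(act$lat[far] - d[far] / v) / (d[far] / v)
  expect_lt(max(rel), 0.03)
})

test_that("sources on scar error; walled-off tissue is flagged unmapped", {
  sc <- strip_scenario(length_mm = 20, width_mm = 10)
  sc$structures <- list(list(label = "scar_patch", shape = "rect",
                             x = c(8, 12), y = c(0, 10)))
  mesh <- generate_surface(sc)
  expect_error(simulate_activation(mesh, cv = rep(1, nrow(mesh$vertices)),
                                   sources = list(list(position = c(10, 5)))),
               "non-conducting")
  expect_warning(
    act <- simulate_activation(mesh, cv = rep(1, nrow(mesh$vertices)),
                               sources = list(list(position = c(0, 5)))),
    "unreachable")
  distal <- mesh$vertices[, 1] > 12 & mesh$label == "conducting"
  expect_true(all(is.na(act$lat[distal])))
  expect_true(all(is.finite(act$lat[mesh$vertices[, 1] < 8 &
                                      mesh$label == "conducting"])))
})

test_that("noiseless annotation recovers planted LAT within one sample", {
  sc <- strip_scenario(seed = 9, length_mm = 40, width_mm = 10,
                       background_cv = 0.8, point_density = 15)
  mesh <- generate_surface(sc)
  act <- simulate_activation(mesh, cv = rep(0.8, nrow(mesh$vertices)),
                             sources = sc$pacing_sources)
  es <- synthesize_electrograms(mesh, act)
  ann <- annotate_sites(es)
  err <- abs(ann$lat_ms - es$sites$true_lat_ms)[ann$used]
  expect_true(all(err <= 1.0 + 1e-9))
})

test_that("with noise, 95 percent of sites annotate within 2 ms", {
  sc <- strip_scenario(seed = 10, length_mm = 40, width_mm = 10,
                       background_cv = 0.8, point_density = 20,
                       noise_mV = 0.02)
  mesh <- generate_surface(sc)
  act <- simulate_activation(mesh, cv = rep(0.8, nrow(mesh$vertices)),
                             sources = sc$pacing_sources)
  es <- synthesize_electrograms(mesh, act)
  ann <- annotate_sites(es)
  err <- abs(ann$lat_ms - es$sites$true_lat_ms)[ann$used]
  expect_gte(mean(err <= 2), 0.95)
})

test_that("slow-corridor sites are fractionated and low-voltage; scar sites unusable", {
  sc <- corridor_scenario(seed = 11, planted_cv = 0.15, noise_mV = 0.02)
  mesh <- generate_surface(sc)
  act <- simulate_activation(mesh)
  es <- synthesize_electrograms(mesh, act)
  ann <- annotate_sites(es)
  in_corr <- es$sites$x > 48 & es$sites$x < 64 & es$sites$y > 11 &
    es$sites$y < 19
  expect_gt(mean(ann$fractionated[in_corr & ann$used]), 0.5)
  expect_true(all(ann$voltage_mV[in_corr & ann$used] < 1.5))
  scar <- mesh$label[es$sites$nearest_vertex] != "conducting"
  expect_true(any(scar))
  expect_true(all(!ann$used[scar]))
  expect_true(all(ann$voltage_mV[scar] < 1.5))
})

test_that("electrogram synthesis is bit-identical under a fixed seed", {
  sc <- strip_scenario(seed = 21, length_mm = 15, width_mm = 6,
                       noise_mV = 0.03)
  mesh <- generate_surface(sc)
  act <- simulate_activation(mesh, cv = rep(1, nrow(mesh$vertices)),
                             sources = sc$pacing_sources)
  e1 <- synthesize_electrograms(mesh, act)
  e2 <- synthesize_electrograms(mesh, act)
  expect_identical(e1$sites, e2$sites)
  expect_identical(e1$bipole_sets[[3]]$bipoles[[2]]$samples,
                   e2$bipole_sets[[3]]$bipoles[[2]]$samples)
  # electrogram rate below 1 kHz violates the annotation contract
  sc$egm$rate_hz <- 500
  expect_error(synthesize_electrograms(mesh, act, config = sc), ">= 1000")
})

test_that("ablation editing: identity, no-op warning, dead-end transection", {
  sc <- strip_scenario(length_mm = 30, width_mm = 10)
  sc$structures <- list(
    list(label = "scar_patch", shape = "rect", x = c(12, 18), y = c(0, 3)),
    list(label = "scar_patch", shape = "rect", x = c(12, 18), y = c(7, 10)))
  mesh <- generate_surface(sc)
  expect_identical(apply_ablation_line(mesh, matrix(numeric(0), 0, 2)), mesh)

  expect_warning(apply_ablation_line(mesh, cbind(c(13, 17), c(1.5, 1.5))),
                 "no-op")

  # transection of the only corridor: distal side becomes unreachable
  cut <- apply_ablation_line(mesh, cbind(c(15.25, 15.25), c(2.5, 7.5)))
  expect_gt(sum(cut$severed), 0)
  expect_warning(
    act <- simulate_activation(cut, cv = rep(1, nrow(mesh$vertices)),
                               sources = list(list(position = c(0, 5)))),
    "unreachable")
  distal <- mesh$vertices[, 1] > 18 & mesh$label == "conducting"
  expect_true(all(is.na(act$lat[distal])))
})

test_that("transection with a detour reverses activation distal to the line", {
  sc <- strip_scenario(length_mm = 60, width_mm = 30,
                       sources = list(list(position = c(0, 15), onset_ms = 0)))
  sc$structures <- list(
    list(label = "scar_patch", shape = "rect", x = c(25, 35), y = c(4, 12)),
    list(label = "scar_patch", shape = "rect", x = c(25, 35), y = c(18, 26)))
  mesh <- generate_surface(sc)
  cv <- rep(1, nrow(mesh$vertices))
  pre <- simulate_activation(mesh, cv = cv, sources = sc$pacing_sources)
  a <- which(mesh$vertices[, 1] == 31 & mesh$vertices[, 2] == 15)
  b <- which(mesh$vertices[, 1] == 34 & mesh$vertices[, 2] == 15)
  expect_gt(pre$lat[b], pre$lat[a])  # antegrade through the corridor

  cut <- apply_ablation_line(mesh, cbind(c(30.25, 30.25), c(3.5, 26.5)))
  post <- simulate_activation(cut, cv = cv, sources = sc$pacing_sources)
  expect_lt(post$lat[b], post$lat[a])  # retrograde: distal gradient flipped
  expect_true(all(is.finite(post$lat[mesh$label == "conducting"])))
})
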
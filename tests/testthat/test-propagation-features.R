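# Propagation features: isochronal crowding counts, deceleration zones,
# extreme slowing, block lines, collisions.

true_lat_ilam <- function(scenario, cv = NULL) {
  mesh <- generate_surface(scenario)
  act <- simulate_activation(mesh, cv = cv, sources = scenario$pacing_sources)
  list(mesh = mesh, act = act,
       im = build_ilam(list(mesh = mesh, vertex_lat = act$lat)))
}

test_that("crowding counts equal the brute-force neighbourhood oracle", {
  f <- true_lat_ilam(corridor_scenario(seed = 2, planted_cv = 0.3,
                                       spacing_mm = 2))
  im <- f$im
  counts <- isochrone_counts(im, radius_mm = 10)
  # oracle: full pairwise geodesic matrix + explicit distinct-index count
  g <- mesh_graph(f$mesh)
  mapped <- which(is.finite(im$lat))
  dmat <- igraph::distances(g, v = mapped, to = mapped)
  set.seed(8)
  for (i in sample(seq_along(mapped), 25)) {
    near <- mapped[dmat[i, ] <= 10]
    expect_equal(counts[mapped[i]],
                 length(unique(im$isochrone[near])))
    expect_equal(count_isochrones_in_radius(im, mapped[i], 10),
                 counts[mapped[i]])
  }
  expect_error(count_isochrones_in_radius(im, which(!is.finite(im$lat))[1], 10),
               "unmapped")
})

test_that("a uniform fast map has no deceleration zones (strict >3 rule)", {
  sc <- strip_scenario(length_mm = 90, width_mm = 20)
  f <- true_lat_ilam(sc, cv = rep(1.2, nrow(generate_surface(sc)$vertices)))
  counts <- isochrone_counts(f$im, 10)
  # evenly spread isochrones: some neighbourhoods reach exactly 3, never more
  expect_lte(max(counts, na.rm = TRUE), 3L)
  expect_equal(detect_deceleration_zones(f$im, counts = counts), list())
})

test_that("a planted slow corridor yields exactly one DZ over that corridor", {
  f <- true_lat_ilam(corridor_scenario(seed = 3, planted_cv = 0.15))
  zones <- detect_deceleration_zones(f$im)
  expect_length(zones, 1L)
  z <- zones[[1]]
  expect_gte(z$peak_isochrone_count, 4L)
  expect_gt(z$area_mm2, 10)
  # the zone overlaps the corridor (x 47-65, y 9.5-20.5, within crowding reach)
  pos <- f$mesh$vertices[z$member_vertices, , drop = FALSE]
  expect_true(any(pos[, 1] >= 47 & pos[, 1] <= 65 &
                    pos[, 2] > 9.5 & pos[, 2] < 20.5))
  expect_lt(abs(z$centroid[1] - 56), 12)
})

test_that("DZ detection is monotone as corridor CV decreases", {
  dz <- vapply(c(1.0, 0.7, 0.45, 0.3, 0.15), function(v) {
    f <- true_lat_ilam(corridor_scenario(seed = 4, planted_cv = v))
    length(detect_deceleration_zones(f$im)) > 0
  }, logical(1))
  expect_true(all(diff(as.integer(dz)) >= 0))  # once present, stays present
  expect_false(dz[1])
  expect_true(dz[5])
})

test_that("extreme slowing needs both dense crowding and fractionation", {
  dz <- structure(list(member_vertices = 1:20, peak_isochrone_count = 7L,
                       centroid = c(0, 0, 0), area_mm2 = 20, extreme = FALSE),
                  class = "deceleration_zone")
  ann_frac <- data.frame(vertex = c(1:8, 100:103),
                         fractionated = c(rep(TRUE, 7), FALSE, rep(FALSE, 4)))
  expect_true(flag_extreme_slowing(dz, ann_frac)$extreme)

  dz_sparse <- dz; dz_sparse$peak_isochrone_count <- 4L
  expect_false(flag_extreme_slowing(dz_sparse, ann_frac)$extreme)

  ann_none <- data.frame(vertex = 1:8, fractionated = FALSE)
  expect_false(flag_extreme_slowing(dz, ann_none)$extreme)
})

test_that("block-line detection needs both a LAT jump and split potentials", {
  mesh <- generate_surface(strip_scenario(length_mm = 30, width_mm = 20))
  x <- mesh$vertices[, 1]
  # wrap-around style field: jump of 40 ms across x = 15, reversed beyond
  lat <- ifelse(x < 15, x, 40 + (30 - x))
  im <- build_ilam(list(mesh = mesh, vertex_lat = lat))
  split_ann <- data.frame(x = rep(15, 5), y = c(2, 6, 10, 14, 18),
                          split = TRUE, gap_ms = 25)
  lines <- detect_block_lines(im, split_ann)
  expect_gte(length(lines), 1L)
  main <- lines[[which.max(vapply(lines, function(l)
    length(l$member_vertices), integer(1)))]]
  pos <- mesh$vertices[main$member_vertices, 1]
  expect_true(all(abs(pos - 15) <= 3))
  expect_true(main$reversal_confirmed)
  expect_equal(main$mean_gap_ms, 25)

  # smooth single-wavefront map: no candidates
  smooth <- build_ilam(list(mesh = mesh, vertex_lat = x + 0.01))
  expect_equal(detect_block_lines(smooth, split_ann), list())

  # jump without split potentials is not a block line
  no_split <- data.frame(x = 15, y = 10, split = FALSE, gap_ms = NA)
  expect_equal(detect_block_lines(im, no_split), list())

  # sub-threshold jump (half of the resulting map's bin width) is no block
  # line: jump 2 ms on a 32 ms span -> bin width 4 ms
  lat_small <- ifelse(x < 15, x, x + 2)
  im_small <- build_ilam(list(mesh = mesh, vertex_lat = lat_small))
  expect_equal(im_small$total_activation_time_ms / 8, 4)
  expect_equal(detect_block_lines(im_small, split_ann), list())
})

test_that("collisions: both-end pacing meets at the midline, offsets shift it", {
  sc <- strip_scenario(length_mm = 50, width_mm = 6,
                       sources = list(list(position = c(0, 3), onset_ms = 0),
                                      list(position = c(50, 3), onset_ms = 0)))
  f <- true_lat_ilam(sc, cv = rep(1, nrow(generate_surface(sc)$vertices)))
  coll <- detect_collisions(f$im)
  expect_gte(length(coll), 1L)
  xs <- f$mesh$vertices[unlist(coll), 1]
  expect_true(all(abs(xs - 25) <= 2))

  # single source: no collision
  f1 <- true_lat_ilam(strip_scenario(length_mm = 50, width_mm = 6))
  expect_equal(detect_collisions(f1$im), list())

  # onset offset 0/20 ms shifts the locus to the brute-force first-arrival one
  sc2 <- strip_scenario(length_mm = 50, width_mm = 6,
                        sources = list(list(position = c(0, 3), onset_ms = 0),
                                       list(position = c(50, 3),
                                            onset_ms = 20)))
  mesh2 <- generate_surface(sc2)
  f2 <- true_lat_ilam(sc2, cv = rep(1, nrow(mesh2$vertices)))
  coll2 <- detect_collisions(f2$im)
  expect_gte(length(coll2), 1L)
  # oracle: arg max over x of min(x, 20 + (50 - x)) -> x = 35
  expect_true(all(abs(mesh2$vertices[unlist(coll2), 1] - 35) <= 2))
})
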
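# Electrogram processing: bipole selection, deflection detection,
# last-deflection annotation, voltage classes, fractionation.

test_that("best-bipole selection maximises peak-to-peak with lowest-index ties", {
  mk <- function(amp) make_egm(50, amplitudes = amp, duration_ms = 80)
  bs <- list(mk(0.8), mk(2.0), mk(1.1))
  sel <- select_best_bipole(bs)
  expect_equal(sel$index, 2L)
  expect_equal(sel$voltage_mV, peak_to_peak(bs[[2]]))

  tie <- list(mk(1.5), mk(1.5), mk(0.4))
  expect_equal(select_best_bipole(tie)$index, 1L)

  expect_error(select_best_bipole(list()), "empty")
})

test_that("selection equals brute-force argmax over 24 random bipoles", {
  set.seed(7)
  for (rep in 1:5) {
    amps <- runif(24, 0.2, 4)
    bs <- lapply(amps, function(a) make_egm(60, amplitudes = a,
                                            duration_ms = 90,
                                            noise_mV = 0.01, seed = rep))
    p2p <- vapply(bs, function(e) max(e$samples) - min(e$samples), numeric(1))
    expect_equal(select_best_bipole(bs)$index, which.max(p2p))
  }
})

test_that("selection is permutation-invariant up to the tie-break", {
  set.seed(11)
  amps <- runif(8, 0.3, 3)
  bs <- lapply(amps, function(a) make_egm(40, amplitudes = a, duration_ms = 70))
  ref <- select_best_bipole(bs)$voltage_mV
  for (rep in 1:5) {
    perm <- sample(8)
    expect_equal(select_best_bipole(bs[perm])$voltage_mV, ref)
  }
})

test_that("deflection detection: flat signal, constructed wavelets, oracle scan", {
  flat <- new_electrogram(rep(0, 200), rate = 1000)
  expect_equal(nrow(detect_deflections(flat)), 0L)

  two <- make_egm(c(50, 90))
  d <- detect_deflections(two)
  expect_equal(nrow(d), 2L)
  # onsets within one sample of the constructed support starts (offset - 12)
  expect_lt(abs(d$onset_ms[1] - 38), 1.5)
  expect_lt(abs(d$onset_ms[2] - 78), 1.5)
  expect_lt(abs(d$offset_ms[1] - 50), 1.01)
  expect_lt(abs(d$offset_ms[2] - 90), 1.01)
})

test_that("deflection count equals a direct threshold-scan oracle", {
  # oracle: count maximal runs of |slope| >= thr after the same merge rule,
  # written as an explicit index scan
  oracle_count <- function(egm, cfg) {
    s <- egm$samples
    dt <- 1000 / egm$rate
    act <- abs(diff(s) / dt) >= cfg$deflection_min_slope
    gaps_allowed <- ceiling(cfg$merge_gap_ms / dt) - 1L
    count <- 0L; run_end <- -Inf; in_run <- FALSE
    runs <- list(); start <- NA
    k <- 1L
    while (k <= length(act)) {
      if (act[k]) {
        if (!in_run) {
          if (k - run_end - 1L <= gaps_allowed && count > 0L) {
            # merge with previous run: reopen it
            in_run <- TRUE
            start <- runs[[count]][1]
            count <- count - 1L
          } else {
            in_run <- TRUE
            start <- k
          }
        }
        run_end <- k
      } else if (in_run) {
        count <- count + 1L
        runs[[count]] <- c(start, run_end)
        in_run <- FALSE
      }
      k <- k + 1L
    }
    if (in_run) { count <- count + 1L; runs[[count]] <- c(start, run_end) }
    # apply excursion and duration significance
    keep <- 0L
    for (r in runs[seq_len(count)]) {
      seg <- s[r[1]:(r[2] + 1L)]
      if (max(seg) - min(seg) >= cfg$noise_floor_mV &&
          (r[2] + 1L - r[1]) * dt >= cfg$min_duration_ms) keep <- keep + 1L
    }
    keep
  }
  cfg <- annotation_config()
  set.seed(3)
  for (rep in 1:6) {
    offsets <- sort(sample(seq(30, 260, by = 25), sample(1:5, 1)))
    egm <- make_egm(offsets, amplitudes = runif(length(offsets), 0.6, 3),
                    duration_ms = 300)
    expect_equal(nrow(detect_deflections(egm, cfg)), oracle_count(egm, cfg))
  }
})

test_that("last-deflection annotation takes the latest offset and flags splits", {
  egm <- make_egm(c(60, 100))
  ann <- annotate_last_deflection(egm)
  expect_lt(abs(ann$lat_ms - 100), 1.01)
  expect_equal(ann$n_deflections, 2L)
  # 40 ms between offsets -> isoelectric gap 28 ms > 20 -> split
  expect_true(ann$split)

  # gap of exactly 20 ms must NOT split (strict >): offsets 28 ms apart
  # give onset(k+1) - offset(k) = 28 - 12 = 16; use 32 -> gap 20
  boundary <- make_egm(c(60, 92))
  ann2 <- annotate_last_deflection(boundary)
  expect_equal(ann2$gap_ms, 20, tolerance = 0.051)
  expect_false(ann2$split)

  # 25 ms isoelectric gap -> split detected
  split25 <- make_egm(c(60, 97))
  ann3 <- annotate_last_deflection(split25)
  expect_equal(ann3$gap_ms, 25, tolerance = 0.051)
  expect_true(ann3$split)

  none <- annotate_last_deflection(new_electrogram(rep(0, 100)))
  expect_false(none$used)
  expect_equal(none$n_deflections, 0L)
})

test_that("split detection is monotone in the gap", {
  cfg <- annotation_config()
  detected <- vapply(seq(14, 40, by = 2), function(gap) {
    egm <- make_egm(c(60, 60 + 12 + gap))
    annotate_last_deflection(egm, cfg)$split
  }, logical(1))
  # once TRUE, stays TRUE for every larger gap
  expect_true(all(diff(as.integer(detected)) >= 0))
  expect_true(any(detected) && !all(detected))
})

test_that("voltage classification uses strict thresholds", {
  expect_equal(classify_voltage(1.6), "normal")
  expect_equal(classify_voltage(1.5), "normal")   # strict "<"
  expect_equal(classify_voltage(1.49), "abnormal")
  expect_equal(classify_voltage(0.5), "abnormal") # strict "<" at scar cutoff
  expect_equal(classify_voltage(0.2), "dense_scar")
  expect_error(classify_voltage(-0.1), "non-negative")
})

test_that("fractionation scoring counts deflections", {
  single <- make_egm(80)
  fs <- fractionation_score(single)
  expect_equal(fs$n_deflections, 1L)
  expect_false(fs$fractionated)

  five <- make_egm(c(60, 78, 96, 114, 132), amplitudes = rep(0.8, 5))
  fs5 <- fractionation_score(five)
  expect_equal(fs5$n_deflections, 5L)
  expect_true(fs5$fractionated)
  expect_gt(fs5$duration_ms, 40)

  flat <- fractionation_score(new_electrogram(rep(0, 150)))
  expect_equal(flat$n_deflections, 0L)
})

test_that("electrogram contracts: rate floor and finite samples", {
  expect_error(new_electrogram(rep(0, 10), rate = 500), ">= 1000")
  expect_error(new_electrogram(c(0, NA, 1)), "finite")
})
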
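make_pair_traj <- function(dists) {
  # two atoms per frame: A fixed at the origin, B at (d, 0, 0)
  n <- length(dists)
  dplyr::bind_rows(lapply(seq_len(n) - 1L, function(f) {
    tibble::tibble(
      frame = f, time = f * 10,
      index = c(0L, 1L), name = c("A", "B"), group = c("GA", "GB"),
      x = c(0, dists[f + 1L]), y = 0, z = 0, charge = 0
    )
  }))
}

test_that("distance series computes per-frame Euclidean distances", {
  traj <- tibble::tibble(
    frame = rep(c(0L, 1L), each = 2), time = rep(c(0, 10), each = 2),
    index = rep(c(0L, 1L), 2), name = rep(c("A", "B"), 2),
    group = rep(c("GA", "GB"), 2),
    x = c(0, 3, 0, 3), y = c(0, 4, 0, 4), z = 0, charge = 0
  )
  ds <- distance_series(traj, "group GA", "group GB")
  expect_equal(ds$distance, c(5, 5))
  expect_error(distance_series(traj, "all", "group GB"), "exactly one")
  empty <- traj[0, ]
  expect_equal(nrow(distance_series(empty, "group GA", "group GB")), 0L)
})

test_that("a generated two-state series survives the trajectory round trip", {
  d <- gen_distance_series(50, seed = 31)
  traj <- make_pair_traj(d$pro_r)
  ds <- distance_series(traj, "name A", "name B")
  expect_equal(ds$distance, d$pro_r, tolerance = 1e-12)
})

test_that("population histograms normalize and find mixture modes", {
  # identical samples: one occupied bin
  h1 <- population_hist(rep(3.14, 100), bin_width = 0.1)
  expect_equal(sum(h1$count > 0), 1L)
  expect_equal(hist_mode(h1), h1$bin_mid[h1$count > 0])
  # density integrates to one for arbitrary inputs
  x <- withr::with_seed(32, rexp(5000, 0.5) + 1)
  h2 <- population_hist(x, bin_width = 0.07)
  expect_equal(sum(h2$density * 0.07), 1, tolerance = 1e-9)
  # two-Gaussian mixture shows local maxima at both component means
  d <- gen_distance_series(2e5, p_near = 0.5, mu_near = 2.6, mu_far = 3.4,
                           sigma = 0.15, seed = 33)
  h3 <- population_hist(d$pro_r, bin_width = 0.1)
  dens <- h3$density
  local_max <- which(dens > dplyr::lag(dens, default = 0) &
                       dens >= dplyr::lead(dens, default = 0))
  peaks <- h3$bin_mid[local_max[dens[local_max] > 0.3 * max(dens)]]
  expect_equal(sort(sapply(c(2.6, 3.4), function(m) peaks[which.min(abs(peaks - m))])),
               c(2.6, 3.4), tolerance = 0.1)
  expect_error(population_hist(numeric(0)), "empty")
})

test_that("mode ties break toward smaller distance", {
  # two equally populated bins
  x <- c(rep(1.05, 10), rep(2.05, 10))
  h <- population_hist(x, bin_width = 0.1)
  expect_equal(hist_mode(h), 1.05, tolerance = 1e-9)
})

test_that("most_populated_frame returns the earliest frame in the mode bin", {
  # the dominant bin (around 2.0 A) is hit at frames 12, 40, 77 only
  dists <- seq(4, 9, length.out = 100)
  dists[c(13, 41, 78)] <- 2.0
  series <- tibble::tibble(frame = 0:99, distance = dists)
  h <- population_hist(series$distance, bin_width = 0.1)
  expect_equal(hist_mode(h), 2.05, tolerance = 1e-9)
  expect_equal(most_populated_frame(series, h), 12L)
  # brute-force oracle scan on random series
  for (s in 1:3) {
    x <- withr::with_seed(70 + s, round(runif(500, 2, 4), 2))
    ser <- tibble::tibble(frame = 0:499, distance = x)
    h <- population_hist(ser$distance, bin_width = 0.1)
    got <- most_populated_frame(ser, h)
    m <- hist_mode(h)
    row <- which(abs(h$bin_mid - m) < 1e-9)
    lo <- h$bin_low[row]; hi <- h$bin_high[row]
    is_last <- hi >= max(h$bin_high)
    expected <- min(ser$frame[ser$distance >= lo &
                                (ser$distance < hi | (is_last & ser$distance <= hi))])
    expect_equal(got, expected)
  }
  # single-frame trajectory
  one <- tibble::tibble(frame = 0L, distance = 3)
  expect_equal(most_populated_frame(one), 0L)
})

test_that("contact occupancy uses a strict below-cutoff rule", {
  expect_equal(contact_occupancy(c(1, 2, 3), 5)$occupancy, 1)
  # value exactly at the cutoff is not in contact
  expect_equal(contact_occupancy(c(4, 5, 6), 5)$occupancy, 1 / 3)
  n <- 1e5
  cs <- gen_contact_series(n, occupancy = 0.88, seed = 35)
  occ <- contact_occupancy(cs, 5)
  expect_lt(abs(occ$occupancy - 0.88), 3 * sqrt(0.88 * 0.12 / n))
})

test_that("enantiomer ratios follow the Boltzmann closed form", {
  r <- enantiomer_ratio(4.8, 7.81, 298.15)
  expect_equal(r$ratio, exp(3.01 / (R_KCAL * 298.15)), tolerance = 1e-12)
  expect_gt(r$ratio, 157)
  expect_lt(r$ratio, 162)
  expect_equal(r$major, "R")
  expect_equal(enantiomer_ratio(3, 3)$ratio, 1)
  expect_equal(enantiomer_ratio(3, 3)$major, "tie")
  # inverse construction: ddE = RT ln(100) gives ratio 100
  dd <- R_KCAL * 298.15 * log(100)
  expect_equal(enantiomer_ratio(0, dd)$ratio, 100, tolerance = 1e-9)
  # swapping barriers swaps the major label, not the ratio
  r2 <- enantiomer_ratio(7.81, 4.8, 298.15)
  expect_equal(r2$ratio, r$ratio)
  expect_equal(r2$major, "S")
})

test_that("spin-state preference is the two-state Boltzmann fraction", {
  expect_equal(spin_state_preference(5, 5), 0.5)
  f3 <- spin_state_preference(4, 7, 298.15)
  expect_equal(f3, 1 / (1 + exp(-3 / (R_KCAL * 298.15))), tolerance = 1e-12)
  expect_gt(f3, 0.99)
  # symmetric swap sums to one
  a <- spin_state_preference(4, 7)
  expect_equal(a + (1 - a), 1)
  # consistency with enantiomer_ratio: percent_major equals the two-state fraction
  r <- enantiomer_ratio(4.8, 7.81)
  expect_equal(r$percent_major / 100,
               spin_state_preference(4.8, 7.81), tolerance = 1e-12)
})

test_that("selectivity is monotone in the barrier gap and in temperature", {
  gaps <- seq(0.5, 5, by = 0.5)
  ratios <- vapply(gaps, function(g) enantiomer_ratio(3, 3 + g)$ratio, 1)
  expect_true(all(diff(ratios) > 0))
  temps <- seq(250, 400, by = 25)
  rt <- vapply(temps, function(tt) enantiomer_ratio(3, 6, tt)$ratio, 1)
  expect_true(all(diff(rt) < 0))
})
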
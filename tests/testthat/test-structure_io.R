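test_that("read_pqr parses records, charges and group labels", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "REMARK generated fixture",
    "ATOM      1  OW  SOLV    1    0.000   0.000   3.000 -0.8340 1.6000"
  ), f)
  at <- read_pqr(f)
  expect_equal(nrow(at), 1L)
  expect_equal(at$charge, -0.834)
  expect_equal(at$group, "SOLV")
  expect_equal(at$index, 0L)
})

test_that("read_pqr of an empty file gives an empty atom table", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(character(), f)
  at <- read_pqr(f)
  expect_equal(nrow(at), 0L)
  expect_true(all(c("index", "group", "x", "charge") %in% names(at)))
})

test_that("malformed PQR records raise errors naming the line", {
  f <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  FE  FE      1    0.000   0.000   0.000  0.5000 1.2000",
    "ATOM      2  O1  O1      1    0.000   0.000"
  ), f)
  expect_error(read_pqr(f), "line 2")
  writeLines("ATOM 1 FE FE 1 0.0 0.0 0.0 notanumber 1.2", f)
  expect_error(read_pqr(f), "line 1")
})

test_that("PQR round-trip preserves fields to declared precision", {
  at <- random_atoms(25, seed = 3)
  at$radius <- withr::with_seed(4, runif(25, 1, 2))
  f <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(at, f)
  back <- read_pqr(f)
  expect_equal(back$index, at$index)
  expect_equal(back$group, at$group)
  expect_equal(back$x, at$x, tolerance = 1e-3)
  expect_equal(back$y, at$y, tolerance = 1e-3)
  expect_equal(back$z, at$z, tolerance = 1e-3)
  expect_equal(back$charge, at$charge, tolerance = 1e-4)
})

test_that("XYZ trajectories parse frames, times and join the charge map", {
  cmap <- make_atoms(x = 1:3, y = 0, z = 0, charge = c(0.5, -0.2, -0.3),
                     group = c("FE", "O1", "TLN"))
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3", "frame 0 time=0.0",
    "Fe 0.0 0.0 0.0", "O 0.0 0.0 1.65", "C 1.0 2.0 3.0",
    "3", "frame 1 time=10.0",
    "Fe 0.1 0.0 0.0", "O 0.0 0.1 1.65", "C 1.0 2.0 3.1"
  ), f)
  traj <- read_xyz_trajectory(f, cmap)
  expect_equal(sort(unique(traj$frame)), c(0L, 1L))
  expect_equal(unique(traj$time), c(0, 10))
  expect_equal(nrow(traj), 6L)
  expect_equal(traj$charge[traj$frame == 1], cmap$charge)
})

test_that("XYZ atom-count mismatch is a structural error", {
  cmap <- make_atoms(x = 1:3, y = 0, z = 0, charge = 0)
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3", "t0", "A 0 0 0", "B 1 0 0", "C 2 0 0",
    "4", "t1", "A 0 0 0", "B 1 0 0", "C 2 0 0", "D 3 0 0"
  ), f)
  expect_error(read_xyz_trajectory(f, cmap), "4 atoms")
})

test_that("generator output survives an XYZ round trip", {
  sys <- tiny_cage(seed = 11, n_frames = 3)
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz_trajectory(sys$trajectory, f)
  back <- read_xyz_trajectory(f, sys$atoms)
  expect_equal(back$x, sys$trajectory$x, tolerance = 1e-3)
  expect_equal(back$y, sys$trajectory$y, tolerance = 1e-3)
  expect_equal(back$z, sys$trajectory$z, tolerance = 1e-3)
  expect_equal(back$time, sys$trajectory$time)
})

test_that("distance-shell selection uses a closed boundary", {
  at <- make_atoms(
    x = c(0, 0, 0), y = c(0, 2.9, 3.1), z = 0,
    charge = 0, group = c("HM1", "SOLV", "SOLV")
  )
  got <- resolve_selection(at, "group SOLV within 3.0 of group HM1")
  expect_equal(got, 1L)
  at2 <- at
  at2$y[2] <- 3.0 # exactly at the boundary: included
  expect_equal(resolve_selection(at2, "group SOLV within 3.0 of group HM1"), 1L)
})

test_that("shell selection matches the brute-force double loop", {
  at <- random_atoms(200, seed = 8, groups = c("HM1", "SOLV", "CAGE"))
  fast <- resolve_selection(at, "group SOLV within 3.0 of group HM1")
  slow <- brute_shell(at,
                      at$index[at$group == "SOLV"],
                      at$index[at$group == "HM1"], 3.0)
  expect_equal(fast, slow)
})

test_that("selections are idempotent, order-independent and compose", {
  at <- random_atoms(60, seed = 9, groups = c("A1", "B2"))
  s1 <- resolve_selection(at, "group A1 or group B2")
  s2 <- resolve_selection(at, "group B2 or group A1")
  expect_equal(s1, s2)
  expect_equal(resolve_selection(at, "group A1 or group A1"),
               resolve_selection(at, "group A1"))
  expect_equal(resolve_selection(at, "not (not group A1)"),
               resolve_selection(at, "group A1"))
  expect_equal(resolve_selection(at, "index 5:9"), 5:9)
  expect_equal(sort(c(resolve_selection(at, "group A1"),
                      resolve_selection(at, "not group A1"))),
               at$index)
})

test_that("unknown labels raise a selection error listing valid labels", {
  at <- random_atoms(10, seed = 2, groups = c("HM1", "CAGE"))
  expect_error(resolve_selection(at, "group NOPE"), "CAGE")
  expect_error(resolve_selection(at, "group NOPE"), "HM1")
})

test_that("axis frame from axis-aligned construction is exact", {
  at <- make_atoms(
    x = c(0, 0, 0), y = c(0, 0, 3), z = c(0, 2, 1),
    charge = 0, group = c("FE", "O1", "TLN"),
    name = c("FE", "O1", "C1")
  )
  ax <- build_axis_frame(at, "group FE", "group O1", "group TLN")
  expect_equal(ax$z_hat, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(ax$y_hat, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(ax$origin, c(0, 0, 1), tolerance = 1e-12)
  # orthonormal right-handed
  expect_equal(sum(ax$x_hat^2), 1, tolerance = 1e-10)
  expect_equal(sum(ax$x_hat * ax$y_hat), 0, tolerance = 1e-10)
  expect_equal(sum(ax$x_hat * (c(ax$y_hat[2] * ax$z_hat[3] - ax$y_hat[3] * ax$z_hat[2],
                                 ax$y_hat[3] * ax$z_hat[1] - ax$y_hat[1] * ax$z_hat[3],
                                 ax$y_hat[1] * ax$z_hat[2] - ax$y_hat[2] * ax$z_hat[1]))),
               1, tolerance = 1e-10)
})

test_that("axis frame is equivariant under rigid motion", {
  sys <- tiny_cage(seed = 5, n_frames = 1)
  at <- sys$atoms
  ax <- build_axis_frame(at)
  for (s in 1:3) {
    rot <- random_rotation(seed = 100 + s)
    shift <- withr::with_seed(200 + s, rnorm(3, sd = 5))
    at_r <- rotate_atoms(at, rot, shift)
    ax_r <- build_axis_frame(at_r)
    expect_equal(ax_r$z_hat, as.numeric(rot %*% ax$z_hat), tolerance = 1e-10)
    expect_equal(ax_r$y_hat, as.numeric(rot %*% ax$y_hat), tolerance = 1e-10)
    expect_equal(ax_r$origin, as.numeric(rot %*% ax$origin) + shift,
                 tolerance = 1e-10)
  }
})

test_that("degenerate axis geometries raise errors", {
  at <- make_atoms(x = c(0, 0, 1), y = c(0, 0, 1), z = c(0, 0.2, 0.1),
                   charge = 0, group = c("FE", "O1", "TLN"))
  expect_error(build_axis_frame(at), "0.5 A")
  at2 <- make_atoms(x = c(0, 0, 0), y = c(0, 0, 0), z = c(0, 2, 5),
                    charge = 0, group = c("FE", "O1", "TLN"))
  expect_error(build_axis_frame(at2), "collinear")
})
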
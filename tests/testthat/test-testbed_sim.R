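# Virtual testbed: field profile, overdamped dynamics, rendering.

test_that("squared-field gradient is antisymmetric and zero at the midline", {
  geo <- electrode_geometry()
  drv <- drive_state(1e5)
  gap <- geo$gaps[geo$ref_gap, ]
  mid <- mean(gap)
  expect_equal(grad_e2_profile(geo, drv, mid), 0)
  # sign flips between the two halves of the gap
  g_left <- grad_e2_profile(geo, drv, mid - 10)
  g_right <- grad_e2_profile(geo, drv, mid + 10)
  expect_equal(g_left, -g_right)
  expect_lt(g_left, 0)
  # zero over the electrode fingers and outside the array
  expect_equal(grad_e2_profile(geo, drv, geo$fingers[2, "xL"] + 1), 0)
  expect_equal(grad_e2_profile(geo, drv, -50), 0)
})

test_that("gradient matches a finite difference of the squared field", {
  geo <- electrode_geometry()
  drv <- drive_state(2e5, vpp = 3)
  x <- geo$gaps[geo$ref_gap, "xL"] + 10  # 10 um inside the gap
  h_um <- 1e-4
  fd <- (field_e2_profile(geo, drv, x + h_um) -
           field_e2_profile(geo, drv, x - h_um)) / (2 * h_um * 1e-6)
  expect_equal(grad_e2_profile(geo, drv, x), fd, tolerance = 1e-3)
})

test_that("one overdamped Euler step equals the hand-computed displacement", {
  geo <- electrode_geometry()
  mat <- material_set()
  drv <- drive_state(1e4)
  cfg <- sim_config()
  x0 <- geo$ref_x_um + 12
  pop <- tibble::tibble(bead_id = 1L, x_um = x0, y_um = 30, radius_um = 1.5)
  stepped <- step_beads(pop, mat, drv, geo, cfg)
  # oracle: x + F dt / (6 pi eta R), assembled independently of step_beads
  f <- dep_force(mat, 1.5e-6, grad_e2_profile(geo, drv, x0), 1e4)
  dx_um <- f / (6 * pi * cfg$eta * 1.5e-6) * cfg$dt_s * 1e6
  expect_equal(stepped$x_um, x0 + dx_um, tolerance = 1e-12)
  expect_equal(stepped$y_um, 30)  # DEP acts along x only
})

test_that("zero Re[K] leaves noiseless positions unchanged", {
  geo <- electrode_geometry()
  mat <- material_set()
  fx <- crossover_frequency(mat)
  set.seed(11)
  pop <- init_beads(geo, 15)
  stepped <- step_beads(pop, mat, drive_state(fx), geo, sim_config())
  expect_equal(stepped$x_um, pop$x_um, tolerance = 1e-9)
})

test_that("attraction shrinks and repulsion grows the distance to the edges", {
  geo <- electrode_geometry()
  mat <- material_set()
  cfg <- sim_config()
  set.seed(12)
  pop <- init_beads(geo, 20)
  edges <- electrode_edges(geo)
  d_edge <- function(p) vapply(p$x_um, function(x) min(abs(x - edges)), numeric(1))
  # pDEP (10 kHz): distance to nearest edge never increases
  p <- pop
  for (i in 1:10) {
    p2 <- step_beads(p, mat, drive_state(1e4), geo, cfg)
    expect_true(all(d_edge(p2) <= d_edge(p) + 1e-9))
    p <- p2
  }
  # beads never leave their gap (clamped at edge positions)
  gap <- geo$gaps[geo$ref_gap, ]
  expect_true(all(p$x_um >= gap[["xL"]] & p$x_um <= gap[["xR"]]))
  # nDEP (10 MHz, above the search band top): distance never decreases
  p <- pop
  for (i in 1:10) {
    p2 <- step_beads(p, mat, drive_state(1e7), geo, cfg)
    expect_true(all(d_edge(p2) >= d_edge(p) - 1e-9))
    p <- p2
  }
})

test_that("noiseless feature sequences are monotone until saturation", {
  geo <- electrode_geometry()
  mat <- material_set()
  set.seed(13)
  beads <- init_beads(geo, 15)
  # pDEP: ground-truth feature non-decreasing
  sim <- simulate_run(beads, data.frame(freq_hz = 1e4, n_frames = 20),
                      mat, geo, sim_config())
  expect_true(all(diff(sim$features$x_true) >= -1e-9))
  # at crossover: feature constant
  fx <- crossover_frequency(mat)
  sim0 <- simulate_run(beads, data.frame(freq_hz = fx, n_frames = 10),
                       mat, geo, sim_config())
  expect_lt(max(sim0$features$x_true) - min(sim0$features$x_true), 1e-6)
})

test_that("mean displacement per step scales as bead radius squared", {
  geo <- electrode_geometry()
  mat <- material_set()
  drv <- drive_state(1e4)
  cfg <- sim_config()
  xs <- geo$ref_x_um + seq(5, 25, by = 5)
  mk <- function(r) tibble::tibble(bead_id = seq_along(xs), x_um = xs,
                                   y_um = 30, radius_um = r)
  d1 <- step_beads(mk(1.5), mat, drv, geo, cfg)$x_um - xs
  d2 <- step_beads(mk(3.0), mat, drv, geo, cfg)$x_um - xs
  expect_equal(d2 / d1, rep(4, length(xs)), tolerance = 1e-9)
})

test_that("seeded runs are bit-reproducible and rendering is a pure view", {
  geo <- small_geometry()
  mat <- material_set()
  sched <- data.frame(freq_hz = c(1e4, 1e6), n_frames = c(5, 5))
  cfg <- sim_config(noise_on = TRUE, seed = 77)
  set.seed(1); beads <- init_beads(geo, 8)
  s1 <- simulate_run(beads, sched, mat, geo, cfg)
  s2 <- simulate_run(beads, sched, mat, geo, cfg)
  expect_identical(s1$trajectory, s2$trajectory)
  # rendered-mode run shares identical trajectories with coordinate mode
  s3 <- simulate_run(beads, sched, mat, geo, cfg, render = TRUE)
  expect_identical(s1$trajectory, s3$trajectory)
  expect_length(s3$frames, 10)
})

test_that("Brownian noise spreads beads with the configured variance", {
  geo <- electrode_geometry()
  mat <- material_set()
  fx <- crossover_frequency(mat)  # no deterministic drift at the crossover
  cfg <- sim_config(noise_on = TRUE)
  pop <- tibble::tibble(bead_id = 1:500,
                        x_um = rep(geo$ref_x_um, 500),
                        y_um = rep(30, 500), radius_um = 1.5)
  set.seed(21)
  stepped <- step_beads(pop, mat, drive_state(fx), geo, cfg)
  d_coef <- 1.380649e-23 * cfg$temp_k / (6 * pi * cfg$eta * 1.5e-6)  # m^2/s
  expected_sd <- sqrt(2 * d_coef * cfg$dt_s) * 1e6
  expect_equal(sd(stepped$x_um - pop$x_um), expected_sd, tolerance = 0.15)
  expect_equal(sd(stepped$y_um - pop$y_um), expected_sd, tolerance = 0.15)
})

test_that("rendered frames are deterministic with beads darkest at centres", {
  geo <- small_geometry()
  # empty population: only background and brighter electrode stripes
  empty <- tibble::tibble(bead_id = integer(0), x_um = numeric(0),
                          y_um = numeric(0), radius_um = numeric(0))
  img0 <- render_frame(empty, geo)
  expect_equal(dim(img0), c(geo$frame_h_px, geo$frame_w_px))
  expect_equal(length(unique(round(img0, 3))) > 1, TRUE)  # stripes visible
  expect_gt(min(img0), 0.3)                               # no dark pixels

  # one bead at a known centre: darkest pixel within 1 px
  pop <- tibble::tibble(bead_id = 1L, x_um = geo$ref_x_um + 7, y_um = 25,
                        radius_um = 1.5)
  img <- render_frame(pop, geo)
  idx <- which(img == min(img), arr.ind = TRUE)[1, ]
  cx <- (pop$x_um - geo$fov_x0_um) / geo$um_per_px - 0.5
  cy <- pop$y_um / geo$um_per_px - 0.5
  expect_lt(abs((idx[["col"]] - 1) - cx), 1.01)
  expect_lt(abs((idx[["row"]] - 1) - cy), 1.01)

  # bit-identical across calls
  expect_identical(img, render_frame(pop, geo))
})

test_that("frame sequences round-trip through PNG files", {
  geo <- small_geometry()
  set.seed(5)
  pop <- init_beads(geo, 5)
  frames <- list(render_frame(pop, geo), render_frame(pop[1:2, ], geo))
  dir <- withr::local_tempdir()
  write_frames(frames, dir)
  back <- read_frames(dir)
  expect_length(back, 2)
  expect_equal(back[[1]], frames[[1]], tolerance = 1 / 255)
})
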
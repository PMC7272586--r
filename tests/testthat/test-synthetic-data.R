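test_that("zero fibers give pure background noise with empty ground truth", {
  spec <- fiber_network_spec(3, edge_um = 5, voxel_um = 0.25,
                             fiber_diameter_um = 0.6, n_fibers = 0,
                             noise_sd = 0.05, seed = 4)
  net <- generate_fiber_network(spec)
  expect_false(any(net$truth$mask))
  expect_lt(max(abs(net$image$data)), 0.05 * 6)  # noise only
})

test_that("spec validation rejects inconsistent fibrous-network requests", {
  expect_error(fiber_network_spec(3, n_fibers = 10, target_pore_um = 5),
               "exactly one")
  expect_error(fiber_network_spec(3, voxel_um = 0.29,
                                  fiber_diameter_um = 0.3, n_fibers = 5),
               "2 voxels")
  expect_error(fiber_network_spec(3, edge_um = 20, target_pore_um = 25),
               "infeasible")
})

test_that("rasterized fiber volume matches the analytic capsule volume", {
  # voxel-count oracle on a single known segment
  h <- 0.25
  dims <- rep(80L, 3L)
  r <- 1.5
  p0 <- matrix(c(2, 10, 10), 1)
  p1 <- matrix(c(18, 10, 10), 1)
  mask <- confinometry:::raster_fibers_cpp(dims, rep(h, 3), p0, p1, r)
  vol_vox <- sum(mask) * h^3
  len <- 16
  vol_true <- pi * r^2 * len + 4 / 3 * pi * r^3  # cylinder + end caps
  expect_lt(abs(vol_vox - vol_true) / vol_true, 0.05)
})

test_that("generators are bit-identical under a fixed seed", {
  spec <- fiber_network_spec(3, edge_um = 8, voxel_um = 0.25,
                             fiber_diameter_um = 0.6, n_fibers = 12,
                             seed = 9)
  a <- generate_fiber_network(spec)
  b <- generate_fiber_network(spec)
  expect_identical(a$image$data, b$image$data)
  expect_identical(a$truth$mask, b$truth$mask)
  spec2 <- spec; spec2$seed <- 10L
  expect_false(identical(generate_fiber_network(spec2)$image$data,
                         a$image$data))

  iv <- invasion_stack_spec(grid_shape = c(2, 2), n_cells = 20, seed = 3,
                            stack_px = 32L, depth_um_total = 120)
  expect_identical(generate_invasion_stacks(iv)$truth,
                   generate_invasion_stacks(iv)$truth)

  fc <- force_curve_spec(E_Pa = 300, noise_sd_pN = 15, seed = 2)
  expect_identical(generate_force_curve(fc)$approach,
                   generate_force_curve(fc)$approach)
})

test_that("invasion generator honours the depth mixture and z metadata", {
  # all cells adherent at the surface
  s0 <- invasion_stack_spec(grid_shape = c(2, 2), n_cells = 50,
                            surface_fraction = 1, seed = 5,
                            stack_px = 32L, depth_um_total = 120)
  expect_true(all(generate_invasion_stacks(s0)$truth$depth_um == 0))

  # Monte-Carlo check of the exponential tail sampler
  s1 <- invasion_stack_spec(grid_shape = c(2, 2), n_cells = 1000,
                            surface_fraction = 0.5, tail_scale_um = 50,
                            seed = 7, stack_px = 16L,
                            depth_um_total = 600)
  tr <- generate_invasion_stacks(s1)$truth
  below <- tr$depth_um[tr$depth_um > 0]
  se <- 50 / sqrt(length(below))
  expect_lt(abs(mean(below) - 50), 3 * se)

  # z-spacing passthrough into the rendered stacks
  s2 <- invasion_stack_spec(grid_shape = c(1, 1), n_cells = 2,
                            z_step_um = 4, seed = 1, stack_px = 16L,
                            depth_um_total = 80)
  st <- generate_invasion_stacks(s2)$stacks[[1]]
  expect_equal(st$voxel_size_um[3], 4)
})

test_that("rendered nucleus blobs sit within one voxel of the truth table", {
  s <- invasion_stack_spec(grid_shape = c(1, 1), n_cells = 1,
                           surface_fraction = 0, tail_scale_um = 30,
                           noise_sd = 0, seed = 11, stack_px = 48L,
                           depth_um_total = 200)
  sim <- generate_invasion_stacks(s)
  img <- sim$stacks[[1]]
  w <- img$data / sum(img$data)
  dims <- dim(img$data)
  centroid <- vapply(1:3, function(ax) {
    marg <- apply(w, ax, sum)
    sum((seq_len(dims[ax]) - 1) * img$voxel_size_um[ax] * marg)
  }, 1.0)
  truth <- unlist(sim$truth[1, c("x_um", "y_um", "z_um")])
  expect_true(all(abs(centroid - truth) <= img$voxel_size_um))
})

test_that("force-curve generator reproduces the Hertz closed form", {
  # F = (4/3) E/(1-nu^2) sqrt(R) delta^(3/2): 300 Pa, nu 0.5, R 3 um,
  # delta 1 um -> 0.9238 nN
  expect_equal(hertz_force(1, 300, 0.5, 3), 0.92376, tolerance = 1e-4)
  expect_identical(hertz_force(0, 300, 0.5, 3), 0)
  expect_identical(hertz_force(-1, 1000, 0.5, 3), 0)

  spec <- force_curve_spec(E_Pa = 300, nu = 0.5, R_um = 3, z0_um = 2,
                           setpoint_nN = 5, noise_sd_pN = 0, seed = 1)
  cv <- generate_force_curve(spec)
  # curve stops at the setpoint
  expect_equal(max(cv$approach$F_nN), 5, tolerance = 0.01)
  # zero force before contact
  pre <- cv$approach$F_nN[cv$approach$z_um < 2]
  expect_true(all(abs(pre) < 1e-12))
  # spot check against the closed form at delta = 1 um
  i <- which.min(abs(cv$approach$z_um - 3))
  expect_equal(cv$approach$F_nN[i],
               hertz_force(cv$approach$z_um[i] - 2, 300, 0.5, 3),
               tolerance = 1e-10)
})

test_that("spike artifacts stand out from the noiseless model by > 5 sd", {
  noise <- 10  # pN
  spec <- force_curve_spec(E_Pa = 300, R_um = 3, noise_sd_pN = noise,
                           spike_prob = 0.02, spike_nN = 2, seed = 21)
  cv <- generate_force_curve(spec)
  clean <- generate_force_curve(force_curve_spec(E_Pa = 300, R_um = 3,
                                                 noise_sd_pN = 0,
                                                 seed = 21))
  dev <- abs(cv$approach$F_nN - clean$approach$F_nN) / (noise * 1e-3)
  expect_gt(max(dev), 5)
})

test_that("force-curve specs at or below the noise floor are rejected", {
  expect_error(force_curve_spec(E_Pa = 100, setpoint_nN = 0.001,
                                noise_sd_pN = 10), "noise floor")
  expect_error(force_curve_spec(E_Pa = -5), "E must be")
})

test_that("nucleus generator renders the requested ellipsoid", {
  spec <- nucleus_volume_spec(semi_axes_um = c(8, 5, 3), voxel_um = 0.5,
                              seed = 3)
  nv <- generate_nucleus_volume(spec)
  vol <- sum(nv$mask) * 0.5^3
  expect_lt(abs(vol - 4 / 3 * pi * 8 * 5 * 3) / (4 / 3 * pi * 120), 0.03)
  # semi-axes are sorted decreasing on construction
  expect_equal(nucleus_volume_spec(c(3, 8, 5))$semi_axes_um, c(8, 5, 3))
})
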
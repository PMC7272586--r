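test_that("well-separated nuclei are all detected within 2 um of truth", {
  spec <- invasion_stack_spec(grid_shape = c(3, 3), n_cells = 30,
                              surface_z_um = 20, surface_fraction = 0.6,
                              tail_scale_um = 50, noise_sd = 0.1,
                              seed = 1)  # SNR ~ 10
  sim <- generate_invasion_stacks(spec)
  tr <- sim$truth
  tr$stack <- sprintf("pos_%02d_%02d", tr$grid_x, tr$grid_y)
  # fixture validity: nuclei are well separated within each stack
  min_sep <- min(vapply(split(tr, tr$stack), function(s) {
    if (nrow(s) < 2) return(Inf)
    min(dist(s[, c("x_um", "y_um", "z_um")]))
  }, 1.0))
  expect_gt(min_sep, 12)
  det <- detect_nuclei(sim$stacks)
  expect_equal(nrow(det), nrow(tr))
  err <- vapply(seq_len(nrow(det)), function(i) {
    cand <- tr[tr$stack == det$stack[i], ]
    min(sqrt((cand$x_um - det$x_um[i])^2 + (cand$y_um - det$y_um[i])^2 +
               (cand$z_um - det$z_um[i])^2))
  }, 1.0)
  expect_lt(max(err), 2)
})

test_that("blank stacks yield zero detections and empty input errors", {
  blank <- image_volume(array(0, c(32, 32, 20)) +
                          stats::rnorm(32 * 32 * 20, 0, 0.05),
                        c(1.3, 1.3, 4))
  expect_equal(nrow(detect_nuclei(list(a = blank, b = blank))), 0L)
  expect_error(detect_nuclei(list()), "no stacks")
})

test_that("two nuclei closer than the merge radius collapse to one", {
  dims <- c(48L, 48L, 30L)
  spacing <- c(1, 1, 4)
  img <- confinometry:::add_blobs_cpp(array(0, dims), dims, spacing,
                                      rbind(c(20, 24, 60), c(21, 24, 60)),
                                      c(4, 4, 4), 1)
  det <- detect_nuclei(image_volume(array(img, dims), spacing))
  expect_equal(nrow(det), 1L)
})

test_that("surface estimation finds the adherent layer mode", {
  # all cells in one plane
  flat <- data.frame(z_um = rep(12, 20))
  expect_equal(estimate_surface(flat, 4)$z0_um, 12)
  expect_error(estimate_surface(data.frame(z_um = 1:5), 4), "too few")

  # 70% surface layer + 30% exponential tail: within one bin of truth
  set.seed(42)
  z <- c(rep(20, 70), 20 + stats::rexp(30, 1 / 60))
  est <- estimate_surface(data.frame(z_um = z), 4)
  expect_lt(abs(est$z0_um - 20), 4)

  # bimodal with the deeper mode smaller: tie-break toward the surface
  bim <- data.frame(z_um = c(rep(8, 12), rep(40, 12), rep(24, 3)))
  expect_equal(estimate_surface(bim, 4)$z0_um, 8)
})

test_that("the 8 um rule is strict and matches direct thresholding", {
  rec <- data.frame(z_um = 10 + c(2, 8, 8.1, 50))
  cls <- classify_invasive(rec, z0_um = 10, threshold_um = 8)
  expect_equal(cls$invasive, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(cls$depth_um, c(2, 8, 8.1, 50))

  # synthetic cohort: flags identical to truth-table thresholding
  spec <- invasion_stack_spec(grid_shape = c(2, 2), n_cells = 1000,
                              surface_z_um = 20, seed = 9,
                              stack_px = 16L, depth_um_total = 400)
  tr <- generate_invasion_stacks(spec)$truth
  cls <- classify_invasive(tr, z0_um = 20, threshold_um = 8)
  expect_identical(cls$invasive, tr$depth_um > 8)

  # all at the surface: nothing invasive
  all0 <- classify_invasive(data.frame(z_um = rep(5, 30)), 5)
  expect_equal(100 * mean(all0$invasive), 0)
})

test_that("invasion summaries equal direct arithmetic", {
  rec <- classify_invasive(data.frame(z_um = c(0, 20, 30)), 0)
  s <- summarize_invasion(rec)
  expect_equal(unname(s$percent_invasive["mean"]), 2 / 3 * 100,
               tolerance = 1e-12)
  rec2 <- classify_invasive(data.frame(z_um = c(0, 0, 10, 20, 30)), 0)
  s2 <- summarize_invasion(rec2)
  expect_equal(unname(s2$invasion_depth_um["mean"]), 20)
  expect_error(summarize_invasion(rec[0, ]), "no cells")

  # five replicates: summary equals per-replicate arithmetic
  set.seed(11)
  truth <- data.frame(z_um = stats::rexp(500, 1 / 30),
                      well = rep(1:5, each = 100))
  cls <- classify_invasive(truth, 0)
  s5 <- summarize_invasion(cls, replicate = "well")
  per <- vapply(split(cls, cls$well),
                function(r) 100 * mean(r$invasive), 1.0)
  expect_equal(unname(s5$percent_invasive["mean"]), mean(per))
  expect_equal(unname(s5$percent_invasive["sd"]), sd(per))

  # invasive + non-invasive percentages always total 100
  expect_equal(unname(s5$percent_invasive["mean"]) +
                 mean(100 - per), 100)
})

test_that("cumulative depth distribution behaves as a proper ECDF", {
  ec <- cumulative_depth(data.frame(depth_um = c(0, 10)))
  expect_equal(ec(5), 0.5)
  expect_equal(ec(10), 1.0)
  one <- cumulative_depth(data.frame(depth_um = 7))
  expect_equal(one(6.9), 0)
  expect_equal(one(7), 1)

  # DKW band against the true exponential CDF at 95%
  set.seed(13)
  n <- 2000
  d <- stats::rexp(n, 1 / 50)
  ec2 <- cumulative_depth(data.frame(depth_um = d))
  grid <- seq(0, 300, by = 1)
  eps <- sqrt(log(2 / 0.05) / (2 * n))
  expect_lt(max(abs(ec2(grid) - stats::pexp(grid, 1 / 50))), eps)

  # monotone, reaching 1
  expect_true(all(diff(ec2(grid)) >= 0))
  expect_equal(ec2(Inf), 1)

  # ECDF at the invasion threshold complements the invasive percentage
  cls <- classify_invasive(data.frame(z_um = c(0, 0, 9, 15, 30)), 0)
  ec3 <- cumulative_depth(cls)
  s <- summarize_invasion(cls)
  expect_equal(ec3(8), 1 - unname(s$percent_invasive["mean"]) / 100)
})

test_that("deepest-fraction selection keeps ties at the boundary", {
  rec <- classify_invasive(data.frame(z_um = 10 + seq(9, 108)), 0)
  top <- deepest_fraction(rec, 0.10)
  expect_equal(nrow(top), 10L)
  expect_equal(sort(top$depth_um), sort(rec$depth_um)[91:100])

  ten <- classify_invasive(data.frame(z_um = 10 + seq(10, 100, by = 10)),
                           0)
  expect_equal(nrow(deepest_fraction(ten, 0.10)), 1L)
  expect_equal(deepest_fraction(ten, 0.10)$depth_um, 110)

  tie <- classify_invasive(
    data.frame(z_um = c(rep(50, 5), seq(10, 40, length.out = 15))), 0)
  expect_equal(nrow(deepest_fraction(tie, 0.10)), 5L)  # all tied at 50
  expect_error(deepest_fraction(ten[1:5, ], 0.10), "too few")
})

test_that("shifting every z leaves depths, flags and summaries unchanged", {
  set.seed(3)
  z <- c(rep(20, 40), 20 + stats::rexp(20, 1 / 80))
  base <- data.frame(z_um = z)
  shifted <- data.frame(z_um = z + 13.7)
  z0a <- estimate_surface(base, 4)$z0_um
  z0b <- estimate_surface(shifted, 4)$z0_um
  expect_equal(z0b, z0a + 13.7)
  a <- classify_invasive(base, z0a)
  b <- classify_invasive(shifted, z0b)
  expect_equal(a$depth_um, b$depth_um)
  expect_identical(a$invasive, b$invasive)
})
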
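test_that("force-curve files round-trip and validate their structure", {
  cv <- generate_force_curve(force_curve_spec(E_Pa = 250, R_um = 3,
                                              noise_sd_pN = 12,
                                              seed = 5))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(cv, f)
  back <- parse_force_curve(f)
  expect_equal(back$approach, cv$approach, tolerance = 1e-12)
  expect_equal(back$retract, cv$retract, tolerance = 1e-12)
  expect_equal(back$R_um, 3)
  expect_equal(back$setpoint_nN, 5)
  expect_equal(back$protocol, "nucleus")

  # shuffled positions are rejected
  lines <- readLines(f)
  body <- grep("^#|^segment", lines, invert = TRUE)
  shuffled <- lines
  set.seed(1)
  shuffled[body] <- sample(lines[body])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(shuffled, f2)
  expect_error(parse_force_curve(f2), "monotone")

  # unknown segment labels are reported
  broken <- sub("^approach", "weird", lines)
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(broken, f3)
  expect_error(parse_force_curve(f3), "segment label")
})

test_that("contact point is recovered on clean and noisy curves", {
  cv <- generate_force_curve(force_curve_spec(E_Pa = 300, R_um = 3,
                                              z0_um = 2,
                                              noise_sd_pN = 0, seed = 1))
  z0 <- estimate_contact_point(cv, "approach")
  expect_lt(abs(z0 - 2), 0.005)  # one sample spacing

  flat <- cv
  flat$approach$F_nN <- stats::rnorm(nrow(flat$approach), 0, 0.005)
  expect_error(estimate_contact_point(flat, "approach"), "no contact")

  # Monte Carlo at 10 pN noise, 5 nN setpoint
  errs <- vapply(1:60, function(s) {
    cvn <- generate_force_curve(force_curve_spec(E_Pa = 300, R_um = 3,
                                                 z0_um = 2,
                                                 noise_sd_pN = 10,
                                                 seed = s))
    abs(estimate_contact_point(cvn, "approach") - 2)
  }, 1.0)
  expect_lt(stats::quantile(errs, 0.95), 3 * 0.005)
})

test_that("noiseless Hertz fits recover the modulus across the range", {
  for (E in c(50, 300, 1000)) for (R in c(3, 22.5))
    for (w in c("full", "top10")) {
      cv <- generate_force_curve(force_curve_spec(E_Pa = E, R_um = R,
                                                  noise_sd_pN = 0,
                                                  seed = 1))
      ft <- hertz_fit(cv, "approach", w)
      expect_lt(abs(ft$E_Pa - E) / E, 1e-3)
    }
  # retract fits agree with approach fits on clean curves
  cv <- generate_force_curve(force_curve_spec(E_Pa = 120, R_um = 22.5,
                                              noise_sd_pN = 0, seed = 2))
  expect_equal(hertz_fit(cv, "retract", "full")$E_Pa,
               hertz_fit(cv, "approach", "full")$E_Pa,
               tolerance = 1e-6)
})

test_that("fitted modulus scales linearly in force and as R^(-1/2)", {
  cv <- generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                              noise_sd_pN = 0, seed = 3))
  doubled <- cv
  doubled$approach$F_nN <- 2 * doubled$approach$F_nN
  doubled$retract$F_nN <- 2 * doubled$retract$F_nN
  z0 <- estimate_contact_point(cv, "approach")
  e1 <- hertz_fit(cv, "approach", "full", z0_um = z0)$E_Pa
  e2 <- hertz_fit(doubled, "approach", "full", z0_um = z0)$E_Pa
  expect_equal(e2, 2 * e1, tolerance = 1e-9)

  # misdeclaring the bead radius by 4x halves the modulus
  e4 <- hertz_fit(cv, "approach", "full", R_um = 12, z0_um = z0)$E_Pa
  expect_equal(e4, e1 / 2, tolerance = 1e-9)
})

test_that("the residual-RMS filter is inclusive at the threshold and monotone", {
  cv <- generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                              noise_sd_pN = 0, seed = 1))
  ft <- hertz_fit(cv, "approach", "full")
  expect_true(rms_filter(ft, 150)$accepted)  # clean fit, RMS ~ 0

  ft$rms_pN <- 150
  expect_true(rms_filter(ft, 150)$accepted)  # inclusive <=
  ft$rms_pN <- 150.001
  expect_false(rms_filter(ft, 150)$accepted)

  # spike-corrupted curve exceeds the threshold
  spiky <- generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                                 noise_sd_pN = 10,
                                                 spike_prob = 0.01,
                                                 spike_nN = 2, seed = 5))
  fs <- hertz_fit(spiky, "approach", "full")
  expect_gt(fs$rms_pN, 150)
  expect_false(rms_filter(fs)$accepted)

  # threshold monotonicity on a batch of noisy curves
  rms <- vapply(1:20, function(s) {
    cvn <- generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                                 noise_sd_pN = 60,
                                                 seed = s))
    hertz_fit(cvn, "approach", "full")$rms_pN
  }, 1.0)
  acc <- vapply(c(100, 150, 200), function(thr) sum(rms <= thr), 1L)
  expect_true(all(diff(acc) >= 0))
  # clean synthetic curves: the accept set is stable across 100-200 pN
  clean <- vapply(1:20, function(s) {
    cvn <- generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                                 noise_sd_pN = 15,
                                                 seed = s))
    hertz_fit(cvn, "approach", "full")$rms_pN
  }, 1.0)
  expect_equal(sum(clean <= 100), sum(clean <= 200))
})

test_that("protocol runs aggregate accepted repeats per cell", {
  noiseless <- lapply(1:5, function(i)
    generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                          noise_sd_pN = 0, seed = i)))
  pr <- run_protocol(list(cell = noiseless), "nucleus")
  expect_equal(pr$per_cell$E_Pa, 200, tolerance = 1e-3)
  expect_equal(pr$per_cell$n_accepted, 5L)

  # two corrupted repeats: the cell mean uses the three accepted ones
  mixed <- c(lapply(1:3, function(i)
    generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                          noise_sd_pN = 5, seed = i))),
    lapply(4:5, function(i)
      generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                            noise_sd_pN = 10,
                                            spike_prob = 0.05,
                                            spike_nN = 3, seed = i))))
  pr2 <- run_protocol(list(cell = mixed), "nucleus")
  expect_equal(pr2$per_cell$n_accepted, 3L)
  clean_fits <- vapply(pr2$fits$cell[1:3], function(f) f$E_Pa, 1.0)
  expect_equal(pr2$per_cell$E_Pa, mean(clean_fits))

  # a cell whose repeats are all rejected is excluded and logged
  allbad <- lapply(1:2, function(i)
    generate_force_curve(force_curve_spec(E_Pa = 200, R_um = 3,
                                          noise_sd_pN = 10,
                                          spike_prob = 0.2, spike_nN = 4,
                                          seed = i)))
  pr3 <- run_protocol(list(good = noiseless[1:2], bad = allbad),
                      "nucleus")
  expect_equal(pr3$excluded, "bad")
  expect_equal(nrow(pr3$per_cell), 1L)
})

test_that("a synthetic cohort median is recovered under noise", {
  set.seed(99)
  true_E <- stats::rlnorm(40, log(150), 0.4)
  cells <- lapply(seq_along(true_E), function(i)
    lapply(1:3, function(r)
      generate_force_curve(force_curve_spec(E_Pa = true_E[i], R_um = 3,
                                            noise_sd_pN = 20,
                                            seed = 1000 * i + r))))
  names(cells) <- sprintf("c%02d", seq_along(cells))
  pr <- run_protocol(cells, "nucleus")
  expect_lt(abs(median(pr$per_cell$E_Pa) - median(true_E)) /
              median(true_E), 0.10)
})
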
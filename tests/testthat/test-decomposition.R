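test_that("cos_sq_alpha maps the physical r_o range onto [0, 1]", {
  expect_equal(cos_sq_alpha(0.4), 1)      # collinear oscillators
  expect_equal(cos_sq_alpha(-0.2), 0)     # perpendicular oscillators
  expect_equal(cos_sq_alpha(0.1), 0.5)    # in-plane term (2cos^2a - 1) vanishes
  expect_error(cos_sq_alpha(0.45), "domain")
  expect_error(cos_sq_alpha(-0.25), "domain")
  # inverse of r_o = (3 cos^2 - 1)/5 over the whole domain
  ro <- seq(-0.2, 0.4, by = 0.01)
  expect_equal((3 * cos_sq_alpha(ro) - 1) / 5, ro, tolerance = 1e-14)
})

test_that("weber_transform reduces as expected at the special points", {
  # r_o = 0.1 -> X = 0, Y carries only the out-of-plane part
  w <- weber_transform(r = 0.05, r_o = 0.1, tau_f_ns = 8)
  expect_equal(w$x, 0)
  # r = r_o -> Y = 0 (no depolarization during the excited state)
  w0 <- weber_transform(r = 0.3, r_o = 0.3, tau_f_ns = 8)
  expect_equal(w0$y, 0)
  expect_error(weber_transform(0, 0.3, 8), "singularity")
  expect_error(weber_transform(0.1, -0.2, 8), "singularity")
  expect_error(weber_transform(-0.05, 0.3, 8), "same sign")
})

test_that("weber_transform inverts the forward model exactly", {
  # worked example: truth (R_ip, R_op) = (31.2, 29.1) MHz, r_o = 0.3, tau = 8
  r <- anisotropy_from_truth(29.1, 31.2, r_o = 0.3, tau_f_ns = 8)
  w <- weber_transform(r, 0.3, 8)
  expect_equal(w$x, 0.8, tolerance = 1e-12)
  expect_equal(w$y, (31.2 * 0.8 + 29.1) / 1000, tolerance = 1e-12)  # 0.054 1/ns
  # and against the independent slow-rotation-relation oracle on a grid
  grid <- expand.grid(ro = c(-0.1, 0.05, 0.15, 0.3), tau = c(5, 8, 11),
                      rip = c(10, 30, 60), rop = c(8, 25, 45))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    r_oracle <- oracle_r_from_rates(g$rop, g$rip, g$ro, g$tau)
    if (abs(r_oracle) >= 0.4 || sign(r_oracle) != sign(g$ro)) next
    w <- weber_transform(r_oracle, g$ro, g$tau)
    expect_equal(w$y, (g$rip * w$x + g$rop) / 1000, tolerance = 1e-12)
  }
})

test_that("fit_rotation_rates recovers an exact line to machine precision", {
  # line parameters from the reference isotropic-vesicle decomposition
  ro <- c(-0.08, 0.05, 0.12, 0.22, 0.30)
  x <- (10 * ro - 1) / (5 * ro + 1)
  y <- (31.2 * x + 29.1) / 1000
  fit <- fit_rotation_rates(data.frame(x = x, y = y))
  expect_equal(fit$r_ip_mhz, 31.2, tolerance = 1e-9)
  expect_equal(fit$r_op_mhz, 29.1, tolerance = 1e-9)
  expect_lt(fit$ci95_op, 1e-6)
  expect_lt(fit$ci95_ip, 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("flat data gives zero slope and errors are specific", {
  x <- c(-1, 0, 0.5, 0.8)
  fit <- fit_rotation_rates(data.frame(x = x, y = rep(0.02, 4)))
  expect_equal(fit$r_ip_mhz, 0, tolerance = 1e-10)
  expect_equal(fit$r_op_mhz, 20, tolerance = 1e-10)
  expect_error(fit_rotation_rates(data.frame(x = c(1, 1, 1), y = 1:3)),
               "rank-deficiency")
  expect_error(fit_rotation_rates(data.frame(x = 1, y = 1)), "at least 2")
  expect_error(fit_rotation_rates(data.frame(x = c(0, 1), y = c(1, 2)),
                                  weights = c(-1, 1)), "nonnegative")
})

test_that("95% CIs of the weighted fit cover truth at nominal rate", {
  # brute-force coverage oracle: 100 seeded repetitions, n = 130,
  # sigma = 10% of mean Y
  ro <- c(-0.08, 0.05, 0.12, 0.22, 0.30)
  x <- rep((10 * ro - 1) / (5 * ro + 1), each = 26)
  mu <- (31.2 * x + 29.1) / 1000
  hits_op <- hits_ip <- 0
  for (s in 1:100) {
    set.seed(s)
    y <- mu + stats::rnorm(130, 0, 0.1 * mean(mu))
    fit <- fit_rotation_rates(data.frame(x = x, y = y))
    hits_op <- hits_op + (abs(fit$r_op_mhz - 29.1) <= fit$ci95_op)
    hits_ip <- hits_ip + (abs(fit$r_ip_mhz - 31.2) <= fit$ci95_ip)
  }
  expect_gte(hits_op, 90)
  expect_gte(hits_ip, 90)
})

test_that("correlation_time matches the published worked values", {
  # printed rates -> printed correlation times after 1-decimal rounding
  expect_equal(round(correlation_time(29.1), 1), 5.7)
  expect_equal(round(correlation_time(40.6), 1), 4.1)
  expect_equal(correlation_time(1000 / 6), 1.0, tolerance = 1e-12)
  expect_error(correlation_time(0), "domain")
  expect_error(correlation_time(-5), "domain")
  # strictly decreasing in the rate
  rates <- seq(5, 80, by = 5)
  expect_true(all(diff(correlation_time(rates)) < 0))
})

test_that("decompose_wavelength_set recovers truth from noiseless sets", {
  phot <- default_photophysics()
  pts <- truth_points(29.1, 31.2, phot)
  dec <- decompose_wavelength_set(pts, phot)
  expect_equal(dec$r_op_mhz, 29.1, tolerance = 1e-8)
  expect_equal(dec$r_ip_mhz, 31.2, tolerance = 1e-8)
  # dropping one wavelength leaves the line determined
  dec4 <- decompose_wavelength_set(pts[pts$excitation_nm != 347, ], phot)
  expect_equal(dec4$r_op_mhz, 29.1, tolerance = 1e-8)
  expect_equal(dec4$n_points, 4)
  # unweighted route agrees on noiseless data
  dec_u <- decompose_wavelength_set(pts, phot, weighting = "none")
  expect_equal(dec_u$r_op_mhz, dec$r_op_mhz, tolerance = 1e-8)
  expect_error(decompose_wavelength_set(pts[pts$excitation_nm == 319, ], phot),
               "insufficient-data")
})

test_that("isotropic truth yields slope = intercept (vesicle-like behaviour)", {
  phot <- default_photophysics()
  for (R in c(20, 35)) {
    dec <- decompose_wavelength_set(truth_points(R, R, phot), phot)
    expect_equal(dec$r_ip_mhz, dec$r_op_mhz, tolerance = 1e-6)
    expect_equal(dec$r_op_mhz, R, tolerance = 1e-6)
  }
})

test_that("an all-X-equal design raises a rank-deficiency error", {
  flat <- photophysics_table(data.frame(
    probe_id = "2-AS", temperature_c = rep(c(21, 47), 5),
    excitation_nm = rep(c(319, 333, 347, 367, 381), each = 2),
    tau_f_ns = 8, r_o = 0.1))
  pts <- truth_points(25, 40, flat, temperature_c = 37)
  expect_error(decompose_wavelength_set(pts, flat), "rank-deficiency")
})

test_that("extrapolation flags propagate into the decomposition", {
  phot <- default_photophysics()   # anchors 21..47
  dec_in <- decompose_wavelength_set(truth_points(25, 30, phot,
                                                  temperature_c = 37), phot)
  expect_false(dec_in$extrapolation_flag)
  dec_out <- decompose_wavelength_set(truth_points(25, 30, phot,
                                                   temperature_c = 50), phot)
  expect_true(dec_out$extrapolation_flag)
})

test_that("decomposition tables collect results for reporting", {
  phot <- default_photophysics()
  decs <- list(decompose_wavelength_set(truth_points(25, 30, phot), phot),
               decompose_wavelength_set(truth_points(40, 50, phot), phot))
  tab <- decomposition_table(decs)
  expect_equal(nrow(tab), 2)
  expect_named(tab, c("probe_id", "condition_id", "temperature_c",
                      "r_op_mhz", "ci95_op", "r_ip_mhz", "ci95_ip",
                      "phi_op_ns", "phi_ip_ns", "n_points", "r_squared",
                      "extrapolation_flag"))
  expect_equal(tab$phi_op_ns, 1000 / (6 * tab$r_op_mhz), tolerance = 1e-9)
})
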
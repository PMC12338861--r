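test_that("binning matches a brute-force partition of the ramp", {
  sc <- scenario_sensitive()
  pts <- batch_anisotropy(simulate_run(sc, "2-AS", seed = 2),
                          warn_flags = FALSE)
  b <- bin_heating_curve(pts, window_c = 2)
  # oracle: direct partition by temperature
  brute <- floor((pts$temperature_c - floor(min(pts$temperature_c))) / 2)
  expect_equal(b$window, as.integer(brute - min(brute) + 1L))
  info <- attr(b, "window_info")
  expect_equal(sum(info$n), nrow(pts))
  # window centers are the mean member temperatures
  expect_equal(info$center_c,
               as.numeric(tapply(pts$temperature_c, b$window, mean)))
})

test_that("all readings at one temperature form a single window", {
  pts <- truth_points(25, 30, default_photophysics())
  b <- bin_heating_curve(pts, window_c = 2)
  expect_equal(unique(b$window), 1L)
  expect_error(bin_heating_curve(pts[0, ]), "empty")
  expect_error(bin_heating_curve(pts, window_c = 0), "window_c")
})

test_that("windows with a single wavelength are flagged", {
  pts <- truth_points(25, 30, default_photophysics())
  pts$temperature_c <- ifelse(pts$excitation_nm == 319, 10, 20)
  b <- bin_heating_curve(pts, window_c = 2)
  info <- attr(b, "window_info")
  expect_true(info$flag_few_wavelengths[info$n_wavelengths == 1])
})

test_that("smoothing reproduces a noiseless monotone profile within 1%", {
  sc <- scenario_sensitive(sigma_rel = 0, temp_jitter_c = 0)
  pts <- do.call(rbind, lapply(1:3, function(k)
    batch_anisotropy(simulate_run(sc, "2-AS", paste0("rep", k), seed = k),
                     warn_flags = FALSE)))
  tab <- decompose_heating_curves(pts, sc$photophysics, window_c = 2)
  prof <- smooth_profiles(tab, bandwidth_c = 5)
  grid <- seq(10, 50, by = 5)
  est <- predict_profiles(prof, grid, mode = "op")
  tr <- truth_rates(sc, "2-AS", grid)$r_op_mhz
  expect_lt(max(abs(est$rate_mhz - tr) / tr), 0.01)
  # profile strictly increasing when the truth is Arrhenius-type
  expect_true(all(diff(est$rate_mhz) > 0))
})

test_that("a constant profile smooths to a constant", {
  tab <- data.frame(probe_id = "2-AS", condition_id = "c",
                    temperature_c = seq(10, 50, by = 2),
                    r_op_mhz = 25, ci95_op = 0.5,
                    r_ip_mhz = 30, ci95_ip = 0.5,
                    extrapolation_flag = FALSE)
  prof <- smooth_profiles(tab, bandwidth_c = 5)
  est <- predict_profiles(prof, c(12, 25, 48), mode = "op")
  expect_equal(est$rate_mhz, rep(25, 3), tolerance = 1e-9)
  expect_error(smooth_profiles(tab[1:3, ]), "span")
})

test_that("pooling three replicates beats any single replicate", {
  # study-level comparison (all probes, both modes): for a single probe and
  # mode the ordering only holds in expectation, across the whole study it
  # is stable
  sc <- scenario_sensitive()
  pts <- lapply(1:3, function(k) do.call(rbind, lapply(
    sc$probes$probe_id, function(p)
      batch_anisotropy(simulate_run(sc, p, paste0("rep", k),
                                    seed = 100 + 7 * k), warn_flags = FALSE))))
  grid <- seq(12, 48, by = 4)
  rel_rmse <- function(p) {
    tab <- decompose_heating_curves(p, sc$photophysics)
    prof <- smooth_profiles(tab)
    e <- c()
    for (m in c("op", "ip")) {
      est <- predict_profiles(prof, grid, mode = m)
      tr <- mapply(function(pb, tc)
        truth_rates(sc, pb, tc)[[paste0("r_", m, "_mhz")]],
        est$probe_id, est$temperature_c)
      e <- c(e, (est$rate_mhz - tr) / tr)
    }
    sqrt(mean(e^2))
  }
  singles <- vapply(pts, rel_rmse, 0)
  pooled <- rel_rmse(do.call(rbind, pts))
  expect_lt(pooled, min(singles))
})

test_that("the gradient surface sits on the exact 5-degree grid with the
           transversal minimum at n = 7-9", {
  sc <- scenario_sensitive(sigma_rel = 0, temp_jitter_c = 0)
  pts <- do.call(rbind, lapply(sc$probes$probe_id, function(p)
    batch_anisotropy(simulate_run(sc, p, seed = 3), warn_flags = FALSE)))
  tab <- decompose_heating_curves(pts, sc$photophysics)
  prof <- smooth_profiles(tab)
  surf <- build_gradient(prof, mode = "op")
  expect_s3_class(surf, "gradient_surface")
  expect_setequal(unique(surf$temperature_c), seq(10, 50, by = 5))
  expect_setequal(unique(surf$position_n), c(2, 7, 9, 12, 16))
  # interface and bilayer-centre maxima, microviscosity-barrier minimum
  for (tc in unique(surf$temperature_c)) {
    s <- surf[surf$temperature_c == tc, ]
    expect_true(s$position_n[which.min(s$rate_mhz)] %in% c(7, 9))
    expect_true(s$position_n[which.max(s$rate_mhz)] %in% c(2, 16))
  }
  # single-probe input gives a one-row-per-temperature surface
  one <- smooth_profiles(tab[tab$probe_id == "2-AS", ])
  s1 <- build_gradient(one, mode = "op")
  expect_equal(unique(s1$position_n), 2L)
})

test_that("in-plane stays above out-of-plane through the full pipeline", {
  sc <- scenario_sensitive()
  pts <- do.call(rbind, lapply(sc$probes$probe_id, function(p)
    do.call(rbind, lapply(1:3, function(k)
      batch_anisotropy(simulate_run(sc, p, paste0("rep", k),
                                    seed = 500 + 10 * k), warn_flags = FALSE)))))
  tab <- decompose_heating_curves(pts, sc$photophysics)
  prof <- smooth_profiles(tab)
  op <- build_gradient(prof, mode = "op")
  ip <- build_gradient(prof, mode = "ip")
  # per-cell diagnostic: R_ip >= R_op (allow CI-level slack)
  slack <- sqrt(op$ci95^2 + ip$ci95^2)
  expect_true(all(ip$rate_mhz - op$rate_mhz > -slack))
})

test_that("comparing a surface with itself gives unit ratios", {
  sc <- scenario_sensitive(sigma_rel = 0, temp_jitter_c = 0)
  pts <- do.call(rbind, lapply(c("2-AS", "16-AP"), function(p)
    batch_anisotropy(simulate_run(sc, p, seed = 6), warn_flags = FALSE)))
  tab <- decompose_heating_curves(pts, sc$photophysics)
  surf <- build_gradient(smooth_profiles(tab), mode = "op")
  cmpr <- compare_gradients(surf, surf)
  expect_equal(cmpr$ratio, rep(1, nrow(cmpr)), tolerance = 1e-12)
  expect_false(any(cmpr$exceeds))
})

test_that("comparison requires matching mode and grid, and skips empty cells", {
  sc <- scenario_sensitive(sigma_rel = 0, temp_jitter_c = 0)
  pts <- do.call(rbind, lapply(c("2-AS", "16-AP"), function(p)
    batch_anisotropy(simulate_run(sc, p, seed = 6), warn_flags = FALSE)))
  tab <- decompose_heating_curves(pts, sc$photophysics)
  prof <- smooth_profiles(tab)
  op <- build_gradient(prof, mode = "op")
  ip <- build_gradient(prof, mode = "ip")
  expect_error(compare_gradients(op, ip), "mode")
  sub <- op[op$position_n == 2, ]
  class(sub) <- class(op)
  expect_error(compare_gradients(op, sub), "grid mismatch")
  b <- op; b$rate_mhz[3] <- NA
  cmpr <- compare_gradients(op, b)
  expect_true(is.na(cmpr$ratio[3]))
  expect_equal(sum(is.na(cmpr$ratio)), 1)
})

test_that("gradient surfaces round-trip through CSV", {
  sc <- scenario_sensitive(sigma_rel = 0, temp_jitter_c = 0)
  pts <- batch_anisotropy(simulate_run(sc, "2-AS", seed = 8),
                          warn_flags = FALSE)
  tab <- decompose_heating_curves(pts, sc$photophysics)
  surf <- build_gradient(smooth_profiles(tab), mode = "ip")
  f <- withr::local_tempfile(fileext = ".csv")
  write_gradient(surf, f)
  back <- read_gradient(f)
  expect_equal(back$rate_mhz, surf$rate_mhz, tolerance = 1e-9)
  expect_equal(back$position_n, surf$position_n)
})
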
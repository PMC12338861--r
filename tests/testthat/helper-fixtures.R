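# shared fixtures: everything is generated in code, nothing on disk

# channels that reproduce a given r exactly with G-factor g
chan <- function(r, g = 1, scale = 1000) {
  channels_from_anisotropy(r, intensity_scale = scale, g_factor = g)
}

# independent oracle for the anisotropy: standard G-factor form
oracle_anisotropy <- function(i_vv, i_vh, i_hv, i_hh) {
  g <- i_hv / i_hh
  (i_vv - g * i_vh) / (i_vv + 2 * g * i_vh)
}

# independent oracle for the planar-rotor r: solve the slow-rotation
# relation r_o/r = 1 + 6 tau [R_ip (2c-1) + R_op c] / (3c-1), c = cos^2(alpha),
# directly, without going through X/Y (rates in MHz, tau in ns)
oracle_r_from_rates <- function(r_op_mhz, r_ip_mhz, r_o, tau_f_ns) {
  cc <- (5 * r_o + 1) / 3
  ratio <- 1 + 6 * tau_f_ns *
    ((r_ip_mhz / 1000) * (2 * cc - 1) + (r_op_mhz / 1000) * cc) / (3 * cc - 1)
  r_o / ratio
}

# two-anchor photophysics table for interpolation tests
tiny_phot <- function() {
  photophysics_table(data.frame(
    probe_id = "2-AS",
    temperature_c = c(37, 47, 37, 47),
    excitation_nm = c(381, 381, 319, 319),
    tau_f_ns = c(8, 6, 8, 6),
    r_o = c(0.30, 0.28, -0.08, -0.09)))
}

# anisotropy points at one temperature for a known (R_op, R_ip) truth,
# optionally with per-channel multiplicative noise
truth_points <- function(r_op_mhz, r_ip_mhz, phot, probe = "2-AS",
                         temperature_c = 37,
                         wavelengths = c(319, 333, 347, 367, 381),
                         n_per_wl = 1, sigma_rel = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- rep(seq_along(wavelengths), each = n_per_wl)
  ph <- lapply(wavelengths, function(w)
    get_photophysics(phot, probe, w, temperature_c))
  r <- vapply(seq_along(wavelengths), function(i)
    anisotropy_from_truth(r_op_mhz, r_ip_mhz, ph[[i]]$r_o, ph[[i]]$tau_f_ns), 0)
  ch <- chan(r[idx])
  if (sigma_rel > 0)
    for (cn in names(ch))
      ch[[cn]] <- ch[[cn]] * (1 + stats::rnorm(length(idx), 0, sigma_rel))
  ch$excitation_nm <- wavelengths[idx]
  ch$temperature_c <- temperature_c
  ch$probe_id <- probe
  batch_anisotropy(ch, warn_flags = FALSE)
}
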
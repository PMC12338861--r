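#' Arrhenius-type rotational rate law
#'
#' Ground-truth rate surfaces in the simulator follow
#' \eqn{R(T) = R_{37} \exp[-E_a/R_{gas} (1/T_K - 1/310.15)]}: an Arrhenius
#' temperature dependence anchored at 37 degC.  Temperatures are degC
#' everywhere in the package; Kelvin conversion happens only here.
#'
#' @param temperature_c temperature (degC).
#' @param rate37_mhz rate at 37 degC (MHz).
#' @param ea_kj_mol apparent activation energy (kJ/mol).
#' @return rate in MHz.
#' @export
arrhenius_rate <- function(temperature_c, rate37_mhz, ea_kj_mol) {
  tk <- temperature_c + 273.15
  rate37_mhz * exp(-(ea_kj_mol * 1000 / 8.314462618) * (1 / tk - 1 / 310.15))
}

#' Construct a synthetic-instrument scenario
#'
#' A scenario bundles everything needed to forward-simulate the
#' spectrofluorometer experiment: per-probe ground-truth Arrhenius
#' parameters for R_op(T) and R_ip(T), an optional temperature-dependent
#' fold modifier (for inhibitor scenarios), a photophysics table, the
#' instrument calibration factor, the noise model and the ramp protocol.
#' All numeric truth parameters are SYNTHETIC: chosen so that rates at
#' 37 degC fall in the 10-90 MHz range typical of anthroyloxy probes in
#' membranes, not literature values.
#'
#' @param condition_id label for the membrane condition.
#' @param probes data frame with columns `probe_id`, `r_op37_mhz`,
#'   `r_ip37_mhz`, `ea_op_kj_mol`, `ea_ip_kj_mol`.
#' @param fold numeric length-4 vector `c(f_lo, f_hi, t_lo, t_hi)` or
#'   `NULL`; when set, both rates are multiplied by a fold factor ramping
#'   linearly from `f_lo` at `t_lo` degC to `f_hi` at `t_hi` degC (clamped
#'   outside).
#' @param photophysics a [photophysics_table()] (default
#'   [default_photophysics()]).
#' @param g_factor instrument calibration factor R_h; scalar or named
#'   vector by wavelength (default 1).
#' @param intensity_scale total intensity scale in arbitrary units.
#' @param sigma_rel relative (multiplicative Gaussian) noise per channel
#'   (default 0.01); `noise = "poisson"` instead draws photon counts with
#'   mean `channel * intensity_scale`.
#' @param noise `"gaussian"` (default) or `"poisson"`.
#' @param temp_jitter_c thermistor noise sd on the recorded temperature
#'   (default 0.02 degC, the stated sensor accuracy).
#' @param ramp_rate_c_per_h,t_start_c,t_end_c thermal ramp protocol
#'   (defaults 12 degC/h, 10 -> 52 degC).
#' @param duration_s run duration override; required when
#'   `t_start_c == t_end_c` (isothermal run), otherwise derived from the
#'   ramp.
#' @param wavelengths excitation wavelength cycle (nm).
#' @param cadence_s length-2 range from which a run's measurement cadence
#'   is drawn uniformly (default `c(72, 122)` s, reproducing 98-180
#'   measurements per run with median near 130), or a single fixed value.
#' @param acquisition `"alternating"` (one wavelength per time point,
#'   cycled; the instrument protocol) or `"simultaneous"` (all wavelengths
#'   at each time point; useful for exact-recovery testing).
#' @param membrane_like assert R_ip(T) >= R_op(T) for all probes across
#'   the ramp (default TRUE).
#' @return object of class `synthetic_scenario`.
#' @export
make_scenario <- function(condition_id, probes, fold = NULL,
                          photophysics = default_photophysics(),
                          g_factor = 1.0, intensity_scale = 1000,
                          sigma_rel = 0.01,
                          noise = c("gaussian", "poisson"),
                          temp_jitter_c = 0.02,
                          ramp_rate_c_per_h = 12, t_start_c = 10,
                          t_end_c = 52, duration_s = NULL,
                          wavelengths = c(319, 333, 347, 367, 381),
                          cadence_s = c(72, 122),
                          acquisition = c("alternating", "simultaneous"),
                          membrane_like = TRUE) {
  noise <- match.arg(noise)
  acquisition <- match.arg(acquisition)
  probes <- as.data.frame(probes, stringsAsFactors = FALSE)
  need <- c("probe_id", "r_op37_mhz", "r_ip37_mhz",
            "ea_op_kj_mol", "ea_ip_kj_mol")
  miss <- setdiff(need, names(probes))
  if (length(miss))
    stop("scenario probes table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.null(fold)) {
    if (length(fold) != 4L || fold[4L] <= fold[3L])
      stop("fold must be c(f_lo, f_hi, t_lo, t_hi) with t_hi > t_lo")
  }
  if (t_end_c < t_start_c) stop("t_end_c must be >= t_start_c")
  if (t_end_c == t_start_c && is.null(duration_s))
    stop("isothermal scenario needs duration_s")
  sc <- structure(list(
    condition_id = condition_id, probes = probes, fold = fold,
    photophysics = photophysics, g_factor = g_factor,
    intensity_scale = intensity_scale, sigma_rel = sigma_rel,
    noise = noise, temp_jitter_c = temp_jitter_c,
    ramp_rate_c_per_h = ramp_rate_c_per_h,
    t_start_c = t_start_c, t_end_c = t_end_c, duration_s = duration_s,
    wavelengths = wavelengths, cadence_s = cadence_s,
    acquisition = acquisition, membrane_like = membrane_like),
    class = "synthetic_scenario")
  tg <- seq(t_start_c, max(t_end_c, t_start_c + 1), length.out = 9)
  for (p in probes$probe_id) {
    tr <- truth_rates(sc, p, tg)
    if (membrane_like && any(tr$r_ip_mhz < tr$r_op_mhz - 1e-9))
      stop("scenario-validation error: R_ip(T) < R_op(T) for probe ", p,
           " in a membrane-like scenario")
    # the implied anisotropy must be physical at every wavelength: for
    # 0 < r_o < 0.1 (X < 0) this requires R_op(T) >= |X| R_ip(T)
    for (wl in wavelengths) {
      ph <- get_photophysics(photophysics, p, wl, tg)
      tryCatch(anisotropy_from_truth(tr$r_op_mhz, tr$r_ip_mhz,
                                     ph$r_o, ph$tau_f_ns),
               error = function(e)
                 stop("scenario-validation error for probe ", p, " at ",
                      wl, " nm: ", conditionMessage(e), call. = FALSE))
    }
  }
  sc
}

#' Ground-truth rates of a scenario
#'
#' @param scenario a `synthetic_scenario`.
#' @param probe_id probe label.
#' @param temperature_c temperatures (degC), vectorised.
#' @return list with `r_op_mhz` and `r_ip_mhz`.
#' @export
truth_rates <- function(scenario, probe_id, temperature_c) {
  row <- scenario$probes[scenario$probes$probe_id == probe_id, , drop = FALSE]
  if (nrow(row) != 1L) stop("unknown probe in scenario: ", probe_id)
  f <- 1
  if (!is.null(scenario$fold)) {
    fp <- scenario$fold
    s <- pmin(pmax((temperature_c - fp[3L]) / (fp[4L] - fp[3L]), 0), 1)
    f <- fp[1L] + (fp[2L] - fp[1L]) * s
  }
  list(r_op_mhz = f * arrhenius_rate(temperature_c, row$r_op37_mhz, row$ea_op_kj_mol),
       r_ip_mhz = f * arrhenius_rate(temperature_c, row$r_ip37_mhz, row$ea_ip_kj_mol))
}

#' Steady-state anisotropy implied by ground-truth rotational rates
#'
#' Inverts the planar-rotor line: \eqn{X = (10 r_o - 1)/(5 r_o + 1)},
#' \eqn{Y = R_{ip} X + R_{op}} (1/ns), then
#' \eqn{r = r_o / [1 + 2 \tau_F (5 r_o + 1) Y / (5 r_o)]}.
#'
#' @param r_op_mhz,r_ip_mhz ground-truth rates (MHz).
#' @param r_o zero-time anisotropy (not -0.2).
#' @param tau_f_ns lifetime (ns).
#' @return anisotropy r; errors if parameters imply a value outside the
#'   physical range (same sign as r_o, `|r| <= |r_o|`, within (-0.2, 0.4)).
#' @export
anisotropy_from_truth <- function(r_op_mhz, r_ip_mhz, r_o, tau_f_ns) {
  if (any(abs(5 * r_o + 1) < 1e-12))
    stop("r_o = -0.2 is singular")
  x <- (10 * r_o - 1) / (5 * r_o + 1)
  y <- (r_ip_mhz * x + r_op_mhz) / 1000  # 1/ns
  denom <- 1 + 2 * tau_f_ns * (5 * r_o + 1) * y / (5 * r_o)
  if (any(denom <= 0))
    stop("scenario-validation error: implied anisotropy leaves (0, r_o]")
  r <- r_o / denom
  bad <- sign(r) != sign(r_o) | abs(r) > abs(r_o) + 1e-12 |
    r <= -0.2 | r >= 0.4
  if (any(bad))
    stop("scenario-validation error: implied anisotropy leaves the physical range")
  r
}

#' Polarized intensity channels realizing a target anisotropy
#'
#' Emits channels with \eqn{I_{vv}/I_{vh} = g (1 + 2r)/(1 - r)} and
#' \eqn{I_{hv}/I_{hh} = g}, so that [compute_anisotropy()] recovers r
#' exactly in the noiseless case for any calibration factor g.
#'
#' @param r target anisotropy, in the open interval (-0.2, 0.4).
#' @param intensity_scale arbitrary intensity unit (sets `i_vh`).
#' @param g_factor instrument calibration factor (> 0).
#' @return data frame with columns `i_vv`, `i_vh`, `i_hv`, `i_hh`.
#' @export
channels_from_anisotropy <- function(r, intensity_scale = 1000, g_factor = 1) {
  if (any(r <= -0.2 | r >= 0.4))
    stop("r must lie in the open interval (-0.2, 0.4)")
  if (any(g_factor <= 0)) stop("g_factor must be > 0")
  data.frame(i_vv = intensity_scale * g_factor * (1 + 2 * r) / (1 - r),
             i_vh = rep_len(intensity_scale, length(r)),
             i_hv = rep_len(intensity_scale * g_factor, length(r)),
             i_hh = rep_len(intensity_scale + 0 * r, length(r)))
}

#' Simulate one heating-curve run
#'
#' Forward model of the experiment: along the thermal ramp the excitation
#' wavelength cycles through the configured set; at each measurement the
#' ground-truth rates at the actual cuvette temperature are converted to a
#' true anisotropy via the scenario photophysics, realized as four
#' polarized channels, and perturbed by the noise model.  The recorded
#' temperature carries thermistor jitter; the underlying ramp does not.
#' Output is fully determined by `seed`.
#'
#' @param scenario a `synthetic_scenario`.
#' @param probe_id probe to simulate.
#' @param replicate_id run label.
#' @param seed integer RNG seed for this run.
#' @return readings data frame in the [read_readings()] dialect.
#' @export
simulate_run <- function(scenario, probe_id, replicate_id = "rep1", seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  dur <- scenario$duration_s
  if (is.null(dur))
    dur <- (scenario$t_end_c - scenario$t_start_c) /
      scenario$ramp_rate_c_per_h * 3600
  cad <- scenario$cadence_s
  cadence <- if (length(cad) == 2L) stats::runif(1, cad[1L], cad[2L]) else cad[1L]
  times <- seq(0, dur, by = cadence)
  n <- length(times)
  wls <- scenario$wavelengths
  if (scenario$acquisition == "alternating") {
    wl <- wls[(seq_len(n) - 1L) %% length(wls) + 1L]
  } else {
    times <- rep(times, each = length(wls))
    wl <- rep(wls, n)
    n <- length(times)
  }
  t_actual <- scenario$t_start_c + scenario$ramp_rate_c_per_h * times / 3600
  t_actual <- pmin(t_actual, scenario$t_end_c)
  t_rec <- t_actual + stats::rnorm(n, 0, scenario$temp_jitter_c)
  g <- scenario$g_factor
  gvec <- if (length(g) > 1L) {
    if (is.null(names(g))) stop("wavelength-dependent g_factor must be named")
    unname(g[as.character(wl)])
  } else rep_len(g, n)
  rr <- truth_rates(scenario, probe_id, t_actual)
  ph <- vapply(seq_len(n), function(i) {
    p <- get_photophysics(scenario$photophysics, probe_id, wl[i], t_actual[i])
    c(p$tau_f_ns, p$r_o)
  }, c(0, 0))
  r_true <- anisotropy_from_truth(rr$r_op_mhz, rr$r_ip_mhz,
                                  r_o = ph[2L, ], tau_f_ns = ph[1L, ])
  ch <- channels_from_anisotropy(r_true, scenario$intensity_scale, gvec)
  if (scenario$noise == "gaussian" && scenario$sigma_rel > 0) {
    for (col in names(ch))
      ch[[col]] <- ch[[col]] * pmax(1 + stats::rnorm(n, 0, scenario$sigma_rel),
                                    .Machine$double.eps)
  } else if (scenario$noise == "poisson") {
    for (col in names(ch))
      ch[[col]] <- pmax(stats::rpois(n, ch[[col]]), 1)
  }
  data.frame(time_s = times, temperature_c = t_rec, excitation_nm = wl,
             ch, probe_id = probe_id,
             condition_id = scenario$condition_id,
             replicate_id = replicate_id, stringsAsFactors = FALSE)
}

#' Simulate and write a full study
#'
#' One run per (scenario, probe, replicate) combination, written as the
#' standard readings CSV, plus a JSON manifest recording the per-run seeds
#' and all ground-truth parameters (so truth can be compared with pipeline
#' output later).
#'
#' @param scenarios list of `synthetic_scenario` objects (one per
#'   condition).
#' @param out_dir output directory (created if needed).
#' @param replicates replicate runs per probe (default 3).
#' @param seed base seed; the run at index i uses `seed * 1000 + i`.
#' @return path to the manifest (invisibly); the manifest lists all files.
#' @export
make_study <- function(scenarios, out_dir, replicates = 3, seed = 1L) {
  if (inherits(scenarios, "synthetic_scenario")) scenarios <- list(scenarios)
  if (length(scenarios) < 1L) stop("need at least one scenario")
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  runs <- list(); i <- 0L
  for (sc in scenarios) {
    for (p in sc$probes$probe_id) {
      for (rep_k in seq_len(replicates)) {
        i <- i + 1L
        run_seed <- as.integer(seed) * 1000L + i
        rep_id <- paste0("rep", rep_k)
        df <- simulate_run(sc, p, rep_id, seed = run_seed)
        fname <- sprintf("%s_%s_%s.csv",
                         gsub("[^A-Za-z0-9_-]", "-", sc$condition_id),
                         gsub("[^A-Za-z0-9_-]", "-", p), rep_id)
        path <- file.path(out_dir, fname)
        write_readings(df, path)
        runs[[i]] <- list(file = fname, condition_id = sc$condition_id,
                          probe_id = p, replicate_id = rep_id,
                          seed = run_seed, n_readings = nrow(df))
      }
    }
  }
  manifest <- list(
    seed = as.integer(seed), replicates = replicates,
    conditions = lapply(scenarios, function(sc) list(
      condition_id = sc$condition_id,
      truth = sc$probes, fold = sc$fold,
      sigma_rel = sc$sigma_rel, noise = sc$noise,
      g_factor = sc$g_factor,
      ramp = list(rate_c_per_h = sc$ramp_rate_c_per_h,
                  t_start_c = sc$t_start_c, t_end_c = sc$t_end_c),
      wavelengths = sc$wavelengths, cadence_s = sc$cadence_s,
      acquisition = sc$acquisition)),
    runs = runs)
  mpath <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(mpath)
}

# ---- built-in membrane scenarios -------------------------------------------

#' Built-in synthetic membrane scenarios
#'
#' Two CHO-plasma-membrane-like conditions and a DPPC-vesicle-like control.
#' `scenario_sensitive()` ("AuxB1-like") has a steep transversal gradient of
#' the out-of-plane rate: maxima at the interface probe (n = 2) and the
#' bilayer-centre probe (n = 16) and a pronounced minimum at n = 7-9 (the
#' microviscosity barrier).  `scenario_resistant()` ("B30-like") flattens
#' that out-of-plane gradient (lower at n = 2, higher at n = 7, 9, 16) while
#' the in-plane profile matches except at n = 16, where it is about twofold
#' lower; cell-wise differences stay within twofold.
#' `scenario_verapamil()` multiplies a resistant-like condition by a fold
#' factor rising linearly from 1.2 at 10 degC to 2.4 at 40 degC and above.
#' `scenario_dppc()` is isotropic (R_op = R_ip), the behaviour of the
#' probes in homogeneous lipid vesicles.  All parameter values are
#' synthetic, chosen for 37 degC rates in the 10-90 MHz range.
#'
#' @param condition_id condition label.
#' @param ... passed on to [make_scenario()] (noise, ramp, ... overrides).
#' @return a `synthetic_scenario`.
#' @name builtin_scenarios
NULL

.probes_sensitive <- function() data.frame(
  probe_id = c("2-AS", "7-AS", "9-AS", "12-AS", "16-AP"),
  r_op37_mhz = c(30, 12, 10, 14, 40),
  r_ip37_mhz = c(36, 16, 14, 18, 80),
  ea_op_kj_mol = 25, ea_ip_kj_mol = 22,
  stringsAsFactors = FALSE)

.probes_resistant <- function() data.frame(
  probe_id = c("2-AS", "7-AS", "9-AS", "12-AS", "16-AP"),
  r_op37_mhz = c(24, 17, 16, 15, 44),
  r_ip37_mhz = c(35, 19, 18, 19, 50),
  ea_op_kj_mol = 25, ea_ip_kj_mol = 22,
  stringsAsFactors = FALSE)

#' @rdname builtin_scenarios
#' @export
scenario_sensitive <- function(condition_id = "sensitive", ...)
  make_scenario(condition_id, .probes_sensitive(), ...)

#' @rdname builtin_scenarios
#' @export
scenario_resistant <- function(condition_id = "resistant", ...)
  make_scenario(condition_id, .probes_resistant(), ...)

#' @rdname builtin_scenarios
#' @export
scenario_verapamil <- function(condition_id = "resistant+verapamil", ...)
  make_scenario(condition_id, .probes_resistant(),
                fold = c(1.2, 2.4, 10, 40), ...)

#' @rdname builtin_scenarios
#' @export
scenario_dppc <- function(condition_id = "dppc", ...) {
  pr <- data.frame(
    probe_id = c("2-AS", "9-AS", "16-AP"),
    r_op37_mhz = c(29.1, 31.5, 40.6),
    r_ip37_mhz = c(31.2, 30.8, 39.5),
    ea_op_kj_mol = 25, ea_ip_kj_mol = 25,
    stringsAsFactors = FALSE)
  make_scenario(condition_id, pr, membrane_like = FALSE, ...)
}

#' Serialize / load a scenario as JSON
#'
#' The photophysics table is embedded in the JSON.  Round-trips all fields
#' losslessly up to JSON number formatting.
#'
#' @param scenario a `synthetic_scenario`.
#' @param path JSON file path.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  x$photophysics <- as.data.frame(x$photophysics)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("condition_id", "probes", "photophysics")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("invalid scenario file: missing field(s) ", paste(miss, collapse = ", "))
  make_scenario(condition_id = x$condition_id,
                probes = as.data.frame(x$probes),
                fold = if (is.null(x$fold) || !length(x$fold)) NULL else as.numeric(x$fold),
                photophysics = photophysics_table(as.data.frame(x$photophysics)),
                g_factor = if (!is.null(x$g_factor)) unlist(x$g_factor) else 1,
                intensity_scale = x$intensity_scale %||% 1000,
                sigma_rel = x$sigma_rel %||% 0.01,
                noise = x$noise %||% "gaussian",
                temp_jitter_c = x$temp_jitter_c %||% 0.02,
                ramp_rate_c_per_h = x$ramp_rate_c_per_h %||% 12,
                t_start_c = x$t_start_c %||% 10,
                t_end_c = x$t_end_c %||% 52,
                duration_s = x$duration_s,
                wavelengths = x$wavelengths %||% c(319, 333, 347, 367, 381),
                cadence_s = x$cadence_s %||% c(72, 122),
                acquisition = x$acquisition %||% "alternating",
                membrane_like = x$membrane_like %||% TRUE)
}
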
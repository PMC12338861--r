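#' Squared cosine of the absorption/emission transition dipole angle
#'
#' The fundamental anisotropy of an immobile fluorophore is
#' \eqn{r_o = (3\cos^2\alpha - 1)/5}, where \eqn{\alpha} is the angle
#' between the absorption and emission transition dipole moments.
#' Inverting gives \eqn{\cos^2\alpha = (5 r_o + 1)/3}, the substitution
#' that linearises the planar-rotor anisotropy relation.
#'
#' @param r_o zero-time anisotropy, in \eqn{[-0.2, 0.4]}.
#' @return \eqn{\cos^2\alpha} in \eqn{[0, 1]}.
#' @export
#' @examples
#' cos_sq_alpha(0.4)   # collinear oscillators -> 1
#' cos_sq_alpha(-0.2)  # perpendicular -> 0
cos_sq_alpha <- function(r_o) {
  bad <- !is.finite(r_o) | r_o < -0.2 | r_o > 0.4
  if (any(bad))
    stop("domain error: r_o must lie in [-0.2, 0.4]; cos^2(alpha) would leave [0, 1]")
  (5 * r_o + 1) / 3
}

#' Transform an anisotropy measurement to planar-rotor (X, Y) coordinates
#'
#' For a planar fluorophore rotating slowly relative to its excited-state
#' lifetime, the steady-state anisotropy r at a wavelength with zero-time
#' anisotropy r_o and lifetime \eqn{\tau_F} satisfies the linear relation
#' \deqn{Y = R_{ip} X + R_{op}}
#' with
#' \deqn{Y = \frac{5 r_o (r_o/r - 1)}{2 \tau_F (5 r_o + 1)}, \qquad
#'       X = \frac{10 r_o - 1}{5 r_o + 1}.}
#' Varying the excitation wavelength varies r_o and hence X, so a
#' multi-wavelength series traces a straight line whose intercept is the
#' out-of-plane rotation rate \eqn{R_{op}} and whose slope is the in-plane
#' rate \eqn{R_{ip}}.  Y carries units 1/ns; rates are converted to MHz
#' (\eqn{\times 1000}) at fitting/reporting time.
#'
#' @param r measured steady-state anisotropy (nonzero, same sign as `r_o`).
#' @param r_o zero-time anisotropy (in \eqn{(-0.2, 0.4]}; the value -0.2
#'   makes the denominator vanish).
#' @param tau_f_ns excited-state lifetime in ns (> 0).
#' @return data frame with columns `x`, `y` (1/ns) and the source `r`,
#'   `r_o`, `tau_f_ns` recorded for diagnostics.  Vectorised.
#' @export
weber_transform <- function(r, r_o, tau_f_ns) {
  n <- max(length(r), length(r_o), length(tau_f_ns))
  r <- rep_len(r, n); r_o <- rep_len(r_o, n); tau_f_ns <- rep_len(tau_f_ns, n)
  if (any(!is.finite(tau_f_ns) | tau_f_ns <= 0))
    stop("tau_f_ns must be positive and finite")
  if (any(r == 0))
    stop("singularity error: r = 0 (anisotropy fully depolarized; r_o/r undefined)")
  if (any(abs(5 * r_o + 1) < .Machine$double.eps * 10))
    stop("singularity error: r_o = -0.2 makes 5*r_o + 1 vanish")
  cos_sq_alpha(r_o)  # domain check on r_o
  if (any(sign(r) != sign(r_o)))
    stop("r and r_o must have the same sign for a physically meaningful ratio")
  x <- (10 * r_o - 1) / (5 * r_o + 1)
  y <- 5 * r_o * (r_o / r - 1) / (2 * tau_f_ns * (5 * r_o + 1))
  data.frame(x = x, y = y, r = r, r_o = r_o, tau_f_ns = tau_f_ns)
}

#' Fit rotational rates by weighted linear regression
#'
#' Weighted least squares of Y on X across the wavelength set.  The slope
#' is the in-plane rate \eqn{R_{ip}}, the intercept the out-of-plane rate
#' \eqn{R_{op}}; both are reported in MHz.  95\% confidence half-widths use
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param points data frame with columns `x`, `y` (1/ns) and optionally
#'   `weight` (nonnegative); as produced by [weber_transform()].
#' @param weights optional numeric vector overriding `points$weight`.
#' @return an object of class `rot_decomposition`: list with `r_op_mhz`,
#'   `r_ip_mhz`, `ci95_op`, `ci95_ip` (half-widths, MHz), `phi_op_ns`,
#'   `phi_ip_ns`, `n_points`, `r_squared`, `residuals`,
#'   `extrapolation_flag`, and any metadata set by callers.
#' @export
fit_rotation_rates <- function(points, weights = NULL) {
  if (is.null(weights)) weights <- points$weight
  x <- points$x; y <- points$y
  if (length(x) < 2L)
    stop("insufficient-data error: need at least 2 points")
  if (!is.null(weights)) {
    if (any(!is.finite(weights) | weights < 0))
      stop("validation error: weights must be nonnegative and finite")
    if (all(weights == 0)) weights <- NULL
  }
  if (length(unique(x)) < 2L)
    stop("rank-deficiency error: all X values identical; slope not estimable")
  fit <- if (is.null(weights)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = weights)
  co <- stats::coef(fit)
  n <- length(x)
  # suppress lm's "essentially perfect fit" chatter on noiseless data
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  tq <- if (n > 2L) stats::qt(0.975, df = n - 2L) else NA_real_
  ci <- if (n > 2L) tq * se else c(0, 0)
  res <- stats::residuals(fit)
  w <- if (is.null(weights)) rep(1, n) else weights
  ybar <- sum(w * y) / sum(w)
  tss <- sum(w * (y - ybar)^2)
  r2 <- if (tss > 0) 1 - sum(w * res^2) / tss else NA_real_
  r_op <- unname(co[1L]) * 1000
  r_ip <- unname(co[2L]) * 1000
  structure(list(
    r_op_mhz = r_op, r_ip_mhz = r_ip,
    ci95_op = unname(ci[1L]) * 1000, ci95_ip = unname(ci[2L]) * 1000,
    phi_op_ns = if (r_op > 0) correlation_time(r_op) else NA_real_,
    phi_ip_ns = if (r_ip > 0) correlation_time(r_ip) else NA_real_,
    n_points = n, r_squared = r2, residuals = res,
    extrapolation_flag = FALSE), class = "rot_decomposition")
}

#' @export
print.rot_decomposition <- function(x, ...) {
  cat(sprintf("Planar-rotor decomposition (%d points, R^2 = %.4f)\n",
              x$n_points, x$r_squared))
  cat(sprintf("  R_op = %.1f +/- %.1f MHz  (phi_op = %.1f ns)\n",
              x$r_op_mhz, x$ci95_op, x$phi_op_ns))
  cat(sprintf("  R_ip = %.1f +/- %.1f MHz  (phi_ip = %.1f ns)\n",
              x$r_ip_mhz, x$ci95_ip, x$phi_ip_ns))
  if (isTRUE(x$extrapolation_flag))
    cat("  [photophysics extrapolated beyond anchor temperatures]\n")
  invisible(x)
}

#' Rotational correlation time from a rotational rate
#'
#' \eqn{\phi = 1/(6R)}; with R in MHz the result is
#' \eqn{10^3/(6 R_{MHz})} ns.  Rounding to one decimal happens only in
#' printed reports, never here.
#'
#' @param rate_mhz rotational rate in MHz (> 0).
#' @return correlation time in ns.
#' @export
#' @examples
#' round(correlation_time(29.1), 1)  # 5.7 ns
correlation_time <- function(rate_mhz) {
  if (any(!is.finite(rate_mhz) | rate_mhz <= 0))
    stop("domain error: rate must be > 0")
  1000 / (6 * rate_mhz)
}

#' Decompose a multi-wavelength anisotropy set at one temperature
#'
#' Composes the photophysics lookup, the planar-rotor transform and the
#' weighted regression for a set of anisotropy points measured at (nearly)
#' one temperature across several excitation wavelengths.  With
#' `weighting = "ivar"`, each point receives an inverse-variance weight with
#' Var(Y) propagated from the replicate scatter of r at its wavelength by
#' the delta method (\eqn{dY/dr = -5 r_o^2/(2\tau_F(5r_o+1) r^2)}); when a
#' wavelength has fewer than two readings the fit falls back to unweighted.
#'
#' @param points data frame of anisotropy points: columns `r`,
#'   `excitation_nm`, `temperature_c`, plus optional `probe_id`,
#'   `condition_id`, `flag_range`.  All rows must share one probe.
#' @param photophysics a [photophysics_table()].
#' @param weighting `"ivar"` (default) or `"none"`.
#' @param r_o_temperature passed to [get_photophysics()].
#' @param drop_flagged exclude rows with `flag_range = TRUE` (default TRUE).
#' @return a `rot_decomposition` (see [fit_rotation_rates()]) with
#'   `temperature_c`, `probe_id`, `condition_id` and
#'   `extrapolation_flag` filled in.
#' @export
decompose_wavelength_set <- function(points, photophysics,
                                     weighting = c("ivar", "none"),
                                     r_o_temperature = c("interpolate", "fixed"),
                                     drop_flagged = TRUE) {
  weighting <- match.arg(weighting)
  r_o_temperature <- match.arg(r_o_temperature)
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  if (drop_flagged && "flag_range" %in% names(points))
    points <- points[!points$flag_range, , drop = FALSE]
  probe <- unique(points$probe_id)
  if (length(probe) > 1L)
    stop("decompose_wavelength_set() expects a single probe; got: ",
         paste(probe, collapse = ", "))
  if (length(probe) == 0L) probe <- NA_character_
  if (nrow(points) < 2L || length(unique(points$excitation_nm)) < 2L)
    stop("insufficient-data error: need anisotropy at >= 2 wavelengths")
  if (weighting == "ivar") {
    # Collapse to per-wavelength mean anisotropies before the (nonlinear,
    # 1/r) transform: averaging r first shrinks the Jensen bias of r_o/r by
    # the per-wavelength count and removes near-singular individual points
    # at wavelengths where r is small.  Each wavelength then contributes one
    # regression point, weighted by the delta-method variance
    # Var(Y) = (dY/dr)^2 sigma_r^2 / n_w, dY/dr = -5 r_o^2/(2 tau (5r_o+1) r^2),
    # under homoscedastic anisotropy noise (sigma_r is nearly wavelength-
    # independent because every channel carries the same relative noise, and
    # it then cancels from the relative weights).  Deliberately NOT the
    # per-wavelength sample variances: with the ~2-5 readings a window
    # holds per wavelength those are so noisy that they cost both
    # efficiency and CI calibration.  Evaluating dY/dr at the mean r keeps
    # the weights uncorrelated with the errors they weight.
    agg <- do.call(rbind, lapply(split(points, points$excitation_nm),
      function(g) data.frame(excitation_nm = g$excitation_nm[1L],
                             r = mean(g$r), var_r = stats::var(g$r),
                             n = nrow(g), temperature_c = mean(g$temperature_c))))
    tau <- ro <- numeric(nrow(agg)); ext <- logical(nrow(agg))
    for (i in seq_len(nrow(agg))) {
      phi <- get_photophysics(photophysics, probe, agg$excitation_nm[i],
                              agg$temperature_c[i], r_o_temperature)
      tau[i] <- phi$tau_f_ns; ro[i] <- phi$r_o; ext[i] <- phi$extrapolated
    }
    usable <- agg$r != 0 & sign(agg$r) == sign(ro)
    if (sum(usable) < 2L)
      stop("insufficient-data error: fewer than 2 wavelengths with usable mean anisotropy")
    agg <- agg[usable, , drop = FALSE]
    tau <- tau[usable]; ro <- ro[usable]; ext <- ext[usable]
    xy <- weber_transform(agg$r, ro, tau)
    dydr <- -5 * ro^2 / (2 * tau * (5 * ro + 1) * agg$r^2)
    weights <- agg$n / dydr^2
    weights <- weights / mean(weights)
    n_readings <- sum(agg$n)
  } else {
    usable <- points$r != 0
    tau <- ro <- numeric(nrow(points)); ext <- logical(nrow(points))
    for (i in seq_len(nrow(points))) {
      phi <- get_photophysics(photophysics, probe, points$excitation_nm[i],
                              points$temperature_c[i], r_o_temperature)
      tau[i] <- phi$tau_f_ns; ro[i] <- phi$r_o; ext[i] <- phi$extrapolated
    }
    usable <- points$r != 0 & sign(points$r) == sign(ro)
    if (sum(usable) < 2L ||
        length(unique(points$excitation_nm[usable])) < 2L)
      stop("insufficient-data error: fewer than 2 wavelengths with usable anisotropy")
    xy <- weber_transform(points$r[usable], ro[usable], tau[usable])
    ext <- ext[usable]
    weights <- NULL
    n_readings <- sum(usable)
  }
  dec <- fit_rotation_rates(xy, weights = weights)
  dec$n_readings <- n_readings
  dec$temperature_c <- mean(points$temperature_c)
  dec$probe_id <- probe
  dec$condition_id <- if ("condition_id" %in% names(points))
    unique(points$condition_id)[1L] else NA_character_
  dec$extrapolation_flag <- any(as.logical(ext))
  dec
}

#' Collect decompositions into the long reporting table
#'
#' @param decs list of `rot_decomposition` objects.
#' @return data frame with one row per decomposition: `probe_id`,
#'   `condition_id`, `temperature_c`, `r_op_mhz`, `ci95_op`, `r_ip_mhz`,
#'   `ci95_ip`, `phi_op_ns`, `phi_ip_ns`, `n_points`, `r_squared`,
#'   `extrapolation_flag`.
#' @export
decomposition_table <- function(decs) {
  if (inherits(decs, "rot_decomposition")) decs <- list(decs)
  out <- do.call(rbind, lapply(decs, function(d) {
    data.frame(probe_id = d$probe_id %||% NA_character_,
               condition_id = d$condition_id %||% NA_character_,
               temperature_c = d$temperature_c %||% NA_real_,
               r_op_mhz = d$r_op_mhz, ci95_op = d$ci95_op,
               r_ip_mhz = d$r_ip_mhz, ci95_ip = d$ci95_ip,
               phi_op_ns = d$phi_op_ns, phi_ip_ns = d$phi_ip_ns,
               n_points = d$n_points, r_squared = d$r_squared,
               extrapolation_flag = d$extrapolation_flag,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
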
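#' Bin a heating curve into temperature windows
#'
#' A heating curve is a time-ordered anisotropy recording for one probe
#' during a slow thermal ramp (default 12 degC/h from 10 to 52 degC) with
#' alternating excitation wavelengths.  Binning groups readings into
#' fixed-width temperature windows; each window is centred on the mean
#' temperature of its members.  Windows containing fewer than two distinct
#' wavelengths are flagged (they cannot support the two-parameter fit).
#'
#' @param points anisotropy points (see [batch_anisotropy()]) for one or
#'   more replicates of one (probe, condition); must have `temperature_c`
#'   and `excitation_nm`.
#' @param window_c window width in degC (default 2).
#' @param t_start_c lower edge of the first window (default
#'   `floor(min(temperature_c))`).
#' @return the input with added integer `window` and numeric
#'   `window_center_c` columns; attribute `"window_info"` is a data frame
#'   (window, center, n, n_wavelengths, flag_few_wavelengths).
#' @export
bin_heating_curve <- function(points, window_c = 2, t_start_c = NULL) {
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  if (nrow(points) == 0L) stop("empty heating curve")
  if (!is.numeric(window_c) || window_c <= 0) stop("window_c must be > 0")
  if (is.null(t_start_c)) t_start_c <- floor(min(points$temperature_c))
  idx <- floor((points$temperature_c - t_start_c) / window_c)
  points$window <- as.integer(idx - min(idx) + 1L)
  centers <- tapply(points$temperature_c, points$window, mean)
  points$window_center_c <- as.numeric(centers[as.character(points$window)])
  nwl <- tapply(points$excitation_nm, points$window,
                function(w) length(unique(w)))
  info <- data.frame(window = as.integer(names(centers)),
                     center_c = as.numeric(centers),
                     n = as.integer(table(points$window)),
                     n_wavelengths = as.integer(nwl),
                     flag_few_wavelengths = as.integer(nwl) < 2L)
  attr(points, "window_info") <- info
  points
}

#' Decompose a heating curve window by window
#'
#' Pools all replicates of one (probe, condition), bins by temperature and
#' runs [decompose_wavelength_set()] in every window with at least two
#' wavelengths.  This is the workhorse that turns continuous heating-curve
#' recordings into R_op(T) / R_ip(T) point estimates.
#'
#' @param points anisotropy points for one or more (probe, condition)
#'   groups; grouping is by `probe_id` and `condition_id`.
#' @param photophysics a [photophysics_table()].
#' @param window_c window width in degC.
#' @inheritParams decompose_wavelength_set
#' @return long decomposition table (see [decomposition_table()]), one row
#'   per (probe, condition, window).
#' @export
decompose_heating_curves <- function(points, photophysics, window_c = 2,
                                     weighting = c("ivar", "none"),
                                     r_o_temperature = c("interpolate", "fixed")) {
  weighting <- match.arg(weighting)
  r_o_temperature <- match.arg(r_o_temperature)
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  if (!"condition_id" %in% names(points)) points$condition_id <- "default"
  groups <- split(points, list(points$probe_id, points$condition_id),
                  drop = TRUE)
  decs <- list()
  for (g in groups) {
    b <- bin_heating_curve(g, window_c = window_c)
    for (w in split(b, b$window)) {
      if (length(unique(w$excitation_nm)) < 2L) next
      dec <- tryCatch(
        decompose_wavelength_set(w, photophysics, weighting = weighting,
                                 r_o_temperature = r_o_temperature),
        error = function(e) NULL)
      if (!is.null(dec)) decs[[length(decs) + 1L]] <- dec
    }
  }
  if (length(decs) == 0L) stop("no usable windows in heating curve data")
  decomposition_table(decs)
}

#' Smooth windowed decompositions into continuous rate profiles
#'
#' Local linear (kernel-weighted) regression of the windowed R_op and R_ip
#' estimates on temperature, pooled over replicates, per probe and
#' condition.  The tricube kernel has half-width `bandwidth_c` (degC);
#' local-linear fitting removes first-order bias so a smooth monotone truth
#' is reproduced accurately.  The profile is evaluable at any temperature
#' inside the data span.
#'
#' @param decompositions long decomposition table from
#'   [decompose_heating_curves()].
#' @param bandwidth_c kernel half-width in degC (default 5).
#' @param min_span_c minimum temperature span required (default 15).
#' @return object of class `rotation_profiles`: the decompositions plus
#'   bandwidth, with [predict_profiles()] for evaluation.
#' @export
smooth_profiles <- function(decompositions, bandwidth_c = 5, min_span_c = 15) {
  d <- as.data.frame(decompositions, stringsAsFactors = FALSE)
  if (nrow(d) < 3L)
    stop("need >= 3 windowed decompositions to smooth")
  span <- diff(range(d$temperature_c))
  if (span < min_span_c)
    stop(sprintf("temperature span %.1f degC too short (need >= %.0f)",
                 span, min_span_c))
  structure(list(data = d, bandwidth_c = bandwidth_c),
            class = "rotation_profiles")
}

# Gaussian-kernel local-linear smoother with optional per-point precision
# weights; bandwidth h is the kernel standard deviation (degC).  Local-linear
# fitting removes first-order bias, so for the smooth near-exponential rate
# profiles only the small curvature term survives.  Returns estimate and
# standard error at each evaluation point.
.locfit <- function(t_obs, y, t_eval, h, prec = NULL) {
  if (is.null(prec) || !any(is.finite(prec) & prec > 0)) {
    prec <- rep(1, length(t_obs))
  } else {
    prec <- prec / stats::median(prec[is.finite(prec) & prec > 0])
    prec[!is.finite(prec) | prec <= 0] <- 1
  }
  est <- se <- dof <- rep(NA_real_, length(t_eval))
  lo <- min(t_obs); hi <- max(t_obs)
  for (k in seq_along(t_eval)) {
    # near the data boundary the one-sided local-linear estimate is
    # variance-inflated, so the kernel is widened there; the regression
    # runs on the inverse absolute temperature (the Arrhenius coordinate),
    # where log-rate profiles are close to straight lines, so the wider
    # one-sided kernel costs almost no smoothing bias
    edge <- t_eval[k] - lo < h || hi - t_eval[k] < h
    hh <- if (edge) 2 * h else h
    w <- exp(-0.5 * ((t_obs - t_eval[k]) / hh)^2) * prec
    use <- w > max(w) * 1e-6
    if (sum(use) < 2L || length(unique(t_obs[use])) < 2L) next
    wi <- w[use]; yi <- y[use]
    ti <- 1 / (t_obs[use] + 273.15) - 1 / (t_eval[k] + 273.15)
    X <- cbind(1, ti)
    XtW <- t(X * wi)
    B <- tryCatch(solve(XtW %*% X), error = function(e) NULL)
    if (is.null(B)) next
    beta <- B %*% (XtW %*% yi)
    resid <- yi - X %*% beta
    # kernel weights are smoothing weights, not precisions: the residuals
    # are (approximately) homoscedastic, so the estimator variance needs
    # the sandwich form  sigma^2 B X'W^2X B , not lm's  sigma^2 B
    p <- ncol(X)
    neff <- sum(wi)^2 / sum(wi^2)
    sigma2 <- sum(wi * resid^2) / sum(wi) * neff / max(neff - p, 0.5)
    V <- B %*% (t(X * wi^2) %*% X) %*% B
    est[k] <- beta[1L]
    se[k] <- sqrt(sigma2 * V[1L, 1L])
    dof[k] <- max(neff - p, 1)
  }
  list(estimate = est, se = se, df = dof)
}

#' Evaluate smoothed rate profiles
#'
#' @param profiles a `rotation_profiles` object from [smooth_profiles()].
#' @param temperatures temperatures (degC) at which to evaluate.
#' @param mode `"op"`, `"ip"`, or both (default).
#' @return data frame: `probe_id`, `condition_id`, `mode`,
#'   `temperature_c`, `rate_mhz`, `ci95` (t-based half-width),
#'   `extrapolation_flag` (photophysics extrapolation seen in any window
#'   inside the kernel support).
#' @export
predict_profiles <- function(profiles, temperatures,
                             mode = c("op", "ip")) {
  stopifnot(inherits(profiles, "rotation_profiles"))
  mode <- match.arg(mode, several.ok = TRUE)
  d <- profiles$data
  h <- profiles$bandwidth_c
  out <- list()
  for (g in split(d, list(d$probe_id, d$condition_id), drop = TRUE)) {
    for (m in mode) {
      y <- if (m == "op") g$r_op_mhz else g$r_ip_mhz
      ci <- if (m == "op") g$ci95_op else g$ci95_ip
      # Rates are positive with roughly multiplicative (Arrhenius-type)
      # temperature dependence and multiplicative window noise, so the
      # smoothing is done on the log scale, where the truth is close to a
      # straight line and the local-linear fit stays reliable at the ends
      # of the ramp.  Nonpositive window estimates (rare, extreme-noise
      # windows) cannot enter the log fit and are excluded here.
      use <- is.finite(y) & y > 0
      gi <- g[use, , drop = FALSE]; yi <- y[use]
      # kernel weights only: window precisions are similar by construction
      # (same design in every window), and estimated per-window CIs are too
      # noisy (3 df) to use as weights without letting a chance small-CI
      # window dominate the local fit
      fit <- .locfit(gi$temperature_c, log(yi), temperatures, h)
      tq <- stats::qt(0.975, fit$df)
      exflag <- vapply(temperatures, function(tc)
        any(gi$extrapolation_flag[abs(gi$temperature_c - tc) < 2 * h]), NA)
      est <- exp(fit$estimate)
      out[[length(out) + 1L]] <- data.frame(
        probe_id = g$probe_id[1L], condition_id = g$condition_id[1L],
        mode = m, temperature_c = temperatures,
        rate_mhz = est, ci95 = tq * fit$se * est,
        extrapolation_flag = exflag, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assemble the transversal depth-by-temperature gradient surface
#'
#' Evaluates each probe's smoothed profile on the 5 degC reporting grid
#' (default 10, 15, ..., 50 degC) and arranges the values by attachment
#' carbon index n, yielding the transversal fluidity-gradient surface for
#' one condition and one rotation mode.
#'
#' @param profiles a `rotation_profiles` object from [smooth_profiles()].
#' @param mode `"op"` (out-of-plane) or `"ip"` (in-plane).
#' @param condition_id condition to extract (default: the single condition
#'   present).
#' @param temperatures grid temperatures (degC), default `seq(10, 50, 5)`.
#' @return object of class `gradient_surface`: data frame `mode`,
#'   `condition_id`, `position_n`, `probe_id`, `temperature_c`,
#'   `rate_mhz`, `ci95`, `extrapolation_flag`.  Missing probes produce
#'   explicit gaps (NA rows) with a warning.
#' @export
build_gradient <- function(profiles, mode = c("op", "ip"),
                           condition_id = NULL,
                           temperatures = seq(10, 50, by = 5)) {
  mode <- match.arg(mode)
  d <- profiles$data
  if (is.null(condition_id)) {
    condition_id <- unique(d$condition_id)
    if (length(condition_id) > 1L)
      stop("multiple conditions present; pass condition_id explicitly")
  }
  sub <- d[d$condition_id == condition_id, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no decompositions for condition ", condition_id)
  sub_prof <- structure(list(data = sub, bandwidth_c = profiles$bandwidth_c),
                        class = "rotation_profiles")
  surf <- predict_profiles(sub_prof, temperatures, mode = mode)
  surf$position_n <- probe_position(surf$probe_id)
  if (any(is.na(surf$rate_mhz)))
    warning("gradient surface has gaps (probes/temperatures without data)")
  surf <- surf[order(surf$position_n, surf$temperature_c),
               c("mode", "condition_id", "position_n", "probe_id",
                 "temperature_c", "rate_mhz", "ci95", "extrapolation_flag")]
  rownames(surf) <- NULL
  class(surf) <- c("gradient_surface", "data.frame")
  surf
}

#' Compare two gradient surfaces cell by cell
#'
#' Element-wise ratio of two surfaces of the same mode on the same
#' (position, temperature) grid, e.g. drug-resistant vs drug-sensitive
#' membranes, or plus/minus an inhibitor.  Confidence half-widths are
#' propagated on the log scale
#' (\eqn{SE_{\log} = \sqrt{(ci_a/1.96 a)^2 + (ci_b/1.96 b)^2}}).  A summary
#' of fold change versus temperature (mean over positions) supports
#' monotonicity checks.
#'
#' @param a,b `gradient_surface` objects with identical mode and grid.
#' @param log_fold_threshold cells with `|log2 fold| >` this value are
#'   listed in the summary (default `log2(1.5)`).
#' @return object of class `gradient_comparison`: data frame with
#'   `position_n`, `temperature_c`, `rate_a`, `rate_b`, `ratio`,
#'   `ci95_lo`, `ci95_hi`, `log2_fold`, `exceeds`; attributes
#'   `"fold_by_temperature"` (mean fold per grid temperature) and
#'   `"mode"`.
#' @export
compare_gradients <- function(a, b, log_fold_threshold = log2(1.5)) {
  if (!identical(unique(a$mode), unique(b$mode)))
    stop("grid mismatch: surfaces have different modes")
  key_a <- paste(a$position_n, a$temperature_c)
  key_b <- paste(b$position_n, b$temperature_c)
  if (!setequal(key_a, key_b))
    stop("grid mismatch: surfaces cover different (position, temperature) cells")
  m <- merge(as.data.frame(a), as.data.frame(b),
             by = c("position_n", "temperature_c"),
             suffixes = c("_a", "_b"))
  ok <- is.finite(m$rate_mhz_a) & is.finite(m$rate_mhz_b) &
    m$rate_mhz_a > 0 & m$rate_mhz_b > 0
  out <- data.frame(position_n = m$position_n,
                    temperature_c = m$temperature_c,
                    rate_a = m$rate_mhz_a, rate_b = m$rate_mhz_b,
                    ratio = ifelse(ok, m$rate_mhz_a / m$rate_mhz_b, NA_real_))
  se_log <- sqrt((m$ci95_a / 1.96 / m$rate_mhz_a)^2 +
                 (m$ci95_b / 1.96 / m$rate_mhz_b)^2)
  out$ci95_lo <- ifelse(ok, out$ratio * exp(-1.96 * se_log), NA_real_)
  out$ci95_hi <- ifelse(ok, out$ratio * exp(+1.96 * se_log), NA_real_)
  out$log2_fold <- log2(out$ratio)
  out$exceeds <- abs(out$log2_fold) > log_fold_threshold
  out <- out[order(out$position_n, out$temperature_c), ]
  rownames(out) <- NULL
  fold_t <- tapply(out$ratio, out$temperature_c, mean, na.rm = TRUE)
  attr(out, "fold_by_temperature") <- data.frame(
    temperature_c = as.numeric(names(fold_t)), mean_fold = as.numeric(fold_t))
  attr(out, "mode") <- unique(a$mode)
  class(out) <- c("gradient_comparison", "data.frame")
  out
}

#' Write / read a gradient surface as long-format CSV
#'
#' @param surface a `gradient_surface`.
#' @param path file path.
#' @export
write_gradient <- function(surface, path) {
  utils::write.csv(as.data.frame(surface), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_gradient
#' @export
read_gradient <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(df) <- c("gradient_surface", "data.frame")
  df
}
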
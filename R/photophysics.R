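#' Probe photophysics anchor tables
#'
#' The decomposition needs, for every probe and excitation wavelength, the
#' mean excited-state lifetime \eqn{\tau_F} (ns) and the zero-time
#' (fundamental) anisotropy \eqn{r_o} at the measurement temperature.  These
#' are never estimated here; they are interpolated in temperature from an
#' anchor table (literature decay-time measurements are typically reported
#' at 21, 37 and 47 degC).  A table is a data frame with columns
#' `probe_id`, `temperature_c`, `excitation_nm`, `tau_f_ns`, `r_o` carrying
#' class `"photophysics"`.
#'
#' @param table data frame with the five columns above.
#' @return validated `photophysics` object.
#' @export
photophysics_table <- function(table) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  need <- c("probe_id", "temperature_c", "excitation_nm", "tau_f_ns", "r_o")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("photophysics table lacks column(s): ", paste(miss, collapse = ", "))
  bad_tau <- which(!is.finite(table$tau_f_ns) | table$tau_f_ns <= 0)
  if (length(bad_tau))
    stop("photophysics validation error: tau_f_ns must be > 0 (row ",
         bad_tau[1L], ")")
  bad_ro <- which(!is.finite(table$r_o) | table$r_o < -0.2 | table$r_o > 0.4)
  if (length(bad_ro))
    stop("photophysics validation error: r_o must lie in [-0.2, 0.4] (row ",
         bad_ro[1L], ")")
  dup <- duplicated(table[, c("probe_id", "temperature_c", "excitation_nm")])
  if (any(dup))
    stop("photophysics validation error: duplicate anchor (row ",
         which(dup)[1L], ")")
  class(table) <- c("photophysics", "data.frame")
  table
}

#' Load a photophysics table from CSV
#'
#' @param path CSV with columns `probe_id`, `temperature_c`,
#'   `excitation_nm`, `tau_f_ns`, `r_o`.
#' @return a validated [photophysics_table()] object.
#' @export
load_photophysics <- function(path) {
  if (!file.exists(path)) stop("photophysics file not found: ", path)
  photophysics_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param table photophysics table.
#' @rdname load_photophysics
#' @export
write_photophysics <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up lifetime and zero-time anisotropy at a temperature
#'
#' Linear interpolation in temperature between the two bracketing anchors
#' for the requested (probe, wavelength); linear extrapolation beyond the
#' outermost anchors, flagged.  Queries at an anchor temperature return the
#' anchor values exactly.  `r_o_temperature = "fixed"` disables temperature
#' dependence of r_o and returns its value at the anchor temperature nearest
#' the query (the literature does not state whether r_o was
#' temperature-interpolated; both behaviours are supported).
#'
#' @param table a [photophysics_table()].
#' @param probe_id,excitation_nm,temperature_c query coordinates.
#' @param r_o_temperature `"interpolate"` (default) or `"fixed"`.
#' @return list with `tau_f_ns`, `r_o`, and logical `extrapolated`.
#' @export
get_photophysics <- function(table, probe_id, excitation_nm, temperature_c,
                             r_o_temperature = c("interpolate", "fixed")) {
  r_o_temperature <- match.arg(r_o_temperature)
  sel <- table$probe_id == probe_id & table$excitation_nm == excitation_nm
  if (!any(sel))
    stop(sprintf("photophysics lookup error: no anchors for probe '%s' at %g nm",
                 probe_id, excitation_nm))
  anch <- table[sel, , drop = FALSE]
  anch <- anch[order(anch$temperature_c), , drop = FALSE]
  tt <- anch$temperature_c
  interp1 <- function(v, x) {
    if (length(tt) == 1L) {
      if (x != tt)
        stop("photophysics lookup error: single anchor temperature, cannot interpolate")
      return(v)
    }
    # linear between bracketing anchors, linear continuation outside
    if (x <= tt[1L]) {
      i <- 1L; j <- 2L
    } else if (x >= tt[length(tt)]) {
      i <- length(tt) - 1L; j <- length(tt)
    } else {
      j <- findInterval(x, tt, rightmost.closed = TRUE) + 1L
      i <- j - 1L
    }
    v[i] + (v[j] - v[i]) * (x - tt[i]) / (tt[j] - tt[i])
  }
  tau <- vapply(temperature_c, function(x) interp1(anch$tau_f_ns, x), 0)
  ro <- if (r_o_temperature == "interpolate") {
    vapply(temperature_c, function(x) interp1(anch$r_o, x), 0)
  } else {
    anch$r_o[vapply(temperature_c,
                    function(x) which.min(abs(tt - x)), 0L)]
  }
  list(tau_f_ns = tau, r_o = ro,
       extrapolated = temperature_c < min(tt) | temperature_c > max(tt))
}

#' Probe depth coordinates
#'
#' The anthroyloxy attachment carbon index n (2, 7, 9, 12, 16) serves as the
#' transversal depth coordinate, from the lipid/water interface (n = 2) to
#' the hydrophobic bilayer centre (n = 16).
#'
#' @param probe_id character vector of probe labels.
#' @return integer attachment positions.
#' @export
#' @examples probe_position(c("2-AS", "16-AP"))
probe_position <- function(probe_id) {
  map <- c("2-AS" = 2L, "7-AS" = 7L, "9-AS" = 9L, "12-AS" = 12L, "16-AP" = 16L)
  pos <- map[probe_id]
  if (anyNA(pos)) {
    # fall back to the leading integer of the label
    num <- suppressWarnings(as.integer(sub("^(\\d+).*$", "\\1", probe_id)))
    pos[is.na(pos)] <- num[is.na(pos)]
  }
  if (anyNA(pos)) stop("unknown probe label(s): ",
                       paste(probe_id[is.na(pos)], collapse = ", "))
  unname(pos)
}

#' Synthetic default photophysics table
#'
#' SYNTHETIC stand-in for the literature anchor table (the real decay-time
#' measurements are external to this package and are not reproduced).
#' Values are physically plausible for n-(9-anthroyloxy) fatty acids in
#' DPPC vesicles: tau_F between 4 and 12 ns, decreasing with temperature;
#' r_o spanning roughly -0.1 to 0.3 across the 319-381 nm vibronic bands,
#' nearly temperature-independent.  Anchors at 21, 37 and 47 degC.  Use only
#' for testing and simulation; supply a measured table for real analyses.
#'
#' @param probes probe labels (default the five standard probes).
#' @param wavelengths excitation wavelengths in nm.
#' @return a [photophysics_table()].
#' @export
default_photophysics <- function(probes = c("2-AS", "7-AS", "9-AS", "12-AS", "16-AP"),
                                 wavelengths = c(319, 333, 347, 367, 381)) {
  # base r_o per vibronic excitation band (nm -> r_o at 37 degC)
  ro_base <- c("319" = -0.08, "333" = 0.05, "347" = 0.12,
               "367" = 0.22, "381" = 0.30)
  extra <- setdiff(as.character(wavelengths), names(ro_base))
  if (length(extra)) {
    # linear-in-wavelength filler for non-standard wavelengths
    fit <- stats::lm(ro ~ nm, data = data.frame(
      nm = as.numeric(names(ro_base)), ro = unname(ro_base)))
    ro_base[extra] <- stats::predict(fit, data.frame(nm = as.numeric(extra)))
  }
  # tau_F at 37 degC per probe; deeper probes slightly longer-lived
  tau37 <- c("2-AS" = 7.8, "7-AS" = 8.6, "9-AS" = 9.0,
             "12-AS" = 9.4, "16-AP" = 10.0)
  tau37_v <- tau37[probes]
  tau37_v[is.na(tau37_v)] <- 8.5
  temps <- c(21, 37, 47)
  grid <- expand.grid(probe_id = probes, temperature_c = temps,
                      excitation_nm = wavelengths,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # lifetime drops ~1.2%/degC around 37 degC; r_o drifts -0.0005/degC
  grid$tau_f_ns <- tau37_v[grid$probe_id] *
    (1 - 0.012 * (grid$temperature_c - 37))
  grid$r_o <- unname(ro_base[as.character(grid$excitation_nm)]) -
    5e-4 * (grid$temperature_c - 37)
  photophysics_table(grid)
}
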
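#' Compute steady-state fluorescence emission anisotropy from one reading
#'
#' Converts the four polarized intensity channels of a single instrument
#' observation into the emission anisotropy
#' \deqn{r = (R_v - R_h)/(R_v + 2 R_h)}
#' where \eqn{R_v = I_{vv}/I_{vh}} is the ratio of vertically to horizontally
#' polarized emission for vertical excitation and \eqn{R_h = I_{hv}/I_{hh}}
#' is the calibration (G) factor correcting for the polarization bias of the
#' detection path.  This is algebraically identical to the usual G-factor
#' form \eqn{(I_{vv} - G I_{vh})/(I_{vv} + 2 G I_{vh})}.
#'
#' @param reading a one-row data frame or named list with numeric fields
#'   `i_vv`, `i_vh`, `i_hv`, `i_hh` (all strictly positive) and optional
#'   metadata fields (`excitation_nm`, `temperature_c`, `time_s`,
#'   `probe_id`, `condition_id`, `replicate_id`) copied through unchanged.
#' @return a one-row data frame with column `r` plus the metadata columns
#'   and a logical `flag_range` marking values outside `[-0.2, 0.4]`.
#' @seealso [batch_anisotropy()] for whole runs.
#' @export
#' @examples
#' compute_anisotropy(list(i_vv = 300, i_vh = 100, i_hv = 50, i_hh = 50))$r
compute_anisotropy <- function(reading) {
  reading <- as.data.frame(reading, stringsAsFactors = FALSE)
  if (nrow(reading) != 1L)
    stop("compute_anisotropy() expects exactly one reading; use batch_anisotropy() for many")
  batch_anisotropy(reading, warn_flags = FALSE)
}

#' Convert a table of polarized readings into anisotropy points
#'
#' Order-preserving, elementwise application of the anisotropy formula.
#' Physically inadmissible values (outside \eqn{[-0.2, 0.4]}) are flagged in
#' the `flag_range` column and collected into a flag report attached as
#' attribute `"flags"`; they are never silently dropped, so that downstream
#' regression weighting can decide inclusion.
#'
#' @param readings data frame with columns `i_vv`, `i_vh`, `i_hv`, `i_hh`
#'   and any metadata columns; one reading per row.
#' @param warn_flags emit a warning summarising out-of-range values
#'   (default `TRUE`).
#' @return data frame of anisotropy points (column `r`, metadata columns,
#'   `flag_range`), with attribute `"flags"` holding the flag report.
#' @export
batch_anisotropy <- function(readings, warn_flags = TRUE) {
  readings <- as.data.frame(readings, stringsAsFactors = FALSE)
  if (nrow(readings) == 0L) {
    if (warn_flags) warning("batch_anisotropy(): empty input, empty output")
    out <- data.frame(r = numeric(0))
    attr(out, "flags") <- data.frame(row = integer(0), r = numeric(0))
    return(out)
  }
  chans <- c("i_vv", "i_vh", "i_hv", "i_hh")
  missing_ch <- setdiff(chans, names(readings))
  if (length(missing_ch))
    stop("missing intensity channel(s): ", paste(missing_ch, collapse = ", "))
  for (ch in chans) {
    v <- readings[[ch]]
    bad <- which(!is.finite(v) | v <= 0)
    if (length(bad))
      stop(sprintf("invalid reading: nonpositive intensity in channel '%s' at row %d",
                   ch, bad[1L]))
  }
  r_v <- readings$i_vv / readings$i_vh
  r_h <- readings$i_hv / readings$i_hh
  r <- (r_v - r_h) / (r_v + 2 * r_h)
  meta <- intersect(c("excitation_nm", "temperature_c", "time_s",
                      "probe_id", "condition_id", "replicate_id"),
                    names(readings))
  out <- cbind(data.frame(r = r), readings[, meta, drop = FALSE])
  out$flag_range <- r < -0.2 | r > 0.4
  flags <- data.frame(row = which(out$flag_range), r = r[out$flag_range])
  attr(out, "flags") <- flags
  if (warn_flags && nrow(flags) > 0L)
    warning(sprintf("%d anisotropy value(s) outside [-0.2, 0.4]; flagged, not dropped",
                    nrow(flags)))
  out
}

#' Read / write polarized readings as delimited text
#'
#' The on-disk dialect is a plain CSV with header columns `time_s`,
#' `temperature_c`, `excitation_nm`, `i_vv`, `i_vh`, `i_hv`, `i_hh`,
#' `probe_id`, `condition_id`, `replicate_id`, one reading per row.
#'
#' @param path file path.
#' @return `read_readings()` returns the readings data frame.
#' @export
read_readings <- function(path) {
  if (!file.exists(path)) stop("readings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "temperature_c", "excitation_nm",
            "i_vv", "i_vh", "i_hv", "i_hh",
            "probe_id", "condition_id", "replicate_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("readings file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df
}

#' @param readings readings data frame.
#' @rdname read_readings
#' @export
write_readings <- function(readings, path) {
  utils::write.csv(readings, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
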
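#' Uniformly sampled trace
#'
#' Container for a recorded or synthetic postsynaptic-current trace:
#' strictly increasing, uniformly spaced times (ms) with one value per
#' sample (typically current in pA, or conductance in uS). Sampling
#' uniformity is validated to 1e-6 ms.
#'
#' @param times sample times (ms), strictly increasing, uniform.
#' @param values sample values, same length as `times` (>= 10 samples).
#' @param units_label text label for the value units (default `"pA"`).
#' @param stim_time optional stimulation time (ms) used by peak detection
#'   and the ratio pipeline.
#' @return an object of class `sampled_trace` with elements `times`,
#'   `values`, `dt`, `units_label`, `stim_time`.
#' @export
sampled_trace <- function(times, values, units_label = "pA",
                          stim_time = NULL) {
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 10)
    stop("trace must have at least 10 samples", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6))
    stop("times must be uniformly spaced (tolerance 1e-6 ms)", call. = FALSE)
  if (!is.null(stim_time)) stopifnot(is.finite(stim_time))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 dt = dt, units_label = units_label, stim_time = stim_time),
            class = "sampled_trace")
}

#' @export
print.sampled_trace <- function(x, ...) {
  cat(sprintf("sampled_trace: %d samples, dt = %.6g ms (%.4g kHz), units %s%s\n",
              length(x$times), x$dt, 1 / x$dt, x$units_label,
              if (is.null(x$stim_time)) ""
              else sprintf(", stim at %g ms", x$stim_time)))
  invisible(x)
}

#' Read a trace from a delimited text file
#'
#' Expects a two-column delimited file with a header line naming the
#' columns `time_ms` and `value` (comma, tab or whitespace separated). If
#' a JSON sidecar `<path>.json` exists, its `stim_time_ms`, `units` and
#' `holding_mV` entries are merged into the trace.
#'
#' @param path path to the trace file.
#' @return a [sampled_trace()]; holding potential, when present in the
#'   sidecar, is attached as attribute `holding_mV`.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L, warn = FALSE)
  fields <- strsplit(trimws(header), "[,\t ]+")[[1]]
  if (length(fields) < 2 || fields[1] != "time_ms" || fields[2] != "value")
    stop("malformed trace header: expected columns 'time_ms,value', got '",
         header, "'", call. = FALSE)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep,
                      colClasses = "numeric"),
    error = function(e) stop("non-numeric or malformed rows in trace file: ",
                             conditionMessage(e), call. = FALSE))
  if (anyNA(df[[1]]) || anyNA(df[[2]]))
    stop("non-numeric rows in trace file", call. = FALSE)
  stim <- NULL
  units <- "pA"
  holding <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$stim_time_ms)) stim <- as.numeric(meta$stim_time_ms)
    if (!is.null(meta$units)) units <- as.character(meta$units)
    if (!is.null(meta$holding_mV)) holding <- as.numeric(meta$holding_mV)
  }
  tr <- sampled_trace(df[[1]], df[[2]], units_label = units, stim_time = stim)
  if (!is.null(holding)) attr(tr, "holding_mV") <- holding
  tr
}

#' Write a trace to a delimited text file
#'
#' Writes the `time_ms,value` CSV format accepted by [read_trace()]; when
#' the trace carries stimulation-time or holding-potential metadata, a
#' JSON sidecar `<path>.json` is written alongside.
#'
#' @param trace a [sampled_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sampled_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,value", con)
  writeLines(sprintf("%.10g,%.10g", trace$times, trace$values), con)
  meta <- list()
  if (!is.null(trace$stim_time)) meta$stim_time_ms <- trace$stim_time
  if (!is.null(attr(trace, "holding_mV")))
    meta$holding_mV <- attr(trace, "holding_mV")
  meta$units <- trace$units_label
  if (length(meta) > 1 || !is.null(trace$stim_time))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Baseline of a trace
#'
#' Mean of the samples in the `baseline_ms` window immediately preceding
#' the stimulation time. Zero if no pre-stimulus samples exist.
#'
#' @param trace a [sampled_trace()] with `stim_time` set.
#' @param baseline_ms length of the pre-stimulus window (ms), default 10.
#' @return scalar baseline in trace units.
#' @export
trace_baseline <- function(trace, baseline_ms = 10) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (is.null(trace$stim_time)) stop("stim_time not set", call. = FALSE)
  pre <- trace$times < trace$stim_time &
    trace$times >= trace$stim_time - baseline_ms
  if (!any(pre)) return(0)
  mean(trace$values[pre])
}

#' Detect the post-stimulus peak of a trace
#'
#' After subtracting the pre-stimulus baseline, returns the time and
#' signed amplitude of the largest-magnitude extremum occurring at or
#' after the stimulation time. Works identically for inward (negative)
#' and outward (positive) currents.
#'
#' @param trace a [sampled_trace()] with `stim_time` set.
#' @param baseline_ms pre-stimulus window used for the baseline (ms).
#' @return list with `time` (ms), `amplitude` (trace units, signed,
#'   baseline-subtracted) and `baseline`.
#' @export
detect_peak <- function(trace, baseline_ms = 10) {
  stopifnot(inherits(trace, "sampled_trace"))
  if (is.null(trace$stim_time)) stop("stim_time not set", call. = FALSE)
  post <- trace$times >= trace$stim_time
  if (!any(post)) stop("no post-stimulus samples", call. = FALSE)
  b <- trace_baseline(trace, baseline_ms)
  v <- trace$values[post] - b
  i <- which.max(abs(v))
  list(time = trace$times[post][i], amplitude = v[i], baseline = b)
}

#' Pointwise subtraction of a scaled template from a trace
#'
#' Used to remove the AMPA component from a raw +40 mV recording:
#' `raw - scale * template`, pointwise on a shared sampling grid. The
#' scale used is recorded as attribute `subtraction_scale` of the result.
#'
#' @param raw a [sampled_trace()].
#' @param template a [sampled_trace()] on the identical time grid.
#' @param scale dimensionless multiplier applied to the template.
#' @return a new [sampled_trace()].
#' @export
subtract_ampa_component <- function(raw, template, scale) {
  stopifnot(inherits(raw, "sampled_trace"),
            inherits(template, "sampled_trace"))
  if (length(raw$times) != length(template$times) ||
      any(abs(raw$times - template$times) > 1e-9))
    stop("raw and template traces must share the sampling grid",
         call. = FALSE)
  out <- sampled_trace(raw$times, raw$values - scale * template$values,
                       units_label = raw$units_label,
                       stim_time = raw$stim_time)
  attr(out, "subtraction_scale") <- scale
  out
}

#' Driving-force ratio scale for AMPA subtraction
#'
#' Default scale for [subtract_ampa_component()]: the linear driving-force
#' ratio `(v_target - e_rev) / (v_template - e_rev)` mapping an AMPA
#' template recorded at `v_template` (typically -70 mV) onto the holding
#' potential of the raw trace (typically +40 mV).
#'
#' @param v_target holding potential of the raw trace (mV).
#' @param v_template holding potential of the template (mV).
#' @param e_rev AMPA reversal potential (mV), default 0.
#' @return dimensionless scale.
#' @export
driving_force_scale <- function(v_target = 40, v_template = -70, e_rev = 0) {
  if (v_template == e_rev)
    stop("template holding potential equals the reversal potential",
         call. = FALSE)
  (v_target - e_rev) / (v_template - e_rev)
}
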
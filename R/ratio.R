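# NMDA/AMPA ratio analysis for paired -70 mV / +40 mV recordings.

#' Quality-control exclusion for paired NMDA/AMPA traces
#'
#' NMDA receptors have slower kinetics than AMPA receptors, so a recording
#' whose NMDA current peaks at or before the AMPA current indicates the
#' NMDA component is absent or contaminated (seen in a subset of
#' fast-spiking interneurons); such pairs are excluded.
#'
#' @param nmda_trace,ampa_trace [sampled_trace()] objects sharing
#'   `stim_time`.
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @return list with `exclude` (logical) and `reason` (text, `NA` if
#'   kept), plus the two detected peak times.
#' @export
qc_exclude_trace <- function(nmda_trace, ampa_trace, baseline_ms = 10) {
  stopifnot(inherits(nmda_trace, "sampled_trace"),
            inherits(ampa_trace, "sampled_trace"))
  if (is.null(nmda_trace$stim_time) || is.null(ampa_trace$stim_time) ||
      nmda_trace$stim_time != ampa_trace$stim_time)
    stop("paired traces must share stim_time", call. = FALSE)
  pn <- detect_peak(nmda_trace, baseline_ms)
  pa <- detect_peak(ampa_trace, baseline_ms)
  exclude <- pn$time <= pa$time
  list(exclude = exclude,
       reason = if (exclude)
         sprintf("NMDA peak (%.4g ms) at or before AMPA peak (%.4g ms)",
                 pn$time, pa$time) else NA_character_,
       nmda_peak_time = pn$time, ampa_peak_time = pa$time)
}

#' NMDA/AMPA ratio from a paired recording
#'
#' The AMPA component is the magnitude of the current peak at -70 mV; the
#' NMDA component is the magnitude of the mean +40 mV current in the
#' window 50--60 ms after stimulation (by then the fast AMPA component
#' has decayed). Both traces are baseline-subtracted using their
#' pre-stimulus samples. The ratio is invariant to common rescaling of
#' the paired traces.
#'
#' @param minus70 [sampled_trace()] recorded at -70 mV, `stim_time` set.
#' @param plus40 [sampled_trace()] recorded at +40 mV, `stim_time` set and
#'   spanning at least `stim_time + 60` ms.
#' @param window_ms two-element window, in ms after stimulation, over
#'   which the +40 mV current is averaged (default `c(50, 60)`).
#' @param baseline_ms pre-stimulus baseline window (ms).
#' @return list with `ratio`, `ampa_component` (pA), `nmda_component`
#'   (pA).
#' @export
nmda_ampa_ratio <- function(minus70, plus40, window_ms = c(50, 60),
                            baseline_ms = 10) {
  stopifnot(inherits(minus70, "sampled_trace"),
            inherits(plus40, "sampled_trace"))
  if (is.null(minus70$stim_time) || is.null(plus40$stim_time))
    stop("both traces need stim_time", call. = FALSE)
  lo <- plus40$stim_time + window_ms[1]
  hi <- plus40$stim_time + window_ms[2]
  if (plus40$times[length(plus40$times)] < hi)
    stop("+40 mV trace does not cover the ", window_ms[1], "-",
         window_ms[2], " ms post-stimulus window", call. = FALSE)
  ampa <- abs(detect_peak(minus70, baseline_ms)$amplitude)
  if (ampa == 0) stop("AMPA component is zero", call. = FALSE)
  b40 <- trace_baseline(plus40, baseline_ms)
  win <- plus40$times >= lo & plus40$times <= hi
  nmda <- abs(mean(plus40$values[win] - b40))
  list(ratio = nmda / ampa, ampa_component = ampa, nmda_component = nmda)
}

#' Group-average NMDA/AMPA ratios
#'
#' Per-cell ratios are averaged within each (input region, cell type)
#' group: the ratio is computed per recording first and the arithmetic
#' mean of those per-cell values is the group estimate (never a ratio of
#' group means).
#'
#' @param per_cell data.frame with columns `group` (label) and `ratio`
#'   (per-cell NMDA/AMPA ratio).
#' @return data.frame with columns `group`, `mean_ratio`, `n`.
#' @export
aggregate_ratios <- function(per_cell) {
  if (!is.data.frame(per_cell) ||
      !all(c("group", "ratio") %in% names(per_cell)))
    stop("per_cell must have columns 'group' and 'ratio'", call. = FALSE)
  if (nrow(per_cell) == 0) stop("no records to aggregate", call. = FALSE)
  if (anyNA(per_cell$ratio)) stop("NA ratios in input", call. = FALSE)
  agg <- stats::aggregate(ratio ~ group, data = per_cell, FUN = mean)
  n <- stats::aggregate(ratio ~ group, data = per_cell, FUN = length)
  data.frame(group = agg$group, mean_ratio = agg$ratio, n = n$ratio)
}
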
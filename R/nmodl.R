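# NMODL mechanism-text emitter.
#
# Produces a NEURON synapse mechanism combining an AMPA and an NMDA
# conductance. Tri-exponential kinetics are expressed with one rise state
# plus two decay states per receptor (the second decay state carries the
# slow component); peak times and normalization factors are precomputed
# (Newton's method for tri-exponential kinetics) and embedded as
# constants, since they depend only on the kinetics, not on simulation
# time. Output is deterministic: identical inputs give byte-identical
# text.

.fmt <- function(x) sprintf("%.12g", x)

.kin_block <- function(k, tag, peak) {
  if (inherits(k, "triexp_kinetics")) {
    tp <- if (inherits(peak, "newton_result")) {
      if (!peak$converged)
        stop("peak time for ", tag, " is not converged", call. = FALSE)
      peak$t_peak
    } else stop("tri-exponential ", tag,
                " needs a newton_result peak time", call. = FALSE)
    factor <- triexp_norm_factor(k, tp)
    list(tri = TRUE, tp = tp, factor = factor, k = k)
  } else if (inherits(k, "biexp_kinetics")) {
    list(tri = FALSE, tp = biexp_peak_time(k),
         factor = biexp_norm_factor(k), k = k)
  } else stop("unsupported kinetics for ", tag, call. = FALSE)
}

.params_for <- function(info, tag) {
  k <- info$k
  if (info$tri) {
    c(sprintf("    tau_r_%s = %s (ms)", tag, .fmt(k$tau_r)),
      sprintf("    tau_f_%s = %s (ms)", tag, .fmt(k$tau_f)),
      sprintf("    tau_s_%s = %s (ms)", tag, .fmt(k$tau_s)),
      sprintf("    If_%s = %s", tag, .fmt(k$i_f)),
      sprintf("    Is_%s = %s", tag, .fmt(k$i_s)),
      sprintf("    gmax_%s = %s (uS)", tag, .fmt(k$gbar)))
  } else {
    c(sprintf("    tau_rise_%s = %s (ms)", tag, .fmt(k$tau_rise)),
      sprintf("    tau_decay_%s = %s (ms)", tag, .fmt(k$tau_decay)),
      sprintf("    gmax_%s = %s (uS)", tag, .fmt(k$gbar)))
  }
}

.states_for <- function(info, tag) {
  up <- toupper(substr(tag, 1, 1))
  if (info$tri) sprintf(c("    A_%s", "    B_%s", "    C_%s"), tag)
  else sprintf(c("    A_%s", "    B_%s"), tag)
}

.derivs_for <- function(info, tag) {
  k <- info$k
  if (info$tri) {
    c(sprintf("    A_%s' = -A_%s/tau_r_%s", tag, tag, tag),
      sprintf("    B_%s' = -B_%s/tau_f_%s", tag, tag, tag),
      sprintf("    C_%s' = -C_%s/tau_s_%s", tag, tag, tag))
  } else {
    c(sprintf("    A_%s' = -A_%s/tau_rise_%s", tag, tag, tag),
      sprintf("    B_%s' = -B_%s/tau_decay_%s", tag, tag, tag))
  }
}

.g_expr <- function(info, tag) {
  if (info$tri)
    sprintf("gmax_%s*factor_%s*(If_%s*B_%s + Is_%s*C_%s - (If_%s + Is_%s)*A_%s)",
            tag, tag, tag, tag, tag, tag, tag, tag, tag)
  else
    sprintf("gmax_%s*factor_%s*(B_%s - A_%s)", tag, tag, tag, tag)
}

.receive_for <- function(info, tag) {
  if (info$tri)
    c(sprintf("    A_%s = A_%s + weight*(If_%s + Is_%s)", tag, tag, tag, tag),
      sprintf("    B_%s = B_%s + weight*If_%s", tag, tag, tag),
      sprintf("    C_%s = C_%s + weight*Is_%s", tag, tag, tag))
  else
    c(sprintf("    A_%s = A_%s + weight", tag, tag),
      sprintf("    B_%s = B_%s + weight", tag, tag))
}

#' Emit NMODL mechanism text for an AMPA + NMDA synapse
#'
#' Generates the source text of a NEURON point-process mechanism with
#' separate AMPA and NMDA conductances. Tri-exponential kinetics produce
#' a rise state plus two decay states per receptor; the peak times
#' (`tp_ampa`, `tp_nmda`) and normalization factors (`factor_ampa`,
#' `factor_nmda`) are embedded as precomputed constants — for
#' tri-exponential kinetics these must come from a converged
#' [newton_peak_time()] result. The NMDA branch applies the sigmoidal
#' magnesium block with the configured constants.
#'
#' @param ampa AMPA kinetics, [biexp_kinetics()] or [triexp_kinetics()].
#' @param nmda NMDA kinetics, same types.
#' @param mg an [mg_block_params()] object for the NMDA branch.
#' @param e_rev shared reversal potential (mV).
#' @param peak_ampa,peak_nmda precomputed peak times: required
#'   `newton_result` objects for tri-exponential kinetics; ignored (closed
#'   form used) for bi-exponential kinetics.
#' @param suffix POINT_PROCESS name (default `"PSCdd"`).
#' @return a single string of NMODL source text.
#' @export
emit_nmodl <- function(ampa, nmda, mg, e_rev = 0,
                       peak_ampa = NULL, peak_nmda = NULL,
                       suffix = "PSCdd") {
  stopifnot(inherits(mg, "mg_block_params"))
  if (inherits(ampa, "triexp_kinetics") && is.null(peak_ampa))
    stop("peak_ampa missing for tri-exponential AMPA kinetics",
         call. = FALSE)
  if (inherits(nmda, "triexp_kinetics") && is.null(peak_nmda))
    stop("peak_nmda missing for tri-exponential NMDA kinetics",
         call. = FALSE)
  ia <- .kin_block(ampa, "ampa", peak_ampa)
  inm <- .kin_block(nmda, "nmda", peak_nmda)
  lines <- c(
    "COMMENT",
    "AMPA + NMDA postsynaptic conductance with double-exponential decay.",
    "Peak times (tp_*) and normalization factors (factor_*) are",
    "precomputed constants: the output of Newton's method for",
    "tri-exponential kinetics, closed form for bi-exponential kinetics.",
    "ENDCOMMENT",
    "",
    "NEURON {",
    sprintf("    POINT_PROCESS %s", suffix),
    "    RANGE g_ampa, g_nmda, i_ampa, i_nmda, e_rev",
    "    NONSPECIFIC_CURRENT i",
    "}",
    "",
    "UNITS {",
    "    (nA) = (nanoamp)",
    "    (mV) = (millivolt)",
    "    (uS) = (microsiemens)",
    "    (mM) = (milli/liter)",
    "}",
    "",
    "PARAMETER {",
    .params_for(ia, "ampa"),
    .params_for(inm, "nmda"),
    sprintf("    tp_ampa = %s (ms)", .fmt(ia$tp)),
    sprintf("    tp_nmda = %s (ms)", .fmt(inm$tp)),
    sprintf("    factor_ampa = %s", .fmt(ia$factor)),
    sprintf("    factor_nmda = %s", .fmt(inm$factor)),
    sprintf("    e_rev = %s (mV)", .fmt(e_rev)),
    sprintf("    mg_a = %s (/mV)", .fmt(mg$a)),
    sprintf("    mg_b = %s (mM)", .fmt(mg$b)),
    sprintf("    mg_conc = %s (mM)", .fmt(mg$mg_conc)),
    "}",
    "",
    "ASSIGNED {",
    "    v (mV)",
    "    i (nA)",
    "    i_ampa (nA)",
    "    i_nmda (nA)",
    "    g_ampa (uS)",
    "    g_nmda (uS)",
    "    mgblock",
    "}",
    "",
    "STATE {",
    .states_for(ia, "ampa"),
    .states_for(inm, "nmda"),
    "}",
    "",
    "INITIAL {",
    sub("^    (\\S+) =.*$", "    \\1 = 0",
        c(.receive_for(ia, "ampa"), .receive_for(inm, "nmda"))),
    "}",
    "",
    "BREAKPOINT {",
    "    SOLVE kinstates METHOD cnexp",
    "    mgblock = 1 / (1 + exp(-mg_a*v) * (mg_conc/mg_b))",
    sprintf("    g_ampa = %s", .g_expr(ia, "ampa")),
    sprintf("    g_nmda = %s", .g_expr(inm, "nmda")),
    "    i_ampa = g_ampa*(v - e_rev)",
    "    i_nmda = g_nmda*mgblock*(v - e_rev)",
    "    i = i_ampa + i_nmda",
    "}",
    "",
    "DERIVATIVE kinstates {",
    .derivs_for(ia, "ampa"),
    .derivs_for(inm, "nmda"),
    "}",
    "",
    "NET_RECEIVE(weight) {",
    .receive_for(ia, "ampa"),
    .receive_for(inm, "nmda"),
    "}")
  paste0(paste(unlist(lines), collapse = "\n"), "\n")
}
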
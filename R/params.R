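#' @useDynLib sancpace, .registration = TRUE
#' @importFrom stats median sd setNames approx rnorm runif
#' @importFrom utils modifyList packageVersion
NULL

# Canonical parameter order.  The C translation in src/sanc_model.c indexes
# the parameter vector positionally; its enum must match this character
# vector exactly.  The trailing drive block (sna0..lcr) is filled in by the
# simulator per protocol segment and is not part of a ModelParams object.
sanc_param_names <- function() {
  c(
    "cm", "vi", "nao", "ko", "cao", "ki",
    "g_cal", "g_cat", "g_hcn", "g_k", "g_kach", "g_bna", "g_bca",
    "e_cal", "e_cat", "e_h",
    "inak_max", "km_nak", "nh_nak", "km_ko",
    "k_ncx", "d_ncx", "gamma_ncx",
    "f_na_hcn", "f_cab", "km_fca",
    "tau_dl", "tau_fl", "tau_dt", "tau_ft", "tau_y", "tau_n", "tau_fca",
    "v_dl", "k_dl", "v_fl", "k_fl", "v_dt", "k_dt", "v_ft", "k_ft",
    "v_y", "k_y", "v_n", "k_n", "v_kach", "k_kach",
    "a_cal", "a_cat", "a_hcn", "a_kach", "a2_sym", "a2_kach", "mod_floor",
    "tau_pka",
    "ipca_max", "km_pca", "s_hcn",
    "q10_rate", "q10_cond", "q10_ca", "t_ref"
  )
}

sanc_drive_names <- function() {
  c("sna0", "sna1", "pna0", "pna1", "seg_t0", "seg_t1", "bt", "lcr")
}

sanc_state_names <- function() {
  c("V", "d_L", "f_L", "f_Ca", "d_T", "f_T", "y", "n", "Nai", "Cai", "pka")
}

#' Default model parameters
#'
#' Returns the tuned parameter set of the reduced mouse sinoatrial node cell
#' model.  At baseline drive (`sna = pna = 1`, 37 degrees C, `lcr = 1`) the
#' model fires spontaneously and rhythmically in the murine range
#' (300-600 beats per minute).
#'
#' Fields (units): membrane capacitance `cm` (pF); intracellular volume `vi`
#' (pL); fixed extracellular/intracellular concentrations `nao`, `ko`, `cao`,
#' `ki` (mM); maximal conductances `g_cal`, `g_cat`, `g_hcn`, `g_k`,
#' `g_kach`, `g_bna` (nS); fixed Ca-current reversals `e_cal`, `e_cat` and
#' funny-current reversal `e_h` (mV); Na/K pump maximum `inak_max` (pA) with
#' half-saturation `km_nak` (mM), Hill coefficient `nh_nak` and external-K
#' half-saturation `km_ko` (mM); Na-Ca exchanger scale `k_ncx` (pA/mM^4),
#' denominator factor `d_ncx` and partition `gamma_ncx`; fraction of the
#' funny current carried by Na `f_na_hcn`; fast-buffer fraction `f_cab` and
#' Ca-dependent-inactivation half-saturation `km_fca` (mM); gate time
#' constants `tau_*` (s) and Boltzmann half-voltages/slopes `v_*`, `k_*`
#' (mV; negative slope = inactivation); autonomic sensitivities `a_cal`,
#' `a_cat`, `a_hcn` (sympathetic) and `a_kach` (parasympathetic); Q10
#' temperature coefficients `q10_rate`, `q10_cond` and reference temperature
#' `t_ref` (degrees C).
#'
#' @param ... named overrides of individual parameters.
#' @return an object of class `sanc_params` (named list).
#' @export
build_default_params <- function(...) {
  p <- list(
    cm = 25, vi = 2.5, nao = 140, ko = 5.4, cao = 1.8, ki = 140,
    g_cal = 20, g_cat = 4, g_hcn = 6, g_k = 13, g_kach = 0.5, g_bna = 1.0,
    g_bca = 0,
    e_cal = 45, e_cat = 45, e_h = -30,
    inak_max = 500, km_nak = 12, nh_nak = 3, km_ko = 1.4,
    k_ncx = 0.015, d_ncx = 1e-4, gamma_ncx = 0.5,
    f_na_hcn = 0.4, f_cab = 0.02, km_fca = 0.001,
    tau_dl = 0.002, tau_fl = 0.1, tau_dt = 0.002, tau_ft = 0.05,
    tau_y = 0.15, tau_n = 0.035, tau_fca = 0.02,
    v_dl = -15, k_dl = 5, v_fl = 20, k_fl = -6,
    v_dt = -50, k_dt = 5, v_ft = -60, k_ft = -6,
    v_y = -55, k_y = -9, v_n = 0, k_n = 15,
    v_kach = -40, k_kach = -15,
    a_cal = 2, a_cat = 2, a_hcn = 0.6, a_kach = 0.3, a2_sym = 2,
    a2_kach = 0.5, mod_floor = 1, tau_pka = 15,
    ipca_max = 0, km_pca = 5e-4, s_hcn = 14,
    q10_rate = 2.3, q10_cond = 1.3, q10_ca = 3.5, t_ref = 37
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p <- modifyList(p, ov)
  }
  validate_params(p)
  structure(p, class = "sanc_params")
}

validate_params <- function(p) {
  need <- sanc_param_names()
  miss <- setdiff(need, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "))
  num <- vapply(p[need], function(x) is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))
  if (!all(num)) stop("non-finite or non-scalar parameter(s): ",
                      paste(need[!num], collapse = ", "))
  nonneg <- c("cm", "vi", "g_cal", "g_cat", "g_hcn", "g_k", "g_kach", "g_bna",
              "inak_max", "k_ncx")
  if (any(unlist(p[nonneg]) < 0)) stop("conductances, capacitance and volumes must be >= 0")
  if (p$q10_rate < 1) stop("q10_rate must be >= 1")
  invisible(TRUE)
}

as_param_vector <- function(params) {
  unlist(params[sanc_param_names()])
}

#' Default drive input
#'
#' Baseline autonomic and environmental drive: sympathetic and
#' parasympathetic multipliers of 1 (preictal baseline), body temperature
#' 37 degrees C, local circadian rhythmicity multiplier 1.
#'
#' @param sna,pna autonomic multipliers (dimensionless, >= 0).
#' @param bt body temperature (degrees C, in \[34, 40\]).
#' @param lcr HCN-expression multiplier (dimensionless, > 0).
#' @return a `sanc_drive` list.
#' @export
drive_input <- function(sna = 1, pna = 1, bt = 37, lcr = 1) {
  if (sna < 0 || pna < 0 || lcr < 0) stop("sna, pna and lcr must be >= 0")
  if (bt < 34 || bt > 40) stop("bt must lie in [34, 40] degrees C")
  structure(list(sna = sna, pna = pna, bt = bt, lcr = lcr),
            class = "sanc_drive")
}

#' Default initial state
#'
#' A diastolic starting point near the limit cycle of the default
#' parameterisation; `run_to_steady()` converges from here in a few seconds
#' of simulated time.
#'
#' @return named numeric state vector (see [check_state()] for fields).
#' @export
default_state <- function() {
  c(V = -60, d_L = 0.001, f_L = 0.95, f_Ca = 0.6, d_T = 0.05, f_T = 0.4,
    y = 0.3, n = 0.01, Nai = 8, Cai = 2e-4, pka = 1)
}

#' Validate a state vector
#'
#' Checks the physiological invariants of the model state: all gating
#' variables in \[0, 1\], strictly positive intracellular Na and Ca, membrane
#' potential within \[-90, +60\] mV, and finiteness throughout.
#'
#' @param state named numeric vector as returned by [default_state()].
#' @return character vector of violations; empty if the state is valid.
#' @export
check_state <- function(state) {
  out <- character(0)
  nm <- sanc_state_names()
  if (!all(nm %in% names(state))) {
    return(paste("missing state field(s):",
                 paste(setdiff(nm, names(state)), collapse = ", ")))
  }
  state <- state[nm]
  if (any(!is.finite(state))) out <- c(out, "non-finite state entry")
  gates <- state[c("d_L", "f_L", "f_Ca", "d_T", "f_T", "y", "n")]
  if (any(gates < 0 | gates > 1, na.rm = TRUE)) out <- c(out, "gate out of [0,1]")
  if (any(state[c("Nai", "Cai")] <= 0, na.rm = TRUE)) out <- c(out, "negative concentration")
  if (is.finite(state["V"]) && (state["V"] < -90 || state["V"] > 60))
    out <- c(out, "membrane potential out of [-90, 60] mV")
  if (is.finite(state["pka"]) && state["pka"] < 0)
    out <- c(out, "negative adrenergic effector state")
  out
}

#' Serialize model parameters to JSON
#'
#' @param params a `sanc_params` object.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(params[sanc_param_names()], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' Unknown keys are rejected so stale or misspelled configuration cannot
#' silently alter the model.
#'
#' @param path JSON file written by [write_params()].
#' @return a `sanc_params` object.
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(p), sanc_param_names())
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  do.call(build_default_params, as.list(p))
}

#' @export
print.sanc_params <- function(x, ...) {
  cat("Mouse SANC model parameters (", length(sanc_param_names()),
      " values)\n", sep = "")
  cat(sprintf("  conductances (nS): g_CaL=%.3g g_CaT=%.3g g_HCN=%.3g g_K=%.3g g_KACh=%.3g g_bNa=%.3g\n",
              x$g_cal, x$g_cat, x$g_hcn, x$g_k, x$g_kach, x$g_bna))
  cat(sprintf("  pump/exchanger: I_NaK_max=%.3g pA (Km %.3g mM), k_NCX=%.3g\n",
              x$inak_max, x$km_nak, x$k_ncx))
  cat(sprintf("  cell: Cm=%.3g pF, Vi=%.3g pL, T_ref=%.3g C\n", x$cm, x$vi, x$t_ref))
  invisible(x)
}
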
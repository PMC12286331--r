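# Reference R implementation of the model equations.  The integrator uses
# the C translation in src/sanc_model.c; a property test keeps the two in
# lock-step, so this file is the authoritative, readable statement of the
# model.

boltz <- function(V, vh, k) 1 / (1 + exp((vh - V) / k))

#' Instantaneous ionic currents
#'
#' Evaluates every membrane current of the reduced SANC model at a given
#' state under a given autonomic/environmental drive.  The Ca-channel
#' conductances follow the slow adrenergic effector state with a linear
#' plus quadratic gain, floored at the basal fraction `mod_floor`; the
#' funny-current conductance follows sympathetic drive linearly (its
#' fast activation-shift lives in [sanc_rhs()]); the muscarinic K
#' conductance tracks transmitter withdrawal at unit gain below baseline
#' and gains a quadratic sensitisation beyond twice-baseline vagal tone;
#' the LCR multiplier scales the funny current proportionally;
#' temperature acts through Q10 factors on conductances (with a steeper
#' coefficient for the Ca channels) and, in [sanc_rhs()], on gating
#' rates.
#'
#' @param state named state vector (see [default_state()]).
#' @param params `sanc_params` object.
#' @param drive `sanc_drive` object from [drive_input()].
#' @return named list of instantaneous currents (pA): `i_cal`, `i_cat`,
#'   `i_hcn`, `i_k`, `i_kach`, `i_nak`, `i_ncx`, `i_bna`, `i_bca`,
#'   `i_pca`, and their sum `i_net`.
#' @export
compute_currents <- function(state, params, drive) {
  if (any(!is.finite(unlist(state)))) stop("non-finite state entry")
  p <- params
  V <- state[["V"]]; Nai <- state[["Nai"]]; Cai <- state[["Cai"]]

  phi_g <- p$q10_cond^((drive$bt - p$t_ref) / 10)
  # Ca-channel availability carries a steeper Q10 than other conductances
  phi_ca <- p$q10_ca^((drive$bt - p$t_ref) / 10)
  rtf <- 0.0861733 * (273.15 + drive$bt)
  e_k <- rtf * log(p$ko / p$ki)
  e_na <- rtf * log(p$nao / Nai)

  # sympathetic targets retain a basal conductance fraction (mod_floor)
  # when drive is withdrawn; muscarinic K floors at zero
  # Ca-channel upregulation follows the slow phosphorylation state; the
  # fast cAMP action on HCN is handled in sanc_rhs via the activation shift
  pk <- if ("pka" %in% names(state)) state[["pka"]] else drive$sna
  ds <- pk - 1
  ds2 <- if (pk > 1) ds^2 else 0
  m_cal <- max(p$mod_floor, 1 + p$a_cal * ds + p$a2_sym * ds2)
  m_cat <- max(p$mod_floor, 1 + p$a_cat * ds + p$a2_sym * ds2)
  m_hcn <- max(p$mod_floor, 1 + p$a_hcn * (drive$sna - 1))
  # muscarinic sensitisation: quadratic term engages beyond pna = 2;
  # below baseline the current tracks transmitter withdrawal at unit gain
  dp <- drive$pna - 1
  dq <- max(0, drive$pna - 2)
  m_kach <- if (drive$pna < 1) drive$pna else
    max(0, 1 + p$a_kach * dp + p$a2_kach * dq^2)

  i_cal <- p$g_cal * phi_ca * m_cal * state[["d_L"]] * state[["f_L"]] *
    state[["f_Ca"]] * (V - p$e_cal)
  i_cat <- p$g_cat * phi_ca * m_cat * state[["d_T"]] * state[["f_T"]] *
    (V - p$e_cat)
  i_hcn <- p$g_hcn * phi_g * m_hcn * drive$lcr * state[["y"]] * (V - p$e_h)
  i_k <- p$g_k * phi_g * state[["n"]] * (V - e_k)
  i_kach <- p$g_kach * phi_g * m_kach * boltz(V, p$v_kach, p$k_kach) * (V - e_k)

  hill <- Nai^p$nh_nak
  i_nak <- p$inak_max * phi_g * hill / (hill + p$km_nak^p$nh_nak) *
    p$ko / (p$ko + p$km_ko)

  na3 <- Nai^3; nao3 <- p$nao^3
  i_ncx <- p$k_ncx * phi_g *
    (na3 * p$cao * exp(p$gamma_ncx * V / rtf) -
       nao3 * Cai * exp(-(1 - p$gamma_ncx) * V / rtf)) /
    (1 + p$d_ncx * (Cai * nao3 + p$cao * na3))

  i_bna <- p$g_bna * (V - e_na)
  i_bca <- p$g_bca * (V - p$e_cal)
  i_pca <- p$ipca_max * phi_g * Cai / (Cai + p$km_pca)

  list(i_cal = i_cal, i_cat = i_cat, i_hcn = i_hcn, i_k = i_k,
       i_kach = i_kach, i_nak = i_nak, i_ncx = i_ncx, i_bna = i_bna,
       i_bca = i_bca, i_pca = i_pca,
       i_net = i_cal + i_cat + i_hcn + i_k + i_kach + i_nak + i_ncx +
         i_bna + i_bca + i_pca)
}

#' Model right-hand side (reference implementation)
#'
#' Time derivative of the full state.  The membrane obeys
#' `dV/dt = -I_net / Cm`; every gate relaxes first-order towards its
#' voltage-dependent steady state (the Ca-dependent inactivation gate of the
#' L-type current relaxes towards `km_fca / (km_fca + Cai)`, so its steady
#' state falls as cytosolic Ca rises); intracellular Na balances the
#' Na-carrying fluxes (background Na, the Na fraction of the funny current,
#' 3 Na per Na/K pump cycle and 3 Na per Na-Ca exchanger cycle); cytosolic
#' Ca balances L- and T-type entry against exchanger extrusion through a
#' fast-buffer fraction.
#'
#' @inheritParams compute_currents
#' @param t time (s); only relevant through `drive` time-dependence, which
#'   is resolved by the caller, so the derivative itself is autonomous.
#' @return list with `dstate` (named derivative vector, per second) and
#'   `currents` (as [compute_currents()]).
#' @export
sanc_rhs <- function(t, state, params, drive) {
  p <- params
  cur <- compute_currents(state, p, drive)
  phi_r <- p$q10_rate^((drive$bt - p$t_ref) / 10)
  V <- state[["V"]]

  d <- numeric(11)
  names(d) <- sanc_state_names()
  d["V"] <- -1000 * cur$i_net / p$cm  # pA/pF = mV/ms; time unit is s
  d["d_L"] <- phi_r * (boltz(V, p$v_dl, p$k_dl) - state[["d_L"]]) / p$tau_dl
  d["f_L"] <- phi_r * (boltz(V, p$v_fl, p$k_fl) - state[["f_L"]]) / p$tau_fl
  d["d_T"] <- phi_r * (boltz(V, p$v_dt, p$k_dt) - state[["d_T"]]) / p$tau_dt
  d["f_T"] <- phi_r * (boltz(V, p$v_ft, p$k_ft) - state[["f_T"]]) / p$tau_ft
  # sympathetic shift of HCN activation, saturating at +/- s_hcn mV
  v_y_eff <- p$v_y + p$s_hcn * tanh(drive$sna - 1)
  d["y"] <- phi_r * (boltz(V, v_y_eff, p$k_y) - state[["y"]]) / p$tau_y
  d["n"] <- phi_r * (boltz(V, p$v_n, p$k_n) - state[["n"]]) / p$tau_n
  fca_inf <- p$km_fca / (p$km_fca + state[["Cai"]])
  d["f_Ca"] <- phi_r * (fca_inf - state[["f_Ca"]]) / p$tau_fca

  d["pka"] <- (drive$sna - state[["pka"]]) / p$tau_pka
  fv <- 96485 * p$vi
  d["Nai"] <- -1000 *
    (cur$i_bna + p$f_na_hcn * cur$i_hcn + 3 * cur$i_nak + 3 * cur$i_ncx) / fv
  d["Cai"] <- -p$f_cab * 1000 *
    (cur$i_cal + cur$i_cat + cur$i_bca + cur$i_pca - 2 * cur$i_ncx) /
    (2 * fv)

  if (any(!is.finite(d))) stop("non-finite derivative: parameter or state corruption")
  list(dstate = d, currents = cur)
}

# Direct call into the compiled core, for the R-vs-C consistency test.
sanc_rhs_compiled <- function(t, state, params, drive) {
  pv <- c(as_param_vector(params),
          setNames(c(drive$sna, drive$sna, drive$pna, drive$pna, 0, 0,
                     drive$bt, drive$lcr), sanc_drive_names()))
  res <- .Call(C_sanc_rhs, as.numeric(t),
               as.numeric(state[sanc_state_names()]), as.numeric(pv))
  names(res$dstate) <- sanc_state_names()
  names(res$out) <- c("i_cal", "i_cat", "i_hcn", "i_k", "i_kach", "i_nak",
                      "i_ncx", "i_bna", "i_bca", "i_pca", "i_net", "sna",
                      "pna")
  res
}
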
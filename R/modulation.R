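# Autonomic clamping protocol and circadian / vigilance state modulation.
#
# External interfaces use percentages, as printed in the seizure literature
# ("S_i from 20% to 220%"); internally every scaling factor is a fraction.
# Conversion happens at the boundary only (see build_grid() and the
# experiment config reader).

#' Seizure protocol (autonomic clamp schedule parameters)
#'
#' The six epileptic parameters plus phase durations.  During the ictal
#' phase, sympathetic and parasympathetic drive are clamped at
#' `S * (1 + Si)` and `P * (1 + Pi)`; after the seizure they ramp linearly
#' over `tau_p` seconds towards `S * (1 + Sp)` and `P * (1 + Pp)`.
#'
#' Defaults follow the standard event: 60 s preictal, 60 s ictal clamp
#' (`tau`), 45 s postictal ramp (`tau_p`), 75 s postictal steady phase —
#' a 4-minute event in total — with ictal sympathetic dominance
#' (`Si > Pi`), postictal parasympathetic dominance (`Pp > Pi`) and minimal
#' postictal sympathetic tone (`Sp = -1`, i.e. -100%).
#'
#' @param Si,Pi ictal scaling factors (fractions; 1.0 means +100%).
#' @param Sp,Pp postictal scaling factors (fractions).
#' @param tau ictal clamp duration (s).
#' @param tau_p postictal ramp duration (s).
#' @param t_pre,t_post preictal and postictal steady durations (s).
#' @return a `seizure_protocol` object.
#' @export
seizure_protocol <- function(Si = 1.0, Pi = 0.1, Sp = -1.0, Pp = 2.0,
                             tau = 60, tau_p = 45, t_pre = 60, t_post = 75) {
  if (any(c(tau, tau_p, t_pre, t_post) <= 0))
    stop("phase durations must be > 0")
  if (any(c(Si, Pi, Sp, Pp) < -1))
    stop("scaling factors below -100% would make an autonomic multiplier negative")
  structure(list(Si = Si, Pi = Pi, Sp = Sp, Pp = Pp, tau = tau,
                 tau_p = tau_p, t_pre = t_pre, t_post = t_post),
            class = "seizure_protocol")
}

protocol_duration <- function(protocol) {
  with(protocol, t_pre + tau + tau_p + t_post)
}

#' @export
print.seizure_protocol <- function(x, ...) {
  cat(sprintf("Autonomic clamp protocol: Si=%+.0f%% Pi=%+.0f%% Sp=%+.0f%% Pp=%+.0f%%\n",
              100 * x$Si, 100 * x$Pi, 100 * x$Sp, 100 * x$Pp))
  cat(sprintf("  phases (s): preictal %g | clamp %g | ramp %g | postictal %g  (total %g)\n",
              x$t_pre, x$tau, x$tau_p, x$t_post, protocol_duration(x)))
  invisible(x)
}

# Circadian waveforms.  Amplitudes are a declared modelling choice
# (config-exposed): parasympathetic tone varies +/-50% peaking at ZT6
# (daytime sleep in a nocturnal mouse), body temperature +/-1 degree C and
# HCN expression (LCR) +/-20%, both peaking at ZT18 (nighttime wakefulness).

#' @rdname circadian_context
#' @export
pna_waveform <- function(zt, amplitude = 0.5) {
  1 + amplitude * cos(2 * pi * (zt - 6) / 24)
}

#' @rdname circadian_context
#' @export
bt_waveform <- function(zt, amplitude = 1.0) {
  37 + amplitude * cos(2 * pi * (zt - 18) / 24)
}

#' @rdname circadian_context
#' @export
lcr_waveform <- function(zt, amplitude = 0.2) {
  1 + amplitude * cos(2 * pi * (zt - 18) / 24)
}

#' Circadian and vigilance state context
#'
#' Builds the zeitgeber-time dependent modulation of parasympathetic tone
#' (`pna_mult`), body temperature (`bt`) and local circadian HCN expression
#' (`lcr_mult`).  Under natural vigilance the animal sleeps at ZT6 (PNA
#' maximal, temperature and LCR minimal) and is awake at ZT18 (the
#' opposite); ZT12 is the sleep-wake transition where all three factors sit
#' at their mesor.  Sympathetic tone carries no circadian variation.
#'
#' Forced vigilance states decouple the sleep-wake cycle from circadian
#' time: the PNA waveform is phase-shifted by 12 h while temperature and
#' LCR keep their natural values.  Forced sleep at ZT6 and forced
#' wakefulness at ZT18 coincide with the natural state and are rejected as
#' undefined.
#'
#' The five canonical study states are (ZT18, natural) = awake,
#' (ZT12, natural) = transition, (ZT6, natural) = sleep,
#' (ZT18, forced_sleep) and (ZT6, forced_awake).
#'
#' @param zt zeitgeber time in hours (ZT0 = lights on; 12h:12h regime).
#' @param vigilance one of `"natural"`, `"forced_sleep"`, `"forced_awake"`.
#' @param amp_pna,amp_bt,amp_lcr waveform amplitudes (fraction, degrees C,
#'   fraction).
#' @return a `circadian_context` object with fields `zt`, `vigilance`,
#'   `pna_mult`, `bt`, `lcr_mult`.
#' @export
circadian_context <- function(zt, vigilance = c("natural", "forced_sleep",
                                                "forced_awake"),
                              amp_pna = 0.5, amp_bt = 1.0, amp_lcr = 0.2) {
  vigilance <- match.arg(vigilance)
  zt <- zt %% 24
  if (vigilance == "forced_sleep" && isTRUE(all.equal(zt, 6)))
    stop("forced sleep at ZT6 coincides with natural sleep (undefined)")
  if (vigilance == "forced_awake" && isTRUE(all.equal(zt, 18)))
    stop("forced wakefulness at ZT18 coincides with natural wakefulness (undefined)")
  pna_zt <- if (vigilance == "natural") zt else (zt + 12) %% 24
  structure(list(zt = zt, vigilance = vigilance,
                 pna_mult = pna_waveform(pna_zt, amp_pna),
                 bt = bt_waveform(zt, amp_bt),
                 lcr_mult = lcr_waveform(zt, amp_lcr)),
            class = "circadian_context")
}

#' @export
print.circadian_context <- function(x, ...) {
  cat(sprintf("Circadian context: ZT%g, %s | PNA x%.3f, BT %.2f C, LCR x%.3f\n",
              x$zt, x$vigilance, x$pna_mult, x$bt, x$lcr_mult))
  invisible(x)
}

#' The five canonical circadian/vigilance states
#'
#' @return named list of [circadian_context()] objects: `awake` (ZT18),
#'   `transition` (ZT12), `sleep` (ZT6), `forced_sleep` (ZT18),
#'   `forced_awake` (ZT6).
#' @export
canonical_states <- function() {
  list(awake = circadian_context(18, "natural"),
       transition = circadian_context(12, "natural"),
       sleep = circadian_context(6, "natural"),
       forced_sleep = circadian_context(18, "forced_sleep"),
       forced_awake = circadian_context(6, "forced_awake"))
}

#' Apply a subset of circadian factors
#'
#' Used to dissect the relative contribution of each circadian factor:
#' listed factors take their zeitgeber-time dependent (natural) values while
#' the others stay at the ZT12 reference (multiplier 1, 37 degrees C).  An
#' empty subset returns the reference context.
#'
#' @param zt zeitgeber time (h).
#' @param factors character subset of `c("PNA", "BT", "LCR")`.
#' @inheritParams circadian_context
#' @return a `circadian_context` object.
#' @export
apply_factor_subset <- function(zt, factors = character(0),
                                amp_pna = 0.5, amp_bt = 1.0, amp_lcr = 0.2) {
  bad <- setdiff(factors, c("PNA", "BT", "LCR"))
  if (length(bad)) stop("unknown circadian factor(s): ", paste(bad, collapse = ", "))
  structure(list(zt = zt %% 24, vigilance = "natural",
                 pna_mult = if ("PNA" %in% factors) pna_waveform(zt, amp_pna) else 1,
                 bt = if ("BT" %in% factors) bt_waveform(zt, amp_bt) else 37,
                 lcr_mult = if ("LCR" %in% factors) lcr_waveform(zt, amp_lcr) else 1),
            class = "circadian_context")
}

#' Build the time-dependent drive schedule of a seizure event
#'
#' Assembles the piecewise autonomic drive over
#' `[0, t_pre + tau + tau_p + t_post]`: baseline until seizure onset at
#' `t = t_pre`, a step to the clamped ictal values `1 + Si` (sympathetic)
#' and `pna_mult * (1 + Pi)` (parasympathetic) held for `tau` seconds, a
#' linear ramp over `tau_p` seconds to the postictal values `1 + Sp` and
#' `pna_mult * (1 + Pp)`, then constant.  Body temperature and LCR are
#' constant at the context values throughout.  The schedule is continuous
#' everywhere except the single step at seizure onset.
#'
#' @param protocol a [seizure_protocol()].
#' @param context a [circadian_context()] (defaults to the ZT12 transition
#'   state).
#' @return a `drive_schedule` object; call it via [drive_at()] or inspect
#'   `$segments` (one row per protocol segment with constant-or-linear
#'   drive endpoints).
#' @export
autonomic_clamp_schedule <- function(protocol,
                                     context = circadian_context(12, "natural")) {
  stopifnot(inherits(protocol, "seizure_protocol"))
  pm <- context$pna_mult
  with(protocol, {
    if (1 + Si < 0 || 1 + Sp < 0 || pm * (1 + Pi) < 0 || pm * (1 + Pp) < 0)
      stop("protocol drives an autonomic multiplier negative")
    t1 <- t_pre; t2 <- t_pre + tau; t3 <- t2 + tau_p; t4 <- t3 + t_post
    seg <- data.frame(
      phase = c("preictal", "ictal", "ramp", "postictal"),
      t0 = c(0, t1, t2, t3), t1 = c(t1, t2, t3, t4),
      sna0 = c(1, 1 + Si, 1 + Si, 1 + Sp),
      sna1 = c(1, 1 + Si, 1 + Sp, 1 + Sp),
      pna0 = pm * c(1, 1 + Pi, 1 + Pi, 1 + Pp),
      pna1 = pm * c(1, 1 + Pi, 1 + Pp, 1 + Pp))
    structure(list(segments = seg, protocol = protocol, context = context,
                   duration = t4, bt = context$bt, lcr = context$lcr_mult),
              class = "drive_schedule")
  })
}

#' Evaluate a drive schedule
#'
#' @param schedule a `drive_schedule` from [autonomic_clamp_schedule()].
#' @param t numeric vector of times (s) within the event.
#' @return data.frame with columns `t`, `sna`, `pna`, `bt`, `lcr`.  At the
#'   onset discontinuity the ictal (right-hand) value is returned.
#' @export
drive_at <- function(schedule, t) {
  seg <- schedule$segments
  # right-closed assignment so t == onset takes the ictal value
  idx <- findInterval(t, seg$t0, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  frac <- (t - seg$t0[idx]) / (seg$t1[idx] - seg$t0[idx])
  frac <- pmin(pmax(frac, 0), 1)
  data.frame(t = t,
             sna = seg$sna0[idx] + frac * (seg$sna1[idx] - seg$sna0[idx]),
             pna = seg$pna0[idx] + frac * (seg$pna1[idx] - seg$pna0[idx]),
             bt = schedule$bt, lcr = schedule$lcr)
}

#' @export
print.drive_schedule <- function(x, ...) {
  cat("Drive schedule over", x$duration, "s\n")
  print(x$segments, row.names = FALSE)
  invisible(x)
}
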
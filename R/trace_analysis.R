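# Action-potential detection, firing-rate measurement, and classification of
# firing windows as rhythmic (R), irregular (I) or no-firing (N).
#
# Default thresholds (all config-exposed): detection threshold -20 mV,
# refractory 20 ms, ISI coefficient-of-variation cutoff 0.15, burst-gap
# multiplier 3, sampling window 15 s, postictal settling delay 30 s, and a
# 30 BPM floor below which a window counts as no-firing.

#' Detect action potentials in a membrane-potential series
#'
#' One event per upward threshold crossing followed by a local maximum;
#' events closer than the refractory period are merged (the larger peak is
#' kept).
#'
#' @param v membrane potential series (mV), uniformly sampled.
#' @param dt sampling interval (s); must be <= 1 ms.
#' @param times optional explicit time grid (checked for uniformity).
#' @param threshold detection threshold (mV).
#' @param refractory minimum separation between events (s).
#' @return an `ap_train`: list with `spikes` (data.frame of `time`,
#'   `amplitude` = peak V in mV) and `isi` (s).
#' @export
detect_aps <- function(v, dt = NULL, times = NULL, threshold = -20,
                       refractory = 0.02) {
  if (is.null(dt)) {
    if (is.null(times)) stop("supply dt or times")
    dd <- diff(times)
    if (max(dd) - min(dd) > 1e-9 * stats::median(dd) + 1e-12)
      stop("non-uniform sampling")
    dt <- stats::median(dd)
  }
  if (dt > 0.001 + 1e-12) stop("sampling rate below 1 kHz")
  if (is.null(times)) times <- (seq_along(v) - 1) * dt
  above <- v >= threshold
  ups <- which(!above[-length(above)] & above[-1]) + 1L
  if (!length(ups)) return(new_ap_train(numeric(0), numeric(0)))
  downs <- which(above[-length(above)] & !above[-1])
  pk_t <- pk_a <- numeric(length(ups))
  for (j in seq_along(ups)) {
    lo <- ups[j]
    hi <- downs[downs >= lo][1]
    if (is.na(hi)) hi <- length(v)
    k <- lo + which.max(v[lo:hi]) - 1L
    # parabolic interpolation for sub-sample peak timing
    off <- 0
    if (k > 1L && k < length(v)) {
      den <- v[k - 1L] - 2 * v[k] + v[k + 1L]
      if (den < 0) off <- max(-0.5, min(0.5, 0.5 * (v[k - 1L] - v[k + 1L]) / den))
    }
    pk_t[j] <- times[k] + off * dt
    pk_a[j] <- v[k]
  }
  # merge events within the refractory period, keeping the larger peak
  keep_t <- keep_a <- numeric(0)
  for (j in seq_along(pk_t)) {
    if (length(keep_t) && pk_t[j] - keep_t[length(keep_t)] < refractory) {
      if (pk_a[j] > keep_a[length(keep_a)]) {
        keep_t[length(keep_t)] <- pk_t[j]; keep_a[length(keep_a)] <- pk_a[j]
      }
    } else {
      keep_t <- c(keep_t, pk_t[j]); keep_a <- c(keep_a, pk_a[j])
    }
  }
  new_ap_train(keep_t, keep_a)
}

new_ap_train <- function(time, amplitude) {
  structure(list(spikes = data.frame(time = time, amplitude = amplitude),
                 isi = diff(time)),
            class = "ap_train")
}

#' @export
print.ap_train <- function(x, ...) {
  n <- nrow(x$spikes)
  cat("AP train:", n, "spikes")
  if (n >= 2) cat(sprintf(", mean ISI %.4f s (%.0f BPM)",
                          mean(x$isi), 60 / mean(x$isi)))
  cat("\n")
  invisible(x)
}

#' Restrict an AP train to a time window
#'
#' @param train an `ap_train`.
#' @param window `c(start, end)` in seconds (inclusive).
#' @return an `ap_train` holding only the spikes inside the window.
#' @export
window_train <- function(train, window) {
  sel <- train$spikes$time >= window[1] & train$spikes$time <= window[2]
  new_ap_train(train$spikes$time[sel], train$spikes$amplitude[sel])
}

#' Firing rate over a window
#'
#' `60 / mean(ISI)` over the spikes falling in the window, in beats per
#' minute; 0 if fewer than two spikes fall in the window.
#'
#' @param train an `ap_train`.
#' @param window `c(start, end)` in seconds (defaults to the full train).
#' @return firing rate (BPM).
#' @export
firing_rate <- function(train, window = NULL) {
  w <- if (is.null(window)) train else window_train(train, window)
  if (nrow(w$spikes) < 2) return(0)
  60 / mean(w$isi)
}

#' Detect beat-to-beat amplitude alternans
#'
#' Flags a run of at least `min_beats` consecutive spikes whose peak
#' amplitudes alternate high/low with per-pair relative difference above
#' `rel_cut` (relative to the larger amplitude of the pair).  The reported
#' ratio is `(mean high - mean low) / mean high` over the longest
#' alternating run.
#'
#' @param train an `ap_train` (needs >= 4 spikes).
#' @param rel_cut relative amplitude-difference threshold.
#' @param min_beats minimum run length in beats.
#' @return list with `flag` (logical) and `ratio` (NA if no alternans).
#' @export
detect_alternans <- function(train, rel_cut = 0.05, min_beats = 4) {
  a <- train$spikes$amplitude
  if (length(a) < min_beats) return(list(flag = FALSE, ratio = NA_real_))
  d <- diff(a)
  rel <- abs(d) / pmax(abs(a[-1]), abs(a[-length(a)]))
  big <- rel > rel_cut & d != 0
  # longest run of spikes whose successive amplitude differences alternate
  # in sign, each difference exceeding the relative cutoff
  best <- run <- 1L
  best_start <- start <- 1L
  for (i in seq_along(d)) {
    if (big[i] && (run == 1L || sign(d[i]) == -sign(d[i - 1]))) {
      if (run == 1L) start <- i
      run <- run + 1L
    } else {
      run <- if (big[i]) 2L else 1L
      start <- i
    }
    if (run > best) { best <- run; best_start <- start }
  }
  if (best < min_beats) return(list(flag = FALSE, ratio = NA_real_))
  seg <- a[best_start:(best_start + best - 1)]
  hi <- mean(seg[seg >= stats::median(seg)])
  lo <- mean(seg[seg < stats::median(seg)])
  list(flag = TRUE, ratio = (hi - lo) / hi)
}

#' Burst structure of an AP train
#'
#' Bursts are delimited where an inter-spike interval exceeds `gap_mult`
#' times the median ISI (a proxy for the intra-burst ISI when spikes
#' cluster).  Burst frequency is the reciprocal of the mean inter-onset
#' interval and is defined only when at least two bursts exist.
#'
#' @param train an `ap_train` with >= 2 spikes.
#' @param gap_mult gap multiplier delimiting bursts.
#' @return list: `onsets` (s), `n_bursts`, `freq_hz` (NA + `freq_defined =
#'   FALSE` for a single burst), `spikes_per_burst`, `intra_fr_bpm`,
#'   `alternans` (from [detect_alternans()]).
#' @export
burst_metrics <- function(train, gap_mult = 3) {
  tt <- train$spikes$time
  if (length(tt) < 2) stop("burst metrics need at least 2 spikes")
  isi <- diff(tt)
  med <- stats::median(isi)
  gap <- isi > gap_mult * med
  onset_idx <- c(1L, which(gap) + 1L)
  onsets <- tt[onset_idx]
  sizes <- diff(c(onset_idx, length(tt) + 1L))
  intra <- isi[!gap]
  n_bursts <- length(onsets)
  freq <- if (n_bursts >= 2) 1 / mean(diff(onsets)) else NA_real_
  list(onsets = onsets, n_bursts = n_bursts, freq_hz = freq,
       freq_defined = n_bursts >= 2,
       spikes_per_burst = mean(sizes),
       intra_fr_bpm = if (length(intra)) 60 / mean(intra) else NA_real_,
       alternans = detect_alternans(train))
}

#' Classify a firing window as rhythmic, irregular or no-firing
#'
#' `N` if the window holds no spikes or the firing rate is below
#' `min_fr_bpm`; otherwise `I` if the ISI coefficient of variation exceeds
#' `cv_cut`, any ISI exceeds `gap_mult` times the median ISI (burst gaps),
#' or amplitude alternans is detected; otherwise `R`.
#'
#' @param train an `ap_train`.
#' @param window `c(start, end)` in seconds, at least 10 s long.
#' @param cv_cut ISI coefficient-of-variation cutoff.
#' @param gap_mult burst-gap multiplier.
#' @param min_fr_bpm firing-rate floor below which the window counts as N.
#' @return a `pattern_label`: list with `label` ("R"/"I"/"N"), `fr_bpm`,
#'   `window`.
#' @export
classify_pattern <- function(train, window = NULL, cv_cut = 0.15,
                             gap_mult = 3, min_fr_bpm = 30) {
  if (is.null(window)) {
    tt <- train$spikes$time
    window <- if (length(tt)) range(tt) else c(0, Inf)
  }
  if (is.finite(window[2]) && diff(window) < 10 - 1e-9)
    stop("classification window must be at least 10 s long")
  w <- window_train(train, window)
  fr <- firing_rate(w)
  # the no-firing floor counts events over the window, so a handful of
  # stray spikes in an otherwise silent window still reads N
  count_rate <- if (is.finite(diff(window))) {
    60 * nrow(w$spikes) / diff(window)
  } else fr
  lab <- if (nrow(w$spikes) == 0 || count_rate < min_fr_bpm) {
    "N"
  } else {
    cv <- if (length(w$isi) >= 2) stats::sd(w$isi) / mean(w$isi) else 0
    gappy <- any(w$isi > gap_mult * stats::median(w$isi))
    alt <- detect_alternans(w)$flag
    if (cv > cv_cut || gappy || alt) "I" else "R"
  }
  structure(list(label = lab, fr_bpm = fr, window = window),
            class = "pattern_label")
}

#' @export
print.pattern_label <- function(x, ...) {
  cat(sprintf("%s (%.0f BPM over [%.1f, %.1f] s)\n",
              x$label, x$fr_bpm, x$window[1], x$window[2]))
  invisible(x)
}

#' Sample the ictal or postictal firing rate of an event trace
#'
#' The ictal window is the last `w_s` seconds of the clamp phase; the
#' postictal window starts `settle_s` seconds after the end of the ramp (so
#' transient post-ramp arrest has cleared) and lasts `w_s` seconds.
#'
#' @param trace a `sanc_trace` from [simulate_event()] (protocol metadata
#'   required).
#' @param phase `"ictal"` or `"postictal"`.
#' @param w_s window length (s).
#' @param settle_s postictal settling delay (s).
#' @param ... thresholds forwarded to [classify_pattern()].
#' @return a `pattern_label` (with `fr_bpm`).
#' @export
sample_phase_fr <- function(trace, phase = c("ictal", "postictal"),
                            w_s = 15, settle_s = 30, ...) {
  phase <- match.arg(phase)
  pr <- trace$protocol
  if (is.null(pr)) stop("trace carries no protocol metadata")
  window <- if (phase == "ictal") {
    c(pr$t_pre + pr$tau - w_s, pr$t_pre + pr$tau)
  } else {
    t0 <- pr$t_pre + pr$tau + pr$tau_p + settle_s
    c(t0, t0 + w_s)
  }
  train <- detect_aps(trace$V, dt = trace$dt, times = trace$time)
  classify_pattern(train, window, ...)
}
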
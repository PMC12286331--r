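# Synthetic membrane-potential traces with known ground truth.  These
# emulate the firing phenotypes the analysis stages must recognise (regular
# pacing, clustered bursting, alternans, quiescence) without the ODE model,
# so detector and classifier can be validated against designed labels.

#' Specification of a synthetic trace
#'
#' @param pattern one of `"regular"`, `"bursting"`, `"quiescent"`,
#'   `"alternans"`, `"jittered"`.
#' @param fr_bpm firing rate (regular/alternans/jittered) or intra-burst
#'   rate (bursting), BPM.
#' @param burst_hz burst-onset frequency (Hz; bursting only).
#' @param spikes_per_burst spikes per burst (bursting only).
#' @param jitter_cv ISI coefficient of variation (jittered only).
#' @param amp_high,amp_low peak potentials (mV); alternans alternates
#'   between the two, other patterns use `amp_high`.
#' @param duration_s trace duration (s).
#' @param sample_hz sampling rate (Hz, >= 1000).
#' @param seed integer; fully determines the output.
#' @return a `trace_spec` list.
#' @export
trace_spec <- function(pattern = c("regular", "bursting", "quiescent",
                                   "alternans", "jittered"),
                       fr_bpm = 400, burst_hz = 0.35, spikes_per_burst = 6,
                       jitter_cv = 0.02, amp_high = 20, amp_low = 10,
                       duration_s = 30, sample_hz = 1000, seed = 1L) {
  pattern <- match.arg(pattern)
  if (sample_hz < 1000) stop("sample_hz must be >= 1000")
  structure(list(pattern = pattern, fr_bpm = fr_bpm, burst_hz = burst_hz,
                 spikes_per_burst = spikes_per_burst, jitter_cv = jitter_cv,
                 amp_high = amp_high, amp_low = amp_low,
                 duration_s = duration_s, sample_hz = sample_hz,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

# Stereotyped AP waveform: raised-cosine upstroke from the -60 mV baseline
# to the peak over 4 ms, exponential repolarisation (tau 8 ms), truncated at
# 40 ms, well separated from the -20 mV detection threshold.
ap_kernel <- function(peak, sample_hz, baseline = -60, rise_s = 0.004,
                      tau_s = 0.008, width_s = 0.04) {
  t <- seq(0, width_s, by = 1 / sample_hz)
  up <- t <= rise_s
  w <- numeric(length(t))
  w[up] <- 0.5 * (1 - cos(pi * t[up] / rise_s))
  w[!up] <- exp(-(t[!up] - rise_s) / tau_s)
  baseline + (peak - baseline) * w
}

spike_times_for <- function(spec) {
  isi <- 60 / spec$fr_bpm
  switch(spec$pattern,
    quiescent = numeric(0),
    regular = ,
    alternans = 0.05 + (seq_len(floor((spec$duration_s - 0.1) / isi) + 1) - 1) * isi,
    jittered = {
      n <- ceiling(spec$duration_s / isi) + 10
      gaps <- isi * (1 + spec$jitter_cv * rnorm(n))
      gaps <- pmax(gaps, 0.045)  # keep APs non-overlapping
      tt <- cumsum(gaps)
      tt[tt < spec$duration_s - 0.05]
    },
    bursting = {
      onsets <- seq(0.5, spec$duration_s - 0.05, by = 1 / spec$burst_hz)
      tt <- as.vector(outer(seq_len(spec$spikes_per_burst) - 1, onsets,
                            function(k, o) o + k * isi))
      sort(tt[tt < spec$duration_s - 0.05])
    })
}

#' Generate a synthetic membrane-potential trace
#'
#' Spike times are drawn per the pattern; each spike is rendered as a
#' stereotyped AP waveform on a -60 mV baseline.  The designed spike train
#' and pattern label are returned alongside the series as ground truth.
#'
#' @param spec a [trace_spec()].
#' @return list: `time` (s), `V` (mV), `truth` (an `ap_train` of designed
#'   spike times/amplitudes), `label` (designed "R"/"I"/"N"), `spec`.
#' @export
generate_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  set.seed(spec$seed)
  tt <- spike_times_for(spec)
  if (length(tt) >= 2 && min(diff(tt)) < 0.04)
    stop("overlapping APs: firing rate exceeds the AP waveform width")
  dt <- 1 / spec$sample_hz
  time <- seq(0, spec$duration_s, by = dt)
  v <- rep(-60, length(time))
  amps <- if (spec$pattern == "alternans") {
    rep_len(c(spec$amp_high, spec$amp_low), length(tt))
  } else rep_len(spec$amp_high, length(tt))
  for (j in seq_along(tt)) {
    ker <- ap_kernel(amps[j], spec$sample_hz)
    i0 <- round(tt[j] / dt) + 1L
    idx <- i0:min(i0 + length(ker) - 1L, length(v))
    seg <- ker[seq_along(idx)]
    v[idx] <- pmax(v[idx], seg)
  }
  label <- switch(spec$pattern,
                  quiescent = "N",
                  bursting = "I",
                  alternans = "I",
                  regular = ,
                  jittered = "R")
  list(time = time, V = v, truth = new_ap_train(tt, amps), label = label,
       spec = spec)
}

#' Degrade a synthetic trace
#'
#' Re-renders the trace with multiplicative ISI jitter and adds Gaussian
#' baseline noise, deterministically under the given seed.  Spike count is
#' preserved.
#'
#' @param trace output of [generate_trace()].
#' @param jitter_cv coefficient of variation of the ISI jitter.
#' @param noise_mv standard deviation of additive Gaussian noise (mV).
#' @param seed integer seed.
#' @return same structure as [generate_trace()] (ground truth updated to
#'   the jittered spike times).
#' @export
degrade <- function(trace, jitter_cv = 0.02, noise_mv = 0, seed = 1L) {
  set.seed(as.integer(seed))
  tt <- trace$truth$spikes$time
  amps <- trace$truth$spikes$amplitude
  spec <- trace$spec
  dt <- 1 / spec$sample_hz
  if (jitter_cv > 0 && length(tt) >= 2) {
    gaps <- diff(c(0, tt))
    gaps <- pmax(gaps * (1 + jitter_cv * rnorm(length(gaps))), 0.045)
    tt <- cumsum(gaps)
    keep <- tt <= spec$duration_s - 0.04
    tt <- tt[keep]; amps <- amps[keep]
  }
  v <- rep(-60, length(trace$time))
  for (j in seq_along(tt)) {
    ker <- ap_kernel(amps[j], spec$sample_hz)
    i0 <- round(tt[j] / dt) + 1L
    idx <- i0:min(i0 + length(ker) - 1L, length(v))
    v[idx] <- pmax(v[idx], ker[seq_along(idx)])
  }
  if (noise_mv > 0) v <- v + rnorm(length(v), sd = noise_mv)
  list(time = trace$time, V = v, truth = new_ap_train(tt, amps),
       label = trace$label, spec = spec)
}

#' Reproducible labelled suite for classifier validation
#'
#' A mixture over all five patterns with parameters drawn from realistic
#' murine ranges (regular/jittered 300-600 BPM; bursts at 0.1-0.4 Hz with
#' 4-10 spikes; alternans with > 10% amplitude alternation).  The same seed
#' always yields the identical suite.
#'
#' @param n_cases number of cases.
#' @param seed integer seed.
#' @param duration_s per-case duration (s).
#' @return list of [trace_spec()] objects with designed labels attached as
#'   attribute `labels`.
#' @export
classifier_suite <- function(n_cases = 200, seed = 1L, duration_s = 30) {
  stopifnot(n_cases >= 1)
  set.seed(as.integer(seed))
  patterns <- sample(c("regular", "bursting", "quiescent", "alternans",
                       "jittered"), n_cases, replace = TRUE)
  specs <- vector("list", n_cases)
  for (i in seq_len(n_cases)) {
    specs[[i]] <- trace_spec(
      pattern = patterns[i],
      fr_bpm = runif(1, 300, 600),
      burst_hz = runif(1, 0.1, 0.4),
      spikes_per_burst = sample(4:10, 1),
      jitter_cv = runif(1, 0.01, 0.05),
      amp_high = runif(1, 15, 30),
      amp_low = runif(1, 5, 12),
      duration_s = duration_s,
      seed = sample.int(1e6, 1))
  }
  labels <- vapply(specs, function(s) switch(s$pattern, quiescent = "N",
                                             bursting = "I", alternans = "I",
                                             "R"), character(1))
  structure(specs, labels = labels, class = "classifier_suite")
}

#' Run the pattern classifier over a suite
#'
#' @param suite a [classifier_suite()].
#' @param jitter_cv,noise_mv optional degradation applied to every case.
#' @param seed seed for the degradation draws.
#' @return list with `accuracy`, `predicted`, `truth`.
#' @export
evaluate_classifier <- function(suite, jitter_cv = 0, noise_mv = 0,
                                seed = 1L) {
  truth <- attr(suite, "labels")
  pred <- character(length(suite))
  for (i in seq_along(suite)) {
    tr <- generate_trace(suite[[i]])
    if (jitter_cv > 0 || noise_mv > 0)
      tr <- degrade(tr, jitter_cv = jitter_cv, noise_mv = noise_mv,
                    seed = seed + i)
    train <- detect_aps(tr$V, dt = 1 / suite[[i]]$sample_hz)
    pred[i] <- classify_pattern(train,
                                c(0, suite[[i]]$duration_s))$label
  }
  list(accuracy = mean(pred == truth), predicted = pred, truth = truth)
}
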
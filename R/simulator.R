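# Stiff integration of the model under a drive schedule.  Each protocol
# segment is integrated separately so the onset step is a solver breakpoint,
# not a surprise; output is sampled uniformly (1 kHz by default),
# independent of the solver's internal steps.

current_names <- function() {
  c("i_cal", "i_cat", "i_hcn", "i_k", "i_kach", "i_nak", "i_ncx", "i_bna",
    "i_bca", "i_pca", "i_net", "sna_c", "pna_c")
}

# One constant-or-ramp segment through the compiled core.
integrate_segment <- function(y0, times, params, sna0, sna1, pna0, pna1,
                              seg_t0, seg_t1, bt, lcr,
                              rtol = 1e-6, atol = 1e-8, hmax = 0.02,
                              currents = TRUE) {
  pv <- c(as_param_vector(params),
          setNames(c(sna0, sna1, pna0, pna1, seg_t0, seg_t1, bt, lcr),
                   sanc_drive_names()))
  out <- deSolve::ode(
    y = setNames(as.numeric(y0[sanc_state_names()]), sanc_state_names()),
    times = times, func = "sanc_derivs", parms = pv,
    dllname = "sancpace", initfunc = "sanc_initmod",
    nout = length(current_names()), outnames = current_names(),
    method = "lsoda", rtol = rtol, atol = atol, hmax = hmax,
    maxsteps = 50000)
  attr_ds <- attributes(out)$istate
  if (!is.null(attr_ds) && attr_ds[1] < 0)
    stop(sprintf("solver failure in segment [%g, %g] s (istate %d)",
                 seg_t0, seg_t1, attr_ds[1]))
  if (nrow(out) < length(times))
    stop(sprintf("solver failure in segment [%g, %g] s at t = %g s",
                 seg_t0, seg_t1, out[nrow(out), "time"]))
  unclass(out)
}

#' Integrate to a steady state under constant drive
#'
#' Runs the model forward under constant drive until it settles on its
#' limit cycle (consecutive inter-spike intervals agree to 0.1%) or, if
#' non-firing, until the membrane is flat (|dV/dt| < 1 mV/s over the last
#' 5 s).  Fails with an error carrying the last state if neither criterion
#' is met within `max_s` seconds.
#'
#' @param params a `sanc_params` object.
#' @param drive a constant [drive_input()].
#' @param max_s maximum simulated duration (s).
#' @param init initial state (defaults to [default_state()]).
#' @param dt output sampling interval (s).
#' @return named steady state vector with attributes `firing` (logical),
#'   `fr_bpm`, `period_s`.
#' @export
run_to_steady <- function(params, drive = drive_input(), max_s = 60,
                          init = default_state(), dt = 0.001) {
  chunk <- 15
  y <- init
  t0 <- 0
  while (t0 < max_s) {
    t1 <- min(t0 + chunk, max_s)
    times <- seq(0, t1 - t0, by = dt)
    out <- integrate_segment(y, times, params,
                             drive$sna, drive$sna, drive$pna, drive$pna,
                             0, 0, drive$bt, drive$lcr)
    y <- out[nrow(out), sanc_state_names()]
    v <- out[, "V"]; tt <- out[, "time"]
    train <- detect_aps(v, dt = dt)
    if (nrow(train$spikes) >= 21) {
      isi <- diff(train$spikes$time)
      recent <- mean(utils::tail(isi, 10))
      prev <- mean(utils::tail(isi, 20)[1:10])
      if (abs(recent - prev) / prev < 0.001) {
        return(structure(y, firing = TRUE, fr_bpm = 60 / recent,
                         period_s = recent))
      }
    } else if (nrow(train$spikes) == 0) {
      sel <- tt >= (t1 - t0) - 5
      dv <- abs(diff(v[sel])) / dt
      if (length(dv) && max(dv) < 1) {
        return(structure(y, firing = FALSE, fr_bpm = 0, period_s = NA_real_))
      }
    }
    t0 <- t1
  }
  cond <- structure(
    class = c("sanc_no_convergence", "error", "condition"),
    list(message = sprintf("no steady state within %g s", max_s),
         call = sys.call(-1), last_state = y))
  stop(cond)
}

preictal_drive <- function(context) {
  drive_input(sna = 1, pna = context$pna_mult, bt = context$bt,
              lcr = context$lcr_mult)
}

#' Simulate a full seizure event
#'
#' Equilibrates the cell under the event's circadian context, then
#' integrates through the preictal, ictal clamp, postictal ramp and
#' postictal steady phases of the autonomic clamping protocol with a
#' stiff-capable adaptive integrator (lsoda; rtol 1e-6, atol 1e-8).
#' Segments are integrated separately so the clamp-onset step is an exact
#' breakpoint.
#'
#' @param protocol a [seizure_protocol()].
#' @param context a [circadian_context()].
#' @param params a `sanc_params` object.
#' @param dt output sampling interval (s; 1 kHz default).
#' @param rtol,atol solver tolerances.
#' @param init_state optional pre-equilibrated preictal state (skips the
#'   equilibration run; used by map sweeps which share one steady state per
#'   context).
#' @param preictal optional precomputed preictal segment (internal, from
#'   [run_map()]).
#' @return a `sanc_trace` object: uniform time grid, membrane potential,
#'   intracellular Na and Ca, per-current series, the analytic drive series,
#'   and protocol/context metadata.
#' @export
simulate_event <- function(protocol, context = circadian_context(12, "natural"),
                           params = build_default_params(), dt = 0.001,
                           rtol = 1e-6, atol = 1e-8,
                           init_state = NULL, preictal = NULL) {
  schedule <- autonomic_clamp_schedule(protocol, context)
  seg <- schedule$segments
  if (is.null(init_state)) {
    init_state <- run_to_steady(params, preictal_drive(context), max_s = 90)
  }
  pieces <- vector("list", nrow(seg))
  y <- init_state
  for (k in seq_len(nrow(seg))) {
    if (k == 1 && !is.null(preictal)) {
      pieces[[1]] <- preictal
      y <- preictal[nrow(preictal), sanc_state_names()]
      next
    }
    times <- seq(seg$t0[k], seg$t1[k], by = dt)
    out <- tryCatch(
      integrate_segment(y, times, params, seg$sna0[k], seg$sna1[k],
                        seg$pna0[k], seg$pna1[k], seg$t0[k], seg$t1[k],
                        schedule$bt, schedule$lcr, rtol = rtol, atol = atol),
      error = function(e) stop(sprintf("phase '%s': %s", seg$phase[k],
                                       conditionMessage(e)), call. = FALSE))
    y <- out[nrow(out), sanc_state_names()]
    pieces[[k]] <- out
  }
  # segments share boundary rows; keep the later segment's row so the
  # recorded drive at the onset discontinuity is the ictal (right-limit)
  # value, matching drive_at()
  for (k in seq_along(pieces)[-length(pieces)])
    pieces[[k]] <- pieces[[k]][-nrow(pieces[[k]]), , drop = FALSE]
  full <- do.call(rbind, pieces)
  dr <- drive_at(schedule, full[, "time"])
  structure(list(
    time = full[, "time"],
    V = full[, "V"], Nai = full[, "Nai"], Cai = full[, "Cai"],
    states = full[, sanc_state_names(), drop = FALSE],
    currents = full[, setdiff(current_names(), c("sna_c", "pna_c")),
                    drop = FALSE],
    sna = dr$sna, pna = dr$pna, bt = dr$bt, lcr = dr$lcr,
    sna_solver = full[, "sna_c"], pna_solver = full[, "pna_c"],
    dt = dt, protocol = protocol, context = context, schedule = schedule,
    params = params, rtol = rtol, atol = atol),
    class = "sanc_trace")
}

#' @export
print.sanc_trace <- function(x, ...) {
  cat(sprintf("SANC trace: %.1f s at %.0f Hz (%d samples)\n",
              max(x$time), 1 / x$dt, length(x$time)))
  print(x$protocol)
  print(x$context)
  invisible(x)
}

#' Write a trace to CSV (+ JSON metadata sidecar)
#'
#' Columnar text with header `time_s,V_mV,Nai_mM,Cai_mM,<currents>,sna,pna,
#' bt_C,lcr`; protocol and context go to `<path>.json`.  The round trip is
#' float64-exact.
#'
#' @param trace a `sanc_trace`.
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  if (!length(trace$time)) stop("empty trace")
  df <- data.table::data.table(
    time_s = trace$time, V_mV = trace$V, Nai_mM = trace$Nai,
    Cai_mM = trace$Cai)
  if (!is.null(trace$currents)) df <- cbind(df, trace$currents)
  df$sna <- trace$sna; df$pna <- trace$pna
  df$bt_C <- rep_len(trace$bt, length(trace$time))
  df$lcr <- rep_len(trace$lcr, length(trace$time))
  # 17 significant digits guarantee an exact double round trip
  chr <- data.table::as.data.table(lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col))
  data.table::fwrite(chr, path, quote = FALSE)
  meta <- list(protocol = unclass(trace$protocol),
               context = unclass(trace$context),
               dt = trace$dt, rtol = trace$rtol, atol = trace$atol)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV file path.
#' @return a `sanc_trace` (metadata-free, with a warning, if the JSON
#'   sidecar is missing).
#' @export
read_trace <- function(path) {
  df <- data.table::fread(path)
  if (!nrow(df)) stop("empty trace file: ", path)
  need <- c("time_s", "V_mV", "Nai_mM", "Cai_mM", "sna", "pna", "bt_C", "lcr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed trace file ", path, ": header lacks column(s) ",
         paste(miss, collapse = ", "))
  meta_path <- paste0(path, ".json")
  protocol <- context <- NULL
  dt <- stats::median(diff(df$time_s))
  rtol <- atol <- NA_real_
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    protocol <- do.call(seizure_protocol, meta$protocol[
      c("Si", "Pi", "Sp", "Pp", "tau", "tau_p", "t_pre", "t_post")])
    context <- circadian_context(meta$context$zt, meta$context$vigilance)
    dt <- meta$dt; rtol <- meta$rtol; atol <- meta$atol
  } else {
    warning("metadata sidecar not found (", meta_path,
            "); returning a metadata-free trace")
  }
  cur_cols <- intersect(setdiff(current_names(), c("sna_c", "pna_c")),
                        names(df))
  structure(list(
    time = df$time_s, V = df$V_mV, Nai = df$Nai_mM, Cai = df$Cai_mM,
    states = NULL,
    currents = if (length(cur_cols)) as.matrix(df[, cur_cols, with = FALSE]),
    sna = df$sna, pna = df$pna, bt = df$bt_C[1], lcr = df$lcr[1],
    dt = dt, protocol = protocol, context = context, params = NULL,
    rtol = rtol, atol = atol),
    class = "sanc_trace")
}
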
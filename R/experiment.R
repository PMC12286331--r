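# Experiment orchestration: named pipelines over the simulator and the
# analysis stages, configured from YAML/JSON, with schema validation and a
# provenance stamp.  The numbered scripts under analysis/ are thin drivers
# over these functions.

experiment_names <- function() {
  c("fig_traces", "fig_maps", "circadian_dissection", "custom")
}

config_schema <- function() {
  list(
    experiment = experiment_names(),
    protocol = c("Si_pct", "Pi_pct", "Sp_pct", "Pp_pct", "tau_s", "tau_p_s",
                 "t_pre_s", "t_post_s"),
    context = c("zt", "vigilance"),
    grid = c("map_type", "n_per_axis"),
    analysis = c("threshold_mv", "refractory_s", "cv_cut", "gap_mult",
                 "w_s", "settle_s", "min_fr_bpm"),
    out_dir = NULL)
}

#' Validate an experiment configuration file
#'
#' Configurations are YAML (or JSON) with blocks `experiment`, `protocol`
#' (percent fields, as printed: `Si_pct`, `Pi_pct`, `Sp_pct`, `Pp_pct`,
#' durations in seconds), `context` (`zt`, `vigilance`), `grid`
#' (`map_type`, `n_per_axis`), `analysis` (classifier thresholds) and
#' `out_dir`.  Unknown keys are rejected by name.
#'
#' @param path configuration file path.
#' @return character vector of problems; empty if valid.
#' @export
validate_config <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path),
                  error = function(e) conditionMessage(e))
  if (is.character(cfg)) return(paste("unparseable config:", cfg))
  schema <- config_schema()
  probs <- character(0)
  bad <- setdiff(names(cfg), names(schema))
  if (length(bad)) probs <- c(probs, paste("unknown top-level key(s):",
                                           paste(bad, collapse = ", ")))
  for (blk in intersect(names(cfg), c("protocol", "context", "grid", "analysis"))) {
    extra <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(extra))
      probs <- c(probs, paste0("unknown key(s) in '", blk, "': ",
                               paste(extra, collapse = ", ")))
  }
  if (!is.null(cfg$experiment) && !cfg$experiment %in% experiment_names())
    probs <- c(probs, paste("unknown experiment:", cfg$experiment))
  if (!is.null(cfg$context$vigilance) &&
      !cfg$context$vigilance %in% c("natural", "forced_sleep", "forced_awake"))
    probs <- c(probs, paste("unknown vigilance state:", cfg$context$vigilance))
  probs
}

config_protocol <- function(blk) {
  if (is.null(blk)) return(seizure_protocol())
  pct <- c(Si = "Si_pct", Pi = "Pi_pct", Sp = "Sp_pct", Pp = "Pp_pct")
  dur <- c(tau = "tau_s", tau_p = "tau_p_s", t_pre = "t_pre_s",
           t_post = "t_post_s")
  args <- list()
  for (nm in names(pct))
    if (!is.null(blk[[pct[[nm]]]])) args[[nm]] <- blk[[pct[[nm]]]] / 100
  for (nm in names(dur))
    if (!is.null(blk[[dur[[nm]]]])) args[[nm]] <- blk[[dur[[nm]]]]
  do.call(seizure_protocol, args)
}

config_context <- function(blk) {
  if (is.null(blk)) return(circadian_context(12, "natural"))
  circadian_context(if (is.null(blk$zt)) 12 else blk$zt,
                    if (is.null(blk$vigilance)) "natural" else blk$vigilance)
}

#' Provenance record
#'
#' Captures what reproduction needs: package and R versions, solver
#' tolerances, and an md5 hash of the (serialised) parameter set.  Stable
#' across reruns of the same configuration.
#'
#' @param params a `sanc_params`.
#' @param rtol,atol solver tolerances in force.
#' @return named list.
#' @export
version_stamp <- function(params = build_default_params(),
                          rtol = 1e-6, atol = 1e-8) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_params(params, tmp)
  list(package = "sancpace",
       version = as.character(packageVersion("sancpace")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       param_md5 = unname(tools::md5sum(tmp)),
       rtol = rtol, atol = atol)
}

#' Run a named experiment
#'
#' Executes one of the standard pipelines and writes its artifacts under
#' `out_dir`:
#' \describe{
#'   \item{fig_traces}{nine seizure events sampling a 3x3 grid of
#'     (`S_i`, `P_p`) with `P_i` = 10% and `S_p` = -100%; writes each trace
#'     plus a summary of (ictal, postictal) labels and region ids.}
#'   \item{fig_maps}{one ictal and one joint map at the configured context
#'     and grid resolution.}
#'   \item{circadian_dissection}{the configured protocol run under each
#'     single circadian factor (\{PNA\}, \{BT\}, \{LCR\}) and the full
#'     natural context at the configured ZT.}
#'   \item{custom}{a single event under the configured protocol/context.}
#' }
#'
#' @param config path to a YAML/JSON config, or an equivalent named list.
#' @param params a `sanc_params`.
#' @param quiet suppress progress notes.
#' @return the summary list, invisibly; artifacts land in `out_dir`.
#' @export
run_experiment <- function(config, params = build_default_params(),
                           quiet = TRUE) {
  if (is.character(config)) {
    probs <- validate_config(config)
    if (length(probs)) stop("invalid config: ", paste(probs, collapse = "; "))
    cfg <- yaml::read_yaml(config)
  } else cfg <- config
  out_dir <- if (is.null(cfg$out_dir)) tempfile("experiment") else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  context <- config_context(cfg$context)
  protocol <- config_protocol(cfg$protocol)
  exp_name <- if (is.null(cfg$experiment)) "custom" else cfg$experiment

  summary <- list(experiment = exp_name, stamp = version_stamp(params))
  if (exp_name == "fig_traces") {
    si <- c(0.4, 1.2, 2.0); pp <- c(0.8, 2.0, 3.8)
    rows <- list()
    steady <- run_to_steady(params, preictal_drive(context), max_s = 90)
    for (a in si) for (b in pp) {
      prot <- seizure_protocol(Si = a, Pi = 0.1, Sp = -1, Pp = b)
      tr <- simulate_event(prot, context, params, init_state = steady)
      li <- sample_phase_fr(tr, "ictal"); lp <- sample_phase_fr(tr, "postictal")
      id <- segment_regions(li$label, lp$label)
      f <- file.path(out_dir, sprintf("trace_Si%03.0f_Pp%03.0f.csv",
                                      100 * a, 100 * b))
      write_trace(tr, f)
      rows[[length(rows) + 1]] <- data.frame(
        Si_pct = 100 * a, Pp_pct = 100 * b, ictal = li$label,
        postictal = lp$label, region = id, ictal_fr = li$fr_bpm,
        postictal_fr = lp$fr_bpm)
      if (!quiet) message("trace Si=", 100 * a, "% Pp=", 100 * b, "% -> region ", id)
    }
    summary$traces <- do.call(rbind, rows)
    data.table::fwrite(summary$traces, file.path(out_dir, "summary.csv"))
  } else if (exp_name == "fig_maps") {
    n <- if (is.null(cfg$grid$n_per_axis)) 8 else cfg$grid$n_per_axis
    for (mt in c("ictal", "postictal")) {
      m <- run_map(build_grid(mt, n), context, params, quiet = quiet)
      write_map(m, file.path(out_dir, mt))
      summary[[paste0(mt, "_areas")]] <- region_areas(m)
    }
  } else if (exp_name == "circadian_dissection") {
    zt <- context$zt
    ctxs <- list(PNA = apply_factor_subset(zt, "PNA"),
                 BT = apply_factor_subset(zt, "BT"),
                 LCR = apply_factor_subset(zt, "LCR"),
                 full = circadian_context(zt, "natural"))
    rows <- list()
    for (nm in names(ctxs)) {
      tr <- simulate_event(protocol, ctxs[[nm]], params)
      li <- sample_phase_fr(tr, "ictal"); lp <- sample_phase_fr(tr, "postictal")
      rows[[nm]] <- data.frame(factors = nm, ictal = li$label,
                               postictal = lp$label,
                               ictal_fr = li$fr_bpm, postictal_fr = lp$fr_bpm)
    }
    summary$dissection <- do.call(rbind, rows)
    data.table::fwrite(summary$dissection, file.path(out_dir, "dissection.csv"))
  } else {
    tr <- simulate_event(protocol, context, params)
    li <- sample_phase_fr(tr, "ictal"); lp <- sample_phase_fr(tr, "postictal")
    pre_fr <- firing_rate(detect_aps(tr$V, dt = tr$dt),
                          c(protocol$t_pre - 15, protocol$t_pre))
    write_trace(tr, file.path(out_dir, "trace.csv"))
    summary$result <- data.frame(preictal_fr = pre_fr, ictal = li$label,
                                 postictal = lp$label, ictal_fr = li$fr_bpm,
                                 postictal_fr = lp$fr_bpm,
                                 region = segment_regions(li$label, lp$label))
    data.table::fwrite(summary$result, file.path(out_dir, "summary.csv"))
  }
  jsonlite::write_json(summary$stamp, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
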
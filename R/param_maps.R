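# Two-dimensional parameter-space maps of seizure outcomes and the
# nine-region ictal-by-postictal taxonomy.
#
# Axis values are percentages, as printed in the protocol literature; they
# are converted to fractional scaling factors at the simulation boundary.
# Grids use n evenly spaced values spanning the printed ranges inclusive
# (40 per axis for the full map); the printed step sizes are arithmetically
# inconsistent with 40 points on the sympathetic axis, so even spacing over
# the printed span is the declared construction.

#' Build a sweep grid
#'
#' Ictal maps vary the ictal sympathetic scaling `S_i` over 20-220% against
#' the ictal parasympathetic scaling `P_i` over -20-40%.  Ictal-postictal
#' (joint) maps vary `S_i` over 20-220% against the postictal
#' parasympathetic scaling `P_p` over 60-400%, with `P_i` fixed at 10% and
#' the postictal sympathetic scaling `S_p` fixed at -100%.
#'
#' @param map_type `"ictal"` or `"postictal"`.
#' @param n_per_axis grid resolution per axis (>= 2; 40 for the full map).
#' @return a `parameter_grid`: axis names and percent values, map type, and
#'   fixed protocol percentages.
#' @export
build_grid <- function(map_type = c("ictal", "postictal"), n_per_axis = 8) {
  map_type <- match.arg(map_type)
  stopifnot(n_per_axis >= 2)
  si <- seq(20, 220, length.out = n_per_axis)
  if (map_type == "ictal") {
    axes <- list(Si_pct = si, Pi_pct = seq(-20, 40, length.out = n_per_axis))
    fixed <- c(Sp_pct = -100, Pp_pct = 200)
  } else {
    axes <- list(Si_pct = si, Pp_pct = seq(60, 400, length.out = n_per_axis))
    fixed <- c(Pi_pct = 10, Sp_pct = -100)
  }
  structure(list(axes = axes, map_type = map_type, fixed = fixed,
                 n_simulations = prod(lengths(axes))),
            class = "parameter_grid")
}

#' @export
print.parameter_grid <- function(x, ...) {
  cat(sprintf("%s parameter grid: %s (%d x %d = %d simulations)\n",
              x$map_type, paste(names(x$axes), collapse = " x "),
              lengths(x$axes)[1], lengths(x$axes)[2], x$n_simulations))
  invisible(x)
}

grid_protocol <- function(grid, i, j) {
  a <- grid$axes
  pct <- c(setNames(a[[1]][i], names(a)[1]), setNames(a[[2]][j], names(a)[2]),
           grid$fixed)
  seizure_protocol(Si = pct[["Si_pct"]] / 100, Pi = pct[["Pi_pct"]] / 100,
                   Sp = pct[["Sp_pct"]] / 100, Pp = pct[["Pp_pct"]] / 100)
}

#' Region id of an (ictal, postictal) label pair
#'
#' The joint taxonomy crosses the ictal and postictal pattern labels:
#' `id = 3 * rank(ictal) + rank(postictal) + 1` with rank R = 0, I = 1,
#' N = 2, so region 1 is rhythmic in both phases, 5 is irregular-irregular
#' (oscillatory events) and 9 is no-firing in both (asystolic events).
#' Rows 1-3 / 4-6 / 7-9 share the ictal label; columns 1,4,7 / 2,5,8 /
#' 3,6,9 share the postictal label.  The map is a bijection
#' \{R,I,N\}^2 -> \{1..9\}.
#'
#' @param ictal_label,postictal_label `"R"`, `"I"` or `"N"` (vectorised).
#' @return integer region id(s) in 1..9.
#' @export
segment_regions <- function(ictal_label, postictal_label) {
  rank <- c(R = 0L, I = 1L, N = 2L)
  if (!all(c(ictal_label, postictal_label) %in% names(rank)))
    stop("labels must be 'R', 'I' or 'N'")
  3L * rank[ictal_label] + rank[postictal_label] + 1L
}

#' Run a parameter-space map
#'
#' One [simulate_event()] plus [sample_phase_fr()] per grid point.  The
#' preictal steady state and the preictal segment depend only on the
#' context, so they are computed once and shared by all grid points; the
#' sweep is deterministic (reruns are bitwise identical).  A per-point
#' solver failure is recorded as a missing cell, not a map abort.
#'
#' @param grid a [build_grid()].
#' @param context a [circadian_context()].
#' @param params a `sanc_params`.
#' @param w_s,settle_s sampling-window parameters (see [sample_phase_fr()]).
#' @param quiet suppress the per-row progress note.
#' @return a `parameter_map`: FR matrix (BPM, phase matching the map type),
#'   ictal and postictal label matrices, region-id matrix, and metadata.
#'   Matrix rows follow the first axis (`S_i`), columns the second.
#' @export
run_map <- function(grid, context = circadian_context(12, "natural"),
                    params = build_default_params(), w_s = 15, settle_s = 30,
                    quiet = TRUE) {
  a1 <- grid$axes[[1]]; a2 <- grid$axes[[2]]
  n1 <- length(a1); n2 <- length(a2)
  fr <- matrix(NA_real_, n1, n2, dimnames = list(a1, a2))
  lab_i <- lab_p <- matrix(NA_character_, n1, n2, dimnames = list(a1, a2))
  steady <- run_to_steady(params, preictal_drive(context), max_s = 90)
  pre <- NULL
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      prot <- grid_protocol(grid, i, j)
      tr <- tryCatch(
        simulate_event(prot, context, params, init_state = steady,
                       preictal = pre),
        error = function(e) NULL)
      if (is.null(tr)) next
      if (is.null(pre)) {
        # reuse the identical preictal segment for the rest of the sweep
        sel <- tr$time <= prot$t_pre
        pre <- cbind(time = tr$time[sel], tr$states[sel, , drop = FALSE],
                     tr$currents[sel, , drop = FALSE],
                     sna_c = tr$sna_solver[sel], pna_c = tr$pna_solver[sel])
      }
      li <- sample_phase_fr(tr, "ictal", w_s = w_s, settle_s = settle_s)
      lp <- sample_phase_fr(tr, "postictal", w_s = w_s, settle_s = settle_s)
      lab_i[i, j] <- li$label
      lab_p[i, j] <- lp$label
      fr[i, j] <- if (grid$map_type == "ictal") li$fr_bpm else lp$fr_bpm
    }
    if (!quiet) message("map row ", i, "/", n1, " done")
  }
  ok <- !is.na(lab_i) & !is.na(lab_p)
  regions <- matrix(NA_integer_, n1, n2, dimnames = list(a1, a2))
  regions[ok] <- segment_regions(lab_i[ok], lab_p[ok])
  structure(list(grid = grid, fr = fr, ictal_label = lab_i,
                 postictal_label = lab_p, regions = regions,
                 context = context, n_missing = sum(!ok)),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  cat(sprintf("%s map (%dx%d) at ZT%g/%s; %d missing cell(s)\n",
              x$grid$map_type, nrow(x$fr), ncol(x$fr), x$context$zt,
              x$context$vigilance, x$n_missing))
  lab <- if (x$grid$map_type == "ictal") x$ictal_label else x$postictal_label
  print(round(100 * region_areas(x), 1))
  invisible(x)
}

#' Fraction of the map occupied by each firing pattern
#'
#' @param map a `parameter_map`.
#' @param phase which label matrix to tally (defaults to the map's own
#'   phase).
#' @return named numeric: fractions of non-missing grid cells labelled R, I
#'   and N (sums to 1).
#' @export
region_areas <- function(map, phase = map$grid$map_type) {
  lab <- if (phase == "ictal") map$ictal_label else map$postictal_label
  lab <- lab[!is.na(lab)]
  if (!length(lab)) stop("map has no classified cells")
  vapply(c(R = "R", I = "I", N = "N"),
         function(l) mean(lab == l), numeric(1))
}

#' Write / read a parameter map
#'
#' `fr.csv`, `ictal_labels.csv`, `postictal_labels.csv` and `regions.csv`
#' (rows = first axis, header = second-axis values) plus `meta.json` in a
#' directory; the round trip is exact.  Missing cells are preserved as
#' empty fields.
#'
#' @param map a `parameter_map`.
#' @param path directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wr <- function(m, f) {
    dt <- data.table::as.data.table(m, keep.rownames = "Si_pct")
    # 17 significant digits keep the numeric round trip exact; missing
    # cells become empty fields
    dt <- data.table::as.data.table(lapply(dt, function(col) {
      if (!is.double(col)) return(col)
      x <- sprintf("%.17g", col)
      x[is.na(col)] <- ""
      x
    }))
    data.table::fwrite(dt, file.path(path, f), quote = FALSE)
  }
  wr(map$fr, "fr.csv")
  wr(map$ictal_label, "ictal_labels.csv")
  wr(map$postictal_label, "postictal_labels.csv")
  wr(map$regions, "regions.csv")
  meta <- list(map_type = map$grid$map_type, axes = map$grid$axes,
               fixed = as.list(map$grid$fixed),
               context = unclass(map$context), n_missing = map$n_missing)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("not a map directory (no meta.json): ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  rd <- function(f, mode) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) stop("malformed map directory: missing ", f)
    dt <- data.table::fread(fp, colClasses = "character", na.strings = "")
    if (names(dt)[1] != "Si_pct")
      stop("malformed map file ", f, ": first header field must be Si_pct")
    m <- as.matrix(dt[, -1])
    rownames(m) <- dt[[1]]
    if (mode != "character") mode(m) <- mode
    m
  }
  grid <- structure(list(axes = meta$axes, map_type = meta$map_type,
                         fixed = unlist(meta$fixed),
                         n_simulations = prod(lengths(meta$axes))),
                    class = "parameter_grid")
  context <- circadian_context(meta$context$zt, meta$context$vigilance)
  structure(list(grid = grid, fr = rd("fr.csv", "numeric"),
                 ictal_label = rd("ictal_labels.csv", "character"),
                 postictal_label = rd("postictal_labels.csv", "character"),
                 regions = rd("regions.csv", "integer"),
                 context = context, n_missing = meta$n_missing),
            class = "parameter_map")
}
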
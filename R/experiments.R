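#' Configure a parameter sweep
#'
#' A sweep drives the full pipeline -- model construction, far-field
#' solution, feature extraction, replicate aggregation -- over one of the
#' standard parameter tables. Three replicate models are built per
#' parameter combination by default (replicate k uses seed
#' `base_seed + k`). The default swept values form the reduced 3 x 3 design
#' (lc in {0.5, 0.7, 0.9} um, delta_n in {0.010, 0.020, 0.030}); pass
#' `lc_values`/`dn_values = NULL` explicitly through [run_sweep()]'s
#' `full = TRUE` for the complete 7-point grids.
#'
#' @param table parameter table tag (see [parameter_grid()]).
#' @param mode sweep mode tag.
#' @param backend solver backend name (see [list_backends()]).
#' @param replicates models per combination (>= 1, default 3).
#' @param base_seed integer base seed.
#' @param ranges list of [angular_range()]s.
#' @param Io reference intensity for mean log-intensity.
#' @param spacing voxel size for model construction, um.
#' @param lc_values,dn_values swept values (subsets of the tabulated ones).
#' @param pad_factor passed to the Born backend.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(table = "table1_dense", mode = "lc_sweep",
                         backend = "born", replicates = 3L, base_seed = 1L,
                         ranges = default_ranges(), Io = 1,
                         spacing = 0.1,
                         lc_values = c(0.5, 0.7, 0.9),
                         dn_values = c(0.010, 0.020, 0.030),
                         pad_factor = 2) {
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(table = table, mode = mode, backend = backend,
         replicates = as.integer(replicates), base_seed = as.integer(base_seed),
         ranges = ranges, Io = Io, spacing = spacing,
         lc_values = lc_values, dn_values = dn_values,
         pad_factor = pad_factor),
    class = "sweep_config"
  )
}

#' Run a parameter sweep through the pipeline
#'
#' For every model specification of the configured table/mode and every
#' replicate seed: build the refractive-index volume, solve the far-field
#' pattern through the configured backend, and extract the feature set per
#' angular range. Fully deterministic for a fixed configuration. Solver
#' refusals propagate with the offending specification attached to the
#' error message.
#'
#' @param config a [sweep_config()].
#' @param full use the complete 7-point lc/delta_n grids instead of the
#'   reduced values in `config`.
#' @return A `sweep_result`: list with `features` (one row per combination
#'   x replicate x range), `summary` (replicate mean and standard error per
#'   combination x range; SE is `NA` when `replicates = 1`), and `config`.
#' @export
run_sweep <- function(config, full = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  specs <- parameter_grid(
    config$table, config$mode,
    lc_values = if (full || config$mode != "lc_sweep") NULL else config$lc_values,
    dn_values = if (full || config$mode != "dn_sweep") NULL else config$dn_values,
    spacing = config$spacing
  )
  wave <- plane_wave(800, specs[[1]]$n_out)

  rows <- list()
  agg <- list()
  for (ci in seq_along(specs)) {
    spec0 <- specs[[ci]]
    sets <- vector("list", config$replicates)
    for (k in seq_len(config$replicates) - 1L) {
      spec <- spec0
      spec$seed <- config$base_seed + k
      vol <- build_model(spec)
      pat <- tryCatch(
        solve_pattern(vol, wave, backend = config$backend,
                      pad_factor = config$pad_factor),
        error = function(e) {
          stop(sprintf("solver '%s' failed for spec [%s]: %s",
                       config$backend, spec_label(spec), conditionMessage(e)),
               call. = FALSE)
        }
      )
      fs <- feature_set(pat, config$ranges, Io = config$Io,
                        replicate_id = k)
      fs <- cbind(spec_columns(spec, ci), as.data.frame(fs))
      sets[[k + 1L]] <- fs
      rows[[length(rows) + 1L]] <- fs
    }
    sm <- aggregate_replicates(lapply(sets, function(d) {
      d[c("range", "mean_intensity", "contrast_theta", "contrast_phi",
          "contrast_ratio", "replicate_id")]
    }))
    agg[[length(agg) + 1L]] <- cbind(spec_columns(spec0, ci), sm)
  }
  features <- do.call(rbind, rows)
  summary <- do.call(rbind, agg)
  rownames(features) <- rownames(summary) <- NULL
  structure(list(features = features, summary = summary, config = config),
            class = "sweep_result")
}

#' @noRd
spec_columns <- function(spec, combo) {
  data.frame(
    combo = combo,
    shape = spec$shape_kind,
    R = if (is.null(spec$R)) NA_real_ else spec$R,
    Sx = if (is.null(spec$Sx)) NA_real_ else spec$Sx,
    Sy = if (is.null(spec$Sy)) NA_real_ else spec$Sy,
    Sz = if (is.null(spec$Sz)) NA_real_ else spec$Sz,
    n = spec$n, n_out = spec$n_out, lc = spec$lc, delta_n = spec$delta_n,
    stringsAsFactors = FALSE
  )
}

#' @noRd
spec_label <- function(spec) {
  geom <- if (spec$shape_kind == "sphere") sprintf("R=%.2f", spec$R) else
    sprintf("S=(%.2f,%.2f,%.2f)", spec$Sx, spec$Sy, spec$Sz)
  sprintf("%s %s n=%.3f n_out=%.3f lc=%.2f dn=%.3f seed=%d",
          spec$shape_kind, geom, spec$n, spec$n_out, spec$lc, spec$delta_n,
          spec$seed)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s / %s, backend %s: %d combinations x %d replicates\n",
              x$config$table, x$config$mode, x$config$backend,
              max(x$summary$combo), x$config$replicates))
  invisible(x)
}

#' Write the per-replicate feature table as CSV
#'
#' Byte-stable for a fixed configuration (deterministic pipeline, fixed
#' number formatting).
#'
#' @param result a `sweep_result`.
#' @param path output CSV path.
#' @export
write_sweep_csv <- function(result, path) {
  df <- result$features
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monotone-trend verdict for a swept feature
#'
#' Examines the replicate-mean series of one feature, in one angular range,
#' against the swept parameter: reports the Spearman sign and whether the
#' series is strictly monotone.
#'
#' @param result a `sweep_result`.
#' @param feature `"mean_intensity"`, `"contrast_theta"`, `"contrast_phi"`
#'   or `"contrast_ratio"`.
#' @param range range name (e.g. `"side"`).
#' @param parameter swept column name (`"lc"` or `"delta_n"`).
#' @return List with `verdict` (`"strictly_increasing"`,
#'   `"strictly_decreasing"`, `"flat"` or `"non_monotone"`), `spearman`
#'   (rank correlation of the mean series with the parameter), `values`
#'   and `parameter_values`.
#' @export
trend_check <- function(result, feature, range, parameter = c("lc", "delta_n")) {
  parameter <- match.arg(parameter)
  col <- paste0(feature, "_mean")
  sm <- result$summary[result$summary$range == range, ]
  if (!nrow(sm)) stop("no such range in sweep summary: ", range, call. = FALSE)
  sm <- sm[order(sm[[parameter]]), ]
  v <- sm[[col]]
  p <- sm[[parameter]]
  dv <- diff(v)
  verdict <- if (all(dv == 0)) "flat"
    else if (all(dv > 0)) "strictly_increasing"
    else if (all(dv < 0)) "strictly_decreasing"
    else "non_monotone"
  rho <- if (all(dv == 0)) 0 else
    suppressWarnings(stats::cor(p, v, method = "spearman"))
  list(verdict = verdict, spearman = rho, values = v, parameter_values = p)
}

#' Size/index-invariance dispersion ratio
#'
#' Quantifies how insensitive a feature is to nuclear size and mean index
#' compared to its sensitivity to the correlation length: the spread
#' (max - min) of the feature across the size/index sweep (at fixed
#' lc = 0.7 um, delta_n = 0.020) divided by the absolute change of the same
#' feature between the smallest and largest swept lc. A ratio below one
#' means geometry/index perturbations move the feature less than the lc
#' span does.
#'
#' @param size_result `sweep_result` of a `size_index_sweep`.
#' @param lc_result `sweep_result` of an `lc_sweep` covering the comparison
#'   span.
#' @param feature feature name (default `"contrast_ratio"`).
#' @param range range name (default `"side"`).
#' @param lc_span the two lc values defining the comparison span (defaults
#'   to the extremes present in `lc_result`).
#' @return List with `dispersion`, `lc_change`, `ratio`.
#' @export
invariance_check <- function(size_result, lc_result,
                             feature = "contrast_ratio", range = "side",
                             lc_span = NULL) {
  col <- paste0(feature, "_mean")
  sz <- size_result$summary[size_result$summary$range == range, ]
  lcs <- lc_result$summary[lc_result$summary$range == range, ]
  if (is.null(lc_span)) lc_span <- range(lcs$lc)
  a <- lcs[[col]][lcs$lc == lc_span[1]]
  b <- lcs[[col]][lcs$lc == lc_span[2]]
  if (!length(a) || !length(b)) {
    stop("lc sweep does not cover the requested span", call. = FALSE)
  }
  lc_change <- abs(b - a)
  if (lc_change == 0) {
    stop("degenerate lc span: feature change is zero, ratio undefined",
         call. = FALSE)
  }
  dispersion <- max(sz[[col]]) - min(sz[[col]])
  list(dispersion = dispersion, lc_change = lc_change,
       ratio = dispersion / lc_change)
}
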
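#' Nuclear image container
#'
#' A 2-d optical-density array with a pixel size in micrometres and an
#' optional boolean nuclear mask. Optical density of a stained pixel is
#' proportional to local DNA concentration, so its spatial correlation
#' carries the chromatin correlation length.
#'
#' @param od 2-d numeric matrix of optical density (arbitrary units).
#' @param pixel_size pixel size, um (default 0.34).
#' @param mask optional logical matrix of the same shape.
#' @return A `nuclear_image` list.
#' @export
nuclear_image <- function(od, pixel_size = 0.34, mask = NULL) {
  stopifnot(is.matrix(od), is.numeric(od))
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (!is.null(mask)) stopifnot(identical(dim(mask), dim(od)))
  structure(list(od = od, pixel_size = pixel_size, mask = mask),
            class = "nuclear_image")
}

#' Autocorrelation of a 1-d optical-density series
#'
#' Biased (divide-by-N), mean-removed autocorrelation normalized at lag
#' zero, as computed by [stats::acf()]: `rho(0) = 1` exactly.
#'
#' @param series numeric vector, length >= 5, non-constant.
#' @param max_lag maximum lag (default: full length - 1).
#' @return Numeric vector `rho(0), rho(1), ...`.
#' @export
line_autocorrelation <- function(series, max_lag = length(series) - 1L) {
  if (length(series) < 5L) stop("series must have length >= 5", call. = FALSE)
  if (stats::sd(series) == 0) stop("constant series: autocorrelation undefined",
                                   call. = FALSE)
  as.vector(stats::acf(series, lag.max = max_lag, plot = FALSE,
                       demean = TRUE, type = "correlation")$acf)
}

#' Fit a Gaussian correlation function to an autocorrelation curve
#'
#' Fits `C(r) = exp(-r^2 / lc^2)` -- amplitude fixed at one, `lc` the only
#' free parameter -- by least squares over the usable lags: lag 0 up to (but
#' excluding) the first lag at which the correlation drops below `cutoff`
#' or turns negative. The goodness of fit `R^2` is computed against the
#' fitted points. A fit is accepted when it has at least four data points
#' and `R^2 > 0.95`; too few usable lags yields a rejected (not failed) fit.
#'
#' @param corr autocorrelation values at lags 0, 1, 2, ... (from
#'   [line_autocorrelation()]).
#' @param pixel_size pixel size, um, converting lags to distances.
#' @param cutoff usable-lag correlation threshold (default 0.05).
#' @return A one-row data frame (`line_fit`): `lc_est` (um), `r_squared`,
#'   `n_points`, `accepted`.
#' @export
fit_gaussian_correlation <- function(corr, pixel_size, cutoff = 0.05) {
  stop_idx <- which(corr < cutoff | corr < 0)
  n_use <- if (length(stop_idx)) min(stop_idx) - 1L else length(corr)
  if (n_use < 4L) {
    return(data.frame(lc_est = NA_real_, r_squared = NA_real_,
                      n_points = n_use, accepted = FALSE))
  }
  y <- corr[seq_len(n_use)]
  r <- (seq_len(n_use) - 1) * pixel_size
  ss <- function(lc) sum((y - exp(-r^2 / lc^2))^2)
  opt <- stats::optimize(ss, interval = c(pixel_size / 50, 50 * max(r)),
                         tol = 1e-9)
  lc_hat <- opt$minimum
  fitted <- exp(-r^2 / lc_hat^2)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  data.frame(lc_est = lc_hat, r_squared = r2, n_points = n_use,
             accepted = isTRUE(r2 > 0.95))
}

#' Correlation length of one region of interest
#'
#' Runs the row/column autocorrelation and constrained Gaussian fit on every
#' row and every column of a rectangular ROI; the ROI estimate is the mean
#' `lc` over all accepted fits (>= 4 points and R^2 > 0.95). Rows or
#' columns that are constant or too short are skipped. Zero accepted fits
#' yields an `NA` estimate (propagated, not fatal).
#'
#' @param image a [nuclear_image()].
#' @param roi integer vector `c(row0, col0, row1, col1)` (inclusive,
#'   1-based).
#' @param cutoff passed to [fit_gaussian_correlation()].
#' @return List with `lc` (um, possibly `NA`), `n_accepted`, and `fits`
#'   (data frame of per-line diagnostics: line type, index, lc, R^2,
#'   points, accepted).
#' @export
roi_lc <- function(image, roi, cutoff = 0.05) {
  stopifnot(inherits(image, "nuclear_image"), length(roi) == 4L)
  sub <- image$od[roi[1]:roi[3], roi[2]:roi[4], drop = FALSE]
  fits <- list()
  run_line <- function(series, type, idx) {
    if (length(series) < 5L || stats::sd(series) == 0) return(NULL)
    f <- fit_gaussian_correlation(line_autocorrelation(series),
                                  image$pixel_size, cutoff)
    cbind(data.frame(line = type, index = idx), f)
  }
  for (i in seq_len(nrow(sub))) fits[[length(fits) + 1L]] <- run_line(sub[i, ], "row", i)
  for (j in seq_len(ncol(sub))) fits[[length(fits) + 1L]] <- run_line(sub[, j], "col", j)
  fits <- do.call(rbind, fits)
  if (is.null(fits) || !any(fits$accepted)) {
    return(list(lc = NA_real_, n_accepted = 0L, fits = fits))
  }
  list(lc = mean(fits$lc_est[fits$accepted]),
       n_accepted = sum(fits$accepted), fits = fits)
}

#' Nucleus-level correlation length from three regions of interest
#'
#' Estimates `lc` in each ROI and averages the per-ROI values; ROIs with no
#' accepted line fits are dropped (and flagged) rather than failing the
#' nucleus. The estimate is reported both in micrometres and in pixels
#' (`lc_px = lc_um / pixel_size`).
#'
#' @param image a [nuclear_image()].
#' @param rois list of three ROI rectangles (`c(row0, col0, row1, col1)`).
#' @param cutoff passed to [fit_gaussian_correlation()].
#' @return An `lc_estimate`: list with `lc_um`, `lc_px`, `roi_values`
#'   (per-ROI um values, `NA` where missing), `n_rois_used`, `incomplete`
#'   flag, and `fits` (all per-line diagnostics).
#' @export
nucleus_lc <- function(image, rois, cutoff = 0.05) {
  stopifnot(length(rois) == 3L)
  per <- lapply(seq_along(rois), function(i) {
    r <- roi_lc(image, rois[[i]], cutoff)
    if (!is.null(r$fits)) r$fits$roi <- i
    r
  })
  vals <- vapply(per, `[[`, numeric(1), "lc")
  used <- !is.na(vals)
  if (!any(used)) {
    warning("no ROI produced an accepted fit; lc estimate is NA")
  }
  lc_um <- if (any(used)) mean(vals[used]) else NA_real_
  structure(
    list(lc_um = lc_um,
         lc_px = lc_um / image$pixel_size,
         roi_values = vals,
         n_rois_used = sum(used),
         incomplete = any(!used),
         fits = do.call(rbind, lapply(per, `[[`, "fits"))),
    class = "lc_estimate"
  )
}

#' Convert a pixel-scale correlation length to micrometres
#'
#' @param lc_px correlation length in pixels.
#' @param pixel_size pixel size, um (default 0.34).
#' @param digits decimals for reporting (default 2, as customarily quoted);
#'   use `NULL` for no rounding.
#' @return Correlation length in um.
#' @export
lc_px_to_um <- function(lc_px, pixel_size = 0.34, digits = 2) {
  um <- lc_px * pixel_size
  if (is.null(digits)) um else round(um, digits)
}

#' @export
print.lc_estimate <- function(x, ...) {
  cat(sprintf("<lc_estimate> lc = %.2f um (%.2f px), %d/3 ROIs used%s\n",
              x$lc_um, x$lc_px, x$n_rois_used,
              if (x$incomplete) " [incomplete]" else ""))
  invisible(x)
}

#' @export
summary.lc_estimate <- function(object, ...) {
  cat(sprintf("Correlation length: %.2f um (%.2f px)\n", object$lc_um, object$lc_px))
  cat("Per-ROI values (um):", paste(sprintf("%.3f", object$roi_values), collapse = ", "), "\n")
  if (!is.null(object$fits)) {
    acc <- object$fits$accepted
    cat(sprintf("Line fits: %d total, %d accepted (>=4 points, R^2 > 0.95)\n",
                nrow(object$fits), sum(acc)))
    if (any(acc)) {
      cat(sprintf("Accepted-fit lc: mean %.3f um, relative sd %.1f%%\n",
                  mean(object$fits$lc_est[acc]),
                  100 * stats::sd(object$fits$lc_est[acc]) /
                    mean(object$fits$lc_est[acc])))
    }
  }
  invisible(object)
}

#' Image-analysis cohort tallies
#'
#' Diagnostic-category counts of the segmented-nucleus image cohort the
#' correlation-length analysis was developed on: negative, CIN 1-3
#' (cervical intraepithelial neoplasia grades).
#'
#' @return Data frame with columns `category` and `n`.
#' @export
cohort_counts <- function() {
  data.frame(category = c("negative", "CIN1", "CIN2", "CIN3"),
             n = c(476L, 155L, 168L, 138L),
             stringsAsFactors = FALSE)
}

#' Read a nuclear image from a TIFF file
#'
#' @param path TIFF path (as written by [make_fixture_suite()]).
#' @param pixel_size pixel size, um.
#' @return A [nuclear_image()].
#' @export
read_nucleus_image <- function(path, pixel_size = 0.34) {
  od <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(od)) == 3L) od <- od[, , 1]
  nuclear_image(od, pixel_size)
}
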
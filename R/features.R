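#' Angular analysis ranges
#'
#' The three polar ranges over which features are computed: small-angle
#' scattering (theta 0-40 deg), side scattering (40-140 deg) and high-angle
#' scattering (140-180 deg), each over the full azimuth. Endpoints are
#' inclusive on both sides, so theta = 40 deg belongs to both the
#' small-angle and side ranges.
#'
#' @param name `"small_angle"`, `"side"` or `"high_angle"`, or use
#'   `angular_range()` directly for a custom range.
#' @param theta_min,theta_max polar bounds, deg (0 <= min < max <= 180).
#' @param phi_min,phi_max azimuthal bounds, deg.
#' @return An `angular_range` list.
#' @export
angular_range <- function(theta_min, theta_max, phi_min = 0, phi_max = 360,
                          name = "custom") {
  if (!(theta_min >= 0 && theta_min < theta_max && theta_max <= 180)) {
    stop("need 0 <= theta_min < theta_max <= 180", call. = FALSE)
  }
  structure(list(theta_min = theta_min, theta_max = theta_max,
                 phi_min = phi_min, phi_max = phi_max, name = name),
            class = "angular_range")
}

#' @rdname angular_range
#' @export
default_ranges <- function() {
  list(small_angle = angular_range(0, 40, name = "small_angle"),
       side = angular_range(40, 140, name = "side"),
       high_angle = angular_range(140, 180, name = "high_angle"))
}

# Row/column index helpers. The phi = 360 column duplicates phi = 0 and is
# dropped before any averaging or pair counting.
#' @noRd
range_rows <- function(range) (range$theta_min:range$theta_max) + 1L

#' @noRd
dedup_cols <- function() 1:360

#' Mean log-intensity over an angular range
#'
#' Arithmetic mean of `log10(I / Io)` over all grid points of the range
#' (duplicated phi = 360 column excluded). Intensities below
#' `floor_frac * max(I)` are floored before the logarithm.
#'
#' @param pattern a `scattering_pattern`.
#' @param range an [angular_range()].
#' @param Io reference intensity (> 0), default 1 in solver output units.
#' @param floor_frac relative intensity floor (default 1e-12).
#' @return A single number (log10 units).
#' @export
mean_log_intensity <- function(pattern, range, Io = 1, floor_frac = 1e-12) {
  if (!is.numeric(Io) || Io <= 0) stop("`Io` must be > 0", call. = FALSE)
  I <- pattern$intensity[range_rows(range), dedup_cols(), drop = FALSE]
  I <- pmax(I, floor_frac * max(pattern$intensity))
  mean(log10(I / Io))
}

#' Full-scale contrast stretch of a log-intensity pattern
#'
#' Maps `L = log10(I)` (after relative flooring) affinely onto integers
#' 0..255: `round(255 (L - Lmin) / (Lmax - Lmin))`, computed over the full
#' 181 x 361 pattern. A constant pattern maps to all zeros and is flagged
#' degenerate. The stretch is invariant under affine maps `L -> a L + b`
#' (a > 0), i.e. under power-law rescaling of the intensities.
#'
#' @inheritParams mean_log_intensity
#' @return A `stretched_pattern`: integer matrix in 0..255 with attributes
#'   `L_range` (the source min/max) and `degenerate`.
#' @export
contrast_stretch <- function(pattern, floor_frac = 1e-12) {
  I <- pattern$intensity
  L <- log10(pmax(I, floor_frac * max(I)))
  lo <- min(L); hi <- max(L)
  if (hi - lo < .Machine$double.eps * 100 * max(1, abs(hi))) {
    out <- matrix(0L, nrow = nrow(I), ncol = ncol(I))
    return(structure(out, L_range = c(lo, hi), degenerate = TRUE,
                     class = c("stretched_pattern", "matrix", "array")))
  }
  out <- matrix(as.integer(round(255 * (L - lo) / (hi - lo))),
                nrow = nrow(I), ncol = ncol(I))
  structure(out, L_range = c(lo, hi), degenerate = FALSE,
            class = c("stretched_pattern", "matrix", "array"))
}

#' Gray-level co-occurrence matrix of a stretched pattern
#'
#' Counts ordered neighbor pairs at offset exactly +1 along the polar
#' (`"theta"`, down a column of the pattern) or azimuthal (`"phi"`, along a
#' row) direction, with both pixels inside the angular range, after
#' quantizing to eight gray levels with `floor(value / 32)` (so 255 maps to
#' level 7). Pairs are ordered (no symmetrization), there is no wrap-around
#' in theta, and the duplicated phi = 360 column is dropped before pairing
#' (no cyclic wrap in phi).
#'
#' @param stretched a [contrast_stretch()] result.
#' @param direction `"theta"` or `"phi"`.
#' @param range an [angular_range()].
#' @return A `glcm` object: 8 x 8 integer count matrix with attributes
#'   `direction` and `range_name`.
#' @export
glcm <- function(stretched, direction = c("theta", "phi"), range) {
  direction <- match.arg(direction)
  q <- matrix(unclass(stretched) %/% 32L,
              nrow = nrow(stretched), ncol = ncol(stretched))
  q <- q[range_rows(range), dedup_cols(), drop = FALSE]
  counts <- glcm_counts(q, direction)
  structure(counts, direction = direction, range_name = range$name,
            class = c("glcm", "matrix", "array"))
}

# ordered pair counting at offset +1 on an arbitrary quantized matrix;
# rows play the theta role, columns the phi role
#' @noRd
glcm_counts <- function(q, direction) {
  if (direction == "theta") {
    if (nrow(q) < 2L) stop("range too thin to form theta pairs", call. = FALSE)
    a <- q[-nrow(q), , drop = FALSE]
    b <- q[-1L, , drop = FALSE]
  } else {
    if (ncol(q) < 2L) stop("range too thin to form phi pairs", call. = FALSE)
    a <- q[, -ncol(q), drop = FALSE]
    b <- q[, -1L, drop = FALSE]
  }
  counts <- matrix(0L, 8, 8)
  tab <- table(factor(a, levels = 0:7), factor(b, levels = 0:7))
  counts[] <- as.integer(tab)
  counts
}

#' Normalize a co-occurrence matrix to probabilities
#'
#' Divides the counts by their total so the entries sum to one.
#'
#' @param g a [glcm()] count matrix.
#' @return An 8 x 8 numeric probability matrix.
#' @export
normalize_glcm <- function(g) {
  tot <- sum(g)
  if (tot <= 0) stop("empty co-occurrence matrix", call. = FALSE)
  unclass(g) / tot
}

#' Haralick contrast of a normalized co-occurrence matrix
#'
#' `sum_ij |i - j|^2 p(i, j)` over the eight gray levels; ranges over
#' `[0, 49]`.
#'
#' @param p an 8 x 8 probability matrix (entries summing to 1).
#' @return A single non-negative number.
#' @export
haralick_contrast <- function(p) {
  i <- 0:7
  sum(outer(i, i, function(a, b) (a - b)^2) * p)
}

#' Intensity and texture features of a scattering pattern
#'
#' Computes, per angular range: the mean log-intensity, the polar contrast
#' (`contrast_theta`, co-occurrence offset along theta), the azimuthal
#' contrast (`contrast_phi`, offset along phi) and the contrast ratio
#' `contrast_phi / contrast_theta`. The contrast stretch is global (over the
#' full pattern) by default; `stretch = "per_range"` restretches within each
#' range instead. A fully constant pattern, or a range with zero polar
#' contrast, makes the contrast ratio undefined: a classed error
#' (`nucscatter_degenerate_pattern`) is signalled rather than an infinity.
#'
#' @param pattern a `scattering_pattern`.
#' @param ranges list of [angular_range()]s (default [default_ranges()]).
#' @param Io reference intensity for the mean log-intensity.
#' @param stretch `"global"` or `"per_range"`.
#' @param floor_frac relative intensity floor before logarithms.
#' @param replicate_id optional identifier stored in the output.
#' @return A `feature_set`: data frame with one row per range and columns
#'   `range`, `mean_intensity`, `contrast_theta`, `contrast_phi`,
#'   `contrast_ratio`, `replicate_id`.
#' @export
feature_set <- function(pattern, ranges = default_ranges(), Io = 1,
                        stretch = c("global", "per_range"),
                        floor_frac = 1e-12, replicate_id = NA_integer_) {
  stretch <- match.arg(stretch)
  sp_global <- contrast_stretch(pattern, floor_frac)
  if (isTRUE(attr(sp_global, "degenerate"))) {
    stop_degenerate("constant pattern: contrast features undefined")
  }
  rows <- lapply(ranges, function(rg) {
    sp <- if (stretch == "global") sp_global else {
      sub <- pattern
      sub$intensity <- pattern$intensity[range_rows(rg), , drop = FALSE]
      s <- contrast_stretch(sub, floor_frac)
      # re-embed so glcm() row indexing by theta still applies
      full <- matrix(0L, 181, 361)
      full[range_rows(rg), ] <- unclass(s)
      structure(full, degenerate = attr(s, "degenerate"),
                class = class(s))
    }
    if (isTRUE(attr(sp, "degenerate"))) {
      stop_degenerate(sprintf("range '%s': constant pattern after stretch", rg$name))
    }
    ct <- haralick_contrast(normalize_glcm(glcm(sp, "theta", rg)))
    cp <- haralick_contrast(normalize_glcm(glcm(sp, "phi", rg)))
    if (ct == 0) {
      stop_degenerate(sprintf(
        "range '%s': polar contrast is zero; contrast ratio undefined", rg$name))
    }
    data.frame(range = rg$name,
               mean_intensity = mean_log_intensity(pattern, rg, Io, floor_frac),
               contrast_theta = ct, contrast_phi = cp,
               contrast_ratio = cp / ct,
               replicate_id = replicate_id,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_set", "data.frame")
  out
}

#' @noRd
stop_degenerate <- function(msg) {
  stop(structure(
    class = c("nucscatter_degenerate_pattern", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Aggregate replicate feature sets
#'
#' Mean and standard error (sample sd / sqrt(k)) of every feature across
#' replicate feature sets, per range. With a single replicate the standard
#' error is undefined and reported as `NA` (not zero).
#'
#' @param sets list of [feature_set()] data frames.
#' @return Data frame with one row per range and `<feature>_mean`,
#'   `<feature>_se` columns, plus `n_replicates`.
#' @export
aggregate_replicates <- function(sets) {
  stopifnot(length(sets) >= 1)
  all <- do.call(rbind, lapply(sets, as.data.frame))
  feats <- c("mean_intensity", "contrast_theta", "contrast_phi", "contrast_ratio")
  out <- lapply(split(all, all$range), function(d) {
    k <- nrow(d)
    row <- data.frame(range = d$range[1], n_replicates = k,
                      stringsAsFactors = FALSE)
    for (f in feats) {
      row[[paste0(f, "_mean")]] <- mean(d[[f]])
      row[[paste0(f, "_se")]] <- if (k > 1) stats::sd(d[[f]]) / sqrt(k) else NA_real_
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
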
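#' Specify a synthetic stained-nucleus image
#'
#' Describes a 2-d optical-density image emulating a Feulgen-thionin-stained
#' nucleus: Gaussian-correlated OD fluctuations with a known correlation
#' length inside an elliptical nuclear mask, uniform background outside,
#' sampled at 0.34 um/pixel by default. The fluctuation field reuses the
#' spectral Gaussian-random-field machinery in two dimensions.
#'
#' @param lc_true true correlation length, um.
#' @param pixel_size um per pixel (default 0.34).
#' @param image_shape `c(rows, cols)` in pixels.
#' @param nucleus_axes elliptical mask semiaxes `c(row, col)`, um.
#' @param od_mean,od_std mean and standard deviation of the in-mask OD
#'   (default ratio 0.25, giving visible chromatin-like texture).
#' @param background_od OD outside the mask.
#' @param roi_size side length of the three square ROIs, pixels (>= 8).
#' @param seed integer seed.
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(lc_true, pixel_size = 0.34,
                                 image_shape = c(72, 64),
                                 nucleus_axes = c(11.5, 9),
                                 od_mean = 1.0, od_std = 0.25,
                                 background_od = 0.1,
                                 roi_size = 20L, seed = 1L) {
  if (lc_true <= 0) stop("`lc_true` must be > 0", call. = FALSE)
  if (pixel_size <= 0) stop("`pixel_size` must be > 0", call. = FALSE)
  if (roi_size < 8L) stop("ROIs must be at least 8x8 pixels", call. = FALSE)
  structure(
    list(lc_true = lc_true, pixel_size = pixel_size,
         image_shape = as.integer(image_shape),
         nucleus_axes = nucleus_axes, od_mean = od_mean, od_std = od_std,
         background_od = background_od, roi_size = as.integer(roi_size),
         seed = as.integer(seed)),
    class = "synthetic_image_spec"
  )
}

#' Generate a synthetic nuclear image with known correlation length
#'
#' Builds the OD field `od_mean + od_std * g2D` inside the elliptical mask
#' (where `g2D` is a unit-variance 2-d Gaussian random field with
#' correlation `exp(-r^2 / lc_true^2)`), `background_od` outside, and
#' proposes three disjoint square ROIs stacked through the nucleus center.
#' The truth record carries `lc_true`, the seed, and the ROI rectangles.
#'
#' @param spec a [synthetic_image_spec()].
#' @return List with `image` (a [nuclear_image()]), `rois` (list of three
#'   `c(row0, col0, row1, col1)` rectangles), and `truth` (list with
#'   `lc_true`, `seed`).
#' @export
make_nucleus_image <- function(spec) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  sh <- spec$image_shape
  # The pixel pitch may under-resolve lc (0.34 um pixels vs lc down to
  # 0.4 um, exactly the diffraction-limited situation being emulated), so
  # synthesize the field on a finer subgrid and decimate: the decimated
  # field is a Gaussian-correlated field sampled at the pixel pitch.
  over <- max(1L, ceiling(4 * spec$pixel_size / spec$lc_true))
  g <- generate_grf(sh * over, spacing = spec$pixel_size / over,
                    lc = spec$lc_true, seed = spec$seed,
                    method = "spectral")$values
  g <- g[seq(1, by = over, length.out = sh[1]),
         seq(1, by = over, length.out = sh[2])]
  ctr <- (sh + 1) / 2
  rr <- (seq_len(sh[1]) - ctr[1]) * spec$pixel_size
  cc <- (seq_len(sh[2]) - ctr[2]) * spec$pixel_size
  m2 <- outer((rr / spec$nucleus_axes[1])^2, (cc / spec$nucleus_axes[2])^2, `+`)
  mask <- m2 <= 1
  od <- matrix(spec$background_od, sh[1], sh[2])
  od[mask] <- spec$od_mean + spec$od_std * g[mask]

  rois <- center_rois(sh, spec$roi_size)
  for (r in rois) {
    block <- mask[r[1]:r[3], r[2]:r[4]]
    if (!all(block)) {
      stop("nuclear mask too small to hold three disjoint ROIs; enlarge ",
           "`nucleus_axes` or shrink `roi_size`", call. = FALSE)
    }
  }
  list(image = nuclear_image(od, spec$pixel_size, mask),
       rois = rois,
       truth = list(lc_true = spec$lc_true, seed = spec$seed,
                    pixel_size = spec$pixel_size))
}

# three disjoint roi_size x roi_size squares stacked vertically about center
#' @noRd
center_rois <- function(sh, k) {
  r0 <- floor(sh[1] / 2) - floor(3 * k / 2)
  c0 <- floor(sh[2] / 2) - floor(k / 2)
  if (r0 < 1 || c0 < 1 || r0 + 3 * k - 1 > sh[1] || c0 + k - 1 > sh[2]) {
    stop("image too small for three disjoint ROIs", call. = FALSE)
  }
  lapply(0:2, function(i) {
    c(r0 + i * k, c0, r0 + i * k + k - 1, c0 + k - 1)
  })
}

#' Generate the full synthetic fixture tree
#'
#' Writes, under `out_dir`: (a) synthetic nuclear images at true
#' correlation lengths 0.4, 0.7 and 1.0 um (`n_image_seeds` seeds each,
#' 32-bit float TIFF); (b) homogeneous reference spheres at R = 3.5, 4.0,
#' 4.5 um; (c) the three default stochastic model trios (dense sphere,
#' inverted-contrast sphere, ellipsoid) at lc = 0.7 um, delta_n = 0.020,
#' three replicate seeds each; and a `manifest.json` listing every file with
#' its ground truth. Regeneration with the same `master_seed` is
#' bit-identical. No network access is required.
#'
#' @param out_dir output directory (created if needed).
#' @param master_seed integer; per-fixture seeds are derived as small
#'   offsets from it.
#' @param n_image_seeds images per lc value (default 20).
#' @param spacing voxel size for the model volumes, um (default 0.05).
#' @return The manifest, invisibly.
#' @export
make_fixture_suite <- function(out_dir, master_seed = 1L,
                               n_image_seeds = 20L, spacing = 0.05) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()

  for (lc in c(0.4, 0.7, 1.0)) {
    for (k in seq_len(n_image_seeds)) {
      seed <- master_seed + round(1000 * lc) + k
      spec <- synthetic_image_spec(lc_true = lc, seed = seed)
      gen <- make_nucleus_image(spec)
      fn <- sprintf("image_lc%.1f_seed%03d.tif", lc, k)
      od <- gen$image$od
      tiff::writeTIFF(od / max(od), file.path(out_dir, fn),
                      bits.per.sample = 32L)
      manifest[[length(manifest) + 1L]] <- list(
        file = fn, kind = "image", lc_true = lc, seed = seed,
        pixel_size_um = spec$pixel_size, od_scale = max(od),
        rois = gen$rois)
    }
  }

  for (R in c(3.5, 4.0, 4.5)) {
    spec <- nuclear_model_spec("sphere", R = R, n = 1.40, n_out = 1.36,
                               lc = 0.7, delta_n = 0, spacing = spacing,
                               seed = master_seed)
    fn <- sprintf("sphere_homog_R%.1f.vol", R)
    save_model(build_model(spec), file.path(out_dir, fn))
    manifest[[length(manifest) + 1L]] <- list(
      file = fn, kind = "homogeneous_sphere", R = R, n = 1.40, n_out = 1.36)
  }

  trios <- list(
    table1_dense = parameter_grid("table1_dense", "lc_sweep",
                                  lc_values = 0.7, spacing = spacing)[[1]],
    table1_inverted = parameter_grid("table1_inverted", "lc_sweep",
                                     lc_values = 0.7, spacing = spacing)[[1]],
    table2 = parameter_grid("table2", "lc_sweep",
                            lc_values = 0.7, spacing = spacing)[[1]]
  )
  for (nm in names(trios)) {
    for (k in 0:2) {
      spec <- trios[[nm]]
      spec$seed <- as.integer(master_seed + k)
      fn <- sprintf("model_%s_rep%d.vol", nm, k)
      save_model(build_model(spec), file.path(out_dir, fn))
      manifest[[length(manifest) + 1L]] <- list(
        file = fn, kind = "stochastic_model", table = nm, lc = 0.7,
        delta_n = 0.020, seed = spec$seed)
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
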
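#' Incident plane-wave configuration
#'
#' An x-polarized plane wave propagating along +z in the background
#' (cytoplasmic) medium. The default vacuum wavelength is 800 nm.
#'
#' @param wavelength_nm vacuum wavelength, nm.
#' @param background_index refractive index of the embedding medium.
#' @return A `plane_wave` list.
#' @export
plane_wave <- function(wavelength_nm = 800, background_index) {
  wavelength_nm <- as.numeric(wavelength_nm)
  background_index <- as.numeric(background_index)
  if (wavelength_nm <= 0) stop("wavelength must be > 0", call. = FALSE)
  if (background_index <= 1 || background_index >= 2) {
    stop("background index must lie in (1, 2)", call. = FALSE)
  }
  structure(
    list(wavelength_nm = wavelength_nm, polarization = "x",
         propagation = "+z", background_index = background_index),
    class = "plane_wave"
  )
}

#' First-Born far-field scattering pattern of a refractive-index volume
#'
#' Computes the azimuth-resolved far-field intensity `I(theta, phi)` on the
#' 181 x 361 one-degree grid (`theta` 0..180 rows, `phi` 0..360 columns)
#' under the first Born approximation: the scattering amplitude is the 3-d
#' Fourier transform of the scattering potential
#' `k0^2 (n(x)^2 - n_out^2)` evaluated on the Ewald sphere
#' `q = k (s_hat - z_hat)`, with `k = 2 pi n_out / lambda_vac` and
#' `s_hat = (sin t cos p, sin t sin p, cos t)`, multiplied by the dipole
#' polarization factor `1 - sin^2(theta) cos^2(phi)` for x-polarized
#' incidence. The transform is evaluated by a zero-padded FFT (pad factor
#' >= 2) with the model center phase-shifted to the grid origin, followed by
#' separable interpolation in q-space (`"tricubic"` Keys interpolation by
#' default; `"trilinear"` available).
#'
#' This solver is perturbative: it reproduces directional structure and the
#' relative behavior of texture features, not absolute intensities of a
#' rigorous electromagnetic solver.
#'
#' @param volume a `refractive_index_volume`.
#' @param wave a [plane_wave()]; its `background_index` should equal the
#'   volume's `n_out`.
#' @param pad_factor zero-padding factor for the FFT grid (>= 2).
#' @param interp `"tricubic"` or `"trilinear"` q-space interpolation.
#' @return A `scattering_pattern`: list with `intensity` (181 x 361 matrix,
#'   non-negative), `theta`, `phi`, `wave`, `solver`, `provenance`.
#' @export
born_far_field <- function(volume, wave, pad_factor = 2,
                           interp = c("tricubic", "trilinear")) {
  stopifnot(inherits(volume, "refractive_index_volume"),
            inherits(wave, "plane_wave"))
  interp <- match.arg(interp)
  if (pad_factor < 2) stop("pad_factor must be >= 2", call. = FALSE)
  lam <- wave$wavelength_nm / 1000          # um
  nb <- wave$background_index
  k0 <- 2 * pi / lam
  k <- k0 * nb
  q_max <- 2 * k
  h <- volume$spacing
  if (h > pi / q_max) {
    stop(sprintf(
      "voxel spacing %.4g um too coarse for q_max; need spacing <= %.4g um",
      h, pi / q_max
    ), call. = FALSE)
  }

  d <- dim(volume$values)
  np <- vapply(pad_factor * d, next_fft_size, integer(1))
  Fpot <- k0^2 * (volume$values^2 - nb^2)
  Fp <- array(0, dim = np)
  Fp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- Fpot
  # center the model at the origin so the transform's phase is structural
  Fp <- circshift(Fp, -(volume$origin - 1L))
  Fh <- stats::fft(Fp) * h^3

  th <- (0:180) * pi / 180
  ph <- (0:360) * pi / 180
  st <- sin(th); ct <- cos(th)
  qx <- k * outer(st, cos(ph))
  qy <- k * outer(st, sin(ph))
  qz <- k * matrix(ct - 1, nrow = 181, ncol = 361)
  dq <- 2 * pi / (np * h)
  amp <- interp_fourier(Fh, np, dq, as.vector(qx), as.vector(qy),
                        as.vector(qz), interp)
  pol <- 1 - outer(st^2, cos(ph)^2)
  inten <- matrix((Mod(amp) / (4 * pi))^2, nrow = 181, ncol = 361) * pol
  inten[inten < 0] <- 0

  structure(
    list(intensity = inten, theta = 0:180, phi = 0:360, wave = wave,
         solver = "born",
         provenance = list(spec = unclass(volume$spec),
                           pad_factor = pad_factor, interp = interp)),
    class = "scattering_pattern"
  )
}

# Separable interpolation of a periodic FFT-ordered complex array at
# arbitrary angular frequencies (qx, qy, qz). Periodic index wrap gives
# negative frequencies for free.
#' @noRd
interp_fourier <- function(Fh, np, dq, qx, qy, qz, method) {
  fx <- qx / dq[1]; fy <- qy / dq[2]; fz <- qz / dq[3]
  i0 <- floor(fx); j0 <- floor(fy); k0 <- floor(fz)
  sx <- fx - i0; sy <- fy - j0; sz <- fz - k0
  if (method == "trilinear") {
    offs <- 0:1
    wx <- cbind(1 - sx, sx); wy <- cbind(1 - sy, sy); wz <- cbind(1 - sz, sz)
  } else {
    offs <- -1:2
    wx <- keys_weights(sx); wy <- keys_weights(sy); wz <- keys_weights(sz)
  }
  n1 <- np[1]; n2 <- np[2]; n3 <- np[3]
  acc <- complex(length(fx))
  for (a in seq_along(offs)) {
    ia <- (i0 + offs[a]) %% n1
    for (b in seq_along(offs)) {
      jb <- (j0 + offs[b]) %% n2
      wab <- wx[, a] * wy[, b]
      for (cc in seq_along(offs)) {
        kc <- (k0 + offs[cc]) %% n3
        lin <- 1 + ia + n1 * (jb + n2 * kc)
        acc <- acc + (wab * wz[, cc]) * Fh[lin]
      }
    }
  }
  acc
}

# Keys cubic-convolution weights (a = -1/2) for offsets -1, 0, 1, 2
#' @noRd
keys_weights <- function(s) {
  s2 <- s * s; s3 <- s2 * s
  cbind(-0.5 * s + s2 - 0.5 * s3,
        1 - 2.5 * s2 + 1.5 * s3,
        0.5 * s + 2 * s2 - 1.5 * s3,
        -0.5 * s2 + 0.5 * s3)
}

#' @export
print.scattering_pattern <- function(x, ...) {
  cat(sprintf(
    "<scattering_pattern> 181x361 deg grid, solver %s, lambda %.0f nm, n_out %.3f\n  intensity range [%.3g, %.3g]\n",
    x$solver, x$wave$wavelength_nm, x$wave$background_index,
    min(x$intensity), max(x$intensity)
  ))
  invisible(x)
}

# Pattern container I/O -------------------------------------------------

#' Save / load a scattering pattern
#'
#' Raw little-endian doubles (`<path>`) plus a JSON sidecar (`<path>.json`)
#' with the grid shape, wave configuration, solver tag and provenance.
#' Bit-exact round trip.
#'
#' @param pattern a `scattering_pattern`.
#' @param path payload path; sidecar gets `.json` appended.
#' @export
save_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "scattering_pattern"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.vector(pattern$intensity), con, size = 8, endian = "little")
  meta <- list(
    format = "nucscatter-pattern-v1",
    dims = dim(pattern$intensity),
    wavelength_nm = pattern$wave$wavelength_nm,
    background_index = pattern$wave$background_index,
    polarization = pattern$wave$polarization,
    propagation = pattern$wave$propagation,
    solver = pattern$solver,
    provenance = pattern$provenance
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_pattern
#' @export
load_pattern <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("missing payload file: ", path, call. = FALSE)
  if (!file.exists(side)) stop("missing sidecar: ", side, call. = FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  required <- c("dims", "wavelength_nm", "background_index", "solver")
  missing <- required[!required %in% names(meta)]
  if (length(missing)) {
    stop("pattern sidecar is missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = prod(meta$dims), size = 8, endian = "little")
  structure(
    list(intensity = matrix(vals, nrow = meta$dims[1], ncol = meta$dims[2]),
         theta = 0:180, phi = 0:360,
         wave = plane_wave(meta$wavelength_nm, meta$background_index),
         solver = meta$solver,
         provenance = meta$provenance),
    class = "scattering_pattern"
  )
}
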
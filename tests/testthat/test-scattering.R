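test_that("Born pattern of a homogeneous sphere matches the analytic form factor", {
  vol <- build_model(nuclear_model_spec("sphere", R = 2.0, n = 1.40,
                                        n_out = 1.36, lc = 0.7, delta_n = 0,
                                        spacing = 0.1, seed = 1))
  wave <- plane_wave(800, 1.36)
  pat <- born_far_field(vol, wave)
  expect_identical(dim(pat$intensity), c(181L, 361L))
  expect_true(all(pat$intensity >= 0))

  th <- (0:180) * pi / 180
  ph <- (0:360) * pi / 180
  k <- 2 * pi * 1.36 / 0.8
  q <- k * sqrt(outer(2 - 2 * cos(th), rep(1, 361)))
  ff <- sphere_form_factor(as.vector(q), 2.0)
  pol <- 1 - outer(sin(th)^2, cos(ph)^2)
  amp <- sqrt(as.vector(pat$intensity / pmax(pol, 1e-300)))
  sel <- abs(ff) > 0.01 * max(abs(ff)) & as.vector(pol) > 1e-6
  s <- sum(amp[sel] * abs(ff[sel])) / sum(ff[sel]^2)
  rel_rms <- sqrt(mean((amp[sel] - s * abs(ff[sel]))^2)) /
    sqrt(mean((s * ff[sel])^2))
  expect_lt(rel_rms, 0.02)

  # spherical symmetry: intensity / polarization factor constant along phi
  # at fixed theta, checked away from form-factor nulls where the relative
  # interpolation tolerance is meaningful
  depol <- pat$intensity / pmax(pol, 1e-300)
  ff_row <- sphere_form_factor(k * sqrt(2 - 2 * cos(th)), 2.0)
  check_rows <- function(thresh, tol) {
    rows <- setdiff(which(abs(ff_row) > thresh * max(abs(ff_row))), 1)
    for (row in rows) {
      v <- depol[row, pol[row, ] > 0.1]
      expect_lt((max(v) - min(v)) / max(v), tol)
    }
  }
  check_rows(0.5, 0.05)   # main lobe: tight
  check_rows(0.1, 0.20)   # weaker signal: voxelization anisotropy shows

  # dipole null along the polarization axis
  expect_equal(pat$intensity[91, 1], 0)
  expect_equal(pat$intensity[91, 181], 0)
})

test_that("Born solver refuses under-resolved volumes and scales exactly with contrast", {
  wave <- plane_wave(800, 1.36)
  coarse <- build_model(nuclear_model_spec("sphere", R = 2.0, n = 1.4,
                                           n_out = 1.36, lc = 1.0, delta_n = 0,
                                           spacing = 0.25, seed = 1))
  expect_error(born_far_field(coarse, wave), "spacing")

  vol <- small_model(seed = 2)
  p1 <- born_far_field(vol, wave)
  vol2 <- vol
  vol2$values <- sqrt(2 * (vol$values^2 - 1.36^2) + 1.36^2)
  p2 <- born_far_field(vol2, wave)
  expect_equal(p2$intensity, 4 * p1$intensity, tolerance = 1e-10)
})

test_that("mirror symmetry: reflected volume gives the phi-reflected pattern", {
  vol <- small_model(seed = 3)
  wave <- plane_wave(800, 1.36)
  p <- born_far_field(vol, wave)
  volm <- vol
  volm$values <- vol$values[, dim(vol$values)[2]:1, ]
  pm <- born_far_field(volm, wave)
  expect_equal(pm$intensity, p$intensity[, 362 - (1:361)], tolerance = 1e-8)
})

test_that("integrated Born power grows with the fluctuation extent", {
  wave <- plane_wave(800, 1.36)
  th <- (0:180) * pi / 180
  w <- sin(th); w[c(1, 181)] <- w[c(1, 181)] / 2
  power <- function(dn) {
    mean(sapply(1:3, function(s) {
      pat <- born_far_field(small_model(seed = s, delta_n = dn), wave)
      sum(rowSums(pat$intensity[, 1:360]) * w)
    }))
  }
  p <- sapply(c(0.01, 0.02, 0.03), power)
  expect_true(all(diff(p) > 0))
})

test_that("Mie oracle: cross-section closure, Rayleigh limit, forward dominance", {
  R <- 4.0; n <- 1.40; n_out <- 1.36
  k <- 2 * pi * n_out / 0.8
  th <- seq(0, 180, by = 0.1)
  S <- mie_amplitudes(th, R, n, n_out)
  integ <- (Mod(S$S1)^2 + Mod(S$S2)^2) * sin(th * pi / 180)
  wq <- rep(0.1 * pi / 180, length(th)); wq[c(1, length(th))] <- wq[1] / 2
  csca_quad <- pi / k^2 * sum(integ * wq)
  csca_series <- mie_qsca(R, n, n_out) * pi * R^2
  expect_lt(abs(csca_quad / csca_series - 1), 0.005)

  pat <- mie_reference(R, n, n_out)
  expect_identical(which.max(pat$intensity[, 1]), 1L)

  ray <- mie_reference(0.01, n, n_out)
  pol <- 1 - outer(sin((0:180) * pi / 180)^2, cos((0:360) * pi / 180)^2)
  expect_lt(max(abs(ray$intensity / max(ray$intensity) - pol)), 0.02)
})

test_that("backend registry enforces the pattern contract", {
  expect_true("born" %in% list_backends())
  vol <- small_model(seed = 1)
  wave <- plane_wave(800, 1.36)
  expect_error(solve_pattern(vol, wave, backend = "fdtd"),
               "unknown backend.*born")

  register_backend("bad_grid", function(volume, wave, ...) {
    as_pattern(matrix(1, 10, 10))
  })
  expect_error(solve_pattern(vol, wave, backend = "bad_grid"), "181x361")

  register_backend("bad_sign", function(volume, wave, ...) {
    m <- matrix(1, 181, 361); m[5, 5] <- -1
    as_pattern(m)
  })
  expect_error(solve_pattern(vol, wave, backend = "bad_sign"), "negative")

  p <- solve_pattern(vol, wave, backend = "born")
  expect_s3_class(p, "scattering_pattern")
})

test_that("pattern containers round-trip and validate metadata", {
  pat <- born_far_field(small_model(seed = 5), plane_wave(800, 1.36))
  path <- file.path(tempdir(), "p1.pat")
  save_pattern(pat, path)
  back <- load_pattern(path)
  expect_identical(back$intensity, pat$intensity)
  expect_identical(back$wave$wavelength_nm, pat$wave$wavelength_nm)
  expect_identical(back$provenance$spec$seed, pat$provenance$spec$seed)

  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$wavelength_nm <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(load_pattern(path), "wavelength_nm")
  unlink(c(path, paste0(path, ".json")))
})
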
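test_that("built models honor the mask, the mean and the fluctuation scale", {
  spec <- nuclear_model_spec("sphere", R = 2.5, n = 1.40, n_out = 1.36,
                             lc = 0.7, delta_n = 0.02, spacing = 0.1, seed = 4)
  vol <- build_model(spec)
  d <- dim(vol$values)
  ctr <- vol$origin
  ax <- lapply(1:3, function(a) (seq_len(d[a]) - ctr[a]) * vol$spacing)
  r2 <- outer(ax[[1]]^2, ax[[2]]^2, `+`)
  r2 <- outer(r2, ax[[3]]^2, `+`)
  # all fluctuating voxels lie inside the analytic surface (allow boundary
  # voxels a half-voxel tolerance for center-rule classification)
  fluct <- vol$values != 1.36
  expect_identical(sum(fluct), vol$mask_count)
  expect_lte(max(r2[fluct]), 2.5^2 * (1 + 1e-12))
  expect_gte(min(r2[!fluct]), 2.5^2 * (1 - 1e-12))
  expect_lt(abs(mean(vol$values[fluct]) - 1.40), 1e-9)
  sdm <- stats::sd(vol$values[fluct])
  expect_gt(sdm, 0.8 * 0.02); expect_lt(sdm, 1.2 * 0.02)
  expect_true(all(vol$values > 1))
})

test_that("zero fluctuation gives an exactly homogeneous nucleus", {
  vol <- build_model(nuclear_model_spec("sphere", R = 1.5, n = 1.4,
                                        n_out = 1.36, lc = 0.7, delta_n = 0,
                                        spacing = 0.1, seed = 1))
  expect_setequal(unique(as.vector(vol$values)), c(1.36, 1.4))
})

test_that("ellipsoid voxelization matches the analytic volume", {
  spec <- nuclear_model_spec("ellipsoid", Sx = 3.0, Sy = 5.0, Sz = 4.0,
                             n = 1.40, n_out = 1.36, lc = 0.7, delta_n = 0,
                             spacing = 0.1, seed = 1)
  vol <- build_model(spec)
  analytic <- (4 / 3) * pi * 3 * 5 * 4 / 0.1^3
  expect_lt(abs(vol$mask_count / analytic - 1), 0.02)
})

test_that("re-centering holds for every seed and unphysical delta_n refuses", {
  for (s in 1:5) {
    spec <- nuclear_model_spec("sphere", R = 1.8, n = 1.40, n_out = 1.36,
                               lc = 0.6, delta_n = 0.03, spacing = 0.1, seed = s)
    vol <- build_model(spec)
    d <- dim(vol$values)
    inside <- vol$values[vol$values != 1.36]
    expect_lt(abs(mean(inside) - 1.40), 1e-9)
  }
  expect_error(
    build_model(nuclear_model_spec("sphere", R = 1.5, n = 1.05, n_out = 1.06,
                                   lc = 0.7, delta_n = 0.03, spacing = 0.1,
                                   seed = 2)),
    "<= 1")
})

test_that("parameter grids reproduce the tabulated designs", {
  g <- parameter_grid("table1_dense", "lc_sweep")
  expect_length(g, 7)
  expect_equal(sapply(g, `[[`, "lc"), seq(0.4, 1.0, by = 0.1))
  expect_true(all(sapply(g, `[[`, "R") == 4.0))
  expect_true(all(sapply(g, `[[`, "n") == 1.40))
  expect_true(all(sapply(g, `[[`, "n_out") == 1.36))
  expect_true(all(sapply(g, `[[`, "delta_n") == 0.020))

  gi <- parameter_grid("table1_inverted", "dn_sweep")
  expect_length(gi, 7)
  expect_equal(sapply(gi, `[[`, "delta_n"), seq(0.005, 0.035, by = 0.005))
  expect_true(all(sapply(gi, `[[`, "n") == 1.36))
  expect_true(all(sapply(gi, `[[`, "n_out") == 1.40))
  expect_true(all(sapply(gi, `[[`, "lc") == 0.7))

  g2 <- parameter_grid("table2", "size_index_sweep")
  expect_length(g2, 9)  # default + 2 off-default each for Sx, Sy, Sz, n
  expect_true(all(sapply(g2, `[[`, "lc") == 0.7))
  expect_true(all(sapply(g2, `[[`, "delta_n") == 0.020))
  expect_setequal(unique(sapply(g2, `[[`, "Sx")), c(2.5, 3.0, 3.5))
  expect_setequal(unique(sapply(g2, `[[`, "Sy")), c(4.5, 5.0, 5.5))
  expect_setequal(unique(sapply(g2, `[[`, "Sz")), c(3.5, 4.0, 4.5))
  expect_setequal(unique(sapply(g2, `[[`, "n")), c(1.39, 1.40, 1.41))

  expect_error(parameter_grid("table1_dense", "lc_sweep", lc_values = 0.45),
               "tabulated")
})

test_that("model containers round-trip losslessly and validate metadata", {
  vol <- small_model(seed = 7)
  path <- file.path(tempdir(), "m1.vol")
  save_model(vol, path)
  back <- load_model(path)
  expect_identical(back$values, vol$values)
  expect_identical(back$spacing, vol$spacing)
  expect_identical(back$spec$seed, vol$spec$seed)
  expect_identical(back$spec$lc, vol$spec$lc)

  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  meta$spacing_um <- NULL
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "spacing_um")
  unlink(c(path, paste0(path, ".json")))
})
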
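# Independent brute-force oracles, deliberately naive.

# ordered co-occurrence counting by explicit double loop
glcm_oracle <- function(q, direction) {
  counts <- matrix(0L, 8, 8)
  nr <- nrow(q); nc <- ncol(q)
  if (direction == "theta") {
    for (i in seq_len(nr - 1)) for (j in seq_len(nc)) {
      counts[q[i, j] + 1L, q[i + 1, j] + 1L] <-
        counts[q[i, j] + 1L, q[i + 1, j] + 1L] + 1L
    }
  } else {
    for (i in seq_len(nr)) for (j in seq_len(nc - 1)) {
      counts[q[i, j] + 1L, q[i, j + 1] + 1L] <-
        counts[q[i, j] + 1L, q[i, j + 1] + 1L] + 1L
    }
  }
  counts
}

contrast_oracle <- function(p) {
  s <- 0
  for (i in 0:7) for (j in 0:7) s <- s + abs(i - j)^2 * p[i + 1, j + 1]
  s
}

mean_log_oracle <- function(intensity, rows, cols, Io) {
  s <- 0; n <- 0
  for (i in rows) for (j in cols) {
    s <- s + log10(intensity[i, j] / Io); n <- n + 1
  }
  s / n
}

# grid search over lc for the constrained Gaussian correlation fit
lc_grid_oracle <- function(y, r, lc_grid = seq(0.05, 3, by = 0.001)) {
  ss <- vapply(lc_grid, function(lc) sum((y - exp(-r^2 / lc^2))^2), numeric(1))
  lc_grid[which.min(ss)]
}

# wrap a bare intensity matrix as a scattering_pattern
as_pattern <- function(intensity, n_out = 1.36) {
  structure(
    list(intensity = intensity, theta = 0:180, phi = 0:360,
         wave = plane_wave(800, n_out), solver = "test", provenance = NULL),
    class = "scattering_pattern"
  )
}

# small stochastic sphere model for solver tests
small_model <- function(seed = 1L, delta_n = 0.02, lc = 0.7, R = 2.0,
                        spacing = 0.1) {
  build_model(nuclear_model_spec("sphere", R = R, n = 1.40, n_out = 1.36,
                                 lc = lc, delta_n = delta_n,
                                 spacing = spacing, seed = seed))
}
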
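# Mie series for a homogeneous sphere in a non-absorbing medium.
# Serves as the independent oracle for the Born solver on homogeneous
# spheres and as the reference any rigorous backend can be validated
# against; it is never the pipeline's solver.

# Lorenz-Mie expansion coefficients a_n, b_n.
# x: size parameter 2*pi*n_out*R/lambda_vac, m: relative index n/n_out.
# Logarithmic derivative by downward recurrence; Riccati-Bessel psi/chi
# upward (stable for real x of this magnitude).
#' @noRd
mie_ab <- function(x, m) {
  nmax <- ceiling(x + 4 * x^(1/3) + 2)
  nmx <- max(nmax, ceiling(abs(m * x))) + 16
  mx <- m * x
  D <- numeric(nmx)
  for (j in nmx:2) {
    D[j - 1] <- j / mx - 1 / (D[j] + j / mx)
  }
  psi_m1 <- cos(x); psi0 <- sin(x)
  chi_m1 <- -sin(x); chi0 <- cos(x)
  a <- complex(nmax); b <- complex(nmax)
  psi_nm1 <- psi0; psi_nm2 <- psi_m1
  chi_nm1 <- chi0; chi_nm2 <- chi_m1
  for (n in seq_len(nmax)) {
    psi <- (2 * n - 1) / x * psi_nm1 - psi_nm2
    chi <- (2 * n - 1) / x * chi_nm1 - chi_nm2
    xi <- complex(real = psi, imaginary = -chi)
    xi_nm1 <- complex(real = psi_nm1, imaginary = -chi_nm1)
    da <- D[n] / m + n / x
    db <- D[n] * m + n / x
    a[n] <- (da * psi - psi_nm1) / (da * xi - xi_nm1)
    b[n] <- (db * psi - psi_nm1) / (db * xi - xi_nm1)
    psi_nm2 <- psi_nm1; psi_nm1 <- psi
    chi_nm2 <- chi_nm1; chi_nm1 <- chi
  }
  list(a = a, b = b, nmax = nmax)
}

# Scattering amplitudes S1(theta), S2(theta) for a vector of angles.
#' @noRd
mie_S12 <- function(x, m, theta) {
  ab <- mie_ab(x, m)
  mu <- cos(theta)
  nt <- length(mu)
  S1 <- complex(nt); S2 <- complex(nt)
  pi_nm1 <- rep(0, nt)   # pi_0
  pi_n <- rep(1, nt)     # pi_1
  for (n in seq_len(ab$nmax)) {
    tau_n <- n * mu * pi_n - (n + 1) * pi_nm1
    fac <- (2 * n + 1) / (n * (n + 1))
    S1 <- S1 + fac * (ab$a[n] * pi_n + ab$b[n] * tau_n)
    S2 <- S2 + fac * (ab$a[n] * tau_n + ab$b[n] * pi_n)
    pi_np1 <- ((2 * n + 1) * mu * pi_n - (n + 1) * pi_nm1) / n
    pi_nm1 <- pi_n
    pi_n <- pi_np1
  }
  list(S1 = S1, S2 = S2, nmax = ab$nmax)
}

#' Mie scattering efficiency of a homogeneous sphere
#'
#' Scattering efficiency `Qsca = (2/x^2) sum (2n+1)(|a_n|^2 + |b_n|^2)` for
#' a sphere of radius `R` and index `n` in a medium of index `n_out`.
#'
#' @param R sphere radius, um.
#' @param n sphere refractive index.
#' @param n_out medium refractive index.
#' @param wavelength_nm vacuum wavelength, nm.
#' @return Dimensionless scattering efficiency.
#' @export
mie_qsca <- function(R, n, n_out, wavelength_nm = 800) {
  x <- 2 * pi * n_out * R / (wavelength_nm / 1000)
  ab <- mie_ab(x, n / n_out)
  nn <- seq_len(ab$nmax)
  (2 / x^2) * sum((2 * nn + 1) * (Mod(ab$a)^2 + Mod(ab$b)^2))
}

#' Mie reference scattering pattern for a homogeneous sphere
#'
#' Full Lorenz-Mie series assembled onto the 181 x 361 degree grid with the
#' azimuthal dependence of x-polarized incidence,
#' `I(theta, phi) = |S2(theta) cos(phi)|^2 + |S1(theta) sin(phi)|^2`
#' (scattering-plane decomposition), in units of `1/k^2` times the squared
#' amplitudes (differential cross-section scale). The series is truncated at
#' the standard size-parameter-based order `x + 4 x^(1/3) + 2`.
#'
#' @inheritParams mie_qsca
#' @param wave optional [plane_wave()]; overrides `wavelength_nm`/`n_out`.
#' @return A `scattering_pattern` with solver tag `"mie"`.
#' @export
mie_reference <- function(R, n, n_out, wavelength_nm = 800, wave = NULL) {
  if (!is.null(wave)) {
    wavelength_nm <- wave$wavelength_nm
    n_out <- wave$background_index
  } else {
    wave <- plane_wave(wavelength_nm, n_out)
  }
  lam <- wavelength_nm / 1000
  x <- 2 * pi * n_out * R / lam
  k <- 2 * pi * n_out / lam
  th <- (0:180) * pi / 180
  S <- mie_S12(x, n / n_out, th)
  ph <- (0:360) * pi / 180
  inten <- (outer(Mod(S$S2)^2, cos(ph)^2) + outer(Mod(S$S1)^2, sin(ph)^2)) / k^2
  structure(
    list(intensity = inten, theta = 0:180, phi = 0:360, wave = wave,
         solver = "mie",
         provenance = list(R = R, n = n, n_out = n_out, nmax = S$nmax)),
    class = "scattering_pattern"
  )
}

#' Mie scattering amplitudes at arbitrary polar angles
#'
#' Complex amplitudes `S1` (perpendicular) and `S2` (parallel) of the
#' Lorenz-Mie series, for quadrature checks and custom angular grids.
#'
#' @param theta_deg polar angles, degrees.
#' @inheritParams mie_qsca
#' @return Data frame with columns `theta_deg`, `S1`, `S2` (complex).
#' @export
mie_amplitudes <- function(theta_deg, R, n, n_out, wavelength_nm = 800) {
  x <- 2 * pi * n_out * R / (wavelength_nm / 1000)
  S <- mie_S12(x, n / n_out, theta_deg * pi / 180)
  data.frame(theta_deg = theta_deg, S1 = S$S1, S2 = S$S2)
}

#' First-Born form factor of a homogeneous sphere (closed form)
#'
#' The normalized amplitude `3 (sin(qR) - qR cos(qR)) / (qR)^3` (1 at
#' `q = 0`), evaluated independently of any FFT. Used as the analytic
#' cross-check of the Born solver.
#'
#' @param q momentum-transfer magnitudes, 1/um.
#' @param R sphere radius, um.
#' @return Numeric vector of the same length as `q`.
#' @export
sphere_form_factor <- function(q, R) {
  u <- q * R
  out <- ifelse(abs(u) < 1e-6,
                1 - u^2 / 10,
                3 * (sin(u) - u * cos(u)) / u^3)
  as.numeric(out)
}
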
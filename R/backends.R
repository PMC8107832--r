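# Solver backend registry. Any far-field solver (e.g. an external rigorous
# FDTD code) can be plugged in by name as long as it honors the contract:
# solve(volume, wave, ...) -> scattering_pattern on the exact 181 x 361 grid
# with finite, non-negative intensities.

.backends <- new.env(parent = emptyenv())

#' Register a far-field solver backend
#'
#' @param name backend name (string).
#' @param fn function `(volume, wave, ...)` returning a
#'   `scattering_pattern`.
#' @export
register_backend <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .backends)
  invisible(name)
}

#' List registered solver backends
#' @return Character vector of backend names.
#' @export
list_backends <- function() sort(ls(envir = .backends))

#' Solve a far-field pattern through a registered backend
#'
#' Dispatches to the named backend and validates its output against the
#' pattern contract (exact 181 x 361 grid, finite non-negative intensity).
#'
#' @param volume a `refractive_index_volume`.
#' @param wave a [plane_wave()].
#' @param backend backend name; see [list_backends()].
#' @param ... passed to the backend.
#' @return A validated `scattering_pattern`.
#' @export
solve_pattern <- function(volume, wave, backend = "born", ...) {
  if (!exists(backend, envir = .backends, inherits = FALSE)) {
    stop(sprintf("unknown backend '%s'; registered: %s",
                 backend, paste(list_backends(), collapse = ", ")),
         call. = FALSE)
  }
  fn <- get(backend, envir = .backends, inherits = FALSE)
  pat <- fn(volume, wave, ...)
  validate_pattern(pat, backend)
}

#' @noRd
validate_pattern <- function(pat, backend) {
  if (!inherits(pat, "scattering_pattern")) {
    stop(sprintf("backend '%s' did not return a scattering_pattern", backend),
         call. = FALSE)
  }
  if (!identical(dim(pat$intensity), c(181L, 361L))) {
    stop(sprintf("backend '%s' emitted a %s grid; the contract requires 181x361",
                 backend, paste(dim(pat$intensity), collapse = "x")),
         call. = FALSE)
  }
  if (any(!is.finite(pat$intensity)) || any(pat$intensity < 0)) {
    stop(sprintf("backend '%s' emitted non-finite or negative intensities", backend),
         call. = FALSE)
  }
  pat
}

.onLoad <- function(libname, pkgname) {
  register_backend("born", born_far_field)
}
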
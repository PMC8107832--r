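# Internal FFT helpers shared by the field generators and the Born solver.

#' @noRd
next_fft_size <- function(n) {
  # smallest 5-smooth integer >= n (mixed-radix FFT friendly)
  stats::nextn(as.integer(n), factors = c(2L, 3L, 5L))
}

#' DFT sample frequencies (cycles per unit length), FFT ordering
#' @noRd
fft_freqs <- function(n, d) {
  half <- floor((n - 1) / 2)
  c(0:half, -(n - half - 1):-1) / (n * d)
}

#' Inverse FFT with 1/N normalization
#' @noRd
ifft <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Circularly shift an array by `s` (one entry per dimension)
#' @noRd
circshift <- function(x, s) {
  d <- dim(x)
  idx <- lapply(seq_along(d), function(a) ((seq_len(d[a]) - 1 - s[a]) %% d[a]) + 1)
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Sum of squared angular frequencies over a 2- or 3-d grid, FFT ordering
#' @noRd
ksq_grid <- function(np, spacing) {
  kax <- lapply(np, function(n) (2 * pi * fft_freqs(n, spacing))^2)
  k2 <- outer(kax[[1]], kax[[2]], `+`)
  if (length(np) == 3) k2 <- outer(k2, kax[[3]], `+`)
  k2
}
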
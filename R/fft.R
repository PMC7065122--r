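# Centred unitary FFT helpers.
#
# Convention used throughout the package: image and k-space grids are
# ny x nx matrices with the DC (ky = 0, kx = 0) sample at grid index
# (ny/2 + 1, nx/2 + 1); transforms are unitary (norm-preserving), so
# Parseval holds without scale factors.

fftshift_mat <- function(x) {
  d <- dim(x)
  i <- c(seq.int(d[1L] %/% 2L + 1L, d[1L]), seq_len(d[1L] %/% 2L))
  j <- c(seq.int(d[2L] %/% 2L + 1L, d[2L]), seq_len(d[2L] %/% 2L))
  x[i, j, drop = FALSE]
}

ifftshift_mat <- function(x) {
  d <- dim(x)
  i <- c(seq.int(d[1L] - d[1L] %/% 2L + 1L, d[1L]), seq_len(d[1L] - d[1L] %/% 2L))
  j <- c(seq.int(d[2L] - d[2L] %/% 2L + 1L, d[2L]), seq_len(d[2L] - d[2L] %/% 2L))
  x[i, j, drop = FALSE]
}

#' Centred unitary 2D FFT (image to k-space)
#'
#' @param img complex or numeric matrix.
#' @return complex matrix of the same size; DC at `(ny/2+1, nx/2+1)`.
#' @export
fft2c <- function(img) {
  fftshift_mat(stats::fft(ifftshift_mat(img))) / sqrt(length(img))
}

#' Centred unitary 2D inverse FFT (k-space to image)
#'
#' @param ksp complex matrix with DC at `(ny/2+1, nx/2+1)`.
#' @return complex image matrix.
#' @export
ifft2c <- function(ksp) {
  fftshift_mat(stats::fft(ifftshift_mat(ksp), inverse = TRUE)) / sqrt(length(ksp))
}

# signed frequency index of each grid row/col under the centred convention
freq_index <- function(n) seq_len(n) - (n %/% 2L + 1L)

# phase factor implementing a translation by `shift` pixels along the
# dimension whose signed frequency indices are `k` (length n):
# image(y - shift) <-> K(k) * exp(-2i pi k shift / n)
shift_phase <- function(n, shift) {
  exp(-2i * pi * freq_index(n) * shift / n)
}
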
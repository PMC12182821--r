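#' Non-uniform Fourier sampling of a 2D image
#'
#' Exact non-uniform discrete Fourier transform
#' `s_j = (1/sqrt(Nx*Ny)) * sum_{p,q} img[p,q] exp(-2*pi*i (kx_j x_p + ky_j y_q))`
#' evaluated separably through two complex matrix products, so the cost is
#' `O(n_k * Nx * Ny)` with BLAS-level throughput and no gridding approximation.
#' The symmetric `1/sqrt(Nx*Ny)` normalisation makes the operator unitary when
#' the sample set is the full Cartesian k-grid.
#'
#' @param img complex (or numeric) `Nx x Ny` matrix.
#' @param k `n_k x 2` matrix of k-space coordinates (cycles/mm).
#' @param x,y voxel-centre coordinates (mm) along the two image axes.
#' @return complex vector of `n_k` samples.
#' @export
ndft_forward <- function(img, k, x, y) {
  Bx <- exp(-2i * pi * outer(k[, 1], x))      # n_k x Nx
  By <- exp(-2i * pi * outer(k[, 2], y))      # n_k x Ny
  rowSums((Bx %*% img) * By) / sqrt(length(x) * length(y))
}

#' Adjoint of [ndft_forward()]
#'
#' `img[p,q] = (1/sqrt(Nx*Ny)) * sum_j s_j exp(+2*pi*i (kx_j x_p + ky_j y_q))`.
#'
#' @param s complex vector of `n_k` samples.
#' @inheritParams ndft_forward
#' @return complex `Nx x Ny` matrix.
#' @export
ndft_adjoint <- function(s, k, x, y) {
  Bx <- exp(-2i * pi * outer(k[, 1], x))
  By <- exp(-2i * pi * outer(k[, 2], y))
  crossprod(Conj(Bx), s * Conj(By)) / sqrt(length(x) * length(y))
}
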
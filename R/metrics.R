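#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10( Nx Ny MAXI^2 / sum((A - R)^2) )` in dB, computed on
#' un-normalised images. `maxi = "auto"` uses the maximum value of the
#' reference image as the peak. Identical images return `Inf`.
#'
#' @param A reconstructed image ([pa_grid()] or matrix).
#' @param R reference image of the same size.
#' @param maxi peak value, or `"auto"`.
#' @return PSNR in dB.
#' @export
psnr <- function(A, R, maxi = "auto") {
  a <- if (inherits(A, "pa_grid")) A$values else as.matrix(A)
  r <- if (inherits(R, "pa_grid")) R$values else as.matrix(R)
  if (!all(dim(a) == dim(r))) stop("images must have the same dimensions")
  if (identical(maxi, "auto")) maxi <- max(r)
  if (!is.numeric(maxi) || maxi <= 0) stop("maxi must be positive")
  sse <- sum((a - r)^2)
  if (sse == 0) return(Inf)
  10 * log10(length(a) * maxi^2 / sse)
}

#' Relative distance to the reference image
#'
#' `d = sqrt( sum((A - R)^2) / sum(R^2) )`; 0 for identical images, 1 for an
#' all-zero reconstruction.
#'
#' @inheritParams psnr
#' @return The scalar distance.
#' @export
distance_d <- function(A, R) {
  a <- if (inherits(A, "pa_grid")) A$values else as.matrix(A)
  r <- if (inherits(R, "pa_grid")) R$values else as.matrix(R)
  if (!all(dim(a) == dim(r))) stop("images must have the same dimensions")
  if (all(r == 0)) stop("reference image must not be all zero")
  sqrt(sum((a - r)^2) / sum(r^2))
}

#' Normalize an image for display
#'
#' Divides all pixels by the maximum value, the convention used for showing
#' reconstructions side by side. Display only — quality metrics are always
#' computed on un-normalised images.
#'
#' @param A a [pa_grid()] or matrix.
#' @return Same type as the input, peak value 1.
#' @export
normalize_for_display <- function(A) {
  a <- if (inherits(A, "pa_grid")) A$values else as.matrix(A)
  m <- max(a)
  if (m <= 0) stop("image has no positive values to normalise by")
  if (inherits(A, "pa_grid")) grid_with_values(A, as.vector(a / m)) else a / m
}

#' Metric report for a reconstruction
#'
#' @param recon a `pa_recon` (or [pa_grid()]).
#' @param reference ground-truth [pa_grid()].
#' @param maxi forwarded to [psnr()].
#' @return A one-row tibble with `psnr`, `distance_d` and the `maxi` used.
#' @export
metric_report <- function(recon, reference, maxi = "auto") {
  img <- if (inherits(recon, "pa_recon")) recon$image else recon
  r <- if (inherits(reference, "pa_grid")) reference$values else reference
  used_maxi <- if (identical(maxi, "auto")) max(r) else maxi
  tibble::tibble(psnr = psnr(img, reference, maxi),
                 distance_d = distance_d(img, reference),
                 maxi = used_maxi)
}
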
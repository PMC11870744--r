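#' Write / read a 3D stack as multi-page TIFF
#'
#' Thin wrappers around the `tiff` package for exchanging rendered or acquired
#' channel volumes. Intensities are scaled to [0, 1] by the stack maximum on
#' write (TIFF float convention); spot detection and Otsu-based segmentation
#' are invariant to that global scale. Page k holds the k-th z-plane, with
#' array axes (x, y).
#'
#' @param a 3D numeric array (x, y, z).
#' @param path TIFF file path.
#' @return `write_stack` returns the scale factor that was divided out,
#'   invisibly; `read_stack` returns a 3D array in [0, 1].
#' @export
write_stack <- function(a, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF stack I/O")
  stopifnot(length(dim(a)) == 3)
  mx <- max(a, 1e-12)
  pages <- lapply(seq_len(dim(a)[3]), function(k) {
    t(pmin(pmax(a[, , k] / mx, 0), 1))   # TIFF pages are row-major (y, x)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(mx)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF stack I/O")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  aperm(simplify2array(lapply(pages, as.matrix)), c(2, 1, 3))
}
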
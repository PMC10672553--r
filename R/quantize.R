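#' Quantize a masked ROI to Ng gray levels
#'
#' Equal-width binning of the in-mask intensity range into `Ng` levels, the
#' shared substrate of all gray-level matrix descriptors. A pixel with
#' intensity x maps to level `floor((x - lo)/(hi - lo) * Ng) + 1`, clipped
#' to `[1, Ng]`, where `lo`/`hi` are the in-mask minimum/maximum; the top
#' edge thus lands in level `Ng` (right-closed last bin). A constant ROI
#' maps entirely to level 1. Calibration on the in-mask min-max makes every
#' downstream matrix descriptor invariant to affine rescaling of the
#' intensities (MRI units are non-quantitative).
#'
#' @param sample an [roi_sample()].
#' @param Ng number of gray levels (>= 2); default 32.
#' @return Object of class `quantized_roi`: list with `levels` (integer
#'   matrix, 1..Ng inside the mask, 0 outside), `mask`, `Ng`, `lo`, `hi`.
#' @examples
#' roi <- roi_sample(matrix(1:64, 8, 8), matrix(TRUE, 8, 8), "s", "BME", "PDFSE")
#' q <- quantize_roi(roi, 4)
#' table(q$levels[q$mask])
#' @export
quantize_roi <- function(sample, Ng = 32L) {
  stopifnot(inherits(sample, "roi_sample"))
  Ng <- as.integer(Ng)
  if (is.na(Ng) || Ng < 2L) stop("Ng must be an integer >= 2", call. = FALSE)
  x <- sample$image
  m <- sample$mask
  lo <- min(x[m]); hi <- max(x[m])
  lev <- matrix(0L, nrow(x), ncol(x))
  if (hi > lo) {
    b <- floor((x[m] - lo) / (hi - lo) * Ng) + 1
    lev[m] <- as.integer(pmin(pmax(b, 1), Ng))
  } else {
    lev[m] <- 1L
  }
  structure(list(levels = lev, mask = m, Ng = Ng, lo = lo, hi = hi),
            class = "quantized_roi")
}

#' @export
print.quantized_roi <- function(x, ...) {
  cat(sprintf("<quantized_roi> %dx%d, Ng=%d, range [%g, %g], %d masked pixels\n",
              nrow(x$levels), ncol(x$levels), x$Ng, x$lo, x$hi, sum(x$mask)))
  invisible(x)
}
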
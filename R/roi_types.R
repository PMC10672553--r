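#' @useDynLib marrowtex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median quantile var sd rnorm runif pchisq pf
#'   pnorm aov TukeyHSD kruskal.test dnorm dist
#' @importFrom utils read.csv write.csv combn head
NULL

GROUP_LEVELS <- c("BME", "INJ", "OST")
SEQUENCE_LEVELS <- c("PDFSE", "STIR")
MIN_ROI_PIXELS <- 16L

#' Construct a validated ROI sample
#'
#' Bundles one subject's 2D intensity image with a binary lesion mask and
#' its diagnostic / sequence labels. All descriptor extraction in the
#' package operates on objects of this class.
#'
#' @param image numeric matrix of intensities (arbitrary scanner units).
#' @param mask logical (or coercible 0/1) matrix, same shape as `image`;
#'   `TRUE` marks pixels inside the region of interest.
#' @param subject_id character scalar.
#' @param group one of `"BME"`, `"INJ"`, `"OST"` (bone-marrow edema,
#'   recent injury, osteoarthritis).
#' @param sequence one of `"PDFSE"`, `"STIR"` (the two MRI sequence
#'   channels).
#' @return An object of class `roi_sample`: a list with elements
#'   `subject_id`, `group`, `sequence`, `image`, `mask`.
#' @examples
#' img <- matrix(rnorm(64), 8, 8)
#' roi <- roi_sample(img, matrix(TRUE, 8, 8), "s1", "BME", "PDFSE")
#' sum(roi$mask)
#' @export
roi_sample <- function(image, mask, subject_id, group, sequence) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (!is.matrix(mask)) stop("`mask` must be a matrix", call. = FALSE)
  if (!all(dim(image) == dim(mask))) {
    stop(sprintf("shape mismatch: image %dx%d vs mask %dx%d",
                 nrow(image), ncol(image), nrow(mask), ncol(mask)),
         call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop("image intensities must all be finite", call. = FALSE)
  }
  mask <- matrix(as.logical(mask != 0), nrow(mask), ncol(mask))
  if (anyNA(mask)) stop("mask contains missing values", call. = FALSE)
  npix <- sum(mask)
  if (npix < MIN_ROI_PIXELS) {
    stop(sprintf("degenerate ROI: mask has %d pixels (< %d required)",
                 npix, MIN_ROI_PIXELS), call. = FALSE)
  }
  if (!is.character(subject_id) || length(subject_id) != 1L) {
    stop("`subject_id` must be a single string", call. = FALSE)
  }
  group <- validate_token(group, GROUP_LEVELS, "group")
  sequence <- validate_token(sequence, SEQUENCE_LEVELS, "sequence")
  structure(
    list(subject_id = subject_id, group = group, sequence = sequence,
         image = image, mask = mask),
    class = "roi_sample"
  )
}

validate_token <- function(x, levels, what) {
  if (!is.character(x) || length(x) != 1L || !(x %in% levels)) {
    stop(sprintf("unknown %s token '%s'; expected one of: %s", what,
                 paste(as.character(x), collapse = ","),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  x
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("<roi_sample> subject %s  group %s  sequence %s  %dx%d image, %d masked pixels\n",
              x$subject_id, x$group, x$sequence,
              nrow(x$image), ncol(x$image), sum(x$mask)))
  invisible(x)
}

masked_values <- function(sample) sample$image[sample$mask]
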
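# Canonical descriptor registry: 81 names, grouped by family, alphabetical
# within family. Column order of every feature table is derived from here.

FO_NAMES <- paste0("fo_", c(
  "energy", "entropy", "iqr", "kurtosis", "mad", "max", "mean", "median",
  "min", "p10", "p25", "p75", "p90", "range", "skewness", "std", "variance"
))

GLCM_NAMES <- paste0("glcm_", c(
  "asm", "autocorrelation", "cluster_prominence", "cluster_shade",
  "contrast", "correlation", "diff_average", "diff_entropy",
  "diff_variance", "entropy", "idm", "imc1", "imc2", "inv_diff",
  "inv_diff_norm", "jmx", "joint_average", "mcc", "sum_average",
  "sum_entropy", "sum_squares", "sum_variance"
))

GLRLM_NAMES <- paste0("glrlm_", c(
  "glnu", "glnun", "glv", "hgre", "lgre", "lre", "lrhge", "lrlge",
  "re", "rlnu", "rlnun", "rlv", "rp", "sre", "srhge", "srlge"
))

GLSZM_NAMES <- paste0("glszm_", c(
  "glnu", "glnun", "glzv", "hgze", "lgze", "lze", "lzhge", "lzlge",
  "sze", "szhge", "szlge", "zp", "zse", "zsnu", "zsnun", "zsv"
))

TAM_NAMES <- paste0("tam_", c(
  "coarseness_entropy", "coarseness_mean", "coarseness_median",
  "coarseness_std", "contrast", "roughness"
))

LBP_NAMES <- paste0("lbp_", c("mean", "median", "npeaks", "uniformity"))

#' Canonical descriptor names
#'
#' The 81 texture descriptors computed by [extract_all()], in the canonical
#' column order: family blocks first-order, GLCM, GLRLM, GLSZM, Tamura,
#' LBP; names alphabetical within each block.
#'
#' @param family optional; one of `"fo"`, `"glcm"`, `"glrlm"`, `"glszm"`,
#'   `"tam"`, `"lbp"` to return a single family's names.
#' @return Character vector of descriptor names (length 81, or the family
#'   size 17/22/16/16/6/4).
#' @export
descriptor_names <- function(family = NULL) {
  fams <- list(fo = FO_NAMES, glcm = GLCM_NAMES, glrlm = GLRLM_NAMES,
               glszm = GLSZM_NAMES, tam = TAM_NAMES, lbp = LBP_NAMES)
  if (is.null(family)) return(unname(unlist(fams)))
  if (!family %in% names(fams)) {
    stop("unknown descriptor family: ", family, call. = FALSE)
  }
  fams[[family]]
}

# entropy in bits of a nonnegative weight vector (normalized internally)
entropy_bits <- function(w) {
  w <- w[w > 0]
  if (!length(w)) return(0)
  p <- w / sum(w)
  -sum(p * log2(p))
}

# equal-width binning of x into nbin bins over [lo, hi]; constant -> bin 1
bin_equal_width <- function(x, nbin, lo = min(x), hi = max(x)) {
  if (hi <= lo) return(rep(1L, length(x)))
  b <- floor((x - lo) / (hi - lo) * nbin) + 1L
  pmin(pmax(b, 1L), nbin)
}
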
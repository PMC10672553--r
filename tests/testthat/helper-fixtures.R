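# shared fixture builders (all data generated in code)

make_roi <- function(values, mask = NULL, group = "BME", sequence = "PDFSE",
                     id = "s1") {
  img <- if (is.matrix(values)) values else matrix(values, 8, 8)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(img), ncol(img))
  roi_sample(img, mask, id, group, sequence)
}

# random masked image: values on a small integer range, random mask with
# at least `min_px` pixels
random_masked_roi <- function(n = 8, min_px = 16, seed = 1) {
  set.seed(seed)
  img <- matrix(runif(n * n, 0, 10), n, n)
  repeat {
    mask <- matrix(runif(n * n) < 0.7, n, n)
    if (sum(mask) >= min_px) break
  }
  roi_sample(img, mask, sprintf("r%d", seed), "BME", "PDFSE")
}

# tiny two-group-size cohort spec for fast end-to-end tests
tiny_spec <- function(seed = 1, n = c(BME = 8L, INJ = 8L, OST = 8L)) {
  cohort_spec(n_per_group = n, size = c(32L, 32L), seed = seed)
}
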
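lev_roi <- function(levels) {
  # ROI whose quantized levels reproduce `levels` exactly (values 1..Ng)
  roi <- roi_sample(matrix(as.numeric(levels), nrow(levels)),
                    matrix(TRUE, nrow(levels), ncol(levels)),
                    "s", "BME", "PDFSE")
  quantize_roi(roi, max(levels))
}

test_that("build_glcm matches hand-enumerated pairs and symmetry relations", {
  # 2x2 levels [[1,2],[1,2]], direction E: both pairs are (1,2)
  # (hand-built quantized object: below the roi_sample size floor on purpose)
  q <- structure(list(levels = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                      mask = matrix(TRUE, 2, 2), Ng = 2L, lo = 0, hi = 1),
                 class = "quantized_roi")
  P <- build_glcm(q, "E")$P
  expect_equal(P[1, 2], 1)
  expect_equal(sum(P), 1)

  # N is the transpose of S on random inputs
  for (seed in 1:5) {
    roi <- random_masked_roi(seed = seed)
    q <- quantize_roi(roi, 4L)
    expect_equal(build_glcm(q, "N")$P, t(build_glcm(q, "S")$P),
                 tolerance = 1e-15)
    expect_equal(build_glcm(q, "E")$P, t(build_glcm(q, "W")$P),
                 tolerance = 1e-15)
  }

  # single-column mask has no E-direction pair
  m <- matrix(FALSE, 20, 4); m[, 2] <- TRUE
  roi <- roi_sample(matrix(rnorm(80), 20, 4), m, "s", "BME", "PDFSE")
  expect_error(build_glcm(quantize_roi(roi, 4L), "E"), "degenerate")
})

test_that("constant ROI gives the closed-form single-cell GLCM", {
  q <- quantize_roi(make_roi(matrix(3, 8, 8)), 32L)
  f <- glcm_features(q)
  expect_equal(unname(f[c("glcm_asm", "glcm_entropy", "glcm_contrast",
                          "glcm_jmx", "glcm_idm")]), c(1, 0, 0, 1, 1))
})

test_that("checkerboard contrast is 1 per direction", {
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1)
  f <- glcm_features(lev_roi(cb))
  expect_equal(unname(f["glcm_contrast"]), 1)
})

test_that("GLCM features equal the exhaustive pair-enumeration oracle", {
  for (seed in 1:20) {
    roi <- random_masked_roi(seed = 100 + seed)
    q <- quantize_roi(roi, 4L)
    per_dir <- list()
    for (d in c("N", "S", "E", "W")) {
      cnt <- oracle_glcm_counts(q$levels, q$mask, d, 4L)
      if (sum(cnt) > 0) per_dir[[d]] <- oracle_glcm_features(cnt)
    }
    want <- Reduce(`+`, per_dir)[names(glcm_features(q))] / length(per_dir)
    expect_equal(glcm_features(q), want, tolerance = 1e-12)
  }
})

test_that("ASM and JMX bounds hold", {
  for (seed in 1:10) {
    f <- glcm_features(quantize_roi(random_masked_roi(seed = seed), 6L))
    expect_gt(f[["glcm_asm"]], 0); expect_lte(f[["glcm_asm"]], 1)
    expect_gt(f[["glcm_jmx"]], 0); expect_lte(f[["glcm_jmx"]], 1)
    expect_lte(f[["glcm_asm"]], f[["glcm_jmx"]] + 1e-12)
  }
})

test_that("build_glrlm decomposes runs and conserves pixel mass", {
  # row [1,1,2,2,2] -> R[1,2] = 1, R[2,3] = 1
  m <- matrix(FALSE, 4, 5); m[1, ] <- TRUE; m[2:4, ] <- TRUE
  lv <- matrix(1, 4, 5); lv[1, ] <- c(1, 1, 2, 2, 2)
  q <- lev_roi(lv)
  R <- build_glrlm(q, "E")$R
  expect_equal(R[1, 2], 1)
  expect_equal(R[2, 3], 1)

  for (seed in 1:20) {
    roi <- random_masked_roi(seed = 200 + seed)
    q <- quantize_roi(roi, 4L)
    for (d in c("N", "E")) {
      g <- build_glrlm(q, d)
      expect_equal(sum(col(g$R) * g$R), sum(roi$mask))   # sum j * R[i,j]
    }
  }
})

test_that("GLRLM closed forms: single run and unit runs", {
  # 1x4 constant line inside a larger mask
  m <- matrix(FALSE, 6, 6); m[3, 2:5] <- TRUE
  # widen to meet the 16-pixel minimum: use a 4x4 block instead and check E
  m2 <- matrix(FALSE, 6, 6); m2[2:5, 2:5] <- TRUE
  roi <- roi_sample(matrix(5, 6, 6), m2, "s", "BME", "PDFSE")
  q <- quantize_roi(roi, 32L)
  g <- build_glrlm(q, "E")
  # four rows of length 4 at level 1
  expect_equal(g$R[1, 4], 4)
  expect_equal(g$Nr, 4)
  fv <- marrowtex:::glrlm_feature_vec(g$R, g$Np)
  expect_equal(unname(fv["glrlm_sre"]), 1 / 16)
  expect_equal(unname(fv["glrlm_lre"]), 16)
  expect_equal(unname(fv["glrlm_rlv"]), 0)
  expect_equal(unname(fv["glrlm_rp"]), 4 / 16)

  # strict checkerboard: all runs have length 1
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1)
  f <- glrlm_features(lev_roi(cb))
  expect_equal(unname(f[c("glrlm_sre", "glrlm_lre", "glrlm_rlv",
                          "glrlm_rp")]), c(1, 1, 0, 1))
})

test_that("GLRLM features equal the independent run-scan oracle", {
  for (seed in 1:20) {
    roi <- random_masked_roi(seed = 300 + seed)
    q <- quantize_roi(roi, 4L)
    per_dir <- lapply(c("N", "S", "E", "W"), function(d) {
      R <- oracle_glrlm_counts(q$levels, q$mask, d, 4L,
                               max(dim(q$levels)))
      oracle_glrlm_features(R, sum(q$mask))
    })
    want <- Reduce(`+`, per_dir) / 4
    expect_equal(glrlm_features(q), want[names(glrlm_features(q))],
                 tolerance = 1e-12)
  }
})

test_that("GLSZM zones are 8-connected and conserve pixel mass", {
  # two diagonally touching same-level pixels form one zone of size 2
  lv <- matrix(1, 5, 5)
  lv[2, 2] <- 2; lv[3, 3] <- 2
  z <- build_glszm(lev_roi(lv))
  expect_equal(z$Z[2, 2], 1)       # one zone of level 2, size 2

  # constant connected ROI -> one zone of size n
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  roi <- roi_sample(matrix(4, 6, 6), m, "s", "BME", "PDFSE")
  z2 <- build_glszm(quantize_roi(roi, 32L))
  expect_equal(z2$Z[1, 16], 1)
  expect_equal(z2$Nz, 1)

  for (seed in 1:20) {
    roi <- random_masked_roi(seed = 400 + seed)
    q <- quantize_roi(roi, 4L)
    z <- build_glszm(q)
    expect_equal(sum(col(z$Z) * z$Z), sum(roi$mask))
  }
})

test_that("strict checkerboard under 8-connectivity has two zones of size 8", {
  # diagonal neighbors of equal level merge: each color is one zone
  cb <- outer(1:4, 1:4, function(i, j) ((i + j) %% 2) + 1)
  q <- lev_roi(cb)
  z <- build_glszm(q)
  expect_equal(z$Nz, 2)
  expect_equal(unname(z$Z[1, 8]), 1)
  expect_equal(unname(z$Z[2, 8]), 1)
  f <- glszm_features(q)
  expect_equal(unname(f["glszm_sze"]), 1 / 64)
})

test_that("single-zone image: zero variances, zone percentage 1/n", {
  m <- matrix(FALSE, 6, 6); m[2:5, 2:5] <- TRUE
  roi <- roi_sample(matrix(4, 6, 6), m, "s", "BME", "PDFSE")
  f <- glszm_features(quantize_roi(roi, 32L))
  expect_equal(unname(f[c("glszm_zsv", "glszm_glzv")]), c(0, 0))
  expect_equal(unname(f["glszm_zp"]), 1 / 16)
})

test_that("GLSZM features equal the independent flood-fill oracle", {
  for (seed in 1:20) {
    roi <- random_masked_roi(seed = 500 + seed)
    q <- quantize_roi(roi, 4L)
    zones <- oracle_zones(q$levels, q$mask)
    want <- oracle_glszm_features(zones, 4L, sum(q$mask))
    expect_equal(glszm_features(q), want[names(glszm_features(q))],
                 tolerance = 1e-12)
  }
})

test_that("matrix families are affine-invariant and mask-independent", {
  roi <- random_masked_roi(seed = 77)
  q1 <- quantize_roi(roi, 5L)
  rescaled <- roi_sample(2.5 * roi$image - 4, roi$mask, "s", "BME", "PDFSE")
  q2 <- quantize_roi(rescaled, 5L)
  expect_equal(glcm_features(q1), glcm_features(q2), tolerance = 1e-12)
  expect_equal(glszm_features(q1), glszm_features(q2), tolerance = 1e-12)

  # changing intensities outside the mask changes nothing
  img3 <- roi$image
  img3[!roi$mask] <- 999
  q3 <- quantize_roi(roi_sample(img3, roi$mask, "s", "BME", "PDFSE"), 5L)
  expect_equal(glcm_features(q1), glcm_features(q3), tolerance = 1e-12)
  expect_equal(glrlm_features(q1), glrlm_features(q3), tolerance = 1e-12)
  expect_equal(glszm_features(q1), glszm_features(q3), tolerance = 1e-12)
})
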
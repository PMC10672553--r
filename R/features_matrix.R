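# Gray-level matrix descriptors: co-occurrence (GLCM), run-length (GLRLM)
# and size-zone (GLSZM) families. Formulas follow the standard reference
# definitions (Haralick for GLCM; Galloway/Chu/Dasarathy for GLRLM;
# Thibault for GLSZM). GLCM/GLRLM use the four axis directions N, S, E, W
# at 1-pixel offset; per-direction features are averaged. GLSZM zones are
# 8-connected components of equal level.

DIR_OFFSETS <- list(N = c(-1L, 0L), S = c(1L, 0L), E = c(0L, 1L),
                    W = c(0L, -1L))

dir_offset <- function(direction) {
  if (!direction %in% names(DIR_OFFSETS)) {
    stop("direction must be one of N, S, E, W", call. = FALSE)
  }
  DIR_OFFSETS[[direction]]
}

#' Build a gray-level co-occurrence matrix
#'
#' Counts ordered level pairs `(level(p), level(p + d))` over all pixel
#' pairs at 1-pixel offset in the given direction where both pixels lie
#' inside the mask, then normalizes by the pair count.
#'
#' @param q a [quantize_roi()] result.
#' @param direction one of `"N"`, `"S"`, `"E"`, `"W"`.
#' @return Object of class `glcm`: list with `P` (Ng x Ng, sums to 1),
#'   `direction`, `offset`, `npairs`.
#' @export
build_glcm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_roi"))
  d <- dir_offset(direction)
  L <- q$levels; M <- q$mask
  nr <- nrow(L); nc <- ncol(L)
  rs <- max(1L, 1L - d[1]):min(nr, nr - d[1])
  cs <- max(1L, 1L - d[2]):min(nc, nc - d[2])
  A <- L[rs, cs, drop = FALSE]
  B <- L[rs + d[1], cs + d[2], drop = FALSE]
  ok <- M[rs, cs, drop = FALSE] & M[rs + d[1], cs + d[2], drop = FALSE]
  n <- sum(ok)
  if (n == 0L) {
    stop("degenerate co-occurrence matrix: no valid pixel pair in direction ",
         direction, call. = FALSE)
  }
  cnt <- tabulate((B[ok] - 1L) * q$Ng + A[ok], nbins = q$Ng^2)
  structure(list(P = matrix(cnt / n, q$Ng, q$Ng), direction = direction,
                 offset = 1L, npairs = n),
            class = "glcm")
}

# the 22 Haralick-family descriptors of one normalized GLCM
glcm_feature_vec <- function(P) {
  Ng <- nrow(P)
  lv <- seq_len(Ng)
  I <- row(P); J <- col(P)
  pi_ <- rowSums(P); pj_ <- colSums(P)
  mux <- sum(lv * pi_); muy <- sum(lv * pj_)
  sx <- sqrt(sum((lv - mux)^2 * pi_)); sy <- sqrt(sum((lv - muy)^2 * pj_))
  ks <- 2:(2 * Ng); kd <- 0:(Ng - 1)
  S <- I + J; D <- abs(I - J)
  psum <- vapply(ks, function(k) sum(P[S == k]), numeric(1))
  pdiff <- vapply(kd, function(k) sum(P[D == k]), numeric(1))
  sa <- sum(ks * psum)
  da <- sum(kd * pdiff)
  H <- entropy_bits(P)
  HX <- entropy_bits(pi_); HY <- entropy_bits(pj_)
  pp <- outer(pi_, pj_)
  nz <- P > 0 & pp > 0
  HXY1 <- -sum(P[nz] * log2(pp[nz]))
  HXY2 <- entropy_bits(pp)
  imc1 <- if (max(HX, HY) > 0) (H - HXY1) / max(HX, HY) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (HXY2 - H))))
  c(glcm_asm = sum(P^2),
    glcm_autocorrelation = sum(I * J * P),
    glcm_cluster_prominence = sum((I + J - mux - muy)^4 * P),
    glcm_cluster_shade = sum((I + J - mux - muy)^3 * P),
    glcm_contrast = sum((I - J)^2 * P),
    glcm_correlation =
      if (sx > 0 && sy > 0) (sum(I * J * P) - mux * muy) / (sx * sy) else 0,
    glcm_diff_average = da,
    glcm_diff_entropy = entropy_bits(pdiff),
    glcm_diff_variance = sum((kd - da)^2 * pdiff),
    glcm_entropy = H,
    glcm_idm = sum(P / (1 + (I - J)^2)),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_inv_diff = sum(P / (1 + D)),
    glcm_inv_diff_norm = sum(P / (1 + D / Ng)),
    glcm_jmx = max(P),
    glcm_joint_average = mux,
    glcm_mcc = glcm_mcc(P, pi_, pj_),
    glcm_sum_average = sa,
    glcm_sum_entropy = entropy_bits(psum),
    glcm_sum_squares = sum((I - mux)^2 * P),
    glcm_sum_variance = sum((ks - sa)^2 * psum))
}

# maximal correlation coefficient: sqrt of the second-largest eigenvalue
# magnitude of Q[i,j] = sum_k P[i,k] P[j,k] / (p_x(i) p_y(k)); 0 when the
# occupied support has rank < 2
glcm_mcc <- function(P, pi_, pj_) {
  keep_i <- pi_ > 0; keep_k <- pj_ > 0
  A <- P[keep_i, keep_k, drop = FALSE] / pi_[keep_i]
  B <- sweep(P[keep_i, keep_k, drop = FALSE], 2, pj_[keep_k], "/")
  if (nrow(A) < 2L) return(0)
  Q <- A %*% t(B)
  ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  if (length(ev) < 2L) return(0)
  sqrt(max(0, min(ev[2], 1)))
}

#' GLCM descriptors of a quantized ROI
#'
#' Computes the 22 Haralick-family descriptors per direction (N, S, E, W,
#' 1-pixel offset) and returns their average over the non-degenerate
#' directions.
#'
#' @param q a [quantize_roi()] result.
#' @return Named numeric vector of length 22 (names `glcm_*`).
#' @export
glcm_features <- function(q) {
  per_dir <- lapply(names(DIR_OFFSETS), function(d) {
    tryCatch(glcm_feature_vec(build_glcm(q, d)$P), error = function(e) NULL)
  })
  per_dir <- Filter(Negate(is.null), per_dir)
  if (!length(per_dir)) {
    stop("degenerate co-occurrence matrix: all four directions empty",
         call. = FALSE)
  }
  Reduce(`+`, per_dir)[GLCM_NAMES] / length(per_dir)
}

#' Build a gray-level run-length matrix
#'
#' Decomposes each maximal in-mask collinear pixel segment along the given
#' direction into maximal constant-level runs; entry `R[i, j]` counts runs
#' of level i and length j. Runs are broken by mask boundaries. Opposite
#' directions yield identical matrices.
#'
#' @inheritParams build_glcm
#' @return Object of class `glrlm`: list with `R` (Ng x Lmax counts),
#'   `Nr` (total run count), `Np` (masked pixel count), `direction`.
#' @export
build_glrlm <- function(q, direction) {
  stopifnot(inherits(q, "quantized_roi"))
  d <- dir_offset(direction)
  L <- q$levels; M <- q$mask
  along_rows <- d[1] == 0L   # E/W scan rows; N/S scan columns
  Lmax <- if (along_rows) ncol(L) else nrow(L)
  R <- matrix(0, q$Ng, Lmax)
  nlines <- if (along_rows) nrow(L) else ncol(L)
  for (s in seq_len(nlines)) {
    lev <- if (along_rows) L[s, ] else L[, s]
    msk <- if (along_rows) M[s, ] else M[, s]
    # mask breaks terminate runs: encode off-mask pixels as level 0
    r <- rle(ifelse(msk, lev, 0L))
    keep <- r$values > 0L
    if (any(keep)) {
      idx <- cbind(r$values[keep], r$lengths[keep])
      for (k in seq_len(nrow(idx))) {
        R[idx[k, 1], idx[k, 2]] <- R[idx[k, 1], idx[k, 2]] + 1
      }
    }
  }
  structure(list(R = R, Nr = sum(R), Np = sum(M), direction = direction),
            class = "glrlm")
}

# the 16 run-length descriptors of one count matrix
glrlm_feature_vec <- function(R, Np) {
  Nr <- sum(R)
  p <- R / Nr
  I <- row(R); J <- col(R)
  ri <- rowSums(R); rj <- colSums(R)
  mui <- sum(I * p); muj <- sum(J * p)
  c(glrlm_glnu = sum(ri^2) / Nr,
    glrlm_glnun = sum(ri^2) / Nr^2,
    glrlm_glv = sum((I - mui)^2 * p),
    glrlm_hgre = sum(I^2 * p),
    glrlm_lgre = sum(p / I^2),
    glrlm_lre = sum(J^2 * p),
    glrlm_lrhge = sum(I^2 * J^2 * p),
    glrlm_lrlge = sum(J^2 * p / I^2),
    glrlm_re = entropy_bits(p),
    glrlm_rlnu = sum(rj^2) / Nr,
    glrlm_rlnun = sum(rj^2) / Nr^2,
    glrlm_rlv = sum((J - muj)^2 * p),
    glrlm_rp = Nr / Np,
    glrlm_sre = sum(p / J^2),
    glrlm_srhge = sum(I^2 * p / J^2),
    glrlm_srlge = sum(p / (I^2 * J^2)))
}

#' GLRLM descriptors of a quantized ROI
#'
#' The 16 run-length descriptors (SRE, LRE, GLNU(N), RLNU(N), RP, LGRE,
#' HGRE, SRLGE, SRHGE, LRLGE, LRHGE, GLV, RLV, RE), averaged over the four
#' axis directions.
#'
#' @param q a [quantize_roi()] result.
#' @return Named numeric vector of length 16 (names `glrlm_*`).
#' @export
glrlm_features <- function(q) {
  per_dir <- lapply(names(DIR_OFFSETS), function(d) {
    g <- build_glrlm(q, d)
    glrlm_feature_vec(g$R, g$Np)
  })
  Reduce(`+`, per_dir)[GLRLM_NAMES] / length(per_dir)
}

#' Build a gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal-level masked pixels; entry
#' `Z[i, s]` counts zones of level i and size s pixels.
#'
#' @param q a [quantize_roi()] result.
#' @return Object of class `glszm`: list with `Z` (Ng x Smax counts),
#'   `Nz` (zone count), `Np` (masked pixel count).
#' @export
build_glszm <- function(q) {
  stopifnot(inherits(q, "quantized_roi"))
  zones <- cpp_zone_sizes(q$levels, q$mask)   # matrix: level, size
  Smax <- max(zones[, 2])
  Z <- matrix(0, q$Ng, Smax)
  for (k in seq_len(nrow(zones))) {
    Z[zones[k, 1], zones[k, 2]] <- Z[zones[k, 1], zones[k, 2]] + 1
  }
  structure(list(Z = Z, Nz = sum(Z), Np = sum(q$mask)), class = "glszm")
}

#' GLSZM descriptors of a quantized ROI
#'
#' The 16 size-zone descriptors (SZE, LZE, LGZE, HGZE, the four
#' joint-emphasis terms, GLNU(N), ZSNU(N), ZP, GLZV, ZSV, ZSE) per the
#' standard size-zone reference definitions; `glszm_glzv` is the
#' gray-level variance of the zone distribution.
#'
#' @param q a [quantize_roi()] result.
#' @return Named numeric vector of length 16 (names `glszm_*`).
#' @export
glszm_features <- function(q) {
  z <- build_glszm(q)
  Z <- z$Z; Nz <- z$Nz
  p <- Z / Nz
  I <- row(Z); S <- col(Z)
  zi <- rowSums(Z); zs <- colSums(Z)
  mui <- sum(I * p); mus <- sum(S * p)
  out <- c(glszm_glnu = sum(zi^2) / Nz,
           glszm_glnun = sum(zi^2) / Nz^2,
           glszm_glzv = sum((I - mui)^2 * p),
           glszm_hgze = sum(I^2 * p),
           glszm_lgze = sum(p / I^2),
           glszm_lze = sum(S^2 * p),
           glszm_lzhge = sum(I^2 * S^2 * p),
           glszm_lzlge = sum(S^2 * p / I^2),
           glszm_sze = sum(p / S^2),
           glszm_szhge = sum(I^2 * p / S^2),
           glszm_szlge = sum(p / (I^2 * S^2)),
           glszm_zp = Nz / z$Np,
           glszm_zse = entropy_bits(p),
           glszm_zsnu = sum(zs^2) / Nz,
           glszm_zsnun = sum(zs^2) / Nz^2,
           glszm_zsv = sum((S - mus)^2 * p))
  out[GLSZM_NAMES]
}
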
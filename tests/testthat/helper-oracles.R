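# Independent brute-force oracles. Everything here is written as plain
# loops over pixels / matrix cells, deliberately sharing no code with the
# package implementation.

ORACLE_DIRS <- list(N = c(-1L, 0L), S = c(1L, 0L), E = c(0L, 1L),
                    W = c(0L, -1L))

# exhaustive pixel-pair enumeration
oracle_glcm_counts <- function(levels, mask, dir, Ng) {
  d <- ORACLE_DIRS[[dir]]
  P <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(levels))) {
    for (c in seq_len(ncol(levels))) {
      r2 <- r + d[1]; c2 <- c + d[2]
      if (r2 < 1 || r2 > nrow(levels) || c2 < 1 || c2 > ncol(levels)) next
      if (!mask[r, c] || !mask[r2, c2]) next
      P[levels[r, c], levels[r2, c2]] <- P[levels[r, c], levels[r2, c2]] + 1
    }
  }
  P
}

# naive Haralick formulas by explicit loops over matrix cells
oracle_glcm_features <- function(P) {
  Ng <- nrow(P)
  P <- P / sum(P)
  px <- rowSums(P); py <- colSums(P)
  mux <- 0; muy <- 0
  for (i in 1:Ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sx <- sqrt(sum(((1:Ng) - mux)^2 * px))
  sy <- sqrt(sum(((1:Ng) - muy)^2 * py))
  psum <- numeric(2 * Ng); pdif <- numeric(Ng)
  out <- c(asm = 0, autocorrelation = 0, cluster_prominence = 0,
           cluster_shade = 0, contrast = 0, correlation = 0,
           diff_average = 0, diff_entropy = 0, diff_variance = 0,
           entropy = 0, idm = 0, imc1 = 0, imc2 = 0, inv_diff = 0,
           inv_diff_norm = 0, jmx = 0, joint_average = mux, mcc = 0,
           sum_average = 0, sum_entropy = 0, sum_squares = 0,
           sum_variance = 0)
  for (i in 1:Ng) for (j in 1:Ng) {
    p <- P[i, j]
    psum[i + j] <- psum[i + j] + p
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + p
    out["asm"] <- out["asm"] + p^2
    out["autocorrelation"] <- out["autocorrelation"] + i * j * p
    out["cluster_prominence"] <- out["cluster_prominence"] +
      (i + j - mux - muy)^4 * p
    out["cluster_shade"] <- out["cluster_shade"] + (i + j - mux - muy)^3 * p
    out["contrast"] <- out["contrast"] + (i - j)^2 * p
    if (p > 0) out["entropy"] <- out["entropy"] - p * log2(p)
    out["idm"] <- out["idm"] + p / (1 + (i - j)^2)
    out["inv_diff"] <- out["inv_diff"] + p / (1 + abs(i - j))
    out["inv_diff_norm"] <- out["inv_diff_norm"] + p / (1 + abs(i - j) / Ng)
    if (p > out["jmx"]) out["jmx"] <- p
    out["sum_squares"] <- out["sum_squares"] + (i - mux)^2 * p
  }
  if (sx > 0 && sy > 0) {
    out["correlation"] <- (out["autocorrelation"] - mux * muy) / (sx * sy)
  }
  for (k in 2:(2 * Ng)) {
    out["sum_average"] <- out["sum_average"] + k * psum[k]
    if (psum[k] > 0) out["sum_entropy"] <- out["sum_entropy"] -
        psum[k] * log2(psum[k])
  }
  for (k in 2:(2 * Ng)) out["sum_variance"] <- out["sum_variance"] +
      (k - out["sum_average"])^2 * psum[k]
  for (k in 0:(Ng - 1)) {
    out["diff_average"] <- out["diff_average"] + k * pdif[k + 1]
    if (pdif[k + 1] > 0) out["diff_entropy"] <- out["diff_entropy"] -
        pdif[k + 1] * log2(pdif[k + 1])
  }
  for (k in 0:(Ng - 1)) out["diff_variance"] <- out["diff_variance"] +
      (k - out["diff_average"])^2 * pdif[k + 1]
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:Ng) for (j in 1:Ng) {
    q <- px[i] * py[j]
    if (q > 0) {
      if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(q)
      hxy2 <- hxy2 - q * log2(q)
    }
  }
  if (max(hx, hy) > 0) out["imc1"] <- (out[["entropy"]] - hxy1) / max(hx, hy)
  out["imc2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - out[["entropy"]]))))
  keep_i <- px > 0; keep_k <- py > 0
  if (sum(keep_i) >= 2) {
    Q <- matrix(0, sum(keep_i), sum(keep_i))
    ii <- which(keep_i); kk <- which(keep_k)
    for (a in seq_along(ii)) for (b in seq_along(ii)) {
      s <- 0
      for (k in kk) s <- s + P[ii[a], k] * P[ii[b], k] / (px[ii[a]] * py[k])
      Q[a, b] <- s
    }
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    if (length(ev) >= 2) out["mcc"] <- sqrt(max(0, min(1, ev[2])))
  }
  names(out) <- paste0("glcm_", names(out))
  out
}

# run scan: walk each line pixel by pixel
oracle_glrlm_counts <- function(levels, mask, dir, Ng, Lmax) {
  R <- matrix(0, Ng, Lmax)
  horiz <- dir %in% c("E", "W")
  nlines <- if (horiz) nrow(levels) else ncol(levels)
  linelen <- if (horiz) ncol(levels) else nrow(levels)
  for (s in seq_len(nlines)) {
    run_lev <- 0L; run_len <- 0L
    for (t in seq_len(linelen)) {
      lv <- if (horiz) levels[s, t] else levels[t, s]
      mk <- if (horiz) mask[s, t] else mask[t, s]
      cur <- if (mk) lv else 0L
      if (cur == run_lev) {
        run_len <- run_len + 1L
      } else {
        if (run_lev > 0L) R[run_lev, run_len] <- R[run_lev, run_len] + 1
        run_lev <- cur; run_len <- 1L
      }
    }
    if (run_lev > 0L) R[run_lev, run_len] <- R[run_lev, run_len] + 1
  }
  R
}

oracle_glrlm_features <- function(R, Np) {
  Nr <- sum(R)
  out <- c(glnu = 0, glnun = 0, glv = 0, hgre = 0, lgre = 0, lre = 0,
           lrhge = 0, lrlge = 0, re = 0, rlnu = 0, rlnun = 0, rlv = 0,
           rp = Nr / Np, sre = 0, srhge = 0, srlge = 0)
  mui <- 0; muj <- 0
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    p <- R[i, j] / Nr
    mui <- mui + i * p; muj <- muj + j * p
  }
  for (i in seq_len(nrow(R))) for (j in seq_len(ncol(R))) {
    p <- R[i, j] / Nr
    if (p == 0) next
    out["glv"] <- out["glv"] + (i - mui)^2 * p
    out["hgre"] <- out["hgre"] + i^2 * p
    out["lgre"] <- out["lgre"] + p / i^2
    out["lre"] <- out["lre"] + j^2 * p
    out["lrhge"] <- out["lrhge"] + i^2 * j^2 * p
    out["lrlge"] <- out["lrlge"] + j^2 * p / i^2
    out["re"] <- out["re"] - p * log2(p)
    out["rlv"] <- out["rlv"] + (j - muj)^2 * p
    out["sre"] <- out["sre"] + p / j^2
    out["srhge"] <- out["srhge"] + i^2 * p / j^2
    out["srlge"] <- out["srlge"] + p / (i^2 * j^2)
  }
  for (i in seq_len(nrow(R))) out["glnu"] <- out["glnu"] + sum(R[i, ])^2
  for (j in seq_len(ncol(R))) out["rlnu"] <- out["rlnu"] + sum(R[, j])^2
  out["glnun"] <- out["glnu"] / Nr^2; out["glnu"] <- out["glnu"] / Nr
  out["rlnun"] <- out["rlnu"] / Nr^2; out["rlnu"] <- out["rlnu"] / Nr
  names(out) <- paste0("glrlm_", names(out))
  out
}

# recursive flood fill (8-connectivity), independent of the C++ stack scan
oracle_zones <- function(levels, mask) {
  nr <- nrow(levels); nc <- ncol(levels)
  seen <- matrix(FALSE, nr, nc)
  zones <- list()
  fill <- function(r, c, lev) {
    if (r < 1 || r > nr || c < 1 || c > nc) return(0)
    if (seen[r, c] || !mask[r, c] || levels[r, c] != lev) return(0)
    seen[r, c] <<- TRUE
    n <- 1
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      n <- n + fill(r + dr, c + dc, lev)
    }
    n
  }
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (mask[r, c] && !seen[r, c]) {
      zones[[length(zones) + 1]] <- c(levels[r, c], fill(r, c, levels[r, c]))
    }
  }
  do.call(rbind, zones)
}

oracle_glszm_features <- function(zones, Ng, Np) {
  Nz <- nrow(zones)
  Smax <- max(zones[, 2])
  Z <- matrix(0, Ng, Smax)
  for (k in seq_len(Nz)) Z[zones[k, 1], zones[k, 2]] <-
      Z[zones[k, 1], zones[k, 2]] + 1
  out <- c(glnu = 0, glnun = 0, glzv = 0, hgze = 0, lgze = 0, lze = 0,
           lzhge = 0, lzlge = 0, sze = 0, szhge = 0, szlge = 0,
           zp = Nz / Np, zse = 0, zsnu = 0, zsnun = 0, zsv = 0)
  mui <- 0; mus <- 0
  for (i in 1:Ng) for (s in 1:Smax) {
    p <- Z[i, s] / Nz
    mui <- mui + i * p; mus <- mus + s * p
  }
  for (i in 1:Ng) for (s in 1:Smax) {
    p <- Z[i, s] / Nz
    if (p == 0) next
    out["glzv"] <- out["glzv"] + (i - mui)^2 * p
    out["hgze"] <- out["hgze"] + i^2 * p
    out["lgze"] <- out["lgze"] + p / i^2
    out["lze"] <- out["lze"] + s^2 * p
    out["lzhge"] <- out["lzhge"] + i^2 * s^2 * p
    out["lzlge"] <- out["lzlge"] + s^2 * p / i^2
    out["sze"] <- out["sze"] + p / s^2
    out["szhge"] <- out["szhge"] + i^2 * p / s^2
    out["szlge"] <- out["szlge"] + p / (i^2 * s^2)
    out["zse"] <- out["zse"] - p * log2(p)
    out["zsv"] <- out["zsv"] + (s - mus)^2 * p
  }
  for (i in 1:Ng) out["glnu"] <- out["glnu"] + sum(Z[i, ])^2
  for (s in 1:Smax) out["zsnu"] <- out["zsnu"] + sum(Z[, s])^2
  out["glnun"] <- out["glnu"] / Nz^2; out["glnu"] <- out["glnu"] / Nz
  out["zsnun"] <- out["zsnu"] / Nz^2; out["zsnu"] <- out["zsnu"] / Nz
  names(out) <- paste0("glszm_", names(out))
  out
}

# min-over-suffix brute force for the Benjamini-Hochberg adjustment
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (pos in seq_len(m)) {
    best <- Inf
    for (pos2 in pos:m) {
      cand <- m * p[o[pos2]] / pos2
      if (cand < best) best <- cand
    }
    adj[o[pos]] <- min(1, best)
  }
  adj
}

# per-pixel LBP codes by direct neighbor comparison
oracle_lbp_hist <- function(img, mask) {
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1), c(1, 1), c(1, 0),
               c(1, -1), c(0, -1))
  counts <- numeric(256)
  for (r in 2:(nrow(img) - 1)) for (c in 2:(ncol(img) - 1)) {
    if (!mask[r, c]) next
    ok <- TRUE
    code <- 0
    for (b in seq_along(offs)) {
      rr <- r + offs[[b]][1]; cc <- c + offs[[b]][2]
      if (!mask[rr, cc]) { ok <- FALSE; break }
      if (img[rr, cc] >= img[r, c]) code <- code + 2^(b - 1)
    }
    if (ok) counts[code + 1] <- counts[code + 1] + 1
  }
  counts / sum(counts)
}
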
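# Tamura texture descriptors and local binary pattern histogram summaries.

# sliding window mean over (2h x 2h)-ish windows via an integral image;
# window at (r, c) spans rows [r - h, r + h - 1] (truncated at borders)
window_mean <- function(img, half) {
  if (half < 1L) return(img)
  nr <- nrow(img); nc <- ncol(img)
  ii <- matrix(0, nr + 1L, nc + 1L)
  ii[-1L, -1L] <- apply(apply(img, 2, cumsum), 1, cumsum) |> t()
  r <- seq_len(nr); c <- seq_len(nc)
  r0 <- pmax(r - half, 1L); r1 <- pmin(r + half - 1L, nr)
  c0 <- pmax(c - half, 1L); c1 <- pmin(c + half - 1L, nc)
  S <- ii[r1 + 1L, c1 + 1L] - ii[r0, c1 + 1L] - ii[r1 + 1L, c0] + ii[r0, c0]
  area <- outer(r1 - r0 + 1L, c1 - c0 + 1L)
  S / area
}

# shift a matrix by (dr, dc), clamping reads at the borders
shift_clamped <- function(x, dr, dc) {
  nr <- nrow(x); nc <- ncol(x)
  x[pmin(pmax(seq_len(nr) + dr, 1L), nr),
    pmin(pmax(seq_len(nc) + dc, 1L), nc), drop = FALSE]
}

#' Tamura texture descriptors
#'
#' Six descriptors. Per-pixel optimal coarseness is computed by the
#' classical Tamura procedure: moving-average images at window sizes
#' \eqn{2^k}, k = 0..4, horizontal/vertical absolute differences of the
#' averages at offset \eqn{\max(1, 2^{k-1})}, per-pixel argmax of the
#' directional difference (ties to the smaller scale), coarseness value
#' \eqn{2^{k_{opt}}}. The coarseness map is restricted to masked pixels
#' whose largest (16 x 16) window fits inside the image; the four
#' "coarseness 1..4" descriptors are its mean, std, median and 32-bin
#' entropy. Contrast is \eqn{\sigma / \alpha_4^{1/4}} with
#' \eqn{\alpha_4 = \mu_4 / \sigma^4} over the masked intensities (0 for a
#' constant ROI); roughness is coarseness-mean + contrast.
#'
#' @param sample an [roi_sample()].
#' @return Named numeric vector of length 6 (names `tam_*`).
#' @export
tamura_features <- function(sample) {
  stopifnot(inherits(sample, "roi_sample"))
  img <- sample$image; m <- sample$mask
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  if (diff(rr) + 1L < 16L || diff(cc) + 1L < 16L) {
    stop("degenerate ROI: mask bounding box smaller than 16x16 ",
         "(required for coarseness windows up to 2^4)", call. = FALSE)
  }
  nr <- nrow(img); nc <- ncol(img)
  best_e <- matrix(-Inf, nr, nc)
  kopt <- matrix(0L, nr, nc)
  for (k in 0:4) {
    A <- window_mean(img, as.integer(2^k / 2))
    d <- max(1L, as.integer(2^(k - 1)))
    Eh <- abs(shift_clamped(A, 0L, d) - shift_clamped(A, 0L, -d))
    Ev <- abs(shift_clamped(A, d, 0L) - shift_clamped(A, -d, 0L))
    E <- pmax(Eh, Ev)
    upd <- E > best_e            # strict: ties keep the smaller scale
    kopt[upd] <- k
    best_e[upd] <- E[upd]
  }
  crs <- 2^kopt
  # valid region: the 16x16 window (half-extent 8) fits inside the image
  valid <- matrix(FALSE, nr, nc)
  if (nr >= 16L && nc >= 16L) valid[9:(nr - 7), 9:(nc - 7)] <- TRUE
  sel <- m & valid
  if (!any(sel)) {
    stop("degenerate ROI: no masked pixel admits the largest coarseness window",
         call. = FALSE)
  }
  cm <- crs[sel]
  crs_mean <- mean(cm)
  crs_std <- sqrt(mean((cm - crs_mean)^2))
  crs_ent <- entropy_bits(tabulate(bin_equal_width(cm, 32L), nbins = 32L))
  x <- img[m]
  s2 <- mean((x - mean(x))^2)
  contrast <- if (s2 > 0) {
    a4 <- mean((x - mean(x))^4) / s2^2
    sqrt(s2) / a4^0.25
  } else 0
  c(tam_coarseness_entropy = crs_ent,
    tam_coarseness_mean = crs_mean,
    tam_coarseness_median = unname(median(cm)),
    tam_coarseness_std = crs_std,
    tam_contrast = contrast,
    tam_roughness = crs_mean + contrast)[TAM_NAMES]
}

LBP_OFFSETS <- cbind(dr = c(-1L, -1L, -1L, 0L, 1L, 1L, 1L, 0L),
                     dc = c(-1L, 0L, 1L, 1L, 1L, 0L, -1L, -1L))

#' Local binary pattern histogram descriptors
#'
#' Computes the 8-neighbor radius-1 LBP code (0..255) of every masked
#' pixel whose eight neighbors are all masked; neighbor >= center sets the
#' bit (so a constant ROI codes to 255). Descriptors of the normalized
#' 256-bin code histogram h: mean code, median code (weighted median),
#' number of peaks (strict local maxima over the occupied bins, circular
#' code space; a single occupied bin counts as one peak), and uniformity
#' \eqn{\sum h_i^2}.
#'
#' @param sample an [roi_sample()].
#' @return Named numeric vector of length 4 (names `lbp_*`).
#' @export
lbp_features <- function(sample) {
  stopifnot(inherits(sample, "roi_sample"))
  h <- lbp_histogram(sample)
  codes <- 0:255
  mean_code <- sum(codes * h)
  med <- codes[which(cumsum(h) >= 0.5)[1]]
  c(lbp_mean = mean_code,
    lbp_median = as.numeric(med),
    lbp_npeaks = circular_peaks(h),
    lbp_uniformity = sum(h^2))[LBP_NAMES]
}

# normalized 256-bin histogram of LBP codes over interior masked pixels
lbp_histogram <- function(sample) {
  img <- sample$image; m <- sample$mask
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3L || nc < 3L) stop("degenerate ROI: no interior masked pixel",
                               call. = FALSE)
  core <- 2:(nr - 1L); corec <- 2:(nc - 1L)
  ctr <- img[core, corec, drop = FALSE]
  code <- matrix(0L, length(core), length(corec))
  interior <- m[core, corec, drop = FALSE]
  for (b in seq_len(8L)) {
    dr <- LBP_OFFSETS[b, 1]; dc <- LBP_OFFSETS[b, 2]
    nb <- img[core + dr, corec + dc, drop = FALSE]
    code <- code + bitwShiftL(1L, b - 1L) * (nb >= ctr)
    interior <- interior & m[core + dr, corec + dc, drop = FALSE]
  }
  if (!any(interior)) stop("degenerate ROI: no interior masked pixel",
                           call. = FALSE)
  cnt <- tabulate(code[interior] + 1L, nbins = 256L)
  cnt / sum(cnt)
}

# strict local maxima among occupied bins on a circular index space
circular_peaks <- function(h) {
  occ <- which(h > 0)
  k <- length(occ)
  if (k == 0L) return(0)
  if (k == 1L) return(1)
  v <- h[occ]
  prev <- v[c(k, seq_len(k - 1L))]
  nxt <- v[c(seq_len(k - 1L) + 1L, 1L)]
  sum(v > prev & v > nxt)
}
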
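# Synthetic three-group, two-channel ROI cohort generator. Each ROI is a
# correlated Gaussian random field (white noise convolved with a Gaussian
# kernel) overlaid with dark piecewise-constant bar-shaped plateaus at
# constant total coverage, sparse deviant single-pixel zones, jittered
# anchor pixels, an affine intensity gain and a random brightness offset,
# masked by an elliptical (or full / blob) mask. The default per-group,
# per-channel parameter table is calibrated so the five composite
# descriptors separate the groups with the study's directionality: PDFSE
# joint maximum / long-run low-gray emphasis / run-length variance ordered
# BME > INJ > OST, and STIR mean absolute deviation / gray-level zone
# variance ordered BME < OST < INJ - while most other descriptors stay
# near their null distributions.

#' Synthetic cohort specification
#'
#' @param n_per_group named integer vector, subjects per group (default
#'   the study sizes 41/37/43).
#' @param size image height and width in pixels (default 48 x 48).
#' @param mask_shape `"ellipse"` (default; exercises boundary-broken runs
#'   and zones), `"full"`, or `"blob"`.
#' @param params data frame with columns `group`, `sequence`,
#'   `correlation_length` (pixels; background field smoothness),
#'   `blob_density` (plateau structures per pixel at constant total
#'   coverage, trading structure size against number; drives run/zone
#'   length statistics), `noise_sd` (intensity gain relative to the
#'   reference white-noise level 2; drives first-order dispersion),
#'   `smoothing` (level dispersion of the plateau structures; low values
#'   concentrate plateau levels into one quantization bin, driving the
#'   joint maximum, while values above 0.5 also spawn deviant
#'   single-pixel zones, driving the gray-level variance of zones).
#'   Defaults to [default_texture_params()].
#' @param subject_jitter lognormal sd of per-subject parameter jitter
#'   (default 0.15: subjects vary around their group's texture by ~15%).
#' @param seed base RNG seed.
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(BME = 41L, INJ = 37L, OST = 43L),
                        size = c(48L, 48L), mask_shape = "ellipse",
                        params = default_texture_params(),
                        subject_jitter = 0.15, seed = 20231120L) {
  stopifnot(all(GROUP_LEVELS %in% names(n_per_group)),
            all(n_per_group >= 1L), length(size) == 2L, all(size >= 24L),
            mask_shape %in% c("full", "ellipse", "blob"),
            subject_jitter >= 0)
  need <- c("group", "sequence", "correlation_length", "blob_density",
            "noise_sd", "smoothing")
  stopifnot(is.data.frame(params), all(need %in% names(params)))
  key <- paste(params$group, params$sequence)
  want <- as.vector(outer(GROUP_LEVELS, SEQUENCE_LEVELS, paste))
  if (!setequal(key, want) || anyDuplicated(key)) {
    stop("params must contain exactly one row per (group, sequence) cell",
         call. = FALSE)
  }
  num <- as.matrix(params[, need[-(1:2)]])
  if (any(!is.finite(num)) || any(params$correlation_length <= 0) ||
      any(params$noise_sd <= 0) || any(params$blob_density < 0) ||
      any(params$smoothing < 0)) {
    stop("invalid texture parameters", call. = FALSE)
  }
  structure(list(n_per_group = n_per_group[GROUP_LEVELS], size = size,
                 mask_shape = mask_shape, params = params,
                 subject_jitter = subject_jitter, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default per-group, per-channel texture parameters
#'
#' The calibrated stated world of the generator (see the methods
#' vignette): in the PDFSE channel edema has fewer, longer, more
#' level-concentrated dark structures (blob_density rises and level
#' concentration falls BME -> INJ -> OST), so joint maximum, long-run
#' low-gray emphasis and run-length variance fall BME > INJ > OST; in the
#' STIR channel the intensity gain and structure-level dispersion rise
#' BME < OST < INJ, so mean absolute deviation and the gray-level
#' variance of zones are lowest in edema.
#'
#' @return Data frame with one row per (group, sequence) cell.
#' @export
default_texture_params <- function() {
  data.frame(
    group    = rep(GROUP_LEVELS, times = 2),
    sequence = rep(SEQUENCE_LEVELS, each = 3),
    #                      BME    INJ    OST           BME    INJ    OST
    correlation_length = c(2.4,   2.4,   2.4,          3.0,   3.0,   3.0),
    blob_density       = c(0.0042, 0.0065, 0.0093,     0.0065, 0.0065, 0.0065),
    noise_sd           = c(2,     2,     2,            2.0,   3.0,   2.1),
    smoothing          = c(0.1,   0.3,   0.55,         0.6,   1.38,  0.85),
    stringsAsFactors = FALSE
  )
}

# separable Gaussian blur with edge renormalization
gaussian_blur <- function(img, sd) {
  if (sd <= 0) return(img)
  r <- max(1L, ceiling(3 * sd))
  k <- dnorm(-r:r, sd = sd)
  smooth_axis <- function(x, along_rows) {
    acc <- matrix(0, nrow(x), ncol(x))
    wsum <- matrix(0, nrow(x), ncol(x))
    n <- if (along_rows) nrow(x) else ncol(x)
    for (o in -r:r) {
      src <- (1:n) + o
      ok <- src >= 1L & src <= n
      w <- k[o + r + 1L]
      if (along_rows) {
        acc[ok, ] <- acc[ok, ] + w * x[src[ok], ]
        wsum[ok, ] <- wsum[ok, ] + w
      } else {
        acc[, ok] <- acc[, ok] + w * x[, src[ok]]
        wsum[, ok] <- wsum[, ok] + w
      }
    }
    acc / wsum
  }
  smooth_axis(smooth_axis(img, TRUE), FALSE)
}

make_mask <- function(size, shape) {
  nr <- size[1]; nc <- size[2]
  if (shape == "full") return(matrix(TRUE, nr, nc))
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  ry <- 0.45 * nr; rx <- 0.45 * nc
  d2 <- outer(((1:nr) - cy) / ry, rep(1, nc))^2 +
        outer(rep(1, nr), ((1:nc) - cx) / rx)^2
  if (shape == "ellipse") return(d2 <= 1)
  # blob: ellipse boundary perturbed by a smooth random field
  g <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), 4)
  g <- g / max(1e-12, sd(g))
  m <- d2 + 0.25 * g <= 1
  if (sum(m) < MIN_ROI_PIXELS) m <- d2 <= 1
  m
}

#' Generate one synthetic ROI
#'
#' Deterministic given `rng_state`. The intensity model, in order: a
#' unit-sd correlated Gaussian field (amplitude 20 around the base level
#' 100) plus reference white noise of sd 2; `round(blob_density * npix)`
#' dark bar-shaped plateaus replacing the field at constant total
#' coverage (~13% of the grid), each at the ROI's base dark level plus an
#' upward level jitter controlled by `smoothing`; sparse deviant
#' single-pixel zones whose count grows with `smoothing` above 0.5, at
#' levels proportional to the anchor span; a group-independent artifact
#' patch; two anchor pixels with jittered near-extreme levels pinning
#' the quantization range; an affine intensity gain `noise_sd / 2` about
#' the mean; and a random brightness offset (sd 30) that decouples
#' absolute intensity location from the group label.
#'
#' @param spec a [cohort_spec()].
#' @param group,sequence cell labels.
#' @param rng_state integer seed for this ROI.
#' @param subject_id subject label stored in the sample.
#' @return An [roi_sample()].
#' @export
generate_roi <- function(spec, group, sequence, rng_state,
                         subject_id = "synthetic") {
  stopifnot(inherits(spec, "cohort_spec"))
  p <- spec$params
  cell <- p[p$group == group & p$sequence == sequence, ]
  if (nrow(cell) != 1L) stop("no parameter cell for ", group, "/", sequence,
                             call. = FALSE)
  nr <- spec$size[1]; nc <- spec$size[2]
  with_seed(rng_state, {
    # differentiated subject-level jitter: structural parameters vary more
    # than the intensity gain (scanner gain is comparatively stable)
    jsd <- spec$subject_jitter
    corr <- cell$correlation_length * exp(rnorm(1, 0, 1.6 * jsd))
    dens <- cell$blob_density * exp(rnorm(1, 0, jsd))
    nsd <- cell$noise_sd * exp(rnorm(1, 0, jsd / 2))

    g <- gaussian_blur(matrix(rnorm(nr * nc), nr, nc), corr)
    g <- g / max(1e-12, sd(g))
    img <- 100 + 20 * g

    # dark piecewise-constant plateaus: elongated bar-shaped hypointense
    # structures (trabecular-like) REPLACE the field with a constant low
    # level. Total plateau coverage is held constant (~10% of the grid):
    # blob_density trades structure LENGTH against structure NUMBER, the
    # size-vs-number axis that run-length and zone-size descriptors
    # measure, without moving the intensity histogram. The per-structure
    # level is the ROI's base dark level plus a jitter of sd
    # 12 * smoothing: smoothing -> 0 makes the plateaus pairwise
    # identical (a dominant co-occurrence cell, high joint maximum),
    # larger smoothing disperses their levels.
    img <- img + 2 * matrix(rnorm(nr * nc), nr, nc)
    nblob <- max(1L, round(dens * nr * nc))
    coverage <- 0.13 * nr * nc
    base_dark <- 100 - runif(1, 45, 55)
    for (b in seq_len(nblob)) {
      w <- sample(1:2, 1)
      len <- max(2L, min(round(coverage / (nblob * 1.5 * w)), 40L))
      # upward-only level jitter: smoothed structures wash toward the
      # background level, so low-gray emphasis falls as smoothing rises
      lev <- base_dark + abs(rnorm(1, 0, 12 * min(cell$smoothing, 0.5)))
      horiz <- runif(1) < 0.5
      if (horiz) {
        r0 <- sample(nr - w + 1L, 1); c0 <- sample(max(1L, nc - len + 1L), 1)
        img[r0:(r0 + w - 1L), c0:min(nc, c0 + len - 1L)] <- lev
      } else {
        r0 <- sample(max(1L, nr - len + 1L), 1); c0 <- sample(nc - w + 1L, 1)
        img[r0:min(nr, r0 + len - 1L), c0:(c0 + w - 1L)] <- lev
      }
    }
    # two anchor pixels near the extreme levels pin the quantization
    # range across groups (calibration markers); their levels carry a
    # small independent jitter so the intensity range is a noisy, not a
    # perfect, readout of the gain
    span_lo <- 85 * exp(rnorm(1, 0, 0.02))
    span_hi <- 85 * exp(rnorm(1, 0, 0.02))
    # single-pixel zones at moderately deviant levels, proportional to
    # the realized anchor span so their quantized position is stable:
    # their count rises with the level-dispersion (smoothing) knob. Each
    # dot is one connected zone but nearly massless in the pixel
    # histogram, so this drives the gray-level variance of the zone
    # distribution with far more leverage than any pixel-weighted
    # descriptor
    ndot <- round(27 * max(0, cell$smoothing - 0.5)^1.5)
    if (ndot > 0) {
      pos <- sample(nr * nc, ndot)
      sgn <- sample(c(-1, 1), ndot, replace = TRUE)
      img[pos] <- 100 + sgn * runif(ndot, 0.56, 0.71) *
        ifelse(sgn > 0, span_hi, span_lo)
    }
    # occasional artifact patch: one small rectangle at a near-extreme
    # level, independent of the group label; it inflates the heavy-tail
    # moments (std, variance) with extra between-subject noise while
    # barely moving the robust mean absolute deviation
    psize <- sample(0:28, 1)
    if (psize > 0) {
      ph <- sample(2:6, 1); pw <- max(1L, ceiling(psize / ph))
      pr <- sample(nr - ph + 1L, 1); pc <- sample(nc - pw + 1L, 1)
      sgn <- sample(c(-1, 1), 1)
      img[pr:(pr + ph - 1L), pc:(pc + pw - 1L)] <- 100 + sgn *
        runif(1, 0.80, 0.96) * (if (sgn > 0) span_hi else span_lo)
    }
    mask <- make_mask(spec$size, spec$mask_shape)
    anchors <- range(which(mask))
    img[anchors[1]] <- 100 - span_lo
    img[anchors[2]] <- 100 + span_hi
    # noise_sd acts as an intensity gain relative to the reference white
    # noise level of 2: it scales first-order dispersion (MAD, std, ...)
    # while leaving every quantization-invariant matrix descriptor alone
    gain <- nsd / 2
    if (abs(gain - 1) > 1e-12) img <- mean(img) + gain * (img - mean(img))
    # per-ROI brightness offset (uncalibrated MRI units): large relative to
    # group contrasts, so absolute-location descriptors carry no group
    # signal, mirroring real non-quantitative MRI intensities
    img <- img + rnorm(1, 0, 30)
    roi_sample(img, mask, subject_id, group, sequence)
  })
}

#' Generate a labeled synthetic cohort
#'
#' One subject per row of the group-size table, each with a PDFSE and a
#' STIR ROI (channels independent given the parameters). Fully
#' deterministic under `spec$seed`. When `dir` is given, images and masks
#' are written (ASCII PGM by default, PNG when `format = "png"`) together
#' with a manifest CSV consumable by [load_cohort_manifest()].
#'
#' @param spec a [cohort_spec()].
#' @param dir optional output directory.
#' @param format `"pgm"` (plain text) or `"png"`.
#' @return List with `samples` (list of [roi_sample()], 2 per subject)
#'   and `manifest` (data frame).
#' @export
generate_cohort <- function(spec, dir = NULL, format = c("pgm", "png")) {
  stopifnot(inherits(spec, "cohort_spec"))
  format <- match.arg(format)
  samples <- list()
  rows <- list()
  idx <- 0L
  for (g in GROUP_LEVELS) {
    for (i in seq_len(spec$n_per_group[[g]])) {
      idx <- idx + 1L
      sid <- sprintf("%s%03d", g, i)
      for (ch in seq_along(SEQUENCE_LEVELS)) {
        sq <- SEQUENCE_LEVELS[ch]
        rs <- (spec$seed %% 1000003L) * 1000L + idx * 2L + ch
        samples[[length(samples) + 1L]] <-
          generate_roi(spec, g, sq, rs, subject_id = sid)
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sid, group = g, sequence = sq,
          image_path = sprintf("%s_%s.%s", sid, sq, format),
          mask_path = sprintf("%s_%s_mask.%s", sid, sq, format),
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(samples)) {
      s <- samples[[k]]
      ipath <- file.path(dir, manifest$image_path[k])
      mpath <- file.path(dir, manifest$mask_path[k])
      if (format == "pgm") {
        lo <- min(s$image); hi <- max(s$image)
        scaled <- (s$image - lo) / max(1e-12, hi - lo) * 65535
        write_pgm(scaled, ipath)
        write_pgm(s$mask * 65535, mpath)
      } else {
        if (!requireNamespace("png", quietly = TRUE)) {
          stop("PNG output requires the 'png' package", call. = FALSE)
        }
        lo <- min(s$image); hi <- max(s$image)
        png::writePNG((s$image - lo) / max(1e-12, hi - lo), ipath)
        png::writePNG(s$mask * 1, mpath)
      }
    }
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(samples = samples, manifest = manifest)
}

#' The five planted discriminative descriptors
#'
#' The composite-descriptor members the default generator is calibrated
#' to separate: joint maximum, long-run low-gray emphasis and run-length
#' variance in the PDFSE channel; mean absolute deviation and gray-level
#' zone variance in the STIR channel.
#'
#' @return Named character vector: wide (sequence-prefixed) feature names.
#' @export
planted_features <- function() {
  c(pdfse_jmx = "pdfse_glcm_jmx",
    pdfse_lrlge = "pdfse_glrlm_lrlge",
    pdfse_rlv = "pdfse_glrlm_rlv",
    stir_mad = "stir_fo_mad",
    stir_glzv = "stir_glszm_glzv")
}
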
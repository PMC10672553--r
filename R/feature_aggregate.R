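#' Extract the complete 81-descriptor feature vector of one ROI
#'
#' Runs all six family extractors on one [roi_sample()]: 17 first-order
#' descriptors on the raw masked intensities, then 22 GLCM + 16 GLRLM +
#' 16 GLSZM descriptors on the [quantize_roi()] levels, 6 Tamura and 4
#' LBP descriptors. Names are namespaced by family (`fo_`, `glcm_`,
#' `glrlm_`, `glszm_`, `tam_`, `lbp_`) and returned in canonical
#' [descriptor_names()] order.
#'
#' @param sample an [roi_sample()].
#' @param Ng number of gray levels for the matrix families (default 32).
#' @return Named numeric vector of length 81, all values finite.
#' @examples
#' roi <- roi_sample(matrix(rnorm(1024), 32, 32), matrix(TRUE, 32, 32),
#'                   "s", "OST", "PDFSE")
#' length(extract_all(roi))
#' @export
extract_all <- function(sample, Ng = 32L) {
  stopifnot(inherits(sample, "roi_sample"))
  q <- quantize_roi(sample, Ng)
  run_family <- function(name, fn) {
    tryCatch(fn, error = function(e) {
      stop(sprintf("family %s failed for subject %s: %s", name,
                   sample$subject_id, conditionMessage(e)), call. = FALSE)
    })
  }
  out <- c(
    run_family("first-order", first_order_features(sample)),
    run_family("GLCM", glcm_features(q)),
    run_family("GLRLM", glrlm_features(q)),
    run_family("GLSZM", glszm_features(q)),
    run_family("Tamura", tamura_features(sample)),
    run_family("LBP", lbp_features(sample))
  )
  out <- out[descriptor_names()]
  if (!all(is.finite(out))) {
    bad <- names(out)[!is.finite(out)]
    stop("non-finite descriptor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Extract features for a whole cohort
#'
#' Applies [extract_all()] to each sample, assembling one row per
#' (subject, sequence). Samples whose extraction fails are skipped with a
#' warning; if more than 10 percent fail, the whole extraction errors.
#'
#' @param samples nonempty list of [roi_sample()] objects.
#' @param Ng gray levels, passed to [extract_all()].
#' @param verbose log per-sample timing to `message()`.
#' @return Cohort feature table: data frame with `subject_id`, `group`,
#'   `sequence` and the 81 descriptor columns, rows in input order.
#' @export
extract_cohort <- function(samples, Ng = 32L, verbose = FALSE) {
  if (!length(samples)) stop("empty sample list", call. = FALSE)
  rows <- vector("list", length(samples))
  failed <- character()
  for (k in seq_along(samples)) {
    s <- samples[[k]]
    t0 <- proc.time()[["elapsed"]]
    fv <- tryCatch(extract_all(s, Ng), error = function(e) {
      warning(sprintf("sample %d (%s/%s) skipped: %s", k, s$subject_id,
                      s$sequence, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(fv)) {
      failed <- c(failed, s$subject_id)
      next
    }
    if (verbose) {
      message(sprintf("extracted %s/%s in %.3fs", s$subject_id, s$sequence,
                      proc.time()[["elapsed"]] - t0))
    }
    rows[[k]] <- data.frame(subject_id = s$subject_id, group = s$group,
                            sequence = s$sequence, t(fv),
                            stringsAsFactors = FALSE)
  }
  rows <- Filter(Negate(is.null), rows)
  if (length(failed) > 0.1 * length(samples)) {
    stop(sprintf("extraction failed for %d of %d samples", length(failed),
                 length(samples)), call. = FALSE)
  }
  if (!length(rows)) stop("all samples failed extraction", call. = FALSE)
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  validate_feature_table(tab)
}
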
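# ROI and feature-table I/O.
#
# Supported image containers: PNG (8/16-bit grayscale, via the `png`
# package), ASCII PGM (P2), and plain-text numeric grids (whitespace- or
# comma-separated). All descriptors are computed after in-ROI min-max
# quantization, so the absolute intensity scale of the container is
# irrelevant downstream.

#' Read a 2D grayscale image
#'
#' Dispatches on file extension: `.png` (grayscale PNG; an RGB image whose
#' channels are identical is accepted), `.pgm` (ASCII "P2"), anything else
#' is parsed as a plain-text numeric grid, one row per line.
#'
#' @param path file path.
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG requires the 'png' package", call. = FALSE)
    }
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    return(unname(a) * 65535)
  }
  if (ext == "pgm") return(read_pgm(path))
  read_text_grid(path)
}

# ASCII PGM (P2). ~tiny format; no R package provides it.
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P2") stop("only ASCII PGM (P2) supported: ", path, call. = FALSE)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])   # toks[4] is maxval
  if (length(vals) != w * h) stop("corrupt PGM: ", path, call. = FALSE)
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(img, path, maxval = 65535) {
  v <- pmin(pmax(round(img), 0), maxval)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(v, 1, paste, collapse = " "), con)
  invisible(path)
}

read_text_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    as.numeric(strsplit(trimws(l), "[,[:space:]]+")[[1]])
  })
  n <- lengths(rows)
  if (length(unique(n)) != 1L) {
    stop("ragged text grid in ", path, call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Load one ROI sample from disk
#'
#' Reads an intensity image and its binary mask and assembles a validated
#' [roi_sample()]. Any nonzero mask pixel counts as inside the ROI, so 0/255
#' PNG masks and 0/1 text grids are both accepted.
#'
#' @param image_path path to the intensity image (PNG, ASCII PGM, or text
#'   grid).
#' @param mask_path path to the mask (same formats).
#' @param subject_id,group,sequence sample labels, see [roi_sample()].
#' @return A validated `roi_sample`.
#' @export
load_roi_sample <- function(image_path, mask_path, subject_id, group,
                            sequence) {
  img <- read_gray_image(image_path)
  msk <- read_gray_image(mask_path)
  roi_sample(img, msk != 0, subject_id, group, sequence)
}

#' Load a cohort manifest
#'
#' The manifest is a CSV with columns `subject_id`, `group`, `sequence`,
#' `image_path`, `mask_path`; relative paths are resolved against the
#' manifest's directory. Row order is preserved.
#'
#' @param manifest_path path to the manifest CSV.
#' @return List of `roi_sample` objects, one per row.
#' @export
load_cohort_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  m <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "sequence", "image_path", "mask_path")
  if (!all(need %in% names(m))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(m$subject_id, m$sequence)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, sequence) in manifest: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  base <- dirname(manifest_path)
  resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
  lapply(seq_len(nrow(m)), function(i) {
    ip <- resolve(m$image_path[i]); mp <- resolve(m$mask_path[i])
    for (p in c(ip, mp)) {
      if (!file.exists(p)) {
        stop(sprintf("manifest row %d: file not found: %s", i, p),
             call. = FALSE)
      }
    }
    load_roi_sample(ip, mp, m$subject_id[i], m$group[i], m$sequence[i])
  })
}

#' Write a cohort feature table to CSV
#'
#' Columns are written in the canonical order: `subject_id`, `group`,
#' `sequence`, then the 81 descriptors of [descriptor_names()]. Values
#' round-trip losslessly to at least 12 significant digits.
#'
#' @param table a cohort feature table as returned by [extract_cohort()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  table <- validate_feature_table(table)
  if (nrow(table) == 0L) stop("empty feature table", call. = FALSE)
  out <- table[, c("subject_id", "group", "sequence", descriptor_names())]
  for (nm in descriptor_names()) out[[nm]] <- sprintf("%.15g", out[[nm]])
  ok <- tryCatch({
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write feature table to ", path, call. = FALSE)
  invisible(path)
}

#' Read a cohort feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return Feature table data frame.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  validate_feature_table(read.csv(path, stringsAsFactors = FALSE))
}

validate_feature_table <- function(table) {
  stopifnot(is.data.frame(table))
  need <- c("subject_id", "group", "sequence", descriptor_names())
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("feature table missing columns: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  }
  vals <- as.matrix(table[, descriptor_names()])
  if (nrow(table) && !all(is.finite(vals))) {
    stop("feature table contains non-finite descriptor values", call. = FALSE)
  }
  table
}
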
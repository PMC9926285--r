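## CSV and image I/O helpers shared by the command-line interface.

#' Write a table as CSV with a metadata header
#'
#' Writes `#`-prefixed metadata lines (tool version, seed, parameters,
#' config hash) followed by a plain RFC-4180 body. Numeric precision is
#' full double precision, so a read-back reproduces the table to well
#' beyond 12 significant digits.
#'
#' @param df A `data.frame`.
#' @param path Output path.
#' @param meta Named character vector or list of metadata entries.
#' @return `path`, invisibly.
#' @export
write_csv_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("phostat"))
  writeLines(sprintf("# phostat version: %s", version), con)
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, as.character(meta[[nm]])), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a metadata-headed CSV
#'
#' Counterpart of [write_csv_meta()]; `#` lines are skipped.
#'
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_csv_meta <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Read a grayscale image or image stack
#'
#' Reads a TIFF (multi-page files become a list of frames) or PNG image as
#' numeric matrices. Multi-channel images are averaged to grayscale.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A list of numeric matrices (length 1 for single images).
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  to_gray <- function(a) {
    if (length(dim(a)) == 3L) a <- apply(a, c(1, 2), mean)
    a
  }
  if (ext %in% c("tif", "tiff")) {
    frames <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    lapply(frames, to_gray)
  } else if (ext == "png") {
    list(to_gray(png::readPNG(path)))
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
}

#' Write a grayscale image stack as 16-bit TIFF
#'
#' Intensities are scaled by `scale` (default: the stack maximum maps to
#' the top of the 16-bit range) and written as a (multi-page) 16-bit
#' grayscale TIFF.
#'
#' @param frames A numeric matrix or list of matrices.
#' @param path Output path.
#' @param scale Intensity divisor; values are clipped to `[0, 1]` after
#'   division.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(frames, path, scale = NULL) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.null(scale)) scale <- max(1, max(vapply(frames, max, numeric(1))))
  frames <- lapply(frames, function(f) pmin(pmax(f / scale, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}
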
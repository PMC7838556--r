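## Plain-format I/O: paired RGB / label PNGs, cohort CSV, result JSON.

#' Read and write RGB tiles and label maps as PNG
#'
#' Tiles are standard 8-bit RGB PNGs. Label maps are single-channel PNGs
#' storing the raw class code in the 8-bit gray value (codes 0-7), so files
#' look near-black in a viewer but round-trip exactly.
#'
#' @param tile Integer `h x w x 3` array in 0-255.
#' @param labels Integer label map matrix.
#' @param path File path.
#' @return Readers return the array/matrix; writers return `path` invisibly.
#' @export
write_tile <- function(tile, path) {
  png::writePNG(tile / 255, path)
  invisible(path)
}

#' @rdname write_tile
#' @export
read_tile <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) img <- img[, , 1:3]
  array(as.integer(round(img * 255)), dim = dim(img))
}

#' @rdname write_tile
#' @export
write_labelmap <- function(labels, path) {
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' @rdname write_tile
#' @export
read_labelmap <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' Read and write a cohort table as CSV
#'
#' Missing flags are encoded as empty fields. Columns follow the
#' [make_cohort()] schema.
#'
#' @param cohort Data frame.
#' @param path File path.
#' @return `read_cohort_csv()` returns a data.frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  if ("lnm" %in% names(df)) df$lnm <- as.logical(df$lnm)
  for (fl in c("rectal", "inadequate_image", "distant_metastasis"))
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  df
}

#' Write a PTS result as JSON
#'
#' @param result A `pts_result` from [compute_pts()].
#' @param path File path.
#' @export
write_pts_json <- function(result, path) {
  stopifnot(inherits(result, "pts_result"))
  jsonlite::write_json(unclass(result), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Three-color PTS overlay
#'
#' Renders tumor, PTS (stroma within the closed tumor region) and everything
#' else as an RGB overlay image (tumor purple, PTS green, other light gray),
#' mirroring the usual tumor/PTS segmentation figure.
#'
#' @param labels Integer label map.
#' @param se Structuring element used for the closing.
#' @param path Optional PNG path; when given the overlay is also written.
#' @return Integer `h x w x 3` array (invisibly when `path` is given).
#' @export
pts_overlay <- function(labels, se = se_disk(64), path = NULL) {
  tumor <- labels == TISSUE_CLASSES[["TUMOR"]]
  region <- close_tumor_region(tumor, se)
  pts <- region & (labels == TISSUE_CLASSES[["STROMA"]])
  h <- nrow(labels); w <- ncol(labels)
  img <- array(230L, c(h, w, 3))
  paint <- function(img, mask, rgb) {
    for (ch in 1:3) { pl <- img[, , ch]; pl[mask] <- rgb[ch]; img[, , ch] <- pl }
    img
  }
  img <- paint(img, tumor, c(120L, 40L, 140L))
  img <- paint(img, pts, c(60L, 170L, 90L))
  if (!is.null(path)) { write_tile(img, path); return(invisible(img)) }
  img
}
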
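#' Structuring elements for binary morphology
#'
#' A structuring element (SE) is a small binary footprint with an origin cell;
#' it probes the image during erosion and dilation. `se_disk()` builds a
#' Euclidean disk (cells within `radius` of the center), `se_square()` a solid
#' square; `structuring_element()` wraps an arbitrary logical matrix.
#'
#' @param radius Disk radius in pixels (>= 0); the footprint is
#'   (2*radius+1) square.
#' @param side Side length in pixels (>= 1).
#' @param footprint Logical (or 0/1) matrix with at least one `TRUE` cell.
#' @param origin Integer (row, col) of the origin inside the footprint;
#'   defaults to the center cell.
#' @return An object of class `struct_elem`: a list with elements `footprint`
#'   (logical matrix), `origin` (integer pair) and `desc` (short label).
#' @examples
#' se_disk(2)
#' se_square(3)
#' @export
structuring_element <- function(footprint, origin = NULL,
                                desc = "custom") {
  footprint <- matrix(as.logical(footprint), nrow = nrow(footprint))
  if (!any(footprint)) stop("structuring element has no TRUE cell", call. = FALSE)
  if (is.null(origin)) origin <- (dim(footprint) + 1L) %/% 2L
  origin <- as.integer(origin)
  if (length(origin) != 2L ||
      origin[1] < 1L || origin[1] > nrow(footprint) ||
      origin[2] < 1L || origin[2] > ncol(footprint)) {
    stop("origin must lie inside the footprint", call. = FALSE)
  }
  structure(list(footprint = footprint, origin = origin, desc = desc),
            class = "struct_elem")
}

#' @rdname structuring_element
#' @export
se_disk <- function(radius) {
  radius <- as.integer(radius)
  if (radius < 0L) stop("radius must be >= 0", call. = FALSE)
  k <- 2L * radius + 1L
  d <- outer((1:k) - radius - 1L, (1:k) - radius - 1L,
             function(i, j) i * i + j * j)
  structuring_element(d <= radius^2, desc = sprintf("disk(r=%d)", radius))
}

#' @rdname structuring_element
#' @export
se_square <- function(side) {
  side <- as.integer(side)
  if (side < 1L) stop("side must be >= 1", call. = FALSE)
  structuring_element(matrix(TRUE, side, side),
                      desc = sprintf("square(%dx%d)", side, side))
}

#' @export
print.struct_elem <- function(x, ...) {
  cat(sprintf("structuring element %s: %dx%d footprint, %d active cells, origin (%d,%d)\n",
              x$desc, nrow(x$footprint), ncol(x$footprint),
              sum(x$footprint), x$origin[1], x$origin[2]))
  invisible(x)
}

# offsets (row, col) of active SE cells relative to the origin
se_offsets <- function(se) {
  w <- which(se$footprint, arr.ind = TRUE)
  cbind(w[, 1] - se$origin[1], w[, 2] - se$origin[2])
}

# shift a logical matrix by (di, dj), filling with `fill`
shift_mask <- function(m, di, dj, fill = FALSE) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  r0 <- max(1L, 1L + di); r1 <- min(h, h + di)
  c0 <- max(1L, 1L + dj); c1 <- min(w, w + dj)
  if (r0 <= r1 && c0 <= c1) {
    out[r0:r1, c0:c1] <- m[(r0:r1) - di, (c0:c1) - dj]
  }
  out
}

#' Binary dilation and erosion
#'
#' Minkowski dilation and erosion of a binary mask by a structuring element.
#' Pixels outside the image are treated as background, so dilation never wraps
#' and erosion shrinks the mask at image borders. Dilation marks a pixel when
#' the reflected SE placed there hits the input; erosion marks a pixel when
#' the SE placed there fits entirely inside the input.
#'
#' Implemented as a union (dilation) or intersection (erosion) of shifted
#' copies of the mask, one shift per active SE cell; cost is
#' O(active cells x pixels).
#'
#' @param mask Logical matrix (`TRUE` = foreground).
#' @param se A [structuring_element()].
#' @return Logical matrix of the same size.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
#' sum(dilate(m, se_square(3)))  # 3x3 block
#' @export
dilate <- function(mask, se) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE  # coerce to logical matrix
  off <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    out <- out | shift_mask(mask, off[k, 1], off[k, 2], fill = FALSE)
  }
  out
}

#' @rdname dilate
#' @export
erode <- function(mask, se) {
  stopifnot(is.matrix(mask))
  mask <- mask & TRUE
  off <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (k in seq_len(nrow(off))) {
    # pixel p keeps TRUE only if mask[p + offset] is TRUE (outside = FALSE)
    out <- out & shift_mask(mask, -off[k, 1], -off[k, 2], fill = FALSE)
  }
  out
}

#' Morphological closing of the tumor mask
#'
#' Delineates the tumor region: dilation followed by erosion with the same SE.
#' Closing fills gaps and interior holes narrower than the SE and never
#' removes foreground (it is extensive and idempotent). The mask is padded
#' with background by the SE footprint extent before closing so that the
#' region is not truncated at image edges.
#'
#' @inheritParams dilate
#' @param tumor_mask Logical matrix of tumor pixels.
#' @return Logical matrix: the closed tumor region, same size as the input.
#' @export
close_tumor_region <- function(tumor_mask, se) {
  pad <- max(dim(se$footprint))
  h <- nrow(tumor_mask); w <- ncol(tumor_mask)
  big <- matrix(FALSE, h + 2L * pad, w + 2L * pad)
  big[pad + (1:h), pad + (1:w)] <- tumor_mask & TRUE
  closed <- erode(dilate(big, se), se)
  closed[pad + (1:h), pad + (1:w), drop = FALSE]
}

#' Peri-tumoral stroma (PTS) score of a label map
#'
#' The tumor mask is closed with the structuring element to obtain the tumor
#' region; the PTS area is the number of stroma pixels lying within that
#' region (including stroma outside the raw tumor mask but inside the closed
#' region — that is what "within the tumor region boundaries" means); the
#' tumor area is the total count of tumor pixels. The PTS score is
#' `pts_area / tumor_area`, dimensionless, >= 0 and possibly > 1.
#'
#' @param labels Integer label map over [TISSUE_CLASSES].
#' @param se Structuring element; default `se_disk(64)` (about a 32 micrometer
#'   reach at 0.5 micrometer/pixel) — wide enough to bridge intra-tumoral gaps
#'   larger than a gland lumen without annexing distant stroma. Report the SE
#'   with any score.
#' @param min_object_size Optional small-object filter: connected tumor
#'   regions (4-connectivity) smaller than this pixel count are dropped from
#'   the mask before closing, to suppress salt noise from imperfect
#'   segmentation. Default 0 (off).
#' @param tumor_class,stroma_class Label codes; defaults from [TISSUE_CLASSES].
#' @return An object of class `pts_result`: list with `tumor_area`, `pts_area`
#'   (pixel counts), `score`, and `se` (descriptor used).
#' @examples
#' w <- make_wsi_labelmap(wsi_geometry_spec(
#'   canvas = c(120, 120), tumor = c(11, 11, 100, 100),
#'   holes = list(c(51, 51, 20, 20))))
#' compute_pts(w$labels, se_disk(15))
#' @export
compute_pts <- function(labels, se = se_disk(64), min_object_size = 0L,
                        tumor_class = TISSUE_CLASSES[["TUMOR"]],
                        stroma_class = TISSUE_CLASSES[["STROMA"]]) {
  stopifnot(is.matrix(labels))
  tumor_mask <- labels == tumor_class
  if (!any(tumor_mask)) stop("no tumor in slide: PTS score undefined", call. = FALSE)
  if (min_object_size > 0L) {
    tumor_mask <- filter_small_objects(tumor_mask, min_object_size)
    if (!any(tumor_mask)) stop("no tumor in slide after small-object filtering",
                               call. = FALSE)
  }
  region <- close_tumor_region(tumor_mask, se)
  tumor_area <- sum(tumor_mask)
  pts_area <- sum(region & (labels == stroma_class))
  structure(list(tumor_area = tumor_area,
                 pts_area = pts_area,
                 score = pts_area / tumor_area,
                 se = se$desc),
            class = "pts_result")
}

#' @export
print.pts_result <- function(x, ...) {
  cat(sprintf("PTS result (SE = %s)\n", x$se))
  cat(sprintf("  tumor area: %d px\n  PTS area:   %d px\n  PTS score:  %.4f\n",
              x$tumor_area, x$pts_area, x$score))
  invisible(x)
}

# drop 4-connected components below min_size pixels (two-pass flood fill)
filter_small_objects <- function(mask, min_size) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  sizes <- integer(0)
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    n <- 0L
    while (length(stack)) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (lab[p] != 0L) next
      lab[p] <- cur
      n <- n + 1L
      i <- (p - 1L) %% h + 1L
      j <- (p - 1L) %/% h + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < h) p + 1L,
              if (j > 1L) p - h, if (j < w) p + h)
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb)) stack <- c(stack, nb)
    }
    sizes[cur] <- n
  }
  keep <- which(sizes >= min_size)
  lab %in% keep & mask
}
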
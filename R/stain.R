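## Macenko stain normalization and per-channel histogram normalization.
##
## The Macenko method works in optical density (OD) space: OD = -log10(I/255).
## Tissue pixels form a wedge between the hematoxylin and eosin absorption
## directions; the method takes the top-2 singular plane of the thresholded OD
## cloud and reads the stain vectors off the extreme percentile angles within
## that plane, then remaps per-pixel stain concentrations to a reference.

#' Convert RGB intensities to optical density and back
#'
#' `rgb_to_od()` maps intensities to `OD = -log10(max(I/255, floor))`;
#' `od_to_rgb()` inverts it (round-half-even, clipped to 0-255). The floor
#' keeps white pixels finite; the pair is inverse above the floor.
#'
#' @param tile Numeric array `h x w x 3` (or any numeric array) of
#'   intensities in 0-255.
#' @param od Nonnegative optical-density array.
#' @param floor Lower bound for `I/255` before the log (default `1/255`).
#' @return Array of the same shape.
#' @examples
#' rgb_to_od(array(25.5, c(1, 1, 3)))  # exactly 1
#' @export
rgb_to_od <- function(tile, floor = 1 / 255) {
  if (floor <= 0 || floor > 1) stop("floor must be in (0, 1]", call. = FALSE)
  -log10(pmax(tile / 255, floor))
}

#' @rdname rgb_to_od
#' @export
od_to_rgb <- function(od) {
  out <- round(255 * 10^(-od))
  out[out < 0] <- 0; out[out > 255] <- 255
  out
}

#' Construct an H&E stain model
#'
#' @param stain_matrix 3 x 2 matrix of unit-norm OD stain vectors, columns
#'   ordered (H, E).
#' @param max_concentrations Length-2 positive vector of robust (99th
#'   percentile) per-stain concentration maxima.
#' @return Object of class `stain_model`.
#' @export
stain_model <- function(stain_matrix, max_concentrations) {
  stain_matrix <- as.matrix(stain_matrix)
  stopifnot(nrow(stain_matrix) == 3, ncol(stain_matrix) == 2)
  nrm <- sqrt(colSums(stain_matrix^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("stain vectors must have unit norm", call. = FALSE)
  if (any(max_concentrations <= 0))
    stop("max_concentrations must be positive", call. = FALSE)
  colnames(stain_matrix) <- c("H", "E")
  rownames(stain_matrix) <- c("R", "G", "B")
  structure(list(stain_matrix = stain_matrix,
                 max_concentrations = as.numeric(max_concentrations)),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("H&E stain model (OD space)\n")
  print(round(x$stain_matrix, 4))
  cat(sprintf("robust max concentrations: H %.4f, E %.4f\n",
              x$max_concentrations[1], x$max_concentrations[2]))
  invisible(x)
}

#' Estimate an H&E stain model from a tile (Macenko)
#'
#' Pixels with OD Euclidean norm above `beta` are taken as tissue; the top-2
#' right singular directions of that OD cloud span the stain plane; the stain
#' vectors are read at the `alpha` and `100 - alpha` percentile angles within
#' the plane. Vector signs are flipped so components are nonnegative (tiny
#' negative residuals are clipped and the vector renormalized). The column
#' with the larger red-channel OD component is labeled H (hematoxylin absorbs
#' red most strongly); robust per-stain maxima are the 99th percentile of
#' nonnegative-least-squares concentrations over tissue pixels.
#'
#' @param od OD array `h x w x 3`, as from [rgb_to_od()].
#' @param beta OD-norm tissue threshold (default 0.15).
#' @param alpha Angular percentile (default 1, i.e. 1st/99th).
#' @param min_tissue Minimum tissue pixel count (default 100); fewer raises an
#'   "insufficient tissue" error (e.g. an all-white tile).
#' @return A [stain_model()].
#' @export
estimate_stain_model <- function(od, beta = 0.15, alpha = 1, min_tissue = 100L) {
  odm <- matrix(od, ncol = 3)
  keep <- sqrt(rowSums(odm^2)) > beta
  if (sum(keep) < min_tissue) {
    stop(sprintf("insufficient tissue: %d pixels above OD threshold (need >= %d)",
                 sum(keep), min_tissue), call. = FALSE)
  }
  odt <- odm[keep, , drop = FALSE]
  v <- svd(odt, nu = 0, nv = 2)$v  # plane of top-2 singular directions
  # orient basis vectors toward the positive octant for a stable angle origin
  for (j in 1:2) if (sum(v[, j]) < 0) v[, j] <- -v[, j]
  proj <- odt %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  # inverse-ECDF quantiles: invariant under pixel duplication
  q <- stats::quantile(phi, c(alpha, 100 - alpha) / 100, names = FALSE, type = 1)
  vecs <- sapply(q, function(a) v %*% c(cos(a), sin(a)))
  for (j in 1:2) {
    if (sum(vecs[, j]) < 0) vecs[, j] <- -vecs[, j]
    vecs[vecs[, j] < 0, j] <- 0          # clip tiny negative residuals
    vecs[, j] <- vecs[, j] / sqrt(sum(vecs[, j]^2))
  }
  # H = column with larger red-absorbing (first) component; tie -> larger angle
  if (vecs[1, 2] > vecs[1, 1]) vecs <- vecs[, 2:1]
  conc <- nnls_two(vecs, odt)
  maxc <- apply(conc, 2, stats::quantile, probs = 0.99, names = FALSE, type = 1)
  maxc[maxc <= 0] <- 1e-6
  stain_model(vecs, maxc)
}

# exact nonnegative least squares for a 3x2 design, vectorized over pixels:
# unconstrained solve, then project infeasible pixels onto the single-stain
# axes and keep the lower-residual candidate
nnls_two <- function(A, B) {
  G <- crossprod(A)            # 2x2
  Gi <- solve(G)
  C <- B %*% A %*% Gi          # n x 2 unconstrained LS
  bad <- which(C[, 1] < 0 | C[, 2] < 0)
  if (length(bad)) {
    Bb <- B[bad, , drop = FALSE]
    c1 <- pmax(0, (Bb %*% A[, 1]) / G[1, 1])  # stain-1-only candidates
    c2 <- pmax(0, (Bb %*% A[, 2]) / G[2, 2])
    r1 <- rowSums((Bb - tcrossprod(c1, A[, 1]))^2)
    r2 <- rowSums((Bb - tcrossprod(c2, A[, 2]))^2)
    use1 <- r1 <= r2
    C[bad, 1] <- ifelse(use1, c1, 0)
    C[bad, 2] <- ifelse(use1, 0, c2)
  }
  C
}

#' Macenko stain normalization
#'
#' Estimates the tile's own stain model, solves per-pixel H/E concentrations
#' by nonnegative least squares, rescales each stain so its robust maximum
#' matches the target's, and recomposes the image with the target stain
#' matrix. Output is clipped to 0-255. Idempotent up to quantization.
#'
#' @param tile Integer RGB array `h x w x 3` in 0-255.
#' @param target Reference [stain_model()].
#' @param beta,alpha,min_tissue Passed to [estimate_stain_model()].
#' @param floor Passed to [rgb_to_od()].
#' @return Normalized integer RGB array, same shape.
#' @export
normalize_macenko <- function(tile, target, beta = 0.15, alpha = 1,
                              min_tissue = 100L, floor = 1 / 255) {
  stopifnot(inherits(target, "stain_model"))
  od <- rgb_to_od(tile, floor)
  src <- estimate_stain_model(od, beta = beta, alpha = alpha,
                              min_tissue = min_tissue)
  odm <- matrix(od, ncol = 3)
  conc <- nnls_two(src$stain_matrix, odm)
  conc <- sweep(conc, 2, target$max_concentrations / src$max_concentrations, `*`)
  od_new <- conc %*% t(target$stain_matrix)
  out <- od_to_rgb(od_new)
  array(as.integer(out), dim = dim(tile))
}

#' Per-channel histogram normalization
#'
#' Affinely rescales each RGB channel so its minimum maps to 0 and its
#' maximum to 255 (round-half-even). A constant channel passes through
#' unchanged — stretching it would fabricate contrast. Idempotent.
#'
#' @param tile Integer RGB array `h x w x 3` in 0-255.
#' @return Integer array of the same shape.
#' @examples
#' histogram_normalize(array(c(10, 60, 110), c(3, 1, 1)))
#' @export
histogram_normalize <- function(tile) {
  out <- tile
  nch <- dim(tile)[3]
  for (ch in seq_len(nch)) {
    x <- tile[, , ch]
    lo <- min(x); hi <- max(x)
    if (hi > lo) out[, , ch] <- round((x - lo) * 255 / (hi - lo))
  }
  array(as.integer(out), dim = dim(tile))
}

#' Read or write a stain model as YAML
#'
#' Serializes the six stain-vector components and two maxima, the reference
#' block handed around between pipeline stages.
#'
#' @param model A [stain_model()].
#' @param path File path.
#' @return `read_stain_model()` returns a [stain_model()];
#'   `write_stain_model()` returns `path` invisibly.
#' @export
write_stain_model <- function(model, path) {
  stopifnot(inherits(model, "stain_model"))
  yaml::write_yaml(list(
    stain_matrix = list(H = as.numeric(model$stain_matrix[, 1]),
                        E = as.numeric(model$stain_matrix[, 2])),
    max_concentrations = model$max_concentrations), path,
    precision = 12L)
  invisible(path)
}

#' @rdname write_stain_model
#' @export
read_stain_model <- function(path) {
  y <- yaml::read_yaml(path)
  stain_model(cbind(y$stain_matrix$H, y$stain_matrix$E),
              y$max_concentrations)
}

#' Default reference H&E stain model
#'
#' The standard hematoxylin/eosin OD vectors (H ~ (0.65, 0.70, 0.29),
#' E ~ (0.07, 0.99, 0.11), normalized) with unit robust maxima; a reasonable
#' fixed target when no cohort-derived reference is supplied.
#'
#' @return A [stain_model()].
#' @export
default_stain_target <- function() {
  h <- c(0.65, 0.70, 0.29); e <- c(0.07, 0.99, 0.11)
  stain_model(cbind(h / sqrt(sum(h^2)), e / sqrt(sum(e^2))), c(1, 1))
}
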
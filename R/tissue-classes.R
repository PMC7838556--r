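#' Tissue class codes
#'
#' Integer label codes for the seven foreground tissue classes segmented from
#' colon-cancer H&E histology, plus a reserved background code. Background is
#' never counted as tissue: it is excluded from Dice evaluation and from PTS
#' scoring.
#'
#' @format A named integer vector with entries `BACKGROUND` (0), `TUMOR` (1,
#'   colon cancer epithelium), `STROMA` (2), `LYMPHOCYTES` (3), `MUCUS` (4),
#'   `ADIPOSE` (5), `MUSCLE` (6, smooth muscle) and `NORMAL` (7, normal colon
#'   mucosa).
#' @export
TISSUE_CLASSES <- c(
  BACKGROUND  = 0L,
  TUMOR       = 1L,
  STROMA      = 2L,
  LYMPHOCYTES = 3L,
  MUCUS       = 4L,
  ADIPOSE     = 5L,
  MUSCLE      = 6L,
  NORMAL      = 7L
)

#' Foreground tissue class codes
#'
#' The seven foreground classes, i.e. [TISSUE_CLASSES] without `BACKGROUND`.
#'
#' @return Named integer vector of length 7.
#' @export
tissue_classes <- function() {
  TISSUE_CLASSES[names(TISSUE_CLASSES) != "BACKGROUND"]
}

#' Default H&E-like rendering palette
#'
#' Per-class mean RGB values (0-255) used by the synthetic tile and slide
#' generators. Colors are loosely H&E-themed (tumor purple, stroma pink-green,
#' lymphocytes dark blue, mucus pale, adipose near-white, muscle salmon,
#' normal mucosa light violet) and pairwise well separated so that classes are
#' learnable from color alone.
#'
#' @return A 7 x 3 numeric matrix, rows named by class.
#' @export
default_class_palette <- function() {
  m <- rbind(
    TUMOR       = c(120,  40, 140),
    STROMA      = c( 90, 180, 120),
    LYMPHOCYTES = c( 40,  50, 160),
    MUCUS       = c(230, 220, 120),
    ADIPOSE     = c(245, 120, 110),
    MUSCLE      = c(235, 150,  60),
    NORMAL      = c(150, 200, 235)
  )
  colnames(m) <- c("R", "G", "B")
  m
}

# validate an integer label map against the class set
assert_labelmap <- function(labels) {
  if (!is.matrix(labels)) stop("label map must be a matrix", call. = FALSE)
  ok <- labels %in% TISSUE_CLASSES
  if (!all(ok)) {
    stop("label map contains values outside the tissue class set", call. = FALSE)
  }
  invisible(labels)
}
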
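## Synthetic ground-truth generators: labeled tiles, whole-slide label maps
## with analytically known PTS scores, and cohorts with a known logit effect.
## Every generator is a pure function of (spec, seed).

# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Specification of synthetic labeled tiles
#'
#' Describes a family of square H&E-like tiles in which each tile carries a
#' single tissue class rendered as its base RGB color plus Gaussian noise,
#' mimicking a patch-classification training archive (patches of one class
#' each, approximately balanced across classes). Classes must be separable:
#' pairwise Euclidean distance between base colors must exceed
#' `min_separation`, otherwise the spec is rejected as unlearnable.
#'
#' @param tile_size Tile side in pixels (default 224, the customary patch
#'   size at 0.5 micrometer/pixel).
#' @param classes Integer codes of the classes to render (default all seven
#'   foreground classes).
#' @param means Per-class base RGB matrix (rows named by class, 0-255);
#'   default [default_class_palette()].
#' @param noise_sd Gaussian RGB noise SD (0-255 scale), default 10.
#' @param grain Texture grain in pixels: noise is drawn on a grid of
#'   `grain x grain` blocks and upscaled, giving coarse blotches rather than
#'   per-pixel speckle when > 1. Default 1.
#' @param min_separation Minimum pairwise distance between base colors
#'   (default 30).
#' @return Object of class `tile_spec`.
#' @export
tile_spec <- function(tile_size = 224L, classes = tissue_classes(),
                      means = default_class_palette(), noise_sd = 10,
                      grain = 1L, min_separation = 30) {
  tile_size <- as.integer(tile_size)
  if (tile_size < 1L) stop("tile_size must be positive", call. = FALSE)
  classes <- as.integer(classes)
  if (!all(classes %in% tissue_classes()))
    stop("classes must be foreground tissue classes", call. = FALSE)
  cls_names <- names(TISSUE_CLASSES)[match(classes, TISSUE_CLASSES)]
  if (!all(cls_names %in% rownames(means)))
    stop("means must have a row for every requested class", call. = FALSE)
  m <- means[cls_names, , drop = FALSE]
  if (length(classes) > 1L) {
    d <- as.matrix(stats::dist(m))
    diag(d) <- Inf
    if (min(d) < min_separation) {
      bad <- which(d == min(d), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "class colors '%s' and '%s' are only %.1f apart (< separability margin %.1f)",
        rownames(m)[bad[1]], rownames(m)[bad[2]], min(d), min_separation),
        call. = FALSE)
    }
  }
  structure(list(tile_size = tile_size, classes = classes, means = m,
                 noise_sd = noise_sd, grain = as.integer(grain),
                 min_separation = min_separation),
            class = "tile_spec")
}

# render one single-class tile: base color + (possibly coarse-grained) noise
render_class_tile <- function(spec, class_name) {
  s <- spec$tile_size
  base <- spec$means[class_name, ]
  tile <- array(rep(base, each = s * s), dim = c(s, s, 3))
  if (spec$noise_sd > 0) {
    g <- max(1L, spec$grain)
    gs <- ceiling(s / g)
    noise <- array(stats::rnorm(gs * gs * 3, 0, spec$noise_sd),
                   dim = c(gs, gs, 3))
    idx <- rep(seq_len(gs), each = g)[1:s]
    tile <- tile + noise[idx, idx, , drop = FALSE]
  }
  array(as.integer(round(pmin(255, pmax(0, tile)))), dim = c(s, s, 3))
}

#' Generate labeled tiles
#'
#' Produces `n` (tile, label-map) pairs with classes assigned round-robin so
#' class counts are approximately equal across the set. Each tile is a single
#' class; its label map is constant at that class. Bit-identical output for
#' identical `(spec, n, seed)`.
#'
#' @param spec A [tile_spec()].
#' @param n Number of tiles (>= 1).
#' @param seed Integer seed.
#' @return List of length `n`; each element has `tile` (integer
#'   `size x size x 3` array, 0-255), `labels` (integer matrix) and `class`
#'   (the class code).
#' @export
make_labeled_tiles <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "tile_spec"))
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  cls <- rep_len(spec$classes, n)
  cls_names <- names(TISSUE_CLASSES)[match(cls, TISSUE_CLASSES)]
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      list(tile = render_class_tile(spec, cls_names[i]),
           labels = matrix(cls[i], spec$tile_size, spec$tile_size),
           class = cls[i])
    })
  })
}

#' Specification of a synthetic whole-slide label map
#'
#' Axis-aligned rectangle geometry (exact integer areas, no anti-aliasing):
#' a filled tumor rectangle, optional interior stroma holes (rectangles
#' strictly inside the tumor and pairwise disjoint), an exterior stroma band
#' around the tumor, remaining canvas filled with a filler class, outermost
#' border background.
#'
#' Rectangles are given as `c(row, col, height, width)` (top-left corner,
#' 1-based).
#'
#' @param canvas `c(height, width)` of the label map.
#' @param tumor Tumor rectangle.
#' @param holes List of hole rectangles (possibly empty).
#' @param band Exterior stroma band width in pixels (default 10).
#' @param filler Class code for the remaining tissue (default `NORMAL`).
#' @param border Background border width (default 2).
#' @return Object of class `wsi_geometry_spec`.
#' @export
wsi_geometry_spec <- function(canvas, tumor, holes = list(), band = 10L,
                              filler = TISSUE_CLASSES[["NORMAL"]],
                              border = 2L) {
  canvas <- as.integer(canvas); tumor <- as.integer(tumor)
  holes <- lapply(holes, as.integer)
  rect_ok <- function(r, h, w) {
    length(r) == 4L && all(r[3:4] >= 1L) && r[1] >= 1L && r[2] >= 1L &&
      (r[1] + r[3] - 1L) <= h && (r[2] + r[4] - 1L) <= w
  }
  if (!rect_ok(tumor, canvas[1], canvas[2]))
    stop("tumor rectangle must lie within the canvas", call. = FALSE)
  inside <- function(hole, outer) {
    hole[1] > outer[1] && hole[2] > outer[2] &&
      (hole[1] + hole[3]) <= (outer[1] + outer[3]) &&
      (hole[2] + hole[4]) <= (outer[2] + outer[4])
  }
  overlap <- function(a, b) {
    a[1] < b[1] + b[3] && b[1] < a[1] + a[3] &&
      a[2] < b[2] + b[4] && b[2] < a[2] + a[4]
  }
  for (hole in holes) {
    if (!inside(hole, tumor))
      stop("each hole must lie strictly inside the tumor rectangle", call. = FALSE)
  }
  if (length(holes) > 1L) {
    for (i in seq_along(holes)[-1]) for (j in seq_len(i - 1L)) {
      if (overlap(holes[[i]], holes[[j]]))
        stop("holes must be pairwise disjoint", call. = FALSE)
    }
  }
  structure(list(canvas = canvas, tumor = tumor, holes = holes,
                 band = as.integer(band), filler = as.integer(filler),
                 border = as.integer(border)),
            class = "wsi_geometry_spec")
}

#' Build a whole-slide label map with known PTS ground truth
#'
#' Constructs the label map described by the spec and returns it with exact
#' pixel-count ground truth. For rectangle-with-rectangular-holes geometry and
#' any structuring element that fills every hole, the closed tumor region is
#' the full tumor rectangle, so the expected PTS score is analytically
#' `sum(hole areas) / tumor area`.
#'
#' @param spec A [wsi_geometry_spec()].
#' @return List with `labels` (integer matrix), `truth` (list: `tumor_area`,
#'   `hole_areas`, `expected_score` — the score for any hole-filling SE).
#' @export
make_wsi_labelmap <- function(spec) {
  stopifnot(inherits(spec, "wsi_geometry_spec"))
  h <- spec$canvas[1]; w <- spec$canvas[2]
  labels <- matrix(spec$filler, h, w)
  b <- spec$border
  if (b > 0L) {
    labels[c(seq_len(min(b, h)), seq(max(1L, h - b + 1L), h)), ] <- TISSUE_CLASSES[["BACKGROUND"]]
    labels[, c(seq_len(min(b, w)), seq(max(1L, w - b + 1L), w))] <- TISSUE_CLASSES[["BACKGROUND"]]
  }
  fill_rect <- function(m, r, val) {
    rows <- r[1]:(r[1] + r[3] - 1L); cols <- r[2]:(r[2] + r[4] - 1L)
    rows <- rows[rows >= 1L & rows <= h]; cols <- cols[cols >= 1L & cols <= w]
    m[rows, cols] <- val
    m
  }
  # exterior stroma band around the tumor
  if (spec$band > 0L) {
    t <- spec$tumor
    labels <- fill_rect(labels, c(t[1] - spec$band, t[2] - spec$band,
                                  t[3] + 2L * spec$band, t[4] + 2L * spec$band),
                        TISSUE_CLASSES[["STROMA"]])
  }
  labels <- fill_rect(labels, spec$tumor, TISSUE_CLASSES[["TUMOR"]])
  for (hole in spec$holes) {
    labels <- fill_rect(labels, hole, TISSUE_CLASSES[["STROMA"]])
  }
  hole_areas <- vapply(spec$holes, function(r) as.numeric(r[3] * r[4]), numeric(1))
  tumor_area <- as.numeric(spec$tumor[3]) * spec$tumor[4] - sum(hole_areas)
  stopifnot(tumor_area == sum(labels == TISSUE_CLASSES[["TUMOR"]]))
  list(labels = labels,
       truth = list(tumor_area = tumor_area,
                    hole_areas = hole_areas,
                    expected_score = sum(hole_areas) / tumor_area))
}

#' Render an RGB image from a label map
#'
#' Paints each class with its palette color plus optional Gaussian noise;
#' background renders near-white (slide glass). Used to turn synthetic
#' whole-slide label maps into images the segmenter can be run on.
#'
#' @param labels Integer label map.
#' @param means Palette as in [tile_spec()].
#' @param noise_sd Gaussian noise SD, default 0.
#' @param seed Seed used when `noise_sd > 0`.
#' @return Integer `h x w x 3` array in 0-255.
#' @export
render_labelmap_rgb <- function(labels, means = default_class_palette(),
                                noise_sd = 0, seed = 1L) {
  pal <- rbind(BACKGROUND = c(248, 248, 248), means)
  codes <- TISSUE_CLASSES[rownames(pal)]
  idx <- match(as.vector(labels), codes)
  if (anyNA(idx)) stop("label map contains classes missing from the palette", call. = FALSE)
  h <- nrow(labels); w <- ncol(labels)
  img <- array(pal[idx, ], dim = c(h, w, 3))
  if (noise_sd > 0) {
    img <- with_seed(seed, img + array(stats::rnorm(h * w * 3, 0, noise_sd),
                                       dim = c(h, w, 3)))
  }
  array(as.integer(round(pmin(255, pmax(0, img)))), dim = c(h, w, 3))
}

#' Specification of a synthetic patient cohort
#'
#' Emulates a colon-cancer cohort table: a nonnegative PTS score drawn from a
#' Beta distribution scaled to `[0, score_max]` and parameterized by target
#' mean/SD; lymph-node metastasis (LNM) drawn Bernoulli with
#' `logit P(LNM) = beta0 + beta1 * PTS`; lymphatic/perineural/venous invasion
#' flags drawn conditionally on LNM and masked to `NA` at per-flag rates;
#' T stage drawn per LNM group. Defaults reproduce the observed-cohort
#' conditions: score mean 0.380 / SD 0.285, slope `log(29.654)` (the reported
#' per-unit odds ratio), intercept set so the marginal LNM rate is about
#' 66/164 at the mean score, flag conditionals and NA rates and per-group
#' T-stage frequencies taken from the reported two-group table.
#'
#' @param n Number of patients (>= 1).
#' @param beta0,beta1 Intercept and slope of the logit of LNM on PTS score.
#' @param score_mean,score_sd,score_max Target mean/SD of the scaled-Beta PTS
#'   distribution on `[0, score_max]`.
#' @param flag_probs Named list (`li`, `pi`, `vi`), each `c(neg=, pos=)`:
#'   P(flag = yes | LNM group).
#' @param na_rates Named vector of NA masking rates for the three flags.
#' @param t_stage_probs List with `neg` and `pos` probability vectors over
#'   T0..T4.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 164L,
                        beta0 = -1.69, beta1 = log(29.654),
                        score_mean = 0.380, score_sd = 0.285, score_max = 1.2,
                        flag_probs = list(li = c(neg = 11 / 90, pos = 42 / 64),
                                          pi = c(neg = 12 / 70, pos = 13 / 45),
                                          vi = c(neg = 13 / 89, pos = 25 / 62)),
                        na_rates = c(li = 10 / 164, pi = 49 / 164, vi = 13 / 164),
                        t_stage_probs = list(
                          neg = c(1, 4, 25, 63, 5) / 98,
                          pos = c(0, 1, 2, 53, 10) / 66)) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  probs <- c(unlist(flag_probs), na_rates,
             unlist(t_stage_probs))
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0,1]", call. = FALSE)
  if (score_mean <= 0 || score_mean >= score_max || score_sd <= 0)
    stop("score mean must be in (0, score_max) with positive SD", call. = FALSE)
  m <- score_mean / score_max
  v <- (score_sd / score_max)^2
  if (v >= m * (1 - m))
    stop("score SD too large for a Beta distribution with this mean", call. = FALSE)
  k <- m * (1 - m) / v - 1
  structure(list(n = n, beta0 = beta0, beta1 = beta1,
                 score_max = score_max, shape1 = m * k, shape2 = (1 - m) * k,
                 flag_probs = flag_probs, na_rates = na_rates,
                 t_stage_probs = t_stage_probs),
            class = "cohort_spec")
}

#' Generate a synthetic cohort table
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return A data.frame with columns `patient_id`, `age`, `sex`, `t_stage`,
#'   `n_stage`, `lnm` (logical), `li`, `pi`, `vi`, `anyi` (each
#'   "yes"/"no"/NA), `pts_score`, and all-`FALSE` exclusion flags `rectal`,
#'   `inadequate_image`, `distant_metastasis`.
#' @export
make_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, {
    n <- spec$n
    pts <- spec$score_max * stats::rbeta(n, spec$shape1, spec$shape2)
    lnm <- stats::runif(n) < stats::plogis(spec$beta0 + spec$beta1 * pts)
    grp <- ifelse(lnm, "pos", "neg")
    draw_flag <- function(name) {
      p <- spec$flag_probs[[name]][grp]
      x <- ifelse(stats::runif(n) < p, "yes", "no")
      x[stats::runif(n) < spec$na_rates[[name]]] <- NA
      x
    }
    li <- draw_flag("li"); pi_ <- draw_flag("pi"); vi <- draw_flag("vi")
    t_lv <- c("T0", "T1", "T2", "T3", "T4")
    t_stage <- character(n)
    for (g in c("neg", "pos")) {
      sel <- grp == g
      if (any(sel)) t_stage[sel] <- sample(t_lv, sum(sel), replace = TRUE,
                                           prob = spec$t_stage_probs[[g]])
    }
    n_stage <- ifelse(!lnm, "N0",
                      ifelse(stats::runif(n) < 46 / 66, "N1", "N2"))
    age <- round(stats::rnorm(n, ifelse(lnm, 61.8, 66.8),
                              ifelse(lnm, 13.6, 13.1)), 1)
    sex <- ifelse(stats::runif(n) < ifelse(lnm, 30 / 66, 48 / 98), "M", "F")
    data.frame(patient_id = sprintf("P%05d", seq_len(n)),
               age = age, sex = sex, t_stage = t_stage, n_stage = n_stage,
               lnm = lnm, li = li, pi = pi_, vi = vi,
               anyi = derive_anyi(li, pi_, vi),
               pts_score = pts,
               rectal = FALSE, inadequate_image = FALSE,
               distant_metastasis = FALSE,
               stringsAsFactors = FALSE)
  })
}
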
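## Patch preparation and evaluation utilities for the tissue segmenter.

# mirror-extension index for one axis: [a,b,c] padded by 2 -> c,b,a,b,c,b,a
# (edge pixel not repeated); padding wider than the axis folds periodically
reflect_idx <- function(n, before, after) {
  if (n == 1L) return(rep(1L, before + 1L + after))
  q <- seq.int(-before, n - 1L + after)     # 0-based positions
  p <- 2L * (n - 1L)
  r <- q %% p
  r <- ifelse(r >= n, p - r, r)
  r + 1L
}

#' Reflect-pad a tile or label map to a target size
#'
#' Pads with mirrored interior values (the edge pixel itself is not repeated)
#' until the array is `target x target`; padding is split as evenly as
#' possible with the extra pixel on the bottom/right. Used to bring training
#' patches up to the network input size. Center-cropping the result recovers
#' the input exactly.
#'
#' @param x Matrix (label map) or `h x w x c` array (RGB tile).
#' @param target Target side length in pixels; must be >= both input sides.
#' @return Padded array, `target x target` (times channels).
#' @examples
#' reflect_pad(matrix(1:9, 3), 5)
#' @export
reflect_pad <- function(x, target) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h > target || w > target)
    stop("input larger than target size; tile the image first", call. = FALSE)
  ph <- target - h; pw <- target - w
  ri <- reflect_idx(h, ph %/% 2L, ph - ph %/% 2L)
  ci <- reflect_idx(w, pw %/% 2L, pw - pw %/% 2L)
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

#' Center-crop an array to a given size
#'
#' Inverse of [reflect_pad()] placement: removes `floor(pad/2)` from the
#' top/left.
#'
#' @param x Matrix or 3-d array.
#' @param h,w Output height and width.
#' @return Cropped array.
#' @export
center_crop <- function(x, h, w) {
  d <- dim(x)
  r0 <- (d[1] - h) %/% 2L
  c0 <- (d[2] - w) %/% 2L
  if (length(d) == 2L) x[r0 + seq_len(h), c0 + seq_len(w), drop = FALSE]
  else x[r0 + seq_len(h), c0 + seq_len(w), , drop = FALSE]
}

# largest-remainder allocation of n into parts proportional to fracs
largest_remainder <- function(n, fracs) {
  raw <- n * fracs
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split labeled pairs into train / validation / test sets
#'
#' Random split stratified by each tile's majority class: global split sizes
#' follow the fractions exactly (largest-remainder rounding) and each stratum
#' is represented in each split proportionally (within one tile). The default
#' 80/10/10 follows the customary patch-archive protocol. Reproducible under
#' `seed`.
#'
#' @param pairs List of `(tile, labels)` pairs as from [make_labeled_tiles()].
#' @param fractions Length-3 nonnegative vector summing to 1.
#' @param seed Integer seed.
#' @return List with elements `train`, `validation`, `test` (disjoint,
#'   exhaustive sublists of `pairs`).
#' @export
split_dataset <- function(pairs, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(pairs) < 10L) stop("need at least 10 pairs to split", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must sum to 1", call. = FALSE)
  maj <- vapply(pairs, function(p) {
    tab <- table(p$labels)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  n <- length(pairs)
  targets <- largest_remainder(n, fractions)  # global (train, val, test)
  strata <- split(seq_len(n), maj)
  with_seed(seed, {
    assign_split <- integer(n)  # 1 train, 2 val, 3 test
    # per-stratum proportional quotas for val and test, remainders assigned
    # globally by largest remainder so global counts are exact
    for (k in 3:2) {
      raw <- vapply(strata, length, integer(1)) * fractions[k]
      quota <- floor(raw)
      short <- targets[k] - sum(quota)
      if (short > 0) {
        extra <- order(raw - quota, decreasing = TRUE)[seq_len(short)]
        quota[extra] <- quota[extra] + 1
      } else if (short < 0) {
        trim <- order(raw - quota)[seq_len(-short)]
        quota[trim] <- quota[trim] - 1
      }
      for (s in seq_along(strata)) {
        free <- strata[[s]][assign_split[strata[[s]]] == 0L]
        take <- sample(free, min(quota[s], length(free)))
        assign_split[take] <- k
      }
    }
    assign_split[assign_split == 0L] <- 1L
    list(train = pairs[assign_split == 1L],
         validation = pairs[assign_split == 2L],
         test = pairs[assign_split == 3L])
  })
}

#' Dice similarity coefficient for one class
#'
#' `2|P ∩ T| / (|P| + |T|)` over the class masks of a predicted and a true
#' label map. When the class is absent from both maps the coefficient is
#' defined as 1 (absence correctly predicted); callers that average per-class
#' Dice over patches exclude such patches from the class's n.
#'
#' @param pred,truth Integer label maps of identical shape.
#' @param cls Class code.
#' @return Numeric in `[0, 1]`.
#' @export
dice_coefficient <- function(pred, truth, cls) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have the same shape", call. = FALSE)
  p <- pred == cls
  t <- truth == cls
  denom <- sum(p) + sum(t)
  if (denom == 0) return(1)
  2 * sum(p & t) / denom
}

#' Per-class Dice evaluation report
#'
#' Computes per-patch, per-class Dice over a test set and summarizes each
#' class by mean, SD and a normal-approximation 95% CI
#' (`mean +/- 1.96 * SD / sqrt(n)`), with n counting only patches where the
#' class occurs in truth or prediction. A pooled `Total` row aggregates all
#' such (patch, class) values.
#'
#' @param pred_labels List of predicted label maps.
#' @param true_labels List of matching ground-truth label maps.
#' @param classes Class codes to evaluate (default the seven tissue classes;
#'   background is never evaluated).
#' @return Object of class `dsc_report`: a data.frame with columns `class`,
#'   `n`, `mean`, `sd`, `ci_lower`, `ci_upper`.
#' @export
evaluate_dsc <- function(pred_labels, true_labels, classes = tissue_classes()) {
  stopifnot(length(pred_labels) == length(true_labels),
            length(pred_labels) >= 1L)
  per <- matrix(NA_real_, length(pred_labels), length(classes))
  for (i in seq_along(pred_labels)) {
    for (j in seq_along(classes)) {
      cls <- classes[j]
      present <- any(pred_labels[[i]] == cls) || any(true_labels[[i]] == cls)
      if (present)
        per[i, j] <- dice_coefficient(pred_labels[[i]], true_labels[[i]], cls)
    }
  }
  summarize <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    s <- if (n > 1) stats::sd(v) else 0
    half <- if (n) 1.96 * s / sqrt(n) else NA_real_
    c(n = n, mean = m, sd = s,
      ci_lower = max(0, m - half), ci_upper = min(1, m + half))
  }
  rows <- t(apply(per, 2, summarize))
  total <- summarize(as.vector(per))
  out <- data.frame(class = c(names(classes), "Total"),
                    rbind(rows, total), row.names = NULL)
  class(out) <- c("dsc_report", "data.frame")
  out
}

#' @export
print.dsc_report <- function(x, digits = 3, ...) {
  cat("Dice similarity report (per-class mean (SD), normal 95% CI)\n")
  df <- as.data.frame(x)
  df$mean <- round(df$mean, digits); df$sd <- round(df$sd, digits)
  df$ci_lower <- round(df$ci_lower, digits); df$ci_upper <- round(df$ci_upper, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Multi-level Otsu tissue mask
#'
#' Thresholds the grayscale image (channel mean) into `levels` strata by
#' exhaustive maximization of the between-class variance over the 0-255
#' histogram; the brightest stratum is taken as background (glass), the rest
#' as tissue.
#'
#' @param tile Integer RGB array in 0-255.
#' @param levels Number of strata (2-4; default 3).
#' @return List with `mask` (logical tissue matrix) and `thresholds`
#'   (increasing integer cut points; gray > last threshold = background).
#' @export
tissue_threshold <- function(tile, levels = 3L) {
  levels <- as.integer(levels)
  if (levels < 2L || levels > 4L) stop("levels must be 2..4", call. = FALSE)
  gray <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
  g <- pmin(255L, pmax(0L, as.integer(round(gray))))
  thr <- multi_otsu_thresholds(tabulate(g + 1L, 256L), levels)
  list(mask = matrix(g <= thr[length(thr)], nrow(gray), ncol(gray)),
       thresholds = thr)
}

# maximize between-class variance sum(w_k * mu_k^2) over threshold tuples
# (recursive exhaustive search on cumulative sums; exact, feasible to k=4)
multi_otsu_thresholds <- function(hist256, levels) {
  p <- hist256 / sum(hist256)
  w <- cumsum(p)
  mu <- cumsum(p * (0:255))
  seg_score <- function(a, b) {  # strata covering gray values a..b (0-based)
    wk <- w[b + 1] - if (a > 0) w[a] else 0
    mk <- mu[b + 1] - if (a > 0) mu[a] else 0
    if (wk <= 0) 0 else mk * mk / wk
  }
  best <- -Inf; best_thr <- NULL
  search <- function(start, remaining, acc, thrs) {
    if (remaining == 1L) {
      sc <- acc + seg_score(start, 255L)
      if (sc > best) { best <<- sc; best_thr <<- thrs }
      return(invisible())
    }
    for (t in start:(256L - remaining)) {
      search(t + 1L, remaining - 1L, acc + seg_score(start, t), c(thrs, t))
    }
  }
  search(0L, levels, 0, integer(0))
  best_thr
}

#' Early-stopping monitor for validation DSC
#'
#' Implements the stopping rule: training halts after the first epoch `e`
#' such that no epoch in `(b, b + patience]` improved the best validation
#' mean DSC (at epoch `b`) by at least `min_gain` relative (default 0.1%).
#' An epoch counts as an improvement only when
#' `dsc > best * (1 + min_gain)`; the best epoch's weights are the ones kept.
#'
#' @param dsc_history Numeric vector of per-epoch validation mean DSC.
#' @param patience Epochs to wait after the best (default 10).
#' @param min_gain Minimum relative improvement (default 0.001 = 0.1%).
#' @return List with `stop_epoch` (last epoch run, or `length(dsc_history)`
#'   if the rule never fired — element `stopped` says which) and `best_epoch`.
#' @export
early_stopping_status <- function(dsc_history, patience = 10L,
                                  min_gain = 0.001) {
  best <- -Inf; best_epoch <- 0L
  for (e in seq_along(dsc_history)) {
    if (dsc_history[e] > best * (1 + min_gain) || best_epoch == 0L) {
      best <- dsc_history[e]; best_epoch <- e
    }
    if (e - best_epoch >= patience) {
      return(list(stop_epoch = e, best_epoch = best_epoch, stopped = TRUE))
    }
  }
  list(stop_epoch = length(dsc_history), best_epoch = best_epoch,
       stopped = FALSE)
}
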
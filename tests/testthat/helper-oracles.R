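# Independent oracles used against the package implementations.

# brute-force dilation straight from the definition: output pixel is TRUE iff
# any active SE cell, placed with its origin at the pixel, covers a TRUE input
brute_dilate <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  off <- which(se$footprint, arr.ind = TRUE)
  off[, 1] <- off[, 1] - se$origin[1]
  off[, 2] <- off[, 2] - se$origin[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    for (k in seq_len(nrow(off))) {
      # reflected SE placed at (i, j) hits the input
      ii <- i - off[k, 1]; jj <- j - off[k, 2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w && mask[ii, jj]) {
        out[i, j] <- TRUE
        break
      }
    }
  }
  out
}

# brute-force erosion: TRUE iff the SE placed at the pixel fits inside the
# input (outside the image counts as background)
brute_erode <- function(mask, se) {
  h <- nrow(mask); w <- ncol(mask)
  off <- which(se$footprint, arr.ind = TRUE)
  off[, 1] <- off[, 1] - se$origin[1]
  off[, 2] <- off[, 2] - se$origin[2]
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    fits <- TRUE
    for (k in seq_len(nrow(off))) {
      ii <- i + off[k, 1]; jj <- j + off[k, 2]
      if (ii < 1 || ii > h || jj < 1 || jj > w || !mask[ii, jj]) {
        fits <- FALSE
        break
      }
    }
    out[i, j] <- fits
  }
  out
}

random_mask <- function(h, w, p = 0.4) matrix(runif(h * w) < p, h, w)

random_se <- function() {
  if (runif(1) < 0.5) {
    se_disk(sample(1:3, 1))
  } else if (runif(1) < 0.5) {
    se_square(sample(2:5, 1))
  } else {
    f <- matrix(runif(9) < 0.6, 3, 3)
    f[2, 2] <- TRUE
    structuring_element(f)
  }
}

# independent reference for the early-stopping rule
ref_stop <- function(dsc, patience = 10L, min_gain = 0.001) {
  best <- dsc[1]; best_e <- 1L
  for (e in seq_along(dsc)) {
    if (dsc[e] > best * (1 + min_gain)) { best <- dsc[e]; best_e <- e }
    if (e - best_e >= patience) return(c(stop = e, best = best_e))
  }
  c(stop = length(dsc), best = best_e)
}

# AUC by trapezoidal integration of the empirical ROC curve
trapezoid_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  tpr <- c(0, tpr, 1); fpr <- c(0, fpr, 1)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# textbook Pearson chi-square: sum (O - E)^2 / E
chisq_by_hand <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# cohort rows reproducing the printed two-group clinicopathological table
# counts (98 LNM-negative / 66 LNM-positive; per-level flag and stage counts)
printed_table1_cohort <- function() {
  expand_counts <- function(neg, pos, levels) {
    data.frame(
      lnm = rep(c(FALSE, TRUE), c(sum(neg), sum(pos))),
      value = c(rep(levels, neg), rep(levels, pos)),
      stringsAsFactors = FALSE)
  }
  li <- expand_counts(c(11, 79, 8), c(42, 22, 2), c("yes", "no", NA))
  vi <- expand_counts(c(13, 76, 9), c(25, 37, 4), c("yes", "no", NA))
  pi_ <- expand_counts(c(12, 58, 28), c(13, 32, 21), c("yes", "no", NA))
  anyi <- expand_counts(c(23, 68, 7), c(45, 20, 1), c("yes", "no", NA))
  tst <- expand_counts(c(1, 4, 25, 63, 5), c(0, 1, 2, 53, 10),
                       c("T0", "T1", "T2", "T3", "T4"))
  sex <- expand_counts(c(48, 50), c(30, 36), c("M", "F"))
  nst <- expand_counts(c(98, 0, 0), c(0, 46, 20), c("N0", "N1", "N2"))
  data.frame(patient_id = sprintf("P%03d", seq_len(164)),
             age = ifelse(tst$lnm, 61.8, 66.8) + rep_len(c(-1, 1), 164),
             sex = sex$value, t_stage = tst$value, n_stage = nst$value,
             lnm = tst$lnm, li = li$value, pi = pi_$value, vi = vi$value,
             anyi = anyi$value,
             pts_score = ifelse(tst$lnm, 0.380, 0.228) +
               rep_len(c(-0.05, 0.05), 164),
             stringsAsFactors = FALSE)
}
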
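## Cohort statistics: exclusion ledger, descriptive table by LNM group,
## univariate logistic odds ratios with Wald intervals, rank-sum ROC AUC with
## DeLong intervals, and the T-stage subgroup report.

#' Apply the slide-exclusion rules in order
#'
#' Records are removed sequentially — rectal cancer, then inadequate image,
#' then distant metastasis — and each record is attributed to the first rule
#' that matches it, so the ledger counts sum exactly to the number removed.
#'
#' @param records Data frame with logical columns `rectal`,
#'   `inadequate_image`, `distant_metastasis`.
#' @return Object of class `exclusion_ledger`: list with `cohort` (the
#'   retained rows), `ledger` (named integer vector of removals per rule),
#'   `n_input`, `n_output`.
#' @export
apply_exclusions <- function(records) {
  rules <- c("rectal", "inadequate_image", "distant_metastasis")
  missing_cols <- setdiff(rules, names(records))
  if (length(missing_cols))
    stop("records lack exclusion flag columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, nrow(records))
  ledger <- stats::setNames(integer(length(rules)), rules)
  for (r in rules) {
    hit <- keep & records[[r]] %in% TRUE
    ledger[r] <- sum(hit)
    keep <- keep & !hit
  }
  structure(list(cohort = records[keep, , drop = FALSE],
                 ledger = ledger,
                 n_input = nrow(records), n_output = sum(keep)),
            class = "exclusion_ledger")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat(sprintf("Exclusion ledger: %d records in, %d retained\n",
              x$n_input, x$n_output))
  for (r in names(x$ledger))
    cat(sprintf("  - %-20s %d removed\n", r, x$ledger[r]))
  invisible(x)
}

#' Derive the AnyI (any invasion) flag
#'
#' "yes" if any of the lymphatic/perineural/venous flags is "yes"; `NA` if
#' none is "yes" but at least one is missing (absence cannot be asserted from
#' incomplete data); "no" otherwise. Vectorized.
#'
#' @param li,pi,vi Character vectors with values "yes", "no" or `NA`.
#' @return Character vector of the same length.
#' @export
derive_anyi <- function(li, pi, vi) {
  m <- cbind(li, pi, vi)
  any_yes <- rowSums(m == "yes", na.rm = TRUE) > 0
  any_na <- rowSums(is.na(m)) > 0
  ifelse(any_yes, "yes", ifelse(any_na, NA, "no"))
}

# two-group continuous summary: mean (SD) per group + pooled-variance t-test
desc_continuous <- function(x, grp) {
  out <- data.frame(
    level = "mean (SD)",
    neg = sprintf("%.1f (%.1f)", mean(x[!grp], na.rm = TRUE),
                  stats::sd(x[!grp], na.rm = TRUE)),
    pos = sprintf("%.1f (%.1f)", mean(x[grp], na.rm = TRUE),
                  stats::sd(x[grp], na.rm = TRUE)))
  p <- tryCatch({
    if (stats::var(x[!grp], na.rm = TRUE) == 0 &&
        stats::var(x[grp], na.rm = TRUE) == 0) {
      warning("zero-variance input to t-test; p reported as NA", call. = FALSE)
      NA_real_
    } else stats::t.test(x[grp], x[!grp], var.equal = TRUE)$p.value
  }, error = function(e) NA_real_)
  list(rows = out, p = p)
}

# categorical summary: n (%) per level incl. an NA row; chi-square excludes NA
desc_categorical <- function(x, grp, levels = NULL) {
  if (is.null(levels)) levels <- sort(unique(x[!is.na(x)]))
  xf <- factor(x, levels = levels)
  rows <- lapply(c(levels, if (anyNA(x)) "NA"), function(lv) {
    sel <- if (identical(lv, "NA")) is.na(xf) else !is.na(xf) & xf == lv
    data.frame(level = lv,
               neg = sprintf("%d (%.1f)", sum(sel & !grp),
                             100 * sum(sel & !grp) / sum(!grp)),
               pos = sprintf("%d (%.1f)", sum(sel & grp),
                             100 * sum(sel & grp) / sum(grp)))
  })
  ok <- !is.na(xf)
  tab <- table(xf[ok], grp[ok])
  p <- if (nrow(tab) > 1 && all(dim(tab) >= 1))
    tryCatch(suppressWarnings(
      stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) NA_real_)
  else NA_real_
  list(rows = do.call(rbind, rows), p = p)
}

#' Descriptive cohort table by LNM group
#'
#' Reproduces the structure of a two-group clinicopathological table: group
#' sizes and shares, mean (SD) with pooled-variance Student's t-test for age
#' and PTS score, and n (%) with Pearson chi-square (no continuity
#' correction) for the categorical variables. Percentages are computed within
#' group over the total group size; missing flags are shown as their own
#' "NA" category but excluded from the tests.
#'
#' @param cohort Data frame as from [make_cohort()] (columns `lnm`, `age`,
#'   `sex`, `t_stage`, `n_stage`, `li`, `pi`, `vi`, `anyi`, `pts_score`).
#' @return Object of class `cohort_table1`: list of per-variable entries,
#'   each with `rows` (level, neg, pos strings) and `p`.
#' @export
table1_descriptives <- function(cohort) {
  grp <- cohort$lnm
  if (!any(grp) || !any(!grp))
    stop("both LNM groups must be nonempty", call. = FALSE)
  out <- list(
    group_sizes = list(
      n = c(neg = sum(!grp), pos = sum(grp)),
      pct = c(neg = 100 * sum(!grp) / length(grp),
              pos = 100 * sum(grp) / length(grp))),
    age = desc_continuous(cohort$age, grp),
    sex = desc_categorical(cohort$sex, grp, c("M", "F")),
    t_stage = desc_categorical(cohort$t_stage, grp,
                               c("T0", "T1", "T2", "T3", "T4")),
    n_stage = desc_categorical(cohort$n_stage, grp, c("N0", "N1", "N2")),
    li = desc_categorical(cohort$li, grp, c("yes", "no")),
    pi = desc_categorical(cohort$pi, grp, c("yes", "no")),
    vi = desc_categorical(cohort$vi, grp, c("yes", "no")),
    anyi = desc_categorical(cohort$anyi, grp, c("yes", "no")),
    pts_score = desc_continuous(cohort$pts_score, grp))
  class(out) <- "cohort_table1"
  out
}

#' @export
print.cohort_table1 <- function(x, ...) {
  cat(sprintf("Cohort by LNM group: negative n=%d (%.1f%%), positive n=%d (%.1f%%)\n",
              x$group_sizes$n["neg"], x$group_sizes$pct["neg"],
              x$group_sizes$n["pos"], x$group_sizes$pct["pos"]))
  for (v in setdiff(names(x), "group_sizes")) {
    cat(sprintf("%s (p = %s)\n", v,
                ifelse(is.na(x[[v]]$p), "NA", format.pval(x[[v]]$p, digits = 3))))
    print(x[[v]]$rows, row.names = FALSE)
  }
  invisible(x)
}

#' Univariate logistic regression
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 x` (via
#' `glm(binomial)`), reported as the odds ratio per unit of `x` with Wald
#' 95% CI `exp(b1 +/- 1.96 SE)` and Wald z p-value. Pairs with missing values
#' are dropped listwise. Complete or quasi-complete separation is flagged
#' (`separation = TRUE`, with a warning) rather than silently returning a
#' huge OR.
#'
#' @param x Numeric predictor (a binary predictor may be given as logical or
#'   0/1).
#' @param y Binary outcome (logical or 0/1).
#' @return Object of class `logistic_result`: list with `coef`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`, `n`, `separation`.
#' @export
logistic_univariate <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(unique(y)) < 2)
    stop("both outcome levels must be present", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("predictor is constant; odds ratio undefined", call. = FALSE)
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  b <- co["x", "Estimate"]; se <- co["x", "Std. Error"]
  separation <- !fit$converged || abs(b) > 15 || se > 100
  if (separation)
    warning("possible complete separation: Wald interval unbounded in practice",
            call. = FALSE)
  structure(list(coef = b, se = se, or = exp(b),
                 ci_lower = exp(b - 1.96 * se),
                 ci_upper = exp(b + 1.96 * se),
                 p_value = co["x", "Pr(>|z|)"],
                 n = length(y), separation = separation),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("univariate logistic fit (n = %d)%s\n", x$n,
              if (x$separation) " [separation flagged]" else ""))
  cat(sprintf("  OR %.3f (95%% CI %.3f-%.3f), p = %s\n",
              x$or, x$ci_lower, x$ci_upper,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' ROC AUC by the rank-sum identity, with DeLong interval
#'
#' AUC is computed through the Mann-Whitney identity with midrank tie
#' handling: the mean placement of positive scores among negatives. The 95%
#' CI uses the DeLong variance (empirical variance of the per-observation
#' placement values), truncated to `[0, 1]`.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary outcome (logical or 0/1).
#' @return Object of class `roc_result`: list with `auc`, `ci_lower`,
#'   `ci_upper`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.logical(labels[ok])
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both outcome levels must be present", call. = FALSE)
  r <- rank(scores)  # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong: placement of each positive among negatives and vice versa
  rpos <- rank(scores[labels])
  rneg <- rank(scores[!labels])
  v10 <- (r[labels] - rpos) / n0          # P(neg < pos_i) with midrank ties
  v01 <- 1 - (r[!labels] - rneg) / n1     # P(pos > neg_j)
  va <- stats::var(v10) / n1 + stats::var(v01) / n0
  half <- 1.96 * sqrt(va)
  structure(list(auc = auc,
                 ci_lower = max(0, auc - half),
                 ci_upper = min(1, auc + half),
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC AUC %.3f (95%% CI %.3f-%.3f); %d positive / %d negative\n",
              x$auc, x$ci_lower, x$ci_upper, x$n_pos, x$n_neg))
  invisible(x)
}

#' PTS-score association report (outcome-wise univariate fits)
#'
#' For each outcome — LNM and the invasion flags — reports the group
#' mean (SD) of the PTS score, a pooled-variance t-test p, and the univariate
#' logistic OR of the outcome on the PTS score with Wald CI.
#'
#' @param cohort Data frame as from [make_cohort()].
#' @param outcomes Character vector of outcome columns (default `lnm`, `li`,
#'   `pi`, `vi`, `anyi`).
#' @return Data frame with one row per outcome (class `pts_association`).
#' @export
pts_association <- function(cohort,
                            outcomes = c("lnm", "li", "pi", "vi", "anyi")) {
  rows <- lapply(outcomes, function(oc) {
    y <- cohort[[oc]]
    if (!is.logical(y)) y <- ifelse(is.na(y), NA, y == "yes")
    ok <- !is.na(y) & !is.na(cohort$pts_score)
    yy <- y[ok]; s <- cohort$pts_score[ok]
    base <- data.frame(outcome = oc,
                       mean_neg = mean(s[!yy]), sd_neg = stats::sd(s[!yy]),
                       mean_pos = mean(s[yy]), sd_pos = stats::sd(s[yy]))
    fit <- tryCatch(logistic_univariate(s, yy), error = function(e) NULL)
    tt <- tryCatch(stats::t.test(s[yy], s[!yy], var.equal = TRUE)$p.value,
                   error = function(e) NA_real_)
    if (is.null(fit)) {
      cbind(base, t_p = tt, or = NA, ci_lower = NA, ci_upper = NA,
            p_value = NA, n = sum(ok))
    } else {
      cbind(base, t_p = tt, or = fit$or, ci_lower = fit$ci_lower,
            ci_upper = fit$ci_upper, p_value = fit$p_value, n = fit$n)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pts_association", "data.frame")
  out
}

#' T-stage subgroup analysis
#'
#' Splits the cohort into early (T0-T2) and late (T3-T4) strata and runs the
#' PTS-score association for each invasion outcome within each stratum.
#' Strata cells with fewer than 2 events (or 2 non-events) are reported as
#' `NA` rows rather than fitted.
#'
#' @param cohort Data frame as from [make_cohort()].
#' @param outcomes Outcome columns (default the invasion flags).
#' @return Data frame with columns `stratum`, `outcome`, group means/SDs,
#'   `or`, `ci_lower`, `ci_upper`, `p_value`, `n` (class `tstage_subgroups`).
#' @export
subgroup_by_tstage <- function(cohort,
                               outcomes = c("li", "pi", "vi", "anyi")) {
  strata <- list(`T0-T2` = cohort$t_stage %in% c("T0", "T1", "T2"),
                 `T3-T4` = cohort$t_stage %in% c("T3", "T4"))
  rows <- lapply(names(strata), function(snm) {
    sub <- cohort[strata[[snm]], , drop = FALSE]
    res <- lapply(outcomes, function(oc) {
      y <- sub[[oc]]
      if (!is.logical(y)) y <- ifelse(is.na(y), NA, y == "yes")
      ok <- !is.na(y) & !is.na(sub$pts_score)
      yy <- y[ok]; s <- sub$pts_score[ok]
      na_row <- data.frame(stratum = snm, outcome = oc,
                           mean_neg = NA_real_, sd_neg = NA_real_,
                           mean_pos = NA_real_, sd_pos = NA_real_,
                           or = NA_real_, ci_lower = NA_real_,
                           ci_upper = NA_real_, p_value = NA_real_,
                           n = sum(ok))
      if (sum(yy) < 2 || sum(!yy) < 2) return(na_row)
      fit <- tryCatch(suppressWarnings(logistic_univariate(s, yy)),
                      error = function(e) NULL)
      if (is.null(fit)) return(na_row)
      data.frame(stratum = snm, outcome = oc,
                 mean_neg = mean(s[!yy]), sd_neg = stats::sd(s[!yy]),
                 mean_pos = mean(s[yy]), sd_pos = stats::sd(s[yy]),
                 or = fit$or, ci_lower = fit$ci_lower,
                 ci_upper = fit$ci_upper, p_value = fit$p_value, n = fit$n)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tstage_subgroups", "data.frame")
  out
}
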
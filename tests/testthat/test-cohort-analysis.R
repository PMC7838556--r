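test_that("exclusion ledger applies rules in order with first-match attribution", {
  # the published workflow counts: 591 collected, 153 rectal, 210 inadequate,
  # 64 metastatic -> 164 analyzed
  rec <- data.frame(patient_id = sprintf("P%03d", 1:591),
                    rectal = rep(c(TRUE, FALSE), c(153, 438)),
                    inadequate_image = rep(c(FALSE, TRUE, FALSE),
                                           c(153, 210, 228)),
                    distant_metastasis = rep(c(FALSE, TRUE, FALSE),
                                             c(363, 64, 164)))
  led <- apply_exclusions(rec)
  expect_equal(unname(led$ledger),
               c(153L, 210L, 64L))
  expect_equal(led$n_output, 164)
  expect_equal(led$n_input - sum(led$ledger), led$n_output)

  # no flags: everything passes
  rec0 <- rec; rec0$rectal <- rec0$inadequate_image <- rec0$distant_metastasis <- FALSE
  led0 <- apply_exclusions(rec0)
  expect_equal(led0$n_output, 591)
  expect_true(all(led0$ledger == 0))

  # doubly-flagged records attribute to the first matching rule only
  rec2 <- data.frame(rectal = c(TRUE, FALSE), inadequate_image = FALSE,
                     distant_metastasis = c(TRUE, TRUE))
  led2 <- apply_exclusions(rec2)
  expect_equal(unname(led2$ledger), c(1L, 0L, 1L))
  expect_error(apply_exclusions(data.frame(x = 1)), "exclusion flag")
})

test_that("AnyI derivation follows the yes/NA/no rule", {
  expect_equal(derive_anyi("yes", NA, "no"), "yes")
  expect_equal(derive_anyi("no", "no", "no"), "no")
  expect_true(is.na(derive_anyi("no", NA, "no")))
  expect_equal(derive_anyi(c("yes", "no", NA), c("no", "no", NA),
                           c("no", "no", NA)),
               c("yes", "no", NA))
})

test_that("descriptive table reproduces the printed group percentages", {
  co <- printed_table1_cohort()
  tab <- table1_descriptives(co)
  expect_equal(round(tab$group_sizes$pct[["neg"]], 1), 59.8)
  expect_equal(round(tab$group_sizes$pct[["pos"]], 1), 40.2)
  # LI yes among LNM-positive: 42/66 = 63.6%
  expect_equal(tab$li$rows$pos[tab$li$rows$level == "yes"], "42 (63.6)")
  # VI yes among LNM-positive: 25/66 = 37.9%
  expect_equal(tab$vi$rows$pos[tab$vi$rows$level == "yes"], "25 (37.9)")
  # T3 / T4 among LNM-positive: 80.3% / 15.2%
  expect_equal(tab$t_stage$rows$pos[tab$t_stage$rows$level == "T3"],
               "53 (80.3)")
  expect_equal(tab$t_stage$rows$pos[tab$t_stage$rows$level == "T4"],
               "10 (15.2)")
  # NA rows displayed
  expect_true("NA" %in% tab$li$rows$level)
})

test_that("chi-square matches the textbook formula on the printed LI table", {
  co <- printed_table1_cohort()
  tab <- table1_descriptives(co)
  # observed 2x2 (rows yes/no, cols LNM-negative/positive), NA excluded
  obs <- matrix(c(11, 79, 42, 22), 2, 2)
  stat <- chisq_by_hand(obs)
  p_hand <- pchisq(stat, df = 1, lower.tail = FALSE)
  expect_equal(tab$li$p, p_hand, tolerance = 1e-12)
})

test_that("zero-variance t-test input reports NA with a warning", {
  co <- printed_table1_cohort()
  co$age <- 50  # constant in both groups
  expect_warning(tab <- table1_descriptives(co), "zero-variance")
  expect_true(is.na(tab$age$p))
})

test_that("binary-predictor logistic OR equals the cross-product ratio", {
  # LI (yes/no) vs LNM from the printed counts: 42,22 / 11,79
  x <- rep(c(1, 0, 1, 0), c(42, 22, 11, 79))
  y <- rep(c(1, 1, 0, 0), c(42, 22, 11, 79))
  fit <- logistic_univariate(x, y)
  or_hand <- (42 * 79) / (22 * 11)
  expect_equal(signif(fit$or, 4), signif(or_hand, 4))
  expect_equal(fit$n, 154)
  expect_false(fit$separation)
  # Wald interval brackets the estimate
  expect_lt(fit$ci_lower, fit$or)
  expect_gt(fit$ci_upper, fit$or)
})

test_that("logistic degenerate inputs are flagged or rejected", {
  expect_error(logistic_univariate(rep(1, 10), rep(c(0, 1), 5)),
               "constant")
  expect_error(logistic_univariate(1:10, rep(1, 10)), "both outcome levels")
  # complete separation is flagged, not silently reported
  x <- c(1:10, 11:20); y <- rep(c(0, 1), each = 10)
  expect_warning(fit <- logistic_univariate(x, y), "separation")
  expect_true(fit$separation)
})

test_that("Wald CIs cover the true slope at the nominal rate", {
  spec <- cohort_spec(n = 2000L, beta0 = -1.5, beta1 = 3.0)
  hits <- 0; est <- numeric(100)
  for (r in 1:100) {
    co <- make_cohort(spec, seed = 5000 + r)
    fit <- logistic_univariate(co$pts_score, co$lnm)
    hits <- hits + (fit$coef - 1.96 * fit$se <= 3 &&
                      3 <= fit$coef + 1.96 * fit$se)
    est[r] <- fit$coef
  }
  expect_gte(hits / 100, 0.90)
  expect_lte(hits / 100, 0.99)
  expect_lt(abs(mean(est) - 3.0), 0.15)
})

test_that("rank-sum AUC has the right limits, symmetries and ties handling", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1)
  set.seed(31)
  s <- rnorm(4000); l <- rbinom(4000, 1, 0.5)  # independent: null
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.03)
  # label flip: AUC -> 1 - AUC
  r <- roc_auc(s, l)
  expect_equal(roc_auc(s, 1 - l)$auc, 1 - r$auc)
  # invariant under monotone transform
  expect_equal(roc_auc(exp(s), l)$auc, r$auc)
  # agreement with trapezoidal integration, including tied scores
  for (i in 1:100) {
    n <- sample(20:60, 1)
    sc <- sample(1:8, n, TRUE)  # heavy ties
    lb <- rbinom(n, 1, 0.5)
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, trapezoid_auc(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep(1, 5)), "both outcome levels")
})

test_that("DeLong interval agrees with the reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (r in 1:5) {
    n <- 150
    lb <- rbinom(n, 1, 0.4)
    sc <- rnorm(n, mean = lb)
    ours <- roc_auc(sc, lb)
    ref <- pROC::ci.auc(pROC::roc(lb, sc, quiet = TRUE), method = "delong")
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-12)
    expect_equal(ours$ci_lower, as.numeric(ref[1]), tolerance = 0.002)
    expect_equal(ours$ci_upper, as.numeric(ref[3]), tolerance = 0.002)
  }
})

test_that("PTS association table fits every outcome", {
  co <- make_cohort(cohort_spec(n = 800L), seed = 13)
  assoc <- pts_association(co)
  expect_equal(assoc$outcome, c("lnm", "li", "pi", "vi", "anyi"))
  lnm_row <- assoc[assoc$outcome == "lnm", ]
  expect_gt(lnm_row$or, 1)  # generator encodes a strong positive effect
  expect_true(all(assoc$ci_lower <= assoc$or & assoc$or <= assoc$ci_upper,
                  na.rm = TRUE))
})

test_that("T-stage subgroups partition the cohort and handle degenerate strata", {
  co <- make_cohort(cohort_spec(n = 400L), seed = 17)
  sub <- subgroup_by_tstage(co)
  expect_setequal(unique(sub$stratum), c("T0-T2", "T3-T4"))
  early <- co$t_stage %in% c("T0", "T1", "T2")
  expect_equal(sum(early) + sum(!early), nrow(co))

  # all records T3: the early stratum is reported as NA rows
  co3 <- co; co3$t_stage <- "T3"
  sub3 <- subgroup_by_tstage(co3)
  expect_true(all(is.na(sub3$or[sub3$stratum == "T0-T2"])))
  expect_true(any(!is.na(sub3$or[sub3$stratum == "T3-T4"])))
})

test_that("an effect confined to late T stages is detected only there", {
  set.seed(19)
  n <- 2000
  t_stage <- sample(c("T1", "T2", "T3", "T4"), n, TRUE)
  late <- t_stage %in% c("T3", "T4")
  pts <- rbeta(n, 1.6, 2.6)
  p_li <- plogis(-1.5 + ifelse(late, 3.0, 0) * pts)
  li <- ifelse(runif(n) < p_li, "yes", "no")
  co <- data.frame(patient_id = as.character(1:n), t_stage = t_stage,
                   li = li, pi = "no", vi = "no", anyi = li,
                   pts_score = pts, stringsAsFactors = FALSE)
  sub <- subgroup_by_tstage(co, outcomes = "li")
  late_row <- sub[sub$stratum == "T3-T4", ]
  early_row <- sub[sub$stratum == "T0-T2", ]
  expect_lt(late_row$p_value, 0.05)
  expect_gt(late_row$ci_lower, 1)
  expect_gt(early_row$p_value, 0.05)
  expect_lt(early_row$ci_lower, 1)
  expect_gt(early_row$ci_upper, 1)
})
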
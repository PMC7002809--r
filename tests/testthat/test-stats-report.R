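test_that("Kruskal-Wallis H matches the rank formula and permutation null", {
  kw <- kruskal_wallis(c(1, 2, 3), c(4, 5, 6))
  expect_equal(kw$statistic, 12 / 42 * (3 * 2.25 + 3 * 2.25) * 2 / 2,
               tolerance = 1e-6)
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kw$p_value, 0.0495, tolerance = 1e-3)

  tied <- kruskal_wallis(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$statistic, 0)
  expect_equal(tied$p_value, 1)

  set.seed(23)
  for (rep in 1:10) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
    x <- round(stats::rnorm(n1, 0, 2), 1)
    y <- round(stats::rnorm(n2, 1, 2), 1)
    kw <- kruskal_wallis(x, y)
    expect_equal(kw$statistic, oracle_kw_h(x, y), tolerance = 1e-10)
    # the chi-square p is an approximation at n = 6..8; its gap to the
    # exact permutation p stays below 0.25 (worst observed ~0.19)
    expect_lt(abs(kw$p_value - oracle_kw_perm_p(x, y)), 0.25)
  }
  expect_error(kruskal_wallis(numeric(0), 1:3), "at least 2")
})

test_that("Bonferroni flags use the family-size-corrected threshold", {
  expect_identical(bonferroni_flags(c(0.001, 0.04)), c(TRUE, FALSE))
  expect_identical(bonferroni_flags(0.04, m = 1), TRUE)
  expect_identical(bonferroni_flags(rep(1, 5)), rep(FALSE, 5))
  expect_identical(bonferroni_flags(numeric(0)), logical(0))
  expect_error(bonferroni_flags(c(0.2, 1.7)), "0, 1")
})

test_that("AUC equals the pairwise count and respects symmetries", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(2, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  set.seed(31)
  for (rep in 1:15) {
    n <- 20
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(pos) || all(pos)) next
    s <- sample(round(stats::rnorm(n, pos, 1.5), 1))
    a <- roc_auc(s, pos)
    expect_identical(a, oracle_auc(s, pos))
    # complement symmetry: negate scores and swap labels
    expect_equal(roc_auc(-s, !pos), a, tolerance = 1e-12)
  }
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("AUC agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(37)
  pos <- c(rep(TRUE, 12), rep(FALSE, 20))
  s <- round(stats::rnorm(32, pos, 1), 1)
  ref <- as.numeric(pROC::auc(pROC::roc(pos, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, pos), ref, tolerance = 1e-12)
})

test_that("Youden cutoff maximises J over every threshold", {
  r <- youden_cutoff(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(r$cutoff, 3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)

  deg <- youden_cutoff(rep(5, 6), rep(c(TRUE, FALSE), 3))
  expect_true(deg$degenerate)
  expect_equal(deg$youden_j, 0)

  set.seed(41)
  for (rep in 1:15) {
    n <- 30
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(1 / 3, 2 / 3))
    if (sum(pos) < 1 || sum(!pos) < 1) next
    s <- round(stats::rnorm(n, pos, 1.2), 1)
    r <- youden_cutoff(s, pos)
    expect_equal(r$youden_j, oracle_best_youden(s, pos), tolerance = 1e-12)
    # internal consistency of the confusion ratios
    ct <- r$counts
    expect_equal(r$sensitivity, ct[["tp"]] / (ct[["tp"]] + ct[["fn"]]))
    expect_equal(r$specificity, ct[["tn"]] / (ct[["tn"]] + ct[["fp"]]))
    expect_equal(r$accuracy, (ct[["tp"]] + ct[["tn"]]) / sum(ct))
  }
})

test_that("diagnostic metrics reproduce hand-checked confusion matrices", {
  m <- diagnostic_metrics(tp = 14, fp = 4, tn = 26, fn = 1)
  expect_equal(unname(m$rounded[c("sensitivity", "specificity", "ppv",
                                  "npv", "accuracy")]),
               c(0.93, 0.87, 0.78, 0.96, 0.89))

  deg <- diagnostic_metrics(tp = 0, fp = 0, tn = 30, fn = 15)
  expect_equal(deg$sensitivity, 0)
  expect_equal(deg$specificity, 1)
  expect_equal(deg$accuracy, 30 / 45)
  expect_true(is.na(deg$ppv))

  perfect <- diagnostic_metrics(tp = 15, fp = 0, tn = 30, fn = 0)
  expect_equal(unname(unlist(perfect[c("sensitivity", "specificity", "ppv",
                                       "npv", "accuracy")])), rep(1, 5))
  expect_error(diagnostic_metrics(0, 0, 0, 5), "invalid")
})

test_that("cohort tables are built with a strong effect favouring SIS", {
  # complementary moderate kinetic signals: their weighted SIS combination
  # separates the groups better than either alone
  set.seed(47)
  n1 <- 20; n0 <- 40
  lab <- c(rep("pCR", n1), rep("non-pCR", n0))
  tab <- data.frame(
    glcm_entropy = stats::rnorm(60, ifelse(lab == "pCR", 3, 0), 4),
    msd = stats::rnorm(60, ifelse(lab == "pCR", 40, 0), 30),
    wos = stats::rnorm(60, ifelse(lab == "pCR", 50, 0), 35))
  tab$sis <- compute_sis(tab$msd, tab$wos)
  out <- build_tables(tab, lab)
  expect_equal(nrow(out$diagnostics), 4)
  expect_equal(out$diagnostics$feature[1], "glcm_entropy")  # texture first
  best <- out$diagnostics$feature[which.max(out$diagnostics$roc_auc)]
  expect_identical(best, "sis")
  # group summary medians carry the configured direction
  gs <- out$group_summary
  expect_true(all(gs$pcr.median > gs$nonpcr.median))

  one <- build_tables(tab[, "sis", drop = FALSE], lab)
  expect_equal(nrow(one$diagnostics), 1)
  expect_error(build_tables(tab, c(rep("pCR", 1), rep("non-pCR", 29))),
               "at least 2")
})

test_that("label permutation calibrates the report to the null", {
  set.seed(53)
  n <- 45
  lab <- c(rep("pCR", 15), rep("non-pCR", 30))
  feats <- paste0("f", 1:10)
  tab <- as.data.frame(stats::setNames(
    lapply(feats, function(f) stats::rnorm(n, 10, 5)), feats))
  n_sig <- 0
  aucs <- matrix(NA_real_, 100, length(feats))
  for (perm in 1:100) {
    pl <- sample(lab)
    out <- build_tables(tab, pl)
    n_sig <- n_sig + any(out$group_summary$bonferroni_significant)
    aucs[perm, ] <- out$diagnostics$roc_auc
  }
  expect_lte(n_sig, 10)  # FWER controlled at 5%, binomial slack to 10/100
  expect_true(all(colMeans(aucs) > 0.4 & colMeans(aucs) < 0.6))
})
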
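## Synthetic metadata tables are enough for split logic: no signals needed.
fake_metadata <- function(n_healthy, n_patient, n_lat = 0) {
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n_healthy + n_patient + n_lat)),
    group = c(rep("healthy", n_healthy), rep("patient", n_patient + n_lat)),
    handedness = "right",
    seizure_hemisphere = c(rep("none", n_healthy + n_patient),
                           rep(c("left", "right"), length.out = n_lat)),
    age_years = 30, medications = "",
    stringsAsFactors = FALSE
  )
}

test_that("splits are disjoint, deterministic and class-balanced", {
  md <- fake_metadata(144, 48)
  s1 <- make_splits(md, n_reps = 10, n_train_ref = 96, seed = 3)
  s2 <- make_splits(md, n_reps = 10, n_train_ref = 96, seed = 3)
  expect_identical(s1, s2)
  expect_length(s1, 10)
  for (sp in s1) {
    expect_length(sp$train_reference_ids, 96)
    expect_length(sp$test_ids, 96)            # 48 healthy + 48 patients
    expect_equal(sum(sp$test_labels), 48)
    expect_length(intersect(sp$train_reference_ids, sp$test_ids), 0)
  }
  ## different repetitions draw different reference samples
  expect_false(identical(sort(s1[[1]]$train_reference_ids),
                         sort(s1[[2]]$train_reference_ids)))
  expect_error(make_splits(fake_metadata(10, 5), n_train_ref = 96),
               "insufficient")
})

test_that("ROC/AUC agree with the pairwise Mann-Whitney oracle", {
  ## lower score => positive
  r <- roc_and_auc(c(0.1, 0.2), c(TRUE, FALSE))
  expect_equal(r$auc, 1)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(tail(r$points$tpr, 1), 1)
  expect_equal(roc_and_auc(rep(0.5, 10), rep(c(TRUE, FALSE), 5))$auc, 0.5)
  expect_error(roc_and_auc(1:3, c(TRUE, TRUE, TRUE)), "class")
  ## O(n^2) oracle: P(score_pos < score_neg) + 0.5 P(tie)
  auc_oracle <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
    mean(cmp)
  }
  set.seed(11)
  for (i in 1:100) {
    n <- sample(4:40, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # induce ties sometimes
    r <- roc_and_auc(scores, labels)
    expect_equal(r$auc, auc_oracle(scores, labels), tolerance = 1e-12)
    ## curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
    ## orientation coherence: negating scores and swapping classes
    expect_equal(roc_and_auc(-scores, !labels)$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("the convex-hull threshold maximizes TPR - FPR over the hull", {
  ## perfect classifier: the selected threshold attains (0, 1)
  r <- roc_and_auc(c(0.1, 0.15, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE))
  thr <- convex_hull_threshold(r)
  expect_equal(prf_metrics(c(0.1, 0.15, 0.8, 0.9),
                           c(TRUE, TRUE, FALSE, FALSE), thr)$recall, 100)
  expect_equal(thr, 0.15)
  ## useless scores: every hull vertex has TPR - FPR = 0
  ru <- roc_and_auc(rep(0.4, 6), rep(c(TRUE, FALSE), 3))
  thr_u <- convex_hull_threshold(ru)
  pt <- ru$points[ru$points$threshold == thr_u, ]
  expect_equal(pt$tpr - pt$fpr, 0)
  ## random small curves: selected vertex attains the global maximum of
  ## tpr - fpr and lies on the exhaustively-computed upper hull
  on_upper_hull <- function(pts, i) {
    for (a in seq_len(nrow(pts))) for (b in seq_len(nrow(pts))) {
      if (pts$fpr[a] < pts$fpr[i] && pts$fpr[i] < pts$fpr[b]) {
        lam <- (pts$fpr[i] - pts$fpr[a]) / (pts$fpr[b] - pts$fpr[a])
        y <- pts$tpr[a] + lam * (pts$tpr[b] - pts$tpr[a])
        if (pts$tpr[i] < y - 1e-12) return(FALSE)
      }
    }
    TRUE
  }
  set.seed(12)
  for (i in 1:30) {
    n <- sample(4:6, 1)
    scores <- round(runif(n), 2)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    r <- roc_and_auc(scores, labels)
    thr <- convex_hull_threshold(r)
    pts <- r$points
    sel <- which(pts$threshold == thr)
    expect_equal(pts$tpr[sel] - pts$fpr[sel], max(pts$tpr - pts$fpr),
                 tolerance = 1e-12)
    expect_true(on_upper_hull(pts, sel))
  }
})

test_that("precision/recall/F1 match hand-computed confusion matrices", {
  p <- prf_metrics(c(0.1, 0.2, 0.8, 0.9), c(TRUE, TRUE, FALSE, FALSE), 0.2)
  expect_equal(unlist(p), c(precision = 100, recall = 100, f1 = 100))
  ## all predicted positive, half truly positive
  p2 <- prf_metrics(c(0.1, 0.2, 0.3, 0.4), c(TRUE, FALSE, TRUE, FALSE), 1)
  expect_equal(p2$precision, 50)
  expect_equal(p2$recall, 100)
  expect_equal(p2$f1, 200 / 3, tolerance = 1e-12)
  ## fixture: scores below 0.35 predicted positive -> TP=2 FP=1 FN=2
  sc <- c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7)
  lb <- c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)
  p3 <- prf_metrics(sc, lb, 0.35)
  expect_equal(p3$precision, 100 * 2 / 3)
  expect_equal(p3$recall, 100 * 2 / 4)
  expect_equal(p3$f1, 2 * p3$precision * p3$recall / (p3$precision + p3$recall))
  expect_warning(p4 <- prf_metrics(sc, lb, 0), "zero predicted")
  expect_true(is.nan(p4$precision))
})

test_that("rank-sum test matches enumeration, wilcox.test and the normal limit", {
  ## identical multisets: exact p = 1 (even with ties)
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  ## {1,2,3} vs {4,5,6}: 2 of the 20 rank assignments are as extreme
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 6)
  expect_equal(r$p_value, 0.1)
  ## tie-free exact p equals wilcox.test's exact p
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(3:6, 1)); b <- rnorm(sample(3:6, 1))
    expect_equal(rank_sum_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-9)
  }
  ## normal approximation within 5% relative of the exact distribution at
  ## n = 12 per group for mid-range p-values (pwilcox as the independent
  ## exact reference; the far tail is outside the approximation's remit)
  checked <- 0
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    appr <- rank_sum_test(a, b, exact = FALSE)$p_value
    u <- rank_sum_test(a, b)$u
    ex <- min(1, 2 * min(pwilcox(u, 12, 12), 1 - pwilcox(u - 1, 12, 12)))
    if (ex >= 0.1) {
      expect_lt(abs(appr - ex) / ex, 0.05)
      checked <- checked + 1
    }
  }
  expect_gte(checked, 5)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("rank-sum p-values are uniform under the null", {
  set.seed(14)
  ps <- replicate(200, rank_sum_test(rnorm(30), rnorm(30), exact = FALSE)$p_value)
  d <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(d, 1.63 / sqrt(200))    # KS 1% critical value
})

test_that("Tukey HSD matches TukeyHSD and its intervals encode significance", {
  set.seed(15)
  g <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 5)
  out <- tukey_hsd(g)
  ## independent route: stats::TukeyHSD on the same data
  df <- data.frame(y = unlist(g), grp = rep(names(g), times = lengths(g)))
  ref <- TukeyHSD(aov(y ~ grp, df))$grp
  cmp <- out$comparisons
  for (j in seq_len(nrow(cmp))) {
    key <- paste0(cmp$group_b[j], "-", cmp$group_a[j])
    key2 <- paste0(cmp$group_a[j], "-", cmp$group_b[j])
    row <- if (key %in% rownames(ref)) -ref[key, c("diff", "upr", "lwr")] else ref[key2, c("diff", "lwr", "upr")]
    expect_equal(unname(unlist(cmp[j, c("diff", "lwr", "upr")])),
                 unname(as.numeric(row)), tolerance = 1e-9)
    expect_equal(cmp$p_adj[j],
                 unname(if (key %in% rownames(ref)) ref[key, "p adj"] else ref[key2, "p adj"]),
                 tolerance = 1e-9)
  }
  ## shifted group significant against both, others not
  expect_true(all(cmp$significant[cmp$group_a == "c" | cmp$group_b == "c"]))
  expect_false(any(cmp$significant[cmp$group_a != "c" & cmp$group_b != "c"]))
  ## balanced design: interval non-overlap <=> pairwise significance
  for (i in 1:10) {
    g2 <- list(x = rnorm(6), y = rnorm(6, sample(c(0, 3), 1)), z = rnorm(6))
    o <- tukey_hsd(g2)
    iv <- o$intervals
    for (j in seq_len(nrow(o$comparisons))) {
      ia <- iv[iv$group == o$comparisons$group_a[j], ]
      ib <- iv[iv$group == o$comparisons$group_b[j], ]
      overlap <- ia$lwr <= ib$upr && ib$lwr <= ia$upr
      expect_equal(!overlap, o$comparisons$significant[j])
    }
  }
  ## identical groups: difference 0, not significant
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(same$comparisons$diff, 0)
  expect_false(same$comparisons$significant)
  expect_error(tukey_hsd(list(a = 1, b = c(1, 2))), "insufficient")
})

test_that("the studentized-range critical value agrees with direct integration", {
  ## independent oracle: P(Q <= q) = E_S[ k Int phi(z) (Phi(z) - Phi(z - qS))^(k-1) dz ]
  ## with S the square root of a chi-squared(df)/df variate
  k <- 3; df <- 21; alpha <- 0.05
  p_range <- function(q) {
    integrate(function(z) k * dnorm(z) * (pnorm(z) - pnorm(z - q))^(k - 1),
              -8, 8)$value
  }
  p_stud <- function(q) {
    integrate(Vectorize(function(s) {
      p_range(q * s) * df^(df / 2) * s^(df - 1) * exp(-df * s^2 / 2) /
        (2^(df / 2 - 1) * gamma(df / 2))
    }), 0.1, 4)$value
  }
  q_oracle <- uniroot(function(q) p_stud(q) - (1 - alpha), c(2, 6), tol = 1e-7)$root
  expect_equal(q_oracle, qtukey(1 - alpha, k, df), tolerance = 1e-4)
})

test_that("stratification predicates select the declared subgroups", {
  md <- fake_metadata(20, 10, 6)
  md$age_years <- c(seq(20, 77, length.out = 20), seq(18, 66, length.out = 16))
  md$handedness[21] <- "left"
  groups <- stratify(md, c(
    young = "group == 'healthy' & age_years >= 20 & age_years <= 35",
    old = "group == 'healthy' & age_years >= 59 & age_years <= 77",
    rh_lat = "handedness == 'right' & seizure_hemisphere != 'none'"
  ))
  expect_equal(length(groups$young), sum(md$age_years <= 35 & md$group == "healthy"))
  expect_equal(length(groups$old), sum(md$age_years >= 59 & md$group == "healthy"))
  ## right-handed AND lateralized filter excludes the left-handed subject
  expect_false("S021" %in% groups$rh_lat)
  expect_true(all(md$seizure_hemisphere[match(groups$rh_lat, md$subject_id)] != "none"))
  empty <- stratify(md, c(none = "age_years > 200"))
  expect_length(empty$none, 0)
  expect_error(stratify(md, c(bad = "iq > 100")), "unknown field")
  expect_error(stratify(md, "age_years > 50"), "named")
})

test_that("the repeated-split task runs end to end on the mini cohort", {
  ft <- mini_features()
  md <- mini_metadata()
  splits <- make_splits(md, n_reps = 3, n_train_ref = 6, seed = 21)
  ms <- run_task(splits, ft, md, task = "healthy_vs_patient")
  expect_equal(nrow(ms), 3)
  s <- attr(ms, "summary")
  expect_true(all(ms$auc >= 0 & ms$auc <= 1))
  ## the injected strong effect separates the groups well
  expect_gt(s$mean[s$metric == "auc"], 0.8)
  ## hemisphere task uses the lateralized right-handed patients
  msh <- run_task(splits, ft, md, task = "hemisphere")
  expect_true(all(msh$auc >= 0 & msh$auc <= 1))
  ## AUC equals the subject-level Mann-Whitney computed independently
  m <- fit_normative(ft, splits[[1]]$train_reference_ids)
  sc <- score_windows(m, ft[ft$subject_id %in% splits[[1]]$test_ids &
                              ft$state == "EC", ])
  est <- subject_estimates(sc)
  scores <- est$pi_hat[match(splits[[1]]$test_ids, est$subject_id)]
  pos <- scores[splits[[1]]$test_labels]; neg <- scores[!splits[[1]]$test_labels]
  oracle <- mean(outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q)))
  expect_equal(ms$auc[1], oracle, tolerance = 1e-12)
})
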
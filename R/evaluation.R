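## Repeated train/test classification framework, ROC analysis with
## convex-hull threshold selection, and the group statistics (rank-sum test,
## Tukey HSD, cohort stratification).

#' Repeated random train/test splits
#'
#' Each repetition draws a fresh random reference sample of healthy subjects
#' for fitting the normative model; the remaining healthy subjects and all
#' patients form the test set. With the default design (144 healthy, 48
#' patients, 96 reference) the test set is automatically class-balanced;
#' otherwise the larger test class is subsampled to balance when
#' `balance = TRUE`.
#'
#' @param metadata cohort metadata (needs columns subject_id, group).
#' @param n_reps number of repetitions (default 10).
#' @param n_train_ref healthy subjects per reference sample (default 96).
#' @param seed integer seed; splits are deterministic given the seed.
#' @param balance class-balance the test set (default TRUE).
#' @return list of `split_plan`s: lists with repetition, train_reference_ids,
#'   test_ids, test_labels (TRUE = patient).
#' @export
make_splits <- function(metadata, n_reps = 10, n_train_ref = 96, seed = 1,
                        balance = TRUE) {
  healthy <- metadata$subject_id[metadata$group == "healthy"]
  patients <- metadata$subject_id[metadata$group == "patient"]
  if (length(healthy) <= n_train_ref) {
    stop(sprintf("insufficient healthy subjects: need > %d, have %d",
                 n_train_ref, length(healthy)), call. = FALSE)
  }
  if (!length(patients)) stop("no patient subjects in metadata", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_reps), function(rep) {
    train <- sample(healthy, n_train_ref)
    test_h <- setdiff(healthy, train)
    test_p <- patients
    if (balance) {
      n_bal <- min(length(test_h), length(test_p))
      if (length(test_h) > n_bal) test_h <- sample(test_h, n_bal)
      if (length(test_p) > n_bal) test_p <- sample(test_p, n_bal)
    }
    structure(
      list(repetition = rep, train_reference_ids = train,
           test_ids = c(test_h, test_p),
           test_labels = c(rep(FALSE, length(test_h)), rep(TRUE, length(test_p)))),
      class = "split_plan"
    )
  })
}

#' ROC curve and AUC
#'
#' Scores are probabilities-of-normality: a lower score indicates the
#' positive class. The curve sweeps all unique scores as thresholds
#' (predicted positive when score <= threshold), starts at (0,0) and ends at
#' (1,1); the trapezoidal AUC equals the Mann-Whitney statistic normalized
#' by n1*n2 with ties counted one half.
#'
#' @param scores numeric scores (lower = more positive).
#' @param labels logical (TRUE = positive) or coercible to logical.
#' @return a `roc_curve`: list with `points` (data.frame threshold, fpr,
#'   tpr) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  n_pos <- sum(labels); n_neg <- sum(!labels)
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) sum(scores <= t & labels) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores <= t & !labels) / n_neg, numeric(1))
  points <- data.frame(threshold = c(-Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' Optimal threshold by the ROC convex-hull method
#'
#' Computes the upper convex hull of the ROC points and returns the
#' threshold of the hull vertex maximizing `tpr - cost_ratio * fpr`
#' (iso-performance slope 1 by default, appropriate for a class-balanced
#' test set). Ties are broken toward higher TPR, then lower threshold.
#'
#' @param roc a `roc_curve`.
#' @param cost_ratio slope of the iso-performance line (default 1).
#' @return the selected threshold (predict positive when score <= threshold).
#' @export
convex_hull_threshold <- function(roc, cost_ratio = 1) {
  pts <- roc$points
  hull_idx <- upper_hull_indices(pts$fpr, pts$tpr)
  cand <- pts[hull_idx, , drop = FALSE]
  obj <- cand$tpr - cost_ratio * cand$fpr
  best <- which(obj == max(obj))
  if (length(best) > 1) best <- best[cand$tpr[best] == max(cand$tpr[best])]
  if (length(best) > 1) best <- best[which.min(cand$threshold[best])]
  cand$threshold[best]
}

## Indices of the upper-left convex hull of an ROC point set (monotone chain
## on the upper side, anchored at (0,0) and (1,1)).
upper_hull_indices <- function(x, y) {
  ord <- order(x, y)
  hull <- integer(0)
  cross <- function(o, a, b) {
    (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o])
  }
  for (i in ord) {
    while (length(hull) >= 2 &&
           cross(hull[length(hull) - 1], hull[length(hull)], i) >= 0) {
      hull <- hull[-length(hull)]
    }
    hull <- c(hull, i)
  }
  hull
}

#' Precision, recall and F1 at a threshold
#'
#' Predicted positive when score <= threshold (lower probability-of-normality
#' means predicted patient). Metrics are percentages; with zero predicted
#' positives precision and F1 are `NaN` with a warning.
#'
#' @param scores numeric scores.
#' @param labels logical (TRUE = positive).
#' @param threshold decision threshold.
#' @return list with precision, recall, f1 (percent).
#' @export
prf_metrics <- function(scores, labels, threshold) {
  labels <- as.logical(labels)
  pred <- scores <= threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels); fn <- sum(!pred & labels)
  if (tp + fp == 0) {
    warning("zero predicted positives: precision undefined")
    precision <- NaN
  } else {
    precision <- 100 * tp / (tp + fp)
  }
  recall <- 100 * tp / (tp + fn)
  f1 <- if (is.nan(precision) || precision + recall == 0) NaN else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' Run a classification task over repeated splits
#'
#' Per repetition: fit the normative model on the reference sample, compute
#' subject-level probabilities-of-normality for the test subjects, and
#' derive ROC/AUC, the convex-hull threshold and precision/recall/F1.
#' Patients are the positive class and a low subject probability indicates
#' positive. The hemisphere task scores right-handed lateralized patients
#' only (left-hemisphere focus = positive) against the healthy-fitted model.
#'
#' @param splits list from [make_splits()].
#' @param features tidy feature table for all subjects.
#' @param metadata cohort metadata.
#' @param task `"healthy_vs_patient"` or `"hemisphere"`.
#' @param subset feature subset (see [window_probability()]).
#' @param montage a [montage_spec()].
#' @return a `metric_set`: data.frame (one row per repetition: auc,
#'   threshold, precision, recall, f1) with a `summary` attribute holding
#'   cross-repetition means and SDs.
#' @export
run_task <- function(splits, features, metadata,
                     task = c("healthy_vs_patient", "hemisphere"),
                     subset = "all", montage = default_montage()) {
  task <- match.arg(task)
  rows <- lapply(splits, function(sp) {
    model <- fit_normative(features, sp$train_reference_ids, montage)
    if (task == "healthy_vs_patient") {
      ids <- sp$test_ids
      labels <- sp$test_labels
    } else {
      keep <- metadata$group == "patient" & metadata$handedness == "right" &
        metadata$seizure_hemisphere %in% c("left", "right")
      ids <- metadata$subject_id[keep]
      labels <- metadata$seizure_hemisphere[keep] == "left"
    }
    if (length(unique(labels)) < 2) {
      stop("AUC undefined: degenerate single-class test set", call. = FALSE)
    }
    tab <- features[features$subject_id %in% ids & features$state == "EC", , drop = FALSE]
    scored <- score_windows(model, tab, subset = subset, montage = montage)
    est <- subject_estimates(scored)
    scores <- est$pi_hat[match(ids, est$subject_id)]
    roc <- roc_and_auc(scores, labels)
    thr <- convex_hull_threshold(roc)
    prf <- prf_metrics(scores, labels, thr)
    data.frame(repetition = sp$repetition, auc = roc$auc, threshold = thr,
               precision = prf$precision, recall = prf$recall, f1 = prf$f1)
  })
  out <- do.call(rbind, rows)
  metric_cols <- c("auc", "precision", "recall", "f1")
  attr(out, "summary") <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(m) mean(out[[m]]), numeric(1)),
    sd = vapply(metric_cols, function(m) sd(out[[m]]), numeric(1))
  )
  class(out) <- c("metric_set", "data.frame")
  out
}

#' @export
print.metric_set <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf("<metric_set> %d repetitions\n", nrow(x)))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %6.2f (%.2f)\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Wilcoxon rank-sum test
#'
#' Midranks for ties. For `n1 + n2 <= 20` (or `exact = TRUE`) the two-sided
#' p-value is computed by exact enumeration of all rank assignments of the
#' observed pooled values (so ties are handled exactly); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @param exact force or forbid exact enumeration (default: automatic).
#' @return list with `statistic` (rank sum W of the first sample), `u`
#'   (Mann-Whitney U), `p_value` (two-sided) and `method`.
#' @export
rank_sum_test <- function(sample_a, sample_b, exact = NULL) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("samples must be non-empty", call. = FALSE)
  }
  n1 <- length(sample_a); n2 <- length(sample_b); n <- n1 + n2
  pooled <- c(sample_a, sample_b)
  r <- rank(pooled)                      # midranks
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (is.null(exact)) exact <- n <= 20
  if (exact) {
    combos <- combn(n, n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
    z <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal approximation with tie and continuity correction"
  }
  list(statistic = w, u = w - n1 * (n1 + 1) / 2, p_value = p, method = method)
}

#' Tukey honestly-significant-difference comparisons
#'
#' Pairwise mean differences with studentized-range critical values
#' (Tukey-Kramer for unequal group sizes), plus per-group comparison
#' intervals `mean_g +/- q/2 * sqrt(MSE / n_g)` whose non-overlap is
#' equivalent to pairwise significance for balanced designs (approximate
#' otherwise).
#'
#' @param samples named list (>= 2 groups, each n >= 2) of numeric vectors.
#' @param alpha familywise error rate (default 0.05).
#' @return list with `comparisons` (data.frame: group_a, group_b, diff, lwr,
#'   upr, p_adj, significant) and `intervals` (data.frame: group, n, mean,
#'   lwr, upr).
#' @export
tukey_hsd <- function(samples, alpha = 0.05) {
  k <- length(samples)
  if (k < 2 || is.null(names(samples))) {
    stop("samples must be a named list of >= 2 groups", call. = FALSE)
  }
  ns <- lengths(samples)
  if (any(ns < 2)) stop("insufficient data: every group needs n >= 2", call. = FALSE)
  means <- vapply(samples, mean, numeric(1))
  df <- sum(ns) - k
  mse <- sum(vapply(samples, function(v) sum((v - mean(v))^2), numeric(1))) / df
  q <- qtukey(1 - alpha, k, df)
  pairs <- combn(k, 2)
  comparisons <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- means[i1] - means[i2]
    se <- sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    hw <- q * se
    data.frame(group_a = names(samples)[i1], group_b = names(samples)[i2],
               diff = d, lwr = d - hw, upr = d + hw,
               p_adj = ptukey(abs(d) / se, k, df, lower.tail = FALSE),
               significant = abs(d) > hw, stringsAsFactors = FALSE)
  }))
  hw_g <- q / 2 * sqrt(mse / ns)
  intervals <- data.frame(group = names(samples), n = as.integer(ns),
                          mean = unname(means), lwr = unname(means - hw_g),
                          upr = unname(means + hw_g), stringsAsFactors = FALSE)
  list(comparisons = comparisons, intervals = intervals)
}

#' Stratify a cohort by metadata predicates
#'
#' Evaluates each predicate expression (a character string referencing
#' metadata columns) within the metadata table and returns the matching
#' subject ids per named group. Groups may overlap or be empty.
#'
#' @param metadata cohort metadata data.frame.
#' @param predicates named character vector of R expressions, e.g.
#'   `c(young = "age_years >= 20 & age_years <= 35")`.
#' @return named list of character vectors of subject ids.
#' @export
stratify <- function(metadata, predicates) {
  if (is.null(names(predicates)) || any(!nzchar(names(predicates)))) {
    stop("predicates must be named", call. = FALSE)
  }
  out <- lapply(predicates, function(p) {
    expr <- parse(text = p)[[1]]
    vars <- all.vars(expr)
    unknown <- setdiff(vars, names(metadata))
    if (length(unknown)) {
      stop("predicate references unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    keep <- eval(expr, metadata, baseenv())
    metadata$subject_id[keep %in% TRUE]
  })
  names(out) <- names(predicates)
  out
}
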
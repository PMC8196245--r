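## Normative model: per-feature empirical CDFs fitted on a healthy reference
## window population, window-level probability-of-normality (geometric mean
## across features, computed in the log domain), subject-level aggregation
## (arithmetic mean, the Bernoulli maximum-likelihood estimate), and
## Wasserstein-distance group contrasts.

#' Fit the normative model
#'
#' Pools the eyes-closed windows of the reference subjects and stores, for
#' each of the 16 features, the sorted sample of log alpha-power fractions.
#' The model is purely data-defined (non-parametric).
#'
#' @param features tidy feature table (see [subject_feature_table()]).
#' @param reference_ids optional subject ids to restrict to; when supplied,
#'   later scoring of any of these ids is the caller's responsibility to
#'   avoid (train/test separation).
#' @param montage a [montage_spec()] fixing the feature order.
#' @return a `normative_model`: list with `samples` (named list of 16 sorted
#'   numeric vectors), `n_ref_windows`, `feature_names`, `reference_ids`.
#' @export
fit_normative <- function(features, reference_ids = NULL,
                          montage = default_montage()) {
  features <- features[features$state == "EC", , drop = FALSE]
  if (!is.null(reference_ids)) {
    features <- features[features$subject_id %in% reference_ids, , drop = FALSE]
  }
  fm <- feature_matrix(features, montage)
  if (anyNA(fm$matrix)) stop("incomplete feature vectors in reference table", call. = FALSE)
  n <- nrow(fm$matrix)
  if (n < 2) stop("insufficient data: need >= 2 reference windows per feature", call. = FALSE)
  samples <- lapply(seq_len(ncol(fm$matrix)), function(j) sort(fm$matrix[, j]))
  names(samples) <- colnames(fm$matrix)
  structure(
    list(samples = samples, n_ref_windows = n,
         feature_names = colnames(fm$matrix),
         reference_ids = sort(unique(fm$index$subject_id))),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat(sprintf("<normative_model> %d features, %d reference windows from %d subjects\n",
              length(x$samples), x$n_ref_windows, length(x$reference_ids)))
  invisible(x)
}

#' Evaluate a feature's empirical CDF
#'
#' Hazen (midrank) plotting position: `F(x) = (#{ref < x} + 0.5 #{ref = x}) / n`,
#' clamped to `[1/(2n), 1 - 1/(2n)]` so that values outside the reference
#' support never annihilate the geometric mean downstream. Set
#' `clamp = FALSE` to obtain the raw plotting position.
#'
#' @param model a `normative_model`.
#' @param feature feature index (1-16) or name.
#' @param x numeric values at which to evaluate.
#' @param clamp clamp away from 0 and 1 (default TRUE).
#' @return probabilities in `[0, 1]`, monotone non-decreasing in `x`.
#' @export
ecdf_eval <- function(model, feature, x, clamp = TRUE) {
  stopifnot(inherits(model, "normative_model"))
  if (is.character(feature)) feature <- match(feature, model$feature_names)
  if (is.na(feature) || feature < 1 || feature > length(model$samples)) {
    stop("unknown feature index", call. = FALSE)
  }
  ref <- model$samples[[feature]]
  n <- length(ref)
  n_less <- findInterval(x, ref, left.open = TRUE)   # ref < x (ties excluded)
  n_leq <- findInterval(x, ref)                      # ref <= x
  p <- (n_less + 0.5 * (n_leq - n_less)) / n
  if (clamp) p <- pmin(pmax(p, 1 / (2 * n)), 1 - 1 / (2 * n))
  p
}

## Resolve a feature subset: indices, names, or one of the named presets.
feature_subset <- function(subset, model_or_names) {
  feat_names <- if (inherits(model_or_names, "normative_model")) {
    model_or_names$feature_names
  } else {
    model_or_names
  }
  if (is.null(subset)) return(seq_along(feat_names))
  if (is.numeric(subset)) {
    if (any(subset < 1 | subset > length(feat_names))) {
      stop("feature subset index out of range", call. = FALSE)
    }
    return(as.integer(subset))
  }
  if (length(subset) == 1 && subset %in% c("all", "frontotemporal", "frontotemporal_high")) {
    ft <- grepl("^(F7-F3|T7-C3|F8-F4|T8-C4)\\.", feat_names)
    idx <- switch(subset,
                  all = seq_along(feat_names),
                  frontotemporal = which(ft),
                  frontotemporal_high = which(ft & grepl("high_alpha$", feat_names)))
    return(idx)
  }
  idx <- match(subset, feat_names)
  if (anyNA(idx)) stop("unknown feature name(s): ",
                       paste(subset[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' Window-level probability-of-normality
#'
#' The combined probability is the geometric mean of the per-feature ECDF
#' probabilities over the feature subset S, computed in the log domain:
#' `exp(mean(log F(x_k)))` for k in S.
#'
#' @param model a `normative_model`.
#' @param fv a `feature_vector`, or a named/ordered numeric vector of 16
#'   log-fractions.
#' @param subset feature subset: indices, names, or one of `"all"`,
#'   `"frontotemporal"`, `"frontotemporal_high"` (default all 16).
#' @param clamp passed to [ecdf_eval()]; disable only for closed-form checks.
#' @return a `window_probability`: list with `per_feature` (named
#'   probabilities over S) and `combined`.
#' @export
window_probability <- function(model, fv, subset = "all", clamp = TRUE) {
  values <- if (inherits(fv, "feature_vector")) fv$values else fv
  if (anyNA(values)) stop("NaN/NA feature in window", call. = FALSE)
  idx <- feature_subset(subset, model)
  p <- vapply(idx, function(k) ecdf_eval(model, k, unname(values[k]), clamp = clamp),
              numeric(1))
  names(p) <- model$feature_names[idx]
  structure(
    list(per_feature = p, combined = exp(mean(log(p)))),
    class = "window_probability"
  )
}

#' Score every window of a feature table
#'
#' Vectorized [window_probability()] over all windows.
#'
#' @param model a `normative_model`.
#' @param features tidy feature table.
#' @param subset feature subset (see [window_probability()]).
#' @param montage a [montage_spec()].
#' @return data.frame with subject_id, window_index, state, combined.
#' @export
score_windows <- function(model, features, subset = "all",
                          montage = default_montage()) {
  fm <- feature_matrix(features, montage)
  if (anyNA(fm$matrix)) stop("incomplete feature vectors in table", call. = FALSE)
  idx <- feature_subset(subset, model)
  logp <- matrix(0, nrow(fm$matrix), length(idx))
  for (j in seq_along(idx)) {
    logp[, j] <- log(ecdf_eval(model, idx[j], fm$matrix[, idx[j]]))
  }
  out <- fm$index
  out$combined <- exp(rowMeans(logp))
  out
}

#' Subject-level probability-of-normality
#'
#' The arithmetic mean of a subject's window-level combined probabilities —
#' the exact maximizer of the Bernoulli likelihood of the window values.
#'
#' @param window_probs numeric vector of one subject's window-level combined
#'   probabilities.
#' @return a `subject_estimate`: list with `n_windows` and `pi_hat`.
#' @export
subject_probability <- function(window_probs) {
  if (!length(window_probs)) stop("insufficient data: zero windows", call. = FALSE)
  structure(list(n_windows = length(window_probs), pi_hat = mean(window_probs)),
            class = "subject_estimate")
}

#' Aggregate scored windows to per-subject estimates
#'
#' @param scored data.frame from [score_windows()].
#' @return data.frame with subject_id, n_windows, pi_hat.
#' @export
subject_estimates <- function(scored) {
  if (!nrow(scored)) stop("insufficient data: zero windows", call. = FALSE)
  agg <- aggregate(scored$combined, by = list(subject_id = scored$subject_id),
                   FUN = function(v) c(n = length(v), m = mean(v)))
  data.frame(subject_id = agg$subject_id,
             n_windows = as.integer(agg$x[, "n"]),
             pi_hat = agg$x[, "m"], stringsAsFactors = FALSE)
}

#' First-order Wasserstein distance between two empirical distributions
#'
#' The area between the two empirical CDFs, computed exactly as the integral
#' of `|Q_a(u) - Q_b(u)|` over the shared quantile grid. For equal sample
#' sizes this reduces to the mean absolute difference of the sorted samples.
#'
#' @param sample_a,sample_b non-empty numeric vectors.
#' @return non-negative distance.
#' @export
wasserstein_1d <- function(sample_a, sample_b) {
  if (!length(sample_a) || !length(sample_b)) {
    stop("samples must be non-empty", call. = FALSE)
  }
  a <- sort(sample_a); b <- sort(sample_b)
  na <- length(a); nb <- length(b)
  u <- sort(unique(c(seq_len(na) / na, seq_len(nb) / nb)))
  widths <- diff(c(0, u))
  qa <- a[ceiling(u * na - 1e-12)]
  qb <- b[ceiling(u * nb - 1e-12)]
  sum(widths * abs(qa - qb))
}

#' Per-feature Wasserstein contrast between two groups
#'
#' For each of the 16 features, the Wasserstein distance between the two
#' groups' pooled window-level log-fraction samples; optionally also the
#' window-level combined probabilities per group under a normative model
#' (boxplot-ready).
#'
#' @param features tidy feature table containing both groups' windows.
#' @param groups named list of exactly two character vectors of subject ids.
#' @param model optional `normative_model` used to score the windows.
#' @param montage a [montage_spec()].
#' @param subset feature subset for the probabilities.
#' @return list with `distances` (data.frame: channel, band, feature,
#'   distance) and, when `model` is given, `probabilities` (data.frame:
#'   group, subject_id, window_index, combined).
#' @export
group_contrast <- function(features, groups, model = NULL,
                           montage = default_montage(), subset = "all") {
  if (length(groups) != 2 || is.null(names(groups))) {
    stop("groups must be a named list of exactly two id vectors", call. = FALSE)
  }
  tabs <- lapply(groups, function(ids) {
    tab <- features[features$subject_id %in% ids & features$state == "EC", , drop = FALSE]
    if (!nrow(tab)) stop("insufficient data: a group has zero windows", call. = FALSE)
    tab
  })
  band_names <- c("low_alpha", "high_alpha")
  keys <- as.vector(t(outer(montage$channel, band_names, paste, sep = ".")))
  dist <- vapply(keys, function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    sa <- tabs[[1]]$log_fraction[tabs[[1]]$channel == parts[1] & tabs[[1]]$band == parts[2]]
    sb <- tabs[[2]]$log_fraction[tabs[[2]]$channel == parts[1] & tabs[[2]]$band == parts[2]]
    wasserstein_1d(sa, sb)
  }, numeric(1))
  distances <- data.frame(
    channel = rep(montage$channel, each = length(band_names)),
    band = rep(band_names, times = nrow(montage)),
    region = rep(montage$region, each = length(band_names)),
    hemisphere = rep(montage$hemisphere, each = length(band_names)),
    feature = keys, distance = unname(dist),
    stringsAsFactors = FALSE
  )
  out <- list(distances = distances)
  if (!is.null(model)) {
    probs <- lapply(names(groups), function(g) {
      sc <- score_windows(model, tabs[[g]], subset = subset, montage = montage)
      cbind(group = g, sc, stringsAsFactors = FALSE)
    })
    out$probabilities <- do.call(rbind, probs)
  }
  out
}
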
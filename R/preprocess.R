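#' Assemble a labelled feature matrix from a cohort of trees
#'
#' Computes the 15-feature vector for each tree and binds the cohort
#' labels. Rows with missing features (trees on which a feature is
#' undefined, e.g. no bifurcation) are dropped with a warning, matching
#' the no-imputation policy.
#'
#' @param trees list of `neuron_tree` objects.
#' @param labels data.frame with one row per tree: `neuron_id`, `area`,
#'   `age_group`. Defaults are generated when omitted.
#' @param drop_incomplete drop rows with any `NA` feature (default TRUE).
#' @return a `feature_matrix`: data.frame with label columns `neuron_id`,
#'   `area`, `age_group` followed by the 15 feature columns.
#' @export
build_feature_matrix <- function(trees, labels = NULL, drop_incomplete = TRUE) {
  if (is.null(labels)) {
    labels <- data.frame(neuron_id = sprintf("neuron_%04d", seq_along(trees)),
                         area = "synthetic", age_group = "unknown")
  }
  stopifnot(nrow(labels) == length(trees))
  if (anyDuplicated(labels$neuron_id)) stop("duplicated neuron ids")
  vals <- t(vapply(trees, compute_feature_vector, numeric(15L)))
  fm <- cbind(labels[, c("neuron_id", "area", "age_group")],
              as.data.frame(vals))
  if (drop_incomplete && anyNA(vals)) {
    bad <- apply(is.na(vals), 1L, any)
    warning(sum(bad), " neuron(s) dropped for undefined features: ",
            paste(utils::head(fm$neuron_id[bad], 5L), collapse = ", "))
    fm <- fm[!bad, , drop = FALSE]
  }
  rownames(fm) <- NULL
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

label_cols <- function(fm) intersect(c("neuron_id", "area", "age_group"), names(fm))

#' Feature columns of a feature matrix
#' @param fm a `feature_matrix`.
#' @return character vector of feature column names.
#' @export
feature_cols <- function(fm) setdiff(names(fm), label_cols(fm))

#' Remove outlier neurons with the boxplot (IQR) rule
#'
#' A neuron is removed when any of its features lies outside
#' `[Q1 - k * IQR, Q3 + k * IQR]` for that feature. Fences are computed
#' per cortical area by default, since areas differ strongly in scale.
#' Features whose IQR is zero (discrete counts concentrated on one value)
#' have no usable box and are skipped rather than allowed to flag every
#' off-mode neuron.
#'
#' @param fm a `feature_matrix`.
#' @param iqr_multiplier the fence multiplier k (default 3, "far out"
#'   fences).
#' @param per_area compute fences within each area (default) or globally.
#' @return list with `matrix` (the filtered `feature_matrix`) and `report`
#'   (a `prune_report`: `outliers_removed` data.frame of neuron id /
#'   triggering feature, and `fraction_removed`).
#' @export
remove_outliers <- function(fm, iqr_multiplier = 3, per_area = TRUE) {
  stopifnot(nrow(fm) >= 5L, iqr_multiplier > 0)
  feats <- feature_cols(fm)
  groups <- if (per_area) fm$area else rep("all", nrow(fm))
  flagged <- character(0); trigger <- character(0)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    for (f in feats) {
      v <- fm[[f]][rows]
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
      iqr <- q[2L] - q[1L]
      if (iqr == 0) next   # degenerate box (discrete feature): no fence
      lo <- q[1L] - iqr_multiplier * iqr
      hi <- q[2L] + iqr_multiplier * iqr
      out <- rows[v < lo | v > hi]
      new <- setdiff(fm$neuron_id[out], flagged)
      flagged <- c(flagged, new)
      trigger <- c(trigger, rep(f, length(new)))
    }
  }
  keep <- !(fm$neuron_id %in% flagged)
  if (!any(keep)) stop("outlier removal would drop every neuron")
  report <- structure(list(
    dropped_features = data.frame(feature = character(0),
                                  partner = character(0), r = numeric(0)),
    outliers_removed = data.frame(neuron_id = flagged, feature = trigger),
    fraction_removed = length(flagged) / nrow(fm)),
    class = "prune_report")
  out_fm <- fm[keep, , drop = FALSE]
  rownames(out_fm) <- NULL
  list(matrix = out_fm, report = report)
}

#' Z-score the feature columns
#'
#' Centers each feature to mean 0 and scales to standard deviation 1 using
#' the population (divide-by-n) convention. The fitted centers and scales
#' are stored as attributes so the transform is exactly invertible with
#' [unscale_features()], and so a scaler fitted on training rows can be
#' applied to held-out rows.
#'
#' @param fm a `feature_matrix`.
#' @param center,scale optional pre-fitted named vectors (e.g. from a
#'   training subset); fitted from `fm` when omitted.
#' @return the scaled `feature_matrix` with attributes `scaled_center` and
#'   `scaled_scale`.
#' @export
scale_features <- function(fm, center = NULL, scale = NULL) {
  feats <- feature_cols(fm)
  if (is.null(center)) {
    center <- vapply(fm[feats], mean, 1)
  }
  if (is.null(scale)) {
    scale <- vapply(feats, function(f) pop_sd(fm[[f]]), 1)
    names(scale) <- feats
  }
  if (any(scale == 0)) {
    stop("constant feature(s), cannot scale: ",
         paste(feats[scale == 0], collapse = ", "))
  }
  for (f in feats) fm[[f]] <- (fm[[f]] - center[[f]]) / scale[[f]]
  attr(fm, "scaled_center") <- center
  attr(fm, "scaled_scale") <- scale
  fm
}

pop_sd <- function(v) sqrt(mean((v - mean(v))^2))

#' Invert a z-score transform
#' @param fm a `feature_matrix` produced by [scale_features()].
#' @return the `feature_matrix` on its original scale.
#' @export
unscale_features <- function(fm) {
  center <- attr(fm, "scaled_center")
  scale <- attr(fm, "scaled_scale")
  if (is.null(center) || is.null(scale)) stop("matrix was not scaled")
  for (f in feature_cols(fm)) fm[[f]] <- fm[[f]] * scale[[f]] + center[[f]]
  attr(fm, "scaled_center") <- NULL
  attr(fm, "scaled_scale") <- NULL
  fm
}

#' Drop one feature of each highly correlated pair
#'
#' Computes Pearson correlations between all feature pairs; whenever
#' |r| exceeds the threshold, one member is dropped. The choice is
#' deterministic: a member on the keep-list survives; otherwise the
#' feature appearing later in column order is dropped. The default
#' keep-list retains `pathDistance` over `euclidean_Distance` and
#' `n_bifs` over `n_branches`, reproducing the 13-feature set the study
#' design retains.
#'
#' @param fm a `feature_matrix`.
#' @param threshold absolute-correlation threshold in (0, 1), default 0.8.
#' @param keep character vector of features preferred for retention.
#' @return list with `matrix` (pruned `feature_matrix`) and `report`
#'   (a `prune_report` listing each dropped feature, its retained partner
#'   and their r).
#' @export
correlation_prune <- function(fm, threshold = 0.8,
                              keep = c("pathDistance", "n_bifs")) {
  stopifnot(nrow(fm) >= 3L, threshold > 0, threshold < 1)
  feats <- feature_cols(fm)
  r <- stats::cor(as.matrix(fm[feats]))
  dropped <- character(0); partner <- character(0); rval <- numeric(0)
  for (i in seq_along(feats)) {
    for (j in seq_along(feats)) {
      if (j <= i) next
      a <- feats[i]; b <- feats[j]
      if (a %in% dropped || b %in% dropped) next
      if (is.na(r[a, b]) || abs(r[a, b]) <= threshold) next
      # decide which of the correlated pair goes
      drop <- if (a %in% keep && !(b %in% keep)) b
              else if (b %in% keep && !(a %in% keep)) a
              else b
      dropped <- c(dropped, drop)
      partner <- c(partner, setdiff(c(a, b), drop))
      rval <- c(rval, r[a, b])
    }
  }
  report <- structure(list(
    dropped_features = data.frame(feature = dropped, partner = partner,
                                  r = rval),
    outliers_removed = data.frame(neuron_id = character(0),
                                  feature = character(0)),
    fraction_removed = 0),
    class = "prune_report")
  out <- fm[, c(label_cols(fm), setdiff(feats, dropped)), drop = FALSE]
  class(out) <- c("feature_matrix", "data.frame")
  list(matrix = out, report = report)
}

#' @export
print.prune_report <- function(x, ...) {
  cat("prune report:", nrow(x$dropped_features), "feature(s) dropped,",
      nrow(x$outliers_removed), "outlier neuron(s) removed (",
      sprintf("%.1f%%", 100 * x$fraction_removed), ")\n")
  if (nrow(x$dropped_features) > 0L) print(x$dropped_features)
  invisible(x)
}
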
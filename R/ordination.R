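#' PCA of a feature subset
#'
#' Eigendecomposition of the covariance of the chosen (already scaled)
#' feature columns. A deterministic sign convention is applied: within
#' each component the largest-magnitude loading is made positive, so
#' loading plots are reproducible across runs and platforms.
#'
#' @param fm a scaled `feature_matrix`.
#' @param subset feature names to use; defaults to all feature columns.
#' @return a `pca_result`: list with `loadings` (features x components,
#'   unit-norm columns), `explained_variance_pct`, `cumulative_pct`,
#'   `scores` (neurons x components), `feature_subset`, and the row
#'   labels (`age_group`, `neuron_id`).
#' @export
fit_pca <- function(fm, subset = NULL) {
  feats <- feature_cols(fm)
  if (is.null(subset)) subset <- feats
  stopifnot(all(subset %in% feats), length(subset) >= 2L)
  x <- as.matrix(fm[subset])
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2L, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(pc$rotation, 2L, flip, `*`)
  scores <- sweep(pc$x, 2L, flip, `*`)
  ev <- pc$sdev^2
  pct <- 100 * ev / sum(ev)
  structure(list(
    loadings = loadings,
    explained_variance_pct = pct,
    cumulative_pct = cumsum(pct),
    scores = scores,
    eigenvalues = ev,
    feature_subset = subset,
    age_group = fm$age_group,
    neuron_id = fm$neuron_id), class = "pca_result")
}

#' Components needed to reach a cumulative variance target
#' @param result a `pca_result`.
#' @param target_pct cumulative explained-variance target (default 95).
#' @return the smallest component count whose cumulative percentage
#'   reaches the target.
#' @export
n_components_for_variance <- function(result, target_pct = 95) {
  which(result$cumulative_pct >= target_pct - 1e-9)[1L]
}

#' Per-age-group convex polygons in the PC1/PC2 plane
#'
#' The polygon of a group is the convex hull of its neurons' (PC1, PC2)
#' scores; groups with fewer than 3 members are skipped with a warning.
#'
#' @param result a `pca_result`.
#' @param groups group label per neuron; defaults to the age groups
#'   stored in the result.
#' @return named list of polygons, each a 2-column matrix of hull
#'   vertices in order.
#' @export
group_polygons <- function(result, groups = result$age_group) {
  xy <- result$scores[, 1:2, drop = FALSE]
  out <- list()
  for (g in unique(groups)) {
    pts <- unique(xy[groups == g, , drop = FALSE])
    if (nrow(pts) < 3L) {
      warning("group '", g, "' has fewer than 3 distinct points; skipped")
      next
    }
    h <- grDevices::chull(pts[, 1L], pts[, 2L])
    out[[g]] <- pts[h, , drop = FALSE]
  }
  out
}

#' Ward hierarchical clustering of PCA scores
#'
#' Agglomerative clustering with Euclidean distances and Ward's minimum-
#' variance linkage (the `ward.D2` criterion, which operates on the
#' distances themselves) on the first components covering the variance
#' target.
#'
#' @param result a `pca_result`, or a plain numeric score matrix.
#' @param labels leaf labels; defaults to the age groups in the result.
#' @param variance_target cumulative variance (in percent) deciding how
#'   many components enter the distance (default 95); ignored for plain
#'   matrices.
#' @return a `cluster_result`: list with `hclust` (the linkage),
#'   `leaf_labels`, `n_components_used`.
#' @export
ward_cluster <- function(result, labels = NULL, variance_target = 95) {
  if (inherits(result, "pca_result")) {
    ncomp <- n_components_for_variance(result, variance_target)
    scores <- result$scores[, seq_len(ncomp), drop = FALSE]
    if (is.null(labels)) labels <- result$age_group
  } else {
    scores <- as.matrix(result)
    ncomp <- ncol(scores)
    if (is.null(labels)) labels <- as.character(seq_len(nrow(scores)))
  }
  rownames(scores) <- make.unique(as.character(labels))
  hc <- stats::hclust(stats::dist(scores), method = "ward.D2")
  structure(list(hclust = hc, leaf_labels = labels,
                 n_components_used = ncomp),
            class = "cluster_result")
}

#' Export a clustering as a Newick string
#' @param cluster a `cluster_result`.
#' @param path optional file to write to.
#' @return the Newick string (invisibly when `path` is given).
#' @export
cluster_newick <- function(cluster, path = NULL) {
  phy <- ape::as.phylo(cluster$hclust)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

# stratified index split: per class, take floor(frac * n_c) for training
stratified_split <- function(labels, train_fraction) {
  train <- integer(0)
  for (g in unique(labels)) {
    rows <- which(labels == g)
    n_tr <- max(1L, floor(train_fraction * length(rows)))
    if (length(rows) < 2L) stop("class '", g, "' has fewer than 2 members")
    train <- c(train, sample(rows, n_tr))
  }
  sort(train)
}

svm_fit_predict <- function(x_tr, y_tr, x_te, kernel, cost) {
  fit <- e1071::svm(x = x_tr, y = factor(y_tr), kernel = kernel, cost = cost)
  as.character(stats::predict(fit, x_te))
}

#' Hold-out SVM validation of age-group separability
#'
#' Stratified random split into training and test rows; optionally the
#' training rows are reduced by PCA to the components covering 95% of
#' variance (the projection is fitted on the training rows only and then
#' applied to the test rows). Scaling is likewise fitted on training rows
#' by default; `paper_exact = TRUE` scales on the full matrix before
#' splitting instead.
#'
#' @param fm an unscaled `feature_matrix`.
#' @param train_fraction training proportion (default 0.7).
#' @param with_pca reduce to 95%-variance components before classifying.
#' @param seed integer seed; the report is reproducible given the seed.
#' @param kernel,cost SVM kernel and regularization (defaults: radial,
#'   cost 1).
#' @param paper_exact fit the scaler on all rows before splitting.
#' @return a `validation_report`: list with `scheme = "holdout"`,
#'   `with_pca`, `accuracy`, `n_test`, `seed`.
#' @export
svm_holdout <- function(fm, train_fraction = 0.7, with_pca = FALSE,
                        seed = 1L, kernel = "radial", cost = 1,
                        paper_exact = FALSE) {
  labels <- fm$age_group
  if (length(unique(labels)) < 2L) stop("need at least 2 classes")
  set.seed(seed)
  if (paper_exact) fm <- scale_features(fm)
  tr <- stratified_split(labels, train_fraction)
  te <- setdiff(seq_len(nrow(fm)), tr)
  fm_tr <- fm[tr, , drop = FALSE]
  if (!paper_exact) {
    fm_tr <- scale_features(fm_tr)
    fm_te <- scale_features(fm[te, , drop = FALSE],
                            center = attr(fm_tr, "scaled_center"),
                            scale = attr(fm_tr, "scaled_scale"))
  } else {
    fm_te <- fm[te, , drop = FALSE]
  }
  x_tr <- as.matrix(fm_tr[feature_cols(fm_tr)])
  x_te <- as.matrix(fm_te[feature_cols(fm_te)])
  if (with_pca) {
    pca <- fit_pca(fm_tr)
    ncomp <- n_components_for_variance(pca, 95)
    keep <- seq_len(ncomp)
    ctr <- colMeans(x_tr)
    x_te <- sweep(x_te, 2L, ctr) %*% pca$loadings[, keep, drop = FALSE]
    x_tr <- pca$scores[, keep, drop = FALSE]
  }
  pred <- svm_fit_predict(x_tr, labels[tr], x_te, kernel, cost)
  structure(list(scheme = "holdout", with_pca = with_pca,
                 accuracy = mean(pred == labels[te]),
                 n_test = length(te), seed = seed),
            class = "validation_report")
}

#' Stratified k-fold cross-validated SVM accuracy
#'
#' @param fm an unscaled `feature_matrix`.
#' @param k fold count (default 10); every class must have at least k
#'   members for stratified folds unless k equals the row count
#'   (leave-one-out).
#' @param with_pca,seed,kernel,cost,paper_exact as in [svm_holdout()].
#' @return a `validation_report` with `scheme = "kfold"`, `accuracy`
#'   (mean over folds), `per_fold`, `seed`.
#' @export
kfold_cv <- function(fm, k = 10L, with_pca = FALSE, seed = 1L,
                     kernel = "radial", cost = 1, paper_exact = FALSE) {
  labels <- fm$age_group
  n <- nrow(fm)
  if (k > n) stop("k exceeds the number of rows")
  if (k < 2L) stop("k must be at least 2")
  set.seed(seed)
  fold <- integer(n)
  if (k == n) {
    fold <- seq_len(n)                       # leave-one-out
  } else {
    for (g in unique(labels)) {              # stratified assignment
      rows <- sample(which(labels == g))
      fold[rows] <- rep_len(seq_len(k), length(rows))
    }
  }
  if (paper_exact) fm <- scale_features(fm)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    te <- which(fold == f); tr <- which(fold != f)
    fm_tr <- fm[tr, , drop = FALSE]
    fm_te <- fm[te, , drop = FALSE]
    if (!paper_exact) {
      fm_tr <- scale_features(fm_tr)
      fm_te <- scale_features(fm_te,
                              center = attr(fm_tr, "scaled_center"),
                              scale = attr(fm_tr, "scaled_scale"))
    }
    x_tr <- as.matrix(fm_tr[feature_cols(fm_tr)])
    x_te <- as.matrix(fm_te[feature_cols(fm_te)])
    if (with_pca) {
      pca <- fit_pca(fm_tr)
      keep <- seq_len(n_components_for_variance(pca, 95))
      x_te <- sweep(x_te, 2L, colMeans(x_tr)) %*%
        pca$loadings[, keep, drop = FALSE]
      x_tr <- pca$scores[, keep, drop = FALSE]
    }
    pred <- svm_fit_predict(x_tr, labels[tr], x_te, kernel, cost)
    acc[f] <- mean(pred == labels[te])
  }
  structure(list(scheme = "kfold", with_pca = with_pca,
                 accuracy = mean(acc), per_fold = acc, seed = seed),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s SVM validation (%s PCA): accuracy %.3f\n",
              x$scheme, if (x$with_pca) "with" else "without", x$accuracy))
  invisible(x)
}
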
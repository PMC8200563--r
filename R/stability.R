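#' Normalized histogram of a feature sample
#'
#' Relative frequencies over the given bin edges. Bins are half-open
#' `[a, b)` except the last, which is closed, so every value inside the
#' edge range lands in exactly one bin.
#'
#' @param values numeric sample (finite, non-empty).
#' @param edges strictly increasing bin edges covering the sample range.
#' @return numeric vector of bin proportions summing to 1.
#' @export
normalized_histogram <- function(values, edges) {
  if (length(values) == 0L || !all(is.finite(values))) {
    stop("empty or non-finite sample")
  }
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (min(values) < edges[1L] || max(values) > edges[length(edges)]) {
    stop("bin edges do not cover the sample range")
  }
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(edges) - 1L)
  counts / length(values)
}

#' L1 distance between two normalized histograms
#'
#' The sum of absolute bin-proportion differences. Ranges from 0
#' (identical distributions at this binning) to 2 (disjoint supports),
#' which makes 1 the natural half-range cutoff for calling a feature
#' stable versus varying.
#'
#' @param p,q proportion vectors of equal length, each summing to 1.
#' @return distance in `[0, 2]`.
#' @export
histogram_distance <- function(p, q) {
  if (length(p) != length(q)) stop("histograms have different lengths")
  sum(abs(p - q))
}

#' Classify features as stable or varying between two age groups
#'
#' For each feature, the two groups' values are binned on a common
#' equal-width grid spanning their pooled range, and the L1 distance
#' between the two normalized histograms is compared with the cutoff:
#' distance < cutoff is "stable", distance >= cutoff is "varying". The
#' comparison is conventionally run between the two oldest consecutive
#' age groups (3.5 vs 7 months, or 7 months vs adult where adult data
#' exist), on z-scored features.
#'
#' @param fm a `feature_matrix` (typically scaled).
#' @param group_a,group_b the two `age_group` labels to compare.
#' @param cutoff stable/varying cutoff on the `[0, 2]` distance scale
#'   (default 1).
#' @param n_bins number of equal-width bins (default 20).
#' @return a `stability_report`: data.frame with `feature`, `distance`,
#'   `call`; attributes `age_pair`, `cutoff` and `binning` (list of bin
#'   edges per feature).
#' @export
classify_features <- function(fm, group_a, group_b, cutoff = 1, n_bins = 20L) {
  for (g in c(group_a, group_b)) {
    if (sum(fm$age_group == g) < 5L) {
      stop("age group '", g, "' absent or has fewer than 5 neurons")
    }
  }
  feats <- feature_cols(fm)
  a_rows <- fm$age_group == group_a
  b_rows <- fm$age_group == group_b
  edges_list <- vector("list", length(feats)); names(edges_list) <- feats
  dist <- numeric(length(feats))
  for (k in seq_along(feats)) {
    va <- fm[[feats[k]]][a_rows]
    vb <- fm[[feats[k]]][b_rows]
    rng <- range(c(va, vb))
    if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)   # constant feature
    edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    edges_list[[k]] <- edges
    dist[k] <- histogram_distance(normalized_histogram(va, edges),
                                  normalized_histogram(vb, edges))
  }
  rep <- data.frame(feature = feats, distance = dist,
                    call = ifelse(dist < cutoff, "stable", "varying"))
  attr(rep, "age_pair") <- c(group_a, group_b)
  attr(rep, "cutoff") <- cutoff
  attr(rep, "binning") <- edges_list
  class(rep) <- c("stability_report", "data.frame")
  rep
}

#' Stable / varying feature sets of a stability report
#' @param report a `stability_report`.
#' @return list with character vectors `stable` and `varying`.
#' @export
stability_partition <- function(report) {
  list(stable = report$feature[report$call == "stable"],
       varying = report$feature[report$call == "varying"])
}
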
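#' Morphological feature names
#'
#' Column order of the per-neuron feature table. `euclidean_Distance` and
#' `n_branches` are the two features later dropped by correlation pruning
#' at the default keep-list.
#' @return character vector of the 15 feature names.
#' @export
feature_names <- function() {
  c("n_stems", "branch_Order", "n_bifs", "bif_ampl_remote",
    "partition_asymmetry", "Length", "Width", "pathDistance", "Height",
    "Depth", "Contraction", "fractal_Dim", "convex_hull",
    "euclidean_Distance", "n_branches")
}

# number of children per node row, plus derived topology masks
topology_tables <- function(tree) {
  nodes <- tree$nodes
  ch <- child_rows(nodes)
  nch <- lengths(ch)
  root <- which(nodes$parent == -1L)
  list(nodes = nodes, ch = ch, nch = nch, root = root,
       xyz = as.matrix(nodes[, c("x", "y", "z")]))
}

#' Topology counts of a dendritic tree
#'
#' Stems are the children of the soma; a node with k >= 2 children counts
#' as (k - 1) bifurcations; tips are childless non-soma nodes; branches are
#' bifurcations plus tips. Branch order of a node is the number of branch
#' points on its path from the soma (each k-furcation passed adds one);
#' `branch_order_max` is the maximum over tips.
#'
#' @param tree a `neuron_tree`.
#' @return named list: `n_stems`, `n_bifurcations`, `n_tips`, `n_branches`,
#'   `branch_order_max`, and `multifurcations` (count of nodes with more
#'   than two children, a data-quality diagnostic).
#' @export
count_topology <- function(tree) {
  tt <- topology_tables(tree)
  nch <- tt$nch; root <- tt$root
  n_stems <- nch[root]
  non_root <- setdiff(seq_len(nrow(tt$nodes)), root)
  n_bif <- sum(pmax(nch[non_root] - 1L, 0L)[nch[non_root] >= 2L])
  n_tips <- sum(nch[non_root] == 0L)
  # order per node: branch points passed strictly between soma and node
  ord <- integer(nrow(tt$nodes))
  for (i in seq_len(nrow(tt$nodes))[-1L]) {   # rows are parent-before-child
    p <- match(tt$nodes$parent[i], tt$nodes$id)
    ord[i] <- ord[p] + if (p != root && nch[p] >= 2L) 1L else 0L
  }
  bomax <- if (n_tips > 0L) max(ord[non_root][nch[non_root] == 0L]) else 0L
  list(n_stems = as.integer(n_stems),
       n_bifurcations = as.integer(n_bif),
       n_tips = as.integer(n_tips),
       n_branches = as.integer(n_bif + n_tips),
       branch_order_max = as.integer(bomax),
       multifurcations = sum(nch[non_root] > 2L))
}

# tips in the subtree rooted at each row (root's value = total tips)
subtree_tips <- function(tt) {
  n <- nrow(tt$nodes)
  tips <- integer(n)
  tips[tt$nch == 0L] <- 1L
  for (i in rev(seq_len(n))) {               # children come after parents
    if (tt$nch[i] > 0L) tips[i] <- sum(tips[tt$ch[[i]]])
  }
  tips[tt$root] <- sum(tips[tt$ch[[tt$root]]])
  tips
}

#' Mean partition asymmetry
#'
#' At a bifurcation whose daughter subtrees hold n1 and n2 tips the
#' asymmetry is |n1 - n2| / (n1 + n2 - 2); a (1,1) bifurcation (0/0 in the
#' formula) is scored 0 ("balanced") by default or excluded. Nodes with k >
#' 2 children contribute the (k - 1) values of a nested first-child versus
#' rest decomposition. The feature is the mean over all contributions.
#'
#' @param tree a `neuron_tree`.
#' @param terminal_bif how to score (1,1) bifurcations: `"zero"` (default)
#'   or `"exclude"`.
#' @return mean asymmetry in `[0, 1]`, or `NA_real_` if the tree has no
#'   bifurcation (or none left after exclusion).
#' @export
partition_asymmetry <- function(tree, terminal_bif = c("zero", "exclude")) {
  terminal_bif <- match.arg(terminal_bif)
  tt <- topology_tables(tree)
  tips <- subtree_tips(tt)
  vals <- numeric(0)
  for (i in setdiff(which(tt$nch >= 2L), tt$root)) {
    t_kids <- tips[tt$ch[[i]]]
    while (length(t_kids) >= 2L) {           # (n1, rest) nested splits
      n1 <- t_kids[1L]; n2 <- sum(t_kids[-1L])
      if (n1 == 1L && n2 == 1L) {
        if (terminal_bif == "zero") vals <- c(vals, 0)
      } else {
        vals <- c(vals, abs(n1 - n2) / (n1 + n2 - 2))
      }
      t_kids <- c(n1 + t_kids[2L], t_kids[-(1:2)])
    }
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Mean branch contraction
#'
#' Per branch segment, the ratio of the straight-line distance between its
#' endpoints to its along-path length; 1 for a straight branch. Zero-length
#' segments are excluded (with a warning). The feature is the mean over
#' segments.
#'
#' @param tree a `neuron_tree`.
#' @return mean contraction in `(0, 1]`, `NA_real_` if no usable segment.
#' @export
contraction <- function(tree) {
  segs <- extract_branches(tree)
  usable <- segs$path_length > 0
  if (any(!usable)) {
    warning(sum(!usable), " zero-length branch(es) excluded from contraction")
  }
  if (!any(usable)) return(NA_real_)
  mean(segs$euclidean_length[usable] / segs$path_length[usable])
}

#' Arbor length and distances from the soma
#'
#' @param tree a `neuron_tree`.
#' @return named list: `length_total` (sum of inter-node Euclidean edge
#'   lengths over all dendritic edges), `euclidean_distance_max` (largest
#'   straight-line node-to-soma distance) and `path_distance_max` (largest
#'   along-tree node-to-soma distance), all in the coordinate units (um).
#' @export
arbor_lengths <- function(tree) {
  d <- node_distances(tree)
  list(length_total = sum(d$edge_len),
       euclidean_distance_max = max(c(0, d$euclid)),
       path_distance_max = max(c(0, d$path)))
}

# per non-root node: edge length to parent, cumulative path distance and
# Euclidean distance from the soma
node_distances <- function(tree) {
  tt <- topology_tables(tree)
  nodes <- tt$nodes; xyz <- tt$xyz
  n <- nrow(nodes)
  p <- match(nodes$parent, nodes$id)
  edge_len <- numeric(n); path <- numeric(n)
  for (i in seq_len(n)[-1L]) {
    edge_len[i] <- sqrt(sum((xyz[i, ] - xyz[p[i], ])^2))
    path[i] <- path[p[i]] + edge_len[i]
  }
  euclid <- sqrt(colSums((t(xyz) - xyz[tt$root, ])^2))
  non_root <- seq_len(n)[-tt$root]
  list(rows = non_root, edge_len = edge_len[non_root],
       path = path[non_root], euclid = euclid[non_root])
}

#' Mean remote bifurcation amplitude
#'
#' At each bifurcation, take the vector from the branch point to the next
#' bifurcation-or-tip reached in each daughter subtree (following
#' continuation nodes); the amplitude is the angle between the two vectors.
#' Nodes with k > 2 children contribute the (k - 1) consecutive-pair
#' angles. Bifurcations with a zero-length remote vector are excluded with
#' a warning.
#'
#' @param tree a `neuron_tree`.
#' @return mean angle in degrees in `[0, 180]`, `NA_real_` if no usable
#'   bifurcation.
#' @export
bif_amplitude_remote <- function(tree) {
  tt <- topology_tables(tree)
  xyz <- tt$xyz
  # remote endpoint row for the subtree entered at child row k
  remote_of <- function(k) {
    while (tt$nch[k] == 1L) k <- tt$ch[[k]][1L]
    k
  }
  angles <- numeric(0); dropped <- 0L
  for (i in setdiff(which(tt$nch >= 2L), tt$root)) {
    kids <- tt$ch[[i]]
    vs <- lapply(kids, function(k) xyz[remote_of(k), ] - xyz[i, ])
    for (j in seq_len(length(vs) - 1L)) {
      a <- vs[[j]]; b <- vs[[j + 1L]]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) { dropped <- dropped + 1L; next }
      cosang <- min(1, max(-1, sum(a * b) / (na * nb)))
      angles <- c(angles, acos(cosang) * 180 / pi)
    }
  }
  if (dropped > 0L) {
    warning(dropped, " bifurcation(s) with zero-length remote vector excluded")
  }
  if (length(angles) == 0L) return(NA_real_)
  mean(angles)
}

#' Principal-axis-aligned arbor extents
#'
#' The node cloud is rotated onto its principal axes; width, height and
#' depth are the coordinate ranges along the first, second and third axis
#' (sorted descending), making the extents invariant to the reconstruction
#' frame's orientation.
#'
#' @param tree a `neuron_tree` with at least 2 nodes.
#' @return named list `width`, `height`, `depth` in um, with
#'   `width >= height >= depth`.
#' @export
bounding_dims <- function(tree) {
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
  if (nrow(xyz) < 2L) stop("bounding_dims needs at least 2 nodes")
  pc <- stats::prcomp(xyz, center = TRUE, scale. = FALSE)
  ext <- unname(apply(pc$x, 2L, function(v) diff(range(v))))
  ext <- sort(c(ext, numeric(3L))[1:3], decreasing = TRUE)
  list(width = ext[1L], height = ext[2L], depth = ext[3L])
}

#' Fractal dimension of the arbor
#'
#' Ordinary least-squares slope of log(path distance from soma) on
#' log(Euclidean distance from soma), one point per non-soma node; the
#' soma and zero-distance nodes are excluded. A perfectly radial arbor has
#' slope 1; tortuosity pushes the slope above 1.
#'
#' @param tree a `neuron_tree`.
#' @return the slope (dimensionless), `NA_real_` if fewer than 3 usable
#'   nodes.
#' @export
fractal_dimension <- function(tree) {
  d <- node_distances(tree)
  ok <- d$euclid > 0 & d$path > 0
  if (sum(ok) < 3L) return(NA_real_)
  lx <- log(d$euclid[ok]); ly <- log(d$path[ok])
  if (stats::var(lx) == 0) return(NA_real_)
  stats::cov(lx, ly) / stats::var(lx)
}

#' Dendritic field (convex hull) area
#'
#' Area of the 2D convex hull of the dendrite-node projections; the
#' paper-style proxy for dendritic field size. Defaults to the file's
#' (x, y) plane; `plane = "pca"` projects onto the first two principal
#' axes of the node cloud instead.
#'
#' @param tree a `neuron_tree`.
#' @param plane `"xy"` (default) or `"pca"`.
#' @return hull area in um^2; 0 with a warning when all projections are
#'   collinear.
#' @export
convex_hull_area <- function(tree, plane = c("xy", "pca")) {
  plane <- match.arg(plane)
  tt <- topology_tables(tree)
  keep <- seq_len(nrow(tt$nodes))[-tt$root]
  if (plane == "xy") {
    pts <- tt$xyz[keep, c(1L, 2L), drop = FALSE]
  } else {
    pc <- stats::prcomp(tt$xyz[keep, , drop = FALSE], center = TRUE)
    pts <- pc$x[, 1:2, drop = FALSE]
  }
  polygon_area_of_hull(pts)
}

# shoelace area of the convex hull of a 2-column point matrix
polygon_area_of_hull <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3L) {
    warning("degenerate point set: convex hull area is 0")
    return(0)
  }
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(h) < 3L) {
    warning("collinear points: convex hull area is 0")
    return(0)
  }
  x <- pts[h, 1L]; y <- pts[h, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Compute the 15-feature morphometric vector of a neuron
#'
#' Features undefined on a given tree (e.g. partition asymmetry of an
#' unbranched arbor) are carried as `NA`, never as 0.
#'
#' @param tree a `neuron_tree`.
#' @param hull_plane projection plane for [convex_hull_area()].
#' @return named numeric vector in the order of [feature_names()].
#' @export
compute_feature_vector <- function(tree, hull_plane = "xy") {
  topo <- count_topology(tree)
  len <- arbor_lengths(tree)
  dims <- bounding_dims(tree)
  v <- c(
    n_stems = topo$n_stems,
    branch_Order = topo$branch_order_max,
    n_bifs = topo$n_bifurcations,
    bif_ampl_remote = bif_amplitude_remote(tree),
    partition_asymmetry = partition_asymmetry(tree),
    Length = len$length_total,
    Width = dims$width,
    pathDistance = len$path_distance_max,
    Height = dims$height,
    Depth = dims$depth,
    Contraction = contraction(tree),
    fractal_Dim = fractal_dimension(tree),
    convex_hull = convex_hull_area(tree, plane = hull_plane),
    euclidean_Distance = len$euclidean_distance_max,
    n_branches = topo$n_branches
  )
  v[feature_names()]
}
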
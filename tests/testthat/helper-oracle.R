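# Independent brute-force oracle for the 15 morphological features.
# Written as plain recursive traversals over the parent table, with its
# own hull (Jarvis march), its own extent rotation (eigen on the explicit
# covariance) and its own regression slope, so it shares no code path with
# the package implementation.

oracle_children <- function(nodes) {
  lapply(seq_len(nrow(nodes)),
         function(i) which(nodes$parent == nodes$id[i]))
}

oracle_tips_below <- function(nodes, ch, i) {
  if (length(ch[[i]]) == 0L) return(1L)
  sum(vapply(ch[[i]], function(k) oracle_tips_below(nodes, ch, k), 1L))
}

oracle_features <- function(tree) {
  nodes <- tree$nodes
  ch <- oracle_children(nodes)
  root <- which(nodes$parent == -1L)
  pt <- function(i) c(nodes$x[i], nodes$y[i], nodes$z[i])
  dist3 <- function(i, j) sqrt(sum((pt(i) - pt(j))^2))

  # --- topology, by recursion ---
  n_stems <- length(ch[[root]])
  is_bif <- vapply(seq_len(nrow(nodes)),
                   function(i) i != root && length(ch[[i]]) >= 2L, TRUE)
  n_bifs <- sum(pmax(lengths(ch) - 1L, 0L)[is_bif])
  is_tip <- vapply(seq_len(nrow(nodes)),
                   function(i) i != root && length(ch[[i]]) == 0L, TRUE)
  n_tips <- sum(is_tip)
  max_order <- function(i, ord) {
    if (length(ch[[i]]) == 0L) return(ord)
    add <- if (i != root && length(ch[[i]]) >= 2L) 1L else 0L
    max(vapply(ch[[i]], function(k) max_order(k, ord + add), 1L))
  }
  branch_order_max <- max_order(root, 0L)

  # --- partition asymmetry (nested first-vs-rest at multifurcations) ---
  pa_vals <- numeric(0)
  for (i in which(is_bif)) {
    tk <- vapply(ch[[i]], function(k) oracle_tips_below(nodes, ch, k), 1L)
    while (length(tk) >= 2L) {
      n1 <- tk[1L]; n2 <- sum(tk[-1L])
      pa_vals <- c(pa_vals,
                   if (n1 + n2 == 2L) 0 else abs(n1 - n2) / (n1 + n2 - 2))
      tk <- c(n1 + tk[2L], tk[-(1:2)])
    }
  }
  pa <- if (length(pa_vals)) mean(pa_vals) else NA_real_

  # --- branch segments by recursion ---
  segs <- list()
  walk_branch <- function(start, kid) {
    path <- c(start, kid)
    while (length(ch[[path[length(path)]]]) == 1L) {
      path <- c(path, ch[[path[length(path)]]])
    }
    segs[[length(segs) + 1L]] <<- path
    end <- path[length(path)]
    for (k in ch[[end]]) walk_branch(end, k)
  }
  for (k in ch[[root]]) walk_branch(root, k)
  contraction_vals <- vapply(segs, function(path) {
    plen <- sum(vapply(seq_len(length(path) - 1L),
                       function(s) dist3(path[s], path[s + 1L]), 1))
    if (plen == 0) return(NA_real_)
    dist3(path[1L], path[length(path)]) / plen
  }, 1)
  contraction_mean <- if (all(is.na(contraction_vals))) NA_real_
                      else mean(contraction_vals, na.rm = TRUE)

  # --- lengths and distances from soma ---
  path_dist <- function(i) {
    if (i == root) return(0)
    p <- which(nodes$id == nodes$parent[i])
    path_dist(p) + dist3(i, p)
  }
  pd <- vapply(seq_len(nrow(nodes)), path_dist, 1)
  ed <- vapply(seq_len(nrow(nodes)), function(i) dist3(i, root), 1)
  length_total <- sum(vapply(seq_len(nrow(nodes))[-root], function(i) {
    dist3(i, which(nodes$id == nodes$parent[i]))
  }, 1))

  # --- remote bifurcation amplitude ---
  remote <- function(i) {
    while (length(ch[[i]]) == 1L) i <- ch[[i]]
    i
  }
  ang_vals <- numeric(0)
  for (i in which(is_bif)) {
    vs <- lapply(ch[[i]], function(k) pt(remote(k)) - pt(i))
    for (j in seq_len(length(vs) - 1L)) {
      a <- vs[[j]]; b <- vs[[j + 1L]]
      na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
      if (na == 0 || nb == 0) next
      cz <- min(1, max(-1, sum(a * b) / (na * nb)))
      ang_vals <- c(ang_vals, acos(cz) * 180 / pi)
    }
  }
  ampl <- if (length(ang_vals)) mean(ang_vals) else NA_real_

  # --- principal-axis extents via eigen of the covariance ---
  xyz <- cbind(nodes$x, nodes$y, nodes$z)
  cen <- sweep(xyz, 2L, colMeans(xyz))
  eg <- eigen(stats::cov(cen), symmetric = TRUE)
  proj <- cen %*% eg$vectors
  ext <- sort(apply(proj, 2L, function(v) max(v) - min(v)),
              decreasing = TRUE)

  # --- fractal dimension via lm ---
  ok <- seq_len(nrow(nodes)) != root & ed > 0 & pd > 0
  fd <- if (sum(ok) >= 3L && stats::var(log(ed[ok])) > 0) {
    unname(stats::coef(stats::lm(log(pd[ok]) ~ log(ed[ok])))[2L])
  } else NA_real_

  # --- convex hull area via Jarvis march ---
  hull_area <- oracle_hull_area(cbind(nodes$x, nodes$y)[-root, , drop = FALSE])

  c(n_stems = n_stems, branch_Order = branch_order_max, n_bifs = n_bifs,
    bif_ampl_remote = ampl, partition_asymmetry = pa,
    Length = length_total, Width = ext[1L], pathDistance = max(pd),
    Height = ext[2L], Depth = ext[3L], Contraction = contraction_mean,
    fractal_Dim = fd, convex_hull = hull_area,
    euclidean_Distance = max(ed), n_branches = n_bifs + n_tips)
}

# gift-wrapping hull + shoelace, independent of grDevices::chull
oracle_hull_area <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- order(pts[, 1], pts[, 2])[1L]
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(nrow(pts))) {
      if (r == p) next
      cr <- cross(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0 || (cr == 0 &&
                     sum((pts[r, ] - pts[p, ])^2) >
                     sum((pts[q, ] - pts[p, ])^2))) {
        q <- r
      }
    }
    p <- q
    if (p == start) break
    if (length(hull) > nrow(pts)) break      # numerical safety
  }
  if (length(hull) < 3L) return(0)
  x <- pts[hull, 1]; y <- pts[hull, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
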
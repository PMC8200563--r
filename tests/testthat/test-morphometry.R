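test_that("topology counts match hand enumeration", {
  expect_equal(count_topology(straight_stem())[1:5],
               list(n_stems = 1L, n_bifurcations = 0L, n_tips = 1L,
                    n_branches = 1L, branch_order_max = 0L))
  expect_equal(count_topology(y_tree())[1:5],
               list(n_stems = 1L, n_bifurcations = 1L, n_tips = 2L,
                    n_branches = 3L, branch_order_max = 1L))
  expect_equal(count_topology(balanced_depth2())[1:5],
               list(n_stems = 1L, n_bifurcations = 3L, n_tips = 4L,
                    n_branches = 7L, branch_order_max = 2L))
})

test_that("a trifurcation counts as two bifurcations and is flagged", {
  tree <- make_tree(id = 1:6, type = c(1L, rep(3L, 5L)),
                    x = c(0, 0, -1, 0, 1, -2), y = c(0, 1, 2, 2, 2, 3),
                    z = numeric(6L), radius = rep(0.5, 6L),
                    parent = c(-1L, 1L, 2L, 2L, 2L, 3L))
  topo <- count_topology(tree)
  expect_equal(topo$n_bifurcations, 2L)
  expect_equal(topo$multifurcations, 1L)
  expect_equal(topo$n_tips, 3L)
})

test_that("partition asymmetry follows |n1-n2|/(n1+n2-2) with (1,1) -> 0", {
  expect_equal(partition_asymmetry(balanced_depth2()), 0)
  expect_equal(partition_asymmetry(caterpillar4()), 2 / 3)
  expect_equal(partition_asymmetry(y_tree()), 0)          # single (1,1)
  expect_true(is.na(partition_asymmetry(y_tree(), terminal_bif = "exclude")))
  expect_true(is.na(partition_asymmetry(straight_stem())))
})

test_that("contraction is straight-line over path length, averaged", {
  expect_equal(contraction(straight_stem()), 1.0)
  l_branch <- make_tree(id = 1:3, type = c(1L, 3L, 3L),
                        x = c(0, 1, 1), y = c(0, 0, 1), z = numeric(3L),
                        radius = rep(0.5, 3L), parent = c(-1L, 1L, 2L))
  expect_equal(contraction(l_branch), sqrt(2) / 2, tolerance = 1e-12)
})

test_that("arbor lengths and soma distances are consistent", {
  expect_equal(unlist(arbor_lengths(straight_stem(n = 10, step = 1))),
               c(length_total = 10, euclidean_distance_max = 10,
                 path_distance_max = 10))
  l_stem <- make_tree(id = 1:3, type = c(1L, 3L, 3L),
                      x = c(0, 1, 1), y = c(0, 0, 1), z = numeric(3L),
                      radius = rep(0.5, 3L), parent = c(-1L, 1L, 2L))
  out <- arbor_lengths(l_stem)
  expect_equal(out$length_total, 2)
  expect_equal(out$euclidean_distance_max, sqrt(2))
  expect_equal(out$path_distance_max, 2)
  set.seed(21)
  for (rep in 1:10) {
    out <- arbor_lengths(random_binary_tree(sample(5:50, 1)))
    expect_gte(out$path_distance_max, out$euclidean_distance_max - 1e-12)
  }
})

test_that("remote bifurcation amplitude uses next bifurcation-or-tip", {
  tree <- make_tree(id = 1:4, type = c(1L, 3L, 3L, 3L),
                    x = c(0, 0, 1, 1), y = c(0, 0.5, 1, -1) + c(0, 0, 0.5, 0.5),
                    z = numeric(4L), radius = rep(0.5, 4L),
                    parent = c(-1L, 1L, 2L, 2L))
  # vectors from the bifurcation: (1,1,0) and (1,-1,0)
  expect_equal(bif_amplitude_remote(tree), 90, tolerance = 1e-9)

  opp <- make_tree(id = 1:4, type = c(1L, 3L, 3L, 3L),
                   x = c(0, 0, 2, -2), y = c(0, 1, 1, 1), z = numeric(4L),
                   radius = rep(0.5, 4L), parent = c(-1L, 1L, 2L, 2L))
  expect_equal(bif_amplitude_remote(opp), 180)
  # continuation nodes are skipped on the way to the remote point
  deep <- make_tree(id = 1:6, type = c(1L, rep(3L, 5L)),
                    x = c(0, 0, 0.5, 1.5, -1, -2), y = c(0, 1, 1.5, 2.5, 2, 3),
                    z = numeric(6L), radius = rep(0.5, 6L),
                    parent = c(-1L, 1L, 2L, 3L, 2L, 5L))
  vs <- rbind(c(1.5, 1.5, 0), c(-2, 2, 0))
  want <- acos(sum(vs[1, ] * vs[2, ]) /
                 prod(sqrt(rowSums(vs^2)))) * 180 / pi
  expect_equal(bif_amplitude_remote(deep), want, tolerance = 1e-9)
})

test_that("principal-axis extents are sorted and rotation invariant", {
  box <- make_tree(id = 1:9, type = c(1L, rep(3L, 8L)),
                   x = c(1.5, rep(c(0, 3), 4L)),
                   y = c(1, 0, 0, 2, 2, 0, 0, 2, 2),
                   z = c(0.5, 0, 0, 0, 0, 1, 1, 1, 1),
                   radius = rep(0.5, 9L),
                   parent = c(-1L, 1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L))
  dims <- bounding_dims(box)
  expect_equal(unlist(dims), c(width = 3, height = 2, depth = 1),
               tolerance = 1e-9)
  dims_rot <- bounding_dims(rotate_tree(box))
  expect_equal(unlist(dims_rot), unlist(dims), tolerance = 1e-6)

  line45 <- make_tree(id = 1:3, type = c(1L, 3L, 3L),
                      x = c(0, 2.5, 5) / sqrt(2), y = c(0, 2.5, 5) / sqrt(2),
                      z = numeric(3L), radius = rep(0.5, 3L),
                      parent = c(-1L, 1L, 2L))
  expect_equal(unlist(bounding_dims(line45)),
               c(width = 5, height = 0, depth = 0), tolerance = 1e-9)
})

test_that("fractal dimension is the log-log regression slope", {
  expect_equal(fractal_dimension(straight_stem(n = 10)), 1.0,
               tolerance = 1e-9)
  # construct a tree on which every non-soma node satisfies
  # path = euclid^1.2 exactly. Each stem is soma -> apex -> tip: the apex
  # sits on the unit circle (path = euclid = 1 = 1^1.2), and the tip at
  # euclidean distance e is angled so that its kinked path length equals
  # e^1.2 (law of cosines fixes the apex-tip angle).
  id <- 1L; type <- 1L; x <- 0; y <- 0; z <- 0; parent <- -1L
  for (k in 1:4) {
    e <- k + 1
    d <- e^1.2 - 1                      # required apex-to-tip leg
    cphi <- (1 + e^2 - d^2) / (2 * e)   # angle between apex and tip rays
    phi <- acos(min(1, max(-1, cphi)))
    alpha <- 2 * pi * k / 5
    apex <- c(cos(alpha), sin(alpha))
    tip <- e * c(cos(alpha + phi), sin(alpha + phi))
    id <- c(id, length(id) + 1L, length(id) + 2L)
    type <- c(type, 3L, 3L)
    x <- c(x, apex[1], tip[1]); y <- c(y, apex[2], tip[2]); z <- c(z, 0, 0)
    parent <- c(parent, 1L, length(id) - 1L)
  }
  tree <- make_tree(id, type, x, y, z, rep(0.5, length(id)), parent)
  expect_equal(fractal_dimension(tree), 1.2, tolerance = 1e-9)
  expect_true(is.na(fractal_dimension(straight_stem(n = 2))))
})

test_that("a tortuous arbor has a larger slope than its straightened version", {
  # straightening repositions every node radially at its original path
  # distance (one ray per stem), so path = euclid everywhere and the
  # straightened slope is exactly 1
  straighten <- function(tree) {
    root <- which(tree$nodes$parent == -1L)
    p <- match(tree$nodes$parent, tree$nodes$id)
    n <- n_nodes(tree)
    pd <- numeric(n); stem <- integer(n)
    xyz <- as.matrix(tree$nodes[, c("x", "y", "z")])
    for (i in seq_len(n)[-root]) {
      pd[i] <- pd[p[i]] + sqrt(sum((xyz[i, ] - xyz[p[i], ])^2))
      stem[i] <- if (p[i] == root) i else stem[p[i]]
    }
    for (i in seq_len(n)[-root]) {
      ang <- stem[i] * 2.399963              # golden-angle ray per stem
      tree$nodes$x[i] <- pd[i] * cos(ang)
      tree$nodes$y[i] <- pd[i] * sin(ang)
      tree$nodes$z[i] <- 0
    }
    tree
  }
  # mild tortuosity only: at large tortuosity the euclidean regressor is
  # noisy and errors-in-variables attenuation can push the slope below 1
  for (seed in c(101, 202, 303)) {
    tortuous <- generate_tree(growth_profile(tortuosity = 0.1), seed = seed)
    fd_t <- fractal_dimension(tortuous)
    fd_s <- fractal_dimension(straighten(tortuous))
    expect_equal(fd_s, 1, tolerance = 1e-9)
    expect_gte(fd_t, fd_s)
  }
})

test_that("convex hull area matches known polygons and ignores interior points", {
  sq <- make_tree(id = 1:5, type = c(1L, rep(3L, 4L)),
                  x = c(0.5, 0, 1, 1, 0), y = c(0.5, 0, 0, 1, 1),
                  z = numeric(5L), radius = rep(0.5, 5L),
                  parent = c(-1L, 1L, 2L, 3L, 4L))
  expect_equal(convex_hull_area(sq), 1.0)
  tri <- make_tree(id = 1:4, type = c(1L, rep(3L, 3L)),
                   x = c(0.2, 0, 2, 0), y = c(0.2, 0, 0, 2),
                   z = numeric(4L), radius = rep(0.5, 4L),
                   parent = c(-1L, 1L, 2L, 3L))
  expect_equal(convex_hull_area(tri), 2.0)
  # adding interior nodes leaves the hull unchanged
  set.seed(31)
  for (rep in 1:5) {
    tree <- random_binary_tree(30L)
    a0 <- convex_hull_area(tree)
    xy <- tree$nodes[, c("x", "y")]
    centroid <- colMeans(xy[-1, ])
    tree$nodes <- rbind(tree$nodes,
                        data.frame(id = 999L, type = 3L, x = centroid[1],
                                   y = centroid[2], z = 0, radius = 0.3,
                                   parent = tree$nodes$id[n_nodes(tree)]))
    expect_equal(convex_hull_area(tree), a0, tolerance = 1e-12)
  }
  collinear <- straight_stem(n = 4)
  expect_warning(a <- convex_hull_area(collinear), "collinear|degenerate")
  expect_equal(a, 0)
})

test_that("feature vector is componentwise consistent and NA-aware", {
  tree <- balanced_depth2()
  v <- compute_feature_vector(tree)
  expect_named(v, feature_names())
  expect_equal(unname(v["Contraction"]), contraction(tree))
  expect_equal(unname(v["convex_hull"]), convex_hull_area(tree))
  expect_equal(unname(v["n_bifs"]), 3)

  v0 <- suppressWarnings(compute_feature_vector(straight_stem()))
  expect_true(is.na(v0["partition_asymmetry"]))
  expect_true(is.na(v0["bif_ampl_remote"]))
  expect_equal(unname(v0["n_branches"]), 1)
})

test_that("features are invariant to rigid motion and equivariant to scale", {
  set.seed(17)
  dimensionless <- c("n_stems", "branch_Order", "n_bifs", "bif_ampl_remote",
                     "partition_asymmetry", "Contraction", "fractal_Dim",
                     "n_branches")
  linear <- c("Length", "Width", "pathDistance", "Height", "Depth",
              "euclidean_Distance")
  for (rep in 1:5) {
    tree <- random_binary_tree(sample(15:50, 1))
    v <- compute_feature_vector(tree)
    s <- runif(1, 0.5, 4)
    vs <- compute_feature_vector(scale_tree(tree, s))
    expect_equal(vs[dimensionless], v[dimensionless], tolerance = 1e-6)
    expect_equal(vs[linear], s * v[linear], tolerance = 1e-6)
    expect_equal(unname(vs["convex_hull"]), s^2 * unname(v["convex_hull"]),
                 tolerance = 1e-6)
    vr <- compute_feature_vector(rotate_tree(tree))
    keep <- setdiff(feature_names(), "convex_hull")  # xy-plane hull rotates
    expect_equal(vr[keep], v[keep], tolerance = 1e-6)
  }
})
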
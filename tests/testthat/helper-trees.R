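# hand-built fixture trees, constructed in code

make_tree <- function(id, type, x, y, z, radius, parent, metadata = list()) {
  swc <- sprintf("%d %d %.17g %.17g %.17g %.17g %d",
                 id, type, x, y, z, radius, parent)
  parse_swc(swc, metadata = metadata)
}

# soma + 3-node straight stem along +y, unit spacing
straight_stem <- function(n = 3L, step = 1) {
  make_tree(id = 1:(n + 1L), type = c(1L, rep(3L, n)),
            x = numeric(n + 1L), y = step * (0:n), z = numeric(n + 1L),
            radius = rep(0.5, n + 1L), parent = c(-1L, 1:n))
}

# 1 stem, 1 bifurcation, 2 tips
y_tree <- function() {
  make_tree(id = 1:4, type = c(1L, 3L, 3L, 3L),
            x = c(0, 0, -1, 1), y = c(0, 1, 2, 2), z = numeric(4L),
            radius = rep(0.5, 4L), parent = c(-1L, 1L, 2L, 2L))
}

# 4-tip caterpillar: each bifurcation splits off one tip
# tip-count pairs at the three bifurcations: (3,1), (2,1), (1,1)
caterpillar4 <- function() {
  make_tree(
    id = 1:8, type = c(1L, rep(3L, 7L)),
    x = c(0, 0, -1, 0, -1, 0, -1, 1),
    y = c(0, 1, 1.5, 2, 2.5, 3, 3.5, 3.5),
    z = numeric(8L), radius = rep(0.5, 8L),
    parent = c(-1L, 1L, 2L, 2L, 4L, 4L, 6L, 6L))
}

# balanced binary tree: 1 stem, bifurcations at depths 1 and 2 -> 4 tips
balanced_depth2 <- function() {
  make_tree(
    id = 1:8, type = c(1L, rep(3L, 7L)),
    x = c(0, 0, -1, 1, -1.5, -0.5, 0.5, 1.5),
    y = c(0, 1, 2, 2, 3, 3, 3, 3),
    z = numeric(8L), radius = rep(0.5, 8L),
    parent = c(-1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
}

# random strictly binary tree with n_total nodes (soma included)
random_binary_tree <- function(n_total = 30L, max_stems = 3L) {
  id <- 1L; type <- 1L
  x <- 0; y <- 0; z <- 0; radius <- 2; parent <- -1L
  nch <- c(0L)
  cap <- c(max_stems)                         # soma child capacity
  while (length(id) < n_total) {
    open <- which(nch < cap)
    p <- if (length(open) > 1L) sample(open, 1L) else open
    new <- length(id) + 1L
    id <- c(id, new); type <- c(type, 3L)
    x <- c(x, x[p] + rnorm(1))
    y <- c(y, y[p] + rnorm(1))
    z <- c(z, z[p] + rnorm(1))
    radius <- c(radius, runif(1, 0.2, 1))
    parent <- c(parent, p)
    nch[p] <- nch[p] + 1L
    nch <- c(nch, 0L)
    cap <- c(cap, 2L)
  }
  make_tree(id, type, x, y, z, radius, parent)
}

# rigid rotation of a tree about the soma
rotate_tree <- function(tree, angles = c(0.3, 0.7, 1.1)) {
  cx <- cos(angles); sx <- sin(angles)
  Rx <- rbind(c(1, 0, 0), c(0, cx[1], -sx[1]), c(0, sx[1], cx[1]))
  Ry <- rbind(c(cx[2], 0, sx[2]), c(0, 1, 0), c(-sx[2], 0, cx[2]))
  Rz <- rbind(c(cx[3], -sx[3], 0), c(sx[3], cx[3], 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  xyz <- as.matrix(tree$nodes[, c("x", "y", "z")]) %*% t(R)
  tree$nodes$x <- xyz[, 1]; tree$nodes$y <- xyz[, 2]; tree$nodes$z <- xyz[, 3]
  tree
}

scale_tree <- function(tree, s) {
  tree$nodes$x <- tree$nodes$x * s
  tree$nodes$y <- tree$nodes$y * s
  tree$nodes$z <- tree$nodes$z * s
  tree
}

# gaussian feature matrix for preprocess/ordination tests
gaussian_fm <- function(n, p = 4L, prefix = "f", age_groups = "g1") {
  vals <- matrix(rnorm(n * p), n, p,
                 dimnames = list(NULL, paste0(prefix, seq_len(p))))
  fm <- cbind(data.frame(neuron_id = sprintf("n%04d", seq_len(n)),
                         area = "A",
                         age_group = rep_len(age_groups, n)),
              as.data.frame(vals))
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}
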
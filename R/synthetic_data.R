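#' Growth profile for the stochastic dendrite generator
#'
#' Parameters of a simple recursive branching model, deliberately minimal:
#' enough to steer size-type features (via `radial_scale`,
#' `segment_length_mean`) independently of topology-type features (via
#' `bifurcation_prob`, `prob_decay`, `n_stems_range`), which is what the
#' stability analysis needs to be testable. No claim of biological realism
#' beyond order-of-magnitude plausibility for layer III basal arbors.
#'
#' @param label age-group name attached to trees from this profile.
#' @param n_stems_range integer range for the number of primary dendrites.
#' @param bifurcation_prob probability that an order-0 branch ends in a
#'   bifurcation; decays as `prob_decay^order` with centrifugal order.
#' @param prob_decay per-order decay of the branching probability.
#' @param nodes_per_branch mean number of sampled points per branch.
#' @param segment_length_mean,segment_length_sd step length (um) between
#'   consecutive points of a branch.
#' @param tortuosity magnitude of the random direction perturbation per
#'   step; 0 gives perfectly straight branches (contraction exactly 1).
#' @param bif_angle_mean,bif_angle_sd opening angle (degrees) between the
#'   two daughter branches at a bifurcation.
#' @param radial_scale global multiplier applied to all coordinates;
#'   doubles arbor extents without touching topology.
#' @param flatness compression of the z axis relative to x/y, emulating
#'   the flattened basal skirt (0 < flatness <= 1).
#' @return a `growth_profile` list.
#' @export
growth_profile <- function(label = "group",
                           n_stems_range = c(4L, 6L),
                           bifurcation_prob = 0.9,
                           prob_decay = 0.6,
                           nodes_per_branch = 5L,
                           segment_length_mean = 12,
                           segment_length_sd = 3,
                           tortuosity = 0.15,
                           bif_angle_mean = 70,
                           bif_angle_sd = 15,
                           radial_scale = 1,
                           flatness = 0.25) {
  stopifnot(bifurcation_prob >= 0, bifurcation_prob <= 1,
            radial_scale > 0, tortuosity >= 0,
            flatness > 0, flatness <= 1,
            length(n_stems_range) == 2L,
            n_stems_range[1L] >= 1L,
            n_stems_range[1L] <= n_stems_range[2L])
  structure(as.list(environment()), class = "growth_profile")
}

unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) c(1, 0, 0) else v / n
}

# random unit vector orthogonal to d
rand_perp <- function(d) {
  repeat {
    u <- stats::rnorm(3L)
    u <- u - sum(u * d) * d
    if (sqrt(sum(u^2)) > 1e-8) return(unit(u))
  }
}

#' Generate one synthetic basal dendritic tree
#'
#' Grows a binary tree by recursive branching: each branch is a short
#' random walk whose direction drifts by `tortuosity` per step; at the
#' branch end, growth either bifurcates into two daughters separated by
#' the profile's opening angle (with probability
#' `bifurcation_prob * prob_decay^order`) or terminates. All coordinates
#' are finally multiplied by `radial_scale`. The same seed reproduces the
#' tree node-for-node.
#'
#' @param profile a [growth_profile()].
#' @param seed integer seed.
#' @return a valid `neuron_tree` (soma at the origin, dendrite nodes type
#'   3).
#' @export
generate_tree <- function(profile, seed = 1L) {
  stopifnot(inherits(profile, "growth_profile"))
  set.seed(seed)
  p <- profile
  rows <- list(list(id = 1L, type = 1L, x = 0, y = 0, z = 0,
                    radius = 6, parent = -1L))
  next_id <- 2L

  add_node <- function(pos, radius, parent) {
    rows[[length(rows) + 1L]] <<- list(id = next_id, type = 3L,
                                       x = pos[1L], y = pos[2L], z = pos[3L],
                                       radius = radius, parent = parent)
    next_id <<- next_id + 1L
    next_id - 1L
  }

  grow_branch <- function(pos, dir, order, parent_id) {
    n_steps <- max(2L, stats::rpois(1L, p$nodes_per_branch))
    radius <- max(0.1, 1.2 * 0.8^order)
    for (s in seq_len(n_steps)) {
      step <- max(0.5, stats::rnorm(1L, p$segment_length_mean,
                                    p$segment_length_sd))
      if (p$tortuosity > 0) {
        dir <- unit(dir + p$tortuosity * stats::rnorm(3L))
      }
      pos <- pos + step * dir
      parent_id <- add_node(pos, radius, parent_id)
    }
    p_bif <- p$bifurcation_prob * p$prob_decay^order
    if (stats::runif(1L) < p_bif) {
      half <- (p$bif_angle_mean +
                 stats::rnorm(1L, 0, p$bif_angle_sd)) * pi / 180 / 2
      half <- min(max(half, 0.05), pi / 2)
      u <- rand_perp(dir)
      d1 <- unit(cos(half) * dir + sin(half) * u)
      d2 <- unit(cos(half) * dir - sin(half) * u)
      grow_branch(pos, d1, order + 1L, parent_id)
      grow_branch(pos, d2, order + 1L, parent_id)
    }
  }

  n_stems <- if (p$n_stems_range[1L] == p$n_stems_range[2L]) {
    p$n_stems_range[1L]
  } else {
    sample(seq(p$n_stems_range[1L], p$n_stems_range[2L]), 1L)
  }
  for (k in seq_len(n_stems)) {
    az <- 2 * pi * (k - 1) / n_stems + stats::runif(1L, 0, pi / 6)
    el <- stats::rnorm(1L, 0, 0.3)
    dir <- unit(c(cos(az) * cos(el), sin(az) * cos(el),
                  p$flatness * sin(el)))
    grow_branch(c(0, 0, 0), dir, 0L, 1L)
  }
  if (length(rows) < 2L) stop("degenerate profile: tree has no dendrite nodes")
  nodes <- data.frame(
    id = vapply(rows, function(r) r$id, 1L),
    type = vapply(rows, function(r) r$type, 1L),
    x = vapply(rows, function(r) r$x, 1),
    y = vapply(rows, function(r) r$y, 1),
    z = vapply(rows, function(r) r$z, 1),
    radius = vapply(rows, function(r) r$radius, 1),
    parent = vapply(rows, function(r) r$parent, 1L))
  nodes$x <- nodes$x * p$radial_scale
  nodes$y <- nodes$y * p$radial_scale
  nodes$z <- nodes$z * p$radial_scale * p$flatness
  structure(list(nodes = nodes, soma_id = 1L,
                 metadata = list(label = p$label, seed = seed)),
            class = "neuron_tree")
}

#' Cohort specification
#'
#' @param profiles list of [growth_profile()]s, one per age group.
#' @param n_per_group tree counts per group (recycled if scalar).
#' @param seed cohort seed; tree i receives the derived seed `seed + i`,
#'   so any individual tree can be regenerated in isolation.
#' @param area area label attached to every tree.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(profiles, n_per_group, seed = 1L, area = "synthetic") {
  n_per_group <- as.integer(rep_len(n_per_group, length(profiles)))
  stopifnot(all(n_per_group >= 1L))
  structure(list(profiles = profiles, n_per_group = n_per_group,
                 seed = as.integer(seed), area = area),
            class = "cohort_spec")
}

#' Default developmental cohort
#'
#' Five age groups shaped like the study's V1 sample (group sizes 25, 41,
#' 28, 33, 105 for 2 days, 3 weeks, 3.5 months, 7 months, adult). All
#' topology parameters are identical across ages; only the radial scale
#' follows the V1-like size trajectory (largest at 2 days, shrinking to
#' 3.5 months, transient growth at 7 months, adult in between), so
#' size-type features change across ages while topology-type features are
#' stationary.
#'
#' @param seed cohort seed.
#' @param n_per_group override the per-group counts.
#' @return a `cohort_spec`.
#' @export
default_cohort_spec <- function(seed = 1L,
                                n_per_group = c(25L, 41L, 28L, 33L, 105L)) {
  ages <- c("2d", "3w", "3.5m", "7m", "adult")
  scales <- c(1.30, 1.15, 0.97, 1.05, 1.00)
  profiles <- Map(function(a, s) growth_profile(label = a, radial_scale = s),
                  ages, scales)
  cohort_spec(unname(profiles), n_per_group, seed = seed, area = "V1like")
}

#' Generate a cohort of synthetic trees
#'
#' @param spec a [cohort_spec()].
#' @return list with `trees` (list of `neuron_tree`) and `labels`
#'   (data.frame `neuron_id`, `area`, `age_group`, `seed`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  trees <- list(); lab <- list()
  counter <- 0L
  for (g in seq_along(spec$profiles)) {
    prof <- spec$profiles[[g]]
    for (i in seq_len(spec$n_per_group[g])) {
      counter <- counter + 1L
      tree_seed <- spec$seed + counter
      trees[[counter]] <- generate_tree(prof, seed = tree_seed)
      lab[[counter]] <- data.frame(
        neuron_id = sprintf("%s_%s_%03d", spec$area, prof$label, i),
        area = spec$area, age_group = prof$label, seed = tree_seed)
    }
  }
  list(trees = trees, labels = do.call(rbind, lab))
}

#' Write a cohort as an SWC directory with a manifest
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (invisibly); files `<neuron_id>.swc`
#'   plus `manifest.csv` appear under `dir`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(nrow(cohort$labels))
  for (i in seq_along(cohort$trees)) {
    files[i] <- paste0(cohort$labels$neuron_id[i], ".swc")
    write_swc(cohort$trees[[i]], file.path(dir, files[i]))
  }
  manifest <- cbind(filename = files, cohort$labels)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read an SWC directory with a manifest back into a cohort
#'
#' @param dir directory containing SWC files and a `manifest.csv` with
#'   columns `filename`, `neuron_id`, `area`, `age_group`.
#' @return list with `trees` and `labels` as in [generate_cohort()].
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  trees <- lapply(file.path(dir, manifest$filename), parse_swc)
  list(trees = trees,
       labels = manifest[, c("neuron_id", "area", "age_group")])
}
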
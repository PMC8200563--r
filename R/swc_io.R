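#' Parse an SWC reconstruction
#'
#' Reads the standard 7-column SWC format (`id type x y z radius parent`,
#' `#` comment lines) into a `neuron_tree`. Both space- and tab-delimited
#' dialects are accepted. Node order in the file is not assumed to be
#' topological: the parser reorders nodes so that every parent precedes its
#' children. Multi-node somas (several type-1 nodes) are collapsed to a
#' single root placed at the first soma node; soma-internal geometry is
#' thereby excluded from all downstream length and hull computations.
#'
#' @param x path to an SWC file, or a character vector of SWC lines.
#' @param metadata optional named list attached to the tree (neuron id,
#'   cortical area, age group, ...).
#' @return a `neuron_tree`: a list with `nodes` (data.frame with columns
#'   `id`, `type`, `x`, `y`, `z`, `radius`, `parent`, parents before
#'   children), `soma_id`, and `metadata` (comment lines preserved under
#'   `$comments`).
#' @examples
#' swc <- c("1 1 0 0 0 1 -1", "2 3 0 5 0 0.5 1", "3 3 0 10 0 0.5 2")
#' tree <- parse_swc(swc)
#' n_nodes(tree)
#' @export
parse_swc <- function(x, metadata = list()) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  lines <- trimws(lines)
  is_comment <- startsWith(lines, "#")
  comments <- lines[is_comment]
  data_lines <- lines[!is_comment & nzchar(lines)]
  if (length(data_lines) == 0L) {
    stop("SWC parse error: no data lines")
  }
  fields <- strsplit(data_lines, "[ \t]+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad) > 0L) {
    stop(sprintf("SWC parse error: line %d does not have 7 fields: '%s'",
                 bad[1L], data_lines[bad[1L]]))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    stop("SWC parse error: non-numeric field")
  }
  nodes <- data.frame(
    id = as.integer(m[, 1L]), type = as.integer(m[, 2L]),
    x = m[, 3L], y = m[, 4L], z = m[, 5L],
    radius = m[, 6L], parent = as.integer(m[, 7L])
  )
  if (any(nodes$radius < 0)) {
    stop("SWC parse error: negative radius at line ",
         which(nodes$radius < 0)[1L])
  }
  if (anyDuplicated(nodes$id)) {
    dup <- nodes$id[duplicated(nodes$id)][1L]
    stop(sprintf("SWC parse error: duplicate node id %d (line %d)",
                 dup, which(nodes$id == dup)[2L]))
  }
  dangling <- !(nodes$parent %in% c(-1L, nodes$id))
  if (any(dangling)) {
    i <- which(dangling)[1L]
    stop(sprintf(
      "SWC parse error: line %d ('%s') refers to undefined parent id %d",
      i, data_lines[i], nodes$parent[i]))
  }
  nodes <- collapse_soma(nodes)
  nodes <- order_topologically(nodes)  # also detects cycles / no root
  metadata$comments <- comments
  tree <- structure(
    list(nodes = nodes, soma_id = nodes$id[nodes$parent == -1L][1L],
         metadata = metadata),
    class = "neuron_tree")
  validate_tree(tree)
  tree
}

# Collapse multi-node somas: the first type-1 node becomes the single root;
# children of any other soma node are re-parented onto it.
collapse_soma <- function(nodes) {
  soma_ids <- nodes$id[nodes$type == 1L]
  if (length(soma_ids) <= 1L) return(nodes)
  root <- soma_ids[1L]
  drop <- setdiff(soma_ids, root)
  nodes$parent[nodes$parent %in% drop] <- root
  nodes <- nodes[!(nodes$id %in% drop), , drop = FALSE]
  nodes$parent[nodes$id == root] <- -1L
  rownames(nodes) <- NULL
  nodes
}

# Breadth-first ordering from the root; errors on multiple roots, cycles,
# or disconnected nodes.
order_topologically <- function(nodes) {
  roots <- which(nodes$parent == -1L)
  if (length(roots) == 0L) {
    stop("SWC parse error: no root node (parent -1)")
  }
  if (length(roots) > 1L) {
    stop("SWC parse error: multiple roots (ids ",
         paste(nodes$id[roots], collapse = ", "), ")")
  }
  idx <- match(nodes$parent, nodes$id)        # NA for root
  children <- split(seq_len(nrow(nodes)), idx)
  order <- integer(nrow(nodes))
  order[1L] <- roots
  head <- 1L; tail <- 1L
  while (head <= tail) {
    kids <- children[[as.character(order[head])]]
    if (!is.null(kids)) {
      order[(tail + 1L):(tail + length(kids))] <- kids
      tail <- tail + length(kids)
    }
    head <- head + 1L
  }
  if (tail < nrow(nodes)) {
    left <- setdiff(seq_len(nrow(nodes)), order[seq_len(tail)])
    stop("SWC parse error: cycle or disconnected component involving node id ",
         nodes$id[left[1L]])
  }
  out <- nodes[order, , drop = FALSE]
  rownames(out) <- NULL
  out
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "neuron_tree"))
  nodes <- tree$nodes
  if (anyDuplicated(nodes$id)) stop("invalid tree: duplicate ids")
  if (sum(nodes$parent == -1L) != 1L) stop("invalid tree: need exactly one root")
  invisible(tree)
}

#' Number of nodes in a neuron tree
#' @param tree a `neuron_tree`.
#' @return integer node count.
#' @export
n_nodes <- function(tree) nrow(tree$nodes)

#' Write a neuron tree in SWC format
#'
#' Emits standard single-space-delimited 7-column SWC with ids renumbered
#' contiguously from 1 in an order where every parent precedes its children.
#'
#' @param tree a `neuron_tree`.
#' @param path optional file path; if omitted, the lines are returned.
#' @return character vector of SWC lines (invisibly when `path` is given).
#' @export
write_swc <- function(tree, path = NULL) {
  validate_tree(tree)
  nodes <- tree$nodes                       # already parent-before-child
  new_id <- seq_len(nrow(nodes))
  new_parent <- ifelse(nodes$parent == -1L, -1L, match(nodes$parent, nodes$id))
  lines <- sprintf("%d %d %.10g %.10g %.10g %.10g %d",
                   new_id, nodes$type, nodes$x, nodes$y, nodes$z,
                   nodes$radius, new_parent)
  comments <- tree$metadata$comments
  out <- c(comments, lines)
  if (is.null(path)) return(out)
  writeLines(out, path)
  invisible(out)
}

# children indices (row numbers) per row; a list parallel to nodes rows
child_rows <- function(nodes) {
  idx <- match(nodes$parent, nodes$id)
  out <- vector("list", nrow(nodes))
  nz <- !is.na(idx)
  sp <- split(seq_len(nrow(nodes))[nz], idx[nz])
  out[as.integer(names(sp))] <- sp
  out
}

#' Decompose a tree into branch segments
#'
#' A segment runs from the soma or a bifurcation to the next bifurcation or
#' tip, passing only through continuation nodes (one child). Each segment
#' carries its centrifugal order: the number of branch points on the path
#' from the soma to the segment start (stems have order 0). A node with k >
#' 2 children starts k segments and counts as (k - 1) bifurcations for
#' order bookkeeping downstream.
#'
#' @param tree a `neuron_tree`.
#' @return data.frame with one row per segment: `start_row`, `end_row` (row
#'   indices into `tree$nodes`), `order`, `path_length`,
#'   `euclidean_length`, and a list-column `rows` of the full row path
#'   (start node included).
#' @export
extract_branches <- function(tree) {
  validate_tree(tree)
  nodes <- tree$nodes
  ch <- child_rows(nodes)
  nch <- lengths(ch)
  root <- which(nodes$parent == -1L)
  xyz <- as.matrix(nodes[, c("x", "y", "z")])

  segs <- list()
  # stack of (start_row, order); branch start is soma or a branch point
  stack <- list(c(root, 0L))
  while (length(stack) > 0L) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    start <- top[1L]; ord <- top[2L]
    for (kid in ch[[start]]) {
      rows <- c(start, kid)
      cur <- kid
      while (nch[cur] == 1L) {
        cur <- ch[[cur]][1L]
        rows <- c(rows, cur)
      }
      d <- sqrt(rowSums((xyz[rows[-1L], , drop = FALSE] -
                         xyz[rows[-length(rows)], , drop = FALSE])^2))
      segs[[length(segs) + 1L]] <- list(
        start_row = start, end_row = cur, order = ord,
        path_length = sum(d),
        euclidean_length = sqrt(sum((xyz[cur, ] - xyz[start, ])^2)),
        rows = rows)
      if (nch[cur] >= 2L) {
        stack[[length(stack) + 1L]] <- c(cur, ord + nch[cur] - 1L)
      }
    }
  }
  data.frame(
    start_row = vapply(segs, `[[`, 1L, "start_row"),
    end_row = vapply(segs, `[[`, 1L, "end_row"),
    order = vapply(segs, `[[`, 1L, "order"),
    path_length = vapply(segs, `[[`, 1, "path_length"),
    euclidean_length = vapply(segs, `[[`, 1, "euclidean_length"),
    rows = I(lapply(segs, `[[`, "rows"))
  )
}
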
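#' Skeletonize a binary airway mask
#'
#' Reduces the mask to a unit-width voxel skeleton by topological thinning
#' (iterative removal of simple points in six directional subpasses, with
#' curve endpoints preserved), then organizes the skeleton voxels into a
#' graph: nodes are endpoints and junctions (voxels whose skeleton degree is
#' not 2, clustered over 26-adjacency), edges are the chains of degree-2
#' voxels between them.
#'
#' @param mask A [voxel_mask()] with exactly one foreground 26-connected
#'   component.
#' @return An object of class `skeleton_graph`: `nodes` (matrix of 1-based
#'   voxel indices, one row per node), `node_degree`, `edges` (list of voxel
#'   index paths, each including both terminal node voxels), `edge_nodes`
#'   (2-column matrix of node indices per edge), plus the mask `spacing`
#'   and `origin` so paths convert to physical mm.
#' @export
skeletonize <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (!any(mask$voxels)) stop("mask is empty", call. = FALSE)
  comp <- mask_components(mask)
  if (length(comp$sizes) > 1L)
    stop("mask has ", length(comp$sizes),
         " foreground components (sizes ",
         paste(utils::head(comp$sizes, 5), collapse = ", "),
         "); expected exactly one", call. = FALSE)
  skel <- .thin3d_cpp(mask$voxels, dim(mask$voxels))
  build_skeleton_graph(skel, mask)
}

build_skeleton_graph <- function(skel, mask) {
  d <- dim(skel)
  lin <- which(skel)
  if (!length(lin)) stop("thinning produced an empty skeleton", call. = FALSE)
  ijk <- cbind((lin - 1) %% d[1] + 1,
               ((lin - 1) %/% d[1]) %% d[2] + 1,
               (lin - 1) %/% (d[1] * d[2]) + 1)
  n <- length(lin)
  pos <- integer(0)
  # adjacency among skeleton voxels (26-neighbourhood)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  loff <- offs[, 1] + d[1] * offs[, 2] + d[1] * d[2] * offs[, 3]
  lin_sorted <- sort(lin)
  rank_of <- match(lin, lin_sorted)
  inv_rank <- order(rank_of)  # lin index (row) for each sorted position
  adj <- vector("list", n)
  for (k in seq_len(nrow(offs))) {
    cand_ijk <- ijk + matrix(offs[k, ], n, 3, byrow = TRUE)
    ok <- cand_ijk[, 1] >= 1 & cand_ijk[, 2] >= 1 & cand_ijk[, 3] >= 1 &
      cand_ijk[, 1] <= d[1] & cand_ijk[, 2] <= d[2] & cand_ijk[, 3] <= d[3]
    cand <- lin + loff[k]
    hit <- rep(NA_integer_, n)
    p <- findInterval(cand[ok], lin_sorted)
    good <- p > 0 & lin_sorted[pmax(p, 1)] == cand[ok]
    hit[which(ok)[good]] <- inv_rank[p[good]]
    for (i in which(!is.na(hit))) adj[[i]] <- c(adj[[i]], hit[i])
  }
  deg <- lengths(adj)
  is_node <- deg != 2L
  if (!any(is_node)) {
    # pure cycle: promote one voxel to a node so tracing terminates
    is_node[1] <- TRUE
  }
  # cluster adjacent node voxels into single junction nodes
  cluster <- integer(n)
  nid <- 0L
  for (s in which(is_node)) {
    if (cluster[s]) next
    nid <- nid + 1L
    stack <- s
    cluster[s] <- nid
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (nb in adj[[cur]]) {
        if (is_node[nb] && !cluster[nb]) {
          cluster[nb] <- nid
          stack <- c(stack, nb)
        }
      }
    }
  }
  # node voxel = cluster member closest to the cluster centroid
  node_vox <- t(vapply(seq_len(nid), function(cid) {
    mem <- which(cluster == cid)
    ctr <- colMeans(ijk[mem, , drop = FALSE])
    mem_d <- rowSums((ijk[mem, , drop = FALSE] -
                        matrix(ctr, length(mem), 3, byrow = TRUE))^2)
    as.numeric(ijk[mem[which.min(mem_d)], ])
  }, numeric(3)))
  # trace edges: from every node voxel into every chain neighbour (or a
  # directly adjacent other cluster)
  used <- logical(n)
  edges <- list()
  edge_nodes <- NULL
  seen_pair <- character()
  for (s in which(is_node)) {
    for (nb in adj[[s]]) {
      if (is_node[nb]) {
        if (cluster[nb] == cluster[s]) next
        key <- paste(sort(c(cluster[s], cluster[nb])), collapse = "-")
        if (key %in% seen_pair) next
        seen_pair <- c(seen_pair, key)
        edges[[length(edges) + 1L]] <- ijk[c(s, nb), , drop = FALSE]
        edge_nodes <- rbind(edge_nodes, c(cluster[s], cluster[nb]))
        next
      }
      if (used[nb]) next
      path <- c(s, nb)
      prev <- s
      cur <- nb
      while (!is_node[cur]) {
        used[cur] <- TRUE
        nxt <- setdiff(adj[[cur]], prev)
        if (!length(nxt)) break  # dangling chain (shouldn't happen)
        # prefer continuing along the chain; junction-adjacent chain voxels
        # can see several cluster members
        nxt <- nxt[1]
        path <- c(path, nxt)
        prev <- cur
        cur <- nxt
      }
      edges[[length(edges) + 1L]] <- ijk[path, , drop = FALSE]
      edge_nodes <- rbind(edge_nodes, c(cluster[s], cluster[cur]))
    }
  }
  structure(list(nodes = node_vox,
                 node_degree = tabulate(as.vector(edge_nodes), nid),
                 edges = edges,
                 edge_nodes = edge_nodes,
                 spacing = mask$spacing, origin = mask$origin,
                 dims = d),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph: %d nodes, %d edges>\n", nrow(x$nodes),
              length(x$edges)))
  invisible(x)
}

#' Root a skeleton graph and prune spurs into a centerline tree
#'
#' Picks the tracheal end (the node nearest `root_hint` when given,
#' otherwise the most cranial endpoint), orients every edge away from it,
#' iteratively removes leaf branches shorter than `min_spur_mm` (never the
#' root branch), merges the degree-2 chains the removals leave behind, and
#' returns the result as a [centerline_tree()] with points in physical mm
#' ordered proximal to distal. Junction endpoints of adjacent branches share
#' the junction voxel's physical center, so parent-child continuity is
#' exact.
#'
#' @param graph A [skeletonize()] result.
#' @param mask The mask the skeleton came from (used for the default spur
#'   threshold).
#' @param min_spur_mm Leaf branches shorter than this are removed. Default:
#'   twice the mean tube radius estimated as `sqrt(V / (pi * L))` from the
#'   mask volume V and total skeleton length L.
#' @param root_hint Optional physical mm point near the tracheal end.
#' @return A [centerline_tree()] (unlabeled).
#' @export
root_and_prune <- function(graph, mask, min_spur_mm = NULL, root_hint = NULL) {
  stopifnot(inherits(graph, "skeleton_graph"))
  to_mm <- function(ijk) {
    sweep(sweep(rbind(ijk) - 1, 2, graph$spacing, "*"), 2, graph$origin, "+")
  }
  node_mm <- to_mm(graph$nodes)
  edges_mm <- lapply(graph$edges, function(e) {
    p <- to_mm(e)
    keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                               p[-nrow(p), , drop = FALSE])^2) > 0)
    p[keep, , drop = FALSE]
  })
  en <- graph$edge_nodes
  if (is.null(min_spur_mm)) {
    vol_mm3 <- sum(mask$voxels) * prod(mask$spacing)
    total_len <- sum(vapply(edges_mm, polyline_length, numeric(1)))
    r_est <- sqrt(vol_mm3 / (pi * max(total_len, 1e-6)))
    min_spur_mm <- 2 * r_est
  }
  deg <- tabulate(as.vector(en), nrow(graph$nodes))
  if (!any(deg == 1L)) stop("skeleton graph has no endpoint", call. = FALSE)
  root_node <- if (!is.null(root_hint)) {
    which.min(rowSums(sweep(node_mm, 2, as.numeric(root_hint), "-")^2))
  } else {
    ends <- which(deg == 1L)
    ends[which.max(node_mm[ends, 3])]
  }

  alive <- rep(TRUE, length(edges_mm))
  repeat {
    changed <- FALSE
    deg <- tabulate(as.vector(en[alive, , drop = FALSE]), nrow(node_mm))
    # prune short leaf edges whose far node is a non-root endpoint
    for (e in which(alive)) {
      for (side in 1:2) {
        far <- en[e, side]
        if (deg[far] == 1L && far != root_node &&
            polyline_length(edges_mm[[e]]) < min_spur_mm) {
          alive[e] <- FALSE
          changed <- TRUE
          break
        }
      }
    }
    deg <- tabulate(as.vector(en[alive, , drop = FALSE]), nrow(node_mm))
    # merge pass-through nodes (degree 2, not root)
    for (v in seq_along(deg)) {
      if (deg[v] != 2L || v == root_node) next
      inc <- which(alive & (en[, 1] == v | en[, 2] == v))
      if (length(inc) != 2L) next
      e1 <- inc[1]; e2 <- inc[2]
      p1 <- edges_mm[[e1]]
      if (en[e1, 2] != v) { p1 <- p1[nrow(p1):1, , drop = FALSE]; en[e1, ] <- rev(en[e1, ]) }
      p2 <- edges_mm[[e2]]
      if (en[e2, 1] != v) { p2 <- p2[nrow(p2):1, , drop = FALSE]; en[e2, ] <- rev(en[e2, ]) }
      merged <- rbind(p1, p2[-1, , drop = FALSE])
      edges_mm[[e1]] <- merged
      en[e1, ] <- c(en[e1, 1], en[e2, 2])
      alive[e2] <- FALSE
      changed <- TRUE
      deg <- tabulate(as.vector(en[alive, , drop = FALSE]), nrow(node_mm))
    }
    if (!changed) break
  }

  edges_mm <- edges_mm[alive]
  en <- en[alive, , drop = FALSE]
  # replace terminal points with the shared node coordinates (junction
  # centers), then orient away from the root by BFS
  for (e in seq_along(edges_mm)) {
    p <- edges_mm[[e]]
    p[1, ] <- node_mm[en[e, 1], ]
    p[nrow(p), ] <- node_mm[en[e, 2], ]
    keep <- c(TRUE, rowSums((p[-1, , drop = FALSE] -
                               p[-nrow(p), , drop = FALSE])^2) > 0)
    edges_mm[[e]] <- p[keep, , drop = FALSE]
  }
  nb <- lapply(seq_len(nrow(node_mm)), function(v)
    which(en[, 1] == v | en[, 2] == v))
  branch_rows <- list()
  visited_edge <- rep(FALSE, length(edges_mm))
  queue <- list(list(node = root_node, parent_branch = NA_character_))
  bid <- 0L
  while (length(queue)) {
    cur <- queue[[1]]
    queue <- queue[-1]
    for (e in nb[[cur$node]]) {
      if (visited_edge[e]) next
      visited_edge[e] <- TRUE
      p <- edges_mm[[e]]
      far <- if (en[e, 1] == cur$node) en[e, 2] else en[e, 1]
      if (en[e, 1] != cur$node) p <- p[nrow(p):1, , drop = FALSE]
      id <- paste0("b", bid)
      bid <- bid + 1L
      branch_rows[[length(branch_rows) + 1L]] <-
        tibble::tibble(id = id, label = NA_character_,
                       parent_id = cur$parent_branch, points = list(p))
      queue[[length(queue) + 1L]] <- list(node = far, parent_branch = id)
    }
  }
  branches <- dplyr::bind_rows(branch_rows)
  if (sum(visited_edge) != length(edges_mm))
    stop("skeleton graph is not connected from the chosen root", call. = FALSE)
  centerline_tree(branches, root_id = branches$id[1])
}

#' Locate the main carina and the two main bronchi
#'
#' The carina is the distal endpoint of the root (tracheal) branch; the two
#' children of the root are the main bronchi, told apart by the sign of the
#' mean x-offset of their points from the carina (x grows toward the
#' patient's left in the canonical frame).
#'
#' @param tree A rooted [centerline_tree()] whose root has exactly two
#'   children.
#' @return A list with `carina` (mm point), `left_id` and `right_id` (branch
#'   ids of the left and right main bronchus).
#' @export
find_carina <- function(tree) {
  stopifnot(inherits(tree, "centerline_tree"))
  kids <- tree_children(tree, tree$root_id)
  if (length(kids) != 2L)
    stop("root has ", length(kids),
         " children; expected 2 main bronchi (re-prune or pass a root hint)",
         call. = FALSE)
  rp <- branch_points(tree, tree$root_id)
  carina <- rp[nrow(rp), ]
  mean_x <- vapply(kids, function(id)
    mean(branch_points(tree, id)[, 1]) - carina[1], numeric(1))
  list(carina = carina,
       left_id = kids[which.max(mean_x)],
       right_id = kids[which.min(mean_x)])
}

#' Extract a rooted centerline tree from a mask in one call
#'
#' [skeletonize()], [root_and_prune()], then (by default) interior
#' smoothing ([smooth_centerline()]) and junction refinement
#' ([refine_junctions()]) to undo voxel jitter and the junction-wedge bias
#' of raw voxel skeletons.
#'
#' @inheritParams root_and_prune
#' @inheritParams skeletonize
#' @param refine Apply smoothing and junction refinement (recommended for
#'   any metric use of the centerline).
#' @return A [centerline_tree()].
#' @export
extract_centerline <- function(mask, min_spur_mm = NULL, root_hint = NULL,
                               refine = TRUE) {
  tree <- root_and_prune(skeletonize(mask), mask, min_spur_mm = min_spur_mm,
                         root_hint = root_hint)
  if (refine)
    tree <- refine_junctions(recenter_centerline(smooth_centerline(tree),
                                                 mask))
  tree
}
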
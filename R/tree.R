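#' Rooted centerline tree of the bronchial airway
#'
#' A `centerline_tree` holds the medial curves of an airway segmentation as
#' a rooted tree. Branches live in a tibble with one row per branch and a
#' `points` list-column: each element is an n x 3 matrix of physical
#' millimetre coordinates ordered proximal to distal. The root branch is the
#' trachea; every non-root branch starts where its parent ends.
#'
#' @param branches A data frame (or tibble) with columns `id` (unique
#'   character), `label` (character, `NA` when unlabeled), `parent_id`
#'   (character, `NA` for the root) and `points` (list of n x 3 numeric
#'   matrices, n >= 2).
#' @param root_id Id of the root (trachea) branch.
#' @param schema_id Label schema the branch labels belong to (`"human"`,
#'   `"porcine"`, or a custom id); `NA` for unlabeled trees.
#' @return An object of class `centerline_tree`.
#' @seealso [validate_tree()], [path_to_root()], [label_schema()]
#' @export
centerline_tree <- function(branches, root_id, schema_id = NA_character_) {
  branches <- tibble::as_tibble(branches)
  need <- c("id", "label", "parent_id", "points")
  if (!all(need %in% names(branches)))
    stop("branches must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  branches$id <- as.character(branches$id)
  branches$label <- as.character(branches$label)
  branches$parent_id <- as.character(branches$parent_id)
  branches$points <- lapply(branches$points, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y", "z")
    p
  })
  structure(list(branches = branches, root_id = as.character(root_id),
                 schema_id = schema_id),
            class = "centerline_tree")
}

#' @export
print.centerline_tree <- function(x, ...) {
  nlab <- sum(!is.na(x$branches$label))
  cat(sprintf("<centerline_tree: %d branches (%d labeled%s), root '%s'>\n",
              nrow(x$branches), nlab,
              if (is.na(x$schema_id)) "" else paste0(", schema ", x$schema_id),
              x$root_id))
  invisible(x)
}

#' @export
as_tibble.centerline_tree <- function(x, ...) x$branches

# ---- branch accessors -------------------------------------------------------

tree_branch <- function(tree, id) {
  i <- match(id, tree$branches$id)
  if (is.na(i)) stop("unknown branch id '", id, "'", call. = FALSE)
  as.list(tree$branches[i, ])
}

#' Point matrix of one branch
#'
#' @param tree A [centerline_tree()].
#' @param id Branch id.
#' @return The branch's n x 3 matrix of mm coordinates (proximal first).
#' @export
branch_points <- function(tree, id) {
  i <- match(id, tree$branches$id)
  if (is.na(i)) stop("unknown branch id '", id, "'", call. = FALSE)
  tree$branches$points[[i]]
}

tree_children <- function(tree, id) {
  tree$branches$id[!is.na(tree$branches$parent_id) &
                     tree$branches$parent_id == id]
}

tree_parent <- function(tree, id) {
  i <- match(id, tree$branches$id)
  if (is.na(i)) stop("unknown branch id '", id, "'", call. = FALSE)
  tree$branches$parent_id[i]
}

# ids ordered so parents precede children
tree_order <- function(tree) {
  out <- tree$root_id
  queue <- tree_children(tree, tree$root_id)
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    out <- c(out, cur)
    queue <- c(queue, tree_children(tree, cur))
  }
  out
}

#' Path from the trachea to a branch
#'
#' Walks parent links from the given branch up to the root and returns the
#' ids in trachea-to-branch order. This is the ancestor chain along which
#' deformations accumulate and get subtracted again.
#'
#' @param tree A [centerline_tree()].
#' @param branch_id Branch id present in the tree.
#' @return Character vector of branch ids, first the root, last `branch_id`.
#' @examples
#' tr <- generate_tree(phantom_spec(depth = 2))
#' path_to_root(tr, tr$branches$id[nrow(tr$branches)])
#' @export
path_to_root <- function(tree, branch_id) {
  stopifnot(inherits(tree, "centerline_tree"))
  if (!branch_id %in% tree$branches$id)
    stop("unknown branch id '", branch_id, "'", call. = FALSE)
  path <- character()
  cur <- branch_id
  repeat {
    path <- c(cur, path)
    if (length(path) > nrow(tree$branches))
      stop("parent chain does not terminate (cycle?)", call. = FALSE)
    p <- tree_parent(tree, cur)
    if (is.na(p)) break
    cur <- p
  }
  path
}

#' Check the structural invariants of a centerline tree
#'
#' Verifies that the tree has exactly one root, unique ids, acyclic and
#' consistent parent references, branches with at least two non-duplicate
#' points, child branches starting where their parent ends (within
#' `tol_mm`), and labels drawn from the active schema when one is set.
#'
#' @param tree A [centerline_tree()].
#' @param tol_mm Continuity tolerance in mm for the parent-end/child-start
#'   coincidence (about one voxel diagonal of the source image).
#' @return A tibble with columns `branch_id`, `rule`, `detail`; zero rows
#'   when every invariant holds.
#' @export
validate_tree <- function(tree, tol_mm = 2) {
  stopifnot(inherits(tree, "centerline_tree"))
  bad <- list()
  note <- function(id, rule, detail) {
    bad[[length(bad) + 1L]] <<- tibble::tibble(branch_id = id, rule = rule,
                                               detail = detail)
  }
  br <- tree$branches
  if (anyDuplicated(br$id))
    note(br$id[duplicated(br$id)][1], "unique-ids", "duplicated branch id")
  roots <- br$id[is.na(br$parent_id)]
  if (length(roots) != 1L || !identical(tree$root_id, roots[1]) ||
      !tree$root_id %in% br$id)
    note(tree$root_id, "single-root",
         sprintf("%d parentless branches; root_id '%s'", length(roots),
                 tree$root_id))
  known <- br$parent_id %in% br$id | is.na(br$parent_id)
  for (id in br$id[!known])
    note(id, "parent-exists", "parent_id not present in tree")
  schema <- if (!is.na(tree$schema_id) &&
                tree$schema_id %in% c("human", "porcine"))
    label_schema(tree$schema_id) else NULL
  for (i in seq_len(nrow(br))) {
    id <- br$id[i]
    p <- br$points[[i]]
    if (nrow(p) < 2L) {
      note(id, "min-points", "fewer than 2 points")
      next
    }
    steps <- sqrt(rowSums((p[-1, , drop = FALSE] -
                             p[-nrow(p), , drop = FALSE])^2))
    if (any(steps == 0))
      note(id, "no-duplicate-points", "consecutive duplicate points")
    pid <- br$parent_id[i]
    if (!is.na(pid) && pid %in% br$id) {
      pp <- br$points[[match(pid, br$id)]]
      gap <- sqrt(sum((p[1, ] - pp[nrow(pp), ])^2))
      if (gap > tol_mm)
        note(id, "parent-continuity",
             sprintf("starts %.3f mm from parent end (tol %.3f)", gap, tol_mm))
    }
    if (!is.null(schema) && !is.na(br$label[i]) &&
        !br$label[i] %in% schema$labels)
      note(id, "label-in-schema",
           sprintf("label '%s' not in schema '%s'", br$label[i],
                   tree$schema_id))
  }
  # cycle / connectivity: walk each branch to the root
  for (id in br$id) {
    cur <- id
    n <- 0L
    ok <- TRUE
    while (!is.na(cur)) {
      n <- n + 1L
      if (n > nrow(br)) {
        note(id, "acyclic", "parent chain does not reach the root")
        ok <- FALSE
        break
      }
      j <- match(cur, br$id)
      if (is.na(j)) break
      cur <- br$parent_id[j]
    }
    if (ok && n > nrow(br)) break
  }
  if (length(bad)) dplyr::distinct(dplyr::bind_rows(bad))
  else tibble::tibble(branch_id = character(), rule = character(),
                      detail = character())
}

# ---- polyline helpers -------------------------------------------------------

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# cumulative arclength from the first point, length nrow(p)
polyline_arclength <- function(p) {
  c(0, cumsum(sqrt(rowSums((p[-1, , drop = FALSE] -
                              p[-nrow(p), , drop = FALSE])^2))))
}

# point at arclength fraction f in [0,1]
polyline_at_fraction <- function(p, f) {
  s <- polyline_arclength(p)
  total <- s[length(s)]
  t(vapply(f, function(fi) {
    target <- fi * total
    j <- findInterval(target, s, rightmost.closed = TRUE)
    j <- max(1L, min(j, nrow(p) - 1L))
    seg <- s[j + 1] - s[j]
    w <- if (seg > 0) (target - s[j]) / seg else 0
    p[j, ] * (1 - w) + p[j + 1, ] * w
  }, numeric(3)))
}

# resample to (approximately) uniform arclength spacing in mm
resample_polyline <- function(p, spacing_mm = 1) {
  total <- polyline_length(p)
  n <- max(2L, ceiling(total / spacing_mm) + 1L)
  polyline_at_fraction(p, seq(0, 1, length.out = n))
}

# ---- labeling ---------------------------------------------------------------

#' Label branches by generation against a schema
#'
#' Assigns anatomical labels to a complete bifurcating tree by walking the
#' schema from the trachea down: the root gets `"trachea"`, its two
#' children become the main bronchi (left/right decided by the sign of the
#' mean x-offset from the carina in the LPS-like frame), and each deeper
#' generation takes schema children of its parent's label in a fixed order.
#' Fails when the schema runs out of children for a label that still has
#' descendants to name.
#'
#' @param tree A [centerline_tree()] whose root has exactly two children.
#' @param schema A [label_schema()].
#' @return The tree with labels and `schema_id` set.
#' @export
label_tree <- function(tree, schema = label_schema("human")) {
  stopifnot(inherits(tree, "centerline_tree"), inherits(schema, "label_schema"))
  br <- tree$branches
  lab <- stats::setNames(rep(NA_character_, nrow(br)), br$id)
  lab[tree$root_id] <- "trachea"
  kids <- tree_children(tree, tree$root_id)
  if (length(kids) != 2L)
    stop("root must have exactly 2 children to label main bronchi",
         call. = FALSE)
  carina <- {
    p <- branch_points(tree, tree$root_id)
    p[nrow(p), ]
  }
  mean_x <- vapply(kids, function(id) {
    mean(branch_points(tree, id)[, 1]) - carina[1]
  }, numeric(1))
  # x grows to the patient's left: larger mean x = left main bronchus
  lab[kids[which.max(mean_x)]] <- "LMB"
  lab[kids[which.min(mean_x)]] <- "RMB"
  queue <- kids
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    ch <- tree_children(tree, cur)
    if (!length(ch)) next
    avail <- schema_children(schema, lab[[cur]])
    if (length(avail) < length(ch))
      stop("schema '", schema$schema_id, "' has ", length(avail),
           " children for '", lab[[cur]], "' but the tree needs ",
           length(ch), call. = FALSE)
    for (k in seq_along(ch)) lab[ch[k]] <- avail[k]
    queue <- c(queue, ch)
  }
  tree$branches$label <- unname(lab[tree$branches$id])
  tree$schema_id <- schema$schema_id
  tree
}

#' Transfer labels from a reference tree by spatial matching
#'
#' Labels an unlabeled (typically skeleton-extracted) tree by matching each
#' of its branches to the closest labeled branch of a reference tree in the
#' same physical space, using the symmetric mean closest-point distance on
#' arclength-resampled polylines. Matches beyond `max_dist_mm` stay
#' unlabeled.
#'
#' @param tree Tree to label.
#' @param reference Labeled tree in the same physical space.
#' @param max_dist_mm Reject matches with mean distance above this.
#' @return `tree` with labels copied from its matches and `schema_id` taken
#'   from the reference.
#' @export
transfer_labels <- function(tree, reference, max_dist_mm = 10) {
  stopifnot(inherits(tree, "centerline_tree"),
            inherits(reference, "centerline_tree"))
  ref <- reference$branches[!is.na(reference$branches$label), ]
  refres <- lapply(ref$points, resample_polyline, spacing_mm = 1)
  lab <- rep(NA_character_, nrow(tree$branches))
  for (i in seq_len(nrow(tree$branches))) {
    p <- resample_polyline(tree$branches$points[[i]], spacing_mm = 1)
    d <- vapply(refres, function(q) mean_closest_distance(p, q), numeric(1))
    j <- which.min(d)
    if (length(j) && d[j] <= max_dist_mm) lab[i] <- ref$label[j]
  }
  # a reference label may win several extracted branches; keep the closest
  for (lb in unique(stats::na.omit(lab))) {
    hits <- which(lab == lb)
    if (length(hits) > 1L) {
      q <- refres[[match(lb, ref$label)]]
      d <- vapply(hits, function(i) {
        mean_closest_distance(resample_polyline(tree$branches$points[[i]], 1), q)
      }, numeric(1))
      lab[setdiff(hits, hits[which.min(d)])] <- NA_character_
    }
  }
  tree$branches$label <- lab
  tree$schema_id <- reference$schema_id
  tree
}

# symmetric mean closest-point distance between two resampled polylines
# (explicit differences: the expanded-square shortcut loses ~1e-7 of
# precision to cancellation, which matters for exact-zero assertions)
mean_closest_distance <- function(p, q) {
  tq <- t(q)
  a <- mean(vapply(seq_len(nrow(p)), function(i)
    sqrt(min(colSums((tq - p[i, ])^2))), numeric(1)))
  tp <- t(p)
  b <- mean(vapply(seq_len(nrow(q)), function(i)
    sqrt(min(colSums((tp - q[i, ])^2))), numeric(1)))
  (a + b) / 2
}
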
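#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Numeric length 3, mm.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L)
  if (max(abs(t(rotation) %*% rotation - diag(3))) > 1e-6 ||
      abs(det(rotation) - 1) > 1e-6)
    stop("rotation must be a proper orthonormal 3x3 matrix", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform: rotation %.3f deg, translation (%.3f, %.3f, %.3f) mm>\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  if (!is.null(attr(x, "rms")))
    cat(sprintf("  landmark residual RMS %.4g mm\n", attr(x, "rms")))
  invisible(x)
}

#' Tidy a rigid transform into one row per matrix entry
#'
#' @param x A [rigid_transform()].
#' @param ... Unused.
#' @return A tibble with columns `component` (`rotation`/`translation`),
#'   `row`, `col`, `value`.
#' @export
tidy.rigid_transform <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(component = "rotation",
                   row = rep(1:3, 3), col = rep(1:3, each = 3),
                   value = as.vector(x$rotation)),
    tibble::tibble(component = "translation", row = 1:3, col = NA_integer_,
                   value = x$translation))
}

#' @export
glance.rigid_transform <- function(x, ...) {
  tibble::tibble(
    rotation_angle_deg = acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi,
    translation_norm_mm = sqrt(sum(x$translation^2)),
    landmark_rms_mm = attr(x, "rms") %||% NA_real_)
}

# closed-form least-squares rigid fit mapping rows of `moving` onto rows of
# `fixed` (Kabsch / orthogonal Procrustes, no scaling)
kabsch <- function(moving, fixed) {
  stopifnot(nrow(moving) == nrow(fixed), nrow(moving) >= 3L)
  mc <- colMeans(moving)
  fc <- colMeans(fixed)
  H <- t(sweep(moving, 2, mc)) %*% sweep(fixed, 2, fc)
  sv <- svd(H)
  s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
  R <- sv$v %*% s %*% t(sv$u)
  t <- fc - as.vector(R %*% mc)
  tf <- rigid_transform(R, t)
  res <- sweep(moving %*% t(R), 2, t, "+") - fixed
  attr(tf, "rms") <- sqrt(mean(rowSums(res^2)))
  tf
}

# landmark set used for registration: tracheal proximal end, carina,
# contralateral main bronchus distal end and its points at arclength
# fractions 0.25/0.5/0.75
registration_landmarks <- function(tree, collapsed_side) {
  car <- find_carina(tree)
  contra_id <- if (collapsed_side == "left") car$right_id else car$left_id
  rp <- branch_points(tree, tree$root_id)
  cp <- branch_points(tree, contra_id)
  rbind(rp[1, ],
        car$carina,
        cp[nrow(cp), ],
        polyline_at_fraction(cp, c(0.25, 0.5, 0.75)))
}

#' Register a collapsed centerline tree to the inflated one
#'
#' Rigid (no scaling) landmark registration: the collapsed-side lung is
#' excluded because it carries the deformation signal, and correspondence
#' is built from structures the collapse leaves intact — the tracheal
#' proximal endpoint, the main carina, the distal endpoint of the
#' contralateral main bronchus, and that bronchus resampled at arclength
#' fractions 0.25/0.5/0.75. Solved in closed form by orthogonal Procrustes.
#'
#' @param fixed Inflated-state [centerline_tree()].
#' @param moving Collapsed-state tree to be aligned onto `fixed`.
#' @param collapsed_side `"left"` or `"right"`: which lung is collapsed.
#' @param dense_refine When both trees carry matching labels, extend the
#'   correspondence set to arclength-resampled points of every matched
#'   branch on the unaffected structures (trachea and the whole
#'   contralateral subtree) and re-solve; hundreds of correspondences
#'   average the per-landmark extraction noise down by an order of
#'   magnitude.
#' @return A [rigid_transform()] mapping `moving` into the frame of
#'   `fixed`; the landmark residual RMS (mm) is attached as attribute
#'   `"rms"`.
#' @export
landmark_registration <- function(fixed, moving,
                                  collapsed_side = c("left", "right"),
                                  dense_refine = TRUE) {
  collapsed_side <- match.arg(collapsed_side)
  lf <- registration_landmarks(fixed, collapsed_side)
  lm <- registration_landmarks(moving, collapsed_side)
  # collinearity guard: landmarks must span a plane
  sv <- svd(sweep(lf, 2, colMeans(lf)))$d
  if (sv[2] < 1e-6 * max(sv[1], 1))
    stop("registration landmarks are (near-)collinear; underdetermined",
         call. = FALSE)
  tf <- kabsch(lm, lf)
  if (!dense_refine) return(tf)
  ref <- reference_correspondences(fixed, moving, collapsed_side)
  if (is.null(ref)) return(tf)
  kabsch(ref$moving, ref$fixed)
}

# dense arclength-matched correspondences over the collapse-unaffected
# structures: trachea plus every matched labeled branch outside the
# collapsed-side main bronchus subtree
reference_correspondences <- function(fixed, moving, collapsed_side,
                                      n_per_branch = 15L) {
  fl <- fixed$branches$label
  ml <- moving$branches$label
  matched <- intersect(fl[!is.na(fl)], ml[!is.na(ml)])
  if (!length(matched)) return(NULL)
  main <- if (collapsed_side == "left") "LMB" else "RMB"
  on_collapsed_side <- function(tree, lb) {
    id <- tree$branches$id[match(lb, tree$branches$label)]
    path <- path_to_root(tree, id)
    main %in% tree$branches$label[match(path, tree$branches$id)]
  }
  use <- matched[!vapply(matched, function(lb)
    on_collapsed_side(fixed, lb) || on_collapsed_side(moving, lb), TRUE)]
  if (length(use) < 2L) return(NULL)
  fr <- seq(0, 1, length.out = n_per_branch)
  fpts <- do.call(rbind, lapply(use, function(lb) polyline_at_fraction(
    fixed$branches$points[[match(lb, fixed$branches$label)]], fr)))
  mpts <- do.call(rbind, lapply(use, function(lb) polyline_at_fraction(
    moving$branches$points[[match(lb, moving$branches$label)]], fr)))
  list(fixed = fpts, moving = mpts)
}

#' Apply a rigid transform to every point of a tree
#'
#' @param tree A [centerline_tree()].
#' @param transform A [rigid_transform()].
#' @return The tree with every point `p` replaced by
#'   `rotation %*% p + translation`; topology, labels and ordering are
#'   untouched.
#' @export
apply_transform <- function(tree, transform) {
  stopifnot(inherits(tree, "centerline_tree"),
            inherits(transform, "rigid_transform"))
  R <- transform$rotation
  tr <- transform$translation
  tree$branches$points <- lapply(tree$branches$points, function(p) {
    q <- sweep(p %*% t(R), 2, tr, "+")
    colnames(q) <- c("x", "y", "z")
    q
  })
  tree
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(a, b)` is the transform applying `b` first, then `a`;
#' `invert_transform(a)` undoes `a`.
#'
#' @param a,b [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(a) {
  rigid_transform(t(a$rotation), -as.vector(t(a$rotation) %*% a$translation))
}
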
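# Forward collapse model: push a measured deformation table back onto an
# inflated centerline tree.

deg2rad <- function(a) a * pi / 180

# Minimal rotation taking unit vector u onto unit vector w (Rodrigues).
rotation_between <- function(u, w) {
  u <- u / sqrt(sum(u^2))
  w <- w / sqrt(sum(w^2))
  v <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  s <- sqrt(sum(v^2))
  c_ <- sum(u * w)
  if (s < 1e-15) {
    if (c_ > 0) return(diag(3))
    # antipodal: rotate 180 deg about any axis orthogonal to u
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- a - sum(a * u) * u
    ax <- ax / sqrt(sum(ax^2))
    return(2 * outer(ax, ax) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# Unit direction whose view angles are closest (least squares) to the
# targets. Each defined view constrains the direction to the half-plane
# spanned by the out-of-plane axis and the in-plane ray at the target
# angle; the intersection is found as the smallest eigenvector of the
# stacked plane normals. `ref` breaks the sign and degenerate ties.
direction_from_angles <- function(theta_axial, theta_coronal, theta_sagittal,
                                  ref) {
  normals <- list()
  if (!is.na(theta_axial)) {
    a <- deg2rad(theta_axial)
    normals <- c(normals, list(c(cos(a), -sin(a), 0)))
  }
  if (!is.na(theta_coronal)) {
    a <- deg2rad(theta_coronal)
    normals <- c(normals, list(c(0, cos(a), -sin(a))))
  }
  if (!is.na(theta_sagittal)) {
    a <- deg2rad(theta_sagittal)
    normals <- c(normals, list(c(cos(a), 0, -sin(a))))
  }
  if (length(normals) < 2L) return(NULL)
  M <- Reduce("+", lapply(normals, function(n) outer(n, n)))
  eg <- eigen(M, symmetric = TRUE)
  w <- eg$vectors[, 3]
  score <- function(v) {
    tot <- 0
    for (spec in list(c("axial", theta_axial), c("coronal", theta_coronal),
                      c("sagittal", theta_sagittal))) {
      tgt <- as.numeric(spec[2])
      if (is.na(tgt)) next
      got <- projected_angle_or_na(v, spec[1])
      tot <- tot + if (is.na(got)) 180 else abs(wrap_angle(got - tgt))
    }
    tot
  }
  if (score(-w) < score(w)) w <- -w
  w
}

# Axis rotation that increases the projected angle of one view by `deg`
# while leaving the out-of-plane component untouched (used when only one
# view is defined).
view_rotation <- function(view, deg) {
  a <- deg2rad(deg)
  switch(view,
         axial = matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                        3, 3),
         coronal = matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)),
                          3, 3),
         sagittal = matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)),
                           3, 3))
}

# scale points along unit direction d about anchor a by factor s
scale_along <- function(p, a, d, s) {
  rel <- sweep(p, 2, a)
  t_ <- rel %*% d
  q <- rel + (s - 1) * (t_ %*% t(d))
  sweep(q, 2, a, "+")
}

#' Apply a deformation table onto an inflated centerline tree
#'
#' The forward model that synthesizes the artificially collapsed
#' centerline. Branches are visited root to leaves. Each branch is (1)
#' re-anchored so its proximal endpoint meets its already-deformed parent's
#' distal endpoint, (2) rotated about that endpoint so its fitted direction
#' attains the view angles implied by its cumulative angular deformation
#' (the sum of independent per-view deltas along its trachea path — the
#' target direction is reconstructed from the three view angles and the
#' branch rotated onto it by the minimal rotation), and (3) scaled along
#' its fitted direction until its centerline length equals the inflated
#' length plus its own length delta (floored at 5 % of the original).
#' Branches without a table entry inherit steps (1)-(2) with zero own
#' deformation. Diameter deltas in the table are reporting-only and are not
#' applied.
#'
#' @param inflated A labeled [centerline_tree()].
#' @param table An [independent_deformations()] table (or any tibble with
#'   `branch_label`, `dtheta_*_deg`, `dlength_mm`, `independent = TRUE`).
#' @return The modeled collapsed [centerline_tree()].
#' @export
apply_deformations <- function(inflated, table) {
  stopifnot(inherits(inflated, "centerline_tree"))
  table <- tibble::as_tibble(table)
  if (!nrow(table)) return(inflated)
  if (!all(table$independent))
    stop("table must contain independent (ancestor-subtracted) deformations",
         call. = FALSE)
  labs <- inflated$branches$label
  unknown <- setdiff(table$branch_label, labs[!is.na(labs)])
  if (length(unknown))
    stop("table labels not in tree: ", paste(unknown, collapse = ", "),
         call. = FALSE)

  br <- inflated$branches
  ord <- tree_order(inflated)
  new_points <- stats::setNames(vector("list", nrow(br)), br$id)
  cum <- stats::setNames(vector("list", nrow(br)), br$id)
  views <- c("axial", "coronal", "sagittal")
  own_of <- function(label) {
    if (is.na(label) || !label %in% table$branch_label)
      return(c(axial = 0, coronal = 0, sagittal = 0, dlength = NA_real_))
    r <- table[match(label, table$branch_label), ]
    c(axial = r$dtheta_axial_deg %||% 0,
      coronal = r$dtheta_coronal_deg %||% 0,
      sagittal = r$dtheta_sagittal_deg %||% 0,
      dlength = r$dlength_mm %||% NA_real_)
  }
  for (id in ord) {
    i <- match(id, br$id)
    p <- br$points[[i]]
    pid <- br$parent_id[i]
    own <- own_of(br$label[i])
    own_ang <- ifelse(is.na(own[views]), 0, own[views])
    cum[[id]] <- if (is.na(pid)) own_ang else cum[[pid]] + own_ang
    # a view whose own delta is flagged undefined carries no target for
    # this branch: excluding it keeps the reconstruction exact in the
    # views that were actually measured
    has_entry <- !is.na(br$label[i]) && br$label[i] %in% table$branch_label
    undefined_view <- has_entry & is.na(own[views])
    # (1) re-anchor to the deformed parent's distal end
    prox <- if (is.na(pid)) p[1, ] else {
      pp <- new_points[[pid]]
      pp[nrow(pp), ]
    }
    p <- sweep(p, 2, p[1, ] - prox)
    # (2) rotate so the fitted direction reaches its cumulative view angles
    u <- fit_branch_vector(p)$direction
    tgt <- vapply(views, function(vw)
      projected_angle_or_na(u, vw, min_inplane = 0.15), numeric(1)) +
      cum[[id]]
    tgt[undefined_view] <- NA_real_
    defined <- !is.na(tgt)
    if (any(abs(cum[[id]]) > 1e-12)) {
      if (sum(defined) >= 2L) {
        w <- direction_from_angles(if (defined[1]) tgt[1] else NA,
                                   if (defined[2]) tgt[2] else NA,
                                   if (defined[3]) tgt[3] else NA, u)
        R <- rotation_between(u, w)
      } else if (sum(defined) == 1L) {
        vw <- views[defined]
        R <- view_rotation(vw, cum[[id]][vw])
      } else R <- diag(3)
      p <- sweep(sweep(p, 2, prox) %*% t(R), 2, prox, "+")
    }
    # (3) length scaling along the (deformed) fitted direction
    if (!is.na(own[["dlength"]])) {
      len0 <- polyline_length(p)
      target <- max(len0 + own[["dlength"]], 0.05 * len0)
      if (abs(target - len0) > 1e-12) {
        d <- fit_branch_vector(p)$direction
        f <- function(s) polyline_length(scale_along(p, p[1, ], d, s)) - target
        s <- tryCatch(stats::uniroot(f, c(1e-3, 20), tol = 1e-10)$root,
                      error = function(e) target / len0)
        p <- scale_along(p, p[1, ], d, s)
      }
    }
    colnames(p) <- c("x", "y", "z")
    new_points[[id]] <- p
  }
  inflated$branches$points <- unname(new_points[inflated$branches$id])
  inflated
}

#' Closest-point distance between two labeled centerline trees
#'
#' Per matched label, the symmetric mean closest-point distance between the
#' two branches after arclength resampling; overall, the per-branch
#' distances averaged with branch-length weights.
#'
#' @param a,b Labeled [centerline_tree()] objects under the same schema.
#' @param resample_mm Resampling step in mm.
#' @return A tibble with `branch_label`, `distance_mm`, `length_mm`; the
#'   length-weighted overall mean is in `attr(, "overall_mm")` and via
#'   [glance()].
#' @export
tree_distance <- function(a, b, resample_mm = 1) {
  stopifnot(inherits(a, "centerline_tree"), inherits(b, "centerline_tree"))
  abr <- a$branches[!is.na(a$branches$label), ]
  bbr <- b$branches[!is.na(b$branches$label), ]
  matched <- intersect(abr$label, bbr$label)
  if (!length(matched)) stop("no matched labels between the trees",
                             call. = FALSE)
  rows <- lapply(matched, function(lb) {
    pa <- resample_polyline(abr$points[[match(lb, abr$label)]], resample_mm)
    pb <- resample_polyline(bbr$points[[match(lb, bbr$label)]], resample_mm)
    tibble::tibble(branch_label = lb,
                   distance_mm = mean_closest_distance(pa, pb),
                   length_mm = polyline_length(
                     abr$points[[match(lb, abr$label)]]))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "overall_mm") <-
    sum(out$distance_mm * out$length_mm) / sum(out$length_mm)
  class(out) <- c("tree_distance", class(out))
  out
}

#' @export
glance.tree_distance <- function(x, ...) {
  tibble::tibble(n_branches = nrow(x),
                 overall_mm = attr(x, "overall_mm"),
                 max_branch_mm = max(x$distance_mm))
}
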
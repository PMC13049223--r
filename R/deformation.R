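#' Least-squares straight vector of a branch
#'
#' Total-least-squares line fit of all points of the branch: the direction
#' is the first principal axis of the point covariance, sign-flipped so it
#' runs proximal to distal (non-negative dot product with distal minus
#' proximal endpoint); the length is the extent of the point projections on
#' the direction; the anchor is the proximal endpoint.
#'
#' @param points An n x 3 matrix of mm coordinates, or a
#'   [centerline_tree()] plus `branch_id`.
#' @param label Optional branch label carried along.
#' @param branch_id Branch id when `points` is a tree (its label is used).
#' @return An object of class `branch_vector`: list with `direction` (unit
#'   3-vector), `length_mm`, `anchor`, `branch_label`.
#' @export
fit_branch_vector <- function(points, label = NA_character_,
                              branch_id = NULL) {
  if (inherits(points, "centerline_tree")) {
    stopifnot(!is.null(branch_id))
    b <- tree_branch(points, branch_id)
    label <- b$label
    points <- b$points[[1]]
  }
  p <- as.matrix(points)
  if (nrow(p) < 2L) stop("need at least 2 points", call. = FALSE)
  ctr <- colMeans(p)
  cen <- sweep(p, 2, ctr)
  if (max(abs(cen)) < 1e-12)
    stop("all points identical; branch vector undefined", call. = FALSE)
  dir <- svd(cen, nu = 0, nv = 1)$v[, 1]
  chord <- p[nrow(p), ] - p[1, ]
  if (sum(dir * chord) < 0) dir <- -dir
  proj <- cen %*% dir
  structure(list(direction = as.numeric(dir),
                 length_mm = as.numeric(max(proj) - min(proj)),
                 anchor = as.numeric(p[1, ]),
                 branch_label = label),
            class = "branch_vector")
}

#' @export
print.branch_vector <- function(x, ...) {
  cat(sprintf("<branch_vector%s: dir (%.3f, %.3f, %.3f), length %.2f mm>\n",
              if (is.na(x$branch_label)) "" else paste0(" ", x$branch_label),
              x$direction[1], x$direction[2], x$direction[3], x$length_mm))
  invisible(x)
}

#' Displacement vector between collapsed and inflated branch vectors
#'
#' The deformation measure per branch: the difference of the scaled branch
#' vectors, collapsed minus inflated, and its norm (the displacement in
#' mm).
#'
#' @param collapsed,inflated [fit_branch_vector()] results for the same
#'   branch label.
#' @return A tibble with one row: `branch_label`, `d_x`, `d_y`, `d_z`,
#'   `d_norm_mm`.
#' @export
displacement <- function(collapsed, inflated) {
  stopifnot(inherits(collapsed, "branch_vector"),
            inherits(inflated, "branch_vector"))
  if (!identical(collapsed$branch_label, inflated$branch_label) &&
      !(is.na(collapsed$branch_label) && is.na(inflated$branch_label)))
    stop("branch labels differ: '", collapsed$branch_label, "' vs '",
         inflated$branch_label, "'", call. = FALSE)
  d <- collapsed$direction * collapsed$length_mm -
    inflated$direction * inflated$length_mm
  tibble::tibble(branch_label = collapsed$branch_label,
                 d_x = d[1], d_y = d[2], d_z = d[3],
                 d_norm_mm = sqrt(sum(d^2)))
}

#' Angle of a 3D vector in an anatomical view plane
#'
#' Full-quadrant arctangent of the vector's projection in the named view:
#' axial uses (x, y), sagittal uses (x, z), coronal uses (y, z); the angle
#' is `atan2(first, second)` in degrees, zero along the second-named axis,
#' in (-180, 180].
#'
#' @param v Numeric length-3 vector.
#' @param view `"axial"`, `"sagittal"` or `"coronal"`.
#' @return Angle in degrees, or an error when both in-plane components are
#'   zero.
#' @examples
#' projected_angle(c(1, 1, 0), "axial")  # 45
#' @export
projected_angle <- function(v, view = c("axial", "sagittal", "coronal")) {
  view <- match.arg(view)
  comp <- switch(view, axial = v[c(1, 2)], sagittal = v[c(1, 3)],
                 coronal = v[c(2, 3)])
  if (all(abs(comp) < 1e-12))
    stop("in-plane projection is the zero vector; angle undefined in the ",
         view, " view", call. = FALSE)
  a <- atan2(comp[1], comp[2]) * 180 / pi
  if (a <= -180) a <- a + 360
  a
}

# wrap degrees into (-180, 180]
wrap_angle <- function(a) {
  w <- ((a + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

# per-view projected angle, NA when undefined; `min_inplane` additionally
# declares the angle undefined when the in-plane magnitude of the unit
# vector is below a floor (within ~asin(min_inplane) of the view axis the
# projected angle is numerically meaningless)
projected_angle_or_na <- function(v, view, min_inplane = 0) {
  if (min_inplane > 0) {
    vn <- v / sqrt(sum(v^2))
    comp <- switch(view, axial = vn[c(1, 2)], sagittal = vn[c(1, 3)],
                   coronal = vn[c(2, 3)])
    if (sqrt(sum(comp^2)) < min_inplane) return(NA_real_)
  }
  tryCatch(projected_angle(v, view), error = function(e) NA_real_)
}

#' Per-view angular deformation between two branch vectors
#'
#' Signed shortest difference of the projected angles, collapsed minus
#' inflated, per view, each wrapped into (-180, 180]. A view in which
#' either vector has a zero in-plane projection is reported `NA`.
#'
#' @inheritParams displacement
#' @return A tibble with one row: `branch_label`, `dtheta_axial_deg`,
#'   `dtheta_coronal_deg`, `dtheta_sagittal_deg`.
#' @export
angular_deformation <- function(collapsed, inflated, min_inplane = 0) {
  stopifnot(inherits(collapsed, "branch_vector"),
            inherits(inflated, "branch_vector"))
  one <- function(view) {
    a <- projected_angle_or_na(collapsed$direction, view, min_inplane)
    b <- projected_angle_or_na(inflated$direction, view, min_inplane)
    if (is.na(a) || is.na(b)) NA_real_ else wrap_angle(a - b)
  }
  tibble::tibble(branch_label = collapsed$branch_label,
                 dtheta_axial_deg = one("axial"),
                 dtheta_coronal_deg = one("coronal"),
                 dtheta_sagittal_deg = one("sagittal"))
}

#' Independent per-branch deformation table for a registered tree pair
#'
#' The central measurement of the package. For every label present in both
#' trees it computes the raw per-view angular change of the fitted branch
#' vectors, then subtracts the raw change of the parent branch so what
#' remains is the branch's own deformation — a rotation of a lobar
#' bronchus no longer shows up in its segmental children. Length changes
#' (and diameter changes when both masks are given), the displacement
#' vector and its norm are attached per branch. Labels present in only one
#' tree are reported in the `"unmatched"` attribute, never silently
#' dropped.
#'
#' @param inflated Labeled inflated-state [centerline_tree()].
#' @param collapsed Labeled collapsed-state tree, already registered into
#'   the inflated frame.
#' @param inflated_mask,collapsed_mask Optional airway masks; when both are
#'   given, per-branch maximal diameters and their differences are
#'   included.
#' @param min_inplane View angles are treated as undefined when the unit
#' direction's in-plane magnitude falls below this floor (default 0.15,
#' i.e. within about 8.6 degrees of the view axis): so close to the axis
#' the projected angle is numerically meaningless and one noisy value
#' would contaminate every descendant through the ancestor subtraction.
#' @param trim_frac Fraction of each branch's arclength excluded at both
#'   ends before fitting the direction used for the view angles. Skeleton
#'   centerlines bend into the junction blobs at their ends; guarding the
#'   fits against those regions leaves the angles unbiased (for a straight
#'   branch the trimmed and untrimmed directions coincide). Displacement
#'   vectors and lengths always use the full branch.
#' @return A tibble of class `deformation_table`, one row per matched
#'   branch: `branch_label`, `d_x`, `d_y`, `d_z`, `d_norm_mm`,
#'   `dtheta_axial_deg`, `dtheta_coronal_deg`, `dtheta_sagittal_deg`
#'   (ancestor-subtracted), `raw_dtheta_*_deg`, `dlength_mm`,
#'   `dlength_pct`, `ddiameter_mm`, `ddiameter_pct`, `independent`
#'   (always `TRUE`). Unmatched labels are in `attr(, "unmatched")`.
#' @export
independent_deformations <- function(inflated, collapsed,
                                     inflated_mask = NULL,
                                     collapsed_mask = NULL,
                                     trim_frac = 0.2, min_inplane = 0.15) {
  stopifnot(inherits(inflated, "centerline_tree"),
            inherits(collapsed, "centerline_tree"))
  ibr <- inflated$branches[!is.na(inflated$branches$label), ]
  cbr <- collapsed$branches[!is.na(collapsed$branches$label), ]
  matched <- intersect(ibr$label, cbr$label)
  unmatched <- union(setdiff(ibr$label, cbr$label),
                     setdiff(cbr$label, ibr$label))
  if (!length(matched)) stop("no labels shared by the two trees",
                             call. = FALSE)
  # raw per-view deltas, lengths, displacement per matched label
  views <- c("axial", "coronal", "sagittal")
  raw <- list()
  trim <- function(p) {
    s <- polyline_arclength(p)
    total <- s[length(s)]
    keep <- which(s >= trim_frac * total & s <= (1 - trim_frac) * total)
    if (length(keep) < 2L) p else p[keep, , drop = FALSE]
  }
  for (lb in matched) {
    ip <- ibr$points[[match(lb, ibr$label)]]
    cp <- cbr$points[[match(lb, cbr$label)]]
    iv <- fit_branch_vector(ip, label = lb)
    cv <- fit_branch_vector(cp, label = lb)
    ilen <- polyline_length(ip)
    clen <- polyline_length(cp)
    ang <- angular_deformation(fit_branch_vector(trim(cp), label = lb),
                               fit_branch_vector(trim(ip), label = lb),
                               min_inplane = min_inplane)
    disp <- displacement(cv, iv)
    raw[[lb]] <- list(iv = iv, cv = cv, ang = ang, disp = disp,
                      ilen = ilen, clen = clen)
  }
  # parent label within the matched set: nearest matched ancestor per the
  # inflated tree's own topology
  id_of <- stats::setNames(ibr$id, ibr$label)
  parent_matched <- function(lb) {
    path <- path_to_root(inflated, id_of[[lb]])
    labs <- inflated$branches$label[match(path, inflated$branches$id)]
    anc <- rev(labs[-length(labs)])
    anc <- anc[!is.na(anc) & anc %in% matched]
    if (length(anc)) anc[1] else NA_character_
  }
  rows <- lapply(matched, function(lb) {
    r <- raw[[lb]]
    par <- parent_matched(lb)
    ind <- vapply(views, function(vw) {
      col <- paste0("dtheta_", vw, "_deg")
      own <- r$ang[[col]]
      if (is.na(own) || is.na(par)) return(own)
      # an ancestor whose in-plane projection vanishes has no defined view
      # angle and contributes nothing to subtract
      pv <- raw[[par]]$ang[[col]]
      if (is.na(pv)) pv <- 0
      wrap_angle(own - pv)
    }, numeric(1))
    dl <- r$clen - r$ilen
    tibble::tibble(
      branch_label = lb,
      d_x = r$disp$d_x, d_y = r$disp$d_y, d_z = r$disp$d_z,
      d_norm_mm = r$disp$d_norm_mm,
      dtheta_axial_deg = ind[["axial"]],
      dtheta_coronal_deg = ind[["coronal"]],
      dtheta_sagittal_deg = ind[["sagittal"]],
      raw_dtheta_axial_deg = r$ang$dtheta_axial_deg,
      raw_dtheta_coronal_deg = r$ang$dtheta_coronal_deg,
      raw_dtheta_sagittal_deg = r$ang$dtheta_sagittal_deg,
      dlength_mm = dl,
      dlength_pct = if (r$ilen > 0) 100 * dl / r$ilen else NA_real_,
      ddiameter_mm = NA_real_, ddiameter_pct = NA_real_,
      independent = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(inflated_mask) && !is.null(collapsed_mask)) {
    for (k in seq_len(nrow(out))) {
      lb <- out$branch_label[k]
      di <- max_branch_diameter(ibr$points[[match(lb, ibr$label)]],
                                inflated_mask)
      dc <- max_branch_diameter(cbr$points[[match(lb, cbr$label)]],
                                collapsed_mask)
      out$ddiameter_mm[k] <- dc - di
      out$ddiameter_pct[k] <- if (di > 0) 100 * (dc - di) / di else NA_real_
    }
  }
  attr(out, "unmatched") <- unmatched
  class(out) <- c("deformation_table", class(out))
  out
}

#' Per-branch medians across a cohort of deformation tables
#'
#' Given one deformation table per subject, returns the per-branch,
#' per-field median across subjects, plus two summaries of the overall
#' displacement: the median of all branch displacement norms pooled, and
#' the median of per-subject median norms (the reporting convention for a
#' cohort median is ambiguous, so both are given).
#'
#' @param tables List of [independent_deformations()] tables.
#' @param group Optional tag (`"left"`/`"right"`) recorded in the output.
#' @return A tibble with one row per branch label and median columns;
#'   attributes `pooled_median_d_norm_mm` and
#'   `median_of_subject_medians_mm` hold the overall summaries, also
#'   available via [glance()].
#' @export
summarize_cohort <- function(tables, group = NA_character_) {
  if (!length(tables)) stop("no deformation tables supplied", call. = FALSE)
  all <- dplyr::bind_rows(lapply(seq_along(tables), function(i) {
    t <- tibble::as_tibble(tables[[i]])
    t$subject <- i
    t
  }))
  med_cols <- c("d_x", "d_y", "d_z", "d_norm_mm", "dtheta_axial_deg",
                "dtheta_coronal_deg", "dtheta_sagittal_deg", "dlength_mm",
                "dlength_pct", "ddiameter_mm", "ddiameter_pct")
  out <- all |>
    dplyr::group_by(.data$branch_label) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(med_cols),
                                   ~ stats::median(.x, na.rm = TRUE)),
                     n_subjects = dplyr::n(), .groups = "drop")
  out$group <- group
  attr(out, "pooled_median_d_norm_mm") <-
    stats::median(all$d_norm_mm, na.rm = TRUE)
  attr(out, "median_of_subject_medians_mm") <-
    stats::median(vapply(tables, function(t)
      stats::median(t$d_norm_mm, na.rm = TRUE), numeric(1)))
  class(out) <- c("cohort_summary", class(out))
  out
}

#' @export
glance.cohort_summary <- function(x, ...) {
  tibble::tibble(
    group = x$group[1],
    n_branches = nrow(x),
    pooled_median_d_norm_mm = attr(x, "pooled_median_d_norm_mm"),
    median_of_subject_medians_mm = attr(x, "median_of_subject_medians_mm"))
}
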
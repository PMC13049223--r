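# Shared fixtures, all built in code.

# straight tube mask along +z
make_cylinder_mask <- function(radius_mm = 3, length_mm = 50, spacing_mm = 1) {
  pts <- cbind(0, 0, seq(0, length_mm, by = 2))
  tree <- centerline_tree(
    tibble::tibble(id = "b0", label = "tube", parent_id = NA_character_,
                   points = list(pts)),
    root_id = "b0")
  voxelize_tree(tree, radius_mm, spacing_mm)
}

# symmetric Y: vertical stem splitting into two oblique children
make_y_tree <- function(split_angle_deg = 36) {
  th <- split_angle_deg * pi / 180
  centerline_tree(tibble::tibble(
    id = c("b0", "b1", "b2"),
    label = NA_character_,
    parent_id = c(NA, "b0", "b0"),
    points = list(
      cbind(0, 0, seq(40, 0, by = -2)),
      rbind(c(0, 0, 0), outer(seq(2, 30, by = 2),
                              c(sin(th), 0, -cos(th)))),
      rbind(c(0, 0, 0), outer(seq(2, 30, by = 2),
                              c(-sin(th), 0, -cos(th)))))),
    root_id = "b0")
}

make_branch <- function(points, id = "b0", label = NA_character_) {
  centerline_tree(tibble::tibble(id = id, label = label,
                                 parent_id = NA_character_,
                                 points = list(points)),
                  root_id = id)
}

rotation_about <- function(axis, angle_deg) {
  ax <- axis / sqrt(sum(axis^2))
  a <- angle_deg * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * K %*% K
}

random_rigid <- function(seed, max_angle_deg = 20, max_shift_mm = 10) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about(ax, stats::runif(1, -max_angle_deg,
                                                  max_angle_deg)),
                  stats::runif(3, -max_shift_mm, max_shift_mm))
}

all_tree_points <- function(tree) do.call(rbind, tree$branches$points)

# brute-force nearest-ancestor walk (independent oracle for path_to_root)
walk_parents <- function(tree, id) {
  out <- id
  repeat {
    i <- match(out[1], tree$branches$id)
    p <- tree$branches$parent_id[i]
    if (is.na(p)) return(out)
    out <- c(p, out)
  }
}

deformation_errors <- function(recovered, truth) {
  m <- merge(as.data.frame(recovered), as.data.frame(truth),
             by = "branch_label", suffixes = c("", ".t"))
  ang <- abs(c(m$dtheta_axial_deg - m$dtheta_axial_deg.t,
               m$dtheta_coronal_deg - m$dtheta_coronal_deg.t,
               m$dtheta_sagittal_deg - m$dtheta_sagittal_deg.t))
  list(angles = ang[!is.na(ang)],
       lengths = abs(m$dlength_mm - m$dlength_mm.t))
}
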
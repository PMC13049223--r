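zero_table <- function(tree) {
  labs <- tree$branches$label
  tibble::tibble(branch_label = labs[!is.na(labs)],
                 dtheta_axial_deg = 0, dtheta_coronal_deg = 0,
                 dtheta_sagittal_deg = 0, dlength_mm = 0,
                 independent = TRUE)
}

test_that("the zero deformation table is the identity", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 23))
  out <- apply_deformations(tr, zero_table(tr))
  expect_lt(max(abs(all_tree_points(out) - all_tree_points(tr))), 1e-12)
})

test_that("a single-branch axial rotation moves the tip by the closed form", {
  tr <- make_branch(cbind(0, seq(0, 20, by = 2), 0), label = "trachea")
  tr$schema_id <- "human"
  tab <- tibble::tibble(branch_label = "trachea", dtheta_axial_deg = 90,
                        dtheta_coronal_deg = NA, dtheta_sagittal_deg = NA,
                        dlength_mm = 0, independent = TRUE)
  out <- apply_deformations(tr, tab)
  tip <- out$branches$points[[1]][11, ]
  # +90 deg in the axial convention turns +y into +x
  expect_equal(tip, c(20, 0, 0), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("length deltas rescale the centerline arclength exactly", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 24))
  tab <- zero_table(tr)
  tab$dlength_mm <- -5
  out <- apply_deformations(tr, tab)
  for (lb in tab$branch_label) {
    l0 <- branch_length(tr$branches$points[[match(lb, tr$branches$label)]])
    l1 <- branch_length(out$branches$points[[match(lb, out$branches$label)]])
    expect_equal(l1, l0 - 5, tolerance = 1e-6)
  }
  # impossible shrinkage floors at 5 % of the original length
  tab$dlength_mm <- -1000
  out2 <- apply_deformations(tr, tab)
  l1 <- branch_length(out2$branches$points[[match("trachea",
                                                  out2$branches$label)]])
  l0 <- branch_length(tr$branches$points[[match("trachea",
                                                tr$branches$label)]])
  expect_equal(l1, 0.05 * l0, tolerance = 1e-6)
  expect_error(apply_deformations(tr, tibble::tibble(
    branch_label = "no-such", dtheta_axial_deg = 0, dtheta_coronal_deg = 0,
    dtheta_sagittal_deg = 0, dlength_mm = 0, independent = TRUE)),
    "not in tree")
})

test_that("forward model and measurement invert each other on phantoms", {
  for (s in 1:4) {
    tr <- generate_tree(phantom_spec(depth = 3, seed = s))
    cp <- collapse_phantom(tr, seed = s + 60, collapse_side = "left")
    table <- independent_deformations(tr, cp$tree)
    modeled <- apply_deformations(tr, table)
    # branch vectors of the modeled tree match the reference collapsed tree
    for (lb in table$branch_label) {
      vm <- fit_branch_vector(modeled$branches$points[[
        match(lb, modeled$branches$label)]])
      vb <- fit_branch_vector(cp$tree$branches$points[[
        match(lb, cp$tree$branches$label)]])
      ang <- acos(min(1, abs(sum(vm$direction * vb$direction)))) * 180 / pi
      expect_lt(ang, 1)
      expect_lt(abs(vm$length_mm - vb$length_mm), 0.5)
    }
    # and the modeled tree is strictly closer than the unmodeled one
    d_model <- attr(tree_distance(modeled, cp$tree), "overall_mm")
    d_null <- attr(tree_distance(tr, cp$tree), "overall_mm")
    expect_lt(d_model, d_null)
  }
})

test_that("connectivity survives deformation application", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 26))
  cp <- collapse_phantom(tr, seed = 27, collapse_side = "right")
  out <- apply_deformations(tr, cp$truth)
  expect_identical(nrow(validate_tree(out, tol_mm = 1e-9)), 0L)
})

test_that("tree distance is zero on identity, exact on rigid offsets", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 28))
  d0 <- tree_distance(tr, tr)
  expect_true(all(d0$distance_mm < 1e-12))
  # offset orthogonal to a straight branch: every point is exactly 3 mm
  # from its counterpart and no sliding along the branch can do better
  tube <- make_branch(cbind(0, 0, seq(0, 30, by = 2)), label = "tube")
  shifted <- apply_transform(tube, rigid_transform(diag(3), c(3, 0, 0)))
  d3 <- tree_distance(tube, shifted)
  expect_equal(d3$distance_mm, 3, tolerance = 1e-9)
  expect_equal(attr(d3, "overall_mm"), 3, tolerance = 1e-9)
  # a general translation can only shrink closest-point distances
  moved <- apply_transform(tr, rigid_transform(diag(3), c(3, 0, 0)))
  dg <- tree_distance(tr, moved)
  expect_true(all(dg$distance_mm > 0 & dg$distance_mm <= 3 + 1e-9))
  expect_error(tree_distance(tr, make_branch(cbind(0, 0, 0:5))),
               "no matched labels")
})

test_that("tree distance equals a brute-force closest-point scan", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 29))
  cp <- collapse_phantom(tr, seed = 30, collapse_side = "left")
  d <- tree_distance(tr, cp$tree, resample_mm = 2)
  for (lb in d$branch_label) {
    pa <- airwaydeform:::resample_polyline(
      tr$branches$points[[match(lb, tr$branches$label)]], 2)
    pb <- airwaydeform:::resample_polyline(
      cp$tree$branches$points[[match(lb, cp$tree$branches$label)]], 2)
    mins_ab <- apply(pa, 1, function(x)
      min(sqrt(colSums((t(pb) - x)^2))))
    mins_ba <- apply(pb, 1, function(x)
      min(sqrt(colSums((t(pa) - x)^2))))
    expect_equal(d$distance_mm[d$branch_label == lb],
                 (mean(mins_ab) + mean(mins_ba)) / 2, tolerance = 1e-12)
  }
})
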
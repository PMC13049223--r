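test_that("generated trees have 2^(depth+1)-1 branches and valid structure", {
  expect_identical(nrow(generate_tree(phantom_spec(depth = 1,
                                                   schema_id = NA))$branches),
                   3L)
  tr <- generate_tree(phantom_spec(depth = 3, seed = 2))
  expect_identical(nrow(tr$branches), 15L)
  expect_identical(nrow(validate_tree(tr)), 0L)
  expect_identical(sum(!is.na(tr$branches$label)), 15L)
  # generation scales: trachea ~16 mm wide, segmental ~4 mm
  radii <- attr(tr, "radii")
  gens <- attr(tr, "generation")
  expect_equal(unname(radii[names(gens)[gens == 0]]), 8)
  expect_equal(unname(radii[names(gens)[gens == 3]][1]), 8 * 0.63^3)
})

test_that("identical spec and seed reproduce identical JSON bytes", {
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_tree(generate_tree(phantom_spec(depth = 3, seed = 42)), f1)
  write_tree(generate_tree(phantom_spec(depth = 3, seed = 42)), f2)
  expect_identical(readLines(f1), readLines(f2))
  f3 <- tempfile(fileext = ".json")
  write_tree(generate_tree(phantom_spec(depth = 3, seed = 43)), f3)
  expect_false(identical(readLines(f1), readLines(f3)))
})

test_that("porcine labeling works at depth 2 and errors at depth 3", {
  tr <- generate_tree(phantom_spec(depth = 2, schema_id = "porcine"))
  expect_true(all(c("trachea", "LMB", "RMB") %in% tr$branches$label))
  expect_identical(tr$schema_id, "porcine")
  expect_error(generate_tree(phantom_spec(depth = 3, schema_id = "porcine")),
               "cannot label")
})

test_that("voxelization contains the centerline and matches capsule volume", {
  pts <- cbind(0, 0, seq(0, 40, by = 2))
  m <- voxelize_tree(make_branch(pts), radii = 3, spacing_mm = 1)
  expect_true(all(airwaydeform:::mask_contains(m, pts)))
  analytic <- (pi * 3^2 * 40 + 4 / 3 * pi * 3^3) / 1000
  expect_equal(mask_volume(m), analytic, tolerance = 0.1)
  # any generated tree: all centerline points foreground, one component
  tr <- generate_tree(phantom_spec(depth = 2, seed = 3))
  mt <- voxelize_tree(tr, attr(tr, "radii"), 1)
  expect_true(all(airwaydeform:::mask_contains(mt, all_tree_points(tr))))
  expect_length(airwaydeform:::mask_components(mt)$sizes, 1L)
})

test_that("tube volume scales with the square of the radius", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 4))
  radii <- attr(tr, "radii")
  v1 <- mask_volume(voxelize_tree(tr, radii, 1))
  v2 <- mask_volume(voxelize_tree(tr, radii * 0.7, 1))
  expect_equal(v2 / v1, 0.7^2, tolerance = 0.1)
})

test_that("zero truth with zero jitter reproduces the tree", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 5))
  zt <- tibble::tibble(branch_label = "trachea", dtheta_axial_deg = 0,
                       dtheta_coronal_deg = 0, dtheta_sagittal_deg = 0,
                       dlength_mm = 0, independent = TRUE)
  cp <- collapse_phantom(tr, truth = zt, seed = 1)
  expect_lt(max(abs(all_tree_points(cp$tree) - all_tree_points(tr))), 1e-12)
})

test_that("deforming one main bronchus leaves the other lung untouched", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 6))
  cp <- collapse_phantom(tr, seed = 7, collapse_side = "left")
  right_ids <- tr$branches$id[vapply(tr$branches$id, function(id) {
    labs <- tr$branches$label[match(path_to_root(tr, id), tr$branches$id)]
    "RMB" %in% labs || identical(labs[length(labs)], "trachea")
  }, TRUE)]
  for (id in right_ids) {
    i <- match(id, tr$branches$id)
    expect_lt(max(abs(cp$tree$branches$points[[i]] -
                        tr$branches$points[[i]])), 1e-9)
  }
  # and the left side did move
  lmb <- match("LMB", tr$branches$label)
  expect_gt(max(abs(cp$tree$branches$points[[lmb]] -
                      tr$branches$points[[lmb]])), 0.5)
})

test_that("sampled ground truth is exactly recoverable on noiseless trees", {
  for (s in 1:3) {
    tr <- generate_tree(phantom_spec(depth = 3, seed = s))
    cp <- collapse_phantom(tr, seed = s + 80, collapse_side = "left")
    rec <- independent_deformations(tr, cp$tree)
    err <- deformation_errors(rec, cp$truth)
    expect_lt(max(err$angles), 1e-4)
    expect_lt(max(err$lengths), 1e-6)
    # truth magnitudes stay within the documented sampling range
    expect_true(all(abs(cp$truth$dtheta_axial_deg) <= 40, na.rm = TRUE))
  }
})

test_that("point jitter is seeded and bounded", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 8))
  a <- collapse_phantom(tr, seed = 9, jitter_sd = 0.2)
  b <- collapse_phantom(tr, seed = 9, jitter_sd = 0.2)
  expect_identical(all_tree_points(a$tree), all_tree_points(b$tree))
  c_ <- collapse_phantom(tr, seed = 10, jitter_sd = 0.2)
  expect_false(identical(all_tree_points(a$tree), all_tree_points(c_$tree)))
})
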
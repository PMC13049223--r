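test_that("a straight cylinder skeletonizes to one edge with two endpoints", {
  g <- skeletonize(make_cylinder_mask(radius_mm = 3, length_mm = 50))
  expect_identical(nrow(g$nodes), 2L)
  expect_length(g$edges, 1L)
  expect_identical(sort(g$node_degree), c(1L, 1L))
})

test_that("a Y phantom skeletonizes to 3 endpoints and 1 junction", {
  m <- voxelize_tree(make_y_tree(), 3, 1)
  g <- skeletonize(m)
  expect_identical(nrow(g$nodes), 4L)
  expect_length(g$edges, 3L)
  expect_identical(sort(g$node_degree), c(1L, 1L, 1L, 3L))
})

test_that("empty and multi-component masks are rejected", {
  empty <- voxel_mask(array(FALSE, c(5, 5, 5)))
  expect_error(skeletonize(empty), "empty")
  two <- array(FALSE, c(12, 6, 6))
  two[2:4, 2:4, 2:4] <- TRUE
  two[8:10, 2:4, 2:4] <- TRUE
  expect_error(skeletonize(voxel_mask(two)), "2 foreground components")
})

test_that("rooting recovers the phantom topology and prunes spurs", {
  m <- voxelize_tree(make_y_tree(), 3, 1)
  g <- skeletonize(m)
  tree <- root_and_prune(g, m)
  expect_identical(nrow(tree$branches), 3L)
  expect_identical(nrow(validate_tree(tree)), 0L)
  # min_spur_mm = 0 keeps every edge
  expect_identical(nrow(root_and_prune(g, m, min_spur_mm = 0)$branches), 3L)
  # root is the most cranial endpoint
  root_pts <- tree$branches$points[[1]]
  expect_gt(root_pts[1, 3], max(root_pts[nrow(root_pts), 3]))
})

test_that("a short spur is pruned and pruning is idempotent", {
  m <- voxelize_tree(make_y_tree(), 3, 1)
  # graft a 2-voxel spur onto a junction-adjacent skeleton voxel by adding
  # a small bump to the mask
  skel <- airwaydeform:::.thin3d_cpp(m$voxels, dim(m$voxels))
  j <- which(skel, arr.ind = TRUE)[1, ]
  bump <- m
  bump$voxels[j[1] + 0:2, j[2], j[3]] <- TRUE
  g <- skeletonize(bump)
  tree <- root_and_prune(g, bump, min_spur_mm = 5)
  expect_identical(nrow(tree$branches), 3L)
  # idempotence on branch geometry: re-pruning an already clean graph
  tree2 <- root_and_prune(skeletonize(m), m, min_spur_mm = 5)
  tree3 <- root_and_prune(skeletonize(m), m, min_spur_mm = 5)
  expect_identical(tree2$branches$points, tree3$branches$points)
})

test_that("every centerline point lies inside the mask foreground", {
  for (s in 1:2) {
    tr <- generate_tree(phantom_spec(depth = 2, seed = s))
    m <- voxelize_tree(tr, attr(tr, "radii"), 1)
    ext <- extract_centerline(m)
    expect_true(all(airwaydeform:::mask_contains(m, all_tree_points(ext))))
  }
})

test_that("phantom voxelize-skeletonize round trip preserves topology", {
  for (s in 1:2) {
    tr <- generate_tree(phantom_spec(depth = 3, seed = s))
    m <- voxelize_tree(tr, attr(tr, "radii"), 1)
    ext <- extract_centerline(m)
    expect_identical(nrow(ext$branches), nrow(tr$branches))
    # rooted-tree isomorphism for complete binary trees: same number of
    # branches per depth level
    depth_counts <- function(t) {
      d <- vapply(t$branches$id, function(id) length(path_to_root(t, id)),
                  integer(1))
      as.integer(table(d))
    }
    expect_identical(depth_counts(ext), depth_counts(tr))
  }
})

test_that("carina sits at the tracheal bifurcation with left/right by x", {
  m <- voxelize_tree(make_y_tree(), 3, 1)
  tree <- root_and_prune(skeletonize(m), m)
  car <- find_carina(tree)
  # construction puts the junction at the origin
  expect_lt(sqrt(sum(car$carina[1:2]^2)), 3)
  expect_gt(mean(branch_points(tree, car$left_id)[, 1]), car$carina[1])
  expect_lt(mean(branch_points(tree, car$right_id)[, 1]), car$carina[1])
})

test_that("a trifurcating root is an anatomy error", {
  th <- 40 * pi / 180
  tri <- centerline_tree(tibble::tibble(
    id = c("b0", "b1", "b2", "b3"),
    label = NA_character_,
    parent_id = c(NA, "b0", "b0", "b0"),
    points = list(cbind(0, 0, seq(30, 0, by = -2)),
                  rbind(c(0, 0, 0), c(20 * sin(th), 0, -20 * cos(th))),
                  rbind(c(0, 0, 0), c(-20 * sin(th), 0, -20 * cos(th))),
                  rbind(c(0, 0, 0), c(0, 20 * sin(th), -20 * cos(th))))),
    root_id = "b0")
  expect_error(find_carina(tri), "expected 2 main bronchi")
})
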
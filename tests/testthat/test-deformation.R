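test_that("branch vector fitting handles collinear points and ordering", {
  v <- fit_branch_vector(rbind(c(0, 0, 0), c(0, 0, 5), c(0, 0, 10)))
  expect_equal(v$direction, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(v$length_mm, 10)
  expect_equal(v$anchor, c(0, 0, 0))
  vr <- fit_branch_vector(rbind(c(0, 0, 10), c(0, 0, 5), c(0, 0, 0)))
  expect_equal(vr$direction, c(0, 0, -1), tolerance = 1e-12)
  expect_error(fit_branch_vector(rbind(c(1, 1, 1), c(1, 1, 1))),
               "identical")
})

test_that("noisy line fits agree with the covariance eigenvector", {
  set.seed(77)
  d <- c(1, 2, -0.5); d <- d / sqrt(sum(d^2))
  t_ <- seq(0, 30, length.out = 100)
  p <- outer(t_, d) + matrix(rnorm(300, 0, 0.1), 100, 3)
  v <- fit_branch_vector(p)
  # independent oracle: leading eigenvector of the covariance
  ev <- eigen(stats::cov(p))$vectors[, 1]
  if (sum(ev * d) < 0) ev <- -ev
  expect_lt(acos(min(1, abs(sum(v$direction * ev)))) * 180 / pi, 1e-6)
  expect_lt(acos(min(1, abs(sum(v$direction * d)))) * 180 / pi, 1)
})

test_that("displacement is the difference of scaled branch vectors", {
  i <- fit_branch_vector(rbind(c(0, 0, 0), c(0, 10, 0)), label = "b")
  c0 <- fit_branch_vector(rbind(c(0, 0, 0), c(0, 10, 0)), label = "b")
  d0 <- displacement(c0, i)
  expect_equal(c(d0$d_x, d0$d_y, d0$d_z), c(0, 0, 0))
  expect_equal(d0$d_norm_mm, 0)

  c1 <- fit_branch_vector(rbind(c(0, 0, 0), c(0, 7, 0)), label = "b")
  d1 <- displacement(c1, i)
  expect_equal(c(d1$d_x, d1$d_y, d1$d_z), c(0, -3, 0), tolerance = 1e-12)
  expect_equal(d1$d_norm_mm, 3)

  set.seed(5)
  R <- rotation_about(rnorm(3), 25)
  dirs <- R %*% c(0, 1, 0)
  c2 <- fit_branch_vector(rbind(c(0, 0, 0), t(8 * dirs)), label = "b")
  d2 <- displacement(c2, i)
  expect_equal(c(d2$d_x, d2$d_y, d2$d_z), as.numeric(8 * dirs - c(0, 10, 0)),
               tolerance = 1e-9)
  other <- fit_branch_vector(rbind(c(0, 0, 0), c(0, 1, 0)), label = "x")
  expect_error(displacement(other, i), "labels differ")
})

test_that("projected angles follow the documented view conventions", {
  expect_equal(projected_angle(c(0, 1, 0), "axial"), 0)
  expect_equal(projected_angle(c(1, 1, 0), "axial"), 45)
  expect_equal(projected_angle(c(1, 0, 1), "sagittal"), 45)
  expect_equal(projected_angle(c(0, 1, 1), "coronal"), 45)
  expect_equal(projected_angle(c(-1, 0, 0), "axial"), -90)
  expect_error(projected_angle(c(0, 0, 1), "axial"), "undefined")
  # rotation-matrix oracle: rotating (0,0,1) by 45 deg about y lands at
  # sagittal angle 45
  v <- as.numeric(rotation_about(c(0, 1, 0), 45) %*% c(0, 0, 1))
  expect_equal(projected_angle(v, "sagittal"), 45, tolerance = 1e-9)
})

test_that("angular deformation wraps, is antisymmetric, and matches rotations", {
  mk <- function(dir) {
    d <- as.numeric(dir)
    fit_branch_vector(rbind(c(0, 0, 0), 10 * d), label = "b")
  }
  i <- mk(c(0, 1, 0))
  expect_equal(unlist(angular_deformation(i, i)[, -1]),
               c(dtheta_axial_deg = 0, dtheta_coronal_deg = 0,
                 dtheta_sagittal_deg = NA), tolerance = 1e-12)
  # 30 deg about z only changes the axial view angle of an in-plane vector
  c30 <- mk(as.numeric(rotation_about(c(0, 0, 1), -30) %*% c(0, 1, 0)))
  a <- angular_deformation(c30, i)
  expect_equal(a$dtheta_axial_deg, 30, tolerance = 1e-9)
  # wraparound: 170 deg to -170 deg is a +20 shortest difference
  i170 <- mk(c(sin(170 * pi / 180), cos(170 * pi / 180), 0))
  cm170 <- mk(c(sin(-170 * pi / 180), cos(-170 * pi / 180), 0))
  expect_equal(angular_deformation(cm170, i170)$dtheta_axial_deg, 20,
               tolerance = 1e-9)
  # antisymmetry
  set.seed(9)
  for (k in 1:5) {
    va <- mk(rnorm(3)); vb <- mk(rnorm(3))
    ab <- angular_deformation(va, vb)
    ba <- angular_deformation(vb, va)
    for (col in names(ab)[-1]) {
      if (is.na(ab[[col]])) next
      w <- airwaydeform:::wrap_angle(ab[[col]] + ba[[col]])
      expect_lt(abs(w), 1e-9)
    }
  }
})

test_that("identical trees give all-zero deformation records", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 8))
  rec <- independent_deformations(tr, tr)
  expect_identical(nrow(rec), 15L)
  expect_true(all(rec$d_norm_mm == 0))
  expect_true(all(rec$dlength_mm == 0))
  for (col in c("dtheta_axial_deg", "dtheta_coronal_deg",
                "dtheta_sagittal_deg"))
    expect_true(all(abs(rec[[col]]) < 1e-9, na.rm = TRUE))
  expect_true(all(rec$independent))
})

test_that("a rigidly rotated lobar subtree deforms only at the lobar branch", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 10))
  rot <- tr
  rul_id <- tr$branches$id[match("RUL", tr$branches$label)]
  anchor <- branch_points(tr, rul_id)[1, ]
  R <- rotation_about(c(0, 0, 1), -15)  # +15 deg in the axial convention
  in_subtree <- vapply(tr$branches$id, function(id)
    rul_id %in% path_to_root(tr, id), TRUE)
  for (i in which(in_subtree))
    rot$branches$points[[i]] <-
      sweep(sweep(rot$branches$points[[i]], 2, anchor) %*% t(R), 2,
            anchor, "+")
  rec <- independent_deformations(tr, rot)
  rul <- rec[rec$branch_label == "RUL", ]
  expect_equal(rul$dtheta_axial_deg, 15, tolerance = 1e-6)
  # independence is exact in the rotated view; other views carry
  # projection cross-talk inherent to the per-view formulation
  descendants <- rec[grepl("^RUL B", rec$branch_label), ]
  expect_gt(nrow(descendants), 0)
  expect_true(all(abs(descendants$dtheta_axial_deg) < 1e-3, na.rm = TRUE))
  others <- rec[!grepl("RUL", rec$branch_label), ]
  for (col in c("dtheta_axial_deg", "dtheta_coronal_deg",
                "dtheta_sagittal_deg"))
    expect_true(all(abs(others[[col]]) < 1e-6, na.rm = TRUE))
})

test_that("deformation records are invariant under global rigid motion", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 13))
  cp <- collapse_phantom(tr, seed = 14, collapse_side = "right")
  rec <- independent_deformations(tr, cp$tree)
  # translation of both trees: every record is unchanged (view angles,
  # vectors, and lengths are all position-free)
  shift <- rigid_transform(diag(3), c(7, -4, 12))
  rec_t <- independent_deformations(apply_transform(tr, shift),
                                    apply_transform(cp$tree, shift))
  for (col in c("dtheta_axial_deg", "dtheta_coronal_deg",
                "dtheta_sagittal_deg", "dlength_mm", "d_norm_mm",
                "d_x", "d_y", "d_z")) {
    both <- !is.na(rec[[col]]) & !is.na(rec_t[[col]])
    expect_true(any(both))
    expect_equal(rec_t[[col]][both], rec[[col]][both], tolerance = 1e-9)
  }
  # rotation of both trees: the frame-free quantities (displacement norm,
  # lengths) are unchanged; per-view angles live in the fixed patient
  # frame by definition, which is why registration precedes measurement
  tf <- random_rigid(15)
  rec_r <- independent_deformations(apply_transform(tr, tf),
                                    apply_transform(cp$tree, tf))
  for (col in c("dlength_mm", "d_norm_mm"))
    expect_equal(rec_r[[col]], rec[[col]], tolerance = 1e-6)
})

test_that("independent deltas telescope back to the raw terminal delta", {
  for (s in 1:3) {
    tr <- generate_tree(phantom_spec(depth = 3, seed = s))
    cp <- collapse_phantom(tr, seed = s + 40, collapse_side = "left")
    rec <- independent_deformations(tr, cp$tree)
    for (lb in rec$branch_label) {
      id <- tr$branches$id[match(lb, tr$branches$label)]
      chain <- tr$branches$label[match(path_to_root(tr, id),
                                       tr$branches$id)]
      for (vw in c("axial", "coronal", "sagittal")) {
        ind <- rec[[paste0("dtheta_", vw, "_deg")]][match(chain,
                                                          rec$branch_label)]
        raw <- rec[[paste0("raw_dtheta_", vw, "_deg")]][match(lb,
                                                              rec$branch_label)]
        if (is.na(raw)) next
        resid <- airwaydeform:::wrap_angle(sum(ind, na.rm = TRUE) - raw)
        expect_lt(abs(resid), 1e-9)
      }
    }
  }
})

test_that("unmatched labels are reported, not dropped silently", {
  tr <- generate_tree(phantom_spec(depth = 3, seed = 17))
  partial <- tr
  drop <- match("RUL B2", partial$branches$label)
  partial$branches$label[drop] <- NA_character_
  rec <- independent_deformations(tr, partial)
  expect_true("RUL B2" %in% attr(rec, "unmatched"))
  expect_false("RUL B2" %in% rec$branch_label)
})

test_that("cohort medians match a sort-based oracle", {
  tr <- generate_tree(phantom_spec(depth = 2, seed = 19))
  tabs <- lapply(1:3, function(k)
    independent_deformations(tr, collapse_phantom(tr, seed = 20 + k,
                                                  collapse_side = "left")$tree))
  s <- summarize_cohort(tabs, group = "left")
  expect_identical(nrow(s), 7L)
  for (lb in s$branch_label) {
    vals <- sort(vapply(tabs, function(t)
      t$d_norm_mm[match(lb, t$branch_label)], numeric(1)))
    expect_equal(s$d_norm_mm[s$branch_label == lb], vals[2])
  }
  pooled <- sort(unlist(lapply(tabs, function(t) t$d_norm_mm)))
  expect_equal(attr(s, "pooled_median_d_norm_mm"), stats::median(pooled))
  one <- summarize_cohort(tabs[1])
  expect_equal(one$d_norm_mm, tabs[[1]]$d_norm_mm[match(one$branch_label,
                                                        tabs[[1]]$branch_label)])
  g <- glance(s)
  expect_identical(g$group, "left")
  expect_error(summarize_cohort(list()), "no deformation tables")
})
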
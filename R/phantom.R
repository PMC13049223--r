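#' Specification for a synthetic bifurcating airway phantom
#'
#' Parameters of a complete binary airway tree at clinically plausible
#' scales: by default the root (trachea) is 50 mm long with an 8 mm radius
#' (16 mm diameter), each generation shortens by the length ratio and
#' narrows by the radius ratio, and children leave the parent axis at the
#' branching angle with seeded jitter. Generation 3 of the defaults gives
#' segmental-scale bronchi (~4 mm diameter, ~20 mm long).
#'
#' @param depth Number of bifurcation generations (>= 1); the tree has
#'   `2^(depth+1) - 1` branches.
#' @param root_length_mm,length_ratio Root branch length and per-generation
#'   length multiplier.
#' @param root_radius_mm,radius_ratio Root tube radius and per-generation
#'   radius multiplier (used at voxelization).
#' @param branching_angle_deg,angle_jitter_deg Mean half-angle between a
#'   child and its parent axis, and the uniform jitter added per child.
#' @param azimuth_jitter_deg Uniform jitter of the child plane's azimuth.
#' @param spacing_mm Isotropic voxel spacing used by [voxelize_tree()].
#' @param seed Integer seed; identical spec + seed reproduces the phantom
#'   bit for bit.
#' @param schema_id Label schema to assign (`"human"`, `"porcine"` or `NA`
#'   for unlabeled); generations 0-3 get trachea/main/lobar/segmental
#'   labels, deeper generations stay unlabeled.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(depth = 3, root_length_mm = 50, length_ratio = 0.75,
                         root_radius_mm = 8, radius_ratio = 0.63,
                         branching_angle_deg = 35, angle_jitter_deg = 5,
                         azimuth_jitter_deg = 15, spacing_mm = 1, seed = 1L,
                         schema_id = "human") {
  stopifnot(depth >= 1, root_length_mm > 0, length_ratio > 0,
            root_radius_mm > 0, radius_ratio > 0, branching_angle_deg > 0,
            angle_jitter_deg >= 0, azimuth_jitter_deg >= 0, spacing_mm > 0)
  structure(list(depth = as.integer(depth), root_length_mm = root_length_mm,
                 length_ratio = length_ratio, root_radius_mm = root_radius_mm,
                 radius_ratio = radius_ratio,
                 branching_angle_deg = branching_angle_deg,
                 angle_jitter_deg = angle_jitter_deg,
                 azimuth_jitter_deg = azimuth_jitter_deg,
                 spacing_mm = spacing_mm, seed = as.integer(seed),
                 schema_id = schema_id),
            class = "phantom_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a phantom centerline tree
#'
#' Builds the complete binary tree of a [phantom_spec()]: the trachea grows
#' caudally (toward -z) from the most cranial point, the two main bronchi
#' split toward the patient's left (+x) and right (-x), and deeper children
#' fan out with jittered branching angles and azimuths. Branch polylines
#' are straight, sampled every ~2 mm. Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return A labeled [centerline_tree()] with per-branch tube radii in
#'   `attr(, "radii")` (named by branch id) and generations in
#'   `attr(, "generation")`.
#' @export
generate_tree <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    rows <- list()
    radii <- numeric()
    gens <- integer()
    bid <- 0L
    new_id <- function() {
      id <- paste0("b", bid)
      bid <<- bid + 1L
      id
    }
    line_points <- function(from, dir, len) {
      n <- max(2L, ceiling(len / 2) + 1L)
      s <- seq(0, len, length.out = n)
      sweep(outer(s, dir), 2, from, "+")
    }
    add_branch <- function(from, dir, gen, parent_id, perp) {
      len <- spec$root_length_mm * spec$length_ratio^gen
      p <- line_points(from, dir, len)
      colnames(p) <- c("x", "y", "z")
      id <- new_id()
      rows[[length(rows) + 1L]] <<-
        tibble::tibble(id = id, label = NA_character_, parent_id = parent_id,
                       points = list(p))
      radii[id] <<- spec$root_radius_mm * spec$radius_ratio^gen
      gens[id] <<- gen
      if (gen < spec$depth) {
        tip <- p[nrow(p), ]
        for (side in c(1, -1)) {
          th <- (spec$branching_angle_deg +
                   stats::runif(1, -spec$angle_jitter_deg,
                                spec$angle_jitter_deg)) * pi / 180
          az <- stats::runif(1, -spec$azimuth_jitter_deg,
                             spec$azimuth_jitter_deg) * pi / 180
          # rotate the lateral offset within the plane orthogonal to dir
          perp2 <- c(dir[2] * perp[3] - dir[3] * perp[2],
                     dir[3] * perp[1] - dir[1] * perp[3],
                     dir[1] * perp[2] - dir[2] * perp[1])
          lat <- cos(az) * perp + sin(az) * perp2
          cdir <- cos(th) * dir + sin(th) * side * lat
          cdir <- cdir / sqrt(sum(cdir^2))
          # child's reference perpendicular: twist so grandchildren leave
          # the parent plane
          cperp <- perp2 - sum(perp2 * cdir) * cdir
          nrm <- sqrt(sum(cperp^2))
          cperp <- if (nrm > 1e-9) cperp / nrm else perp
          add_branch(tip, cdir, gen + 1L, id, cperp)
        }
      }
      id
    }
    add_branch(from = c(0, 0, 0), dir = c(0, 0, -1), gen = 0L,
               parent_id = NA_character_, perp = c(1, 0, 0))
    tree <- centerline_tree(dplyr::bind_rows(rows), root_id = "b0")
    if (!is.na(spec$schema_id))
      tree <- label_tree_generations(tree, label_schema(spec$schema_id),
                                     max_generation = 3L)
    attr(tree, "radii") <- radii
    attr(tree, "generation") <- gens
    tree
  })
}

# label a complete bifurcating tree down to `max_generation`; errors when
# the schema lacks children for a label whose tree branch still has
# children within that range
label_tree_generations <- function(tree, schema, max_generation = 3L) {
  br <- tree$branches
  lab <- stats::setNames(rep(NA_character_, nrow(br)), br$id)
  lab[tree$root_id] <- "trachea"
  kids <- tree_children(tree, tree$root_id)
  if (length(kids) != 2L)
    stop("labeling needs a bifurcating root", call. = FALSE)
  rp <- branch_points(tree, tree$root_id)
  carina <- rp[nrow(rp), ]
  mean_x <- vapply(kids, function(id)
    mean(branch_points(tree, id)[, 1]) - carina[1], numeric(1))
  lab[kids[which.max(mean_x)]] <- "LMB"
  lab[kids[which.min(mean_x)]] <- "RMB"
  queue <- kids
  gen <- stats::setNames(rep(1L, length(kids)), kids)
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    ch <- tree_children(tree, cur)
    if (!length(ch) || gen[[cur]] + 1L > max_generation) next
    # prefer schema children that themselves have children when the tree
    # continues below them
    avail <- schema_children(schema, lab[[cur]])
    deeper_needed <- gen[[cur]] + 1L < max_generation &&
      any(vapply(ch, function(x) length(tree_children(tree, x)) > 0, TRUE))
    if (deeper_needed) {
      fertile <- avail[vapply(avail, function(a)
        length(schema_children(schema, a)) >= 2L, TRUE)]
      avail <- c(fertile, setdiff(avail, fertile))
    }
    if (length(avail) < length(ch))
      stop("schema '", schema$schema_id, "' cannot label generation ",
           gen[[cur]] + 1L, " under '", lab[[cur]], "'", call. = FALSE)
    for (k in seq_along(ch)) {
      lab[ch[k]] <- avail[k]
      gen[ch[k]] <- gen[[cur]] + 1L
      queue <- c(queue, ch[k])
    }
  }
  tree$branches$label <- unname(lab[tree$branches$id])
  tree$schema_id <- schema$schema_id
  tree
}

#' Voxelize a centerline tree into a binary tube mask
#'
#' Sweeps a sphere of the branch radius along every branch polyline
#' (capsule union). The grid covers the tree with a margin of the largest
#' radius plus two voxels; every centerline point is guaranteed foreground.
#'
#' @param tree A [centerline_tree()].
#' @param radii Tube radius per branch: a single number, or a named vector
#'   keyed by branch id (e.g. `attr(generate_tree(spec), "radii")`).
#' @param spacing_mm Isotropic voxel spacing.
#' @return A [voxel_mask()].
#' @export
voxelize_tree <- function(tree, radii, spacing_mm = 1) {
  stopifnot(inherits(tree, "centerline_tree"))
  ids <- tree$branches$id
  r_of <- if (length(radii) == 1L && is.null(names(radii)))
    stats::setNames(rep(radii, length(ids)), ids) else radii[ids]
  if (any(is.na(r_of))) stop("missing radius for some branch", call. = FALSE)
  floor_r <- 0.5 * spacing_mm
  if (any(r_of < floor_r)) {
    warning("radii below half the voxel spacing clamped to ", floor_r,
            " mm", call. = FALSE)
    r_of <- pmax(r_of, floor_r)
  }
  allp <- do.call(rbind, tree$branches$points)
  rmax <- max(r_of)
  lo <- apply(allp, 2, min) - rmax - 2 * spacing_mm
  hi <- apply(allp, 2, max) + rmax + 2 * spacing_mm
  dims <- pmax(ceiling((hi - lo) / spacing_mm) + 1L, 3L)
  vox <- array(FALSE, dims)
  for (i in seq_along(ids)) {
    r <- r_of[[i]]
    samp <- resample_polyline(tree$branches$points[[i]],
                              spacing_mm = spacing_mm / 2)
    for (k in seq_len(nrow(samp))) {
      c_ijk <- (samp[k, ] - lo) / spacing_mm + 1
      rad_vox <- r / spacing_mm
      i0 <- pmax(1L, floor(c_ijk - rad_vox))
      i1 <- pmin(dims, ceiling(c_ijk + rad_vox))
      xs <- i0[1]:i1[1]; ys <- i0[2]:i1[2]; zs <- i0[3]:i1[3]
      dx2 <- (xs - c_ijk[1])^2
      dy2 <- (ys - c_ijk[2])^2
      dz2 <- (zs - c_ijk[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      sub <- vox[xs, ys, zs, drop = FALSE]
      vox[xs, ys, zs] <- sub | (d2 <= rad_vox^2)
      # centerline containment guarantee even for sub-voxel radii
      nn <- pmin(pmax(round(c_ijk), 1L), dims)
      vox[nn[1], nn[2], nn[3]] <- TRUE
    }
  }
  voxel_mask(vox, spacing = rep(spacing_mm, 3), origin = lo)
}

#' Collapse a phantom with known ground truth
#'
#' Builds a synthetic collapsed state of a labeled phantom tree together
#' with the exact deformation table that produced it. When no truth table
#' is supplied, per-branch deformations are sampled for the collapsed side
#' only (the contralateral side is what registration leans on, exactly as
#' in a unilateral pneumothorax): hierarchical random rotations whose
#' induced independent per-view angle deltas stay within
#' `max_angle_deg`, and length scales uniform in `length_scale`. The
#' collapsed tree is produced by [apply_deformations()], so the returned
#' table is exactly recoverable by [independent_deformations()] on
#' noiseless trees. Optional isotropic point jitter emulates measurement
#' noise.
#'
#' @param tree A labeled [centerline_tree()] (e.g. [generate_tree()]).
#' @param truth Optional deformation table; sampled when `NULL`.
#' @param seed Integer seed for sampling and jitter.
#' @param collapse_side `"left"` or `"right"`: which lung deforms.
#' @param max_angle_deg Cap on the magnitude of sampled independent
#'   per-view angle deltas.
#' @param length_scale Range of the per-branch length scale factors.
#' @param jitter_sd Standard deviation (mm) of Gaussian point jitter added
#'   to the collapsed tree (0 = noiseless).
#' @return A list with `tree` (collapsed [centerline_tree()]) and `truth`
#'   (the deformation table actually applied).
#' @export
collapse_phantom <- function(tree, truth = NULL, seed = 1L,
                             collapse_side = c("left", "right"),
                             max_angle_deg = 40, length_scale = c(0.6, 1),
                             jitter_sd = 0) {
  stopifnot(inherits(tree, "centerline_tree"))
  collapse_side <- match.arg(collapse_side)
  if (is.null(truth))
    truth <- with_seed(seed, sample_ground_truth(tree, collapse_side,
                                                 max_angle_deg, length_scale))
  collapsed <- apply_deformations(tree, truth)
  if (jitter_sd > 0) {
    collapsed$branches$points <- with_seed(seed + 1L,
      lapply(collapsed$branches$points, function(p) {
        q <- p + matrix(stats::rnorm(length(p), sd = jitter_sd), nrow(p), 3)
        colnames(q) <- c("x", "y", "z")
        q
      }))
  }
  list(tree = collapsed, truth = truth)
}

# sample a consistent ground-truth table: hierarchical rotations on the
# collapsed side; truth deltas are the per-view angle changes the sampled
# new directions induce, so the table is consistent by construction
sample_ground_truth <- function(tree, collapse_side, max_angle_deg,
                                length_scale) {
  main_label <- if (collapse_side == "left") "LMB" else "RMB"
  br <- tree$branches
  labeled <- br$id[!is.na(br$label)]
  # collapsed-side branches: labeled descendants of the collapsed main
  side_ids <- labeled[vapply(labeled, function(id) {
    path <- path_to_root(tree, id)
    main_label %in% br$label[match(path, br$id)]
  }, TRUE)]
  u <- lapply(stats::setNames(labeled, labeled), function(id)
    fit_branch_vector(branch_points(tree, id))$direction)
  Rcum <- list()
  raw <- list()
  views <- c("axial", "coronal", "sagittal")
  angles_of <- function(v) vapply(views, function(vw)
    projected_angle_or_na(v, vw, min_inplane = 0.15), numeric(1))
  rows <- list()
  for (id in tree_order(tree)) {
    if (!id %in% labeled) next
    pid_chain <- rev(path_to_root(tree, id))[-1]
    par <- pid_chain[pid_chain %in% labeled][1]
    Rpar <- if (!is.na(par) && !is.null(Rcum[[par]])) Rcum[[par]] else diag(3)
    deform_here <- id %in% side_ids
    if (deform_here) {
      for (try in 1:60) {
        ang <- stats::runif(1, 0, 25) * (0.85^(try - 1)) * pi / 180
        ax <- stats::rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0),
                    3, 3)
        rho <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
        Rc <- rho %*% Rpar
        v <- as.numeric(Rc %*% u[[id]])
        rawb <- wrap_angle(angles_of(v) - angles_of(u[[id]]))
        rawp <- if (!is.na(par)) raw[[par]] else c(0, 0, 0)
        rawp[is.na(rawp)] <- 0
        ind <- wrap_angle(rawb - rawp)
        if (all(is.na(ind) | abs(ind) <= max_angle_deg) &&
            sum(!is.na(rawb)) >= 2) break
      }
      Rcum[[id]] <- Rc
      raw[[id]] <- rawb
      len <- polyline_length(branch_points(tree, id))
      dl <- (stats::runif(1, length_scale[1], length_scale[2]) - 1) * len
    } else {
      Rcum[[id]] <- Rpar
      v <- as.numeric(Rcum[[id]] %*% u[[id]])
      raw[[id]] <- wrap_angle(angles_of(v) - angles_of(u[[id]]))
      rawp <- if (!is.na(par)) raw[[par]] else c(0, 0, 0)
      rawp[is.na(rawp)] <- 0
      ind <- wrap_angle(raw[[id]] - rawp)
      dl <- 0
    }
    lb <- br$label[match(id, br$id)]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      branch_label = lb,
      dtheta_axial_deg = ind[[1]], dtheta_coronal_deg = ind[[2]],
      dtheta_sagittal_deg = ind[[3]],
      dlength_mm = dl, independent = TRUE)
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("deformation_table", class(out))
  out
}

#' Ellipsoid mask (parenchyma stand-in)
#'
#' Axis-aligned solid ellipsoid, used as a simple parenchyma phantom for
#' volume computations and as an analytic volume oracle.
#'
#' @param semi_axes_mm Numeric length 3.
#' @param spacing_mm Isotropic voxel spacing.
#' @param margin_mm Background margin around the ellipsoid.
#' @return A [voxel_mask()].
#' @export
ellipsoid_mask <- function(semi_axes_mm, spacing_mm = 1, margin_mm = 2) {
  a <- as.numeric(semi_axes_mm)
  stopifnot(length(a) == 3L, all(a > 0))
  lo <- -a - margin_mm
  dims <- ceiling((2 * (a + margin_mm)) / spacing_mm) + 1L
  xs <- lo[1] + (seq_len(dims[1]) - 1) * spacing_mm
  ys <- lo[2] + (seq_len(dims[2]) - 1) * spacing_mm
  zs <- lo[3] + (seq_len(dims[3]) - 1) * spacing_mm
  vox <- outer(outer((xs / a[1])^2, (ys / a[2])^2, "+"), (zs / a[3])^2,
               "+") <= 1
  voxel_mask(vox, spacing = rep(spacing_mm, 3), origin = lo)
}
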
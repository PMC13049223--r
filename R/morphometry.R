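#' Branch length along the centerline
#'
#' Sum of Euclidean distances between consecutive centerline points, so the
#' curved shape of the branch counts, not just the straight gap between its
#' endpoints.
#'
#' @param points An n x 3 matrix of mm coordinates (n >= 2), or a
#'   [centerline_tree()] together with `branch_id`.
#' @param branch_id Branch id when `points` is a tree.
#' @return Length in mm.
#' @examples
#' branch_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
branch_length <- function(points, branch_id = NULL) {
  if (inherits(points, "centerline_tree")) {
    stopifnot(!is.null(branch_id))
    points <- branch_points(points, branch_id)
  }
  points <- as.matrix(points)
  if (nrow(points) < 2L)
    stop("a branch needs at least 2 points", call. = FALSE)
  polyline_length(points)
}

#' Maximal branch diameter by orthogonal ray casting
#'
#' At each interior centerline point, rays are cast in `n_directions`
#' evenly spaced directions within the plane orthogonal to the local
#' tangent (central differences; one-sided at the ends). Each ray marches
#' in steps of a quarter of the smallest spacing component until the
#' trilinearly interpolated mask drops below 0.5; the point's diameter is
#' the largest sum over antipodal ray pairs, and the branch value is the
#' maximum over interior points. Points within one local radius of either
#' endpoint are excluded so junction blobs cannot dominate; if that leaves
#' nothing, the midpoint alone is used (with a warning).
#'
#' @param branch An n x 3 point matrix or a [centerline_tree()] (then give
#'   `branch_id`).
#' @param mask The airway [voxel_mask()] the centerline came from.
#' @param n_directions Number of ray directions per point (even).
#' @param branch_id Branch id when `branch` is a tree.
#' @return Maximal diameter in mm (never below the smallest spacing
#'   component).
#' @export
max_branch_diameter <- function(branch, mask, n_directions = 36,
                                branch_id = NULL) {
  if (inherits(branch, "centerline_tree")) {
    stopifnot(!is.null(branch_id))
    branch <- branch_points(branch, branch_id)
  }
  stopifnot(inherits(mask, "voxel_mask"), n_directions >= 4)
  p <- resample_polyline(as.matrix(branch),
                         spacing_mm = max(min(mask$spacing), 0.5))
  n <- nrow(p)
  inside <- mask_contains(mask, p)
  if (!all(inside))
    stop(sum(!inside), " centerline point(s) outside the mask foreground",
         call. = FALSE)
  step <- 0.25 * min(mask$spacing)
  # lumen-scale search radius: generous for any airway, but bounded so rays
  # do not traverse the whole volume
  max_r <- min(max(dim(mask$voxels) * mask$spacing), 50)
  rr <- seq(step, max_r, by = step)
  nsteps <- length(rr)
  phis <- seq(0, 2 * pi, length.out = n_directions + 1)[seq_len(n_directions)]

  point_diameter <- function(i) {
    tang <- if (i == 1) p[2, ] - p[1, ]
    else if (i == n) p[n, ] - p[n - 1, ]
    else p[i + 1, ] - p[i - 1, ]
    tang <- tang / sqrt(sum(tang^2))
    # orthonormal basis of the normal plane
    a <- if (abs(tang[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- a - sum(a * tang) * tang
    u <- u / sqrt(sum(u^2))
    v <- c(tang[2] * u[3] - tang[3] * u[2],
           tang[3] * u[1] - tang[1] * u[3],
           tang[1] * u[2] - tang[2] * u[1])
    dirs <- outer(cos(phis), u) + outer(sin(phis), v)
    samp <- dirs[rep(seq_len(n_directions), each = nsteps), ] * rep(rr, n_directions)
    vals <- matrix(mask_interp(mask, sweep(samp, 2, p[i, ], "+")),
                   nrow = nsteps)
    r <- vapply(seq_len(n_directions), function(j) {
      k <- which(vals[, j] < 0.5)
      if (!length(k)) return(max_r)
      k <- k[1]
      # sub-step boundary: linear interpolation of the 0.5 crossing
      if (k == 1L) return(rr[1] * 0.5 / max(1 - vals[1, j], 0.5))
      v0 <- vals[k - 1L, j]
      v1 <- vals[k, j]
      rr[k - 1L] + step * (v0 - 0.5) / max(v0 - v1, 1e-9)
    }, numeric(1))
    half <- n_directions / 2
    max(r[seq_len(half)] + r[seq_len(half) + half])
  }

  # local radius (median of three stations) decides the endpoint exclusion
  # zone; junction blobs extend roughly one parent radius into the branch,
  # so the zone is half again as wide as the local radius
  stations <- unique(pmax(1L, pmin(n, round(n * c(0.25, 0.5, 0.75)))))
  local_r <- stats::median(vapply(stations, point_diameter, numeric(1))) / 2
  s <- polyline_arclength(p)
  interior <- which(s > 1.5 * local_r & s < s[n] - 1.5 * local_r)
  if (!length(interior)) {
    warning("branch too short for interior points; using midpoint only",
            call. = FALSE)
    interior <- ceiling(n / 2)
  }
  d <- max(vapply(interior, point_diameter, numeric(1)))
  max(d, min(mask$spacing))
}

#' Collapse-versus-inflated difference with percent change
#'
#' The sign convention of the reported tables: `difference = collapsed -
#' inflated`, so negative values mean the collapsed measurement is smaller.
#' Percent is relative to the inflated value and is `NA` when that is not
#' positive.
#'
#' @param inflated,collapsed Numeric vectors of paired measurements (mm,
#'   mL, ...).
#' @return A tibble with columns `inflated`, `collapsed`, `difference`,
#'   `percent`.
#' @examples
#' difference_report(16.85, 13.84)  # -3.01 mm, -17.9 %
#' @export
difference_report <- function(inflated, collapsed) {
  stopifnot(length(inflated) == length(collapsed))
  difference <- collapsed - inflated
  percent <- ifelse(inflated > 0, 100 * difference / inflated, NA_real_)
  tibble::tibble(inflated = inflated, collapsed = collapsed,
                 difference = difference, percent = percent)
}

#' Per-branch morphometry table for one state
#'
#' Lengths (and, when a mask is supplied, maximal diameters) of every
#' labeled branch of a tree, as one tidy row per branch.
#'
#' @param tree A labeled [centerline_tree()].
#' @param mask Optional airway [voxel_mask()]; without it diameters are
#'   `NA`.
#' @param state `"inflated"` or `"collapsed"`, recorded in the output.
#' @param labels Branch labels to measure (default: all labeled branches).
#' @return A tibble with columns `branch_label`, `state`, `length_mm`,
#'   `max_diameter_mm`.
#' @export
measure_tree <- function(tree, mask = NULL,
                         state = c("inflated", "collapsed"), labels = NULL) {
  state <- match.arg(state)
  br <- tree$branches[!is.na(tree$branches$label), ]
  if (!is.null(labels)) br <- br[br$label %in% labels, ]
  tibble::tibble(
    branch_label = br$label,
    state = state,
    length_mm = vapply(br$points, polyline_length, numeric(1)),
    max_diameter_mm = if (is.null(mask)) NA_real_ else
      vapply(br$points, max_branch_diameter, numeric(1), mask = mask))
}
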
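#' Binary voxel mask with physical geometry
#'
#' Wraps a 3D logical array together with the voxel spacing (mm), the
#' physical position of voxel (1,1,1) and an orientation code. All geometry
#' downstream of I/O works in physical millimetres: voxel `(i,j,k)`
#' (1-based) sits at `origin + (c(i,j,k) - 1) * spacing`. The canonical
#' anatomical frame is LPS-like: x grows to the patient's left, y grows
#' posteriorly, z grows cranially.
#'
#' @param voxels 3D logical (or coercible) array; `TRUE`/nonzero is
#'   foreground.
#' @param spacing Numeric length 3, mm per voxel along x, y, z; all > 0.
#' @param origin Numeric length 3, physical mm coordinate of voxel (1,1,1).
#' @param orientation Axis-direction code; `"LPS"` is the canonical frame.
#' @return An object of class `voxel_mask`.
#' @examples
#' m <- voxel_mask(array(TRUE, c(4, 4, 4)), spacing = c(1, 1, 1))
#' mask_volume(m)  # 0.064 mL
#' @export
voxel_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       orientation = "LPS") {
  stopifnot(length(dim(voxels)) == 3L)
  voxels <- array(as.logical(voxels), dim = dim(voxels))
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values (mm)", call. = FALSE)
  orientation <- match.arg(orientation, c("LPS", "RAS", "LAS", "RPS",
                                          "LPI", "RAI", "LAI", "RPI"))
  structure(list(voxels = voxels, spacing = spacing, origin = origin,
                 orientation = orientation),
            class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<voxel_mask %dx%dx%d, spacing %.3gx%.3gx%.3g mm, %d foreground (%.2f mL)>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              sum(x$voxels), mask_volume(x)))
  invisible(x)
}

#' Foreground volume of a mask in millilitres
#'
#' Foreground voxel count times the voxel volume, `prod(spacing)`, converted
#' from cubic millimetres to mL. Used for parenchymal (per-lobe or total
#' lung) volumes.
#'
#' @param mask A [voxel_mask()].
#' @return Volume in mL (0 for an empty mask).
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "voxel_mask"))
  sum(mask$voxels) * prod(mask$spacing) / 1000
}

# voxel (i,j,k) 1-based -> physical mm (rows of a matrix)
voxel_to_mm <- function(mask, ijk) {
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

# physical mm -> continuous 1-based voxel coordinate
mm_to_voxel <- function(mask, xyz) {
  xyz <- rbind(xyz)
  sweep(sweep(xyz, 2, mask$origin, "-"), 2, mask$spacing, "/") + 1
}

# trilinear interpolation of the binary mask at physical points (n x 3);
# outside the volume -> 0
mask_interp <- function(mask, xyz) {
  v <- mm_to_voxel(mask, xyz)
  d <- dim(mask$voxels)
  i0 <- floor(v)
  f <- v - i0
  out <- numeric(nrow(v))
  vol <- mask$voxels
  for (corner in 0:7) {
    dx <- bitwAnd(corner, 1L)
    dy <- bitwAnd(bitwShiftR(corner, 1L), 1L)
    dz <- bitwAnd(bitwShiftR(corner, 2L), 1L)
    ii <- i0[, 1] + dx
    jj <- i0[, 2] + dy
    kk <- i0[, 3] + dz
    w <- (if (dx) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dz) f[, 3] else 1 - f[, 3])
    ok <- ii >= 1 & jj >= 1 & kk >= 1 & ii <= d[1] & jj <= d[2] & kk <= d[3]
    if (any(ok)) {
      val <- vol[cbind(ii[ok], jj[ok], kk[ok])]
      out[ok] <- out[ok] + w[ok] * val
    }
  }
  out
}

# nearest-voxel foreground test for physical points
mask_contains <- function(mask, xyz) {
  v <- round(mm_to_voxel(mask, xyz))
  d <- dim(mask$voxels)
  ok <- v[, 1] >= 1 & v[, 2] >= 1 & v[, 3] >= 1 &
    v[, 1] <= d[1] & v[, 2] <= d[2] & v[, 3] <= d[3]
  res <- logical(nrow(v))
  if (any(ok)) res[ok] <- mask$voxels[cbind(v[ok, 1], v[ok, 2], v[ok, 3])]
  res
}

# 26-connected component labelling; returns list(labels = int array,
# sizes = int vector sorted decreasing)
mask_components <- function(mask) {
  lab <- .cc_label26_cpp(mask$voxels, dim(mask$voxels))
  sizes <- tabulate(lab[lab > 0])
  list(labels = lab, sizes = sort(sizes, decreasing = TRUE))
}
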
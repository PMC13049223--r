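# Readers and writers: NIfTI / NRRD masks, centerline JSON, transform JSON,
# deformation CSV.

#' Read a binary segmentation mask
#'
#' NIfTI (`.nii`, `.nii.gz`) via RNifti, NRRD (`.nrrd`) via a built-in
#' reader (raw and gzip encodings, diagonal space directions). Any nonzero
#' voxel is foreground. NIfTI images carrying an xform are reoriented to
#' the canonical LPS-like frame; images without one are taken as already
#' canonical.
#'
#' @param path File path.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(read_nrrd(path))
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), "D", call. = FALSE)
  xf <- RNifti::xform(img)
  origin <- c(0, 0, 0)
  if (!is.null(attr(xf, "code")) && attr(xf, "code") > 0) {
    # NIfTI world coordinates are RAS; the package frame is LPS (x left,
    # y posterior, z superior), so reorient the array to "LPS" axis order
    # and negate the x/y world offsets
    try(RNifti::orientation(img) <- "LPS", silent = TRUE)
    xf <- RNifti::xform(img)
    origin <- c(-xf[1, 4], -xf[2, 4], xf[3, 4])
    spacing <- sqrt(colSums(xf[1:3, 1:3]^2))
    if (any(spacing <= 0)) stop("non-positive voxel spacing in header",
                                call. = FALSE)
    return(voxel_mask(array(as.array(img) != 0, dim(img)),
                      spacing = spacing, origin = origin))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(spacing <= 0)) stop("non-positive voxel spacing in header",
                              call. = FALSE)
  voxel_mask(array(as.array(img) != 0, dim(img)), spacing = spacing,
             origin = origin)
}

#' Write a mask
#'
#' Format chosen from the extension: `.nii`/`.nii.gz` (NIfTI, qform set to
#' the canonical LPS-like frame) or `.nrrd` (gzip encoding).
#'
#' @param mask A [voxel_mask()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "voxel_mask"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return(write_nrrd(mask, path))
  img <- RNifti::asNifti(array(as.integer(mask$voxels), dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  # LPS frame encoded in the RAS-world qform: negate x and y
  mat <- diag(c(-mask$spacing[1], -mask$spacing[2], mask$spacing[3], 1))
  mat[1:3, 4] <- c(-mask$origin[1], -mask$origin[2], mask$origin[3])
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- minimal NRRD -----------------------------------------------------------

read_nrrd <- function(path) {
  all_bytes <- readBin(path, "raw", n = file.size(path))
  # header ends at the first blank line (\n\n)
  nl <- which(all_bytes == as.raw(10L))
  split_at <- NA_integer_
  for (k in seq_along(nl)[-1]) {
    if (nl[k] == nl[k - 1] + 1L) {
      split_at <- nl[k]
      break
    }
  }
  if (is.na(split_at)) stop("malformed NRRD: no header terminator",
                            call. = FALSE)
  header <- strsplit(rawToChar(all_bytes[seq_len(split_at - 2L)]),
                     "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", header[1])) stop("not an NRRD file: ", path,
                                       call. = FALSE)
  fields <- list()
  for (line in header[-1]) {
    if (!nzchar(line) || grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header missing field '", f, "'",
                                   call. = FALSE)
    fields[[f]]
  }
  dimn <- as.integer(need("dimension"))
  if (dimn != 3L) stop("expected a 3D NRRD, got dimension ", dimn,
                       call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- tolower(need("encoding"))
  spacing <- c(1, 1, 1)
  if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    if (max(abs(m - diag(diag(m)))) > 1e-9)
      stop("only diagonal NRRD space directions are supported", call. = FALSE)
    spacing <- abs(diag(m))
  } else if (!is.null(fields[["spacings"]])) {
    spacing <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  }
  origin <- c(0, 0, 0)
  if (!is.null(fields[["space origin"]]))
    origin <- as.numeric(strsplit(gsub("[()]", "",
                                       fields[["space origin"]]), ",")[[1]])
  n <- prod(sizes)
  bytes_per <- switch(type,
                      "unsigned char" = , "uchar" = , "uint8" = , "uint8_t" = 1L,
                      "short" = , "int16" = , "int16_t" = ,
                      "unsigned short" = , "uint16" = , "uint16_t" = 2L,
                      "int" = , "int32" = , "int32_t" = ,
                      "unsigned int" = , "uint32" = , "uint32_t" = 4L,
                      "float" = 4L, "double" = 8L,
                      stop("unsupported NRRD type '", type, "'", call. = FALSE))
  raw_data <- all_bytes[(split_at + 1L):length(all_bytes)]
  if (enc == "gzip" || enc == "gz") raw_data <- memDecompress(raw_data, "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding '", enc, "'",
                              call. = FALSE)
  what <- if (type %in% c("float", "double")) "double" else "integer"
  vals <- readBin(raw_data, what, n = n, size = bytes_per,
                  signed = !(bytes_per == 1L || grepl("^u", type)),
                  endian = "little")
  voxel_mask(array(vals != 0, sizes), spacing = spacing, origin = origin)
}

write_nrrd <- function(mask, path) {
  d <- dim(mask$voxels)
  hdr <- c("NRRD0004",
           "# written by airwaydeform",
           "type: unsigned char",
           "dimension: 3",
           "space: left-posterior-superior",
           paste0("sizes: ", paste(d, collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%.9g,0,0) (0,%.9g,0) (0,0,%.9g)",
                          mask$spacing[1], mask$spacing[2], mask$spacing[3])),
           "kinds: domain domain domain",
           "endian: little",
           "encoding: gzip",
           paste0("space origin: ", sprintf("(%.9g,%.9g,%.9g)",
                                            mask$origin[1], mask$origin[2],
                                            mask$origin[3])),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(memCompress(as.raw(as.integer(mask$voxels)), "gzip"), con)
  invisible(path)
}

# ---- centerline JSON --------------------------------------------------------

#' Read and write centerline trees as JSON
#'
#' Schema: `{"schema_id", "root_id", "branches": [{"id", "label",
#' "parent_id", "points": [[x,y,z], ...]}]}`, coordinates in mm serialized
#' at 9 significant digits so write-read round-trips are exact at that
#' precision.
#'
#' @param tree A [centerline_tree()].
#' @param path File path.
#' @return `read_tree()`: a [centerline_tree()]; `write_tree()`: `path`,
#'   invisibly.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "centerline_tree"))
  br <- tree$branches
  branches <- lapply(seq_len(nrow(br)), function(i) {
    list(id = br$id[i],
         label = if (is.na(br$label[i])) NULL else br$label[i],
         parent_id = if (is.na(br$parent_id[i])) NULL else br$parent_id[i],
         points = lapply(seq_len(nrow(br$points[[i]])), function(k)
           as.numeric(signif(br$points[[i]][k, ], 9))))
  })
  obj <- list(schema_id = if (is.na(tree$schema_id)) NULL else tree$schema_id,
              root_id = tree$root_id, branches = branches)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("root_id", "branches"))
    if (is.null(obj[[key]]))
      stop("centerline JSON missing required key '", key, "'", call. = FALSE)
  rows <- lapply(obj$branches, function(b) {
    for (key in c("id", "points"))
      if (is.null(b[[key]]))
        stop("branch entry missing required key '", key, "'", call. = FALSE)
    p <- do.call(rbind, lapply(b$points, as.numeric))
    tibble::tibble(id = as.character(b$id),
                   label = b$label %||% NA_character_,
                   parent_id = if (is.null(b$parent_id)) NA_character_
                   else as.character(b$parent_id),
                   points = list(p))
  })
  br <- dplyr::bind_rows(rows)
  if (anyDuplicated(br$id))
    stop("duplicated branch id '", br$id[duplicated(br$id)][1],
         "' in centerline JSON", call. = FALSE)
  centerline_tree(br, root_id = obj$root_id,
                  schema_id = obj$schema_id %||% NA_character_)
}

# ---- transform JSON ---------------------------------------------------------

#' Read and write rigid transforms as JSON
#'
#' The rotation is stored row-major under `"rotation"`, the translation
#' under `"translation_mm"`.
#'
#' @param transform A [rigid_transform()].
#' @param path File path.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  obj <- list(rotation = lapply(1:3, function(i)
    as.numeric(transform$rotation[i, ])),
    translation_mm = as.numeric(transform$translation),
    landmark_rms_mm = attr(transform, "rms") %||% NA_real_)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  obj <- jsonlite::fromJSON(path)
  tf <- rigid_transform(t(matrix(as.numeric(t(obj$rotation)), 3, 3)),
                        obj$translation_mm)
  if (!is.null(obj$landmark_rms_mm) && !is.na(obj$landmark_rms_mm))
    attr(tf, "rms") <- obj$landmark_rms_mm
  tf
}

# ---- tables -----------------------------------------------------------------

#' Write and read deformation tables as CSV
#'
#' Comma-separated, UTF-8, `.` decimal, fixed header from the table's
#' columns.
#'
#' @param table A deformation (or any) tibble.
#' @param path File path.
#' @export
write_deformation_csv <- function(table, path) {
  utils::write.csv(tibble::as_tibble(table), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_deformation_csv
#' @export
read_deformation_csv <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(path, fileEncoding = "UTF-8",
                                           check.names = FALSE))
  if ("independent" %in% names(out))
    out$independent <- as.logical(out$independent)
  class(out) <- c("deformation_table", class(out))
  out
}
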
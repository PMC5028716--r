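#' Construct a CT image volume
#'
#' An `image_volume` is a 3D scalar grid in Hounsfield units (HU) with an
#' anisotropic voxel spacing and a world origin, both in millimetres. Arrays
#' are indexed `(x, y, z)` with axial slices along the third dimension;
#' voxel centres sit at `origin + (index - 1) * spacing` (indices 1-based in
#' R, the world position of voxel `[1, 1, 1]` is `origin`).
#'
#' @param data 3D numeric array of intensities (HU). All values must be
#'   finite.
#' @param spacing numeric length-3 vector, mm per voxel along (x, y, z);
#'   all components must be positive.
#' @param origin numeric length-3 vector, world position (mm) of the first
#'   voxel centre.
#' @return An object of class `image_volume` (a list with elements `data`,
#'   `spacing`, `origin`).
#' @seealso [lesion_mask()], [read_volume()], [resample_isotropic()]
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("dimensionality error: image data must be a 3D array, got ",
         length(dim(data)), "D", call. = FALSE)
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite values", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("origin must be 3 finite values", call. = FALSE)
  if (any(!is.finite(data)))
    stop("image data contains non-finite values", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin),
            class = "image_volume")
}

#' Construct a binary lesion mask
#'
#' A `lesion_mask` shares the grid geometry of a companion [image_volume()].
#' Voxel values are strictly 0 (background) or 1 (lesion).
#'
#' @param data 3D array of 0/1 (or logical) values.
#' @inheritParams image_volume
#' @return An object of class `lesion_mask`.
#' @export
lesion_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L)
    stop("dimensionality error: mask data must be a 3D array", call. = FALSE)
  storage.mode(data) <- "double"
  if (!all(data %in% c(0, 1)))
    stop("mask values must be 0 or 1", call. = FALSE)
  v <- image_volume(data, spacing, origin)
  class(v) <- c("lesion_mask", "image_volume")
  v
}

#' @export
print.image_volume <- function(x, ...) {
  kind <- if (inherits(x, "lesion_mask")) "lesion_mask" else "image_volume"
  cat(sprintf("<%s> %s voxels, spacing (%s) mm, origin (%s) mm\n",
              kind, paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = ", "),
              paste(format(x$origin), collapse = ", ")))
  if (kind == "lesion_mask")
    cat(sprintf("  foreground voxels: %d\n", sum(x$data > 0)))
  invisible(x)
}

#' Bundle one subject's paired scans
#'
#' A subject study holds the baseline ("pre") and follow-up ("post")
#' image/mask pairs for one subject, with a binary mutation label
#' (1 = sensitising mutant, 0 = wild-type).
#'
#' @param subject_id character scalar.
#' @param label 0 or 1.
#' @param pre,post lists with elements `image` ([image_volume()]) and
#'   `mask` ([lesion_mask()]); each pair is validated with [validate_pair()].
#' @return An object of class `subject_study`.
#' @export
subject_study <- function(subject_id, label, pre, post) {
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  validate_pair(pre$image, pre$mask)
  validate_pair(post$image, post$mask)
  structure(list(subject_id = as.character(subject_id), label = as.integer(label),
                 pre = pre, post = post),
            class = "subject_study")
}

#' Validate an image/mask pair
#'
#' Checks that the mask is co-registered with the image: identical shape,
#' and spacing/origin equal within 1e-6 mm, and that the mask contains at
#' least one foreground voxel.
#'
#' @param volume an [image_volume()].
#' @param mask a [lesion_mask()].
#' @return The list `list(image = volume, mask = mask)`, invisibly usable
#'   downstream; errors on any mismatch.
#' @export
validate_pair <- function(volume, mask) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "lesion_mask"))
  if (!identical(dim(volume$data), dim(mask$data)))
    stop("geometry error: mask shape (", paste(dim(mask$data), collapse = "x"),
         ") differs from image shape (", paste(dim(volume$data), collapse = "x"), ")",
         call. = FALSE)
  if (any(abs(volume$spacing - mask$spacing) > 1e-6))
    stop("geometry error: mask spacing differs from image spacing", call. = FALSE)
  if (any(abs(volume$origin - mask$origin) > 1e-6))
    stop("geometry error: mask origin differs from image origin", call. = FALSE)
  if (sum(mask$data) < 1)
    stop("degenerate lesion: mask has no foreground voxels", call. = FALSE)
  list(image = volume, mask = mask)
}

file_format <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) return("nifti")
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) return("nrrd")
  stop("format error: unsupported file extension for '", path,
       "' (expected .nii, .nii.gz or .nrrd)", call. = FALSE)
}

#' Read a volume from NIfTI or NRRD
#'
#' Spacing is taken from the NIfTI `pixdim` / NRRD `space directions`
#' header fields and the origin from the NIfTI qform/sform translation /
#' NRRD `space origin`. Voxel values are returned unchanged. Off-diagonal
#' (rotated/sheared) orientation matrices are rejected rather than silently
#' resampled.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.nrrd` file.
#' @return An [image_volume()].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(file_format(path), nifti = read_nifti_volume(path), nrrd = read_nrrd_volume(path))
}

#' Read a binary mask from NIfTI or NRRD
#'
#' @inheritParams read_volume
#' @return A [lesion_mask()]; errors if the payload is not 0/1-valued.
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  lesion_mask(v$data, v$spacing, v$origin)
}

#' Write a volume (or mask) to NIfTI or NRRD
#'
#' The output format follows the file extension. Round-trips through
#' [read_volume()] preserve data, spacing and origin.
#'
#' @param volume an [image_volume()] or [lesion_mask()].
#' @param path destination path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  switch(file_format(path),
         nifti = write_nifti_volume(volume, path),
         nrrd = write_nrrd_volume(volume, path))
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) {
    dim(a) <- dim(a)[1:3]
  } else if (length(dim(a)) != 3L) {
    stop("dimensionality error: expected a 3D payload in '", path,
         "', got ", length(dim(a)), "D", call. = FALSE)
  }
  sp <- as.numeric(RNifti::pixdim(img))[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("format error: non-positive pixdim in NIfTI header of '", path, "'",
         call. = FALSE)
  xf <- RNifti::xform(img)
  rot <- xf[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4 * max(abs(diag(rot))))
    stop("format error: NIfTI xform of '", path,
         "' has off-diagonal orientation terms; only axis-aligned grids are supported",
         call. = FALSE)
  org <- as.numeric(xf[1:3, 4])
  if (attr(xf, "code") %in% c(0L, NA)) org <- c(0, 0, 0)
  storage.mode(a) <- "double"
  attributes(a) <- list(dim = dim(a))
  # pixdim is stored as 32-bit float in the NIfTI header; snap values that
  # are within float precision of a short decimal back to it
  sp <- round(sp, 6)
  org <- round(org, 5)
  image_volume(a, sp, org)
}

write_nifti_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  m <- diag(c(volume$spacing, 1))
  m[1:3, 4] <- volume$origin
  RNifti::`qform<-`(img, structure(m, code = 2L)) -> img
  RNifti::writeNifti(img, path, datatype = "double")
}

## Minimal NRRD reader/writer (raw encoding, little-endian, 3D double/float/
## int payloads, axis-aligned space directions). NRRD stores the fastest-
## varying axis first, matching R's column-major (x, y, z) layout.
read_nrrd_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000[1-5]$", magic))
    stop("format error: missing NRRD magic in '", path, "'", call. = FALSE)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("format error: truncated NRRD header in '", path, "'", call. = FALSE)
    if (line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):=?\\s*(.*)$", line))[[1]]
    if (length(kv) != 3L) stop("format error: unparsable NRRD header line '", line, "'", call. = FALSE)
    fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("format error: NRRD header of '", path, "' lacks field '", key, "'", call. = FALSE)
    fields[[key]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("dimensionality error: NRRD payload in '", path, "' is ",
         fields[["dimension"]], "D, expected 3D", call. = FALSE)
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  enc <- tolower(need("encoding"))
  if (enc != "raw")
    stop("format error: unsupported NRRD encoding '", enc, "'", call. = FALSE)
  type <- tolower(need("type"))
  endian <- tolower(fields[["endian"]] %||% "little")
  parse_vecs <- function(s) {
    m <- gregexpr("\\(([^)]*)\\)", s)[[1]]
    vs <- regmatches(s, gregexpr("\\(([^)]*)\\)", s))[[1]]
    lapply(vs, function(v) as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]))
  }
  if (!is.null(fields[["space directions"]])) {
    dirs <- parse_vecs(fields[["space directions"]])
    dm <- do.call(rbind, dirs)
    if (max(abs(dm - diag(diag(dm)))) > 1e-9)
      stop("format error: NRRD space directions of '", path,
           "' are not axis-aligned", call. = FALSE)
    sp <- diag(dm)
  } else if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else {
    sp <- c(1, 1, 1)
  }
  org <- if (!is.null(fields[["space origin"]]))
    parse_vecs(fields[["space origin"]])[[1]] else c(0, 0, 0)
  n <- prod(sizes)
  spec <- switch(type,
    "double" = list(what = "double", size = 8L),
    "float" = list(what = "double", size = 4L),
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1L),
    stop("format error: unsupported NRRD type '", type, "'", call. = FALSE))
  vals <- readBin(con, spec$what, n = n, size = spec$size,
                  endian = if (endian == "big") "big" else "little",
                  signed = spec$size > 1L)
  if (length(vals) != n)
    stop("format error: NRRD payload of '", path, "' is truncated", call. = FALSE)
  a <- array(as.double(vals), dim = sizes)
  image_volume(a, sp, org)
}

write_nrrd_volume <- function(volume, path) {
  d <- dim(volume$data)
  hdr <- c(
    "NRRD0004",
    "# generated by deltarad",
    "type: double",
    "dimension: 3",
    "space dimension: 3",
    paste0("sizes: ", paste(d, collapse = " ")),
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            volume$spacing[1], volume$spacing[2], volume$spacing[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            volume$origin[1], volume$origin[2], volume$origin[3]),
    "encoding: raw",
    "endian: little",
    "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con, sep = "\n")
  writeBin(as.double(volume$data), con, size = 8L, endian = "little")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resample an image/mask pair to isotropic resolution
#'
#' The image is interpolated trilinearly and the mask by nearest neighbour,
#' onto a grid with the requested isotropic spacing covering the same world
#' extent (to within one voxel). The mask stays strictly binary.
#'
#' @param volume an [image_volume()].
#' @param mask the companion [lesion_mask()].
#' @param target_spacing positive scalar, mm.
#' @return A list `list(image =, mask =)` on the new grid.
#' @export
resample_isotropic <- function(volume, mask, target_spacing) {
  validate_pair(volume, mask)
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L || target_spacing <= 0)
    stop("target_spacing must be a positive scalar (mm)", call. = FALSE)
  if (all(abs(volume$spacing - target_spacing) < 1e-12))
    return(list(image = volume, mask = mask))
  d <- dim(volume$data)
  extent <- (d - 1) * volume$spacing
  nd <- pmax(1L, as.integer(round(extent / target_spacing)) + 1L)
  gx <- volume$origin[1] + (seq_len(nd[1]) - 1) * target_spacing
  gy <- volume$origin[2] + (seq_len(nd[2]) - 1) * target_spacing
  gz <- volume$origin[3] + (seq_len(nd[3]) - 1) * target_spacing
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  iv <- interp_trilinear(volume$data, volume$spacing, volume$origin, pts)
  # points marginally outside due to rounding: clamp by nearest neighbour
  out <- is.na(iv)
  if (any(out)) iv[out] <- interp_nearest_clamped(volume$data, volume$spacing, volume$origin, pts[out, , drop = FALSE])
  mv <- interp_nearest_clamped(mask$data, mask$spacing, mask$origin, pts)
  newimg <- image_volume(array(iv, nd), rep(target_spacing, 3), volume$origin)
  if (sum(mv) < 1)
    stop("degenerate lesion: mask is empty after resampling to ",
         target_spacing, " mm", call. = FALSE)
  newmask <- lesion_mask(array(mv, nd), rep(target_spacing, 3), mask$origin)
  list(image = newimg, mask = newmask)
}

interp_nearest_clamped <- function(a, spacing, origin, pts) {
  d <- dim(a)
  ix <- pmin(pmax(round((pts[, 1] - origin[1]) / spacing[1]) + 1, 1), d[1])
  iy <- pmin(pmax(round((pts[, 2] - origin[2]) / spacing[2]) + 1, 1), d[2])
  iz <- pmin(pmax(round((pts[, 3] - origin[3]) / spacing[3]) + 1, 1), d[3])
  a[cbind(ix, iy, iz)]
}

#' Read a cohort from a manifest CSV
#'
#' The manifest has columns `subject_id, label, pre_image, pre_mask,
#' post_image, post_mask`; paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param manifest_csv path to the manifest file.
#' @return A list of [subject_study()] objects.
#' @export
read_cohort <- function(manifest_csv) {
  if (!file.exists(manifest_csv)) stop("file not found: ", manifest_csv, call. = FALSE)
  tab <- utils::read.csv(manifest_csv, stringsAsFactors = FALSE)
  req <- c("subject_id", "label", "pre_image", "pre_mask", "post_image", "post_mask")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  base <- dirname(normalizePath(manifest_csv))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    subject_study(
      tab$subject_id[i], tab$label[i],
      pre = list(image = read_volume(resolve(tab$pre_image[i])),
                 mask = read_mask(resolve(tab$pre_mask[i]))),
      post = list(image = read_volume(resolve(tab$post_image[i])),
                  mask = read_mask(resolve(tab$post_mask[i]))))
  })
}

#' Write a cohort as NIfTI pairs plus a manifest CSV
#'
#' @param cohort list of [subject_study()] objects.
#' @param dir output directory (created if absent).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort, function(s) {
    paths <- c(pre_image = paste0(s$subject_id, "_pre.nii.gz"),
               pre_mask = paste0(s$subject_id, "_pre_mask.nii.gz"),
               post_image = paste0(s$subject_id, "_post.nii.gz"),
               post_mask = paste0(s$subject_id, "_post_mask.nii.gz"))
    write_volume(s$pre$image, file.path(dir, paths["pre_image"]))
    write_volume(s$pre$mask, file.path(dir, paths["pre_mask"]))
    write_volume(s$post$image, file.path(dir, paths["post_image"]))
    write_volume(s$post$mask, file.path(dir, paths["post_mask"]))
    data.frame(subject_id = s$subject_id, label = s$label,
               pre_image = paths[["pre_image"]], pre_mask = paths[["pre_mask"]],
               post_image = paths[["post_image"]], post_mask = paths[["post_mask"]],
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "cohort_manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
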
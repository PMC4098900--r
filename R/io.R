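# Volume/mask I/O. NIfTI-1 goes through RNifti; NRRD is a deliberately small
# reader/writer for the raw little-endian single-file flavor this package
# emits (no installed R package covers NRRD). Masks are stored as unsigned
# 8-bit label volumes with the 0/1 convention.

#' Read / write image volumes and masks
#'
#' Formats are chosen by file extension: `.nrrd` or `.nii`/`.nii.gz`.
#' Round-trips preserve grid shape, spacing and voxel values (bit-exactly for
#' integer masks). NIfTI inputs with a non-axis-aligned orientation are
#' refused rather than silently reoriented; 2D images are refused (the
#' package is 3D-only).
#'
#' @param path file path ending in `.nrrd`, `.nii` or `.nii.gz`.
#' @param x an `image_volume` or `seg_mask`.
#' @return `read_volume` returns an `image_volume`; `read_mask` a `seg_mask`;
#'   the writers return `path` invisibly.
#' @export
read_volume <- function(path) {
  arr <- read_any(path)
  image_volume(arr, attr(arr, "spacing"))
}

#' @rdname read_volume
#' @export
read_mask <- function(path) {
  arr <- read_any(path)
  vals <- unique(as.vector(arr))
  if (!all(vals %in% c(0, 1)))
    stopf("mask file %s contains values other than 0/1", path)
  seg_mask(arr != 0, attr(arr, "spacing"))
}

#' @rdname read_volume
#' @export
write_volume <- function(x, path) {
  write_any(as_array_keep(x), spacing(x), path, type = "double")
  invisible(path)
}

#' @rdname read_volume
#' @export
write_mask <- function(x, path) {
  arr <- array(as.integer(as.logical(x)), dim(x))
  write_any(arr, spacing(x), path, type = "uint8")
  invisible(path)
}

is_nrrd <- function(path) grepl("\\.nrrd$", path, ignore.case = TRUE)
is_nifti <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

read_any <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is_nrrd(path)) return(read_nrrd(path))
  if (is_nifti(path)) return(read_nifti_checked(path))
  stopf("unsupported image format: %s (use .nrrd, .nii or .nii.gz)", path)
}

write_any <- function(arr, spacing, path, type) {
  if (is_nrrd(path)) return(write_nrrd(arr, spacing, path, type))
  if (is_nifti(path)) return(write_nifti_checked(arr, spacing, path, type))
  stopf("unsupported image format: %s (use .nrrd, .nii or .nii.gz)", path)
}

read_nifti_checked <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stopf("%s is %dD; this package requires 3D volumes", path, length(d))
  # refuse oblique/rotated orientations: the voxel grid is the coordinate
  # frame here, and silent resampling would corrupt features
  xf <- try(RNifti::xform(img), silent = TRUE)
  if (!inherits(xf, "try-error") && !is.null(xf)) {
    rot <- abs(xf[1:3, 1:3])
    offdiag <- rot; diag(offdiag) <- 0
    if (any(offdiag > 1e-4 * max(rot)))
      stopf(paste0("%s has a non-axis-aligned orientation; ",
                   "resample it to the voxel grid before use"), path)
  }
  sp <- attr(img, "pixdim")[1:3]
  arr <- array(as.numeric(img), d)
  attr(arr, "spacing") <- as.numeric(sp)
  arr
}

write_nifti_checked <- function(arr, spacing, path, type) {
  dt <- if (type == "uint8") "uint8" else "double"
  attr(arr, "pixdim") <- as.numeric(spacing)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = dt), path)
  path
}

# --- minimal NRRD (single file, raw encoding, little endian) ---------------

write_nrrd <- function(arr, spacing, path, type = c("double", "uint8")) {
  type <- match.arg(type)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(
    "NRRD0004",
    "# generated by radrobust",
    sprintf("type: %s", type),
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(arr), collapse = " ")),
    sprintf("spacings: %s", paste(format(spacing, digits = 17), collapse = " ")),
    "encoding: raw",
    "endian: little",
    ""  # blank line terminates the header
  )
  writeLines(hdr, con, sep = "\n")
  if (type == "uint8") {
    writeBin(as.raw(as.integer(arr)), con)
  } else {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  }
  path
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: bytes up to the first blank line ("\n\n")
  bytes <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) stopf("unexpected end of NRRD header in %s", path)
    bytes <- c(bytes, b)
    nb <- length(bytes)
    if (nb >= 2L && bytes[nb] == as.raw(10L) && bytes[nb - 1L] == as.raw(10L))
      break
  }
  hdr <- strsplit(rawToChar(bytes), "\n", fixed = TRUE)[[1]]
  if (!grepl("^NRRD", hdr[1])) stopf("%s is not an NRRD file", path)
  fields <- hdr[grepl(":", hdr, fixed = TRUE) & !grepl("^#", hdr)]
  kv <- do.call(rbind, strsplit(fields, ":\\s*"))
  get_field <- function(key, default = NULL) {
    i <- match(tolower(key), tolower(kv[, 1]))
    if (is.na(i)) default else kv[i, 2]
  }
  ndim <- as.integer(get_field("dimension"))
  if (!identical(ndim, 3L))
    stopf("%s is %dD; this package requires 3D volumes", path, ndim)
  sizes <- as.integer(strsplit(trimws(get_field("sizes")), "\\s+")[[1]])
  sp_str <- get_field("spacings")
  spn <- if (is.null(sp_str)) c(1, 1, 1)
         else as.numeric(strsplit(trimws(sp_str), "\\s+")[[1]])
  type <- tolower(get_field("type"))
  enc <- tolower(get_field("encoding", "raw"))
  if (enc != "raw") stopf("NRRD encoding '%s' not supported (raw only)", enc)
  n <- prod(sizes)
  if (type %in% c("double", "float64")) {
    vals <- readBin(con, "double", n = n, size = 8, endian = "little")
  } else if (type %in% c("uchar", "uint8", "unsigned char", "uint8_t")) {
    vals <- as.integer(readBin(con, "raw", n = n))
  } else if (type %in% c("short", "int16", "signed short")) {
    vals <- readBin(con, "integer", n = n, size = 2, endian = "little")
  } else if (type %in% c("int", "int32", "signed int")) {
    vals <- readBin(con, "integer", n = n, size = 4, endian = "little")
  } else if (type %in% c("float", "float32")) {
    vals <- readBin(con, "double", n = n, size = 4, endian = "little")
  } else {
    stopf("NRRD type '%s' not supported", type)
  }
  if (length(vals) != n) stopf("truncated NRRD data in %s", path)
  arr <- array(as.numeric(vals), sizes)
  attr(arr, "spacing") <- spn
  arr
}

# --- study manifest ---------------------------------------------------------

#' Read / write a study manifest
#'
#' The manifest is a JSON file listing, for every stored segmentation, the
#' tumor id, observer group (`manual` / `semiauto`), observer id, run id,
#' volume and mask paths (relative to the manifest directory) and the seed
#' used to generate it.
#'
#' @param records data frame with columns `tumor`, `group`, `observer`,
#'   `run`, `volume`, `mask`, `seed`.
#' @param path manifest file path.
#' @export
write_manifest <- function(records, path) {
  need <- c("tumor", "group", "observer", "run", "volume", "mask", "seed")
  miss <- setdiff(need, names(records))
  if (length(miss)) stopf("manifest lacks columns: %s", paste(miss, collapse = ", "))
  jsonlite::write_json(list(format = "radrobust-manifest-v1",
                            records = records),
                       path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "radrobust-manifest-v1"))
    stopf("%s is not a radrobust manifest", path)
  obj$records
}
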
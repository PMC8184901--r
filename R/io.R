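#' Read a volume from NIfTI or MetaImage
#'
#' Reads a 3D scalar volume with its spacing and origin. Format is inferred
#' from the extension (`.nii`, `.nii.gz` for NIfTI-1; `.mha`, `.mhd` for
#' MetaImage). The axis convention is normalised so that spacing is positive
#' on all axes and axial slices are planes of constant third index: axes
#' stored flipped on disk are reversed in memory with the origin adjusted, so
#' voxel world coordinates are unchanged. If a sidecar file `<path>.yaml`
#' exists its `intensity_kind` entry sets the intensity kind; otherwise
#' `kind` is used.
#'
#' @param path file path.
#' @param kind fallback intensity kind when no sidecar is present.
#' @return A [voxel_grid].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, kind = "unitless") {
  if (!file.exists(path))
    stop("cannot read volume: file not found: ", path, call. = FALSE)
  fmt <- volume_format(path)
  v <- switch(fmt,
              nifti = read_nifti_grid(path, kind),
              meta  = read_meta_grid(path, kind))
  sidecar <- paste0(path, ".yaml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    if (!is.null(meta$intensity_kind)) v$kind <- meta$intensity_kind
  }
  v
}

#' Write a volume to NIfTI or MetaImage
#'
#' Integer-mode arrays are stored as 32-bit integers (8-bit for pure 0/1
#' masks) and round-trip bit-compatibly; floating-point arrays are stored in
#' double precision. A sidecar `<path>.yaml` records the intensity kind so
#' [read_volume()] can restore it.
#'
#' @param v a [voxel_grid] or [binary_mask].
#' @param path output path (`.nii`, `.nii.gz`, `.mha` or `.mhd`).
#' @param sidecar write the intensity-kind sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, sidecar = TRUE) {
  v <- as_grid(v)
  fmt <- volume_format(path)
  ok <- tryCatch({
    switch(fmt,
           nifti = write_nifti_grid(v, path),
           meta  = write_meta_grid(v, path))
    TRUE
  }, error = function(e) {
    stop("cannot write volume to ", path, ": ", conditionMessage(e), call. = FALSE)
  })
  if (sidecar)
    yaml::write_yaml(list(intensity_kind = v$kind), paste0(path, ".yaml"))
  invisible(path)
}

volume_format <- function(path) {
  low <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", low)) return("nifti")
  if (grepl("\\.(mha|mhd)$", low)) return("meta")
  stop("unrecognised volume format (expected .nii[.gz], .mha or .mhd): ",
       path, call. = FALSE)
}

## ---- NIfTI via RNifti ----

read_nifti_grid <- function(path, kind) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))  # strip niftiImage attributes
  if (length(dim(arr)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(arr)), "D", call. = FALSE)
  aff <- RNifti::xform(img)
  grid_from_affine(arr, aff, kind)
}

write_nifti_grid <- function(v, path) {
  if (is.integer(v$data)) {
    dt <- if (all(v$data %in% c(0L, 1L))) "uint8" else "int32"
  } else dt <- "double"
  img <- RNifti::asNifti(v$data)
  RNifti::pixdim(img) <- v$spacing
  aff <- diag(c(v$spacing, 1))
  aff[1:3, 4] <- v$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
}

# Convert array + affine to a voxel_grid, accepting axis-aligned (diagonal up
# to sign) affines only; flipped axes are reversed in memory so world
# coordinates of every voxel are preserved.
grid_from_affine <- function(arr, aff, kind) {
  lin <- aff[1:3, 1:3]
  offdiag <- lin; diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4 * max(abs(lin))))
    stop("oblique volume orientations are not supported", call. = FALSE)
  sp <- diag(lin)
  origin <- aff[1:3, 4]
  for (ax in 1:3) {
    if (sp[ax] < 0) {
      n <- dim(arr)[ax]
      idx <- rev(seq_len(n))
      arr <- switch(ax, arr[idx, , , drop = FALSE],
                    arr[, idx, , drop = FALSE],
                    arr[, , idx, drop = FALSE])
      origin[ax] <- origin[ax] + (n - 1) * sp[ax]
      sp[ax] <- -sp[ax]
    }
  }
  voxel_grid(arr, sp, origin, kind = kind)
}

## ---- MetaImage (.mha / .mhd + .raw) ----
## Minimal reader/writer for the uncompressed binary MetaIO dialect.

meta_types <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_INT = "int32",
                MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_meta_grid <- function(path, kind) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L)
      stop("MetaImage format error: missing field ElementDataFile", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) next
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  for (f in c("DimSize", "ElementType", "ElementSpacing"))
    if (is.null(hdr[[f]]))
      stop("MetaImage format error: missing field ", f, call. = FALSE)
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  sp <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  if (!is.null(hdr$CompressedData) && tolower(hdr$CompressedData) == "true")
    stop("compressed MetaImage data is not supported", call. = FALSE)
  type <- hdr$ElementType
  if (!type %in% names(meta_types))
    stop("MetaImage format error: unsupported ElementType ", type, call. = FALSE)
  n <- prod(dims)
  datafile <- hdr$ElementDataFile
  read_block <- function(c2) {
    what <- switch(type, MET_UCHAR = "integer", MET_SHORT = "integer",
                   MET_INT = "integer", "double")
    size <- switch(type, MET_UCHAR = 1L, MET_SHORT = 2L, MET_INT = 4L,
                   MET_FLOAT = 4L, MET_DOUBLE = 8L)
    signed <- type != "MET_UCHAR"
    readBin(c2, what = what, n = n, size = size, signed = signed,
            endian = "little")
  }
  if (identical(datafile, "LOCAL")) {
    vals <- read_block(con)
  } else {
    raw_path <- file.path(dirname(path), datafile)
    if (!file.exists(raw_path))
      stop("MetaImage data file not found: ", raw_path, call. = FALSE)
    c2 <- file(raw_path, "rb"); on.exit(close(c2), add = TRUE)
    vals <- read_block(c2)
  }
  if (length(vals) != n)
    stop("MetaImage format error: truncated data block", call. = FALSE)
  arr <- array(vals, dim = dims)
  voxel_grid(arr, sp, origin, kind = kind)
}

write_meta_grid <- function(v, path) {
  type <- if (is.integer(v$data)) {
    if (all(v$data %in% c(0L, 1L))) "MET_UCHAR" else "MET_INT"
  } else "MET_DOUBLE"
  is_mha <- grepl("\\.mha$", tolower(path))
  datafile <- if (is_mha) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                  ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("DimSize =", paste(dim(v$data), collapse = " ")),
           paste("ElementSpacing =", paste(format(v$spacing, scientific = FALSE),
                                           collapse = " ")),
           paste("Offset =", paste(format(v$origin, scientific = FALSE),
                                   collapse = " ")),
           paste("ElementType =", type),
           paste("ElementDataFile =", datafile))
  size <- switch(type, MET_UCHAR = 1L, MET_INT = 4L, MET_DOUBLE = 8L)
  vals <- as.vector(v$data)
  write_block <- function(con) writeBin(vals, con, size = size, endian = "little")
  if (is_mha) {
    con <- file(path, "wb"); on.exit(close(con), add = TRUE)
    writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
    write_block(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(con), add = TRUE)
    write_block(con)
  }
}
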
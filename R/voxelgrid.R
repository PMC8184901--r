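#' Voxel grids
#'
#' A `voxel_grid` is a 3D scalar lattice with physical spacing (mm), a world
#' origin (mm, voxel-centre convention) and a declared intensity kind. It is
#' the common parent of CT volumes (Hounsfield units), quantitative SPECT
#' volumes (activity concentration, Bq/ml), cumulated-activity maps (Bq s)
#' and dose maps (Gy). Axial slices are planes of constant third index (z);
#' sagittal and coronal slices are planes of constant first and second index.
#'
#' World coordinates are in mm; voxel indices are 1-based in R but the world
#' position of voxel (i,j,k) is `origin + (c(i,j,k) - 1) * spacing` (voxel
#' centres), so the first voxel centre sits at the origin.
#'
#' @param data numeric 3D array.
#' @param spacing numeric length-3, voxel spacing in mm; strictly positive.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @param kind intensity kind, one of `"HU"`, `"activity_conc_Bq_per_ml"`,
#'   `"activity_Bq"`, `"cumulated_Bq_s"`, `"dose_Gy"`, `"unitless"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing, origin = c(0, 0, 0),
                       kind = c("unitless", "HU", "activity_conc_Bq_per_ml",
                                "activity_Bq", "cumulated_Bq_s", "dose_Gy")) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  origin <- as.numeric(origin)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing, origin = origin, kind = kind),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %s  dim %s  spacing %s mm  origin %s mm\n",
              x$kind, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 4), collapse = ", ")))
  invisible(x)
}

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

#' Volume of one voxel in millilitres
#'
#' @param v a `voxel_grid` or a binary mask.
#' @return dx*dy*dz / 1000, in ml.
#' @export
voxel_volume_ml <- function(v) {
  v <- as_grid(v)
  prod(v$spacing) / 1000
}

#' World coordinates of voxel indices
#'
#' @param v a `voxel_grid`.
#' @param ijk integer matrix (n x 3) or length-3 vector of 1-based indices.
#' @return n x 3 matrix of world coordinates in mm (voxel centres).
#' @export
world_coords <- function(v, ijk) {
  v <- as_grid(v)
  ijk <- rbind(ijk)
  sweep(sweep(ijk - 1, 2, v$spacing, `*`), 2, v$origin, `+`)
}

# geometry equality used by mask/dose operations
same_geometry <- function(a, b, tol = 1e-6) {
  a <- as_grid(a); b <- as_grid(b)
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Binary organ masks
#'
#' A `binary_mask` wraps a `voxel_grid` whose values are exactly 0 or 1,
#' together with an organ label. Masks share spacing and origin with the
#' image they were derived from and are the currency passed from
#' segmentation to dosimetry.
#'
#' @param grid a `voxel_grid` (values coerced to 0/1 after validation) or a
#'   3D array of 0/1 values.
#' @param label organ name.
#' @param spacing,origin used when `grid` is a bare array.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, label = "organ", spacing = NULL, origin = c(0, 0, 0)) {
  if (is_voxel_grid(grid)) {
    g <- grid
  } else {
    if (is.null(spacing)) stop("`spacing` required when `grid` is an array", call. = FALSE)
    g <- voxel_grid(grid, spacing, origin, kind = "unitless")
  }
  vals <- g$data
  if (!all(vals %in% c(0, 1)))
    stop("mask values must be exactly 0 or 1", call. = FALSE)
  storage.mode(g$data) <- "integer"
  g$kind <- "unitless"
  structure(list(grid = g, label = label), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> '%s'  %d voxels set, dim %s, spacing %s mm\n",
              x$label, sum(x$grid$data), paste(dim(x$grid$data), collapse = "x"),
              paste(signif(x$grid$spacing, 4), collapse = "x")))
  invisible(x)
}

is_binary_mask <- function(x) inherits(x, "binary_mask")

# accept either a voxel_grid or a binary_mask wherever geometry/data is needed
as_grid <- function(x) {
  if (is_binary_mask(x)) x$grid
  else if (is_voxel_grid(x)) x
  else stop("expected a voxel_grid or binary_mask", call. = FALSE)
}

#' Number of set voxels in a mask
#' @param m a `binary_mask`.
#' @return integer count.
#' @export
mask_count <- function(m) {
  stopifnot(is_binary_mask(m))
  sum(m$grid$data)
}

#' Mask volume in millilitres
#' @param m a `binary_mask`.
#' @return volume in ml.
#' @export
mask_volume_ml <- function(m) mask_count(m) * voxel_volume_ml(m)

#' Centroid of a mask in world coordinates
#' @param m a `binary_mask`.
#' @return length-3 world coordinates (mm) of the voxel-centre centroid.
#' @export
mask_centroid <- function(m) {
  stopifnot(is_binary_mask(m))
  idx <- which(m$grid$data == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no centroid", call. = FALSE)
  colMeans(world_coords(m$grid, idx))
}
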
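#' Window a CT volume to a normalised soft-tissue range
#'
#' Clips Hounsfield values to `[lo, hi]` and rescales affinely to `[0, 1]`.
#' The default window of -100 to 200 HU targets abdominal soft tissue, where
#' raw HU values of neighbouring organs overlap and direct thresholding is
#' unreliable. The mapping is monotone in the input.
#'
#' @param ct a [voxel_grid] with `kind = "HU"`.
#' @param lo,hi window bounds in HU; `lo < hi`.
#' @return A unitless [voxel_grid] with values in `[0, 1]`.
#' @export
hu_window <- function(ct, lo = -100, hi = 200) {
  stopifnot(is_voxel_grid(ct))
  if (ct$kind != "HU")
    stop("hu_window expects a volume of kind 'HU', got '", ct$kind, "'", call. = FALSE)
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi)
    stop("window bounds must satisfy lo < hi", call. = FALSE)
  out <- (pmin(pmax(ct$data, lo), hi) - lo) / (hi - lo)
  voxel_grid(array(out, dim(ct$data)), ct$spacing, ct$origin, kind = "unitless")
}

#' Resample a volume onto another grid geometry
#'
#' Maps the target voxel centres into the source volume through world
#' coordinates and interpolates: trilinear for images, nearest-neighbour for
#' masks (`method = "auto"` picks by input class). Target voxels outside the
#' source extent are filled with `fill`.
#'
#' @param v a [voxel_grid] or [binary_mask].
#' @param target a [voxel_grid] or [binary_mask] supplying the output
#'   geometry (its data are ignored).
#' @param method `"auto"`, `"linear"` or `"nearest"`.
#' @param fill value for voxels outside the source volume.
#' @return The resampled object, of the same class as `v`.
#' @export
resample_to <- function(v, target, method = c("auto", "linear", "nearest"),
                        fill = 0) {
  method <- match.arg(method)
  mask_in <- is_binary_mask(v)
  if (method == "auto") method <- if (mask_in) "nearest" else "linear"
  src <- as_grid(v)
  tgt <- as_grid(target)
  if (same_geometry(src, tgt)) {
    return(if (mask_in) v else src)
  }
  # world overlap check on bounding boxes (voxel-centre extents)
  lo_s <- src$origin; hi_s <- src$origin + (dim(src$data) - 1) * src$spacing
  lo_t <- tgt$origin; hi_t <- tgt$origin + (dim(tgt$data) - 1) * tgt$spacing
  if (any(hi_s < lo_t) || any(hi_t < lo_s))
    stop("source and target geometries do not overlap in world space", call. = FALSE)
  dt <- dim(tgt$data)
  # continuous (0-based) source index of every target voxel centre, per axis
  cont <- lapply(1:3, function(ax) {
    w <- tgt$origin[ax] + (seq_len(dt[ax]) - 1) * tgt$spacing[ax]
    (w - src$origin[ax]) / src$spacing[ax]
  })
  out <- if (method == "nearest")
    interp_nearest3(src$data, cont, fill)
  else
    interp_trilinear3(src$data, cont, fill)
  g <- voxel_grid(array(out, dt), tgt$spacing, tgt$origin, kind = src$kind)
  if (mask_in) {
    storage.mode(g$data) <- "integer"
    binary_mask(g, label = v$label)
  } else g
}

# cont: list of per-axis continuous 0-based indices; vectorized over the
# full target lattice via outer sums on linear indices.
interp_nearest3 <- function(a, cont, fill) {
  d <- dim(a)
  idx <- lapply(1:3, function(ax) {
    i <- round(cont[[ax]]) + 1
    i[i < 1 | i > d[ax]] <- NA
    i
  })
  n1 <- length(idx[[1]]); n2 <- length(idx[[2]]); n3 <- length(idx[[3]])
  lin <- rep(idx[[1]], times = n2 * n3) +
    rep(rep((idx[[2]] - 1) * d[1], each = n1), times = n3) +
    rep((idx[[3]] - 1) * d[1] * d[2], each = n1 * n2)
  out <- a[lin]
  out[is.na(out)] <- fill
  out
}

interp_trilinear3 <- function(a, cont, fill) {
  d <- dim(a)
  f <- lapply(1:3, function(ax) {
    x <- cont[[ax]]
    i0 <- floor(x)
    w <- x - i0
    # clamp cells fully outside -> NA; boundary cells clamp to edge sample
    out_of <- x < -1e-9 | x > d[ax] - 1 + 1e-9
    i0c <- pmin(pmax(i0, 0), d[ax] - 1)
    i1c <- pmin(i0c + 1, d[ax] - 1)
    w[i1c == i0c] <- 0
    i0c[out_of] <- NA
    i1c[out_of] <- NA
    list(i0 = i0c + 1, i1 = i1c + 1, w = w)
  })
  n <- vapply(cont, length, 1L)
  rep3 <- function(v1, v2, v3) {
    rep(v1, times = n[2] * n[3]) +
      rep(rep(v2, each = n[1]), times = n[3]) +
      rep(v3, each = n[1] * n[2])
  }
  w1 <- rep3(f[[1]]$w, numeric(n[2]), numeric(n[3]))
  w2 <- rep3(numeric(n[1]), f[[2]]$w, numeric(n[3]))
  w3 <- rep3(numeric(n[1]), numeric(n[2]), f[[3]]$w)
  acc <- numeric(prod(n))
  for (b1 in 0:1) for (b2 in 0:1) for (b3 in 0:1) {
    i1 <- if (b1) f[[1]]$i1 else f[[1]]$i0
    i2 <- if (b2) f[[2]]$i1 else f[[2]]$i0
    i3 <- if (b3) f[[3]]$i1 else f[[3]]$i0
    lin <- rep3(i1, (i2 - 1) * d[1], (i3 - 1) * d[1] * d[2])
    wt <- (if (b1) w1 else 1 - w1) * (if (b2) w2 else 1 - w2) *
      (if (b3) w3 else 1 - w3)
    v <- a[lin]
    v[is.na(v)] <- fill
    acc <- acc + wt * v
  }
  acc
}

#' Resize a 2D binary mask by linear interpolation
#'
#' Bilinearly interpolates the 0/1 field to the requested shape and
#' re-binarises at 0.5, the convention used when predicted masks at reduced
#' resolution (e.g. 256 x 256) are restored to the native grid (512 x 512).
#'
#' @param m 2D matrix of 0/1 values.
#' @param out_shape integer length-2 target (rows, cols).
#' @return Integer 0/1 matrix of dimension `out_shape`.
#' @export
resize_mask <- function(m, out_shape) {
  if (!is.matrix(m) || !all(m %in% c(0, 1)))
    stop("`m` must be a 2D binary (0/1) matrix", call. = FALSE)
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 2L || any(out_shape < 1L))
    stop("`out_shape` must be two positive integers", call. = FALSE)
  f <- resize_field(m, out_shape)
  out <- matrix(as.integer(f >= 0.5), out_shape[1], out_shape[2])
  out
}

# bilinear resize of a numeric 2D field, pixel-centre aligned at the corners
resize_field <- function(m, out_shape) {
  d <- dim(m)
  axis_idx <- function(n_in, n_out) {
    if (n_out == 1L) return(list(i0 = 1L, i1 = 1L, w = 0))
    x <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
    i0 <- pmin(floor(x), n_in - 1 - 1e-12)
    i0 <- pmax(i0, 0)
    w <- x - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    w[i1 == i0] <- 0
    list(i0 = i0 + 1, i1 = i1 + 1, w = w)
  }
  r <- axis_idx(d[1], out_shape[1])
  c_ <- axis_idx(d[2], out_shape[2])
  m00 <- m[r$i0, c_$i0, drop = FALSE]; m10 <- m[r$i1, c_$i0, drop = FALSE]
  m01 <- m[r$i0, c_$i1, drop = FALSE]; m11 <- m[r$i1, c_$i1, drop = FALSE]
  wr <- matrix(r$w, out_shape[1], out_shape[2])
  wc <- matrix(c_$w, out_shape[1], out_shape[2], byrow = TRUE)
  m00 * (1 - wr) * (1 - wc) + m10 * wr * (1 - wc) +
    m01 * (1 - wr) * wc + m11 * wr * wc
}

## ---- internal array machinery shared by phantom / kinetics / dosimetry ----

# separable Gaussian blur in physical units; each 1D kernel is discretely
# normalised so the array sum is conserved up to zero-padding truncation.
gauss_blur3 <- function(a, sigma_mm, spacing) {
  if (sigma_mm <= 0) return(a)
  for (ax in 1:3) {
    sig_vox <- sigma_mm / spacing[ax]
    r <- max(1L, ceiling(3 * sig_vox))
    k <- exp(-0.5 * ((-r:r) / sig_vox)^2)
    k <- k / sum(k)
    a <- conv_axis(a, k, ax)
  }
  a
}

# 1D convolution along axis `ax` with zero padding, via shifted adds
conv_axis <- function(a, k, ax) {
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    s <- j - r - 1L
    out <- out + k[j] * shift_array(a, s, ax)
  }
  out
}

# shift array along one axis by s voxels (positive = towards higher index),
# zero-filling the vacated slab
shift_array <- function(a, s, ax) {
  if (s == 0L) return(a)
  d <- dim(a)
  n <- d[ax]
  if (abs(s) >= n) return(array(0, d))
  out <- array(0, d)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  ix <- function(x, take) switch(ax,
                                 x[take, , , drop = FALSE],
                                 x[, take, , drop = FALSE],
                                 x[, , take, drop = FALSE])
  if (ax == 1) out[dst, , ] <- ix(a, src)
  else if (ax == 2) out[, dst, ] <- ix(a, src)
  else out[, , dst] <- ix(a, src)
  out
}

# zero-padded 3D convolution of `a` with centred kernel `k` via FFT;
# output has the dimensions of `a`
conv3_fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  if (any(dk %% 2L == 0L)) stop("kernel extents must be odd", call. = FALSE)
  dp <- da + dk - 1L
  pa <- array(0, dp); pa[seq_len(da[1]), seq_len(da[2]), seq_len(da[3])] <- a
  pk <- array(0, dp); pk[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  conv <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) / prod(dp)
  r <- (dk - 1L) / 2L
  conv[r[1] + seq_len(da[1]), r[2] + seq_len(da[2]), r[3] + seq_len(da[3])]
}

# connected components of a logical/0-1 array (2D or 3D, face connectivity)
# via the voxel adjacency graph
label_components <- function(mask) {
  d <- dim(mask)
  if (length(d) == 2L) {
    return(EBImage::bwlabel(matrix(as.numeric(mask), d[1], d[2])))
  }
  on <- which(mask != 0)
  lab <- array(0L, d)
  if (length(on) == 0L) return(lab)
  pos <- arrayInd(on, d)
  id <- seq_along(on)
  node_of <- array(0L, d)
  node_of[on] <- id
  edges <- integer(0)
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- pos[, ax] < d[ax]
    nb <- on[ok] + strides[ax]
    nb_id <- node_of[nb]
    has <- nb_id > 0L
    if (any(has))
      edges <- c(edges, rbind(id[ok][has], nb_id[has]))
  }
  g <- igraph::make_graph(edges = edges, n = length(on), directed = FALSE)
  comp <- igraph::components(g)$membership
  lab[on] <- as.integer(comp)
  lab
}

# keep the largest connected component of a 0/1 array
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return(array(as.integer(mask != 0), dim(mask)))
  tab <- tabulate(lab[lab > 0L])
  array(as.integer(lab == which.max(tab)), dim(mask))
}

# round half away from zero
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
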
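#' 2.5D slice-stack segmentation machinery
#'
#' A per-slice segmentation backend consumes a `slice_stack` — an odd number
#' of adjacent 2D frames from one anatomical plane with the prediction
#' target in the middle — and returns a `slice_result` (binary mask,
#' confidence score, bounding box, success flag). The functions here provide
#' everything around such a backend: stack assembly, plane-wise volume
#' segmentation, repair of failed slices, pixel-wise consensus across the
#' three orthogonal planes, and Dice evaluation. A deterministic classical
#' backend ([reference_backend()]) stands in where a trained convolutional
#' model would plug in.
#'
#' @name segmentation25d
NULL

plane_axis <- function(plane) {
  switch(plane, sagittal = 1L, coronal = 2L, axial = 3L,
         stop("plane must be axial, sagittal or coronal", call. = FALSE))
}

get_slice <- function(a, plane, i) {
  switch(plane_axis(plane), a[i, , ], a[, i, ], a[, , i])
}

set_slice <- function(a, plane, i, s) {
  ax <- plane_axis(plane)
  if (ax == 1L) a[i, , ] <- s else if (ax == 2L) a[, i, ] <- s else a[, , i] <- s
  a
}

#' Assemble 2.5D slice stacks from a volume
#'
#' Produces one stack per slice of the requested plane; each stack holds the
#' target slice in the middle and `k` context slices on either side. Edge
#' slices are padded by repeating the boundary slice, so every stack has
#' exactly `2k + 1` frames. `k = 0` degenerates to pure 2D slices.
#'
#' @param v a [voxel_grid].
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param k context half-width (non-negative integer).
#' @return List of `slice_stack` objects, one per slice.
#' @export
build_stacks <- function(v, plane = "axial", k = 1L) {
  stopifnot(is_voxel_grid(v))
  k <- as.integer(k)
  if (k < 0L) stop("`k` must be >= 0", call. = FALSE)
  n <- dim(v$data)[plane_axis(plane)]
  if (k >= n) stop("`k` must be smaller than the slice count (", n, ")", call. = FALSE)
  lapply(seq_len(n), function(i) {
    idx <- pmin(pmax(i + (-k:k), 1L), n)
    structure(list(frames = lapply(idx, function(j) get_slice(v$data, plane, j)),
                   center_index = i, plane = plane, k = k),
              class = "slice_stack")
  })
}

#' Per-slice segmentation result
#'
#' @param mask 2D 0/1 matrix (empty when `success = FALSE`).
#' @param score confidence in `[0, 1]`.
#' @param success whether the backend produced a mask for this slice.
#' @param bbox `(row0, col0, row1, col1)` covering all positive pixels, or
#'   `NULL` when unsuccessful.
#' @return An object of class `slice_result`.
#' @export
slice_result <- function(mask, score = 0, success = TRUE, bbox = NULL) {
  if (!success) mask[] <- 0L
  if (success && sum(mask) > 0 && is.null(bbox)) {
    idx <- which(mask != 0, arr.ind = TRUE)
    bbox <- c(min(idx[, 1]), min(idx[, 2]), max(idx[, 1]), max(idx[, 2]))
  }
  structure(list(mask = mask, score = score, success = success, bbox = bbox),
            class = "slice_result")
}

#' Wrap a per-slice function as a segmentation backend
#'
#' The contract every backend must satisfy: given a `slice_stack`, return a
#' `slice_result`, deterministically for identical input (backends with
#' internal randomness must accept and fix a seed at construction).
#'
#' @param fun function taking a `slice_stack` and returning a `slice_result`.
#' @param name backend name used in logs and provenance.
#' @return An object of class `segmenter_backend`.
#' @export
segmenter_backend <- function(fun, name = "custom") {
  stopifnot(is.function(fun))
  structure(list(fun = fun, name = name), class = "segmenter_backend")
}

#' Segment every slice of one plane
#'
#' Runs the backend on each 2.5D stack of the plane and assembles the
#' per-slice masks into a mask volume aligned with `v`. Slices where the
#' backend reports `success = FALSE` stay empty and are flagged for repair
#' by [interpolate_missing()].
#'
#' @param v a [voxel_grid] (typically a CT volume).
#' @param plane `"axial"`, `"sagittal"` or `"coronal"`.
#' @param backend a `segmenter_backend`.
#' @param k context half-width passed to [build_stacks()].
#' @return `list(mask = binary_mask, success = logical per slice)`.
#' @export
segment_plane <- function(v, plane = "axial", backend, k = 1L) {
  stopifnot(inherits(backend, "segmenter_backend"))
  stacks <- build_stacks(v, plane, k)
  out <- array(0L, dim(v$data))
  success <- logical(length(stacks))
  for (i in seq_along(stacks)) {
    res <- tryCatch(backend$fun(stacks[[i]]),
                    error = function(e) stop("backend '", backend$name,
                                             "' failed on ", plane, " slice ", i,
                                             ": ", conditionMessage(e), call. = FALSE))
    if (!inherits(res, "slice_result"))
      stop("backend '", backend$name, "' returned a non-slice_result on ",
           plane, " slice ", i, call. = FALSE)
    success[i] <- isTRUE(res$success)
    if (success[i]) out <- set_slice(out, plane, i, as.integer(res$mask != 0))
  }
  list(mask = binary_mask(voxel_grid(out, v$spacing, v$origin), label = backend$name),
       success = success)
}

# signed Euclidean distance field of a 2D binary slice (pixels): positive
# inside, negative outside; degenerate all-0 / all-1 slices get a large
# constant magnitude so interpolation against them behaves like copy/shrink
signed_distance2 <- function(m) {
  big <- sum(dim(m))
  if (all(m == 0)) return(matrix(-big, nrow(m), ncol(m)))
  if (all(m == 1)) return(matrix(big, nrow(m), ncol(m)))
  md <- matrix(as.numeric(m), nrow(m), ncol(m))
  EBImage::distmap(md) - EBImage::distmap(1 - md)
}

#' Repair failed slices by shape interpolation
#'
#' Every failed slice is reconstructed from the nearest successful slices
#' above and below: their signed Euclidean distance fields are combined as a
#' linear interpolation weighted by slice distance and re-thresholded at the
#' zero level set, so a failed slice midway between a small and a large
#' cross-section yields an intermediate contour rather than either
#' neighbour. Failed runs touching the volume ends copy the nearest
#' successful slice.
#'
#' @param maskvol a [binary_mask] volume from [segment_plane()].
#' @param success logical per-slice success flags.
#' @param plane plane along which the slices were predicted.
#' @return The repaired [binary_mask].
#' @export
interpolate_missing <- function(maskvol, success, plane = "axial") {
  stopifnot(is_binary_mask(maskvol))
  a <- maskvol$grid$data
  n <- dim(a)[plane_axis(plane)]
  if (length(success) != n)
    stop("`success` must have one flag per ", plane, " slice", call. = FALSE)
  ok <- which(success)
  if (length(ok) == 0L)
    stop("no successful slices to interpolate from", call. = FALSE)
  sdf_cache <- new.env(parent = emptyenv())
  sdf_of <- function(i) {
    key <- as.character(i)
    if (is.null(sdf_cache[[key]]))
      sdf_cache[[key]] <- signed_distance2(get_slice(a, plane, i))
    sdf_cache[[key]]
  }
  for (i in seq_len(n)[!success]) {
    lo <- ok[ok < i]; hi <- ok[ok > i]
    if (length(lo) == 0L) {
      s <- get_slice(a, plane, min(hi))
    } else if (length(hi) == 0L) {
      s <- get_slice(a, plane, max(lo))
    } else {
      p <- max(lo); q <- min(hi)
      w <- (i - p) / (q - p)
      sd <- (1 - w) * sdf_of(p) + w * sdf_of(q)
      s <- (sd > 0) + 0L
    }
    a <- set_slice(a, plane, i, s)
  }
  binary_mask(voxel_grid(a, maskvol$grid$spacing, maskvol$grid$origin),
              label = maskvol$label)
}

#' Pixel-wise consensus of three plane-wise segmentations
#'
#' Majority vote: a voxel is set iff at least two of the three plane-wise
#' mask volumes set it. All masks must share one grid geometry.
#'
#' @param m_ax,m_sag,m_cor [binary_mask] volumes from the axial, sagittal
#'   and coronal runs.
#' @return The consensus [binary_mask].
#' @export
consensus <- function(m_ax, m_sag, m_cor) {
  masks <- list(m_ax, m_sag, m_cor)
  stopifnot(all(vapply(masks, is_binary_mask, TRUE)))
  if (!same_geometry(m_ax, m_sag) || !same_geometry(m_ax, m_cor))
    stop("consensus requires identical mask geometries", call. = FALSE)
  votes <- m_ax$grid$data + m_sag$grid$data + m_cor$grid$data
  binary_mask(voxel_grid(array(as.integer(votes >= 2L), dim(votes)),
                         m_ax$grid$spacing, m_ax$grid$origin),
              label = m_ax$label)
}

#' Dice similarity coefficient
#'
#' `2|A ∩ B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#'
#' @param a,b [binary_mask] objects (or 0/1 arrays of equal dimension).
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (is_binary_mask(a) && is_binary_mask(b)) {
    if (!same_geometry(a, b))
      stop("dice requires identical mask geometries", call. = FALSE)
    a <- a$grid$data; b <- b$grid$data
  }
  if (!identical(dim(a), dim(b)))
    stop("dice requires identical mask dimensions", call. = FALSE)
  na <- sum(a != 0); nb <- sum(b != 0)
  if (na + nb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (na + nb)
}

#' Deterministic classical per-slice backend
#'
#' A threshold-and-components stand-in for a trained per-slice model, so the
#' full pipeline runs with no learned weights: the centre frame is windowed
#' to `[0, 1]` ([hu_window()] semantics), thresholded, and connected
#' components below `min_area_px` are dropped. The slice fails
#' (`success = FALSE`) when no component survives, exercising the same
#' failure path a learned backend exhibits on a small share of low-dose CT
#' slices. The score is the mean windowed intensity over the predicted mask.
#'
#' @param window HU window `(lo, hi)` applied to the centre frame.
#' @param threshold binarisation threshold on the windowed `[0, 1]` scale.
#' @param min_area_px minimum component area in pixels.
#' @return A `segmenter_backend`.
#' @export
reference_backend <- function(window = c(-100, 200), threshold = 0.4,
                              min_area_px = 10L) {
  if (length(window) != 2L || window[1] >= window[2])
    stop("`window` must be (lo, hi) with lo < hi", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must be in (0, 1)", call. = FALSE)
  fun <- function(stack) {
    f <- stack$frames[[stack$k + 1L]]
    win <- (pmin(pmax(f, window[1]), window[2]) - window[1]) /
      (window[2] - window[1])
    bin <- matrix(as.numeric(win >= threshold), nrow(f), ncol(f))
    lab <- EBImage::bwlabel(bin)
    keep <- which(tabulate(lab[lab > 0]) >= min_area_px)
    if (length(keep) == 0L)
      return(slice_result(matrix(0L, nrow(f), ncol(f)), score = 0, success = FALSE))
    mask <- matrix(as.integer(lab %in% keep), nrow(f), ncol(f))
    slice_result(mask, score = mean(win[mask == 1L]))
  }
  segmenter_backend(fun, name = "reference")
}

#' Threshold-based segmentation directly on SPECT
#'
#' The automated part of direct SPECT delineation: voxels at or above
#' `frac` times the maximum intensity (the maximum taken inside
#' `seed_region` when given, and the thresholding restricted to it) are
#' selected and the largest connected component is retained.
#'
#' @param spect a [voxel_grid] of activity concentration.
#' @param frac fraction of the maximum, in `(0, 1)`.
#' @param seed_region optional [binary_mask] restricting the search.
#' @param label organ label for the result.
#' @return A [binary_mask].
#' @export
spect_threshold_segment <- function(spect, frac = 0.42, seed_region = NULL,
                                    label = "organ") {
  stopifnot(is_voxel_grid(spect))
  if (frac <= 0 || frac >= 1)
    stop("`frac` must be in (0, 1)", call. = FALSE)
  vals <- spect$data
  if (!is.null(seed_region)) {
    stopifnot(is_binary_mask(seed_region))
    if (!same_geometry(spect, seed_region))
      stop("seed region must share the SPECT geometry", call. = FALSE)
    vals <- vals * seed_region$grid$data
  }
  mx <- max(vals)
  if (mx <= 0) stop("SPECT volume is all zero within the search region", call. = FALSE)
  sel <- largest_component(vals >= frac * mx)
  binary_mask(voxel_grid(sel, spect$spacing, spect$origin), label = label)
}

#' Consensus segmentation of a volume across the three planes
#'
#' Convenience wrapper running [segment_plane()] on the axial, sagittal and
#' coronal planes (with failed-slice repair per plane) and combining the
#' three mask volumes by [consensus()] majority vote.
#'
#' @inheritParams segment_plane
#' @return `list(mask = binary_mask, success = list per plane)`.
#' @export
segment_consensus <- function(v, backend, k = 1L) {
  runs <- lapply(c("axial", "sagittal", "coronal"), function(p) {
    r <- segment_plane(v, p, backend, k)
    if (any(r$success) && !all(r$success))
      r$mask <- interpolate_missing(r$mask, r$success, p)
    r
  })
  list(mask = consensus(runs[[1]]$mask, runs[[2]]$mask, runs[[3]]$mask),
       success = lapply(runs, `[[`, "success"))
}
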
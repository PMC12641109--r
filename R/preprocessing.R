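#' Standardize volume geometry
#'
#' Resamples a volume to 1 mm isotropic spacing (trilinear interpolation;
#' nearest-neighbour for masks) and then center-crops / zero-pads to the
#' standard 240 x 240 x 150 grid used by the downstream video pipeline.
#' A volume already at the target spacing and shape passes through
#' unchanged.
#'
#' @param vol an [mri_volume()] or [segmentation_mask()]
#' @param target_shape integer length-3 output grid
#' @param target_spacing numeric length-3 output spacing in mm
#' @param method `"linear"` (volumes) or `"nearest"` (masks); defaults to
#'   nearest for `segmentation_mask` input
#' @return object of the same class on the standard grid
#' @export
standardize_geometry <- function(vol,
                                 target_shape = c(240L, 240L, 150L),
                                 target_spacing = c(1, 1, 1),
                                 method = NULL) {
  is_mask <- inherits(vol, "segmentation_mask")
  if (!is_mask && !inherits(vol, "mri_volume")) {
    stop("vol must be an mri_volume or segmentation_mask")
  }
  if (is.null(method)) method <- if (is_mask) "nearest" else "linear"
  method <- match.arg(method, c("linear", "nearest"))
  if (any(vol$spacing_mm <= 0) || any(target_spacing <= 0)) {
    stop("non-positive spacing")
  }

  arr <- vol$data
  sp <- vol$spacing_mm
  if (!isTRUE(all.equal(sp, target_spacing))) {
    arr <- resample_trilinear(arr, sp, target_spacing, method)
  }
  arr <- center_crop_pad(arr, target_shape)
  if (is_mask) {
    segmentation_mask(arr, target_spacing)
  } else {
    mri_volume(arr, target_spacing, vol$modality)
  }
}

# separable axis-by-axis resampling; output voxel i (0-based) sits at world
# position i*out_sp and maps to input index i*out_sp/in_sp (edge-clamped)
resample_trilinear <- function(arr, in_sp, out_sp, method) {
  for (ax in 1:3) {
    L <- dim(arr)[ax]
    L2 <- max(1L, as.integer(round(L * in_sp[ax] / out_sp[ax])))
    if (L2 == L && isTRUE(all.equal(in_sp[ax], out_sp[ax]))) next
    pos <- (seq_len(L2) - 1) * out_sp[ax] / in_sp[ax]
    if (method == "nearest") {
      idx <- pmin(pmax(round(pos) + 1, 1), L)
      arr <- index_axis(arr, ax, idx)
    } else {
      lo <- pmin(pmax(floor(pos) + 1, 1), L)
      hi <- pmin(lo + 1, L)
      w <- pos - (lo - 1)
      w[hi == lo] <- 0
      a_lo <- index_axis(arr, ax, lo)
      a_hi <- index_axis(arr, ax, hi)
      wb <- broadcast_axis(w, dim(a_lo), ax)
      arr <- a_lo * (1 - wb) + a_hi * wb
    }
  }
  arr
}

index_axis <- function(arr, ax, idx) {
  switch(ax,
         arr[idx, , , drop = FALSE],
         arr[, idx, , drop = FALSE],
         arr[, , idx, drop = FALSE])
}

broadcast_axis <- function(w, dims, ax) {
  perm <- switch(ax, c(1, 2, 3), c(2, 1, 3), c(2, 3, 1))
  aperm(array(w, dim = dims[perm]), order(perm))
}

center_crop_pad <- function(arr, target) {
  out <- array(0, dim = target)
  src0 <- dst0 <- integer(3)
  len <- integer(3)
  for (ax in 1:3) {
    L <- dim(arr)[ax]
    Tn <- target[ax]
    if (L >= Tn) {
      src0[ax] <- floor((L - Tn) / 2)
      dst0[ax] <- 0L
      len[ax] <- Tn
    } else {
      src0[ax] <- 0L
      dst0[ax] <- floor((Tn - L) / 2)
      len[ax] <- L
    }
  }
  out[dst0[1] + seq_len(len[1]), dst0[2] + seq_len(len[2]),
      dst0[3] + seq_len(len[3])] <-
    arr[src0[1] + seq_len(len[1]), src0[2] + seq_len(len[2]),
        src0[3] + seq_len(len[3])]
  out
}

# round half away from zero (pinned for bit-reproducibility)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Percentile intensity normalization to the 8-bit range
#'
#' Maps the 1st-99th percentile of all voxel intensities linearly onto
#' 0-255, clipping below/above, then rounds half-away-from-zero. A constant
#' volume (degenerate percentiles) maps to all zeros with a warning.
#'
#' @param vol an [mri_volume()]
#' @param probs lower/upper percentile, default `c(0.01, 0.99)`
#' @return an [mri_volume()] with integer-valued data in \[0, 255\]
#' @export
normalize_intensity <- function(vol, probs = c(0.01, 0.99)) {
  stopifnot(inherits(vol, "mri_volume"))
  q <- stats::quantile(vol$data, probs = probs, names = FALSE, type = 7)
  p1 <- q[1]; p99 <- q[2]
  if (p99 <= p1) {
    warning("degenerate percentiles (constant volume); returning zeros")
    out <- array(0, dim = dim(vol$data))
  } else {
    scaled <- pmin(pmax((vol$data - p1) / (p99 - p1), 0), 1)
    out <- round_half_away(255 * scaled)
  }
  v <- mri_volume(out, vol$spacing_mm, vol$modality)
  attr(v, "percentiles") <- c(p1 = p1, p99 = p99)
  v
}

#' Whole-tumor bounding box
#'
#' The fixed 128 x 128 box shared by all frames of a subject: its top-left
#' corner is the minimum foreground row / column of the tumor mask over all
#' slices (0-based), clamped so the box stays inside the frame. If the
#' tumor extent exceeds 128 voxels in a direction the min-corner anchor is
#' kept and the tumor is truncated.
#'
#' @param mask a [segmentation_mask()]
#' @param size box side length in voxels (128)
#' @return a `bounding_box` list with 0-based `row0`, `col0`, `height`,
#'   `width`
#' @export
compute_bounding_box <- function(mask, size = 128L) {
  stopifnot(inherits(mask, "segmentation_mask"))
  d <- dim(mask$data)
  if (d[1] < size || d[2] < size) {
    stop("mask in-plane extent smaller than the bounding box")
  }
  fg <- which(mask$data != 0, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask")
  row0 <- min(fg[, 1]) - 1L   # 0-based
  col0 <- min(fg[, 2]) - 1L
  row0 <- min(row0, d[1] - size)
  col0 <- min(col0, d[2] - size)
  structure(list(row0 = as.integer(row0), col0 = as.integer(col0),
                 height = as.integer(size), width = as.integer(size)),
            class = "bounding_box")
}

#' Convert a normalized volume to a 150-frame video clip
#'
#' Frame k is slice k of the 8-bit volume, cropped losslessly to the fixed
#' bounding box. Every clip has exactly 150 frames of 128 x 128 pixels
#' regardless of tumor extent.
#'
#' @param vol8 normalized, geometry-standardized [mri_volume()] (150
#'   slices, values 0-255)
#' @param box a `bounding_box` from [compute_bounding_box()]
#' @return a `video_clip`: integer array `frames` (150 x 128 x 128) plus
#'   `source_modality`
#' @export
volume_to_video <- function(vol8, box) {
  stopifnot(inherits(vol8, "mri_volume"), inherits(box, "bounding_box"))
  d <- dim(vol8$data)
  if (d[3] != 150L) stop("volume must have exactly 150 slices")
  if (box$row0 < 0 || box$col0 < 0 ||
      box$row0 + box$height > d[1] || box$col0 + box$width > d[2]) {
    stop("bounding box outside volume")
  }
  if (min(vol8$data) < 0 || max(vol8$data) > 255) {
    stop("volume is not 8-bit normalized")
  }
  rows <- box$row0 + seq_len(box$height)
  cols <- box$col0 + seq_len(box$width)
  cropped <- vol8$data[rows, cols, , drop = FALSE]
  frames <- aperm(cropped, c(3, 1, 2))   # frame, row, col
  structure(list(frames = frames, source_modality = vol8$modality),
            class = "video_clip")
}

#' Delta contrast-enhancement volume
#'
#' Voxelwise T1wCE minus T1 subtraction, computed before intensity
#' normalization so the difference image receives its own 0-255 mapping.
#'
#' @param t1wce,t1 geometry-standardized [mri_volume()]s of equal shape
#' @return an [mri_volume()] with modality `"delta"`
#' @export
compute_delta_volume <- function(t1wce, t1) {
  stopifnot(inherits(t1wce, "mri_volume"), inherits(t1, "mri_volume"))
  if (!identical(dim(t1wce$data), dim(t1$data))) stop("shape mismatch")
  if (!isTRUE(all.equal(t1wce$spacing_mm, t1$spacing_mm))) {
    stop("spacing mismatch")
  }
  mri_volume(t1wce$data - t1$data, t1$spacing_mm, "delta")
}

#' Full preprocessing pipeline for one subject
#'
#' Fixed order: standardize geometry (volumes trilinear, mask nearest) ->
#' compute the delta volume -> percentile-normalize each of the five
#' volumes -> derive the whole-tumor bounding box from the standardized
#' mask -> crop each volume into a 150-frame clip. Returns the five clips
#' in branch order plus a metadata record.
#'
#' @param volumes named list with elements `t1`, `t1wce`, `t2`, `flair`
#'   ([mri_volume()]s)
#' @param mask a [segmentation_mask()] aligned with the volumes
#' @return list with `clips` (named list `flair`, `t1`, `t2`, `t1wce`,
#'   `delta_t1` of `video_clip`s) and `meta` (bounding box + per-modality
#'   percentiles)
#' @export
preprocess_subject <- function(volumes, mask) {
  need <- c("t1", "t1wce", "t2", "flair")
  if (!all(need %in% names(volumes))) {
    stop("volumes must contain t1, t1wce, t2, flair")
  }
  std <- lapply(volumes[need], standardize_geometry)
  mask_std <- standardize_geometry(mask)
  delta <- compute_delta_volume(std$t1wce, std$t1)
  five <- c(std, list(delta = delta))
  norm <- lapply(five, normalize_intensity)
  box <- compute_bounding_box(mask_std)
  clip_of <- function(mod) volume_to_video(norm[[mod]], box)
  clips <- list(flair = clip_of("flair"), t1 = clip_of("t1"),
                t2 = clip_of("t2"), t1wce = clip_of("t1wce"),
                delta_t1 = clip_of("delta"))
  pct <- lapply(norm, function(v) attr(v, "percentiles"))
  list(clips = clips, meta = list(bounding_box = box, percentiles = pct))
}

#' Write preprocessing outputs
#'
#' Clips are written as raw headerless 8-bit frame dumps (one file per
#' branch, `150*128*128` bytes, frame-major) plus a JSON sidecar recording
#' shapes, the bounding box and the normalization percentiles.
#'
#' @param prep output of [preprocess_subject()]
#' @param dir output directory
#' @param prefix file prefix
#' @export
write_preprocessed <- function(prep, dir, prefix = "subject") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in names(prep$clips)) {
    con <- file(file.path(dir, sprintf("%s_%s.u8", prefix, b)), "wb")
    writeBin(as.integer(aperm(prep$clips[[b]]$frames, c(3, 2, 1))), con,
             size = 1)
    close(con)
  }
  side <- list(frames = 150L, height = 128L, width = 128L,
               branches = names(prep$clips),
               bounding_box = unclass(prep$meta$bounding_box),
               percentiles = prep$meta$percentiles)
  jsonlite::write_json(side, file.path(dir, paste0(prefix, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
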
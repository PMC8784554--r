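#' Window a CT volume to the soft-tissue brain range and normalize
#'
#' Clamps intensities to `[lo, hi]` HU (the recommended 0-100 HU brain
#' window by default) and rescales the result linearly to `[0, 1]` for
#' network input. The operation is idempotent on already-windowed data up
#' to the final rescale.
#'
#' @param ct a [ct_volume()] or bare numeric array.
#' @param lo,hi window bounds in HU, `lo < hi`.
#' @param rescale if `TRUE` (default) map `[lo, hi]` linearly onto `[0, 1]`.
#' @return object of the same kind as `ct` with transformed intensities.
#' @export
window_hu <- function(ct, lo = 0, hi = 100, rescale = TRUE) {
  if (lo >= hi) stopf("window requires lo < hi (got %g, %g)", lo, hi)
  x <- vol_data(ct)
  x <- pmin(pmax(x, lo), hi)
  if (rescale) x <- (x - lo) / (hi - lo)
  if (inherits(ct, "ct_volume")) ct_volume(x, ct$spacing_mm) else x
}

#' Merge per-tissue probability maps into a single coded label volume
#'
#' Assigns each voxel the code of the class with the highest input value
#' (1 GM, 2 WM, 3 CSF) when that maximum reaches `threshold`, and
#' background (0) otherwise. Ties among maxima are broken by the fixed
#' priority GM > WM > CSF (the lowest code wins), which makes the merge
#' deterministic.
#'
#' @param gm,wm,csf same-shaped arrays with values in `[0, 1]`.
#' @param threshold minimum winning value required to leave background.
#' @param spacing_mm voxel spacing recorded on the output.
#' @return a [label_volume()].
#' @export
merge_labels <- function(gm, wm, csf, threshold = 0.5,
                         spacing_mm = vol_spacing(gm)) {
  g <- vol_data(gm); w <- vol_data(wm); c_ <- vol_data(csf)
  if (!all(dim(g) == dim(w)) || !all(dim(g) == dim(c_)))
    stopf("gm/wm/csf shapes differ")
  rng <- range(g, w, c_)
  if (rng[1] < 0 || rng[2] > 1) stopf("inputs must lie in [0, 1]")
  p <- cbind(as.vector(g), as.vector(w), as.vector(c_))
  best <- max.col(p, ties.method = "first")   # lowest code wins ties
  top <- p[cbind(seq_len(nrow(p)), best)]
  code <- ifelse(top >= threshold, best, 0L)
  label_volume(array(as.integer(code), dim = dim(g)), spacing_mm)
}

#' One-hot encode a merged label volume
#'
#' Converts codes `{0, 1, 2, 3}` into a 4-channel indicator array with
#' channel order (background, GM, WM, CSF); channels sum to one at every
#' voxel.
#'
#' @param m a [label_volume()] or integer array with codes in `{0,1,2,3}`.
#' @return numeric 4D array `dim(m) x 4`.
#' @export
to_categorical <- function(m) {
  x <- vol_data(m)
  if (!all(x %in% 0:3)) stopf("label codes must be in {0, 1, 2, 3}")
  out <- vapply(0:3, function(k) as.numeric(x == k),
                numeric(length(x)))
  array(out, dim = c(dim(x), 4L))
}

#' Per-class binary mask of a merged label volume
#'
#' @param m a [label_volume()] or integer array.
#' @param code tissue code (1 GM, 2 WM, 3 CSF, 0 background).
#' @return numeric 0/1 array of the same shape.
#' @export
class_mask <- function(m, code) {
  x <- vol_data(m)
  array(as.numeric(x == code), dim = dim(x))
}

#' Resize a volume to a target grid
#'
#' Intensity volumes are resampled by separable linear interpolation; label
#' volumes by nearest neighbour, which preserves the code set (no invented
#' codes). Resizing to the identical shape returns the input bit-exactly.
#' Spacing metadata is rescaled so physical extent is preserved.
#'
#' @param vol a [ct_volume()], [label_volume()] or bare array.
#' @param target_shape integer triple (or same length as `dim(vol)`).
#' @param kind `"intensity"` (linear) or `"label"` (nearest). Passing a
#'   `label_volume` with `kind = "intensity"` is rejected: linear
#'   interpolation would corrupt the codes.
#' @return resized object of the same kind as the input.
#' @export
resize_volume <- function(vol, target_shape,
                          kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  x <- vol_data(vol)
  if (inherits(vol, "label_volume") && kind == "intensity")
    stopf("label volumes must be resized with kind = 'label' (nearest neighbour)")
  target_shape <- as.integer(target_shape)
  if (length(target_shape) != length(dim(x)))
    stopf("target_shape must have %d entries", length(dim(x)))
  if (any(target_shape < 1L)) stopf("target dims must be positive")
  if (all(target_shape == dim(x))) {
    out <- x
  } else {
    out <- x
    for (ax in seq_along(target_shape)) {
      if (dim(out)[ax] != target_shape[ax])
        out <- resample_axis(out, ax, target_shape[ax],
                             linear = (kind == "intensity"))
    }
  }
  if (inherits(vol, "ct_volume") || inherits(vol, "label_volume")) {
    sp <- vol$spacing_mm * dim(x) / target_shape
    if (inherits(vol, "label_volume")) label_volume(out, sp)
    else ct_volume(out, sp)
  } else out
}

# Separable resampling of one axis with centre-aligned coordinates
# (output voxel centre c maps to input coordinate (c + 0.5) * n_in/n_out - 0.5).
resample_axis <- function(x, axis, n_out, linear = TRUE) {
  d <- dim(x)
  n_in <- d[axis]
  pos <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5  # 1-based input coords
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = n_in)
  if (linear) {
    lo <- pmin(pmax(floor(pos), 1L), n_in)
    hi <- pmin(lo + 1L, n_in)
    w <- pos - lo
    res <- m[lo, , drop = FALSE] * (1 - w) + m[hi, , drop = FALSE] * w
  } else {
    idx <- pmin(pmax(round(pos), 1L), n_in)
    res <- m[idx, , drop = FALSE]
    if (is.integer(x)) storage.mode(res) <- "integer"
  }
  out <- array(res, dim = c(n_out, d[-axis]))
  aperm(out, order(perm))
}
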
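#' Fuse single-task probability maps by the voxel-wise maximum rule
#'
#' For three stacked slice-wise prediction maps `I_GM`, `I_WM`, `I_CSF`,
#' each voxel is assigned to the tissue class with the maximum intensity at
#' that voxel, so the resulting masks have no overlapping voxels by
#' construction. A voxel whose winning intensity falls below
#' `bg_threshold` is assigned to background: the verbal maximum rule alone
#' would force air outside the head into a tissue class. Ties among maxima
#' are broken by the fixed priority GM > WM > CSF.
#'
#' @param gm,wm,csf same-shaped probability arrays in `[0, 1]`.
#' @param bg_threshold minimum winning probability required to leave
#'   background (default 0.5).
#' @param spacing_mm voxel spacing recorded on the output.
#' @return a [label_volume()] (0 background, 1 GM, 2 WM, 3 CSF).
#' @export
fuse_argmax <- function(gm, wm, csf, bg_threshold = 0.5,
                        spacing_mm = vol_spacing(gm)) {
  merge_labels(gm, wm, csf, threshold = bg_threshold,
               spacing_mm = spacing_mm)
}

#' Binarize a multitask probability map by global thresholding
#'
#' Applies a global threshold (default 0.5) to the GM, WM and CSF channels
#' of a four-channel softmax prediction. The comparison is inclusive
#' (`>= t`), so a channel at exactly the threshold is kept. With softmax
#' inputs and `t >= 0.5` at most one channel can pass per voxel, so the
#' masks are pairwise disjoint.
#'
#' @param prob4 4D array (x, y, z, channel), channel order (background, GM,
#'   WM, CSF), values in `[0, 1]`.
#' @param t threshold, strictly inside `(0, 1)`.
#' @return named list of binary 0/1 arrays `gm`, `wm`, `csf`.
#' @export
binarize_threshold <- function(prob4, t = 0.5) {
  if (t <= 0 || t >= 1) stopf("threshold must lie strictly in (0, 1)")
  if (length(dim(prob4)) != 4L || dim(prob4)[4] != 4L)
    stopf("prob4 must be a 4-channel array (background, GM, WM, CSF)")
  rng <- range(prob4)
  if (rng[1] < 0 || rng[2] > 1) stopf("channels must lie in [0, 1]")
  d <- dim(prob4)[1:3]
  list(gm = array(as.numeric(prob4[, , , 2] >= t), d),
       wm = array(as.numeric(prob4[, , , 3] >= t), d),
       csf = array(as.numeric(prob4[, , , 4] >= t), d))
}
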
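#' Plan a deterministic sliding-window patch grid
#'
#' Computes every patch origin for tiling a volume with fixed-size patches,
#' sliding with the given per-axis step. By default patches are
#' 128 x 128 x 32 with a step of 64 in x and y and a single z position
#' (patch depth = volume depth), the tiling used for acquisition-scale
#' 512 x 512 x 32 volumes, which yields 7 x 7 x 1 = 49 patches. Origins are
#' ordered x fastest, then y, then z.
#'
#' @param volume_shape integer triple.
#' @param patch_shape integer triple, each `<=` the volume dimension.
#' @param step positive integer triple; `NULL` (default) uses
#'   `c(64, 64, patch_shape[3])`.
#' @return an object of class `patch_grid` with fields `volume_shape`,
#'   `patch_shape`, `step`, `origins` (n x 3 matrix of 0-based voxel
#'   offsets) and `n_patches`.
#' @export
plan_grid <- function(volume_shape, patch_shape = c(128L, 128L, 32L),
                      step = NULL) {
  volume_shape <- as.integer(check_triple(volume_shape, "volume_shape",
                                          integer = TRUE))
  patch_shape <- as.integer(check_triple(patch_shape, "patch_shape",
                                         integer = TRUE))
  if (is.null(step)) step <- c(64L, 64L, patch_shape[3])
  step <- as.integer(check_triple(step, "step", integer = TRUE))
  if (any(patch_shape > volume_shape))
    stopf("patch_shape %s exceeds volume_shape %s",
          paste(patch_shape, collapse = "x"),
          paste(volume_shape, collapse = "x"))
  pos <- lapply(1:3, function(ax)
    seq.int(0L, volume_shape[ax] - patch_shape[ax], by = step[ax]))
  origins <- as.matrix(expand.grid(x = pos[[1]], y = pos[[2]], z = pos[[3]],
                                   KEEP.OUT.ATTRS = FALSE))
  storage.mode(origins) <- "integer"
  structure(list(volume_shape = volume_shape, patch_shape = patch_shape,
                 step = step, origins = origins,
                 n_patches = nrow(origins)),
            class = "patch_grid")
}

#' @export
print.patch_grid <- function(x, ...) {
  counts <- vapply(1:3, function(ax)
    length(unique(x$origins[, ax])), integer(1))
  cat(sprintf("<patch_grid> %s volume, %s patches, step %s: %s = %d patches\n",
              paste(x$volume_shape, collapse = "x"),
              paste(x$patch_shape, collapse = "x"),
              paste(x$step, collapse = "x"),
              paste(counts, collapse = " x "), x$n_patches))
  invisible(x)
}

grid_covers_volume <- function(grid) {
  all((grid$volume_shape - grid$patch_shape) %% grid$step == 0L)
}

#' Extract the ordered patch list of a volume
#'
#' Works identically for plain 3D volumes and channelled 4D volumes
#' (spatial dims first, channels last, carried through unchanged).
#'
#' @param vol array whose first three dims equal `grid$volume_shape`, with
#'   an optional trailing channel dim; or a `ct_volume` / `label_volume`.
#' @param grid a [plan_grid()] result.
#' @return list of `grid$n_patches` arrays in grid order.
#' @export
extract_patches <- function(vol, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  x <- vol_data(vol)
  d <- dim(x)
  if (length(d) < 3L || !all(d[1:3] == grid$volume_shape))
    stopf("volume shape %s does not match grid volume_shape %s",
          paste(d, collapse = "x"),
          paste(grid$volume_shape, collapse = "x"))
  p <- grid$patch_shape
  has_ch <- length(d) == 4L
  lapply(seq_len(grid$n_patches), function(i) {
    o <- grid$origins[i, ]
    if (has_ch)
      x[(o[1] + 1L):(o[1] + p[1]), (o[2] + 1L):(o[2] + p[2]),
        (o[3] + 1L):(o[3] + p[3]), , drop = FALSE]
    else
      x[(o[1] + 1L):(o[1] + p[1]), (o[2] + 1L):(o[2] + p[2]),
        (o[3] + 1L):(o[3] + p[3]), drop = FALSE]
  })
}

#' Stitch patch-wise values back into a volume
#'
#' Recombines an ordered patch list into the full volume. Where patches
#' overlap, the voxel value is the arithmetic mean of all covering patches
#' (a symmetric rule that leaves agreeing predictions unchanged and keeps
#' softmax channel sums normalized). If the grid does not tile the volume
#' fully, an error points to [pad_to_grid()].
#'
#' @param patches list of arrays as produced by [extract_patches()] (3D, or
#'   4D with a channel dim shared by all patches).
#' @param grid the [plan_grid()] used for extraction.
#' @return array of shape `grid$volume_shape` (plus the channel dim if the
#'   patches carried one).
#' @export
stitch_patches <- function(patches, grid) {
  stopifnot(inherits(grid, "patch_grid"))
  if (length(patches) != grid$n_patches)
    stopf("expected %d patches, got %d", grid$n_patches, length(patches))
  if (!grid_covers_volume(grid))
    stopf(paste("grid leaves voxels uncovered ((dim - patch) not divisible",
                "by step); pad the volume with pad_to_grid() and crop after",
                "stitching"))
  p <- grid$patch_shape
  d1 <- dim(patches[[1]])
  has_ch <- length(d1) == 4L
  n_ch <- if (has_ch) d1[4] else 1L
  out_dim <- c(grid$volume_shape, if (has_ch) n_ch)
  acc <- array(0, dim = out_dim)
  cnt <- array(0, dim = grid$volume_shape)
  for (i in seq_len(grid$n_patches)) {
    pt <- patches[[i]]
    if (!all(dim(pt)[1:3] == p)) stopf("patch %d has wrong shape", i)
    o <- grid$origins[i, ]
    ix <- (o[1] + 1L):(o[1] + p[1])
    iy <- (o[2] + 1L):(o[2] + p[2])
    iz <- (o[3] + 1L):(o[3] + p[3])
    if (has_ch) acc[ix, iy, iz, ] <- acc[ix, iy, iz, ] + pt
    else acc[ix, iy, iz] <- acc[ix, iy, iz] + pt
    cnt[ix, iy, iz] <- cnt[ix, iy, iz] + 1
  }
  if (any(cnt == 0)) stopf("internal error: uncovered voxels after tiling")
  if (has_ch) acc / replicate(n_ch, cnt) else acc / cnt
}

#' Pad a volume so a patch grid tiles it exactly
#'
#' Symmetric zero-padding up to the next size where
#' `(dim - patch) %% step == 0`; [crop_to_shape()] undoes it after
#' stitching.
#'
#' @param vol 3D or 4D array (or wrapped volume).
#' @param patch_shape,step as in [plan_grid()].
#' @return list with `data` (padded array) and `offset` (0-based origin of
#'   the original volume inside the padded one).
#' @export
pad_to_grid <- function(vol, patch_shape = c(128L, 128L, 32L), step = NULL) {
  x <- vol_data(vol)
  if (is.null(step)) step <- c(64L, 64L, patch_shape[3])
  d <- dim(x)[1:3]
  target <- pmax(d, patch_shape)
  rem <- (target - patch_shape) %% step
  target <- target + ifelse(rem == 0L, 0L, step - rem)
  lo <- (target - d) %/% 2L
  out_dim <- c(target, if (length(dim(x)) == 4L) dim(x)[4])
  out <- array(0, dim = out_dim)
  ix <- (lo[1] + 1L):(lo[1] + d[1])
  iy <- (lo[2] + 1L):(lo[2] + d[2])
  iz <- (lo[3] + 1L):(lo[3] + d[3])
  if (length(dim(x)) == 4L) out[ix, iy, iz, ] <- x else out[ix, iy, iz] <- x
  list(data = out, offset = as.integer(lo))
}

#' @rdname pad_to_grid
#' @param padded a padded array.
#' @param offset,shape origin and shape of the region to recover.
#' @export
crop_to_shape <- function(padded, offset, shape) {
  ix <- (offset[1] + 1L):(offset[1] + shape[1])
  iy <- (offset[2] + 1L):(offset[2] + shape[2])
  iz <- (offset[3] + 1L):(offset[3] + shape[3])
  if (length(dim(padded)) == 4L) padded[ix, iy, iz, , drop = FALSE]
  else padded[ix, iy, iz, drop = FALSE]
}

#' Slice a volume into an ordered axial stack, and back
#'
#' `extract_slices` splits a volume along z into 2D slices in ascending z
#' order; `stack_slices` reassembles them, so
#' `stack_slices(extract_slices(v))` is the identity.
#'
#' @param vol 3D array or wrapped volume.
#' @return `extract_slices`: list of matrices; `stack_slices`: 3D array.
#' @export
extract_slices <- function(vol) {
  x <- vol_data(vol)
  if (length(dim(x)) != 3L) stopf("extract_slices expects a 3D volume")
  lapply(seq_len(dim(x)[3]), function(k) x[, , k])
}

#' @rdname extract_slices
#' @param slices list of equally-shaped matrices, ascending z.
#' @export
stack_slices <- function(slices) {
  if (!length(slices)) stopf("empty slice list")
  d <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), d), logical(1))
  if (!all(ok)) stopf("inconsistent slice shapes")
  array(unlist(slices, use.names = FALSE), dim = c(d, length(slices)))
}
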
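#' Continuous Dice coefficient between a soft prediction and a binary mask
#'
#' The continuous Dice score generalizes the Dice coefficient to a
#' probabilistic prediction `b` compared against a binary reference `a`:
#' \deqn{d_c = \frac{2\sum_i a_i b_i}{c\sum_i a_i + \sum_i b_i}, \quad
#'       c = \frac{\sum_i a_i b_i}{\sum_i a_i\,\mathrm{sign}(b_i)}}
#' with `c = 1` when its denominator vanishes. On binary predictions
#' `c = 1` and the measure reduces to the classical Dice coefficient
#' `2|A n B| / (|A| + |B|)`. Conventions for degenerate inputs: both masks
#' empty returns 1; an empty reference against a non-empty prediction (or
#' vice versa) returns 0.
#'
#' @param pred numeric array in `[0, 1]`.
#' @param ref binary array of the same shape.
#' @return scalar in `[0, 1]`.
#' @export
continuous_dice <- function(pred, ref) {
  b <- as.vector(vol_data(pred))
  a <- as.vector(vol_data(ref))
  if (length(a) != length(b)) stopf("pred and ref shapes differ")
  if (min(b) < 0 || max(b) > 1) stopf("pred must lie in [0, 1]")
  if (!all(a %in% c(0, 1))) stopf("ref must be binary")
  inter <- sum(a * b)
  sum_b <- sum(b)
  if (sum(a) == 0 && sum_b == 0) return(1)
  denom_c <- sum(a * sign(b))
  c_ <- if (denom_c > 0) inter / denom_c else 1
  den <- c_ * sum(a) + sum_b
  if (den == 0) return(0)
  2 * inter / den
}

# 6-connectivity boundary: mask voxels with at least one face neighbour
# outside the mask (volume edges count as outside).
boundary_mask <- function(A) {
  d <- dim(A)
  inside <- A > 0
  core <- inside
  shift_and <- function(cur, ax, by) {
    n <- d[ax]
    idx <- pmin(pmax(seq_len(n) + by, 1L), n)
    edge <- if (by > 0) n else 1L
    out <- switch(ax,
                  inside[idx, , , drop = FALSE],
                  inside[, idx, , drop = FALSE],
                  inside[, , idx, drop = FALSE])
    # voxels whose neighbour falls off the volume are boundary
    switch(ax,
           out[edge, , ] <- FALSE,
           out[, edge, ] <- FALSE,
           out[, , edge] <- FALSE)
    cur & out
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) core <- shift_and(core, ax, by)
  inside & !core
}

# mm coordinates of the TRUE voxels of a mask.
mask_points_mm <- function(mask, spacing_mm) {
  idx <- which(mask, arr.ind = TRUE)
  sweep(idx, 2L, spacing_mm, `*`)
}

min_dists <- function(P, Q, chunk = 512L) {
  # directed minimum Euclidean distances from each row of P to the set Q
  q2 <- rowSums(Q^2)
  out <- numeric(nrow(P))
  for (s in seq(1L, nrow(P), by = chunk)) {
    ii <- s:min(s + chunk - 1L, nrow(P))
    Pc <- P[ii, , drop = FALSE]
    d2 <- outer(rowSums(Pc^2), q2, `+`) - 2 * tcrossprod(Pc, Q)
    out[ii] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  out
}

#' Directed boundary-to-boundary surface distances
#'
#' Extracts the 6-connectivity boundary voxels of two binary masks and
#' returns, in mm under the (possibly anisotropic) voxel spacing, the
#' minimum distance from every boundary point of `A` to the boundary of
#' `B` and vice versa. This is the shared kernel for [ahd()] and [mhd()].
#'
#' @param A,B non-empty binary 3D arrays of equal shape.
#' @param spacing_mm voxel spacing triple in mm.
#' @return list with numeric vectors `a_to_b` and `b_to_a`.
#' @export
surface_distances <- function(A, B, spacing_mm = c(0.5, 0.5, 5)) {
  Aa <- vol_data(A) > 0; Bb <- vol_data(B) > 0
  if (!all(dim(Aa) == dim(Bb))) stopf("mask shapes differ")
  if (!any(Aa) || !any(Bb))
    stopf("surface distance is undefined for an empty mask")
  spacing_mm <- check_triple(spacing_mm, "spacing_mm")
  Pa <- mask_points_mm(boundary_mask(Aa), spacing_mm)
  Pb <- mask_points_mm(boundary_mask(Bb), spacing_mm)
  list(a_to_b = min_dists(Pa, Pb), b_to_a = min_dists(Pb, Pa))
}

#' Average Hausdorff distance (mm)
#'
#' Pooled symmetric mean of the directed minimum boundary distances:
#' `(sum_a min_b d + sum_b min_a d) / (|boundary A| + |boundary B|)`.
#' Symmetric in its arguments and zero iff the boundaries coincide.
#'
#' @inheritParams surface_distances
#' @return scalar distance in mm.
#' @export
ahd <- function(A, B, spacing_mm = c(0.5, 0.5, 5)) {
  sd_ <- surface_distances(A, B, spacing_mm)
  (sum(sd_$a_to_b) + sum(sd_$b_to_a)) /
    (length(sd_$a_to_b) + length(sd_$b_to_a))
}

#' Modified Hausdorff distance (mm)
#'
#' The Dubuisson-Jain modified Hausdorff distance: the maximum of the two
#' directed mean boundary distances,
#' `max(mean_a min_b d, mean_b min_a d)`.
#'
#' @inheritParams surface_distances
#' @return scalar distance in mm.
#' @export
mhd <- function(A, B, spacing_mm = c(0.5, 0.5, 5)) {
  sd_ <- surface_distances(A, B, spacing_mm)
  max(mean(sd_$a_to_b), mean(sd_$b_to_a))
}

#' Volumetric error
#'
#' Scale-free volume disagreement `|vA - vB| / (vA + vB)`, in `[0, 1]`,
#' symmetric, zero iff the volumes are equal.
#'
#' @param vA,vB non-negative volumes (any common unit), `vA + vB > 0`.
#' @return scalar in `[0, 1]`.
#' @export
volumetric_error <- function(vA, vB) {
  if (vA < 0 || vB < 0 || vA + vB <= 0)
    stopf("volumes must be non-negative with a positive sum")
  abs(vA - vB) / (vA + vB)
}

#' Mask volume in liters
#'
#' Voxel count times voxel volume (mm^3), converted to liters (1 L =
#' 10^6 mm^3).
#'
#' @param mask binary array (or anything coercible; positive entries
#'   count).
#' @param spacing_mm voxel spacing triple in mm.
#' @return volume in liters.
#' @export
volume_liters <- function(mask, spacing_mm = c(0.5, 0.5, 5)) {
  spacing_mm <- check_triple(spacing_mm, "spacing_mm")
  sum(vol_data(mask) > 0) * prod(spacing_mm) * 1e-6
}

#' Cohort-level Pearson correlation of tissue volumes
#'
#' Standard product-moment correlation between predicted and reference
#' per-subject volumes; requires at least three subjects and non-zero
#' variance on both sides.
#'
#' @param pred_volumes,ref_volumes numeric vectors of equal length >= 3.
#' @return Pearson r.
#' @export
cohort_pearson <- function(pred_volumes, ref_volumes) {
  if (length(pred_volumes) != length(ref_volumes))
    stopf("volume vectors differ in length")
  if (length(pred_volumes) < 3L)
    stopf("Pearson correlation needs at least 3 subjects")
  if (stats::sd(pred_volumes) == 0 || stats::sd(ref_volumes) == 0)
    stopf("Pearson correlation is undefined under zero variance")
  stats::cor(pred_volumes, ref_volumes)
}

TISSUES <- c(gm = 1L, wm = 2L, csf = 3L)

#' Evaluate one subject's prediction against its reference labels
#'
#' Computes the per-tissue metric row: continuous Dice between the soft
#' probability map and the binary reference, AHD and MHD between the
#' binarized prediction and the reference mask, volumetric error, and both
#' volumes in liters. Reference masks are the per-class binarizations of
#' the merged ground-truth label. An empty prediction or reference mask
#' leaves the distance columns `NA` (the distances are undefined there).
#'
#' @param probs named list `gm`, `wm`, `csf` of probability arrays.
#' @param pred_masks named list `gm`, `wm`, `csf` of binary arrays (the
#'   binarized prediction).
#' @param ref a [label_volume()] of ground-truth codes.
#' @param subject_id,model_tag identifiers copied into the rows.
#' @return data.frame with one row per tissue: `subject_id`, `tissue`,
#'   `model_tag`, `d_c`, `ahd_mm`, `mhd_mm`, `ve`, `v_ct_liters`,
#'   `v_ref_liters`.
#' @export
evaluate_subject <- function(probs, pred_masks, ref, subject_id = "s1",
                             model_tag = "2D") {
  spacing <- vol_spacing(ref)
  rows <- lapply(names(TISSUES), function(tis) {
    ref_mask <- class_mask(ref, TISSUES[[tis]])
    pm <- vol_data(pred_masks[[tis]])
    d_c <- continuous_dice(probs[[tis]], ref_mask)
    have_both <- any(pm > 0) && any(ref_mask > 0)
    data.frame(
      subject_id = subject_id, tissue = toupper(tis), model_tag = model_tag,
      d_c = d_c,
      ahd_mm = if (have_both) ahd(pm, ref_mask, spacing) else NA_real_,
      mhd_mm = if (have_both) mhd(pm, ref_mask, spacing) else NA_real_,
      ve = volumetric_error(volume_liters(pm, spacing),
                            volume_liters(ref_mask, spacing)),
      v_ct_liters = volume_liters(pm, spacing),
      v_ref_liters = volume_liters(ref_mask, spacing),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evaluate a directory of predictions against reference labels
#'
#' Pairs subjects by id between a prediction directory (per-tissue
#' probability maps `prob_<id>_<tissue>.nii.gz`) and a reference directory
#' (`labels_<id>.nii.gz`), binarizes each prediction with the rule of its
#' model family (argmax fusion for slice-wise 2D predictions, global 0.5
#' thresholding for multitask 3D predictions), and returns the full
#' per-subject metric table. Subjects present on one side only are skipped
#' with a warning.
#'
#' @param pred_dir,ref_dir directories of NIfTI files as above.
#' @param model_tag `"2D"` or `"3D"`; selects the binarization rule.
#' @return data.frame of [evaluate_subject()] rows for all paired
#'   subjects.
#' @export
evaluate_testset <- function(pred_dir, ref_dir, model_tag = c("2D", "3D")) {
  model_tag <- match.arg(model_tag)
  pred_ids <- unique(sub("^prob_(.*)_(gm|wm|csf)\\.nii\\.gz$", "\\1",
                         list.files(pred_dir,
                                    pattern = "^prob_.*\\.nii\\.gz$")))
  ref_ids <- sub("^labels_(.*)\\.nii\\.gz$", "\\1",
                 list.files(ref_dir, pattern = "^labels_.*\\.nii\\.gz$"))
  only <- c(setdiff(pred_ids, ref_ids), setdiff(ref_ids, pred_ids))
  if (length(only))
    warning(sprintf("skipping unpaired subjects: %s",
                    paste(sort(only), collapse = ", ")))
  ids <- sort(intersect(pred_ids, ref_ids))
  rows <- lapply(ids, function(id) {
    probs <- lapply(c(gm = "gm", wm = "wm", csf = "csf"), function(tis) {
      f <- file.path(pred_dir, sprintf("prob_%s_%s.nii.gz", id, tis))
      vol_data(read_ct_volume(f))
    })
    ref <- read_label_volume(file.path(ref_dir,
                                       sprintf("labels_%s.nii.gz", id)))
    masks <- binarize_prediction(probs, model_tag)
    evaluate_subject(probs, masks, ref, subject_id = id,
                     model_tag = model_tag)
  })
  do.call(rbind, rows)
}

# The two published binarization rules, keyed by model family.
binarize_prediction <- function(probs, model_tag) {
  if (model_tag == "2D") {
    fused <- fuse_argmax(probs$gm, probs$wm, probs$csf)
    list(gm = class_mask(fused, 1L), wm = class_mask(fused, 2L),
         csf = class_mask(fused, 3L))
  } else {
    d <- dim(probs$gm)
    bg <- pmax(1 - probs$gm - probs$wm - probs$csf, 0)
    prob4 <- array(c(bg, probs$gm, probs$wm, probs$csf), dim = c(d, 4L))
    binarize_threshold(prob4, 0.5)
  }
}

#' Summarize a metric table into the benchmark report layout
#'
#' Aggregates the per-subject rows into mean +/- SD per model family and
#' tissue for d_c, VE, AHD, MHD and V_CT, plus one cohort-level Pearson r
#' per tissue (NA when fewer than three subjects are available).
#'
#' @param metrics data.frame of [evaluate_subject()] rows.
#' @return data.frame with one row per model_tag x tissue.
#' @export
summarize_metrics <- function(metrics) {
  parts <- split(metrics, list(metrics$model_tag, metrics$tissue),
                 drop = TRUE)
  rows <- lapply(parts, function(df) {
    r <- if (nrow(df) >= 3L &&
             stats::sd(df$v_ct_liters) > 0 && stats::sd(df$v_ref_liters) > 0)
      cohort_pearson(df$v_ct_liters, df$v_ref_liters) else NA_real_
    data.frame(model_tag = df$model_tag[1], tissue = df$tissue[1],
               n = nrow(df),
               d_c_mean = mean(df$d_c), d_c_sd = stats::sd(df$d_c),
               r = r,
               ve_mean = mean(df$ve), ve_sd = stats::sd(df$ve),
               ahd_mean = mean(df$ahd_mm, na.rm = TRUE),
               ahd_sd = stats::sd(df$ahd_mm, na.rm = TRUE),
               mhd_mean = mean(df$mhd_mm, na.rm = TRUE),
               mhd_sd = stats::sd(df$mhd_mm, na.rm = TRUE),
               v_ct_mean = mean(df$v_ct_liters),
               v_ct_sd = stats::sd(df$v_ct_liters),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$model_tag, out$tissue), ]
}
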
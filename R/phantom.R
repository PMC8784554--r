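#' Specify a digital head phantom
#'
#' A phantom specification fully determines (together with its seed) a paired
#' pseudo-CT / tissue-label volume: a nested-ellipsoid head with a skull
#' shell, an outer CSF rim, a cortical gray-matter ribbon, a white-matter
#' core and CSF-coded ventricular cavities. Intensities are drawn per tissue
#' from Gaussian Hounsfield-unit distributions, and the thick-slice
#' partial-volume effect is simulated by averaging `z_supersampling` thin
#' sub-slices into every acquired slice, mimicking anisotropic head CT
#' (default grid 0.5 x 0.5 x 5 mm).
#'
#' Default HU parameters place brain tissue inside the 0-100 HU brain
#' window with a ~10 HU gray/white contrast, as in real CT: background
#' -1000, CSF 8 +/- 4, GM 38 +/- 5, WM 28 +/- 5, skull 800 +/- 100.
#'
#' @param matrix_size integer triple (nx, ny, nz).
#' @param voxel_size_mm positive triple, default `c(0.5, 0.5, 5)`.
#' @param tissue_hu named list mapping `background`, `csf`, `gm`, `wm`,
#'   `skull` to `c(mean, sd)` in HU.
#' @param noise_sd_hu additive Gaussian image noise (HU), applied after
#'   partial-volume averaging.
#' @param z_supersampling positive integer; thin sub-slices simulated per
#'   acquired slice. 1 disables through-plane partial volume.
#' @param head_radius_frac outer head semi-axes as a fraction of the
#'   half-field-of-view per axis.
#' @param skull_thickness_frac skull shell thickness as a fraction of the
#'   head radius.
#' @param csf_rim_frac outer CSF rim thickness as a fraction of the brain
#'   radius.
#' @param gm_thickness_vox cortical ribbon thickness in in-plane voxels.
#' @param ventricle_scale ventricle semi-axes as a fraction of the
#'   white-matter core radius; 0 removes the ventricles.
#' @param jitter_frac per-subject random scaling of all radii (uniform in
#'   `[1 - jitter_frac, 1 + jitter_frac]`), so that cohort-level volume
#'   statistics are non-degenerate.
#' @param contrast_margin minimum required |GM - WM| mean separation in HU.
#' @param seed integer; the phantom is a pure function of spec + seed.
#' @param preset optional shortcut: `"desk"` (64 x 64 x 8, CPU-friendly),
#'   `"desk-noiseless"` (same geometry, all intensity SDs and noise zero),
#'   `"paper-shape"` (512 x 512 x 32 acquisition-scale grid).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(64L, 64L, 8L),
                         voxel_size_mm = c(0.5, 0.5, 5),
                         tissue_hu = list(
                           background = c(-1000, 0),
                           csf = c(8, 4),
                           gm = c(38, 5),
                           wm = c(28, 5),
                           skull = c(800, 100)),
                         noise_sd_hu = 2,
                         z_supersampling = 4L,
                         head_radius_frac = 0.92,
                         skull_thickness_frac = 0.10,
                         csf_rim_frac = 0.10,
                         gm_thickness_vox = 5,
                         ventricle_scale = 0.35,
                         jitter_frac = 0.05,
                         contrast_margin = 5,
                         seed = 1L,
                         preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("desk", "desk-noiseless", "paper-shape"))
    if (preset == "paper-shape") matrix_size <- c(512L, 512L, 32L)
    if (preset == "desk-noiseless") {
      noise_sd_hu <- 0
      tissue_hu <- lapply(tissue_hu, function(p) c(p[[1]], 0))
    }
  }
  spec <- structure(list(
    matrix_size = as.integer(check_triple(matrix_size, "matrix_size",
                                          integer = TRUE)),
    voxel_size_mm = check_triple(voxel_size_mm, "voxel_size_mm"),
    tissue_hu = tissue_hu,
    noise_sd_hu = noise_sd_hu,
    z_supersampling = as.integer(z_supersampling),
    head_radius_frac = head_radius_frac,
    skull_thickness_frac = skull_thickness_frac,
    csf_rim_frac = csf_rim_frac,
    gm_thickness_vox = gm_thickness_vox,
    ventricle_scale = ventricle_scale,
    jitter_frac = jitter_frac,
    contrast_margin = contrast_margin,
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  needed <- c("background", "csf", "gm", "wm", "skull")
  if (!all(needed %in% names(spec$tissue_hu)))
    stopf("tissue_hu must name all of: %s", paste(needed, collapse = ", "))
  for (nm in needed) {
    p <- spec$tissue_hu[[nm]]
    if (length(p) != 2L || !is.numeric(p) || p[[2]] < 0)
      stopf("tissue_hu$%s must be c(mean, sd) with sd >= 0", nm)
  }
  mu <- vapply(spec$tissue_hu, function(p) p[[1]], numeric(1))
  if (mu[["csf"]] >= mu[["gm"]])
    stopf("CSF mean HU must be below GM mean HU")
  if (abs(mu[["gm"]] - mu[["wm"]]) < spec$contrast_margin)
    stopf("|GM - WM| mean contrast %.1f HU is below the %.1f HU margin",
          abs(mu[["gm"]] - mu[["wm"]]), spec$contrast_margin)
  if (spec$noise_sd_hu < 0) stopf("noise_sd_hu must be non-negative")
  if (spec$z_supersampling < 1L) stopf("z_supersampling must be >= 1")
  if (spec$head_radius_frac <= 0 || spec$head_radius_frac > 1)
    stopf("head_radius_frac must be in (0, 1]")
  for (f in c("skull_thickness_frac", "csf_rim_frac"))
    if (spec[[f]] < 0 || spec[[f]] >= 1) stopf("%s must be in [0, 1)", f)
  if (spec$gm_thickness_vox <= 0) stopf("gm_thickness_vox must be positive")
  if (spec$ventricle_scale < 0 || spec$ventricle_scale > 0.6)
    stopf("ventricle_scale must be in [0, 0.6] so ventricles stay inside WM")
  geom <- phantom_geometry(spec, jitter = FALSE)
  if (any(geom$gm_inner <= 0))
    stopf("cortical ribbon (%g voxels) does not fit: increase matrix_size %s",
          spec$gm_thickness_vox, paste(spec$matrix_size, collapse = "x"))
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %s @ %s mm, z-supersampling %d, noise %.1f HU, seed %d\n",
              paste(x$matrix_size, collapse = "x"),
              paste(format(x$voxel_size_mm), collapse = "x"),
              x$z_supersampling, x$noise_sd_hu, x$seed))
  invisible(x)
}

# Jittered per-subject geometry, all in mm relative to the volume centre.
phantom_geometry <- function(spec, jitter = TRUE) {
  half_fov <- spec$matrix_size * spec$voxel_size_mm / 2
  scale <- c(1, 1, 1)
  if (jitter && spec$jitter_frac > 0) {
    scale <- with_local_seed(derive_seeds(spec$seed, 1, stream = 1L), {
      stats::runif(3, 1 - spec$jitter_frac, 1 + spec$jitter_frac)
    })
  }
  head_r <- spec$head_radius_frac * half_fov * scale
  brain_r <- head_r * (1 - spec$skull_thickness_frac)
  csf_inner <- brain_r * (1 - spec$csf_rim_frac)
  gm_thick_mm <- spec$gm_thickness_vox * spec$voxel_size_mm[[1]]
  gm_inner <- csf_inner - gm_thick_mm
  vent_r <- spec$ventricle_scale * gm_inner
  vent_off <- 0.4 * gm_inner[[1]]
  list(head_r = head_r, brain_r = brain_r, csf_inner = csf_inner,
       gm_inner = gm_inner, vent_r = vent_r,
       vent_centers = list(c(-vent_off, 0, 0), c(vent_off, 0, 0)))
}

# Material codes used internally for CT simulation (skull is distinct from
# air even though both are label-background).
MAT_AIR <- 0L; MAT_GM <- 1L; MAT_WM <- 2L; MAT_CSF <- 3L; MAT_SKULL <- 4L

# Rasterize the material volume on the in-plane grid at arbitrary z
# positions (mm, centre-origin). Returns an integer array nx x ny x length(z).
rasterize_materials <- function(spec, geom, z_mm) {
  n <- spec$matrix_size
  vx <- spec$voxel_size_mm
  x <- (seq_len(n[1]) - (n[1] + 1) / 2) * vx[1]
  y <- (seq_len(n[2]) - (n[2] + 1) / 2) * vx[2]
  x2 <- matrix(x^2, n[1], n[2])
  y2 <- matrix(y^2, n[1], n[2], byrow = TRUE)
  xg <- matrix(x, n[1], n[2])
  out <- array(MAT_AIR, dim = c(n[1], n[2], length(z_mm)))
  ell2 <- function(z, r) x2 / r[1]^2 + y2 / r[2]^2 + (z / r[3])^2
  for (k in seq_along(z_mm)) {
    z <- z_mm[[k]]
    slab <- matrix(MAT_AIR, n[1], n[2])
    inside_head <- ell2(z, geom$head_r) <= 1
    slab[inside_head] <- MAT_SKULL
    slab[ell2(z, geom$brain_r) <= 1] <- MAT_CSF
    slab[ell2(z, geom$csf_inner) <= 1] <- MAT_GM
    in_wm <- ell2(z, geom$gm_inner) <= 1
    slab[in_wm] <- MAT_WM
    if (all(geom$vent_r > 0)) {
      for (ctr in geom$vent_centers) {
        d2 <- (xg - ctr[1])^2 / geom$vent_r[1]^2 + y2 / geom$vent_r[2]^2 +
          ((z - ctr[3]) / geom$vent_r[3])^2
        slab[in_wm & d2 <= 1] <- MAT_CSF
      }
    }
    out[, , k] <- slab
  }
  out
}

# z positions (mm) of acquired slice centres.
slice_centers_mm <- function(spec) {
  n <- spec$matrix_size[3]
  (seq_len(n) - (n + 1) / 2) * spec$voxel_size_mm[3]
}

#' Generate the ground-truth tissue label volume of a phantom
#'
#' Rasterizes the nested-compartment head geometry at the acquired slice
#' centres and recodes materials to the tissue labels (0 background/skull,
#' 1 GM, 2 WM, 3 CSF). Per-subject geometric jitter is drawn from the spec
#' seed, so identical spec + seed gives bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return a [label_volume()] carrying the jittered geometry as an attribute
#'   (used by [simulate_ct()] to stay consistent with the labels).
#' @export
generate_label_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_geometry(spec)
  mat <- rasterize_materials(spec, geom, slice_centers_mm(spec))
  lab <- materials_to_labels(mat)
  out <- label_volume(lab, spec$voxel_size_mm)
  attr(out, "geometry") <- geom
  out
}

materials_to_labels <- function(mat) {
  lab <- array(0L, dim = dim(mat))
  lab[mat == MAT_GM] <- 1L
  lab[mat == MAT_WM] <- 2L
  lab[mat == MAT_CSF] <- 3L
  lab
}

#' Simulate the pseudo-CT volume paired with a label volume
#'
#' Each thin sub-slice voxel is drawn from its material's Gaussian HU
#' distribution; `z_supersampling` sub-slices are averaged into every
#' acquired slice, producing the through-plane partial-volume mixing typical
#' of 5 mm CT; finally additive Gaussian scanner noise (`noise_sd_hu`) is
#' applied. Deterministic given the spec seed.
#'
#' @param labels the [generate_label_volume()] output (its attached jittered
#'   geometry is reused so CT and labels describe the same head), or any
#'   `label_volume` on the spec grid.
#' @param spec the [phantom_spec()] that produced `labels`.
#' @return a [ct_volume()] in HU on the same grid as `labels`.
#' @export
simulate_ct <- function(labels, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!inherits(labels, "label_volume")) stopf("labels must be a label_volume")
  if (!all(dim(labels$data) == spec$matrix_size))
    stopf("labels grid %s does not match spec matrix_size %s",
          paste(dim(labels$data), collapse = "x"),
          paste(spec$matrix_size, collapse = "x"))
  geom <- attr(labels, "geometry") %||% phantom_geometry(spec)
  s <- spec$z_supersampling
  n <- spec$matrix_size
  dz <- spec$voxel_size_mm[3]
  zc <- slice_centers_mm(spec)
  # sub-slice centres covering each acquired slice
  sub <- ((seq_len(s) - 0.5) / s - 0.5) * dz
  z_fine <- as.vector(outer(sub, zc, `+`))
  mat <- rasterize_materials(spec, geom, z_fine)
  mu <- c(spec$tissue_hu$background[1], spec$tissue_hu$gm[1],
          spec$tissue_hu$wm[1], spec$tissue_hu$csf[1], spec$tissue_hu$skull[1])
  sd_ <- c(spec$tissue_hu$background[2], spec$tissue_hu$gm[2],
           spec$tissue_hu$wm[2], spec$tissue_hu$csf[2], spec$tissue_hu$skull[2])
  ct <- with_local_seed(derive_seeds(spec$seed, 1, stream = 2L), {
    idx <- as.vector(mat) + 1L
    fine <- mu[idx]
    if (any(sd_ > 0)) fine <- fine + sd_[idx] * stats::rnorm(length(idx))
    fine <- array(fine, dim = dim(mat))
    acq <- array(0, dim = n)
    for (k in seq_len(n[3])) {
      sl <- fine[, , ((k - 1L) * s + 1L):(k * s), drop = FALSE]
      acq[, , k] <- rowMeans(sl, dims = 2)
    }
    if (spec$noise_sd_hu > 0)
      acq <- acq + array(stats::rnorm(length(acq), sd = spec$noise_sd_hu),
                         dim = n)
    acq
  })
  ct_volume(ct, spec$voxel_size_mm)
}

#' Write a reproducible synthetic cohort to disk
#'
#' Generates `n` phantom subjects (per-subject seeds derived from
#' `seed`, per-subject geometric jitter) and writes paired NIfTI volumes
#' `ct_XXXX.nii.gz` / `labels_XXXX.nii.gz` plus a `manifest.csv` with
#' columns `subject_id`, `ct_path`, `label_path`, `split`, `seed`.
#'
#' @param n number of subjects.
#' @param spec a [phantom_spec()]; its own seed is ignored in favour of the
#'   per-subject derived seeds.
#' @param out_dir output directory (created if missing).
#' @param seed master seed for the whole cohort.
#' @param split_fractions named numeric vector of split weights; defaults to
#'   the 500-train / 234-test cohort proportions. Subjects are assigned by
#'   rounding `n * fraction` (training first), with the remainder becoming
#'   test subjects.
#' @return the manifest as a data.frame (invisibly written to
#'   `out_dir/manifest.csv`).
#' @export
make_dataset <- function(n, spec, out_dir, seed = spec$seed,
                         split_fractions = c(train = 500, test = 234) / 734) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)
  if (!all(c("train", "test") %in% names(split_fractions)))
    stopf("split_fractions must name 'train' and 'test'")
  n_train <- min(n, round(n * split_fractions[["train"]]))
  split <- c(rep("train", n_train), rep("test", n - n_train))
  seeds <- derive_seeds(seed, n, stream = 3L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- seeds[[i]]
    lab <- generate_label_volume(sp)
    ct <- simulate_ct(lab, sp)
    id <- sprintf("%04d", i)
    ct_path <- file.path(out_dir, sprintf("ct_%s.nii.gz", id))
    lab_path <- file.path(out_dir, sprintf("labels_%s.nii.gz", id))
    write_volume(ct, ct_path)
    write_volume(lab, lab_path)
    rows[[i]] <- data.frame(subject_id = id, ct_path = ct_path,
                            label_path = lab_path, split = split[[i]],
                            seed = seeds[[i]], stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
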
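test_that("label volumes contain all four tissue codes and are deterministic", {
  sp <- desk_spec(seed = 21)
  lab <- generate_label_volume(sp)
  expect_setequal(unique(as.vector(lab$data)), 0:3)
  expect_identical(dim(lab$data), sp$matrix_size)
  lab2 <- generate_label_volume(sp)
  expect_identical(lab$data, lab2$data)
  ct <- simulate_ct(lab, sp)
  ct2 <- simulate_ct(lab2, sp)
  expect_identical(ct$data, ct2$data)
  expect_identical(dim(ct$data), dim(lab$data))
  expect_true(all(is.finite(ct$data)))
  # different seed gives a different head (jitter + noise)
  sp3 <- desk_spec(seed = 22)
  expect_false(identical(generate_label_volume(sp3)$data, lab$data))
})

test_that("ventricle scale controls CSF cavities interior to white matter", {
  find_interior_csf <- function(spec) {
    lab <- generate_label_volume(spec)$data
    comp <- connected_components(lab == 3L)
    interior <- 0L
    for (cc in seq_len(max(comp, 0L))) {
      mask <- comp == cc
      # a component is interior if every outside-the-component face
      # neighbour of its voxels is WM
      bd <- which(boundary_mask_ref(array(as.numeric(mask), dim(mask))))
      d <- dim(mask)
      touches_non_wm <- FALSE
      for (v in bd) {
        k <- (v - 1L) %/% (d[1] * d[2]); r <- (v - 1L) %% (d[1] * d[2])
        i <- r %% d[1] + 1L; j <- r %/% d[1] + 1L; k <- k + 1L
        for (nb in list(c(i - 1L, j, k), c(i + 1L, j, k), c(i, j - 1L, k),
                        c(i, j + 1L, k), c(i, j, k - 1L), c(i, j, k + 1L))) {
          if (any(nb < 1L) || nb[1] > d[1] || nb[2] > d[2] || nb[3] > d[3]) {
            touches_non_wm <- TRUE; next
          }
          code <- lab[nb[1], nb[2], nb[3]]
          if (code != 2L && !mask[nb[1], nb[2], nb[3]]) touches_non_wm <- TRUE
        }
        if (touches_non_wm) break
      }
      if (!touches_non_wm) interior <- interior + 1L
    }
    interior
  }
  expect_identical(find_interior_csf(desk_spec(seed = 5,
                                               ventricle_scale = 0)), 0L)
  expect_gt(find_interior_csf(desk_spec(seed = 5)), 0L)
})

test_that("noiseless zero-SD CT is piecewise constant at the tissue means", {
  sp <- desk_spec(seed = 3, noiseless = TRUE, z_supersampling = 1L)
  lab <- generate_label_volume(sp)
  ct <- simulate_ct(lab, sp)
  expect_equal(unique(ct$data[lab$data == 1L]), sp$tissue_hu$gm[1])
  expect_equal(unique(ct$data[lab$data == 2L]), sp$tissue_hu$wm[1])
  expect_equal(unique(ct$data[lab$data == 3L]), sp$tissue_hu$csf[1])
  vals <- unique(as.vector(ct$data))
  means <- vapply(sp$tissue_hu, `[[`, numeric(1), 1L)
  expect_true(all(vals %in% means))
})

test_that("pure-tissue intensities match the spec means within sampling error", {
  sp <- desk_spec(seed = 8, z_supersampling = 1L)
  lab <- generate_label_volume(sp)
  ct <- simulate_ct(lab, sp)
  wm <- ct$data[lab$data == 2L]
  tot_sd <- sqrt(sp$tissue_hu$wm[2]^2 + sp$noise_sd_hu^2)
  se <- tot_sd / sqrt(length(wm))
  expect_lt(abs(mean(wm) - sp$tissue_hu$wm[1]), 2 * se)
})

test_that("through-plane supersampling produces partial-volume mixing", {
  sp <- desk_spec(seed = 4, noiseless = TRUE, z_supersampling = 10L)
  lab <- generate_label_volume(sp)
  ct <- simulate_ct(lab, sp)
  # the head tapers along z, so slices near the poles mix tissue with
  # neighbouring compartments: intermediate values must exist
  vals <- unique(round(as.vector(ct$data), 6))
  means <- vapply(sp$tissue_hu, `[[`, numeric(1), 1L)
  mixed <- setdiff(vals, round(means, 6))
  expect_gt(length(mixed), 0)
  gm <- sp$tissue_hu$gm[1]; csf <- sp$tissue_hu$csf[1]
  between <- mixed[mixed > csf & mixed < gm]
  expect_gt(length(between), 0)
})

test_that("each brain tissue occupies at least 1% of in-head voxels", {
  for (seed in c(1, 17, 33)) {
    lab <- generate_label_volume(desk_spec(seed = seed))$data
    in_head <- sum(lab > 0L)
    for (code in 1:3)
      expect_gt(sum(lab == code) / in_head, 0.01)
  }
})

test_that("impossible geometry is rejected with a parameter error", {
  expect_error(phantom_spec(matrix_size = c(8, 8, 4), gm_thickness_vox = 20),
               "does not fit")
  expect_error(phantom_spec(tissue_hu = list(
    background = c(-1000, 0), csf = c(50, 4), gm = c(38, 5),
    wm = c(28, 5), skull = c(800, 100))), "CSF")
  expect_error(phantom_spec(tissue_hu = list(
    background = c(-1000, 0), csf = c(8, 4), gm = c(30, 5),
    wm = c(28, 5), skull = c(800, 100))), "contrast")
})

test_that("make_dataset writes paired NIfTIs that round-trip exactly", {
  out <- withr::local_tempdir()
  man <- make_dataset(3, desk_spec(), out, seed = 42)
  expect_equal(nrow(man), 3)
  expect_length(list.files(out, pattern = "\\.nii\\.gz$"), 6)
  expect_true(file.exists(file.path(out, "manifest.csv")))
  # reload one pair and compare to a regenerated in-memory original
  sp <- desk_spec()
  sp$seed <- man$seed[2]
  lab <- generate_label_volume(sp)
  ct <- simulate_ct(lab, sp)
  lab_r <- read_label_volume(man$label_path[2])
  ct_r <- read_ct_volume(man$ct_path[2])
  expect_identical(lab_r$data, lab$data)
  expect_equal(ct_r$data, ct$data, tolerance = 1e-6)
  expect_equal(lab_r$spacing_mm, sp$voxel_size_mm)
})

test_that("split assignment follows the rounded cohort proportions", {
  out <- withr::local_tempdir()
  man <- make_dataset(10, desk_spec(), out, seed = 1)
  expect_equal(sum(man$split == "train"), 7)  # round(10 * 500/734)
  expect_equal(sum(man$split == "test"), 3)
  # per-subject seeds are distinct and reproducible
  man2 <- make_dataset(10, desk_spec(), withr::local_tempdir(), seed = 1)
  expect_identical(man$seed, man2$seed)
  expect_equal(anyDuplicated(man$seed), 0)
})
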
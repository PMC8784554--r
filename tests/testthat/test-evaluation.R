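test_that("continuous Dice handles exact, disjoint and hand-worked cases", {
  A <- array(0, c(4, 4, 2)); A[2:3, 2:3, 1] <- 1
  expect_equal(continuous_dice(A, A), 1)
  B <- array(0, c(4, 4, 2)); B[1, 1, 2] <- 1
  expect_equal(continuous_dice(B, A), 0)
  expect_equal(continuous_dice(array(0, c(2, 2, 1)), array(0, c(2, 2, 1))), 1)
  # three-voxel case computed by an explicit loop over the definition
  a <- c(1, 1, 0); b <- c(0.5, 1.0, 0.2)
  inter <- 0; csum <- 0
  for (i in 1:3) {
    inter <- inter + a[i] * b[i]
    csum <- csum + a[i] * (b[i] > 0)
  }
  cc <- inter / csum
  expected <- 2 * inter / (cc * sum(a) + sum(b))
  got <- continuous_dice(array(b, c(3, 1, 1)), array(a, c(3, 1, 1)))
  expect_equal(got, expected)
  expect_equal(got, 0.9375)
  expect_error(continuous_dice(array(1.2, c(1, 1, 1)),
                               array(1, c(1, 1, 1))), "\\[0, 1\\]")
})

test_that("continuous Dice reduces to classical Dice on binary inputs", {
  for (seed in 1:8) {
    A <- random_blob(c(10, 10, 6), seed)
    B <- random_blob(c(10, 10, 6), seed + 100)
    classical <- if (sum(A) + sum(B) == 0) 1 else
      2 * sum(A * B) / (sum(A) + sum(B))
    expect_equal(continuous_dice(B, A), classical, tolerance = 1e-12)
  }
})

test_that("surface distances respect anisotropic spacing", {
  A <- array(0, c(8, 8, 4)); A[2, 2, 1] <- 1
  B <- array(0, c(8, 8, 4)); B[2, 2, 3] <- 1
  sd_ <- surface_distances(A, B, c(0.5, 0.5, 5))
  expect_equal(sd_$a_to_b, 10)
  expect_equal(sd_$b_to_a, 10)
  expect_equal(ahd(A, B, c(0.5, 0.5, 5)), 10)
  expect_equal(mhd(A, B, c(0.5, 0.5, 5)), 10)
  same <- surface_distances(A, A, c(0.5, 0.5, 5))
  expect_true(all(c(same$a_to_b, same$b_to_a) == 0))
  expect_error(surface_distances(A, array(0, c(8, 8, 4))), "empty")
})

test_that("AHD and MHD equal O(n^2) brute-force references", {
  for (seed in 1:6) {
    A <- random_blob(c(9, 9, 5), seed)
    B <- random_blob(c(9, 9, 5), seed + 50)
    sp <- c(0.5, 0.5, 5)
    ref <- brute_surface_stats(A, B, sp)
    expect_equal(ahd(A, B, sp), ref$ahd, tolerance = 1e-10)
    expect_equal(mhd(A, B, sp), ref$mhd, tolerance = 1e-10)
    # the directed distance multisets agree too
    sd_ <- surface_distances(A, B, sp)
    expect_equal(sort(sd_$a_to_b), ref$mins_ab, tolerance = 1e-10)
    expect_equal(sort(sd_$b_to_a), ref$mins_ba, tolerance = 1e-10)
    # symmetry of ahd
    expect_equal(ahd(A, B, sp), ahd(B, A, sp), tolerance = 1e-12)
  }
})

test_that("metrics are invariant to simultaneous axis permutation", {
  A <- random_blob(c(8, 10, 6), 7)
  B <- random_blob(c(8, 10, 6), 77)
  sp <- c(0.5, 0.7, 5)
  perm <- c(3, 1, 2)
  Ap <- aperm(A, perm); Bp <- aperm(B, perm); spp <- sp[perm]
  expect_equal(ahd(A, B, sp), ahd(Ap, Bp, spp), tolerance = 1e-10)
  expect_equal(mhd(A, B, sp), mhd(Ap, Bp, spp), tolerance = 1e-10)
  expect_equal(continuous_dice(B, A), continuous_dice(Bp, Ap))
  expect_equal(volume_liters(A, sp), volume_liters(Ap, spp))
})

test_that("volumetric error and volumes follow their definitions", {
  expect_equal(volumetric_error(0.5, 0.5), 0)
  expect_equal(volumetric_error(1, 3), 0.5)
  expect_equal(volumetric_error(2, 0), 1)
  expect_equal(volumetric_error(3, 1), volumetric_error(1, 3))
  expect_error(volumetric_error(0, 0), "positive")
  one <- array(0, c(4, 4, 2)); one[1, 1, 1] <- 1
  expect_equal(volume_liters(one, c(0.5, 0.5, 5)), 1.25e-6)
  set.seed(9)
  m <- array(rbinom(800, 1, 0.3), c(10, 10, 8))
  expect_equal(volume_liters(m, c(0.5, 0.5, 5)),
               sum(m) * 1.25e-6)
})

test_that("cohort Pearson correlation matches the textbook formula", {
  v <- c(0.5, 0.6, 0.7, 0.55)
  expect_equal(cohort_pearson(v, v), 1)
  expect_equal(cohort_pearson(v, -v + 2), -1)
  set.seed(10)
  x <- runif(20); y <- x + rnorm(20, sd = 0.1)
  n <- length(x)
  manual <- (sum(x * y) - n * mean(x) * mean(y)) /
    sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(cohort_pearson(x, y), manual, tolerance = 1e-12)
  expect_error(cohort_pearson(x[1:2], y[1:2]), "3 subjects")
  expect_error(cohort_pearson(rep(1, 5), y[1:5]), "variance")
})

test_that("a perfect prediction yields perfect subject metrics", {
  lab <- generate_label_volume(desk_spec(seed = 30))
  probs <- list(gm = class_mask(lab, 1), wm = class_mask(lab, 2),
                csf = class_mask(lab, 3))
  rows <- evaluate_subject(probs, probs, lab, "s1", "2D")
  expect_equal(nrow(rows), 3)
  expect_equal(rows$d_c, rep(1, 3))
  expect_equal(rows$ve, rep(0, 3))
  expect_equal(rows$ahd_mm, rep(0, 3))
  expect_equal(rows$mhd_mm, rep(0, 3))
  expect_equal(rows$v_ct_liters, rows$v_ref_liters)
  smry <- summarize_metrics(rbind(rows, rows))
  expect_true(all(is.na(smry$r)))  # undefined under n < 3
  expect_equal(smry$d_c_mean, rep(1, 3))
})

test_that("directory evaluation pairs subjects and warns on orphans", {
  td <- withr::local_tempdir()
  pred_dir <- file.path(td, "pred"); ref_dir <- file.path(td, "ref")
  dir.create(pred_dir); dir.create(ref_dir)
  for (id in c("0001", "0002")) {
    lab <- generate_label_volume(desk_spec(seed = 40 + as.integer(id)))
    write_volume(lab, file.path(ref_dir, sprintf("labels_%s.nii.gz", id)))
    for (tis in c("gm", "wm", "csf")) {
      code <- c(gm = 1, wm = 2, csf = 3)[[tis]]
      write_volume(ct_volume(class_mask(lab, code), lab$spacing_mm),
                   file.path(pred_dir,
                             sprintf("prob_%s_%s.nii.gz", id, tis)))
    }
  }
  lab3 <- generate_label_volume(desk_spec(seed = 49))
  write_volume(lab3, file.path(ref_dir, "labels_0003.nii.gz"))
  expect_warning(tab <- evaluate_testset(pred_dir, ref_dir, "2D"), "0003")
  expect_equal(nrow(tab), 2 * 3)
  expect_equal(tab$d_c, rep(1, 6))
  expect_equal(tab$ve, rep(0, 6))
})
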
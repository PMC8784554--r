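test_that("grid planning reproduces the acquisition-scale tilings", {
  g <- plan_grid(c(512, 512, 32))
  expect_equal(g$n_patches, 49L)
  expect_equal(plan_grid(c(128, 128, 32))$n_patches, 1L)
  expect_equal(plan_grid(c(256, 256, 32))$n_patches, 9L)
  expect_identical(plan_grid(c(128, 128, 32))$origins[1, ],
                   c(x = 0L, y = 0L, z = 0L))
  expect_error(plan_grid(c(64, 64, 8), c(128, 128, 32)), "exceeds")
})

test_that("origin count matches exhaustive enumeration for many shapes", {
  set.seed(10)
  for (rep in 1:25) {
    vs <- sample(8:64, 3, replace = TRUE)
    ps <- pmin(vs, sample(4:32, 3, replace = TRUE))
    st <- sample(1:16, 3, replace = TRUE)
    g <- plan_grid(vs, ps, st)
    counts <- vapply(1:3, function(ax)
      sum(seq(0, vs[ax], by = st[ax]) + ps[ax] <= vs[ax]), integer(1))
    expect_equal(g$n_patches, prod(counts))
    # every origin + patch fits, origins unique, x varies fastest
    expect_true(all(t(g$origins) + ps <= vs))
    expect_equal(anyDuplicated(g$origins), 0)
    if (g$n_patches > 1 && counts[1] > 1)
      expect_equal(unname(g$origins[2, 1] - g$origins[1, 1]), st[1])
  }
})

test_that("extraction equals naive triple-loop slicing", {
  set.seed(11)
  v <- array(seq_len(24 * 20 * 6), c(24, 20, 6))
  g <- plan_grid(c(24, 20, 6), c(8, 8, 4), c(8, 4, 2))
  ps <- extract_patches(v, g)
  expect_length(ps, g$n_patches)
  for (i in seq_len(g$n_patches)) {
    o <- g$origins[i, ]
    manual <- v[o[1] + 1:8, o[2] + 1:8, o[3] + 1:4]
    expect_identical(ps[[i]], manual)
  }
  # ramp volume: the patch at a known origin starts at that voxel's value
  i2 <- which(g$origins[, 1] == 8 & g$origins[, 2] == 0 &
                g$origins[, 3] == 0)[1]
  expect_equal(ps[[i2]][1, 1, 1], v[9, 1, 1])
  expect_error(extract_patches(array(0, c(9, 9, 3)), g), "does not match")
})

test_that("stitching inverts extraction and averages overlaps", {
  set.seed(12)
  v <- array(runif(32 * 32 * 8), c(32, 32, 8))
  g <- plan_grid(dim(v), c(16, 16, 8), c(8, 8, 8))
  expect_equal(stitch_patches(extract_patches(v, g), g), v)
  # two overlapping constant patches average to 0.5 in the overlap
  g1 <- plan_grid(c(24, 8, 4), c(16, 8, 4), c(8, 8, 4))
  p0 <- array(0, c(16, 8, 4)); p1 <- array(1, c(16, 8, 4))
  st <- stitch_patches(list(p0, p1), g1)
  expect_true(all(st[1:8, , ] == 0))
  expect_true(all(st[9:16, , ] == 0.5))
  expect_true(all(st[17:24, , ] == 1))
})

test_that("stitching random probabilities matches accumulate-and-divide", {
  set.seed(13)
  g <- plan_grid(c(24, 24, 8), c(16, 16, 8), c(8, 8, 8))
  patches <- lapply(seq_len(g$n_patches), function(i)
    array(runif(16 * 16 * 8 * 4), c(16, 16, 8, 4)))
  st <- stitch_patches(patches, g)
  acc <- array(0, c(24, 24, 8, 4)); cnt <- array(0, c(24, 24, 8, 4))
  for (i in seq_len(g$n_patches)) {
    o <- g$origins[i, ]
    for (ch in 1:4) {
      acc[o[1] + 1:16, o[2] + 1:16, o[3] + 1:8, ch] <-
        acc[o[1] + 1:16, o[2] + 1:16, o[3] + 1:8, ch] + patches[[i]][, , , ch]
      cnt[o[1] + 1:16, o[2] + 1:16, o[3] + 1:8, ch] <-
        cnt[o[1] + 1:16, o[2] + 1:16, o[3] + 1:8, ch] + 1
    }
  }
  expect_equal(st, acc / cnt, tolerance = 1e-12)
})

test_that("non-tiling grids are rejected and padding repairs them", {
  g <- plan_grid(c(20, 16, 4), c(16, 16, 4), c(8, 8, 4))  # x leaves 4 voxels
  patches <- extract_patches(array(1, c(20, 16, 4)), g)
  expect_error(stitch_patches(patches, g), "pad_to_grid")
  v <- array(runif(20 * 16 * 4), c(20, 16, 4))
  pd <- pad_to_grid(v, c(16, 16, 4), c(8, 8, 4))
  g2 <- plan_grid(dim(pd$data), c(16, 16, 4), c(8, 8, 4))
  st <- stitch_patches(extract_patches(pd$data, g2), g2)
  expect_equal(crop_to_shape(st, pd$offset, dim(v)), v)
})

test_that("slice stacks index and round-trip exactly", {
  set.seed(14)
  v <- array(runif(12 * 10 * 5), c(12, 10, 5))
  sl <- extract_slices(v)
  expect_length(sl, 5)
  for (k in 1:5) expect_identical(sl[[k]], v[, , k])
  expect_identical(stack_slices(sl), v)
  expect_error(stack_slices(list(matrix(0, 2, 2), matrix(0, 3, 2))),
               "inconsistent")
})
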
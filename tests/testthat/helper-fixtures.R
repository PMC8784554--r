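# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; nothing is read from disk.

desk_spec <- function(seed = 11L, noiseless = FALSE, ...) {
  phantom_spec(preset = if (noiseless) "desk-noiseless" else "desk",
               seed = seed, ...)
}

# n paired, windowed subjects with per-subject seeds derived from `seed`
make_subjects <- function(n, spec = desk_spec(), seed = 100L) {
  lapply(seq_len(n), function(i) {
    sp <- spec
    sp$seed <- seed + i
    lab <- generate_label_volume(sp)
    ct <- simulate_ct(lab, sp)
    list(ct = window_hu(ct), lab = lab)
  })
}

slices_xy <- function(subjects, code) {
  list(x = unlist(lapply(subjects, function(s) extract_slices(s$ct$data)),
                  recursive = FALSE),
       y = unlist(lapply(subjects,
                         function(s) extract_slices(class_mask(s$lab, code))),
                  recursive = FALSE))
}

binary_dice <- function(pred, ref, t = 0.5) {
  pb <- pred >= t
  rb <- ref == 1
  if (!any(pb) && !any(rb)) return(1)
  2 * sum(pb & rb) / (sum(pb) + sum(rb))
}

# random compact binary mask: a blurred blob thresholded to keep the
# boundary voxel count moderate
random_blob <- function(dim3, seed, fill = 0.2) {
  set.seed(seed)
  ctr <- dim3 / 2 + stats::runif(3, -dim3 / 6, dim3 / 6)
  rad <- dim3 * stats::runif(3, 0.15, 0.3)
  g <- expand.grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]),
                   z = seq_len(dim3[3]))
  d2 <- ((g$x - ctr[1]) / rad[1])^2 + ((g$y - ctr[2]) / rad[2])^2 +
    ((g$z - ctr[3]) / rad[3])^2
  array(as.numeric(d2 <= 1), dim = dim3)
}

# O(n^2) double-loop oracle for directed mean/pooled boundary distances
brute_surface_stats <- function(A, B, spacing) {
  pts <- function(M) {
    idx <- which(boundary_mask_ref(M), arr.ind = TRUE)
    sweep(idx, 2, spacing, `*`)
  }
  Pa <- pts(A); Pb <- pts(B)
  mins_ab <- apply(Pa, 1, function(p)
    min(sqrt(colSums((t(Pb) - p)^2))))
  mins_ba <- apply(Pb, 1, function(p)
    min(sqrt(colSums((t(Pa) - p)^2))))
  list(ahd = (sum(mins_ab) + sum(mins_ba)) / (length(mins_ab) + length(mins_ba)),
       mhd = max(mean(mins_ab), mean(mins_ba)),
       mins_ab = sort(mins_ab), mins_ba = sort(mins_ba))
}

# independent boundary definition: voxel-wise loop over the 6 neighbours
boundary_mask_ref <- function(A) {
  d <- dim(A)
  out <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (A[i, j, k] <= 0) next
    nb <- c(
      if (i > 1) A[i - 1, j, k] else 0, if (i < d[1]) A[i + 1, j, k] else 0,
      if (j > 1) A[i, j - 1, k] else 0, if (j < d[2]) A[i, j + 1, k] else 0,
      if (k > 1) A[i, j, k - 1] else 0, if (k < d[3]) A[i, j, k + 1] else 0)
    if (any(nb <= 0)) out[i, j, k] <- TRUE
  }
  out
}

# 6-connectivity connected components by BFS; labels an integer array
connected_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      k <- (v - 1L) %/% (d[1] * d[2])
      r <- (v - 1L) %% (d[1] * d[2])
      i <- r %% d[1] + 1L; j <- r %/% d[1] + 1L; k <- k + 1L
      for (nb in list(c(i - 1L, j, k), c(i + 1L, j, k), c(i, j - 1L, k),
                      c(i, j + 1L, k), c(i, j, k - 1L), c(i, j, k + 1L))) {
        if (any(nb < 1L) || nb[1] > d[1] || nb[2] > d[2] || nb[3] > d[3])
          next
        lin <- nb[1] + d[1] * (nb[2] - 1L) + d[1] * d[2] * (nb[3] - 1L)
        if (mask[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  lab
}
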
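#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards so generators never perturb user sessions.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from a master seed, stably across platforms.
# Kept below 2^31 - 1 so they remain valid R integers.
derive_seeds <- function(master_seed, n, stream = 0L) {
  with_local_seed(as.integer(master_seed) + 1000003L * as.integer(stream), {
    sample.int(.Machine$integer.max - 1L, n)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_triple <- function(x, name, positive = TRUE, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || anyNA(x))
    stopf("'%s' must be a numeric triple", name)
  if (positive && any(x <= 0)) stopf("'%s' must be positive", name)
  if (integer && any(x != as.integer(x))) stopf("'%s' must be integer-valued", name)
  as.numeric(x)
}

#' Construct a CT volume
#'
#' A CT volume is a 3D numeric array of Hounsfield-unit intensities together
#' with its voxel spacing in millimetres. Anisotropic spacing (for example
#' 0.5 x 0.5 x 5 mm for thick-slice head CT) is carried through all
#' downstream geometry-aware computations.
#'
#' @param data numeric 3D array of intensities (HU, or normalized units after
#'   windowing).
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @return an object of class `ct_volume` with elements `data` and
#'   `spacing_mm`.
#' @export
ct_volume <- function(data, spacing_mm = c(0.5, 0.5, 5)) {
  if (length(dim(data)) != 3L) stopf("CT data must be a 3D array")
  if (!all(is.finite(data))) stopf("CT data must be finite")
  structure(list(data = data, spacing_mm = check_triple(spacing_mm, "spacing_mm")),
            class = "ct_volume")
}

#' Construct a tissue label volume
#'
#' Integer-coded tissue map sharing the CT grid. Coding: 0 background
#' (including skull and air), 1 gray matter, 2 white matter, 3 cerebrospinal
#' fluid. Every voxel carries exactly one code.
#'
#' @param data integer 3D array with values in `{0, 1, 2, 3}`.
#' @param spacing_mm positive numeric triple in mm.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(data, spacing_mm = c(0.5, 0.5, 5)) {
  if (length(dim(data)) != 3L) stopf("label data must be a 3D array")
  if (!all(data %in% 0:3)) stopf("label codes must be in {0, 1, 2, 3}")
  d <- array(as.integer(data), dim = dim(data))
  structure(list(data = d, spacing_mm = check_triple(spacing_mm, "spacing_mm")),
            class = "label_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels, spacing %s mm, range [%.1f, %.1f]\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(x$data, levels = 0:3,
                      labels = c("background", "GM", "WM", "CSF")))
  cat(sprintf("<label_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing_mm), collapse = "x")))
  print(tab)
  invisible(x)
}

# Accept either a wrapped volume or a bare array.
vol_data <- function(x) {
  if (inherits(x, "ct_volume") || inherits(x, "label_volume")) x$data else x
}

vol_spacing <- function(x, default = c(0.5, 0.5, 5)) {
  if (inherits(x, "ct_volume") || inherits(x, "label_volume")) x$spacing_mm else default
}

#' Read and write paired volumes as NIfTI-1
#'
#' Thin wrappers over [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' preserve voxel spacing through the NIfTI header `pixdim` fields.
#'
#' @param x a `ct_volume` or `label_volume`.
#' @param path file path, conventionally ending in `.nii.gz`.
#' @return `write_volume` returns `path` invisibly; `read_ct_volume` /
#'   `read_label_volume` return the reconstructed object.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(vol_data(x), reference = NULL)
  RNifti::pixdim(img) <- vol_spacing(x)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.numeric(img), dim = dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname write_volume
#' @export
read_label_volume <- function(path) {
  img <- RNifti::readNifti(path)
  label_volume(array(as.integer(round(img)), dim = dim(img)),
               RNifti::pixdim(img)[1:3])
}
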
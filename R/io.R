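#' Read and write volumes as NIfTI
#'
#' Thin wrappers around RNifti that carry the voxel spacing into and out of
#' the NIfTI header. Label volumes round-trip integer-exact.
#'
#' @param grid A [voxel_grid()].
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` a
#'   `voxel_grid`.
#' @export
write_volume <- function(grid, path) {
  img <- RNifti::asNifti(grid$data)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dat <- array(as.numeric(img), dim(img)[1:3])
  if (any(!is.finite(dat))) abort(sprintf("Non-finite voxels in %s.", path))
  voxel_grid(dat, spacing = RNifti::pixdim(img)[1:3])
}

#' Read and write diffusion series with FSL-style bval/bvec sidecars
#'
#' The 4-D signal is written as NIfTI; b-values and directions go to
#' `<stem>.bval` / `<stem>.bvec` text sidecars (one row of b-values; three
#' rows of direction components).
#'
#' @param series A [diffusion_series()].
#' @param path Path to the 4-D NIfTI; sidecar paths are derived from it.
#' @return `write_series()` returns `path` invisibly; `read_series()` a
#'   `diffusion_series`.
#' @export
write_series <- function(series, path) {
  img <- RNifti::asNifti(series$data)
  RNifti::pixdim(img) <- c(series$spacing, 1)
  RNifti::writeNifti(img, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  writeLines(paste(format(series$scheme$b, trim = TRUE), collapse = " "),
             paste0(stem, ".bval"))
  bv <- rbind(series$scheme$gx, series$scheme$gy, series$scheme$gz)
  writeLines(apply(bv, 1, function(r)
    paste(format(r, trim = TRUE), collapse = " ")), paste0(stem, ".bvec"))
  invisible(path)
}

#' @rdname write_series
#' @param b_low_cutoff Fitting cutoff recorded on the re-read scheme.
#' @export
read_series <- function(path, b_low_cutoff = 200) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) abort(sprintf("%s is not a 4-D series.", path))
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  bval_path <- paste0(stem, ".bval")
  bvec_path <- paste0(stem, ".bvec")
  if (!file.exists(bval_path) || !file.exists(bvec_path)) {
    abort(sprintf("Missing bval/bvec sidecar for %s.", path))
  }
  b <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (length(b) != dim(img)[4]) {
    abort(sprintf("Series has %d volumes but %d b-values.",
                  dim(img)[4], length(b)))
  }
  sch <- tibble::tibble(volume = seq_along(b), b = b,
                        gx = bv[1, ], gy = bv[2, ], gz = bv[3, ])
  sch <- structure(sch, b_low_cutoff = b_low_cutoff,
                   class = c("acquisition_scheme", class(sch)))
  diffusion_series(array(as.numeric(img), dim(img)),
                   sch, spacing = RNifti::pixdim(img)[1:3])
}

#' Resample a label grid through a rigid world transform
#'
#' Hook for co-registering label volumes between spaces when the inputs are
#' not already aligned: each target voxel centre is mapped through the
#' inverse of the supplied 4x4 world-coordinate rigid transform and assigned
#' the nearest-neighbour source label. With the identity transform and equal
#' grids this is a no-op.
#'
#' @param labels A label [voxel_grid()].
#' @param transform 4x4 rigid transform matrix (world mm coordinates,
#'   source to target).
#' @param target_dim Dimensions of the target grid (default: same).
#' @param target_spacing Spacing of the target grid in mm (default: same).
#' @return A label `voxel_grid` on the target grid; voxels mapping outside
#'   the source get 0.
#' @export
resample_labels_rigid <- function(labels, transform = diag(4),
                                  target_dim = dim(labels$data),
                                  target_spacing = labels$spacing) {
  if (!all(dim(transform) == c(4, 4))) abort("`transform` must be 4x4.")
  inv <- solve(transform)
  ijk <- arrayInd(seq_len(prod(target_dim)), target_dim)
  world <- cbind(sweep(ijk - 1, 2, target_spacing, `*`), 1)
  src <- world %*% t(inv)
  src_ijk <- round(sweep(src[, 1:3, drop = FALSE], 2, labels$spacing, `/`)) + 1
  ok <- src_ijk[, 1] >= 1 & src_ijk[, 1] <= dim(labels$data)[1] &
    src_ijk[, 2] >= 1 & src_ijk[, 2] <= dim(labels$data)[2] &
    src_ijk[, 3] >= 1 & src_ijk[, 3] <= dim(labels$data)[3]
  out <- numeric(prod(target_dim))
  out[ok] <- labels$data[src_ijk[ok, , drop = FALSE]]
  voxel_grid(array(out, target_dim), spacing = target_spacing)
}
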
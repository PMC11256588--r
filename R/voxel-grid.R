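#' Voxel grids
#'
#' A `voxel_grid` is the package's universal spatial carrier: a 3-D array of
#' scalars or integer labels plus the physical voxel spacing in millimetres.
#' All distance computations in the package are carried out in physical mm,
#' honouring anisotropic spacing (the acquisition this package targets uses
#' 2 x 2 x 4 mm voxels).
#'
#' @param data A 3-D numeric or logical array.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @return A `voxel_grid` object.
#' @examples
#' g <- voxel_grid(array(0, c(8, 8, 4)), spacing = c(2, 2, 4))
#' dim(g)
#' @export
voxel_grid <- function(data, spacing = c(2, 2, 4)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array.")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three positive voxel edge lengths in mm.")
  }
  structure(list(data = data, spacing = spacing), class = "voxel_grid")
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]
  ))
  rng <- range(x$data, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d NA\n",
              rng[1], rng[2], sum(is.na(x$data))))
  invisible(x)
}

#' Coerce to a voxel grid
#'
#' @param x An array, `voxel_grid`, or `niftiImage`.
#' @param spacing Spacing in mm, used when `x` carries none.
#' @return A `voxel_grid`.
#' @export
as_voxel_grid <- function(x, spacing = c(2, 2, 4)) {
  if (inherits(x, "voxel_grid")) return(x)
  if (inherits(x, "niftiImage")) {
    return(voxel_grid(array(as.numeric(x), dim(x)[1:3]),
                      spacing = RNifti::pixdim(x)[1:3]))
  }
  voxel_grid(x, spacing = spacing)
}

# mm coordinates of the voxel centres along each axis (0-based indexing:
# voxel i sits at (i - 1) * spacing; only relative distances matter here)
axis_mm <- function(n, step) (seq_len(n) - 1) * step

# n x 3 matrix of mm coordinates for a logical mask or linear indices
voxel_coords_mm <- function(idx, dims, spacing) {
  if (is.logical(idx)) idx <- which(idx)
  ijk <- arrayInd(idx, dims)
  sweep(ijk - 1, 2, spacing, `*`)
}

stopifnot_same_grid <- function(a, b, what = c("grids", "grids")) {
  if (!identical(dim(a$data), dim(b$data))) {
    abort(sprintf(
      "%s (%s) and %s (%s) are not on the same grid.",
      what[1], paste(dim(a$data), collapse = "x"),
      what[2], paste(dim(b$data), collapse = "x")
    ))
  }
  if (max(abs(a$spacing - b$spacing)) > 1e-9) {
    abort(sprintf(
      "%s and %s differ in voxel spacing (%s vs %s mm).",
      what[1], what[2],
      paste(signif(a$spacing, 4), collapse = "x"),
      paste(signif(b$spacing, 4), collapse = "x")
    ))
  }
  invisible(TRUE)
}

# Binary dilation of a logical 3-D array by `iterations` steps of the
# face-connected (6-neighbour) or full (26-neighbour) structuring element.
dilate_mask <- function(mask, iterations = 1L,
                        connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  d <- dim(mask)
  shift1 <- function(m, axis, by) {
    out <- array(FALSE, d)
    n <- d[axis]
    if (abs(by) >= n) return(out)
    src <- if (by > 0) 1:(n - by) else (1 - by):n
    dst <- if (by > 0) (1 + by):n else 1:(n + by)
    ix <- list(1:d[1], 1:d[2], 1:d[3])
    src_ix <- ix; src_ix[[axis]] <- src
    dst_ix <- ix; dst_ix[[axis]] <- dst
    out[dst_ix[[1]], dst_ix[[2]], dst_ix[[3]]] <-
      m[src_ix[[1]], src_ix[[2]], src_ix[[3]]]
    out
  }
  for (it in seq_len(iterations)) {
    grown <- mask
    for (axis in 1:3) {
      grown <- grown | shift1(mask, axis, 1L) | shift1(mask, axis, -1L)
    }
    if (connectivity == "full") {
      # full connectivity: one pass per axis chained gives the 26-neighbour
      # cube after sweeping all three axes on the running result
      grown <- mask
      for (axis in 1:3) {
        grown <- grown | shift1(grown, axis, 1L) | shift1(grown, axis, -1L)
      }
    }
    mask <- grown
  }
  mask
}

# Minimum Euclidean mm distance from each queried voxel to a seed voxel set.
# Exact brute force over the seed set; seeds are small (tens of voxels).
min_dist_mm <- function(query_idx, seed_idx, dims, spacing) {
  q <- voxel_coords_mm(query_idx, dims, spacing)
  s <- voxel_coords_mm(seed_idx, dims, spacing)
  if (nrow(s) == 0L) abort("Seed set is empty.")
  d2 <- matrix(Inf, nrow(q), 1)
  best <- rep(Inf, nrow(q))
  for (j in seq_len(nrow(s))) {
    dj <- (q[, 1] - s[j, 1])^2 + (q[, 2] - s[j, 2])^2 + (q[, 3] - s[j, 3])^2
    best <- pmin(best, dj)
  }
  sqrt(best)
}
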
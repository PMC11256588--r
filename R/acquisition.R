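#' Low-b acquisition scheme
#'
#' Builds the per-volume table of b-values and gradient directions. The
#' default reproduces the low-b protocol this package targets: b-values
#' 0, 10, 20, 30, 50, 70, 90, 110, 130, 150, 170, 200, 500, 800, 1000 and
#' 1500 s/mm2, five b = 0 volumes, and each non-zero b-value acquired under
#' three gradient directions. CSF is treated as isotropic, so the three
#' directions act as replicate samples of the same decay.
#'
#' @param b_values Distinct b-values in s/mm2.
#' @param n_b0 Number of b = 0 volumes.
#' @param n_directions Gradient directions per non-zero b-value.
#' @param b_low_cutoff Pseudodiffusivity fitting cutoff in s/mm2; volumes
#'   with `b <= b_low_cutoff` enter the fit (IVIM pseudo-diffusion dominates
#'   the decay only at low b).
#' @return An `acquisition_scheme`: a tibble with columns `volume`, `b`,
#'   `gx`, `gy`, `gz`, plus attributes `b_low_cutoff`.
#' @examples
#' sch <- acquisition_scheme()
#' nrow(sch)              # 5 + 15 * 3 = 50 volumes
#' sum(unique(sch$b) <= 200)  # 12 distinct low-b values
#' @export
acquisition_scheme <- function(b_values = c(0, 10, 20, 30, 50, 70, 90, 110,
                                            130, 150, 170, 200, 500, 800,
                                            1000, 1500),
                               n_b0 = 5L, n_directions = 3L,
                               b_low_cutoff = 200) {
  if (any(b_values < 0)) abort("b-values must be non-negative.")
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(0, 1, 1) / sqrt(2),
                c(1, 0, 1) / sqrt(2))
  dirs <- dirs[rep_len(seq_len(nrow(dirs)), n_directions), , drop = FALSE]
  nz <- sort(unique(b_values[b_values > 0]))
  tab <- rbind(
    tibble::tibble(b = rep(0, n_b0), gx = 0, gy = 0, gz = 0),
    tidyr::crossing(b = nz, dir = seq_len(n_directions)) |>
      dplyr::mutate(gx = dirs[.data$dir, 1], gy = dirs[.data$dir, 2],
                    gz = dirs[.data$dir, 3]) |>
      dplyr::select(-"dir")
  )
  tab <- tibble::tibble(volume = seq_len(nrow(tab)), tab)
  if (length(unique(tab$b[tab$b <= b_low_cutoff])) < 2L) {
    abort("Scheme needs at least 2 distinct b-values at or below the cutoff.")
  }
  structure(tab, b_low_cutoff = b_low_cutoff,
            class = c("acquisition_scheme", class(tab)))
}

#' A 4-D diffusion series
#'
#' @param data 4-D array, last dimension indexing volumes.
#' @param scheme An [acquisition_scheme()] with one row per volume.
#' @param spacing Voxel spacing in mm.
#' @return A `diffusion_series`.
#' @export
diffusion_series <- function(data, scheme, spacing = c(2, 2, 4)) {
  if (length(dim(data)) != 4L) abort("`data` must be a 4-D array.")
  if (dim(data)[4] != nrow(scheme)) {
    abort(sprintf("Series has %d volumes but the scheme lists %d b-values.",
                  dim(data)[4], nrow(scheme)))
  }
  structure(list(data = data, scheme = scheme, spacing = as.numeric(spacing)),
            class = "diffusion_series")
}

#' @export
print.diffusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<diffusion_series> %d x %d x %d voxels, %d volumes, %d distinct b\n",
              d[1], d[2], d[3], d[4], length(unique(x$scheme$b))))
  invisible(x)
}
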
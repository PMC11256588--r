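#' Locate the start of the third ventricle
#'
#' The seed region anchoring the ventricular distance zones: the lateral
#' ventricle masks are dilated by a fixed number of voxels and the overlap
#' of the dilated mask with the third ventricle is the seed (the junction
#' near the foramina of Monro).
#'
#' @param lateral_mask,third_mask Logical 3-D arrays (or [voxel_grid()]s);
#'   must be non-empty and disjoint.
#' @param dilation_voxels Dilation iterations (default 3).
#' @param connectivity `"face"` (6-neighbour, default) or `"full"`
#'   (26-neighbour) structuring element.
#' @return Logical array marking the seed voxels.
#' @export
find_third_ventricle_start <- function(lateral_mask, third_mask,
                                       dilation_voxels = 3L,
                                       connectivity = c("face", "full")) {
  connectivity <- match.arg(connectivity)
  if (inherits(lateral_mask, "voxel_grid")) lateral_mask <- lateral_mask$data > 0
  if (inherits(third_mask, "voxel_grid")) third_mask <- third_mask$data > 0
  if (!any(lateral_mask) || !any(third_mask)) {
    abort("Lateral and third ventricle masks must both be non-empty.")
  }
  if (any(lateral_mask & third_mask)) {
    abort("Lateral and third ventricle masks overlap; they must be disjoint.")
  }
  seed <- dilate_mask(lateral_mask, dilation_voxels, connectivity) & third_mask
  if (!any(seed)) {
    abort(sprintf(
      "No overlap between the %d-voxel-dilated lateral ventricles and the third ventricle: check mask geometry/registration.",
      dilation_voxels))
  }
  seed
}

#' Assign ventricular distance zones
#'
#' Each lateral- or third-ventricle voxel is binned by its minimum
#' Euclidean distance in mm to the seed set, into half-open bins
#' `[0,5), [5,10), [10,15), [15,20)`. Third-ventricle zones count outward
#' (zone 1 nearest the seed); lateral-ventricle zones count inward (zone 1
#' is the 15-20 mm shell). Voxels 20 mm or farther are not analysed.
#'
#' @param seed Logical seed array from [find_third_ventricle_start()].
#' @param lateral_mask,third_mask Logical ventricle masks.
#' @param edges Zone bin edges in mm, strictly increasing.
#' @param spacing Voxel spacing in mm.
#' @return A `zone_grid`: integer `zones` array (0 = unassigned) plus a
#'   `table` tibble mapping codes to ventricle, zone number and mm range.
#' @export
assign_zones <- function(seed, lateral_mask, third_mask,
                         edges = c(0, 5, 10, 15, 20), spacing = c(2, 2, 4)) {
  if (inherits(lateral_mask, "voxel_grid")) lateral_mask <- lateral_mask$data > 0
  if (inherits(third_mask, "voxel_grid")) third_mask <- third_mask$data > 0
  if (!any(seed)) abort("Seed set is empty.")
  if (any(diff(edges) <= 0)) abort("Zone edges must be strictly increasing.")
  dims <- dim(seed)
  nb <- length(edges) - 1L
  tab <- dplyr::bind_rows(
    tibble::tibble(ventricle = "third", bin = seq_len(nb),
                   zone = seq_len(nb)),
    tibble::tibble(ventricle = "lateral", bin = seq_len(nb),
                   zone = rev(seq_len(nb)))
  ) |>
    dplyr::mutate(code = dplyr::row_number(),
                  d_lo = edges[.data$bin], d_hi = edges[.data$bin + 1L]) |>
    dplyr::select("code", "ventricle", "zone", "d_lo", "d_hi")
  zones <- array(0L, dims)
  for (vent in c("third", "lateral")) {
    m <- if (vent == "third") third_mask else lateral_mask
    idx <- which(m)
    if (!length(idx)) next
    dmm <- min_dist_mm(idx, which(seed), dims, spacing)
    bin <- findInterval(dmm, edges, rightmost.closed = FALSE)
    ok <- bin >= 1L & bin <= nb & dmm < edges[nb + 1L]
    # rows of `tab` for this ventricle are ordered by distance bin, so the
    # k-th row is the code of bin k
    vt <- tab[tab$ventricle == vent, ]
    zones[idx[ok]] <- vt$code[bin[ok]]
  }
  structure(list(zones = zones, table = tab, edges = edges,
                 spacing = spacing),
            class = "zone_grid")
}

#' @export
print.zone_grid <- function(x, ...) {
  cat(sprintf("<zone_grid> %d zoned voxels in %d zones\n",
              sum(x$zones > 0), nrow(x$table)))
  invisible(x)
}

#' Median pseudodiffusivity per ventricular zone
#'
#' Same conventions as [region_mpd()]: median of voxel D* per zone, missing
#' when a zone is empty.
#'
#' @param pdiff A `pdiff_map`.
#' @param zones A `zone_grid` from [assign_zones()].
#' @return A tibble `ventricle`, `zone`, `mpd`, `n_voxels`, `missing`.
#' @export
zone_mpd <- function(pdiff, zones) {
  if (!identical(dim(pdiff$d_star), dim(zones$zones))) {
    abort("Pseudodiffusivity map and zone grid are not on the same grid.")
  }
  idx <- which(zones$zones > 0 & !is.na(pdiff$d_star))
  zl <- zones$zones[idx]
  dv <- pdiff$d_star[idx]
  med <- vapply(zones$table$code, function(cd) {
    v <- dv[zl == cd]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  n <- vapply(zones$table$code, function(cd) sum(zl == cd), integer(1))
  tibble::tibble(ventricle = zones$table$ventricle, zone = zones$table$zone,
                 mpd = med, n_voxels = n, missing = n == 0L)
}
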
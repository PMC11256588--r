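# Nearest-labeled-voxel lookup in physical mm on an anisotropic grid.
# Iterates over atlas voxels in ascending label-code order and updates only
# on strictly smaller squared distance, so exact ties resolve to the lowest
# label code. Arithmetic matches a per-pair brute-force scan term for term.
nn_label_mm <- function(query_idx, atlas_idx, atlas_codes, dims, spacing) {
  ord <- order(atlas_codes, atlas_idx)
  atlas_idx <- atlas_idx[ord]
  atlas_codes <- atlas_codes[ord]
  q <- voxel_coords_mm(query_idx, dims, spacing)
  a <- voxel_coords_mm(atlas_idx, dims, spacing)
  best_code <- rep(NA_integer_, nrow(q))
  # With integer mm coordinates every term of the expanded squared distance
  # q^2 - 2qa + a^2 is an exact integer in double precision, so the BLAS
  # cross-product path ranks candidates identically to the per-pair scan
  # (the per-row constant q^2 cannot change the argmin and is dropped).
  exact_blas <- all(spacing == round(spacing))
  chunk <- 4096L
  a2 <- rowSums(a^2)
  for (lo in seq(1L, nrow(q), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(q))
    rows <- lo:hi
    if (exact_blas) {
      score <- tcrossprod(cbind(2 * q[rows, , drop = FALSE], -1),
                          cbind(a, a2))
      best_code[rows] <- atlas_codes[max.col(score, ties.method = "first")]
    } else {
      d2 <- outer(q[rows, 1], a[, 1], `-`)^2 +
        outer(q[rows, 2], a[, 2], `-`)^2 +
        outer(q[rows, 3], a[, 3], `-`)^2
      # atlas columns are in ascending code order, so the first argmin is
      # the lowest code among exact ties
      best_code[rows] <- atlas_codes[max.col(-d2, ties.method = "first")]
    }
  }
  best_code
}

#' Parcellate the CSF mask by nearest gray-matter landmark
#'
#' Every subarachnoid voxel of the CSF mask receives the label of the
#' gray-matter atlas voxel nearest to it in Euclidean distance, computed in
#' physical millimetres so anisotropic voxels (2 x 2 x 4 mm) are honoured.
#' Ventricular voxels keep their anatomical ventricle labels and are not
#' propagated into. At exactly equal distance the lowest label code wins,
#' which makes the output deterministic.
#'
#' @param atlas A label [voxel_grid()] of gray-matter landmark codes
#'   (0 = unlabeled); every labeled voxel must lie inside the gray-matter
#'   mask of `anatomical`.
#' @param mask A [csf_mask()].
#' @param anatomical Anatomical label `voxel_grid` providing ventricle and
#'   gray-matter codes.
#' @param dictionary Region dictionary tibble (see [phantom_dictionary()]).
#' @param gm_codes,ventricle_codes Anatomical codes for cortical gray
#'   matter and for the ventricles.
#' @return A `csf_parcellation`: the label grid over the CSF mask, the
#'   dictionary, and a per-label count table.
#' @export
propagate_labels <- function(atlas, mask, anatomical,
                             dictionary = phantom_dictionary(),
                             gm_codes = c(3L, 42L),
                             ventricle_codes = c(4L, 43L, 14L, 15L)) {
  atlas <- as_voxel_grid(atlas)
  anatomical <- as_voxel_grid(anatomical)
  dims <- dim(atlas$data)
  if (!identical(dims, dim(mask$mask))) {
    abort("Atlas and CSF mask are not on the same grid.")
  }
  atlas_idx <- which(atlas$data > 0)
  if (!length(atlas_idx)) abort("Empty gray-matter atlas.")
  if (!all(anatomical$data[atlas_idx] %in% gm_codes)) {
    abort("Atlas voxels found outside the gray-matter mask; restrict the atlas to GM before parcellating.")
  }
  labels <- array(0L, dims)
  vent <- mask$mask & array(anatomical$data %in% ventricle_codes, dims)
  labels[vent] <- as.integer(anatomical$data[vent])
  sas_idx <- which(mask$mask & !vent)
  if (length(sas_idx)) {
    labels[sas_idx] <- nn_label_mm(sas_idx, atlas_idx,
                                   as.integer(atlas$data[atlas_idx]),
                                   dims, atlas$spacing)
  }
  new_parcellation(labels, atlas$spacing, dictionary)
}

new_parcellation <- function(labels, spacing, dictionary) {
  voxvol <- prod(spacing)
  lab <- labels[labels > 0]
  n_vox <- vapply(dictionary$code, function(cd) sum(lab == cd), integer(1))
  counts <- tibble::tibble(
    code = dictionary$code, name = dictionary$name, side = dictionary$side,
    class = dictionary$class, region = dictionary$region,
    n_voxels = n_vox, volume_mm3 = n_vox * voxvol
  )[order(dictionary$code), ]
  structure(list(labels = labels, spacing = spacing,
                 dictionary = dictionary, counts = counts),
            class = "csf_parcellation")
}

#' @export
print.csf_parcellation <- function(x, ...) {
  cat(sprintf("<csf_parcellation> %d labeled voxels, %d regions\n",
              sum(x$labels > 0), sum(x$counts$n_voxels > 0)))
  print(x$counts, n = 5)
  invisible(x)
}

#' Merge left and right regions
#'
#' Collapses lateralized label codes into their merged bilateral region,
#' summing voxel counts and volumes; midline regions pass through. A merged
#' region with one side absent is kept, with the missing side noted.
#'
#' @param parcellation A `csf_parcellation`.
#' @return A tibble, one row per merged region: `region`, `class`,
#'   `n_voxels`, `volume_mm3`, `missing_side`.
#' @export
merge_bilateral <- function(parcellation) {
  cnt <- parcellation$counts
  if (any(!cnt$side %in% c("left", "right", "midline"))) {
    abort("Laterality flag missing for one or more label codes.")
  }
  cnt |>
    dplyr::group_by(.data$region, .data$class) |>
    dplyr::summarise(
      missing_side = paste(.data$side[.data$n_voxels == 0 &
                                        .data$side != "midline"],
                           collapse = ","),
      n_voxels = sum(.data$n_voxels),
      volume_mm3 = sum(.data$volume_mm3),
      .groups = "drop"
    ) |>
    dplyr::select("region", "class", "n_voxels", "volume_mm3",
                  "missing_side")
}

#' Cohort-wide small-region exclusion rule
#'
#' A region with fewer than `min_voxels` voxels in at least
#' `subject_fraction` of the cohort is dropped from all analyses. If the
#' shortfall affects fewer subjects than that, the region is kept and the
#' affected subjects' MPD is marked missing instead.
#'
#' @param cohort_counts Tibble with columns `subject`, `region`,
#'   `n_voxels`.
#' @param min_voxels Minimum voxel count (default 10).
#' @param subject_fraction Fraction of subjects at which the shortfall
#'   becomes cohort-wide (default 0.5).
#' @return A list: `region_status` (region, n_below, frac_below, dropped)
#'   and `subject_missing` (subject, region, missing) for kept regions.
#' @examples
#' counts <- tidyr::crossing(subject = 1:10, region = c("a", "b")) |>
#'   dplyr::mutate(n_voxels = ifelse(region == "a" & subject <= 6, 8L, 50L))
#' apply_exclusion_rule(counts)$region_status
#' @export
apply_exclusion_rule <- function(cohort_counts, min_voxels = 10L,
                                 subject_fraction = 0.5) {
  if (any(cohort_counts$n_voxels < 0)) abort("Voxel counts must be >= 0.")
  status <- cohort_counts |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_below = sum(.data$n_voxels < min_voxels),
                     frac_below = mean(.data$n_voxels < min_voxels),
                     .groups = "drop") |>
    dplyr::mutate(dropped = .data$frac_below >= subject_fraction)
  missing <- cohort_counts |>
    dplyr::semi_join(dplyr::filter(status, !.data$dropped), by = "region") |>
    dplyr::transmute(.data$subject, .data$region,
                     missing = .data$n_voxels < min_voxels)
  list(region_status = status, subject_missing = missing)
}
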
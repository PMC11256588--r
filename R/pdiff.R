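#' Fit pseudodiffusivity at a single voxel
#'
#' The low-b decay is modelled as single-compartment isotropic
#' pseudo-diffusion, `S(b) = S(0) exp(-b D*)`, and fitted by ordinary least
#' squares of `log S` on `b` over all volumes with `b <= b_max`; `D*` is
#' minus the slope. Every volume is one point: the replicate gradient
#' directions per b-value (CSF is isotropic, so they are replicates) and
#' each b = 0 volume all enter unweighted. Non-positive signals are dropped
#' pointwise; if fewer than two distinct b-values survive, the voxel is
#' marked missing.
#'
#' @param signals Per-volume signal values.
#' @param b Per-volume b-values in s/mm2 (or an [acquisition_scheme()]).
#' @param b_max Low-b cutoff in s/mm2 (default 200, where incoherent-motion
#'   attenuation dominates thermal diffusion).
#' @return A list: `d_star` (mm2/s), `s0`, `r_squared`, `n_points`,
#'   `n_dropped`, `missing`.
#' @examples
#' b <- c(0, 10, 20, 30, 50, 70, 90, 110, 130, 150, 170, 200)
#' fit_voxel_pdiff(1000 * exp(-b * 3e-3), b)$d_star
#' @export
fit_voxel_pdiff <- function(signals, b, b_max = 200) {
  if (inherits(b, "acquisition_scheme") || is.data.frame(b)) b <- b$b
  if (length(signals) != length(b)) {
    abort("`signals` and `b` must have the same length.")
  }
  use <- b <= b_max
  s <- signals[use]; bb <- b[use]
  pos <- s > 0
  n_dropped <- sum(!pos)
  s <- s[pos]; bb <- bb[pos]
  if (length(unique(bb)) < 2L) {
    return(list(d_star = NA_real_, s0 = NA_real_, r_squared = NA_real_,
                n_points = length(s), n_dropped = n_dropped, missing = TRUE))
  }
  y <- log(s)
  bc <- bb - mean(bb)
  slope <- sum(bc * y) / sum(bc^2)
  intercept <- mean(y) - slope * mean(bb)
  res <- y - (intercept + slope * bb)
  tss <- sum((y - mean(y))^2)
  list(d_star = -slope, s0 = exp(intercept),
       r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
       n_points = length(s), n_dropped = n_dropped, missing = FALSE)
}

#' Fit a pseudodiffusivity map over the eligible CSF voxels
#'
#' Runs the log-linear fit of [fit_voxel_pdiff()] at every eligible voxel.
#' Eligibility is the CSF mask: free-water fraction passing the configured
#' comparator against 0.8 plus a ventricular/subarachnoid label.
#'
#' @param series A [diffusion_series()].
#' @param mask A [csf_mask()] or logical array of eligible voxels.
#' @param b_max Low-b cutoff in s/mm2.
#' @return A `pdiff_map`: `d_star`, `r_squared`, `n_points` arrays (NA
#'   outside eligibility), the eligibility mask, and counts of dropped
#'   points / failed voxels.
#' @export
fit_pdiff_map <- function(series, mask, b_max = 200) {
  m <- if (inherits(mask, "csf_mask")) mask$mask else mask
  dims <- dim(series$data)[1:3]
  if (!identical(dim(m), dims)) {
    abort("Eligibility mask and series are not on the same grid.")
  }
  b <- series$scheme$b
  use <- b <= b_max
  bb <- b[use]
  if (length(unique(bb)) < 2L) {
    abort("Fewer than 2 distinct b-values at or below `b_max`.")
  }
  idx <- which(m)
  nvox <- prod(dims)
  sig <- series$data[outer(idx, (which(use) - 1L) * nvox, `+`)]
  dim(sig) <- c(length(idx), sum(use))
  d_star <- r2 <- npts <- array(NA_real_, dims)
  all_pos <- rowSums(sig <= 0) == 0L
  n_failed <- 0L
  if (any(all_pos)) {
    y <- log(sig[all_pos, , drop = FALSE])
    bc <- bb - mean(bb)
    denom <- sum(bc^2)
    slope <- as.numeric(y %*% bc) / denom
    ybar <- rowMeans(y)
    fit_res <- y - outer(slope, bb) - (ybar - slope * mean(bb))
    tss <- rowSums((y - ybar)^2)
    rss <- rowSums(fit_res^2)
    ii <- idx[all_pos]
    d_star[ii] <- -slope
    r2[ii] <- ifelse(tss > 0, 1 - rss / tss, NA_real_)
    npts[ii] <- length(bb)
  }
  for (k in which(!all_pos)) {
    f <- fit_voxel_pdiff(sig[k, ], bb, b_max = b_max)
    if (f$missing) {
      n_failed <- n_failed + 1L
    } else {
      d_star[idx[k]] <- f$d_star
      r2[idx[k]] <- f$r_squared
      npts[idx[k]] <- f$n_points
    }
  }
  structure(list(d_star = d_star, r_squared = r2, n_points = npts,
                 eligible = m, spacing = series$spacing, b_max = b_max,
                 n_eligible = length(idx), n_failed = n_failed),
            class = "pdiff_map")
}

#' @export
print.pdiff_map <- function(x, ...) {
  cat(sprintf("<pdiff_map> %d eligible voxels (b <= %g), %d failed fits\n",
              x$n_eligible, x$b_max, x$n_failed))
  cat(sprintf("  D* median %.3g mm2/s\n", median(x$d_star, na.rm = TRUE)))
  invisible(x)
}

#' Median pseudodiffusivity per CSF region
#'
#' The MPD of a region is the median of voxel D* across the region's
#' voxels; the median resists outlier voxels. For bilateral regions the
#' left and right medians are averaged weighted by the volume of the
#' corresponding sides; midline regions pass through. Empty regions come
#' back missing.
#'
#' @param pdiff A `pdiff_map` from [fit_pdiff_map()].
#' @param parcellation A `csf_parcellation` on the same grid.
#' @return A tibble, one row per merged region: `region`, `class`, `mpd`,
#'   `n_voxels`, `volume_mm3`, `missing`.
#' @export
region_mpd <- function(pdiff, parcellation) {
  if (!identical(dim(pdiff$d_star), dim(parcellation$labels))) {
    abort("Pseudodiffusivity map and parcellation are not on the same grid.")
  }
  voxvol <- prod(parcellation$spacing)
  dict <- parcellation$dictionary
  idx <- which(parcellation$labels > 0 & !is.na(pdiff$d_star))
  lab <- as.integer(parcellation$labels[idx])
  dv <- pdiff$d_star[idx]
  med <- vapply(dict$code, function(cd) {
    v <- dv[lab == cd]
    if (length(v)) median(v) else NA_real_
  }, numeric(1))
  n <- vapply(dict$code, function(cd) sum(lab == cd), integer(1))
  regions <- sort(unique(dict$region))
  rows <- lapply(regions, function(rg) {
    sel <- dict$region == rg
    ntot <- sum(n[sel])
    tibble::tibble(
      region = rg, class = dict$class[sel][1],
      mpd = if (ntot > 0) sum(med[sel] * n[sel], na.rm = TRUE) / ntot
            else NA_real_,
      n_voxels = ntot, volume_mm3 = ntot * voxvol, missing = ntot == 0L)
  })
  dplyr::bind_rows(rows)
}

#' Per-region median of a scalar map
#'
#' Median of a scalar (e.g. CBF) over each label of a label grid; even
#' counts use the usual mean-of-middle-two convention. Labels absent from
#' the grid come back missing.
#'
#' @param scalar A scalar [voxel_grid()].
#' @param labels A label `voxel_grid` on the same grid.
#' @param codes Label codes to summarise (default: all present).
#' @return A tibble `code`, `median`, `n_voxels`.
#' @export
regional_scalar_median <- function(scalar, labels, codes = NULL) {
  scalar <- as_voxel_grid(scalar); labels <- as_voxel_grid(labels)
  stopifnot_same_grid(scalar, labels, c("scalar map", "labels"))
  lab <- as.integer(labels$data)
  if (is.null(codes)) codes <- sort(unique(lab[lab > 0]))
  purrr::map_dfr(codes, function(cd) {
    v <- scalar$data[lab == cd]
    tibble::tibble(code = cd,
                   median = if (length(v)) median(v) else NA_real_,
                   n_voxels = length(v))
  })
}

#' Intraparenchymal volume from an anatomical segmentation
#'
#' Sum of cerebral gray- and white-matter voxel volumes (FreeSurfer codes
#' 2, 3, 41, 42 by default); optionally also the fraction of intracranial
#' volume.
#'
#' @param seg A label [voxel_grid()].
#' @param codes Label codes counted as parenchyma.
#' @param icv Optional intracranial volume in mm3 (> 0).
#' @return A list: `volume_mm3` and, when `icv` is given, `fraction`.
#' @export
intraparenchymal_volume <- function(seg, codes = c(2L, 3L, 41L, 42L),
                                    icv = NULL) {
  seg <- as_voxel_grid(seg)
  vol <- sum(seg$data %in% codes) * prod(seg$spacing)
  out <- list(volume_mm3 = vol)
  if (!is.null(icv)) {
    if (icv <= 0) abort("Intracranial volume must be positive.")
    out$fraction <- vol / icv
  }
  out
}
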
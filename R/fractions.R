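#' Two-class soft segmentation of corrected FA
#'
#' Deterministic stand-in for an EM tissue segmenter: 2-means on the masked
#' intensities with fixed initialization at the 10th and 90th percentiles,
#' followed by a soft assignment in which a voxel's white-matter fraction is
#' its relative closeness to the higher-intensity (WM) center. Free-water
#' corrected FA is high in white matter and low elsewhere, so the
#' higher-FA class is taken as WM.
#'
#' @param cfa A [voxel_grid()] of corrected FA values in `[0, 1]`.
#' @param brain_mask Logical array; voxels outside get WM fraction 0.
#' @param max_iter,tol 2-means iteration controls.
#' @return A `voxel_grid` of WM fractions in `[0, 1]`, with attributes
#'   `centers` and `degenerate`. A constant-intensity input is a degenerate
#'   single-class case: all-zero WM fraction plus a warning.
#' @export
segment_two_class <- function(cfa, brain_mask, max_iter = 100, tol = 1e-8) {
  cfa <- as_voxel_grid(cfa)
  x <- cfa$data[brain_mask]
  if (any(x < 0 | x > 1, na.rm = TRUE)) {
    abort("Corrected FA must lie in [0, 1] within the mask.")
  }
  centers <- unname(quantile(x, c(0.1, 0.9), names = FALSE))
  if (diff(centers) < 1e-12) {
    warn("Constant-intensity input: single-class degenerate case, returning all-zero WM fraction.")
    out <- array(0, dim(cfa$data))
    wm <- voxel_grid(out, cfa$spacing)
    attr(wm, "centers") <- centers
    attr(wm, "degenerate") <- TRUE
    return(wm)
  }
  for (it in seq_len(max_iter)) {
    assign_hi <- abs(x - centers[2]) < abs(x - centers[1])
    new <- c(mean(x[!assign_hi]), mean(x[assign_hi]))
    if (any(is.na(new))) break  # one cluster emptied; keep previous centers
    if (max(abs(new - centers)) < tol) { centers <- new; break }
    centers <- new
  }
  centers <- sort(centers)
  d_lo <- abs(x - centers[1]); d_hi <- abs(x - centers[2])
  frac <- d_lo / (d_lo + d_hi)
  frac[d_lo + d_hi == 0] <- 0.5
  out <- array(0, dim(cfa$data))
  out[brain_mask] <- frac
  wm <- voxel_grid(out, cfa$spacing)
  attr(wm, "centers") <- centers
  attr(wm, "degenerate") <- FALSE
  wm
}

#' Gray-matter fraction as the closure of CSF and WM fractions
#'
#' `gm = 1 - csf - wm`, clipped to `[0, 1]`; the clip count is reported as
#' an attribute. If CSF + WM exceeds 1 by more than 1e-3 at over 1% of
#' voxels the inputs are inconsistent and an error is raised.
#'
#' @param csf,wm Fraction [voxel_grid()]s in `[0, 1]`.
#' @return A `voxel_grid` of GM fractions with attribute `n_clipped`.
#' @examples
#' csf <- voxel_grid(array(0.2, c(8, 8, 8)))
#' wm <- voxel_grid(array(0.3, c(8, 8, 8)))
#' range(gm_fraction(csf, wm)$data)  # 0.5
#' @export
gm_fraction <- function(csf, wm) {
  csf <- as_voxel_grid(csf); wm <- as_voxel_grid(wm)
  stopifnot_same_grid(csf, wm, c("csf fraction", "wm fraction"))
  tot <- csf$data + wm$data
  over <- tot > 1 + 1e-3
  if (mean(over) > 0.01) {
    abort(sprintf(
      "CSF + WM fractions exceed 1 at %.1f%% of voxels: inconsistent inputs.",
      100 * mean(over)))
  }
  gm <- pmin(pmax(1 - tot, 0), 1)
  out <- voxel_grid(array(gm, dim(csf$data)), csf$spacing)
  attr(out, "n_clipped") <- sum(tot > 1 | tot < 0)
  out
}

#' Pseudo-T2 image from GM and CSF fractions
#'
#' Mixes the gray-matter and CSF fraction maps in a 1:2 ratio, normalized
#' by 3 so the output stays in `[0, 1]`. The doubled CSF weight boosts
#' CSF contrast, which is what the downstream CSF segmentation needs.
#'
#' @param gm,csf Fraction [voxel_grid()]s.
#' @return A scalar `voxel_grid`, `(gm + 2 csf) / 3`.
#' @export
pseudo_t2 <- function(gm, csf) {
  gm <- as_voxel_grid(gm); csf <- as_voxel_grid(csf)
  stopifnot_same_grid(gm, csf, c("gm fraction", "csf fraction"))
  voxel_grid((gm$data + 2 * csf$data) / 3, gm$spacing)
}

#' CSF mask from free-water fraction and anatomical labels
#'
#' A voxel enters the CSF mask when its free-water fraction passes the
#' threshold AND its anatomical label is ventricular or subarachnoid. The
#' comparator is configurable because the two natural readings ("larger
#' than 0.8" vs "0.8 or larger") differ at exact equality; the default is
#' `">="`, shared with the fitting stage's eligibility rule.
#'
#' @param csf_fraction Free-water fraction [voxel_grid()].
#' @param anatomical Anatomical label [voxel_grid()].
#' @param threshold Free-water threshold (default 0.8).
#' @param comparator `"ge"` (default) or `"gt"`.
#' @param csf_codes Label codes counting as ventricle/subarachnoid.
#' @return A `csf_mask`: logical array + the thresholds used.
#' @export
csf_mask <- function(csf_fraction, anatomical, threshold = 0.8,
                     comparator = c("ge", "gt"),
                     csf_codes = c(4L, 43L, 14L, 15L, 24L)) {
  comparator <- match.arg(comparator)
  csf_fraction <- as_voxel_grid(csf_fraction)
  anatomical <- as_voxel_grid(anatomical)
  stopifnot_same_grid(csf_fraction, anatomical,
                      c("free-water fraction", "anatomical labels"))
  fw_ok <- if (comparator == "gt") csf_fraction$data > threshold
           else csf_fraction$data >= threshold
  label_ok <- array(anatomical$data %in% csf_codes, dim(anatomical$data))
  mask <- fw_ok & label_ok
  if (!any(mask)) {
    abort(sprintf(
      "Empty CSF mask: %d voxels pass the free-water criterion, %d carry a ventricle/subarachnoid label, none pass both.",
      sum(fw_ok), sum(label_ok)))
  }
  structure(list(mask = mask, spacing = csf_fraction$spacing,
                 threshold = threshold, comparator = comparator,
                 csf_codes = csf_codes),
            class = "csf_mask")
}

#' @export
print.csf_mask <- function(x, ...) {
  cat(sprintf("<csf_mask> %d voxels (free-water %s %.3g + CSF label)\n",
              sum(x$mask), if (x$comparator == "gt") ">" else ">=",
              x$threshold))
  invisible(x)
}

#' Tissue fractions from free-water and corrected FA inputs
#'
#' Convenience wrapper chaining [segment_two_class()] and [gm_fraction()]:
#' the free-water fraction is the CSF fraction, WM comes from the two-class
#' split of corrected FA (or is supplied directly), and GM closes the sum
#' to one.
#'
#' @param free_water Free-water fraction [voxel_grid()].
#' @param cfa Corrected FA `voxel_grid` (ignored when `wm` is given).
#' @param brain_mask Logical array of brain voxels.
#' @param wm Optional precomputed WM fraction `voxel_grid`.
#' @return A `tissue_fractions` list: `csf`, `wm`, `gm` grids and a
#'   `wm_estimated` flag.
#' @export
tissue_fractions <- function(free_water, cfa = NULL, brain_mask = NULL,
                             wm = NULL) {
  free_water <- as_voxel_grid(free_water)
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim(free_water$data))
  estimated <- is.null(wm)
  if (estimated) {
    if (is.null(cfa)) abort("Supply either `cfa` or a precomputed `wm`.")
    wm <- segment_two_class(cfa, brain_mask)
    # WM cannot exceed the non-free-water share of the voxel
    wm$data <- pmin(wm$data, 1 - free_water$data)
  } else {
    wm <- as_voxel_grid(wm)
  }
  gm <- gm_fraction(free_water, wm)
  structure(list(csf = free_water, wm = wm, gm = gm,
                 wm_estimated = estimated),
            class = "tissue_fractions")
}
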
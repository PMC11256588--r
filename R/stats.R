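#' z-transform a numeric vector over its non-missing entries
#'
#' Centering and scaling used throughout the association layer; all
#' variables except sex are z-transformed before regression.
#'
#' @param x Numeric vector.
#' @return `(x - mean) / sd` over non-missing entries; constant input
#'   errors.
#' @export
z_transform <- function(x) {
  m <- mean(x, na.rm = TRUE)
  s <- sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) abort("Cannot z-transform a constant column.")
  (x - m) / s
}

#' Aggregated Cauchy association test (ACAT)
#'
#' Combines p-values through the Cauchy transform:
#' `T = sum(w_i tan((0.5 - p_i) pi))` with equal weights, and
#' `p = 0.5 - atan(T) / pi`. The combination is robust to dependence among
#' the component tests and reduces to the identity at a single p-value.
#' Exact 0 or 1 inputs are clamped to `[1e-15, 1 - 1e-15]` with a warning.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param weights Optional non-negative weights, normalized to sum to 1
#'   (default equal).
#' @return The combined p-value.
#' @examples
#' acat(c(0.5, 0.5, 0.5))  # 0.5
#' acat(0.2)               # 0.2
#' @export
acat <- function(p, weights = NULL) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p <- p[!is.na(p)]
  if (!length(p)) return(NA_real_)
  eps <- 1e-15
  n_clamped <- sum(p < eps | p > 1 - eps)
  if (n_clamped > 0) {
    warn(sprintf("%d p-value(s) at 0 or 1 clamped to [%g, %g].",
                 n_clamped, eps, 1 - eps))
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  if (is.null(weights)) weights <- rep(1 / length(p), length(p))
  else weights <- weights / sum(weights)
  t_stat <- sum(weights * tan((0.5 - p) * pi))
  0.5 - atan(t_stat) / pi
}

#' Voxel-subsampling reproducibility of an MPD value
#'
#' Coefficient of variation of the region MPD under repeated random
#' subsampling of the region's voxels: 95% of voxels, drawn without
#' replacement, 100 times; CoV = sd / mean of the replicate MPDs.
#'
#' @param values Voxel D* values of the region.
#' @param side Optional side label per voxel ("left"/"right"/"midline");
#'   when given, each replicate MPD is the volume-weighted average of the
#'   per-side medians, matching [region_mpd()].
#' @param subsample Fraction of voxels per replicate (default 0.95).
#' @param reps Number of replicates (default 100).
#' @param seed RNG seed.
#' @return A list: `cov`, `replicates`, `n_voxels`.
#' @export
voxel_bootstrap_cov <- function(values, side = NULL, subsample = 0.95,
                                reps = 100L, seed = 1L) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("Need at least 2 voxels for a reproducibility CoV.")
  m <- max(1L, floor(n * subsample))
  stat <- function(ii) {
    if (is.null(side)) return(median(values[ii]))
    s <- side[ii]
    meds <- tapply(values[ii], s, median)
    wts <- tapply(values[ii], s, length)
    sum(meds * wts) / sum(wts)
  }
  repl <- with_seed_local(seed, {
    vapply(seq_len(reps), function(r) stat(sample.int(n, m)), numeric(1))
  })
  mu <- mean(repl)
  if (mu == 0) abort("Mean of replicate MPDs is zero; CoV undefined.")
  list(cov = sd(repl) / mu, replicates = repl, n_voxels = n)
}

#' Reproducibility CoV for every region of a parcellation
#'
#' Applies [voxel_bootstrap_cov()] to each merged region of a
#' pseudodiffusivity map.
#'
#' @param pdiff A `pdiff_map`.
#' @param parcellation A `csf_parcellation`.
#' @param min_voxels Regions below this voxel count come back missing.
#' @inheritParams voxel_bootstrap_cov
#' @return A tibble `region`, `cov`, `n_voxels`.
#' @export
reproducibility_cov <- function(pdiff, parcellation, subsample = 0.95,
                                reps = 100L, seed = 1L, min_voxels = 10L) {
  idx <- which(parcellation$labels > 0 & !is.na(pdiff$d_star))
  dict <- parcellation$dictionary
  codes <- as.integer(parcellation$labels[idx])
  df <- tibble::tibble(
    region = dict$region[match(codes, dict$code)],
    side = dict$side[match(codes, dict$code)],
    d = pdiff$d_star[idx]
  )
  regs <- sort(unique(dict$region))
  purrr::imap_dfr(setNames(regs, regs), function(rg, nm) {
    sub <- df[df$region == rg, ]
    if (nrow(sub) < min_voxels) {
      return(tibble::tibble(region = rg, cov = NA_real_,
                            n_voxels = nrow(sub)))
    }
    bs <- voxel_bootstrap_cov(sub$d, side = sub$side, subsample = subsample,
                              reps = reps,
                              seed = derive_seed(seed, match(rg, regs)))
    tibble::tibble(region = rg, cov = bs$cov, n_voxels = bs$n_voxels)
  })
}

# Pearson r / p / n over pairwise-complete columns of a data frame
pairwise_pearson <- function(dat) {
  cols <- names(dat)
  k <- length(cols)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(cols, cols))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ok <- complete.cases(dat[[i]], dat[[j]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= 3 && sd(dat[[i]][ok]) > 0 && sd(dat[[j]][ok]) > 0) {
      ct <- cor.test(dat[[i]][ok], dat[[j]][ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p, n = n)
}

#' Inter-regional correlation of MPD
#'
#' Pearson correlation of regional MPD between every pair of CSF regions
#' across the cohort, with pairwise-complete missing handling and
#' Benjamini-Hochberg adjustment across all unique region pairs as one
#' family.
#'
#' @param frame Cohort tibble with one row per subject.
#' @param regions Region column names (default: all columns starting
#'   `"mpd_"`).
#' @return A `cbss_cor` object: symmetric `r`, `p`, `p_adj`, `n` matrices
#'   and a tidy `pairs` tibble. Pairs involving a constant column are
#'   undefined (NA).
#' @export
interregional_correlation <- function(frame, regions = NULL) {
  regions <- regions %||% grep("^mpd_", names(frame), value = TRUE)
  if (length(regions) < 2) abort("Need at least two region columns.")
  pw <- pairwise_pearson(frame[regions])
  ut <- upper.tri(pw$r)
  p_adj <- pw$p
  p_adj[ut] <- p.adjust(pw$p[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  pairs <- which(ut, arr.ind = TRUE) |>
    tibble::as_tibble() |>
    dplyr::transmute(region1 = regions[.data$row],
                     region2 = regions[.data$col],
                     r = pw$r[ut], n = pw$n[ut], p = pw$p[ut],
                     p_adj = p_adj[ut])
  structure(list(r = pw$r, p = pw$p, p_adj = p_adj, n = pw$n,
                 pairs = pairs, method = "pearson"),
            class = "cbss_cor")
}

#' @export
print.cbss_cor <- function(x, ...) {
  cat(sprintf("<cbss_cor> %d region pairs (%s)\n", nrow(x$pairs), x$method))
  print(x$pairs, n = 5)
  invisible(x)
}

#' Cohort-bootstrap correlation with Cauchy combination
#'
#' Robustness companion to [interregional_correlation()]: 95% of the cohort
#' is drawn without replacement, the pairwise Pearson correlations are
#' computed, and this is repeated ten times. Per pair, the correlation is
#' averaged over the draws and the final p-value is the ACAT combination of
#' the draws' Pearson p-values.
#'
#' @inheritParams interregional_correlation
#' @param subsample Cohort fraction per draw (default 0.95; `floor(n *
#'   subsample)` subjects).
#' @param reps Number of draws (default 10).
#' @param seed RNG seed.
#' @return A `cbss_cor` with `r` the averaged correlation and `p` the
#'   ACAT-combined p-value (BH applied across pairs on the combined
#'   p-values).
#' @export
cohort_bootstrap_acat <- function(frame, regions = NULL, subsample = 0.95,
                                  reps = 10L, seed = 1L) {
  if (reps < 1) abort("`reps` must be at least 1.")
  regions <- regions %||% grep("^mpd_", names(frame), value = TRUE)
  n <- nrow(frame)
  m <- max(3L, floor(n * subsample))
  draws <- with_seed_local(seed, {
    purrr::map(seq_len(reps), function(r) {
      pairwise_pearson(frame[sample.int(n, m), regions])
    })
  })
  k <- length(regions)
  r_bar <- Reduce(`+`, purrr::map(draws, "r")) / reps
  p_comb <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ps <- purrr::map_dbl(draws, \(d) d$p[i, j])
    p_comb[i, j] <- p_comb[j, i] <- acat(ps)
  }
  ut <- upper.tri(r_bar)
  p_adj <- p_comb
  p_adj[ut] <- p.adjust(p_comb[ut], method = "BH")
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  pairs <- which(ut, arr.ind = TRUE) |>
    tibble::as_tibble() |>
    dplyr::transmute(region1 = regions[.data$row],
                     region2 = regions[.data$col],
                     r = r_bar[ut], p = p_comb[ut], p_adj = p_adj[ut])
  structure(list(r = r_bar, p = p_comb, p_adj = p_adj, n = NULL,
                 pairs = pairs, reps = reps, subsample = subsample,
                 method = "pearson + ACAT over cohort bootstrap"),
            class = "cbss_cor")
}

#' Covariate-adjusted association of regional MPD with an outcome
#'
#' For each predictor column, fits ordinary least squares of the z-scored
#' outcome on the z-scored predictor plus covariates (continuous covariates
#' z-scored; sex enters untransformed as 0/1) with listwise deletion, and
#' reports the standardized slope of the predictor, the marginal Pearson
#' correlation, and the slope p-value. Benjamini-Hochberg adjustment is
#' applied across predictors (the CSF regions) per outcome.
#'
#' @param frame Cohort tibble, one row per subject.
#' @param predictors Predictor column names (region or zone MPD columns).
#' @param outcome Outcome column name (a cognitive score or age).
#' @param covariates Covariate column names; default age, sex and years of
#'   education. Use `character(0)` for unadjusted models (e.g. age as
#'   outcome).
#' @param binary_covariates Covariates excluded from z-transformation.
#' @return A `cbss_association` with a tidy result table and the fitted
#'   models.
#' @export
adjusted_association <- function(frame, predictors, outcome,
                                 covariates = c("age", "sex", "education"),
                                 binary_covariates = "sex") {
  fits <- list()
  rows <- purrr::map_dfr(predictors, function(px) {
    dat <- frame[c(px, outcome, covariates)]
    dat <- dat[complete.cases(dat), ]
    nn <- nrow(dat)
    if (nn <= length(covariates) + 2) {
      abort(sprintf("Only %d complete rows for %s ~ %s: too few for %d covariates.",
                    nn, outcome, px, length(covariates)))
    }
    ztrans <- setdiff(c(px, outcome, covariates), binary_covariates)
    dat[ztrans] <- lapply(dat[ztrans], z_transform)
    mm <- stats::model.matrix(
      ~ ., data = dat[c(px, covariates)])
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      bad <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      abort(paste("Collinear model columns:", paste(bad, collapse = ", ")))
    }
    fml <- stats::reformulate(c(px, covariates), response = outcome)
    fit <- lm(fml, data = dat)
    fits[[px]] <<- fit
    sm <- summary(fit)$coefficients
    tibble::tibble(predictor = px, outcome = outcome,
                   slope = unname(coef(fit)[px]),
                   se = sm[px, "Std. Error"],
                   r = cor(dat[[px]], dat[[outcome]]),
                   p = sm[px, "Pr(>|t|)"], n = nn)
  })
  rows$p_adj <- p.adjust(rows$p, method = "BH")
  structure(list(results = rows, fits = fits, covariates = covariates),
            class = "cbss_association")
}

#' @export
print.cbss_association <- function(x, ...) {
  cat(sprintf("<cbss_association> outcome %s, %d predictors, adjusted for {%s}\n",
              x$results$outcome[1], nrow(x$results),
              paste(x$covariates, collapse = ", ")))
  print(x$results, n = 8)
  invisible(x)
}

#' Sex difference in regional MPD
#'
#' Two-sided Wilcoxon rank-sum test of region MPD by sex: exact null
#' distribution when both groups have 25 or fewer observations and no ties,
#' normal approximation with tie correction otherwise.
#'
#' @param frame Cohort tibble.
#' @param regions Region MPD column names (default: all `"mpd_"` columns).
#' @param sex_col Name of the 0/1 sex column.
#' @return A tibble `region`, `statistic` (rank-sum W), `p`, `p_adj` (BH
#'   across regions), `n0`, `n1`.
#' @export
sex_difference <- function(frame, regions = NULL, sex_col = "sex") {
  regions <- regions %||% grep("^mpd_", names(frame), value = TRUE)
  out <- purrr::map_dfr(regions, function(rg) {
    ok <- complete.cases(frame[[rg]], frame[[sex_col]])
    x <- frame[[rg]][ok & frame[[sex_col]] == 0]
    y <- frame[[rg]][ok & frame[[sex_col]] == 1]
    if (!length(x) || !length(y)) {
      abort(sprintf("Both sexes must be present to test %s.", rg))
    }
    exact <- max(length(x), length(y)) <= 25 &&
      !anyDuplicated(c(x, y))
    wt <- wilcox.test(x, y, exact = exact, correct = !exact)
    tibble::tibble(region = rg, statistic = unname(wt$statistic),
                   p = wt$p.value, n0 = length(x), n1 = length(y))
  })
  out$p_adj <- p.adjust(out$p, method = "BH")
  out
}

#' Per-subject MPD-CBF profile correlation and its change with age
#'
#' For each subject, the Pearson correlation between the vector of regional
#' MPD values and the matched vector of regional CBF values (requiring at
#' least `min_regions` complete pairs), followed by an unadjusted
#' association of that per-subject correlation with age.
#'
#' @param frame Cohort tibble containing `mpd_<region>` and `cbf_<region>`
#'   columns plus `age`.
#' @param regions Merged region names to use.
#' @param min_regions Minimum complete region pairs per subject (default 3).
#' @return A list: `subject_r` (subject, r, n_regions) and `age_association`
#'   (a `cbss_association` of the profile correlation on age).
#' @export
mpd_cbf_profile_correlation <- function(frame, regions, min_regions = 3L) {
  subject_r <- purrr::pmap_dfr(
    list(seq_len(nrow(frame))), function(i) {
      mpd <- as.numeric(frame[i, paste0("mpd_", regions)])
      cbf <- as.numeric(frame[i, paste0("cbf_", regions)])
      ok <- complete.cases(mpd, cbf)
      tibble::tibble(
        subject = frame$subject[i],
        r = if (sum(ok) >= min_regions) cor(mpd[ok], cbf[ok]) else NA_real_,
        n_regions = sum(ok))
    })
  aug <- dplyr::left_join(subject_r, frame[c("subject", "age")],
                          by = "subject")
  assoc <- if (sum(complete.cases(aug$r, aug$age)) > 2) {
    adjusted_association(aug, predictors = "r", outcome = "age",
                         covariates = character(0))
  }
  list(subject_r = subject_r, age_association = assoc)
}
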
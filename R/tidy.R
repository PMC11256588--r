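#' Tidy an inter-regional correlation result
#'
#' @param x A `cbss_cor`.
#' @param ... Unused.
#' @return The unique-pair tibble: `region1`, `region2`, `r`, `p`, `p_adj`.
#' @export
tidy.cbss_cor <- function(x, ...) x$pairs

#' @rdname tidy.cbss_cor
#' @param alpha Significance level applied to the BH-adjusted p-values.
#' @export
glance.cbss_cor <- function(x, alpha = 0.05, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs),
                 n_significant = sum(x$pairs$p_adj < alpha, na.rm = TRUE),
                 mean_abs_r = mean(abs(x$pairs$r), na.rm = TRUE),
                 method = x$method)
}

#' Tidy a covariate-adjusted association result
#'
#' @param x A `cbss_association`.
#' @param ... Unused.
#' @return One row per predictor: standardized slope, SE, marginal Pearson
#'   r, raw and BH-adjusted p, n.
#' @export
tidy.cbss_association <- function(x, ...) x$results

#' @rdname tidy.cbss_association
#' @param alpha Significance level applied to the BH-adjusted p-values.
#' @export
glance.cbss_association <- function(x, alpha = 0.05, ...) {
  tibble::tibble(outcome = x$results$outcome[1],
                 n_predictors = nrow(x$results),
                 n_significant = sum(x$results$p_adj < alpha, na.rm = TRUE),
                 covariates = paste(x$covariates, collapse = "+"))
}
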
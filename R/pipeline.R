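#' Pipeline configuration
#'
#' Collects every tunable of the CSF-based spatial statistics pipeline in
#' one validated object that round-trips through JSON. Unknown keys are
#' rejected.
#'
#' @param phantom A [phantom_spec()] describing the synthetic cohort to
#'   generate (the packaged input source; external data can be fed to the
#'   stage functions directly).
#' @param fw_threshold Free-water threshold for CSF eligibility.
#' @param fw_comparator `"ge"` or `"gt"`, shared between the CSF mask and
#'   the fitting eligibility rule.
#' @param b_max Low-b fitting cutoff in s/mm2.
#' @param min_voxels,subject_fraction Small-region exclusion rule
#'   parameters (see [apply_exclusion_rule()]).
#' @param dilation_voxels Lateral-ventricle dilation for the third-ventricle
#'   start (see [find_third_ventricle_start()]).
#' @param zone_edges Ventricular zone bin edges in mm.
#' @param outcomes Cognitive outcome columns to associate with MPD.
#' @param covariates Adjustment covariates for cognitive outcomes.
#' @param sensitivity Also adjust for intraparenchymal volume and volume
#'   fraction.
#' @param cov_reps,cov_subsample Voxel-bootstrap reproducibility settings.
#' @param boot_reps,boot_subsample Cohort-bootstrap correlation settings.
#' @param seed Master seed; per-stage seeds are derived from it.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `cbss_config`.
#' @export
cbss_config <- function(phantom = phantom_spec(), fw_threshold = 0.8,
                        fw_comparator = c("ge", "gt"), b_max = 200,
                        min_voxels = 10L, subject_fraction = 0.5,
                        dilation_voxels = 3L,
                        zone_edges = c(0, 5, 10, 15, 20),
                        outcomes = c("MMSE", "MOCA", "STM", "LTM", "TMTA"),
                        covariates = c("age", "sex", "education"),
                        sensitivity = FALSE,
                        cov_reps = 100L, cov_subsample = 0.95,
                        boot_reps = 10L, boot_subsample = 0.95,
                        seed = 1L, out_dir = NULL) {
  fw_comparator <- match.arg(fw_comparator)
  structure(list(phantom = phantom, fw_threshold = fw_threshold,
                 fw_comparator = fw_comparator, b_max = b_max,
                 min_voxels = as.integer(min_voxels),
                 subject_fraction = subject_fraction,
                 dilation_voxels = as.integer(dilation_voxels),
                 zone_edges = zone_edges, outcomes = outcomes,
                 covariates = covariates, sensitivity = sensitivity,
                 cov_reps = as.integer(cov_reps),
                 cov_subsample = cov_subsample,
                 boot_reps = as.integer(boot_reps),
                 boot_subsample = boot_subsample,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "cbss_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param config A `cbss_config`.
#' @param path JSON file path.
#' @return `write_config()` the path, invisibly; `read_config()` a
#'   `cbss_config`. Unknown keys in the JSON are rejected.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$phantom <- unclass(x$phantom)
  x$phantom$d_star <- as.list(x$phantom$d_star)
  x$phantom$scheme <- as.data.frame(x$phantom$scheme)
  x$phantom$effects <- as.data.frame(x$phantom$effects)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(cbss_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown)) {
    abort(paste("Unknown configuration key(s):",
                paste(unknown, collapse = ", ")))
  }
  ph_known <- names(formals(phantom_spec))
  ph_unknown <- setdiff(names(x$phantom), ph_known)
  if (length(ph_unknown)) {
    abort(paste("Unknown phantom key(s):", paste(ph_unknown, collapse = ", ")))
  }
  ph <- x$phantom
  ph$shape <- as.integer(ph$shape)
  ph$d_star <- unlist(ph$d_star)
  sch <- tibble::as_tibble(ph$scheme)
  ph$scheme <- acquisition_scheme(b_values = unique(sch$b),
                                  n_b0 = sum(sch$b == 0),
                                  n_directions = max(table(sch$b[sch$b > 0])))
  ph$effects <- tibble::as_tibble(ph$effects)
  spec <- do.call(phantom_spec, ph)
  x$phantom <- spec
  x$out_dir <- x$out_dir %||% NULL
  do.call(cbss_config, x)
}

# one subject through fractions -> parcellation -> pdiff -> finemap
process_subject <- function(subject, config) {
  anat <- subject$anatomy
  brain <- anat$data > 0
  tf <- tissue_fractions(subject$free_water, subject$cfa, brain_mask = brain)
  pt2 <- pseudo_t2(tf$gm, tf$csf)
  mask <- csf_mask(subject$free_water, anat,
                   threshold = config$fw_threshold,
                   comparator = config$fw_comparator)
  parc <- propagate_labels(subject$atlas, mask, anat)
  pd <- fit_pdiff_map(subject$series, mask, b_max = config$b_max)
  rt <- region_mpd(pd, parc)
  lat <- array(anat$data %in% c(4L, 43L), dim(anat$data))
  third <- array(anat$data == 14L, dim(anat$data))
  seed <- find_third_ventricle_start(lat, third,
                                     dilation_voxels = config$dilation_voxels)
  zg <- assign_zones(seed, lat, third, edges = config$zone_edges,
                     spacing = anat$spacing)
  zt <- zone_mpd(pd, zg)
  dict <- parc$dictionary
  sulcal <- dict[dict$class != "ventricle", ]
  gm_all <- array(anat$data %in% c(3L, 42L), dim(anat$data))
  cortical_cbf <- median(subject$cbf$data[gm_all])
  reg_cbf <- regional_scalar_median(subject$cbf, subject$atlas,
                                    codes = sulcal$code) |>
    dplyr::left_join(dict[c("code", "region")], by = "code") |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(cbf = sum(.data$median * .data$n_voxels) /
                       sum(.data$n_voxels), .groups = "drop")
  ipv <- intraparenchymal_volume(anat, icv = sum(brain) * prod(anat$spacing))
  list(region_table = rt, zone_table = zt, pdiff = pd, parcellation = parc,
       pseudo_t2 = pt2, cortical_cbf = cortical_cbf, regional_cbf = reg_cbf,
       ipv = ipv$volume_mm3, ipv_fraction = ipv$fraction)
}

# assemble the subjects x variables cohort frame, applying the small-region
# exclusion rule to the region MPD columns
build_cohort_frame <- function(region_tables, zone_tables, cbf_rows,
                               covariates, min_voxels = 10L,
                               subject_fraction = 0.5) {
  counts <- region_tables |>
    dplyr::select("subject", "region", "n_voxels")
  rule <- apply_exclusion_rule(counts, min_voxels = min_voxels,
                               subject_fraction = subject_fraction)
  kept <- rule$region_status$region[!rule$region_status$dropped]
  mpd_wide <- region_tables |>
    dplyr::filter(.data$region %in% kept) |>
    dplyr::left_join(rule$subject_missing, by = c("subject", "region")) |>
    dplyr::mutate(mpd = ifelse(.data$missing.y | .data$missing.x,
                               NA_real_, .data$mpd)) |>
    dplyr::select("subject", "region", "mpd") |>
    tidyr::pivot_wider(names_from = "region", values_from = "mpd",
                       names_prefix = "mpd_")
  zone_wide <- zone_tables |>
    dplyr::mutate(zone_col = sprintf("mpd_%s_ventricle_zone%d",
                                     .data$ventricle, .data$zone)) |>
    dplyr::select("subject", "zone_col", "mpd") |>
    tidyr::pivot_wider(names_from = "zone_col", values_from = "mpd")
  frame <- covariates |>
    dplyr::left_join(mpd_wide, by = "subject") |>
    dplyr::left_join(zone_wide, by = "subject") |>
    dplyr::left_join(cbf_rows, by = "subject")
  attr(frame, "exclusion") <- rule$region_status
  frame
}

#' Run the full CSF-based spatial statistics pipeline
#'
#' Drives phantom generation, tissue fractions, CSF parcellation,
#' pseudodiffusivity fitting, ventricular fine mapping and the cohort
#' statistics battery, writing tabular outputs and a JSON run manifest.
#' Re-running with the same configuration overwrites deterministically:
#' the tabular outputs are byte-identical.
#'
#' @param config A [cbss_config()].
#' @return A `cbss_run`: the cohort frame, all result tables, and the
#'   manifest. If `config$out_dir` is set, tables are written there as CSV
#'   plus `manifest.json`.
#' @export
run_cbss <- function(config) {
  stopifnot(inherits(config, "cbss_config"))
  spec <- config$phantom
  manifest <- list(package = "cbss",
                   version = as.character(utils::packageVersion("cbss")),
                   seed = config$seed, stages = list())
  t_all <- Sys.time()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e) e)
    entry <- list(name = name,
                  status = if (inherits(res, "error")) "failed" else "complete",
                  seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3))
    if (inherits(res, "error")) entry$error <- conditionMessage(res)
    manifest$stages[[name]] <<- entry
    if (inherits(res, "error")) abort(sprintf("Stage '%s' failed: %s",
                                              name, conditionMessage(res)))
    res
  }

  covariates <- stage("phantom", cohort_covariates(spec))
  n <- spec$n_subjects
  region_tables <- zone_tables <- list()
  cbf_rows <- list()
  cov_tables <- list()
  frac_counts <- parc_counts <- fit_counts <- zone_counts <- 0L
  per_subject <- stage("fractions", {
    # fractions / parcellation / pdiff / finemap run per subject; their
    # stage records aggregate voxel counts across the cohort
    for (i in seq_len(n)) {
      subj <- generate_subject(spec, i)
      res <- process_subject(subj, config)
      frac_counts <- frac_counts + sum(subj$anatomy$data > 0)
      parc_counts <- parc_counts + sum(res$parcellation$labels > 0)
      fit_counts <- fit_counts + res$pdiff$n_eligible
      zone_counts <- zone_counts + sum(res$zone_table$n_voxels)
      region_tables[[i]] <- dplyr::mutate(res$region_table, subject = i,
                                          .before = 1)
      zone_tables[[i]] <- dplyr::mutate(res$zone_table, subject = i,
                                        .before = 1)
      cbf_rows[[i]] <- tibble::tibble(
        subject = i, cortical_cbf = res$cortical_cbf,
        ipv = res$ipv, ipv_fraction = res$ipv_fraction) |>
        dplyr::bind_cols(tidyr::pivot_wider(res$regional_cbf,
                                            names_from = "region",
                                            values_from = "cbf",
                                            names_prefix = "cbf_"))
      cov_tables[[i]] <- reproducibility_cov(
        res$pdiff, res$parcellation, subsample = config$cov_subsample,
        reps = config$cov_reps, seed = derive_seed(config$seed, 7000L + i),
        min_voxels = config$min_voxels) |>
        dplyr::mutate(subject = i, .before = 1)
    }
    list(brain_voxels = frac_counts)
  })
  region_tables <- dplyr::bind_rows(region_tables)
  zone_tables <- dplyr::bind_rows(zone_tables)
  cbf_rows <- dplyr::bind_rows(cbf_rows)
  cov_table <- dplyr::bind_rows(cov_tables)
  manifest$stages$fractions$brain_voxels <- frac_counts
  manifest$stages$parcellation <- list(name = "parcellation",
                                       status = "complete",
                                       labeled_voxels = parc_counts)
  manifest$stages$pdiff <- list(
    name = "pdiff", status = "complete", fitted_voxels = fit_counts,
    b_values_used = length(unique(spec$scheme$b[spec$scheme$b <= config$b_max])))
  manifest$stages$finemap <- list(name = "finemap", status = "complete",
                                  zoned_voxels = zone_counts)

  frame <- build_cohort_frame(region_tables, zone_tables, cbf_rows,
                              covariates, min_voxels = config$min_voxels,
                              subject_fraction = config$subject_fraction)
  stats_out <- stage("stats", {
    mpd_cols <- grep("^mpd_(?!.*zone)", names(frame), value = TRUE,
                     perl = TRUE)
    zone_cols <- grep("^mpd_.*zone", names(frame), value = TRUE)
    res <- list()
    if (n >= 4 && length(mpd_cols) >= 2) {
      res$correlation <- interregional_correlation(frame, mpd_cols)
      res$correlation_boot <- cohort_bootstrap_acat(
        frame, mpd_cols, subsample = config$boot_subsample,
        reps = config$boot_reps, seed = derive_seed(config$seed, 11L))
    }
    if (n > length(config$covariates) + 3) {
      assoc <- purrr::map(setNames(config$outcomes, config$outcomes),
                          \(oc) adjusted_association(frame, mpd_cols, oc,
                                                     config$covariates))
      assoc$age <- adjusted_association(frame, mpd_cols, "age",
                                        covariates = character(0))
      res$associations <- dplyr::bind_rows(purrr::map(assoc, "results"))
      res$zone_associations <- dplyr::bind_rows(purrr::map(
        setNames(config$outcomes, config$outcomes),
        \(oc) adjusted_association(frame, zone_cols, oc,
                                   config$covariates)$results))
      if (isTRUE(config$sensitivity)) {
        res$sensitivity <- dplyr::bind_rows(purrr::map(
          setNames(config$outcomes, config$outcomes), \(oc) dplyr::bind_rows(
            adjusted_association(frame, mpd_cols, oc,
                                 c(config$covariates, "ipv"))$results |>
              dplyr::mutate(adjustment = "ipv"),
            adjusted_association(frame, mpd_cols, oc,
                                 c(config$covariates, "ipv_fraction"))$results |>
              dplyr::mutate(adjustment = "ipv_fraction"))))
      }
      res$sex <- sex_difference(frame, mpd_cols)
      sulcal <- unique(phantom_dictionary()$region[
        phantom_dictionary()$class != "ventricle"])
      res$cbf_cortical <- adjusted_association(
        frame, mpd_cols, "cortical_cbf", covariates = c("age", "sex"))
      cbf_rows_assoc <- purrr::map_dfr(sulcal, function(rg) {
        adjusted_association(frame, paste0("mpd_", rg), paste0("cbf_", rg),
                             covariates = c("age", "sex"))$results
      })
      cbf_rows_assoc$p_adj <- p.adjust(cbf_rows_assoc$p, method = "BH")
      res$cbf_regional <- cbf_rows_assoc
      res$cbf_profile <- mpd_cbf_profile_correlation(frame, sulcal)
    }
    res
  })

  manifest$seconds_total <- round(as.numeric(Sys.time() - t_all,
                                             units = "secs"), 3)
  out <- structure(list(frame = frame, region_tables = region_tables,
                        zone_tables = zone_tables,
                        reproducibility = cov_table,
                        exclusion = attr(frame, "exclusion"),
                        stats = stats_out, manifest = manifest,
                        config = config),
                   class = "cbss_run")
  if (!is.null(config$out_dir)) write_run(out, config$out_dir)
  out
}

# write tabular outputs + manifest; CSVs are deterministic byte-for-byte
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(dir, "config.json")
  write_config(run$config, cfg_path)
  run$manifest$config_hash <- unname(tools::md5sum(cfg_path))
  wr <- function(x, f) if (!is.null(x)) {
    readr::write_csv(x, file.path(dir, f))
  }
  wr(run$region_tables, "region_mpd.csv")
  wr(run$zone_tables, "zone_mpd.csv")
  wr(run$frame, "cohort_frame.csv")
  wr(run$reproducibility, "reproducibility_cov.csv")
  wr(run$exclusion, "region_exclusion.csv")
  if (!is.null(run$stats$correlation)) {
    wr(run$stats$correlation$pairs, "interregional_correlation.csv")
  }
  if (!is.null(run$stats$correlation_boot)) {
    wr(run$stats$correlation_boot$pairs, "correlation_bootstrap_acat.csv")
  }
  wr(run$stats$associations, "associations.csv")
  wr(run$stats$zone_associations, "zone_associations.csv")
  wr(run$stats$sensitivity, "associations_sensitivity.csv")
  wr(run$stats$sex, "sex_differences.csv")
  wr(run$stats$cbf_regional, "cbf_associations.csv")
  if (!is.null(run$stats$cbf_profile)) {
    wr(run$stats$cbf_profile$subject_r, "mpd_cbf_profile.csv")
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.cbss_run <- function(x, ...) {
  st <- purrr::map_chr(x$manifest$stages, "status")
  cat(sprintf("<cbss_run> %d subjects, %d/%d stages complete\n",
              x$config$phantom$n_subjects, sum(st == "complete"),
              length(st)))
  invisible(x)
}
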
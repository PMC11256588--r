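#' Region dictionary of the digital head phantom
#'
#' The phantom carries a toy sulcus/cistern atlas: four bilateral
#' gray-matter landmark regions (two sulci, two cisterns; odd codes left,
#' even codes right) plus the ventricular system. Anatomical segmentation
#' codes follow the FreeSurfer convention where one exists (2/41 cerebral
#' white matter, 3/42 cortex, 4/43 lateral ventricles, 14/15 third and
#' fourth ventricles); code 24 marks the subarachnoid space.
#'
#' @return A tibble with columns `code`, `name`, `side`
#'   (left/right/midline), `class` (sulcus/cistern/ventricle) and `region`
#'   (the merged bilateral region name).
#' @export
phantom_dictionary <- function() {
  tibble::tribble(
    ~code, ~name,                        ~side,     ~class,      ~region,
    101L, "central_sulcus_left",         "left",    "sulcus",    "central_sulcus",
    102L, "central_sulcus_right",        "right",   "sulcus",    "central_sulcus",
    103L, "parietooccipital_sulcus_left", "left",   "sulcus",    "parietooccipital_sulcus",
    104L, "parietooccipital_sulcus_right", "right", "sulcus",    "parietooccipital_sulcus",
    105L, "suprasellar_cistern_left",    "left",    "cistern",   "suprasellar_cistern",
    106L, "suprasellar_cistern_right",   "right",   "cistern",   "suprasellar_cistern",
    107L, "ambient_cistern_left",        "left",    "cistern",   "ambient_cistern",
    108L, "ambient_cistern_right",       "right",   "cistern",   "ambient_cistern",
    4L,   "lateral_ventricle_left",      "left",    "ventricle", "lateral_ventricle",
    43L,  "lateral_ventricle_right",     "right",   "ventricle", "lateral_ventricle",
    14L,  "third_ventricle",             "midline", "ventricle", "third_ventricle",
    15L,  "fourth_ventricle",            "midline", "ventricle", "fourth_ventricle"
  )
}

# anatomical segmentation codes used by the phantom
anat_codes <- list(
  wm = c(left = 2L, right = 41L), gm = c(left = 3L, right = 42L),
  lateral = c(left = 4L, right = 43L), third = 14L, fourth = 15L, sas = 24L
)

#' Specify a digital head phantom
#'
#' Defines the synthetic study conditions: grid geometry, per-region true
#' pseudodiffusivity, the acquisition scheme, the noise model, cohort size,
#' and covariate effects planted on regional pseudodiffusivity. True D*
#' defaults place ventricles and cisterns above sulci, in the
#' 1-3 x 10^-3 mm2/s range typical of CSF pseudo-diffusion; tissue decays
#' with a slower apparent diffusivity. Noise defaults to Rician (magnitude
#' MRI) at sigma = 2% of S0.
#'
#' @param shape Grid dimensions in voxels (each axis >= 8).
#' @param spacing Voxel spacing in mm (default 2 x 2 x 4).
#' @param d_star Named vector of true regional pseudodiffusivity in mm2/s,
#'   one entry per merged region of [phantom_dictionary()].
#' @param d_tissue Apparent diffusivity of GM/WM tissue in mm2/s.
#' @param s0 Signal at b = 0.
#' @param noise One of "rician", "gaussian", "none".
#' @param sigma Noise level as a fraction of `s0`.
#' @param scheme An [acquisition_scheme()].
#' @param n_subjects Cohort size (>= 1).
#' @param between_subject_cv Relative SD of each region's D* across
#'   subjects.
#' @param effects Tibble with columns `region`, `covariate`, `slope`:
#'   planted standardized slopes of regional (or ventricular-zone) D* on a
#'   covariate. `region` may be a merged region name or
#'   `"<third|lateral>_ventricle_zone<1-4>"`.
#' @param cbf_coupling List `base`, `age_slope`: per-subject coupling of the
#'   regional CBF profile to the regional D* profile, increasing with age.
#' @param jitter_mm Amplitude of per-subject geometry jitter in mm.
#' @param seed Master RNG seed.
#' @return A validated `phantom_spec`.
#' @examples
#' spec <- phantom_spec(n_subjects = 2, noise = "none")
#' subj <- generate_subject(spec, 1)
#' subj$anatomy
#' @export
phantom_spec <- function(shape = c(24, 24, 16), spacing = c(2, 2, 4),
                         d_star = c(central_sulcus = 1.2e-3,
                                    parietooccipital_sulcus = 1.4e-3,
                                    suprasellar_cistern = 2.2e-3,
                                    ambient_cistern = 2.0e-3,
                                    lateral_ventricle = 3.0e-3,
                                    third_ventricle = 2.6e-3,
                                    fourth_ventricle = 2.4e-3),
                         d_tissue = 0.7e-3, s0 = 1000,
                         noise = c("rician", "gaussian", "none"),
                         sigma = 0.02, scheme = acquisition_scheme(),
                         n_subjects = 1L, between_subject_cv = 0.1,
                         effects = NULL,
                         cbf_coupling = list(base = 0.4, age_slope = 0.3),
                         jitter_mm = 1, seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L)) {
    abort("Degenerate grid: the phantom needs at least 8 voxels per axis.")
  }
  if (any(d_star <= 0)) abort("All regional D* must be positive.")
  if (sigma < 0) abort("`sigma` must be non-negative.")
  if (n_subjects < 1) abort("`n_subjects` must be at least 1.")
  effects <- tibble::as_tibble(effects %||% list())
  if (nrow(effects) == 0) {
    effects <- tibble::tibble(region = character(), covariate = character(),
                              slope = numeric())
  }
  known <- c(names(d_star),
             paste0(rep(c("third_ventricle_zone", "lateral_ventricle_zone"),
                        each = 4), 1:4))
  bad <- setdiff(effects$region, known)
  if (length(bad)) abort(paste("Unknown effect region(s):",
                               paste(bad, collapse = ", ")))
  if (anyDuplicated(effects$region)) {
    abort("At most one planted effect per region.")
  }
  if (any(abs(effects$slope) > 1)) {
    abort("Planted standardized slopes must lie in [-1, 1].")
  }
  structure(list(shape = shape, spacing = as.numeric(spacing),
                 d_star = d_star, d_tissue = d_tissue, s0 = s0,
                 noise = noise, sigma = sigma, scheme = scheme,
                 n_subjects = as.integer(n_subjects),
                 between_subject_cv = between_subject_cv, effects = effects,
                 cbf_coupling = cbf_coupling, jitter_mm = jitter_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# run expr under a temporary RNG state; restores the caller's stream
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed fan-out, kept inside 32-bit integer range
derive_seed <- function(seed, key) {
  as.integer((as.double(seed) * 48271 + key * 9973) %% 2147483629) + 1L
}

#' Cohort covariates of a phantom specification
#'
#' Age, sex, years of education and five continuous cognitive scores (MMSE,
#' MOCA, STM, LTM, TMTA) for the whole cohort, generated deterministically
#' from the spec seed. Cognitive scores decline mildly with age (TMTA, a
#' timed test, increases); sex is coded 0 = male, 1 = female. The returned
#' tibble also carries the planted per-subject effect latents used by
#' [generate_subject()] as an attribute.
#'
#' @param spec A [phantom_spec()].
#' @return A tibble, one row per subject.
#' @export
cohort_covariates <- function(spec) {
  n <- spec$n_subjects
  with_seed_local(derive_seed(spec$seed, 1L), {
    age <- rnorm(n, 70, 8)
    sex <- rbinom(n, 1, 0.6)
    education <- pmax(0, rnorm(n, 12, 3.5))
    zage <- if (n > 1) as.numeric(scale(age)) else 0
    cog_latent <- function(rho) {
      l <- rho * zage + sqrt(1 - rho^2) * rnorm(n)
      if (n > 1) as.numeric(scale(l)) else l
    }
    lat <- list(MMSE = cog_latent(-0.3), MOCA = cog_latent(-0.3),
                STM = cog_latent(-0.25), LTM = cog_latent(-0.25),
                TMTA = cog_latent(0.3))
    cov <- tibble::tibble(
      subject = seq_len(n), age = age, sex = sex, education = education,
      MMSE = 27 + 2 * lat$MMSE, MOCA = 24 + 3 * lat$MOCA,
      STM = 12 + 3 * lat$STM, LTM = 10 + 3 * lat$LTM,
      TMTA = 60 + 20 * lat$TMTA
    )
    # per-subject effect latents u_r: planted regions mix the covariate's
    # cohort z-score with independent noise so that corr(u_r, z_cov) equals
    # the planted standardized slope; unplanted regions are pure noise
    zcov <- function(v) if (n > 1) as.numeric(scale(v)) else 0
    regions <- union(names(spec$d_star), spec$effects$region)
    u <- matrix(rnorm(n * length(regions)), n,
                dimnames = list(NULL, regions))
    for (k in seq_len(nrow(spec$effects))) {
      e <- spec$effects[k, ]
      z <- zcov(cov[[e$covariate]])
      u[, e$region] <- e$slope * z + sqrt(1 - e$slope^2) * rnorm(n)
    }
    attr(cov, "effect_latents") <- u
    cov
  })
}

# ellipsoid membership helper: normalized squared radius on the mm grid
norm_r2 <- function(coords, center, semi) {
  ((coords[, 1] - center[1]) / semi[1])^2 +
    ((coords[, 2] - center[2]) / semi[2])^2 +
    ((coords[, 3] - center[3]) / semi[3])^2
}

# subject geometry: anatomical label array + atlas label array
phantom_geometry <- function(spec, subject_index) {
  d <- spec$shape; sp <- spec$spacing
  with_seed_local(derive_seed(spec$seed, 100L + subject_index), {
    jit <- function() runif(3, -spec$jitter_mm, spec$jitter_mm)
    coords <- voxel_coords_mm(seq_len(prod(d)), d, sp)
    extent <- (d - 1) * sp
    center <- extent / 2
    semi <- 0.45 * extent *
      (1 + runif(3, -0.02, 0.02) * (spec$jitter_mm > 0))
    r2 <- norm_r2(coords, center, semi)
    anat <- integer(prod(d))
    left <- coords[, 1] < center[1]
    anat[r2 < 1] <- anat_codes$sas
    gm_band <- r2 >= 0.62^2 & r2 < 0.82^2
    anat[gm_band & left] <- anat_codes$gm["left"]
    anat[gm_band & !left] <- anat_codes$gm["right"]
    wm_band <- r2 < 0.62^2
    anat[wm_band & left] <- anat_codes$wm["left"]
    anat[wm_band & !left] <- anat_codes$wm["right"]
    # ventricles override interior tissue
    # long paraventricular blobs: horns reach > 15 mm from the junction so
    # every distance zone is populated
    lat_semi <- c(4, 16, 8)
    cl <- center + c(-8, -5, 6) + jit()
    cr <- center + c(8, -5, 6) + jit()
    anat[norm_r2(coords, cl, lat_semi) < 1 & r2 < 0.9^2] <-
      anat_codes$lateral["left"]
    anat[norm_r2(coords, cr, lat_semi) < 1 & r2 < 0.9^2] <-
      anat_codes$lateral["right"]
    third <- abs(coords[, 1] - center[1]) < 2 &
      abs(coords[, 2] - center[2]) < 3 &
      coords[, 3] >= center[3] - 18 & coords[, 3] <= center[3] + 6
    anat[third & anat %in% c(0L, anat_codes$wm, anat_codes$gm,
                             anat_codes$sas) & r2 < 1] <- anat_codes$third
    fourth <- norm_r2(coords, center + c(0, 0, -26), c(3, 4, 4)) < 1
    anat[fourth & r2 < 1 & !(anat %in% anat_codes$lateral) &
           anat != anat_codes$third] <- anat_codes$fourth
    # atlas: GM ribbon partitioned into octants -> 4 bilateral landmarks
    atlas <- integer(prod(d))
    gm <- anat %in% anat_codes$gm
    ant <- coords[, 2] < center[2]
    sup <- coords[, 3] >= center[3]
    atlas[gm & sup & ant] <- 101L
    atlas[gm & sup & !ant] <- 103L
    atlas[gm & !sup & ant] <- 105L
    atlas[gm & !sup & !ant] <- 107L
    atlas[gm & !left & atlas > 0L] <- atlas[gm & !left & atlas > 0L] + 1L
    list(anat = array(anat, d), atlas = array(atlas, d))
  })
}

# per-voxel generating D* over the grid, given subject geometry and the
# subject's per-region D* draws (named vector, merged region names; zone
# entries override inside the named ventricular distance zone)
phantom_dstar_map <- function(spec, geom, region_d, zone_d = NULL) {
  d <- spec$shape
  dict <- phantom_dictionary()
  dmap <- array(NA_real_, d)
  anat <- geom$anat
  dmap[anat %in% c(anat_codes$wm, anat_codes$gm)] <- spec$d_tissue
  for (vc in c(anat_codes$lateral, anat_codes$third, anat_codes$fourth)) {
    reg <- dict$region[match(vc, dict$code)]
    dmap[anat == vc] <- region_d[[reg]]
  }
  sas <- which(anat == anat_codes$sas)
  if (length(sas)) {
    atlas_idx <- which(geom$atlas > 0L)
    codes <- nn_label_mm(sas, atlas_idx, geom$atlas[atlas_idx], d,
                         spec$spacing)
    regs <- dict$region[match(codes, dict$code)]
    dmap[sas] <- region_d[regs]
  }
  if (!is.null(zone_d) && length(zone_d)) {
    zones <- phantom_true_zones(spec, geom)
    for (zn in names(zone_d)) {
      dmap[zones == zn] <- zone_d[[zn]]
    }
  }
  dmap
}

# generating-side ventricular zone labels (character array; "" elsewhere),
# using the same seed/zone definitions the analysis applies
phantom_true_zones <- function(spec, geom) {
  lat <- array(geom$anat %in% anat_codes$lateral, spec$shape)
  third <- geom$anat == anat_codes$third
  seed <- find_third_ventricle_start(lat, third)
  zg <- assign_zones(seed, lat, third, spacing = spec$spacing)
  out <- array("", spec$shape)
  for (k in seq_len(nrow(zg$table))) {
    out[zg$zones == zg$table$code[k]] <-
      sprintf("%s_ventricle_zone%d", zg$table$ventricle[k], zg$table$zone[k])
  }
  out
}

#' Generate one phantom subject
#'
#' Builds the full set of per-subject inputs the pipeline consumes:
#' anatomical labels, gray-matter atlas labels, free-water fraction,
#' corrected FA, the low-b diffusion series, a CBF map, and the subject's
#' covariate row. CSF voxels decay as `S(b) = S0 exp(-b D*)` with the
#' region's (or ventricular zone's) subject-specific D*; tissue decays with
#' the slower `d_tissue`; noise is added per the spec's noise model.
#'
#' @param spec A [phantom_spec()].
#' @param subject_index Subject number in `1:n_subjects`.
#' @return A `phantom_subject` list: `anatomy`, `atlas`, `free_water`,
#'   `cfa`, `cbf` ([voxel_grid()]s), `series` ([diffusion_series()]),
#'   `covariates` (one-row tibble) and `truth` (generating D* per region and
#'   per voxel).
#' @export
generate_subject <- function(spec, subject_index) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (subject_index < 1 || subject_index > spec$n_subjects) {
    abort("`subject_index` outside 1:n_subjects.")
  }
  cov <- cohort_covariates(spec)
  u <- attr(cov, "effect_latents")
  cv <- spec$between_subject_cv
  draw <- pmax(1 + cv * u[subject_index, ], 0.2)
  region_d <- spec$d_star * draw[names(spec$d_star)]
  zone_regions <- grep("_zone[1-4]$", colnames(u), value = TRUE)
  zone_d <- NULL
  if (length(zone_regions)) {
    base <- spec$d_star[sub("_zone[1-4]$", "", zone_regions)]
    zone_d <- setNames(base * draw[zone_regions], zone_regions)
  }
  geom <- phantom_geometry(spec, subject_index)
  dmap <- phantom_dstar_map(spec, geom, region_d, zone_d)
  d <- spec$shape; sp <- spec$spacing
  anat <- geom$anat
  csf <- anat %in% c(anat_codes$lateral, anat_codes$third,
                     anat_codes$fourth, anat_codes$sas)
  tissue <- anat %in% c(anat_codes$wm, anat_codes$gm)
  gm <- anat %in% anat_codes$gm
  with_seed_local(derive_seed(spec$seed, 5000L + subject_index), {
    nvox <- prod(d)
    fw <- numeric(nvox)
    fw[csf] <- pmin(1, pmax(0.95, 0.98 + rnorm(sum(csf), 0, 0.005)))
    fw[gm] <- pmin(0.3, pmax(0, 0.12 + rnorm(sum(gm), 0, 0.03)))
    fw[anat %in% anat_codes$wm] <-
      pmin(0.3, pmax(0, 0.05 + rnorm(sum(anat %in% anat_codes$wm), 0, 0.02)))
    cfa <- numeric(nvox)
    cfa[anat %in% anat_codes$wm] <-
      pmin(1, pmax(0, rnorm(sum(anat %in% anat_codes$wm), 0.65, 0.05)))
    cfa[gm] <- pmin(1, pmax(0, rnorm(sum(gm), 0.15, 0.03)))
    cfa[csf] <- pmin(1, pmax(0, rnorm(sum(csf), 0.03, 0.01)))
    # noiseless decay, then the spec's noise model
    b <- spec$scheme$b
    dvec <- as.numeric(dmap)
    dvec[is.na(dvec)] <- 0
    # noise is applied to the head (object signal); background air stays
    # zero -- no stage reads outside the head
    head_idx <- which(csf | tissue)
    sig <- matrix(0, nvox, length(b))
    decay <- spec$s0 * exp(-outer(dvec[head_idx], b))
    if (spec$noise != "none" && spec$sigma > 0) {
      s <- spec$sigma * spec$s0
      if (spec$noise == "gaussian") {
        decay <- decay + matrix(rnorm(length(decay), 0, s), nrow(decay))
      } else {
        decay <- sqrt((decay +
                         matrix(rnorm(length(decay), 0, s), nrow(decay)))^2 +
                        matrix(rnorm(length(decay), 0, s), nrow(decay))^2)
      }
    }
    sig[head_idx, ] <- decay
    # CBF: regional GM profile coupled to the subject's D* profile with a
    # coupling strength that increases with (cohort-standardized) age
    cbf <- numeric(nvox)
    cbf[anat %in% anat_codes$wm] <- 20
    cbf[csf] <- 5
    zage <- if (spec$n_subjects > 1) {
      as.numeric(scale(cov$age))[subject_index]
    } else 0
    beta <- spec$cbf_coupling$base + spec$cbf_coupling$age_slope * zage
    beta <- max(-0.99, min(0.99, beta))
    dict <- phantom_dictionary()
    sulcal <- unique(dict$region[dict$class != "ventricle"])
    prof <- region_d[sulcal]
    w <- as.numeric(scale(prof))
    eps <- rnorm(length(sulcal))
    cbf_r <- 50 + 6 * (beta * w + sqrt(1 - beta^2) * eps)
    atlas_reg <- dict$region[match(as.integer(geom$atlas), dict$code)]
    idx_gm <- which(gm & geom$atlas > 0L)
    cbf[idx_gm] <- cbf_r[match(atlas_reg[idx_gm], sulcal)] +
      rnorm(length(idx_gm), 0, 1)
    list(
      anatomy = voxel_grid(array(anat, d), sp),
      atlas = voxel_grid(array(geom$atlas, d), sp),
      free_water = voxel_grid(array(fw, d), sp),
      cfa = voxel_grid(array(cfa, d), sp),
      cbf = voxel_grid(array(cbf, d), sp),
      series = diffusion_series(array(sig, c(d, length(b))), spec$scheme, sp),
      covariates = cov[subject_index, ],
      truth = list(d_star_map = dmap, region_d = region_d, zone_d = zone_d,
                   regional_cbf = setNames(cbf_r, sulcal))
    ) |> structure(class = "phantom_subject")
  })
}

#' Generate a phantom cohort
#'
#' Subjects share the atlas topology but differ in jittered geometry,
#' subject-level regional D* draws, noise, and covariates.
#'
#' @param spec A [phantom_spec()].
#' @return A `phantom_cohort`: list of subjects, the covariate table, and
#'   the region dictionary.
#' @export
generate_cohort <- function(spec) {
  subjects <- purrr::map(seq_len(spec$n_subjects),
                         \(i) generate_subject(spec, i))
  structure(list(subjects = subjects,
                 covariates = cohort_covariates(spec),
                 dictionary = phantom_dictionary()),
            class = "phantom_cohort")
}

#' Write a phantom subject to disk
#'
#' Volumes go out as NIfTI, the diffusion series with FSL-style bval/bvec
#' sidecars, covariates as CSV.
#'
#' @param subject A `phantom_subject`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(subject$anatomy, file.path(dir, "anatomy.nii.gz"))
  write_volume(subject$atlas, file.path(dir, "atlas.nii.gz"))
  write_volume(subject$free_water, file.path(dir, "free_water.nii.gz"))
  write_volume(subject$cfa, file.path(dir, "cfa.nii.gz"))
  write_volume(subject$cbf, file.path(dir, "cbf.nii.gz"))
  write_series(subject$series, file.path(dir, "lowb.nii.gz"))
  readr::write_csv(subject$covariates, file.path(dir, "covariates.csv"))
  invisible(dir)
}
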
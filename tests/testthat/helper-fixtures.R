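# Small fixtures and independent oracles used across the test files.

# brute-force nearest-neighbor labeling: per-query loop over every atlas
# voxel, squared mm distance accumulated per pair, ties to the lowest code
oracle_nn_labels <- function(query_idx, atlas_idx, atlas_codes, dims,
                             spacing) {
  qi <- arrayInd(query_idx, dims)
  ai <- arrayInd(atlas_idx, dims)
  out <- integer(length(query_idx))
  for (k in seq_along(query_idx)) {
    best <- Inf
    cand <- integer(0)
    for (j in seq_along(atlas_idx)) {
      d2 <- sum(((qi[k, ] - ai[j, ]) * spacing)^2)
      if (d2 < best) {
        best <- d2
        cand <- atlas_codes[j]
      } else if (d2 == best) {
        cand <- c(cand, atlas_codes[j])
      }
    }
    out[k] <- min(cand)
  }
  out
}

# brute-force iterated face-connected dilation: a voxel joins if any
# 6-neighbour is in the mask
oracle_dilate_face <- function(mask, iterations) {
  d <- dim(mask)
  for (it in seq_len(iterations)) {
    idx <- which(!mask)
    ijk <- arrayInd(idx, d)
    grow <- logical(length(idx))
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      nb <- ijk
      nb[, ax] <- nb[, ax] + s
      ok <- nb[, ax] >= 1 & nb[, ax] <= d[ax]
      grow[ok] <- grow[ok] | mask[nb[ok, , drop = FALSE]]
    }
    mask[idx[grow]] <- TRUE
  }
  mask
}

# a random synthetic labeled volume: atlas voxels (code 101+), ventricle
# voxels (code 14), subarachnoid voxels (code 24), all with CSF-level
# free water; returns the pieces propagate_labels() needs
random_label_phantom <- function(seed, max_dim = 20L, n_atlas = 40L,
                                 n_sas = 150L, n_vent = 10L) {
  set.seed(seed)
  dims <- sample(8:max_dim, 3, replace = TRUE)
  nvox <- prod(dims)
  vox <- sample.int(nvox, n_atlas + n_sas + n_vent)
  atlas_idx <- vox[seq_len(n_atlas)]
  sas_idx <- vox[n_atlas + seq_len(n_sas)]
  vent_idx <- vox[n_atlas + n_sas + seq_len(n_vent)]
  atlas <- array(0L, dims)
  atlas[atlas_idx] <- sample(101:106, n_atlas, replace = TRUE)
  anat <- array(0L, dims)
  anat[atlas_idx] <- 3L
  anat[sas_idx] <- 24L
  anat[vent_idx] <- 14L
  fw <- array(0, dims)
  fw[c(sas_idx, vent_idx)] <- 0.95
  spacing <- c(2, 2, 4)
  list(dims = dims, spacing = spacing,
       atlas = cbss::voxel_grid(atlas, spacing),
       anat = cbss::voxel_grid(anat, spacing),
       fw = cbss::voxel_grid(fw, spacing),
       atlas_idx = sort(atlas_idx), sas_idx = sort(sas_idx))
}

# tiny phantom spec used where full realism is not needed
tiny_spec <- function(...) {
  phantom_spec(shape = c(16, 16, 10), noise = "none", sigma = 0,
               between_subject_cv = 0, jitter_mm = 0, ...)
}

# run one subject through mask -> fit -> zones -> zone MPD (the path whose
# output the fine-mapping statistics consume)
zone_chain <- function(subject, b_max = 200) {
  anat <- subject$anatomy
  mask <- csf_mask(subject$free_water, anat)
  pd <- fit_pdiff_map(subject$series, mask, b_max = b_max)
  lat <- array(anat$data %in% c(4L, 43L), dim(anat$data))
  third <- array(anat$data == 14L, dim(anat$data))
  sd <- find_third_ventricle_start(lat, third)
  zg <- assign_zones(sd, lat, third, spacing = anat$spacing)
  zone_mpd(pd, zg)
}
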
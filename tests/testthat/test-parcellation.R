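test_that("nearest labeled voxel wins, with lowest-code tie-break", {
  d <- c(5, 3, 3)
  atlas <- array(0L, d)
  anat <- array(0L, d)
  atlas[1, 1, 1] <- 101L; atlas[5, 1, 1] <- 102L
  anat[atlas > 0] <- 3L
  fw <- array(0, d)
  csf_vox <- rbind(c(2, 1, 1), c(4, 1, 1), c(3, 1, 1))
  anat[csf_vox] <- 24L; fw[csf_vox] <- 1
  dict <- tibble::tibble(code = c(101L, 102L),
                         name = c("a_left", "b_left"),
                         side = "left", class = "sulcus",
                         region = c("a", "b"))
  sp <- c(1, 1, 1)
  m <- csf_mask(voxel_grid(fw, sp), voxel_grid(anat, sp))
  p <- propagate_labels(voxel_grid(atlas, sp), m, voxel_grid(anat, sp),
                        dictionary = dict)
  expect_equal(p$labels[2, 1, 1], 101L)   # strictly nearer to A
  expect_equal(p$labels[4, 1, 1], 102L)   # strictly nearer to B
  expect_equal(p$labels[3, 1, 1], 101L)   # equidistant: lowest code
})

test_that("anisotropic spacing is honoured: 3 in-plane steps beat 1 slice", {
  d <- c(8, 3, 4)
  atlas <- array(0L, d); anat <- array(0L, d); fw <- array(0, d)
  # candidate A: 3 steps along x (3 mm at 1 mm); candidate B: 1 slice (4 mm)
  atlas[1, 1, 2] <- 105L   # same slice, 3 in-plane steps from the query
  atlas[4, 1, 1] <- 101L   # adjacent slice, directly below the query
  anat[atlas > 0] <- 3L
  anat[4, 1, 2] <- 24L; fw[4, 1, 2] <- 1
  dict <- tibble::tibble(code = c(101L, 105L), name = c("b", "a"),
                         side = "midline", class = "cistern",
                         region = c("b", "a"))
  sp <- c(1, 1, 4)
  m <- csf_mask(voxel_grid(fw, sp), voxel_grid(anat, sp))
  p <- propagate_labels(voxel_grid(atlas, sp), m, voxel_grid(anat, sp),
                        dictionary = dict)
  expect_equal(p$labels[4, 1, 2], 105L)  # 3 mm in-plane beats 4 mm slice
})

test_that("propagation matches the brute-force all-pairs oracle on random volumes", {
  for (seed in 1:8) {
    ph <- random_label_phantom(seed)
    dict <- tibble::tibble(code = c(101:106, 14L),
                           name = c(paste0("r", 1:6), "third_ventricle"),
                           side = "midline",
                           class = c(rep("sulcus", 6), "ventricle"),
                           region = c(paste0("r", 1:6), "third_ventricle"))
    m <- csf_mask(ph$fw, ph$anat)
    p <- propagate_labels(ph$atlas, m, ph$anat, dictionary = dict)
    want <- oracle_nn_labels(ph$sas_idx, ph$atlas_idx,
                             as.integer(ph$atlas$data[ph$atlas_idx]),
                             ph$dims, ph$spacing)
    expect_identical(as.integer(p$labels[ph$sas_idx]), want)
    # ventricle voxels keep their anatomical labels
    vent <- which(ph$anat$data == 14L)
    expect_true(all(p$labels[vent] == 14L))
  }
})

test_that("relabeling atlas codes by a bijection relabels the output alike", {
  ph <- random_label_phantom(99)
  # make the phantom tie-free by keeping one voxel per code
  keep <- !duplicated(ph$atlas$data[ph$atlas_idx])
  atlas2 <- array(0L, ph$dims)
  atlas2[ph$atlas_idx[keep]] <- ph$atlas$data[ph$atlas_idx[keep]]
  anat <- ph$anat; anat$data[ph$atlas_idx[!keep]] <- 0L
  dict <- tibble::tibble(code = 101:106, name = paste0("r", 1:6),
                         side = "midline", class = "sulcus",
                         region = paste0("r", 1:6))
  m <- csf_mask(ph$fw, anat)
  p1 <- propagate_labels(voxel_grid(atlas2, ph$spacing), m, anat,
                         dictionary = dict)
  # bijection: 101..106 -> 206..201 (order reversed)
  remap <- setNames(206:201, 101:106)
  atlas3 <- atlas2
  atlas3[atlas3 > 0] <- remap[as.character(atlas3[atlas3 > 0])]
  dict3 <- dict; dict3$code <- unname(remap[as.character(dict$code)])
  p2 <- propagate_labels(voxel_grid(atlas3, ph$spacing), m, anat,
                         dictionary = dict3)
  got <- p2$labels[ph$sas_idx]
  want <- unname(remap[as.character(p1$labels[ph$sas_idx])])
  # equivariance is exact wherever the nearest atlas voxel is unique; find
  # those queries with a direct distance scan
  ai <- which(atlas2 > 0)
  qi <- arrayInd(ph$sas_idx, ph$dims)
  aj <- arrayInd(ai, ph$dims)
  unique_min <- vapply(seq_along(ph$sas_idx), function(k) {
    d2 <- colSums((t(aj) - qi[k, ])^2 * ph$spacing^2)
    sum(d2 == min(d2)) == 1L
  }, logical(1))
  expect_true(any(unique_min))
  expect_identical(got[unique_min], want[unique_min])
})

test_that("atlas outside the GM mask and empty atlases are rejected", {
  ph <- random_label_phantom(3)
  m <- csf_mask(ph$fw, ph$anat)
  bad_anat <- ph$anat
  bad_anat$data[ph$atlas_idx[1]] <- 0L
  expect_error(propagate_labels(ph$atlas, m, bad_anat), "outside the gray")
  empty <- voxel_grid(array(0L, ph$dims), ph$spacing)
  expect_error(propagate_labels(empty, m, ph$anat), "Empty gray-matter atlas")
})

test_that("bilateral merge sums counts and notes a missing side", {
  dict <- phantom_dictionary()
  labels <- array(0L, c(6, 6, 4))
  labels[1:10] <- 101L   # left central sulcus, 10 voxels
  labels[11:40] <- 102L  # right central sulcus, 30 voxels
  labels[41:45] <- 14L   # third ventricle (midline)
  labels[46:50] <- 105L  # left suprasellar only
  p <- structure(list(labels = labels, spacing = c(2, 2, 4),
                      dictionary = dict),
                 class = "csf_parcellation")
  p$counts <- cbss:::new_parcellation(labels, c(2, 2, 4), dict)$counts
  merged <- merge_bilateral(p)
  cs <- merged[merged$region == "central_sulcus", ]
  expect_equal(cs$n_voxels, 40L)
  expect_equal(cs$missing_side, "")
  expect_equal(merged$n_voxels[merged$region == "third_ventricle"], 5L)
  ss <- merged[merged$region == "suprasellar_cistern", ]
  expect_equal(ss$n_voxels, 5L)
  expect_equal(ss$missing_side, "right")
})

test_that("exclusion rule drops cohort-wide or marks per-subject missing", {
  mk <- function(frac_small) {
    tidyr::crossing(subject = 1:10, region = c("small", "big")) |>
      dplyr::mutate(n_voxels = ifelse(
        region == "small" & subject <= 10 * frac_small, 8L, 50L))
  }
  # 60% of subjects below 10 voxels: dropped everywhere
  r1 <- apply_exclusion_rule(mk(0.6))
  expect_true(r1$region_status$dropped[r1$region_status$region == "small"])
  # 30%: kept, those subjects marked missing
  r2 <- apply_exclusion_rule(mk(0.3))
  expect_false(r2$region_status$dropped[r2$region_status$region == "small"])
  miss <- r2$subject_missing
  expect_equal(sum(miss$missing[miss$region == "small"]), 3L)
  # all regions comfortable: nothing dropped, nothing missing
  r3 <- apply_exclusion_rule(mk(0))
  expect_false(any(r3$region_status$dropped))
  expect_false(any(r3$subject_missing$missing))
  # boundary: exactly 50% below threshold counts as cohort-wide
  r4 <- apply_exclusion_rule(mk(0.5))
  expect_true(r4$region_status$dropped[r4$region_status$region == "small"])
})
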
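test_that("the third-ventricle start is the dilated-lateral overlap", {
  d <- c(12, 6, 6)
  lateral <- array(FALSE, d); third <- array(FALSE, d)
  lateral[1:3, , ] <- TRUE
  third[5:12, , ] <- TRUE   # abutting face at x = 4/5 boundary, 1 gap voxel
  seed <- find_third_ventricle_start(lateral, third)
  # dilation by 3 reaches x = 4, 5, 6; overlap with third = x in 5:6
  expect_true(all(which(seed, arr.ind = TRUE)[, 1] %in% 5:6))
  expect_equal(sum(seed), 2 * 6 * 6)
  # face-to-face abutment: first 3 layers of the third mask
  third2 <- array(FALSE, d); third2[4:12, , ] <- TRUE
  seed2 <- find_third_ventricle_start(lateral, third2)
  expect_true(all(which(seed2, arr.ind = TRUE)[, 1] %in% 4:6))
  # separated by more than 3 voxels: error
  far <- array(FALSE, d); far[8:12, , ] <- TRUE
  expect_error(find_third_ventricle_start(lateral, far), "No overlap")
  expect_error(find_third_ventricle_start(lateral, lateral), "disjoint")
})

test_that("dilation matches a brute-force 6-connected oracle on the phantom", {
  for (seed in c(2, 9)) {
    spec <- phantom_spec(shape = c(16, 16, 10), seed = seed)
    s <- generate_subject(spec, 1)
    lat <- array(s$anatomy$data %in% c(4L, 43L), dim(s$anatomy$data))
    third <- s$anatomy$data == 14L
    got <- find_third_ventricle_start(lat, third)
    want <- oracle_dilate_face(lat, 3L) & third
    expect_identical(got, want)
  }
})

test_that("zones bin distance half-open with per-ventricle numbering", {
  d <- c(30, 3, 3)
  lateral <- array(FALSE, d); third <- array(FALSE, d)
  seed <- array(FALSE, d); seed[1, 1, 1] <- TRUE
  sp <- c(1, 1, 1)
  # voxels at x offsets 0..29 from the seed, 1 mm spacing
  third[1:8, 1, 1] <- TRUE
  lateral[10:30, 2, 1] <- TRUE
  zg <- assign_zones(seed, lateral, third, spacing = sp)
  zt <- zg$table
  code_of <- function(v, z) zt$code[zt$ventricle == v & zt$zone == z]
  # third-ventricle voxel 3 mm away: zone 1
  expect_equal(zg$zones[4, 1, 1], code_of("third", 1))
  # exactly 5.0 mm: second bin (half-open edges)
  expect_equal(zg$zones[6, 1, 1], code_of("third", 2))
  # lateral voxel ~17 mm away: zone 1 (the 15-20 mm shell)
  d17 <- sqrt(16^2 + 1)  # x offset 16, y offset 1 -> 16.03 mm
  expect_true(d17 >= 15 && d17 < 20)
  expect_equal(zg$zones[17, 2, 1], code_of("lateral", 1))
  # ~22 mm away: no zone
  expect_equal(zg$zones[23, 2, 1], 0L)
  # zones partition the <= 20 mm shell per ventricle
  dmm <- sqrt((seq_len(30) - 1)^2 + 1)
  inside <- which(lateral, arr.ind = TRUE)
  lab <- zg$zones[lateral]
  expect_true(all((lab > 0) == (sqrt((inside[, 1] - 1)^2 + 1) < 20)))
})

test_that("enlarging the seed never increases any voxel's distance", {
  spec <- phantom_spec(shape = c(16, 16, 10), seed = 4)
  s <- generate_subject(spec, 1)
  lat <- array(s$anatomy$data %in% c(4L, 43L), dim(s$anatomy$data))
  third <- s$anatomy$data == 14L
  seed1 <- find_third_ventricle_start(lat, third)
  seed2 <- cbss:::dilate_mask(seed1, 1L) & (third | lat)
  dims <- dim(seed1)
  idx <- which(third & !seed2)
  d1 <- cbss:::min_dist_mm(idx, which(seed1), dims, s$anatomy$spacing)
  d2 <- cbss:::min_dist_mm(idx, which(seed2), dims, s$anatomy$spacing)
  expect_true(all(d2 <= d1 + 1e-12))
})

test_that("zone MPD summarises medians per zone with missing handling", {
  d <- c(30, 3, 3)
  lateral <- array(FALSE, d); third <- array(FALSE, d)
  seed <- array(FALSE, d); seed[1, 1, 1] <- TRUE
  third[1:7, 1, 1] <- TRUE
  zg <- assign_zones(seed, lateral, third, spacing = c(1, 1, 1))
  dstar <- array(NA_real_, d)
  dstar[1:7, 1, 1] <- 2e-3
  dstar[6, 1, 1] <- 4e-3   # second bin holds {2, 4} x 10-3 -> 3e-3
  pd <- structure(list(d_star = dstar, spacing = c(1, 1, 1)),
                  class = "pdiff_map")
  zt <- zone_mpd(pd, zg)
  expect_equal(zt$mpd[zt$ventricle == "third" & zt$zone == 1], 2e-3)
  expect_equal(zt$mpd[zt$ventricle == "third" & zt$zone == 2], 3e-3)
  expect_true(all(zt$missing[zt$ventricle == "lateral"]))
})

test_that("planted zone-1 elevation appears in the fitted zone ordering", {
  eff <- tibble::tibble(region = "third_ventricle_zone1",
                        covariate = "STM", slope = 0.9)
  spec <- phantom_spec(n_subjects = 4, effects = eff, noise = "none",
                       sigma = 0, seed = 8)
  zs <- purrr::map_dfr(1:4, function(i) {
    s <- generate_subject(spec, i)
    z <- zone_chain(s)
    z$subject <- i
    z$truth_zone1 <- s$truth$zone_d[["third_ventricle_zone1"]]
    z
  })
  z1 <- zs[zs$ventricle == "third" & zs$zone == 1, ]
  expect_equal(order(z1$mpd), order(z1$truth_zone1))
})
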
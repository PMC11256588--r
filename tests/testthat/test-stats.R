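test_that("ACAT reduces to identity, fixes 0.5, and is permutation-invariant", {
  expect_equal(acat(0.2), 0.2, tolerance = 1e-14)
  expect_equal(acat(rep(0.5, 7)), 0.5, tolerance = 1e-14)
  p <- c(0.03, 0.2, 0.77, 0.41)
  expect_equal(acat(p), acat(rev(p)), tolerance = 1e-15)
  tiny <- suppressWarnings(acat(c(1e-20, 0.5)))
  expect_true(tiny > 0 && tiny < 1)
  expect_warning(acat(c(0, 0.5)), "clamped")
  expect_error(acat(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("voxel-subsampling CoV is zero for constant regions and seeded", {
  expect_equal(voxel_bootstrap_cov(rep(2e-3, 50), seed = 3)$cov, 0)
  v <- rnorm(100, 3e-3, 3e-4)
  a <- voxel_bootstrap_cov(v, seed = 9)
  b <- voxel_bootstrap_cov(v, seed = 9)
  expect_identical(a$cov, b$cov)
  expect_false(identical(a$cov, voxel_bootstrap_cov(v, seed = 10)$cov))
})

test_that("CoV from a two-point region matches a high-rep independent oracle", {
  # region of 100 voxels: 50 at 2e-3, 50 at 4e-3
  v <- rep(c(2e-3, 4e-3), each = 50)
  got <- voxel_bootstrap_cov(v, reps = 100, seed = 1)$cov
  # independent re-implementation, 1e4 replicates
  set.seed(77)
  m <- floor(0.95 * length(v))
  reps <- replicate(1e4, median(v[sample.int(length(v), m)]))
  oracle <- sd(reps) / mean(reps)
  se <- oracle / sqrt(2 * (100 - 1))  # approx SE of a CoV at 100 reps
  expect_lt(abs(got - oracle), 4 * se + 0.02 * oracle)
})

test_that("inter-regional correlation handles identity, nulls, and BH family", {
  set.seed(5)
  x <- rnorm(40)
  frame <- tibble::tibble(mpd_a = x, mpd_b = x, mpd_c = rnorm(40))
  cc <- interregional_correlation(frame)
  ab <- cc$pairs[cc$pairs$region1 == "mpd_a" & cc$pairs$region2 == "mpd_b", ]
  expect_equal(ab$r, 1, tolerance = 1e-12)
  expect_lt(ab$p, 1e-12)
  # BH is the step-up over the unique pairs as one family
  manual <- p.adjust(cc$pairs$p, method = "BH")
  expect_equal(cc$pairs$p_adj, manual)
  # constant column: undefined pairs
  frame$mpd_d <- 1
  cc2 <- interregional_correlation(frame)
  expect_true(all(is.na(
    cc2$pairs$r[cc2$pairs$region1 == "mpd_d" | cc2$pairs$region2 == "mpd_d"])))
  # tidy/glance accessors
  expect_identical(tidy(cc), cc$pairs)
  expect_equal(glance(cc)$n_pairs, 3)
})

test_that("null correlations reject at the nominal rate", {
  set.seed(31)
  hits <- 0L
  nsim <- 1000
  for (i in seq_len(nsim)) {
    p <- cor.test(rnorm(93), rnorm(93))$p.value
    hits <- hits + (p < 0.05)
  }
  rate <- hits / nsim
  se2 <- 2 * sqrt(0.05 * 0.95 / nsim)
  expect_lt(abs(rate - 0.05), se2)
})

test_that("cohort bootstrap averages r and combines p-values by ACAT", {
  set.seed(12)
  n <- 60
  x <- rnorm(n)
  frame <- tibble::tibble(mpd_a = x, mpd_b = 0.7 * x + rnorm(n, 0, 0.6),
                          mpd_c = rnorm(n))
  cb <- cohort_bootstrap_acat(frame, reps = 10, seed = 4)
  expect_equal(nrow(cb$pairs), 3)
  expect_true(all(cb$pairs$p > 0 & cb$pairs$p < 1))
  # determinism under the seed
  cb2 <- cohort_bootstrap_acat(frame, reps = 10, seed = 4)
  expect_identical(cb$pairs, cb2$pairs)
  # the strongly coupled pair combines to a smaller p than the null pair
  p_ab <- cb$pairs$p[cb$pairs$region1 == "mpd_a" & cb$pairs$region2 == "mpd_b"]
  p_ac <- cb$pairs$p[cb$pairs$region1 == "mpd_a" & cb$pairs$region2 == "mpd_c"]
  expect_lt(p_ab, p_ac)
})

test_that("adjusted association recovers a planted standardized slope", {
  set.seed(42)
  slopes <- replicate(200, {
    x <- rnorm(500)
    y <- 0.4 * x + rnorm(500, 0, sqrt(0.84))
    frame <- tibble::tibble(mpd_r = x, STM = y)
    adjusted_association(frame, "mpd_r", "STM",
                         covariates = character(0))$results$slope
  })
  expect_lt(abs(mean(slopes) - 0.4), 0.05)
})

test_that("association degenerate cases behave as contracted", {
  set.seed(2)
  frame <- tibble::tibble(mpd_r = rnorm(50), age = rnorm(50, 70, 8),
                          sex = rbinom(50, 1, 0.5),
                          education = rnorm(50, 12, 3))
  frame$STM <- frame$mpd_r
  out <- suppressWarnings(
    adjusted_association(frame, "mpd_r", "STM", covariates = character(0)))
  expect_equal(out$results$slope, 1, tolerance = 1e-12)
  expect_lt(out$results$p, 1e-12)
  # standardized simple regression slope equals Pearson r
  frame$LTM <- 0.3 * frame$mpd_r + rnorm(50)
  o2 <- adjusted_association(frame, "mpd_r", "LTM",
                             covariates = character(0))
  expect_equal(o2$results$slope, o2$results$r, tolerance = 1e-12)
  # a covariate identical to the predictor is collinear, named in the error
  frame$dup <- frame$mpd_r
  expect_error(adjusted_association(frame, "mpd_r", "LTM",
                                    covariates = "dup"),
               "Collinear.*dup")
  expect_error(adjusted_association(frame[1:4, ], "mpd_r", "LTM"),
               "too few")
})

test_that("z-transformed columns have mean 0 and unit sd over non-missing", {
  x <- c(rnorm(30), NA, NA)
  z <- z_transform(x)
  expect_equal(mean(z, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_equal(sd(z, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_error(z_transform(rep(3, 5)), "constant")
})

test_that("sex difference uses the exact rank-sum null for small groups", {
  frame <- tibble::tibble(mpd_r = c(1, 2, 3, 4, 5, 6),
                          sex = c(0, 0, 0, 1, 1, 1))
  out <- sex_difference(frame, "mpd_r")
  # exhaustive enumeration over C(6,3) = 20 assignments
  sums <- combn(6, 3, sum)
  obs <- sum(1:3)
  extreme <- mean(abs(sums - mean(sums)) >= abs(obs - mean(sums)))
  expect_equal(out$p, extreme)   # = 0.1
  expect_equal(out$p, 0.1)
  # label permutation leaves p unchanged
  frame2 <- frame[c(4, 5, 6, 1, 2, 3), ]
  frame2$sex <- c(0, 0, 0, 1, 1, 1)
  expect_equal(sex_difference(frame2, "mpd_r")$p, out$p)
  # identical groups: statistic at the null center
  frame3 <- tibble::tibble(mpd_r = rep(c(1, 2, 3), 2),
                           sex = rep(c(0, 1), each = 3))
  expect_gt(sex_difference(frame3, "mpd_r")$p, 0.99)
  expect_error(sex_difference(tibble::tibble(mpd_r = 1:3, sex = 0), "mpd_r"),
               "Both sexes")
})

test_that("per-subject MPD-CBF profile correlation hits the exact poles", {
  frame <- tibble::tibble(
    subject = 1:2, age = c(60, 80),
    mpd_a = c(1, 3), mpd_b = c(2, 2), mpd_c = c(3, 1),
    cbf_a = c(2, 10), cbf_b = c(4, 20), cbf_c = c(6, 30))
  out <- mpd_cbf_profile_correlation(frame, c("a", "b", "c"))
  expect_equal(out$subject_r$r, c(1, -1), tolerance = 1e-12)
  expect_null(out$age_association)   # two subjects cannot support the fit
  frame3 <- frame; frame3$cbf_c <- NA
  out3 <- mpd_cbf_profile_correlation(frame3, c("a", "b", "c"))
  expect_true(all(is.na(out3$subject_r$r)))   # < 3 complete regions
})

test_that("planted age-increasing MPD-CBF coupling is recovered from the phantom", {
  spec <- phantom_spec(n_subjects = 40, seed = 14,
                       cbf_coupling = list(base = 0.3, age_slope = 0.5))
  cov <- cohort_covariates(spec)
  rows <- purrr::map_dfr(seq_len(40), function(i) {
    s <- generate_subject(spec, i)
    mpd <- s$truth$region_d[names(s$truth$regional_cbf)]
    tibble::tibble(subject = i, r = cor(mpd, s$truth$regional_cbf))
  })
  rows$age <- cov$age
  assoc <- adjusted_association(rows, "r", "age", covariates = character(0))
  expect_gt(assoc$results$slope, 0)
  expect_lt(assoc$results$p, 0.05)
})
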
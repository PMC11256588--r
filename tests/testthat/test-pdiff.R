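test_that("log-linear fit recovers exact exponentials and degenerate cases", {
  sch <- acquisition_scheme()
  b <- sch$b
  for (dtrue in c(0.5e-3, 1e-3, 3e-3, 10e-3)) {
    f <- fit_voxel_pdiff(1000 * exp(-b * dtrue), b)
    expect_equal(f$d_star, dtrue, tolerance = 1e-9)
    expect_equal(f$s0, 1000, tolerance = 1e-6)
  }
  # constant signal: zero pseudodiffusivity
  expect_equal(fit_voxel_pdiff(rep(500, length(b)), b)$d_star, 0)
  # non-positive signals dropped pointwise; too few distinct b -> missing
  y <- 1000 * exp(-b * 3e-3)
  y[b > 0] <- -1
  f <- fit_voxel_pdiff(y, b)
  expect_true(f$missing)
  expect_equal(f$n_dropped, sum(b > 0 & b <= 200))
})

test_that("fit is invariant under signal scaling and uses only b <= cutoff", {
  sch <- acquisition_scheme()
  b <- sch$b
  y <- 800 * exp(-b * 2e-3)
  f1 <- fit_voxel_pdiff(y, b)
  f2 <- fit_voxel_pdiff(5 * y, b)
  expect_equal(f1$d_star, f2$d_star, tolerance = 1e-12)
  # a curved (bi-exponential) signal changes fit when cutoff changes,
  # but an exact mono-exponential does not
  f3 <- fit_voxel_pdiff(y, b, b_max = 150)
  expect_equal(f1$d_star, f3$d_star, tolerance = 1e-12)
  expect_equal(f1$n_points, sum(b <= 200))
  expect_equal(f3$n_points, sum(b <= 150))
})

test_that("under Rician noise the log-linear median tracks a nonlinear oracle", {
  skip_if_not_installed("minpack.lm")
  set.seed(11)
  sch <- acquisition_scheme()
  b <- sch$b[sch$b <= 200]
  s0 <- 1000; dtrue <- 3e-3; sig <- 0.02 * s0
  n <- 400
  ll <- nl <- numeric(n)
  for (i in seq_len(n)) {
    clean <- s0 * exp(-b * dtrue)
    y <- sqrt((clean + rnorm(length(b), 0, sig))^2 +
                rnorm(length(b), 0, sig)^2)
    ll[i] <- fit_voxel_pdiff(y, b)$d_star
    fit <- minpack.lm::nlsLM(y ~ a * exp(-b * D),
                             start = list(a = s0, D = 2e-3))
    nl[i] <- coef(fit)[["D"]]
  }
  expect_lt(abs(median(ll) - median(nl)) / median(nl), 0.02)
})

test_that("region MPD is a median with volume-weighted bilateral averaging", {
  dict <- phantom_dictionary()
  d <- c(8, 8, 4)
  labels <- array(0L, d)
  dstar <- array(NA_real_, d)
  # midline region: median robust to an outlier
  labels[1:3] <- 14L
  dstar[1:3] <- c(1e-3, 2e-3, 100e-3)
  # paired region: left median 2e-3 (10 voxels), right 4e-3 (30 voxels)
  labels[11:20] <- 101L; dstar[11:20] <- 2e-3
  labels[21:50] <- 102L; dstar[21:50] <- 4e-3
  parc <- cbss:::new_parcellation(labels, c(2, 2, 4), dict)
  pd <- structure(list(d_star = dstar, spacing = c(2, 2, 4)),
                  class = "pdiff_map")
  rt <- region_mpd(pd, parc)
  expect_equal(rt$mpd[rt$region == "third_ventricle"], 2e-3)
  expect_equal(rt$mpd[rt$region == "central_sulcus"],
               (2e-3 * 10 + 4e-3 * 30) / 40)
  expect_true(rt$missing[rt$region == "fourth_ventricle"])
  # MPD lies within the voxel range and ignores voxel order
  perm <- sample(seq_along(dstar))
  dstar2 <- array(dstar[perm], d); labels2 <- array(labels[perm], d)
  rt2 <- region_mpd(structure(list(d_star = dstar2, spacing = c(2, 2, 4)),
                              class = "pdiff_map"),
                    cbss:::new_parcellation(labels2, c(2, 2, 4), dict))
  expect_equal(rt2$mpd, rt$mpd)
})

test_that("map fitting recovers the generator's planted D* end to end", {
  spec <- tiny_spec()
  s <- generate_subject(spec, 1)
  mask <- csf_mask(s$free_water, s$anatomy)
  pd <- fit_pdiff_map(s$series, mask)
  parc <- propagate_labels(s$atlas, mask, s$anatomy)
  rt <- region_mpd(pd, parc)
  truth <- s$truth$region_d
  for (rg in rt$region[!rt$missing]) {
    expect_lt(abs(rt$mpd[rt$region == rg] - truth[[rg]]) / truth[[rg]],
              1e-9)
  }
})

test_that("regional estimate variability shrinks as voxel count grows", {
  set.seed(21)
  sch <- acquisition_scheme()
  b <- sch$b[sch$b <= 200]
  s0 <- 1000; dtrue <- 3e-3; sig <- 0.02 * s0
  clean <- s0 * exp(-b * dtrue)
  bc <- b - mean(b)
  one_median <- function(n) {
    y <- sqrt((matrix(rnorm(n * length(b), 0, sig), n) +
                 rep(clean, each = n))^2 +
                matrix(rnorm(n * length(b), 0, sig), n)^2)
    median(-(log(y) %*% bc) / sum(bc^2))
  }
  sds <- vapply(c(10, 100, 1000), function(n) {
    sd(vapply(1:30, function(r) one_median(n), numeric(1)))
  }, numeric(1))
  expect_true(sds[1] > sds[2] && sds[2] > sds[3])
})

test_that("scalar medians and intraparenchymal volume follow conventions", {
  d <- c(8, 8, 4)
  lab <- array(0L, d); lab[1:2] <- 3L
  sc <- array(0, d); sc[1:2] <- c(40, 60)
  out <- regional_scalar_median(voxel_grid(sc, c(2, 2, 4)),
                                voxel_grid(lab, c(2, 2, 4)))
  expect_equal(out$median[out$code == 3], 50)   # mean of middle two
  out2 <- regional_scalar_median(voxel_grid(sc, c(2, 2, 4)),
                                 voxel_grid(lab, c(2, 2, 4)),
                                 codes = c(3L, 42L))
  expect_true(is.na(out2$median[out2$code == 42]))
  seg <- array(0L, d); seg[1:100] <- 2L
  ipv <- intraparenchymal_volume(voxel_grid(seg, c(2, 2, 4)))
  expect_equal(ipv$volume_mm3, 1600)
  expect_equal(intraparenchymal_volume(voxel_grid(seg, c(2, 2, 4)),
                                       icv = 2000)$fraction, 0.8)
  none <- array(0L, d)
  expect_equal(intraparenchymal_volume(voxel_grid(none, c(2, 2, 4)))$volume_mm3, 0)
  expect_error(intraparenchymal_volume(voxel_grid(seg, c(2, 2, 4)), icv = 0),
               "positive")
})
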
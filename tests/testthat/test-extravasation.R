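test_that("distance map is exact Euclidean in microns", {
  full <- matrix(TRUE, 6, 6)
  expect_true(all(distance_map(full, 1)$values == 0))
  expect_error(distance_map(matrix(FALSE, 4, 4), 1), "empty")

  one <- matrix(FALSE, 16, 16)
  one[5, 5] <- TRUE
  dm <- distance_map(one, 1)
  expect_equal(dm$values[8, 9], 5)  # 3-4-5 triangle
  expect_equal(dm$values[5, 5], 0)

  set.seed(13)
  m <- matrix(runif(32 * 32) < 0.08, 32, 32)
  if (!any(m)) m[3, 3] <- TRUE
  dm <- distance_map(m, 0.5)
  expect_equal(dm$values, oracle_distmap(m, 0.5), tolerance = 1e-12)
  expect_true(all((dm$values == 0) == m))
})

test_that("distance map is 1-Lipschitz across neighboring pixels", {
  set.seed(14)
  m <- matrix(runif(48 * 48) < 0.03, 48, 48)
  if (!any(m)) m[10, 10] <- TRUE
  ps <- 0.8
  v <- distance_map(m, ps)$values
  lim <- ps * sqrt(2) + 1e-9
  expect_true(all(abs(diff(v)) <= lim))          # vertical neighbors
  expect_true(all(abs(diff(t(v))) <= lim))       # horizontal neighbors
})

test_that("the red noise mask keeps signal and drops the noise floor", {
  # lumens at 100 over exact zero background
  red <- matrix(0, 20, 20)
  red[8:12, 8:12] <- 100
  expect_identical(antibody_noise_mask(red), red > 0)

  # low-amplitude noise floor << signal: masked integral ~ noiseless integral
  set.seed(15)
  noisy <- red + matrix(abs(rnorm(400, 0, 1)), 20, 20)
  mask <- antibody_noise_mask(noisy)
  expect_equal(sum(noisy[mask]), sum(red), tolerance = 0.02)

  # all-signal image: Otsu splits the jitter, at least half the pixels remain
  set.seed(16)
  flat <- matrix(1000 + rnorm(400, 0, 0.5), 20, 20)
  expect_gte(sum(antibody_noise_mask(flat)), 200)
})

test_that("purely intravascular signal gives a flat negative profile", {
  inside <- matrix(FALSE, 24, 24)
  inside[11:14, 11:14] <- TRUE
  labels <- matrix(1L, 24, 24)
  dist <- distance_map(inside, 1)
  red <- matrix(0, 24, 24)
  red[12:13, 12:13] <- 50
  noise <- red > 0
  p <- delta_ab_profile(1L, labels, inside, dist, red, noise, 1)
  expect_true(all(p$delta_ab == -200))
  expect_equal(p$delta_ab_max, -200)
  expect_false(p$extravasated)
  expect_equal(p$extravasation_range_um, 0)
})

test_that("a single extravascular hot pixel sets the range and maximum", {
  inside <- matrix(FALSE, 64, 64)
  inside[32, 16] <- TRUE
  labels <- matrix(1L, 64, 64)
  dist <- distance_map(inside, 1)
  red <- matrix(0, 64, 64)
  red[32, 46] <- 7.5   # exactly 30 um from the inside pixel
  noise <- red > 0
  p <- delta_ab_profile(1L, labels, inside, dist, red, noise, 1)
  expect_equal(p$delta_ab_max, 7.5)
  expect_equal(p$extravasation_range_um, 30)
  expect_true(p$extravasated)
  expect_true(all(p$delta_ab[p$distances_um < 30] == 0))
  expect_true(all(p$delta_ab[p$distances_um >= 30] == 7.5))
  expect_error(delta_ab_profile(9L, labels, inside, dist, red, noise, 1),
               "empty|undefined")
})

test_that("profiles match the brute-force integration oracle on leaky fields", {
  cfg <- small_config(seed = 21, n_vessels = 2, lambda = 15, sigma = 0,
                      leaky_fraction = 1, min_separation_um = 24)
  f <- generate_field(cfg)
  seg <- segment_vessels(f$blue)
  noise <- antibody_noise_mask(f$red)
  dist <- distance_map(seg$inside_mask, 1)
  for (k in seq_len(seg$n_vessels)) {
    got <- delta_ab_profile(k, seg$labels, seg$inside_mask, dist,
                            f$red, noise, 1)
    ref <- oracle_delta_ab(k, seg$labels, seg$inside_mask, dist$values,
                           f$red$values, noise, 1)
    expect_equal(got$delta_ab, ref$delta_ab, tolerance = 1e-12)
    expect_equal(got$delta_ab_max, ref$delta_ab_max, tolerance = 1e-12)
    expect_equal(got$extravasation_range_um, ref$extravasation_range_um)
    expect_equal(got$extravasated, ref$extravasated)
  }
})

test_that("estimated range grows with the simulated decay length", {
  med <- vapply(c(5, 15, 45), function(lam) {
    f <- generate_field(small_config(seed = 31, n_vessels = 1, lambda = lam,
                                     sigma = 0, size = 64L))
    seg <- segment_vessels(f$blue)
    tab <- profiles_table(profile_all(seg, f$red))
    median(tab$extravasation_range_um)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("profiles are monotone, conserve the masked integral and ignore label ids", {
  cfg <- small_config(seed = 22, n_vessels = 2, lambda = 10, sigma = 2,
                      leaky_fraction = 0.5, min_separation_um = 24)
  f <- generate_field(cfg)
  seg <- segment_vessels(f$blue)
  noise <- antibody_noise_mask(f$red)
  profs <- profile_all(seg, f$red, noise_mask = noise)
  expect_length(profs, seg$n_vessels)

  total <- 0
  for (p in profs) {
    expect_true(all(diff(p$delta_ab) >= -1e-12))
    expect_equal(p$delta_ab_max, p$delta_ab[length(p$delta_ab)])
    expect_equal(p$delta_ab_max, max(p$delta_ab))
    i_in <- -p$delta_ab[1]
    total <- total + i_in + (p$delta_ab_max + i_in)
  }
  expect_equal(total, sum(f$red$values[noise]), tolerance = 1e-9)

  # permuting label ids permutes profiles without changing any value
  perm <- rev(seq_len(seg$n_vessels))
  relab <- matrix(perm[seg$labels], nrow(seg$labels), ncol(seg$labels))
  dist <- distance_map(seg$inside_mask, 1)
  for (k in seq_len(seg$n_vessels)) {
    p1 <- profs[[k]]
    p2 <- delta_ab_profile(perm[k], relab, seg$inside_mask, dist, f$red,
                           noise, 1)
    expect_equal(p1$delta_ab, p2$delta_ab)
    expect_equal(p1$extravasation_range_um, p2$extravasation_range_um)
  }
})
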
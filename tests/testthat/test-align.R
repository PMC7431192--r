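# Superposition primitive, TM-score, and the fragment-seeded aligner.

test_that("kabsch recovers exact rigid transforms and the identity", {
  set.seed(11)
  P <- matrix(rnorm(30, sd = 5), 10, 3)
  R <- random_rotation()
  t <- c(3, -2, 7)
  Q <- P %*% t(R) + matrix(t, 10, 3, byrow = TRUE)
  fit <- kabsch_superpose(P, Q)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, R, tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(fit$translation, t, tolerance = 1e-9)
  self <- kabsch_superpose(P, P)
  expect_equal(self$rotation, diag(3), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(self$translation, c(0, 0, 0), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
})

test_that("kabsch rmsd matches a rotation-search oracle on random clouds", {
  for (s in 1:3) {
    set.seed(100 + s)
    P <- matrix(rnorm(30, sd = 4), 10, 3)
    Q <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_superpose_rmsd(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("d0 formula applies the 0.5 A floor for short references", {
  expect_equal(tm_d0(15), 0.5)
  expect_equal(tm_d0(5), 0.5)
  expect_equal(tm_d0(100), 1.24 * (100 - 15)^(1 / 3) - 1.8)
  expect_gt(tm_d0(400), tm_d0(100))
})

test_that("tm_score is 1 for identical structures under full mapping", {
  x <- ca_coords(make_random_fold(60, seed = 21))
  mp <- cbind(1:60, 1:60)
  expect_true(tm_score(mp, x, x) == 1)
  expect_error(tm_score(cbind(c(1, 3, 2), c(1, 2, 3)), x, x),
               "strictly increasing")
})

test_that("self-alignment and rigid invariance are exact", {
  m <- make_random_fold(90, seed = 31)
  al <- fragment_align(m, m)
  expect_true(al$tm_score == 1)
  expect_identical(al$mapping[, 1], al$mapping[, 2])
  expect_equal(al$n_aligned, 90)
  for (s in 1:3) {
    mt <- perturb_copy(m, noise_sd = 0, seed = 40 + s)
    expect_lt(abs(fragment_align(m, mt)$tm_score - 1), 1e-6)
  }
})

test_that("aligner matches the exhaustive-seed DP oracle on small toys", {
  for (s in 1:3) {
    a <- make_random_fold(28, seed = 300 + s)
    b <- perturb_copy(make_random_fold(30, seed = 400 + s), noise_sd = 0,
                      seed = s)
    xa <- ca_coords(a); xb <- ca_coords(b)
    orc <- oracle_fragment_align(xa, xb, F = 4)
    impl <- fragment_align(a, b, fragment_len = 4, stride = 1, top_k = 10000)
    expect_equal(impl$tm_score, orc$tm, tolerance = 1e-6)
    expect_equal(unname(impl$mapping), unname(orc$mapping),
                 ignore_attr = TRUE)
  }
})

test_that("bidirectional scores follow the stationary-length normalization", {
  short <- make_random_fold(70, seed = 51)
  # longer structure containing the short one plus extra residues
  extra <- make_random_fold(30, seed = 52)
  ex <- atom_coords(extra)
  ex <- sweep(ex, 2, colMeans(ex))
  ex <- sweep(ex, 2, -(colMeans(atom_coords(short)) + c(40, 0, 0)))
  long_xyz <- rbind(atom_coords(short), ex)
  long <- ca_model(long_xyz, id = "long")
  both <- align_pair_bidirectional(short, long)
  expect_equal(both$ab$mobile_id, "rf0051")
  # same pair, smaller normalization length wins
  expect_lt(both$ab$tm_score, both$ba$tm_score)
  same <- align_pair_bidirectional(short, perturb_copy(short, seed = 5))
  expect_true(same$ab$tm_score == 1 && same$ba$tm_score == 1)
})

test_that("expected TM-score decreases with coordinate noise", {
  m <- make_random_fold(80, seed = 61)
  mean_tm <- vapply(c(0.2, 0.8, 1.6), function(sd) {
    mean(vapply(1:4, function(s)
      fragment_align(m, perturb_copy(m, noise_sd = sd, seed = 70 + s))$tm_score,
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_tm) < 0))
  expect_gt(mean_tm[1], 0.9)
})

test_that("degenerate inputs raise informative errors", {
  a <- ca_model(cbind(c(1, 2), 0, 0))
  b <- ca_model(cbind(1:10 * 2, 0, 0))
  expect_error(fragment_align(a, b), "at least 3")
  m <- make_random_fold(20, seed = 71)
  m$atoms$elety[5] <- "CB"   # residue 5 loses its CA
  expect_error(fragment_align(m, b), "A:5:")
})
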
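# HOLE-style profiling, tangency-based lining assignment, windows, labels.

cyl_fixture <- function() {
  make_tetramer_pore(pore_spec(data.frame(z = c(-5, 5), wall_radius = 6),
                               atom_vdw = 1.85))
}

hourglass_fixture <- function() {
  make_tetramer_pore(pore_spec(data.frame(z = c(-6, 0, 6),
                                          wall_radius = c(6, 3, 6)),
                               atom_vdw = 1.85))
}

test_that("cylinder fixture recovers the closed-form radius everywhere", {
  p <- pore_profile(cyl_fixture(), axis = c(0, 0, 1), start = c(0, 0, 0),
                    step = 0.5, vdw_set = c(C = 1.85))
  s <- p$samples[p$samples$z >= -4.5 & p$samples$z <= 4.5, ]
  expect_gt(nrow(s), 10)
  expect_true(all(abs(s$radius - 4.15) <= 0.05))
  expect_true(all(diff(p$samples$z) > 0))
})

test_that("hourglass constriction matches the dense-grid oracle", {
  hg <- hourglass_fixture()
  p <- pore_profile(hg, axis = c(0, 0, 1), start = c(0, 0, -4), step = 0.25,
                    vdw_set = c(C = 1.85))
  got <- min(p$samples$radius)
  oracle <- oracle_plane_radius(hg, z0 = 0, spacing = 0.02, vdw = 1.85)
  expect_equal(got, oracle, tolerance = 0.05)
  expect_equal(got, 3 - 1.85, tolerance = 0.05)   # analytic minimum
  expect_equal(p$samples$z[which.min(p$samples$radius)], 0, tolerance = 0.26)
})

test_that("cylinder wall residues all line the pore with equal minima", {
  m <- cyl_fixture()
  p <- pore_profile(m, axis = c(0, 0, 1), start = c(0, 0, 0), step = 0.25,
                    vdw_set = c(C = 1.85))
  lin <- lining_residues(m, p, vdw_set = c(C = 1.85))
  rt <- residue_table(m)
  expect_setequal(names(lin$min_radius), rt$key)
  expect_true(all(abs(lin$min_radius - 4.15) <= 0.06))
})

test_that("a residue retracted behind the wall stops lining", {
  m <- cyl_fixture()
  a <- m$atoms
  key <- residue_key(a$chain, a$resno, a$insert)
  victim <- rt_key <- residue_table(m)$key[10]
  idx <- key == victim
  # push the whole residue 1 A radially outward
  r <- sqrt(a$x[idx]^2 + a$y[idx]^2)
  m$atoms$x[idx] <- a$x[idx] * (r + 1) / r
  m$atoms$y[idx] <- a$y[idx] * (r + 1) / r
  p <- pore_profile(m, axis = c(0, 0, 1), start = c(0, 0, 0), step = 0.25,
                    vdw_set = c(C = 1.85))
  lin <- lining_residues(m, p, vdw_set = c(C = 1.85))
  expect_false(victim %in% names(lin$min_radius))
})

test_that("hourglass constriction residues carry the global minimum", {
  hg <- hourglass_fixture()
  p <- pore_profile(hg, axis = c(0, 0, 1), start = c(0, 0, -4), step = 0.25,
                    vdw_set = c(C = 1.85))
  lin <- lining_residues(hg, p, vdw_set = c(C = 1.85))
  gmin <- min(p$samples$radius)
  expect_true(all(lin$min_radius >= gmin - 1e-9))
  # the ring at z = 0 is the constriction
  mid <- unique(hg$atoms$resno[abs(hg$atoms$z) < 1e-6])
  mid_keys <- grep(paste0(":", mid, ":"), names(lin$min_radius), value = TRUE)
  expect_true(length(mid_keys) >= 1)
  expect_equal(min(lin$min_radius[mid_keys]), gmin, tolerance = 1e-9)
})

test_that("profiles are invariant under rigid motion", {
  hg <- hourglass_fixture()
  p1 <- pore_profile(hg, axis = c(0, 0, 1), start = c(0, 0, -4), step = 0.5,
                     vdw_set = c(C = 1.85))
  set.seed(17)
  R <- random_rotation(); t <- c(5, -8, 2)
  hg2 <- transform_model(hg, R, t)
  p2 <- pore_profile(hg2, axis = as.numeric(R %*% c(0, 0, 1)),
                     start = as.numeric(R %*% c(0, 0, -4) + t), step = 0.5,
                     vdw_set = c(C = 1.85))
  expect_equal(nrow(p1$samples), nrow(p2$samples))
  expect_equal(p2$samples$radius, p1$samples$radius, tolerance = 0.02)
})

test_that("window minima and conduction labels behave at their boundaries", {
  hg <- hourglass_fixture()
  p <- pore_profile(hg, axis = c(0, 0, 1), start = c(0, 0, -4), step = 0.25,
                    vdw_set = c(C = 1.85))
  expect_equal(window_min_radius(p), min(p$samples$radius))
  wide_end <- window_min_radius(p, window = c(-6, -4))
  expect_gt(wide_end, window_min_radius(p, window = c(-1, 1)))
  lin <- lining_residues(hg, p, vdw_set = c(C = 1.85))
  expect_equal(window_min_radius(lin), min(lin$min_radius))
  expect_identical(classify_conduction(c(0.9, 1.0, 3.29, 3.3, 4.09, 4.1, 4.4)),
                   c("sub-dehydrated", "dehydrated-only", "dehydrated-only",
                     "hydrated-Na", "hydrated-Na", "hydrated-Ca", "hydrated-Ca"))
})

test_that("a start point inside an atom is rejected", {
  m <- cyl_fixture()
  a1 <- as.numeric(m$atoms[1, c("x", "y", "z")])
  expect_error(pore_profile(m, axis = c(0, 0, 1), start = a1,
                            vdw_set = c(C = 1.85)),
               "inside an atom")
})
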
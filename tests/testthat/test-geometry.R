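test_that("center_of_mass is the mass-weighted mean position", {
  fr <- make_frame(c("C1", "H1"), c("X", "X"), c(1L, 1L), c("C", "H"),
                   matrix(c(0, 0, 0, 13.019, 0, 0), 2, byrow = TRUE))
  # hand evaluation of sum(m_i x_i)/sum(m_i)
  expect_equal(center_of_mass(fr, 1:2)[1],
               (12.011 * 0 + 1.008 * 13.019) / (12.011 + 1.008),
               tolerance = 1e-12)

  fr2 <- make_frame(c("O1", "O2"), c("X", "X"), c(1L, 1L), c("O", "O"),
                    matrix(c(0, 0, 0, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(center_of_mass(fr2, 1:2), c(1, 0, 0))
  expect_equal(center_of_mass(fr2, 1L), c(0, 0, 0))
})

test_that("pseudodihedral follows the IUPAC sign convention", {
  expect_equal(pseudodihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  expect_equal(abs(pseudodihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))), 180)
  expect_equal(pseudodihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)), 90)
  expect_error(pseudodihedral(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)),
               "degenerate")
  expect_error(pseudodihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("pseudodihedral is reversal-symmetric and rotation-invariant", {
  set.seed(11)
  for (i in 1:20) {
    pts <- lapply(1:4, function(j) rnorm(3, sd = 3))
    d1 <- pseudodihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
    d2 <- pseudodihedral(pts[[4]], pts[[3]], pts[[2]], pts[[1]])
    expect_equal(d1, d2, tolerance = 1e-9)
    R <- random_rotation()
    tr <- rnorm(3, sd = 10)
    rot <- lapply(pts, function(p) as.numeric(R %*% p + tr))
    expect_equal(pseudodihedral(rot[[1]], rot[[2]], rot[[3]], rot[[4]]), d1,
                 tolerance = 1e-9 * max(1, abs(d1)))
  }
})

test_that("eversion angle recovers the programmed rotation exactly", {
  sched <- c(0, 40, 90, 220)
  traj <- generate_toy_eversion_trajectory(sched, seed = 2)
  defn <- attr(traj, "definition")
  expect_equal(eversion_series(traj, defn)$angle, sched, tolerance = 1e-6)

  # rigid tumbling of every frame leaves the coordinate unchanged
  tum <- transform_traj(traj, random_rotation(seed = 9), c(5, -3, 12))
  expect_equal(eversion_series(tum, defn)$angle, sched, tolerance = 1e-6)
})

test_that("eversion angle is monotone in a monotone rotation schedule", {
  sched <- seq(-60, 250, by = 10)
  traj <- generate_toy_eversion_trajectory(sched, seed = 4)
  ang <- eversion_series(traj, attr(traj, "definition"))$angle
  expect_true(all(diff(ang) > 0))
  expect_equal(ang, sched, tolerance = 1e-6)
})

test_that("unwrapping makes the eversion axis continuous past 180 degrees", {
  expect_equal(unwrap_eversion(-140, 0), 220)
  expect_equal(unwrap_eversion(-80, 0), -80)
  expect_equal(unwrap_eversion(170, 0), 170)
})

test_that("distances use atoms or group COMs and honor the 3-4-5 triangle", {
  fr <- make_frame(c("N7", "N"), c("DG", "GLY"), c(7L, 264L), c("N", "N"),
                   matrix(c(0, 0, 0, 3, 4, 0), 2, byrow = TRUE))
  a <- selection("n7", "A", 7L, "N7")
  b <- selection("glyn", "A", 264L, "N")
  expect_equal(atom_distance(fr, a, b), 5)
  expect_equal(atom_distance(fr, a, a), 0)
  expect_equal(gap_distance(fr, a, b), 5)

  fr2 <- make_frame(c("N7", "N"), c("DG", "GLY"), c(7L, 264L), c("N", "N"),
                    matrix(c(0, 0, 0, 0, 0, 2.9), 2, byrow = TRUE))
  expect_equal(atom_distance(fr2, a, b), 2.9)
})

test_that("hydrogen bonds require both distance and angle criteria", {
  mk <- function(d_xyz, h_xyz, a_xyz) {
    make_frame(c("N", "H", "O"), c("X", "X", "Y"), c(1L, 1L, 2L),
               c("N", "H", "O"), rbind(d_xyz, h_xyz, a_xyz))
  }
  crit <- hbond_criterion(3.5, 135)
  don <- sel_atom("A", 1L, "N"); hyd <- sel_atom("A", 1L, "H")
  acc <- sel_atom("A", 2L, "O")

  # ideal linear geometry at 2.8 A
  expect_true(hbond_present(mk(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0)),
                            don, hyd, acc, crit))
  # too far
  expect_false(hbond_present(mk(c(0, 0, 0), c(1, 0, 0), c(5, 0, 0)),
                             don, hyd, acc, crit))
  # distance passes (3.4) but angle 120 fails the 135 cutoff
  h <- c(1, 0, 0)
  acc_xyz <- h + 2.6 * c(cos(120 * pi / 180), sin(120 * pi / 180), 0)
  fr <- mk(c(0, 0, 0), h, acc_xyz)
  expect_lt(atom_distance(fr, don, acc), 3.5)
  expect_false(hbond_present(fr, don, hyd, acc, crit))
})

test_that("twist angle recovers a constructed rotation and flips with chirality", {
  mk_step <- function(twist_deg, mirror = FALSE) {
    rot <- function(v, deg) {
      r <- deg * pi / 180
      c(cos(r) * v[1] - sin(r) * v[2], sin(r) * v[1] + cos(r) * v[2], v[3])
    }
    a1 <- c(5, 0, 0); a2 <- c(-5, 0, 0)
    b1 <- rot(a1, twist_deg) + c(0, 0, 3.4)
    b2 <- rot(a2, twist_deg) + c(0, 0, 3.4)
    xyz <- rbind(a1, a2, b1, b2)
    if (mirror) xyz[, 1] <- -xyz[, 1]
    make_frame(rep("C1'", 4), rep("DG", 4), c(10L, 110L, 11L, 111L),
               rep("C", 4), xyz)
  }
  sels <- list(sel_atom("A", 10L, "C1'"), sel_atom("A", 110L, "C1'"),
               sel_atom("A", 11L, "C1'"), sel_atom("A", 111L, "C1'"))
  fr <- mk_step(36)
  expect_equal(do.call(twist_angle, c(list(fr), sels)), 36, tolerance = 1e-6)
  expect_equal(do.call(twist_angle, c(list(mk_step(0)), sels)), 0, tolerance = 1e-9)
  expect_equal(do.call(twist_angle, c(list(mk_step(36, mirror = TRUE)), sels)),
               -36, tolerance = 1e-6)
})

test_that("geometric observables are invariant under rigid motion", {
  traj <- generate_toy_eversion_trajectory(c(30, 120), seed = 5)
  fr <- get_frame(traj, 1)
  selA <- sel_resid(fr, 8L); selB <- sel_resid(fr, 9L)
  d0 <- atom_distance(fr, selA, selB)
  co0 <- center_of_mass(fr, selA)
  R <- random_rotation(seed = 13); tr <- c(-4, 8, 1)
  fr_t <- get_frame(transform_traj(traj, R, tr), 1)
  expect_equal(atom_distance(fr_t, selA, selB), d0, tolerance = 1e-9)
  expect_equal(center_of_mass(fr_t, selA), as.numeric(R %*% co0 + tr),
               tolerance = 1e-9)
})
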
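# Analysis coordinates: DNA axis, symmetry axis, zeta/eta, RMSD, per-SHL
# sliding and the loop coordinate.

test_that("circle_fit is exact on noiseless circles", {
  th <- seq(0, 2 * pi, length.out = 11)[-11]
  xy <- cbind(1 + 10 * cos(th), 2 + 10 * sin(th))
  cf <- circle_fit(xy)
  expect_equal(cf$center, c(1, 2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(cf$radius, 10, tolerance = 1e-9)
})

test_that("the DNA axis of straight ideal B-DNA is the true helical axis", {
  s <- straight_bdna(n_bp = 41)
  ax <- dna_axis(s)
  # true axis is the z axis: radial deviation under 0.5 A
  expect_lt(max(sqrt(ax$points[, 1]^2 + ax$points[, 2]^2)), 0.5)
  # fitted tube radius within 5% of the phosphate radial distance
  expect_lt(max(abs(ax$radius - 9.4) / 9.4), 0.05)
  # tangents along +z (increasing bp)
  expect_gt(min(ax$tangents[, 3]), 0.99)
  expect_error(dna_axis(straight_bdna(n_bp = 12)), "31")
})

test_that("the DNA axis transforms equivariantly under rigid motions", {
  s <- straight_bdna(n_bp = 41)
  ax <- dna_axis(s, bp = 15:25)
  set.seed(5)
  M <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(M) < 0) M[, 1] <- -M[, 1]
  shift <- c(4, -7, 11)
  s2 <- s
  coords(s2) <- sweep(coords(s) %*% M, 2, shift, "+")
  ax2 <- dna_axis(s2, bp = 15:25)
  expect_lt(max(abs(ax2$points -
                      sweep(ax$points %*% M, 2, shift, "+"))), 1e-9)
})

test_that("symmetry_axis recovers exact and noisy constructed axes", {
  # midpoints exactly on a line -> that line, residual 0
  s <- ideal
  sym <- symmetry_axis(s, toward = bp_center(s, 111))
  expect_equal(abs(sym$direction), c(1, 0, 0), tolerance = 1e-9,
               ignore_attr = TRUE)
  # built-in C2 axis of the fixture is the x axis: within 0.1 degree
  ang <- acos(min(1, abs(sum(sym$direction * c(1, 0, 0))))) * 180 / pi
  expect_lt(ang, 0.1)
  # isotropic noise sigma = 0.1 A: direction within 1 degree of truth
  set.seed(9)
  worst <- 0
  for (rep in 1:5) {
    sn <- s
    coords(sn) <- coords(s) + matrix(rnorm(3 * nrow(s$beads), 0, 0.1),
                                     ncol = 3)
    symn <- symmetry_axis(sn, toward = bp_center(sn, 111))
    angn <- acos(min(1, abs(sum(symn$direction * c(1, 0, 0))))) * 180 / pi
    worst <- max(worst, angn)
  }
  expect_lt(worst, 1)
  # degenerate: coincident midpoints
  flat <- s
  xyz <- coords(s); xyz[s$beads$kind == "CA", ] <- 0
  coords(flat) <- xyz
  expect_error(symmetry_axis(flat), "coincide")
})

test_that("zeta is zero at the dyad and advances with the wrap azimuth", {
  expect_equal(sliding_zeta(ideal, 111), 0, tolerance = 1e-9)
  # independent closed form from the construction: the tracked base pair,
  # advanced +5 bp by screw motion, sits 5 azimuthal bp steps from the
  # dyad; the angle subtended at the core centroid follows from the
  # superhelix parameters by plain trigonometry
  sp <- ideal_spec
  dphi <- 2 * pi * sp$rise / sp$L_turn        # azimuth per bp (rad)
  g_off <- core_centroid(ideal)[1]            # centroid x offset
  bpc5 <- bp_center(advance_screw(ideal, 5), 111)
  r5 <- sqrt(sum(bpc5[1:2]^2))                 # bp-center radius
  expected <- atan2(r5 * sin(5 * dphi), r5 * cos(5 * dphi) - g_off) * 180 / pi
  z5 <- sliding_zeta(advance_screw(ideal, 5), 111)
  expect_gt(z5, 0)                            # +bp motion is positive
  expect_equal(z5, expected, tolerance = 0.1)
  # a -5 bp advance gives the (nearly) symmetric negative angle; the
  # strand-1-only normal breaks exact antisymmetry at the 0.1 deg level
  expect_lt(abs(sliding_zeta(advance_screw(ideal, -5), 111) + z5), 0.1)
})

test_that("the zeta sign convention is intrinsic to the bp ordering", {
  s5 <- advance_screw(ideal, 5)
  z <- sliding_zeta(s5, 111)
  # mirror image: bp ordering still defines counter-clockwise, so the
  # sign of a +bp displacement is preserved
  sm <- s5
  xyz <- coords(s5); xyz[, 3] <- -xyz[, 3]
  coords(sm) <- xyz
  expect_equal(sliding_zeta(sm, 111), z, tolerance = 1e-6)
})

test_that("zeta_to_bp inverts the reference table", {
  tab <- zeta_table(ideal, 91:131)
  # exact entries map to integer base pairs
  expect_equal(zeta_to_bp(tab$zeta, tab), as.numeric(tab$bp))
  # midpoints interpolate linearly
  mid <- (tab$zeta[15] + tab$zeta[16]) / 2
  expect_equal(zeta_to_bp(mid, tab), (tab$bp[15] + tab$bp[16]) / 2)
  # outside the window: extrapolation with a warning
  expect_warning(out <- zeta_to_bp(tab$zeta[41] + 2, tab), "extrapolat")
  expect_gt(out, tab$bp[41])
  expect_error(zeta_to_bp(0, tab[0, ]), "empty")
})

test_that("eta advances by one twist step per screw bp and 360 per turn", {
  e <- vapply(0:10, function(k) rotation_eta(advance_screw(ideal, k), 111), 0)
  eu <- e
  for (i in 2:11) eu[i] <- eu[i] + 360 * round((eu[i - 1] - eu[i]) / 360)
  d <- diff(eu)
  # 36 deg/bp from the 10 bp/turn twist, within the reference-direction
  # wobble of the fixture
  expect_true(all(abs(d - 36) < 1.5))
  # one full twist (10 bp) accumulates ~360 deg after unwrapping
  expect_equal(eu[11] - eu[1], 360, tolerance = 360 * 0.02)
})

test_that("eta is nearly constant under rigid (rotation-uncoupled) jumps", {
  tau <- 360 / ideal_spec$dna_twist
  e0 <- rotation_eta(ideal, 111)
  for (sh in c(-5, 5)) {
    sj <- nucleoslide:::.regen_dna(ideal, sh, -tau * sh)
    expect_lt(abs(rotation_eta(sj, 111) - e0), 5)
  }
})

test_that("analyze_trajectory couples eta to sliding on screw trajectories", {
  traj <- make_trajectory(ideal, trajectory_spec(mode = "screw",
                                                 n_frames = 11,
                                                 sweep = c(-5, 5)))
  res <- analyze_trajectory(traj)
  expect_equal(nrow(res), 11)
  # recovered sliding matches the generator's ground truth
  truth <- traj$truth$shift_bp - traj$truth$shift_bp[1]
  expect_lt(max(abs(res$bp_shift - truth)), 0.1)
  fit <- stats::lm(eta ~ bp_shift, data = res)
  expect_equal(unname(stats::coef(fit)[2]), 36, tolerance = 0.5 / 36)
  # trailing moving average is exposed but optional
  sm <- analyze_trajectory(traj, smooth = 3)
  expect_true(all(is.na(sm$eta[1:2])))
})

test_that("jump trajectories slide in 5-bp steps with flat eta", {
  traj <- make_trajectory(ideal, trajectory_spec(mode = "jump",
                                                 n_frames = 12, seed = 3,
                                                 range_bp = 5))
  res <- analyze_trajectory(traj)
  truth <- traj$truth$shift_bp - traj$truth$shift_bp[1]
  expect_lt(max(abs(res$bp_shift - truth)), 0.25)
  expect_true(all(abs(truth) %in% c(0, 5, 10)))
  expect_lt(diff(range(res$eta)), 5)
})

test_that("rmsd_central is zero on self and rigid copies, else per formula", {
  expect_lt(rmsd_central(ideal, ideal), 1e-9)
  rot <- rigid_move(ideal, 4)
  expect_lt(rmsd_central(rot, ideal), 1e-6)
  # displace one measured bead by 2 A after fitting: RMSD = 2/sqrt(N)
  fr <- ideal
  bps <- 101:120
  rows <- unlist(lapply(bps, function(b) bp_rows(ideal, b)))
  xyz <- coords(fr)
  xyz[rows[1], ] <- xyz[rows[1], ] + c(2, 0, 0)
  coords(fr) <- xyz
  expect_equal(rmsd_central(fr, ideal), 2 / sqrt(length(rows)),
               tolerance = 1e-6)
  # a screw-advanced register moves the measured DNA: RMSD far from zero
  expect_gt(rmsd_central(advance_screw(ideal, 5), ideal), 5)
})

test_that("per-SHL sliding distinguishes cooperative from sequential motion", {
  # screw: all SHLs move together (within 0.3 bp)
  ts <- make_trajectory(ideal, trajectory_spec(mode = "screw", n_frames = 4,
                                               sweep = c(0, 3)))
  ss <- shl_sliding(ts, shls = c(0, 2, 4), bp_per_turn = 10)
  m <- matrix(ss$bp_shift, nrow = 4)
  expect_lt(max(apply(m, 1, function(r) diff(range(r)))), 0.3)
  # jump: a single simultaneous 5-bp step at all SHLs
  tj <- make_trajectory(ideal, trajectory_spec(mode = "jump", n_frames = 2,
                                               sweep = c(0, 5)))
  sj <- shl_sliding(tj, shls = c(0, 2, 4), bp_per_turn = 10)
  mj <- matrix(sj$bp_shift, nrow = 2)
  expect_true(all(abs(mj[2, ] - 5) < 0.5))
  # loop: SHLs step sequentially, from the nucleation end inward
  tl <- make_trajectory(ideal, trajectory_spec(mode = "loop", n_frames = 9))
  sl <- shl_sliding(tl, shls = c(0, 2, 4, 6), bp_per_turn = 10)
  ml <- matrix(sl$bp_shift, nrow = 9)   # columns: SHL 0, 2, 4, 6
  first_pass <- apply(ml, 2, function(x) which(x > 5)[1])
  expect_true(all(diff(first_pass) < 0))   # SHL 6 first, SHL 0 last
})

test_that("loop_delta_r measures radial bulges where the loop sits", {
  expect_equal(loop_delta_r(ideal, ideal, c(91, 111, 131)), c(0, 0, 0))
  # displace one base pair radially outward by 3 A
  fr <- ideal
  rows <- bp_rows(ideal, 111)
  xyz <- coords(fr)
  ctr <- core_centroid(ideal)
  dir <- (bp_center(ideal, 111) - ctr)
  dir <- dir / sqrt(sum(dir^2))
  xyz[rows, ] <- sweep(xyz[rows, ], 2, 3 * dir, "+")
  coords(fr) <- xyz
  expect_equal(loop_delta_r(fr, ideal, 111), 3, tolerance = 1e-9)
  # synthetic loop mid-propagation: bulge at SHL 4, none at SHL 0
  tl <- make_trajectory(ideal, trajectory_spec(mode = "loop", n_frames = 9))
  mid <- frame_structure(tl, 3)
  dr <- loop_delta_r(mid, ideal, 111 + 10 * c(0, 4))
  expect_lt(abs(dr[1]), 0.5)
  expect_gt(dr[2], 1)
})

test_that("coordinates are invariant under rigid motion of the frame", {
  s5 <- advance_screw(ideal, 5)
  z0 <- sliding_zeta(s5, 111)
  e0 <- rotation_eta(s5, 111)
  sm <- rigid_move(s5, 12)
  expect_equal(sliding_zeta(sm, 111), z0, tolerance = 1e-6)
  expect_equal(rotation_eta(sm, 111), e0, tolerance = 1e-6)
})
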
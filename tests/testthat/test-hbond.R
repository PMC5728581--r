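# The sliding-invariant hydrogen-bond potential.

test_that("f_dist matches its analytic values and is a unit even bump", {
  expect_equal(f_dist(0), 1)
  expect_equal(f_dist(1, sigma = 1), exp(-1))
  expect_equal(f_dist(3, sigma = 1), exp(-9))
  expect_equal(f_dist(-0.7), f_dist(0.7))
  dr <- seq(0, 5, by = 0.1)
  expect_true(all(diff(f_dist(dr)) < 0))
  expect_true(all(f_dist(seq(-8, 8, 0.3)) <= 1 & f_dist(seq(-8, 8, 0.3)) > 0))
})

test_that("g_ang has the piecewise form with compact support and continuity", {
  expect_equal(g_ang(0), 1)
  expect_equal(g_ang(15, delta_phi = 10), 0.5)   # 1 - cos^2(3 pi/4)
  expect_equal(g_ang(20, delta_phi = 10), 0)
  expect_equal(g_ang(25, delta_phi = 10), 0)
  expect_equal(g_ang(-15, delta_phi = 10), 0.5)
  # continuity at the window edges
  eps <- 1e-9
  expect_equal(g_ang(10 + eps), 1, tolerance = 1e-6)
  expect_equal(g_ang(20 - eps), 0, tolerance = 1e-6)
  x <- seq(-30, 30, by = 0.25)
  expect_true(all(g_ang(x) >= 0 & g_ang(x) <= 1))
})

test_that("bond_geometry reproduces constructed geometries", {
  # collinear CA triplet on x; P displaced 5 A along y from the donor
  b <- rbind(
    data.frame(chain = "A", resid = 1:3, kind = "CA",
               x = c(-3.8, 0, 3.8), y = 0, z = 0),
    data.frame(chain = "I", resid = 1, kind = c("P", "S"),
               x = c(0, 3), y = c(5, 5), z = 0))
  s <- cg_structure(b)
  g <- bond_geometry(s, "A", 2, "I", 1)
  expect_equal(g$r, 5)
  expect_equal(g$theta, 90)
  # phi: angle at P between donor CA (along -y) and sugar (along +x)
  expect_equal(g$phi, 90)
  # planar construction: sugar at (3,8) puts P->S at 45 deg above +x,
  # i.e. 135 deg from the P->CA direction (-y)
  b2 <- b
  b2[b2$kind == "S", c("x", "y")] <- c(3, 8)
  g2 <- bond_geometry(cg_structure(b2), "A", 2, "I", 1)
  expect_equal(g2$phi, 135)
  # donor at a chain terminus cannot be evaluated
  expect_error(bond_geometry(s, "A", 1, "I", 1), "neighbour")
})

test_that("extract_hbond_model averages copies and rejects tail donors", {
  base <- rbind(
    data.frame(chain = "A", resid = 1:3, kind = "CA",
               x = c(-3.8, 0, 3.8), y = 0, z = 0, tail = FALSE),
    data.frame(chain = "I", resid = 1, kind = c("P", "S"),
               x = c(0, 3), y = c(4.8, 4.8), z = 0, tail = FALSE))
  s1 <- cg_structure(base)
  base$y[base$kind %in% c("P", "S")] <- 5.2
  s2 <- cg_structure(base)
  pairs <- data.frame(donor_chain = "A", donor_resid = 2,
                      p_chain = "I", p_resid = 1)
  m <- extract_hbond_model(list(s1, s2), pairs)
  expect_equal(m$bonds$r0, 5)        # mean of 4.8 and 5.2
  expect_equal(m$bonds$theta0, 90)
  # single structure: native frame reproduces its own parameters
  m1 <- extract_hbond_model(s1, pairs)
  g <- bond_geometry(s1, "A", 2, "I", 1)
  expect_equal(m1$bonds$r0, g$r)
  expect_equal(m1$bonds$phi0, g$phi)
  base$tail[base$chain == "A"] <- TRUE
  expect_error(extract_hbond_model(cg_structure(base), pairs), "tail")
})

test_that("a native bond scores occupancy 1 and energy -epsilon", {
  b <- rbind(
    data.frame(chain = "A", resid = 1:3, kind = "CA",
               x = c(-3.8, 0, 3.8), y = 0, z = 0),
    data.frame(chain = "I", resid = 1, kind = c("P", "S"),
               x = c(0, 3), y = c(5, 5), z = 0))
  s <- cg_structure(b)
  m <- extract_hbond_model(s, data.frame(donor_chain = "A", donor_resid = 2,
                                         p_chain = "I", p_resid = 1))
  hb <- hb_energy(s, m)
  expect_equal(hb$occupancy, 1)
  expect_equal(hb$energy, -1.2)
  # rotating the phosphate/sugar pair 25 degrees about the donor takes
  # the bond angle beyond 2*delta_phi and kills the bond entirely
  s2 <- s
  xyz <- coords(s2)
  ps <- which(s2$beads$kind %in% c("P", "S"))
  a <- 25 * pi / 180
  R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  xyz[ps, ] <- xyz[ps, ] %*% R   # rotate about the donor (origin)
  coords(s2) <- xyz
  hb2 <- hb_energy(s2, m)
  expect_equal(hb2$energy, 0)
})

test_that("hb_energy equals the brute-force double sum over all pairs", {
  # several donors and phosphates scattered within interaction range
  set.seed(42)
  prot <- data.frame(chain = "A", resid = 1:9, kind = "CA",
                     x = seq(0, 30, length.out = 9) + rnorm(9, 0, 0.5),
                     y = rnorm(9, 0, 0.5), z = rnorm(9, 0, 0.5))
  dna <- do.call(rbind, lapply(1:8, function(k)
    data.frame(chain = "I", resid = k, kind = c("P", "S"),
               x = (k - 1) * 4 + rnorm(1, 0, 1),
               y = 5 + rnorm(1, 0, 1), z = rnorm(1, 0, 1) + c(0, 2))))
  s <- cg_structure(rbind(prot, dna))
  bonds <- data.frame(donor_chain = "A", donor_resid = c(2, 5, 8),
                      r0 = 5, theta0 = 90, phi0 = 100)
  m <- hbond_model(bonds, epsilon = 1.7, sigma = 2.5, delta_phi = 40)
  hb <- hb_energy(s, m)
  # independent oracle: naive loops over every (bond, phosphate) pair
  oracle <- 0
  for (i in seq_len(nrow(bonds))) {
    for (k in 1:8) {
      g <- bond_geometry(s, "A", bonds$donor_resid[i], "I", k)
      oracle <- oracle + f_dist(g$r - bonds$r0[i], m$sigma) *
        g_ang(g$theta - bonds$theta0[i], m$delta_phi) *
        g_ang(g$phi - bonds$phi0[i], m$delta_phi)
    }
  }
  expect_gt(oracle, 0.01)  # the toy must actually exercise the sum
  expect_equal(sum(hb$occupancy), oracle, tolerance = 1e-12)
  expect_equal(hb$energy, -1.7 * oracle, tolerance = 1e-12)
})

test_that("hb_energy is exactly linear in epsilon", {
  m2 <- ideal_hb
  m2$epsilon <- 2.9
  e1 <- hb_energy(ideal, ideal_hb)$energy
  e2 <- hb_energy(ideal, m2)$energy
  expect_identical(e2, (2.9 / ideal_hb$epsilon) * e1)
})

test_that("the potential is invariant under rotation-coupled sliding", {
  e0 <- hb_energy(ideal, ideal_hb)$energy
  for (d in c(-1, 1, 3)) {
    ed <- hb_energy(advance_screw(ideal, d), ideal_hb)$energy
    expect_lt(abs(ed - e0) / abs(e0), 1e-6)
  }
})

test_that("narrow widths prevent double counting from neighbouring phosphates", {
  hb <- hb_energy(ideal, ideal_hb)
  # every donor binds exactly its native phosphate: occupancy within 0.01
  # of 1, so non-native phosphates contribute < 0.01
  expect_true(all(abs(hb$occupancy - 1) < 0.01))
  expect_equal(hb$energy, -ideal_hb$epsilon * nrow(ideal_hb$bonds),
               tolerance = 1e-6)
})
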
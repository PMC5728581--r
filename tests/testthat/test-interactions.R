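# Excluded volume, Debye-Hueckel electrostatics and contact counting.

two_bead <- function(r, kinds = c("CA", "P"), radius = c(3, 2.9),
                     charge = c(1, 1)) {
  cg_structure(data.frame(
    chain = c("A", if (kinds[2] == "CA") "B" else "I"), resid = 1,
    kind = kinds, x = c(0, r), y = 0, z = 0,
    charge = charge, radius = radius))
}

test_that("excluded volume matches its analytic two-bead values", {
  p <- interaction_params()
  sig <- p$radius_scale * (3 + 2.9) / 2
  s <- two_bead(sig)
  expect_equal(excluded_volume(s, p), p$exv_epsilon)
  expect_equal(excluded_volume(two_bead(2 * sig), p), p$exv_epsilon / 4096)
  expect_error(excluded_volume(two_bead(0), p), "singular")
})

test_that("excluded volume equals a brute-force pair sum on a toy", {
  set.seed(7)
  prot <- data.frame(chain = "A", resid = 1:5, kind = "CA",
                     x = runif(5, 0, 12), y = runif(5, 0, 12),
                     z = runif(5, 0, 12), charge = 0, radius = 3)
  dna <- data.frame(chain = "I", resid = 1:5,
                    kind = c("P", "S", "B", "S", "B"),
                    x = runif(5, 0, 12), y = runif(5, 0, 12),
                    z = runif(5, 0, 12), charge = 0,
                    radius = runif(5, 2, 4))
  s <- cg_structure(rbind(prot, dna))
  p <- interaction_params()
  oracle <- 0
  for (i in 1:5) for (j in 1:5) {
    ri <- prot[i, ]; rj <- dna[j, ]
    r <- sqrt((ri$x - rj$x)^2 + (ri$y - rj$y)^2 + (ri$z - rj$z)^2)
    sig <- p$radius_scale * (ri$radius + rj$radius) / 2
    oracle <- oracle + p$exv_epsilon * (sig / r)^12
  }
  expect_equal(excluded_volume(s, p), oracle, tolerance = 1e-9)
})

test_that("Debye-Hueckel matches the screened-Coulomb closed form", {
  p <- interaction_params(ionic_strength = 0.15, permittivity = 78)
  ld <- debye_length(p)
  lb <- bjerrum_length(p)
  s <- two_bead(ld, kinds = c("CA", "CA"))
  expect_equal(debye_huckel(s, p, classes = "protein-protein"),
               lb * exp(-1) / ld)
  # bilinearity: doubling both charges quadruples the energy
  s2 <- two_bead(ld, kinds = c("CA", "CA"), charge = c(2, 2))
  expect_equal(debye_huckel(s2, p, classes = "protein-protein"),
               4 * debye_huckel(s, p, classes = "protein-protein"))
  expect_error(interaction_params(ionic_strength = 0), "positive")
})

test_that("the empirical dielectric reproduces published reference values", {
  # pure water at 298 K is close to 78.5
  p <- interaction_params(ionic_strength = 1e-9, temperature = 298)
  expect_equal(permittivity(p), 78.5, tolerance = 0.01)
})

test_that("Debye-Hueckel equals a brute-force pair sum with class charges", {
  set.seed(11)
  prot <- data.frame(chain = "A", resid = 1:2, kind = "CA",
                     x = c(0, 5), y = 0, z = 0, charge = c(1, -1), radius = 3)
  dna <- data.frame(chain = "I", resid = 1:2, kind = c("P", "P"),
                    x = c(2, 7), y = 4, z = 0, charge = -1, radius = 2.9)
  s <- cg_structure(rbind(prot, dna))
  p <- interaction_params(ionic_strength = 0.2, permittivity = 78)
  lb <- bjerrum_length(p); ld <- debye_length(p)
  xyz <- coords(s)
  dh <- function(i, j, qi, qj) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    lb * qi * qj * exp(-r / ld) / r
  }
  oracle <- dh(1, 3, 1, -1) + dh(1, 4, 1, -1) +   # protein-DNA at -1e
    dh(2, 3, -1, -1) + dh(2, 4, -1, -1) +
    dh(3, 4, -0.6, -0.6)                           # DNA-DNA at -0.6e
  expect_equal(debye_huckel(s, p), oracle, tolerance = 1e-12)
})

test_that("pair energies are invariant under rigid motions", {
  s <- toy_duplex()
  p <- interaction_params(permittivity = 78)
  e0 <- c(excluded_volume(s, p), debye_huckel(s, p),
          hb_energy(s, hbond_model(data.frame(
            donor_chain = "A", donor_resid = 2, r0 = 8, theta0 = 90,
            phi0 = 90), sigma = 3, delta_phi = 45))$energy)
  for (seed in 1:3) {
    sm <- rigid_move(s, seed)
    e1 <- c(excluded_volume(sm, p), debye_huckel(sm, p),
            hb_energy(sm, hbond_model(data.frame(
              donor_chain = "A", donor_resid = 2, r0 = 8, theta0 = 90,
              phi0 = 90), sigma = 3, delta_phi = 45))$energy)
    expect_equal(e1, e0, tolerance = 1e-9)
  }
})

test_that("electrostatic energy decays monotonically with salt", {
  s <- toy_duplex()
  salts <- c(0.05, 0.1, 0.2, 0.5, 1, 2)
  e <- vapply(salts, function(cs)
    abs(debye_huckel(s, interaction_params(ionic_strength = cs,
                                           permittivity = 78))), 0)
  expect_true(all(diff(e) < 0))
})

test_that("contact counting applies the 12 A cutoff to the histone core", {
  mk <- function(d) cg_structure(data.frame(
    chain = c("A", "A", "I", "I"), resid = c(1, 2, 1, 1),
    kind = c("CA", "CA", "P", "S"),
    x = c(0, 2, d, d), y = 0, z = 0,
    tail = c(FALSE, TRUE, FALSE, FALSE)))
  expect_equal(count_contacts(mk(11)), 1)   # 11 A from the core bead at 0
  # 13 A from the core bead; the tail bead at x=2 (11 A away) is excluded
  expect_equal(count_contacts(mk(13)), 0)
})

test_that("contact count is monotone in the cutoff and matches brute force", {
  cuts <- c(6, 9, 12, 15, 20)
  counts <- vapply(cuts, function(cc) count_contacts(ideal, cc), 0L)
  expect_true(all(diff(counts) >= 0))
  # brute-force oracle at 12 A
  xyz <- coords(ideal)
  core <- xyz[ideal$core_rows, , drop = FALSE]
  ph <- xyz[ideal$phosphate_rows, , drop = FALSE]
  oracle <- sum(vapply(seq_len(nrow(ph)), function(k)
    min(sqrt((core[, 1] - ph[k, 1])^2 + (core[, 2] - ph[k, 2])^2 +
               (core[, 3] - ph[k, 3])^2)) <= 12, TRUE))
  expect_equal(count_contacts(ideal, 12), oracle)
  expect_gt(oracle, 0)
})

test_that("titration curves summarize ensembles with standard errors", {
  tr1 <- make_trajectory(ideal, trajectory_spec(mode = "static", n_frames = 1))
  one <- titration_curve(list(tr1), salt = 0.1)
  expect_equal(one$mean_contacts, count_contacts(ideal))
  expect_true(is.na(one$se))
  tr3 <- make_trajectory(ideal, trajectory_spec(mode = "static", n_frames = 3))
  const <- titration_curve(list(tr3), salt = 0.1)
  expect_equal(const$se, 0)
  # two-level synthetic ensemble: frames at two distinct counts
  s_far <- ideal
  coords(s_far) <- coords(ideal) + matrix(rep(c(500, 0, 0),
                                              each = nrow(ideal$beads)), ncol = 3)
  # move only the DNA far away in half the frames
  f_far <- coords(ideal)
  dna_rows <- which(ideal$beads$kind != "CA")
  f_far[dna_rows, 1] <- f_far[dna_rows, 1] + 500
  tr2 <- cg_trajectory(ideal, list(coords(ideal), f_far, coords(ideal), f_far))
  two <- titration_curve(list(tr2), salt = 1)
  c0 <- count_contacts(ideal)
  expect_equal(two$mean_contacts, c0 / 2)
  expect_equal(two$se, stats::sd(c(c0, 0, c0, 0)) / 2)
  expect_error(titration_curve(list()), "empty")
  # burn-in removes leading frames
  burnt <- titration_curve(list(tr2), salt = 1, burn_in_frames = 2)
  expect_equal(burnt$n_frames, 2)
})
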
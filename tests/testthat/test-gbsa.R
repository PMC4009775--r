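ion_topology <- function(q = 1, gb_radius = 2.09, n = 1L) {
  topology(data.frame(
    name = paste0("I", seq_len(n)), element = "X", resname = "ION",
    resid = seq_len(n), chain = "A", charge = q, rmin2 = 1.7, eps = 0.1,
    gb_radius = gb_radius, gb_screen = 0.8))
}

test_that("effective Born radii reduce to intrinsic radii in isolation and match the descreening integral", {
  top1 <- topology(data.frame(
    name = "I1", element = "X", resname = "ION", resid = 1, chain = "A",
    charge = 0, rmin2 = 1.7, eps = 0.1, gb_radius = 1.5, gb_screen = 0.8))
  r <- effective_born_radii(top1, matrix(c(0, 0, 0), 1))
  expect_equal(as.numeric(r), 1.5 - 0.09, tolerance = 1e-12)

  # vanishing descreening at huge separation
  top2 <- ion_topology(0, 1.5, 2)
  r2 <- effective_born_radii(top2, rbind(c(0, 0, 0), c(1e4, 0, 0)))
  expect_equal(as.numeric(r2), rep(1.5 - 0.09, 2), tolerance = 1e-6)

  # pairwise descreening against the numerical Coulomb-field integral
  at <- data.frame(name = c("A", "B"), element = "X", resname = "X",
                   resid = 1:2, chain = "A", charge = 0, rmin2 = 1.7,
                   eps = 0.1, gb_radius = c(1.59, 1.79),
                   gb_screen = c(0.8, 0.85))
  topp <- topology(at)
  for (d in c(2.0, 3.0, 4.5)) {
    r <- effective_born_radii(topp, rbind(c(0, 0, 0), c(d, 0, 0)))
    o1 <- 1 / hct_inverse_radius_oracle(1.5, 0.85 * 1.7, d)
    o2 <- 1 / hct_inverse_radius_oracle(1.7, 0.8 * 1.5, d)
    expect_equal(as.numeric(r[1]), o1, tolerance = 0.02)
    expect_equal(as.numeric(r[2]), o2, tolerance = 0.02)
  }
  expect_gt(min(r), 0)
})

test_that("GB polar energy reproduces the Born formula and its pairwise limits", {
  top <- ion_topology()
  co <- matrix(c(0, 0, 0), 1)
  r <- effective_born_radii(top, co)
  born <- -0.5 * 332.06 * (1 - 1 / 78.5) * 1 / 2.0
  expect_equal(gb_polar_energy(top, co, r), born, tolerance = 1e-9)
  # zero charges give zero energy
  top0 <- ion_topology(q = 0)
  expect_equal(gb_polar_energy(top0, co, r), 0)
  # r -> 0 limit of two +1 charges approaches a q = 2 ion with the
  # harmonic-style radius behavior of f_GB; compare to direct evaluation
  top2 <- ion_topology(n = 2)
  for (d in c(1e-3, 0.1, 1)) {
    co2 <- rbind(c(0, 0, 0), c(d, 0, 0))
    r2 <- rep(2.0, 2)
    fgb <- sqrt(d^2 + 4 * exp(-d^2 / 16))
    direct <- -0.5 * 332.06 * (1 - 1 / 78.5) * (1 / 2 + 1 / 2 + 2 / fgb)
    expect_equal(gb_polar_energy(top2, co2, r2), direct, tolerance = 1e-9)
  }
  expect_error(gb_polar_energy(top2, co2, r2[1]), "length")
})

test_that("two distant ions decompose into Born self-energies plus screened Coulomb", {
  top <- ion_topology(n = 2)
  co <- rbind(c(0, 0, 0), c(100, 0, 0))
  r <- effective_born_radii(top, co)
  e <- gb_polar_energy(top, co, r)
  analytic <- 2 * (-0.5 * 332.06 * (1 - 1 / 78.5) / 2.0) -
    332.06 * (1 - 1 / 78.5) / 100
  expect_equal(e, analytic, tolerance = abs(analytic) * 1e-3)
})

test_that("Shrake-Rupley SASA matches analytic sphere areas", {
  one <- topology(data.frame(
    name = "A", element = "X", resname = "X", resid = 1, chain = "A",
    charge = 0, rmin2 = 1.9, eps = 0.1, gb_radius = 1.5, gb_screen = 0.8))
  s1 <- sasa(one, matrix(c(0, 0, 0), 1))
  expect_equal(s1$total, 4 * pi * 3.3^2, tolerance = 0.01 * 4 * pi * 3.3^2)
  # far-apart atoms are additive
  two <- topology(data.frame(
    name = c("A", "B"), element = "X", resname = "X", resid = 1:2,
    chain = "A", charge = 0, rmin2 = c(1.9, 1.6), eps = 0.1,
    gb_radius = 1.5, gb_screen = 0.8))
  s2 <- sasa(two, rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(s2$total, 4 * pi * (3.3^2 + 3.0^2), tolerance = 1e-6)
  # complete burial of a small atom inside a large one
  engulf <- topology(data.frame(
    name = c("A", "B"), element = "X", resname = "X", resid = 1:2,
    chain = "A", charge = 0, rmin2 = c(3.0, 0.4), eps = 0.1,
    gb_radius = 1.5, gb_screen = 0.8))
  s3 <- sasa(engulf, rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_equal(s3$per_atom[2], 0)
  # two-sphere overlap across a grid of separations, within 1% at 960 points
  for (d in seq(0.5, 6.4, length.out = 21)) {
    st <- sasa(two, rbind(c(0, 0, 0), c(d, 0, 0)))$total
    ana <- two_sphere_sasa(3.3, 3.0, d)
    expect_equal(st, ana, tolerance = 0.01 * ana)
  }
})

test_that("surface-area energy is linear in SASA", {
  expect_equal(asa_energy(1000, sasa_params(gamma = 0.005, b = 0)), 5.0)
  expect_equal(asa_energy(1000, sasa_params(gamma = 0)), 0)
  expect_equal(asa_energy(136.85, sasa_params(gamma = 0.0072)), 0.98532,
               tolerance = 1e-9)
})

test_that("molecular-mechanics terms evaluate the AMBER functional forms", {
  # single bond: k (b - b0)^2
  at <- data.frame(name = c("A", "B"), element = "C", resname = "X",
                   resid = 1:2, chain = "A", charge = 0, rmin2 = 1.7,
                   eps = 0, gb_radius = 1.7, gb_screen = 0.72)
  top <- topology(at, bonds = cbind(1L, 2L),
                  bond_params = data.frame(kb = 300, b0 = 1.0))
  e <- mm_energy(top, rbind(c(0, 0, 0), c(1.1, 0, 0)))
  expect_equal(e$bond, 3.0, tolerance = 1e-9)
  # LJ pair at r = Rmin gives -eps (unbonded pair)
  at2 <- at; at2$eps <- 0.2
  top2 <- topology(at2)
  e2 <- mm_energy(top2, rbind(c(0, 0, 0), c(3.4, 0, 0)))
  expect_equal(e2$lj, -0.2, tolerance = 1e-9)
  # Coulomb k q1 q2 / r
  at3 <- at; at3$charge <- c(1, -1)
  e3 <- mm_energy(topology(at3), rbind(c(0, 0, 0), c(3.3206, 0, 0)))
  expect_equal(e3$coulomb, -100.0, tolerance = 1e-9)
  # 1-2 and 1-3 exclusions, 1-4 scaling on a 4-atom chain
  chain <- make_chain_topology(1, charge = 0.3)
  co <- build_coordinates_from_torsions(chain, 180)
  em <- mm_energy(chain, co)
  q <- chain$atoms$charge
  d14 <- sqrt(sum((co[1, ] - co[4, ])^2))
  expect_equal(em$coulomb, (1 / 1.2) * 332.06 * q[1] * q[4] / d14,
               tolerance = 1e-9)
})

test_that("snapshot energies are internally consistent, rigid-motion invariant and extensive", {
  top <- make_toy_topology(3)
  set.seed(41)
  ts <- enumerate_torsions(top)
  co <- build_coordinates_from_torsions(top, runif(ts$n, -180, 180))
  dec <- snapshot_energy(top, co)
  expect_equal(dec$e_mm,
               dec$bond + dec$angle + dec$torsion + dec$lj + dec$coulomb +
                 dec$gb + dec$offset, tolerance = 1e-9)
  expect_gte(dec$sasa, 0)
  # rigid motion leaves every term unchanged
  R <- random_rotation()
  co2 <- sweep(co %*% t(R), 2, -c(5, -3, 11))
  dec2 <- snapshot_energy(top, co2)
  for (f in c("bond", "angle", "torsion", "lj", "coulomb", "gb", "e_mm",
              "sasa", "e_asa"))
    expect_equal(dec2[[f]], dec[[f]], tolerance = 1e-6,
                 label = paste("term", f))
  # a far-away duplicate doubles every term
  atoms2 <- rbind(top$atoms, top$atoms)
  atoms2$resid <- c(top$atoms$resid, top$atoms$resid + 3L)
  n <- n_atoms(top)
  top2 <- topology(atoms2,
                   bonds = rbind(top$bonds, top$bonds + n),
                   bond_params = rbind(top$bond_params, top$bond_params),
                   angles = rbind(top$angles, top$angles + n),
                   angle_params = rbind(top$angle_params, top$angle_params),
                   torsions = rbind(top$torsions, top$torsions + n),
                   torsion_params = rbind(top$torsion_params,
                                          top$torsion_params))
  co_dup <- rbind(co, sweep(co, 2, -c(500, 0, 0)))
  dec_dup <- snapshot_energy(top2, co_dup)
  for (f in c("bond", "angle", "torsion", "lj", "coulomb", "gb", "e_mm",
              "sasa"))
    expect_equal(dec_dup[[f]], 2 * dec[[f]], tolerance = 1e-4,
                 label = paste("term", f))
})

test_that("ensemble averaging is an arithmetic mean with a faithful per-frame series", {
  top <- make_chain_topology(3, charge = 0.2)
  set.seed(42)
  e <- sample_ensemble(top, torsion_spec("vonmises", kappa = 3), 20, seed = 42)
  avg <- ensemble_average(e)
  expect_equal(avg$e_mm_mean, mean(avg$series$e_mm), tolerance = 1e-12)
  expect_equal(avg$e_asa_mean, mean(avg$series$e_asa), tolerance = 1e-12)
  expect_equal(nrow(avg$series), 20L)
  # identical frames average to the single-frame value
  e1 <- ensemble(top, e$xyz[rep(1, 5), ])
  avg1 <- ensemble_average(e1)
  d1 <- snapshot_energy(top, frame_coords(e, 1))
  expect_equal(avg1$e_mm_mean, d1$e_mm, tolerance = 1e-12)
  # strided subsampling uses the requested number of frames
  avg5 <- ensemble_average(e, energy_frames = 5)
  expect_equal(length(avg5$frames_used), 5L)
})
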
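test_that("Kabsch superposition recovers exact rigid transforms and rejects degenerate fits", {
  set.seed(31)
  X <- matrix(rnorm(30), 10)
  s0 <- kabsch_superpose(X, X)
  expect_lt(s0$rmsd, 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)

  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  Y <- sweep(X %*% t(R), 2, -c(1, 2, 3))
  s <- kabsch_superpose(X, Y)
  expect_lt(s$rmsd, 1e-10)
  expect_equal(crossprod(s$rotation), diag(3), tolerance = 1e-9)
  expect_equal(det(s$rotation), 1, tolerance = 1e-9)

  expect_error(kabsch_superpose(X[1:2, ], Y[1:2, ]), "degenerate")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition RMSD equals the quaternion-method oracle on random pairs", {
  set.seed(32)
  for (rep in 1:100) {
    P <- matrix(rnorm(30), 10)
    Q <- matrix(rnorm(30), 10)
    expect_equal(kabsch_superpose(P, Q)$rmsd, quaternion_rmsd(P, Q),
                 tolerance = 1e-9)
  }
})

test_that("rmsd honors fit/measure split and is symmetric and rigid-motion invariant", {
  set.seed(33)
  A <- matrix(rnorm(60), 20)
  expect_equal(rmsd(A, A), 0, tolerance = 1e-12)
  # displace measured atoms by a uniform 1 A after fitting on an immobile set
  B <- A
  B[11:20, 1] <- B[11:20, 1] + 1
  expect_equal(rmsd(A, B, measure = 11:20, fit = 1:10), 1.0,
               tolerance = 1e-9)
  # symmetry and brute-force agreement when fit = measure
  Br <- matrix(rnorm(60), 20)
  expect_equal(rmsd(A, Br), rmsd(Br, A), tolerance = 1e-9)
  sup <- kabsch_superpose(A, Br)
  moved <- apply_transform(A, sup)
  expect_equal(rmsd(A, Br), sqrt(mean(rowSums((moved - Br)^2))),
               tolerance = 1e-12)
  # common rigid transform of both frames leaves RMSD unchanged
  for (rep in 1:10) {
    R <- random_rotation(); t <- rnorm(3)
    A2 <- sweep(A %*% t(R), 2, -t); B2 <- sweep(Br %*% t(R), 2, -t)
    expect_equal(rmsd(A2, B2), rmsd(A, Br), tolerance = 1e-9)
  }
  expect_error(rmsd(A, Br, measure = integer(0)), "empty")
})

test_that("dihedral follows the IUPAC sign convention and matches independent oracles", {
  # planar trans and cis
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(dihedral(trans, 1:4), 180)
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(dihedral(cis, 1:4), 0)
  # constructed -90/+90 geometries, sign checked against the projection
  # triple-product oracle
  g <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, -1, 1))
  expect_equal(dihedral(g, 1:4), -90)
  expect_equal(dihedral_oracle(g, 1:4), -90, tolerance = 1e-9)
  set.seed(34)
  for (rep in 1:50) {
    co <- matrix(rnorm(12), 4)
    expect_equal(dihedral(co, 1:4), dihedral_oracle(co, 1:4),
                 tolerance = 1e-7)
  }
  # rigid-motion invariance; mirror reflection flips the sign
  co <- matrix(rnorm(12), 4)
  R <- random_rotation()
  expect_equal(dihedral(sweep(co %*% t(R), 2, -c(1, 2, 3)), 1:4),
               dihedral(co, 1:4), tolerance = 1e-9)
  mir <- co; mir[, 3] <- -mir[, 3]
  expect_equal(dihedral(mir, 1:4), -dihedral(co, 1:4), tolerance = 1e-9)
  # collinear central bond is undefined
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0))
  expect_error(dihedral(line, 1:4), "collinear")
})

test_that("torsion enumeration counts non-terminal bonds with lowest-index flanks", {
  top <- make_chain_topology(1)  # 4-atom linear chain
  ts <- enumerate_torsions(top)
  expect_equal(ts$n, 1L)
  expect_equal(ts$quads[1, ], c(1L, 2L, 3L, 4L))
  for (n in c(5L, 9L, 23L)) {
    topn <- make_chain_topology(n - 3L)
    expect_equal(enumerate_torsions(topn)$n, n - 3L)
  }
  # toy peptide chain: Nd = 3 * n_residues - 2 (terminal N-CA and C-O bonds
  # excluded), flanking atoms take the lowest index
  toy <- make_toy_topology(3)
  ts3 <- enumerate_torsions(toy)
  expect_equal(ts3$n, 7L)
  expect_equal(ts3$quads[1, ], c(1L, 2L, 3L, 4L))  # psi-like, O as d atom
  nb <- lapply(seq_len(n_atoms(toy)), function(i)
    sort(unique(c(toy$bonds[toy$bonds[, 1] == i, 2],
                  toy$bonds[toy$bonds[, 2] == i, 1]))))
  for (k in seq_len(ts3$n)) {
    q <- ts3$quads[k, ]
    expect_equal(q[1], min(setdiff(nb[[q[2]]], q[3])))
    expect_equal(q[4], min(setdiff(nb[[q[3]]], q[2])))
  }
  nob <- topology(toy$atoms)
  expect_warning(empty <- enumerate_torsions(nob), "no bonds")
  expect_equal(empty$n, 0L)
})

test_that("contact counting matches a brute-force all-pairs scan", {
  # constructed shells: waters at 2.1, 2.9, 3.4 A with cutoff 3.0
  atoms <- data.frame(
    name = c("ZN", "O", "O", "O"), element = c("ZN", "O", "O", "O"),
    resname = c("ZN", "HOH", "HOH", "HOH"), resid = 1:4, chain = "A")
  top <- topology(atoms)
  co <- rbind(c(0, 0, 0), c(2.1, 0, 0), c(0, 2.9, 0), c(0, 0, 3.4))
  e <- ensemble(top, matrix(flatten_2 <- as.numeric(t(co)), 1))
  cs <- count_contacts(e, atom_selection(1), atom_selection(2:4), 3.0)
  expect_equal(cs$counts, 2L)
  # average over frames is the arithmetic mean
  e2 <- ensemble(top, rbind(e$xyz, as.numeric(t(co * 3))))
  cs2 <- count_contacts(e2, atom_selection(1), atom_selection(2:4), 3.0)
  expect_equal(cs2$average, mean(c(2L, 0L)))
  # random configurations vs the double-loop oracle
  set.seed(35)
  for (rep in 1:100) {
    n <- 12L
    coords <- matrix(runif(3 * n, 0, 6), n)
    er <- ensemble(topology(data.frame(
      name = paste0("X", 1:n), element = "C", resname = "UNK",
      resid = 1:n, chain = "A")), matrix(as.numeric(t(coords)), 1))
    ctr <- sample(n, 2); par <- setdiff(seq_len(n), ctr)
    got <- count_contacts(er, atom_selection(ctr), atom_selection(par), 2.5)
    expect_identical(got$counts, brute_contacts(coords, ctr, par, 2.5))
  }
})

test_that("region RMSD table localizes a constructed displacement", {
  top <- make_toy_topology(100)
  set.seed(36)
  ts <- enumerate_torsions(top)
  ref <- build_coordinates_from_torsions(top, runif(ts$n, 150, 210))
  moved <- ref
  idx <- which(top$atoms$resid %in% 10:12)
  moved[idx, 2] <- moved[idx, 2] + 2
  traj <- ensemble(top, matrix(flatten <- as.numeric(t(moved)), 1))
  regions <- list(
    loop10 = select(top, "resid 10-12 and main-chain"),
    far = select(top, "resid 60-70 and main-chain"),
    whole = select(top, "main-chain"))
  tab <- region_rmsd_table(traj, list(start = ref), regions)
  r <- function(nm) tab$rmsd[tab$region == nm]
  expect_gt(r("loop10"), 1.8)
  expect_lt(r("far"), 0.2)
  # whole-main-chain row equals plain rmsd with fit = measure
  mc <- as.integer(select(top, "main-chain"))
  expect_equal(r("whole"), rmsd(moved, ref, measure = mc),
               tolerance = 1e-9)
  # identical frame gives zeros everywhere
  tab0 <- region_rmsd_table(ensemble(top, matrix(as.numeric(t(ref)), 1)),
                            list(start = ref), regions)
  expect_lt(max(tab0$rmsd), 1e-9)
  expect_error(region_rmsd_table(traj, list(start = ref),
                                 list(bad = atom_selection(integer(0)))),
               "no atoms")
})
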
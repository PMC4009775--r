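test_that("free-energy records satisfy the G1/G2/TS identities", {
  top <- make_chain_topology(4, charge = 0.1)
  e <- sample_ensemble(top, torsion_spec("vonmises", kappa = 2), 50,
                       seed = 81)
  suppressWarnings(
    rec <- free_energy_of_ensemble(e, label = "test", energy_frames = 10))
  expect_equal(rec$g2 - rec$g1, rec$ts, tolerance = 1e-12)
  expect_equal(rec$g2, rec$e_mm + rec$e_asa, tolerance = 1e-12)
  expect_lte(rec$g1, rec$g2 + 1e-12)  # S >= 0 here
  # identical frames with discrete entropy: TS = 0, G1 = G2
  co <- frame_coords(e, 1)
  e1 <- ensemble(top, rbind(flatten_coords_test(co), flatten_coords_test(co)))
  suppressWarnings(
    rec1 <- free_energy_of_ensemble(e1, entropy_mode = "discrete"))
  expect_equal(rec1$ts, 0)
  expect_equal(rec1$g1, rec1$g2)
  # a single frame is rejected unless explicitly allowed
  es <- ensemble(top, e$xyz[1, , drop = FALSE])
  expect_error(free_energy_of_ensemble(es), "single frame")
  suppressWarnings(
    recs <- free_energy_of_ensemble(es, allow_single_frame = TRUE))
  expect_equal(recs$ts, 0)
})

test_that("replicate aggregation reproduces the published free-energy table", {
  tb <- reference_tables()$free_energy_runs
  # row-wise recombination: G1 = G2 + printed(-TS) within rounding
  for (form in c("crystal", "nmr")) {
    recs <- records_from_table(tb, form)
    g1 <- vapply(recs, function(r) r$g1, numeric(1))
    expect_lt(max(abs(g1 - tb$g1[tb$form == form])), 0.02)
    sm <- summarize_replicates(recs)
    expect_equal(sm$n, 10L)
  }
  sm_nmr <- summarize_replicates(records_from_table(tb, "nmr"))
  sm_x <- summarize_replicates(records_from_table(tb, "crystal"))
  expect_equal(unname(sm_nmr$mean["g1"]), -12893.79, tolerance = 0.02)
  expect_equal(unname(sm_x$mean["g1"]), -12801.62, tolerance = 0.02)
  expect_equal(unname(-sm_nmr$mean["ts"]), -6972.17, tolerance = 0.02)
  # identical records: mean is the record, sigma 0
  same <- records_from_table(tb, "nmr")[c(1, 1)]
  smi <- summarize_replicates(same)
  expect_equal(unname(smi$sd["g1"]), 0)
  expect_error(summarize_replicates(same[1]), ">= 2")
})

test_that("state comparison has the published sign structure and is antisymmetric", {
  tb <- reference_tables()$free_energy_runs
  a <- summarize_replicates(records_from_table(tb, "crystal"))
  b <- summarize_replicates(records_from_table(tb, "nmr"))
  cmp <- compare_states(a, b)
  # entropy-inclusive stability favors the solution form by ~92 kcal/mol,
  # beyond one replicate sigma; without entropy the sign reverses
  expect_equal(cmp$dg1, -92.17, tolerance = 0.02)
  expect_true(cmp$significant["g1"])
  expect_gt(cmp$dg2, 0)
  expect_lt(cmp$dg1, 0)
  rev <- compare_states(b, a)
  expect_equal(rev$dg1, -cmp$dg1, tolerance = 1e-12)
  expect_equal(rev$dg2, -cmp$dg2, tolerance = 1e-12)
  same <- compare_states(a, a)
  expect_equal(same$dg1, 0)
  expect_false(any(same$significant))
})

test_that("two-state recovery: entropy difference drives G1 against an opposing enthalpy", {
  sys <- make_two_state_system(0, 8, n_torsions = 20, n_frames = 20000,
                               seed = 82, delta_h = -10)
  sa0 <- sasa_params(gamma = 0)  # non-interacting reference chain
  recA <- suppressWarnings(free_energy_of_ensemble(
    sys$ensembleA, sa = sa0, bin_width = 12, energy_frames = 20,
    label = "A"))
  recB <- suppressWarnings(free_energy_of_ensemble(
    sys$ensembleB, sa = sa0, bin_width = 12, energy_frames = 20,
    label = "B"))
  dts <- recB$ts - recA$ts
  expect_equal(dts, sys$truth$dts, tolerance = abs(sys$truth$dts) * 0.05)
  # enthalpy offset is reproduced exactly on the non-interacting chain
  expect_equal(recB$g2 - recA$g2, -10, tolerance = 1e-9)
  # signs: B is enthalpically favored (dG2 < 0) but entropically
  # penalized enough that dG1 > 0
  expect_lt(recB$g2 - recA$g2, 0)
  expect_gt(recB$g1 - recA$g1, 0)
})

test_that("pathway profiles preserve waypoint order, detect barriers and mirror on reversal", {
  top <- make_chain_topology(5)
  mk <- function(seed) sample_ensemble(top, torsion_spec("vonmises",
                                                         mu = 60, kappa = 30),
                                       40, seed = seed)
  # barrier: middle waypoint has a +30 kcal/mol enthalpy offset
  top_hi <- make_chain_topology(5, energy_offset = 30)
  mk_hi <- function(seed) sample_ensemble(top_hi, torsion_spec("vonmises",
                                                               mu = 60,
                                                               kappa = 30),
                                          40, seed = seed)
  wps <- list(`1` = list(mk(1), mk(2)),
              `2` = list(mk_hi(3), mk_hi(4)),
              `3` = list(mk(5), mk(6)))
  prof <- suppressWarnings(build_profile(wps, energy_frames = 10))
  m <- profile_means(prof)
  expect_equal(m$waypoint, 1:3)
  expect_gt(m$g2[2], max(m$g2[c(1, 3)]))  # interior maximum
  expect_gt(m$g1[2], max(m$g1[c(1, 3)]))
  # identical waypoints give a flat profile
  flat <- suppressWarnings(build_profile(
    list(a = list(mk(1)), b = list(mk(1))), energy_frames = 10))
  fm <- profile_means(flat)
  expect_equal(fm$g2[1], fm$g2[2], tolerance = 1e-9)
  # reversal mirrors the values
  revp <- suppressWarnings(build_profile(rev(wps), energy_frames = 10))
  rm_ <- profile_means(revp)
  expect_equal(rm_$g2, rev(m$g2), tolerance = 1e-9)
  expect_error(build_profile(list(a = list(mk(1)))), ">= 2 waypoints")
})

test_that("the replicate table CSV uses the G2 / -TS / G1 layout with Average and sigma rows", {
  tb <- reference_tables()$free_energy_runs
  sums <- list(crystal = summarize_replicates(records_from_table(tb, "crystal")),
               nmr = summarize_replicates(records_from_table(tb, "nmr")))
  f <- tempfile(fileext = ".csv")
  write_free_energy_table(sums, f)
  out <- utils::read.csv(f)
  expect_equal(names(out), c("form", "run", "g2", "minus_ts", "g1"))
  expect_equal(nrow(out), 24L)  # 10 runs + Average + sigma, per form
  avg <- out[out$form == "nmr" & out$run == "Average", ]
  expect_equal(avg$g1, -12893.79, tolerance = 0.02)
  expect_equal(avg$minus_ts, -6972.17, tolerance = 0.02)
})
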
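test_that("torsion histograms are anchored at -180, normalized and circular", {
  top <- make_chain_topology(1)
  # identical frames occupy a single bin with P = 1
  co <- build_coordinates_from_torsions(top, 42)
  e <- ensemble(top, rbind(flatten_coords_test(co), flatten_coords_test(co)))
  ts <- enumerate_torsions(top)
  h <- histogram_torsions(e, ts, 30)[[1]]
  expect_equal(sum(h$p), 1, tolerance = 1e-12)
  expect_equal(sum(h$p > 0), 1L)
  expect_equal(which(h$p > 0), floor((42 + 180) / 30) + 1L)
  # 12 bin-center angles at w = 30 are exactly uniform
  angs <- matrix(seq(-165, 165, by = 30), ncol = 1)
  hu <- histogram_angles(angs, 30)[[1]]
  expect_equal(hu$p, rep(1 / 12, 12), tolerance = 1e-12)
  # -180 goes to the first bin; +180 wraps onto it (identified angle)
  hb <- histogram_angles(matrix(c(-180, 180), ncol = 1), 30)[[1]]
  expect_equal(hb$p[1], 1)
  expect_error(histogram_angles(angs, 25), "divide")
})

test_that("discrete and differential entropies obey their closed forms and bounds", {
  delta <- histogram_angles(matrix(rep(10, 50), ncol = 1), 30)
  expect_equal(entropy(delta, mode = "discrete")$s, 0)
  unif <- histogram_angles(matrix(seq(-165, 165, by = 30), ncol = 1), 30)
  expect_equal(entropy(unif, mode = "discrete")$s, log(12), tolerance = 1e-12)
  expect_equal(entropy(unif, mode = "differential")$s, log(2 * pi),
               tolerance = 1e-12)
  # differential uniform entropy is bin-width independent
  for (w in c(12, 30, 60, 120)) {
    centers <- seq(-180 + w / 2, 180 - w / 2, by = w)
    hu <- histogram_angles(matrix(centers, ncol = 1), w)
    expect_equal(entropy(hu, mode = "differential")$s, log(2 * pi),
                 tolerance = 1e-12)
  }
  # discrete entropy is maximized by uniformity: any perturbation decreases it
  set.seed(51)
  for (rep in 1:20) {
    p <- rep(1 / 12, 12)
    d <- runif(12); d <- d - mean(d)
    p2 <- p + 0.05 * d
    p2 <- pmax(p2, 1e-9); p2 <- p2 / sum(p2)
    s2 <- -sum(p2 * log(p2))
    expect_lt(s2, log(12) + 1e-12)
  }
  # additivity over independent torsions
  set.seed(52)
  a1 <- matrix(runif(5000, -180, 180), ncol = 1)
  a2 <- matrix(rvonmises(5000, 0, 3) * 180 / pi, ncol = 1)
  s_joint <- entropy(histogram_angles(cbind(a1, a2), 30))$s
  s_sep <- entropy(histogram_angles(a1, 30))$s +
    entropy(histogram_angles(a2, 30))$s
  expect_equal(s_joint, s_sep, tolerance = 1e-12)
  expect_error(entropy(c(histogram_angles(a1, 30), histogram_angles(a1, 60))),
               "mixed")
})

test_that("TS conversion uses kB T with entropy in nats", {
  expect_equal(ts_term(1, 300), 0.59616123, tolerance = 1e-6)
  expect_equal(ts_term(0, 300), 0)
  unif <- histogram_angles(matrix(seq(-165, 165, by = 30), ncol = 1), 30)
  res <- entropy(unif, mode = "differential", temperature = 300)
  expect_equal(res$ts, 0.0019872041 * 300 * log(2 * pi), tolerance = 1e-9)
  expect_equal(res$ts, 1.0956, tolerance = 1e-3)
  expect_error(ts_term(1, -1), "temperature")
})

test_that("estimator recovers analytic entropies of synthetic distributions", {
  r1 <- entropy_parameter_recovery(torsion_spec("uniform"), 1e5, seed = 3)
  expect_lt(abs(r1$error), 0.01)
  r2 <- entropy_parameter_recovery(torsion_spec("vonmises", kappa = 2),
                                   1e5, seed = 4)
  expect_equal(r2$analytic, 1.2663, tolerance = 1e-4)
  expect_lt(abs(r2$error), 0.03)
  r3 <- entropy_parameter_recovery(torsion_spec("fixed", theta0 = 17),
                                   1000, seed = 5, mode = "discrete")
  expect_identical(r3$estimate, 0)
  # joint refinement (n = 1e5, w = 12) tightens the von Mises error
  r4 <- entropy_parameter_recovery(torsion_spec("vonmises", kappa = 2),
                                   1e5, seed = 4, bin_width = 12)
  expect_lt(abs(r4$error), 0.05)
  expect_lt(abs(r4$error), abs(r2$error))
})

test_that("bin-width sensitivity is flat for smooth distributions except at coarse bins", {
  top <- make_chain_topology(5)
  e <- sample_ensemble(top, torsion_spec("vonmises", mu = 60, kappa = 2),
                       20000, seed = 53)
  ts <- enumerate_torsions(top)
  tab <- bin_sensitivity(e, ts)
  expect_equal(tab$bin_width, c(12, 30, 60, 120))
  fine <- tab$ts[tab$bin_width %in% c(12, 30, 60)]
  spread_fine <- diff(range(fine)) / abs(mean(fine))
  dev120 <- abs(tab$ts[tab$bin_width == 120] - mean(fine)) / abs(mean(fine))
  expect_lt(spread_fine, 0.08)
  expect_gt(dev120, 2 * spread_fine)
  # delta distributions: discrete-mode TS is zero at every width
  co <- build_coordinates_from_torsions(top, rep(42, ts$n))
  ed <- ensemble(top, rbind(flatten_coords_test(co), flatten_coords_test(co)))
  tabd <- bin_sensitivity(ed, ts, mode = "discrete")
  expect_equal(tabd$ts, rep(0, 4))
  # uniform torsions: differential TS identical across widths up to noise
  eu <- sample_ensemble(top, torsion_spec("uniform"), 20000, seed = 54)
  tabu <- bin_sensitivity(eu, ts)
  expect_lt(attr(tabu, "relative_spread"), 0.02)
})
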
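#' Free energy of a conformational ensemble (GBSA enthalpy + torsion entropy)
#'
#' Chains the GBSA ensemble average and the dihedral-histogram entropy into
#' the two free energies
#' \deqn{G_1 = \langle E^{MM}\rangle + \langle E^{ASA}\rangle - T S, \qquad
#'       G_2 = \langle E^{MM}\rangle + \langle E^{ASA}\rangle}
#' (kcal/mol), i.e. with and without the conformational-entropy term.
#' \code{G2 - G1 = TS} holds identically for every record.
#'
#' @param e \code{ensemble} with a parameterized topology; at least 2
#'   frames unless \code{allow_single_frame} (entropy needs a distribution)
#' @param gb a \code{\link{gb_params}}
#' @param sa a \code{\link{sasa_params}}
#' @param torsions \code{torsion_set}; default all-rotatable torsions of
#'   the topology
#' @param entropy_mode \code{"differential"} (default) or \code{"discrete"}
#' @param bin_width histogram bin width in degrees (default 30)
#' @param temperature temperature in K (default 300)
#' @param energy_frames optional cap on frames used for the energy average
#'   (see \code{\link{ensemble_average}}); the entropy always uses all
#'   frames
#' @param label form label
#' @param run replicate/run identifier
#' @param allow_single_frame if TRUE, a 1-frame ensemble yields TS = 0 and
#'   G1 = G2 instead of an error
#' @return object of class \code{free_energy_record}
#' @export
free_energy_of_ensemble <- function(e, gb = gb_params(), sa = sasa_params(),
                                    torsions = NULL,
                                    entropy_mode = c("differential",
                                                     "discrete"),
                                    bin_width = 30, temperature = 300,
                                    energy_frames = NULL,
                                    label = "form", run = 1L,
                                    allow_single_frame = FALSE) {
  entropy_mode <- match.arg(entropy_mode)
  if (n_frames(e) < 2L && !allow_single_frame)
    stop("entropy is undefined for a single frame; need >= 2 frames ",
         "(or set allow_single_frame = TRUE to get G2 only, TS = 0)")
  if (is.null(torsions)) torsions <- enumerate_torsions(e$topology)
  avg <- ensemble_average(e, gb, sa, energy_frames = energy_frames)
  if (n_frames(e) >= 2L && torsions$n > 0L) {
    hs <- histogram_torsions(e, torsions, bin_width)
    ent <- entropy(hs, mode = entropy_mode, temperature = temperature)
    s <- ent$s; ts <- ent$ts
  } else {
    s <- 0; ts <- 0
  }
  free_energy_record(label = label, run = run,
                     e_mm = avg$e_mm_mean, e_asa = avg$e_asa_mean,
                     s = s, ts = ts, mode = entropy_mode,
                     temperature = temperature, n_frames = n_frames(e),
                     nd = torsions$n)
}

#' Assemble a free-energy record from its components
#'
#' @param label form label
#' @param run replicate id
#' @param e_mm ensemble-averaged E^MM (kcal/mol)
#' @param e_asa ensemble-averaged E^ASA (kcal/mol)
#' @param s conformational entropy (nats)
#' @param ts TS term (kcal/mol); default \code{kB * temperature * s}
#' @param mode entropy mode used
#' @param temperature temperature (K)
#' @param n_frames frame count
#' @param nd torsion count
#' @export
free_energy_record <- function(label, run = 1L, e_mm = 0, e_asa = 0,
                               s = 0, ts = KB_KCALMOL * temperature * s,
                               mode = "differential", temperature = 300,
                               n_frames = NA_integer_, nd = NA_integer_) {
  g2 <- e_mm + e_asa
  structure(list(label = label, run = run, e_mm = e_mm, e_asa = e_asa,
                 s = s, ts = ts, g1 = g2 - ts, g2 = g2, mode = mode,
                 temperature = temperature, n_frames = n_frames, nd = nd),
            class = "free_energy_record")
}

#' @export
print.free_energy_record <- function(x, ...) {
  cat(sprintf("free energy '%s' (run %s): <E^MM> = %.3f, <E^ASA> = %.3f, TS = %.3f\n  G1 = %.3f, G2 = %.3f kcal/mol (%s entropy, %g K)\n",
              x$label, as.character(x$run), x$e_mm, x$e_asa, x$ts,
              x$g1, x$g2, x$mode, x$temperature))
  invisible(x)
}

#' Aggregate replicate free-energy records
#'
#' Arithmetic mean and standard deviation of G1, G2 and TS across
#' independent replicate runs of one form. The default deviation uses the
#' population (n) denominator, the convention that reproduces the
#' published replicate table's sigma row exactly; the sample (n - 1)
#' estimator is available via \code{sd_method}.
#'
#' @param records list of at least two \code{free_energy_record}s
#' @param sd_method \code{"population"} (default) or \code{"sample"}
#' @return object of class \code{replicate_summary}
#' @export
summarize_replicates <- function(records,
                                 sd_method = c("population", "sample")) {
  sd_method <- match.arg(sd_method)
  if (length(records) < 2L) stop("need >= 2 replicate records")
  stopifnot(all(vapply(records, inherits, logical(1), "free_energy_record")))
  pull <- function(f) vapply(records, function(r) r[[f]], numeric(1))
  g1 <- pull("g1"); g2 <- pull("g2"); ts <- pull("ts")
  modes <- unique(vapply(records, function(r) r$mode, character(1)))
  temps <- unique(vapply(records, function(r) r$temperature, numeric(1)))
  if (length(modes) != 1L) stop("records mix entropy modes")
  if (length(temps) != 1L) stop("records mix temperatures")
  dev <- if (sd_method == "population")
    function(x) sqrt(mean((x - mean(x))^2))
  else stats::sd
  structure(list(
    label = records[[1]]$label, records = records, n = length(records),
    mean = c(g1 = mean(g1), g2 = mean(g2), ts = mean(ts)),
    sd = c(g1 = dev(g1), g2 = dev(g2), ts = dev(ts)),
    sd_method = sd_method, mode = modes, temperature = temps),
    class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("replicate_summary '%s' (%d runs):\n", x$label, x$n))
  cat(sprintf("  G1 = %.2f +/- %.2f, G2 = %.2f +/- %.2f, TS = %.2f +/- %.2f kcal/mol\n",
              x$mean["g1"], x$sd["g1"], x$mean["g2"], x$sd["g2"],
              x$mean["ts"], x$sd["ts"]))
  invisible(x)
}

#' Compare two forms (two-state stability)
#'
#' Differences are state B minus state A, with standard deviations
#' propagated in quadrature. The significance flag follows the loose
#' one-standard-deviation criterion customary for this kind of replicate
#' table: TRUE when |dG| exceeds the larger of the two replicate sigmas
#' (not a formal test).
#'
#' @param a,b \code{replicate_summary} objects with matching entropy mode
#'   and temperature
#' @return list of class \code{state_comparison}: \code{dg1}, \code{dg2},
#'   \code{dts}, propagated \code{sd}, logical \code{significant} per
#'   quantity
#' @export
compare_states <- function(a, b) {
  stopifnot(inherits(a, "replicate_summary"), inherits(b, "replicate_summary"))
  if (a$mode != b$mode) stop("entropy mode mismatch between states")
  if (a$temperature != b$temperature) stop("temperature mismatch between states")
  delta <- b$mean - a$mean
  sd_q <- sqrt(a$sd^2 + b$sd^2)
  sig <- abs(delta) > pmax(a$sd, b$sd)
  structure(list(a = a$label, b = b$label,
                 dg1 = unname(delta["g1"]), dg2 = unname(delta["g2"]),
                 dts = unname(delta["ts"]), sd = sd_q, significant = sig),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("state comparison %s -> %s (B - A):\n", x$a, x$b))
  cat(sprintf("  dG1 = %.2f (sig: %s), dG2 = %.2f (sig: %s), dTS = %.2f kcal/mol\n",
              x$dg1, x$significant["g1"], x$dg2, x$significant["g2"], x$dts))
  invisible(x)
}

#' Free-energy profile along an ordered set of pathway waypoints
#'
#' For each waypoint (an ordered label plus one ensemble per replicate),
#' computes replicate free-energy records and their summary, producing the
#' G1 and G2 series along the pathway.
#'
#' @param waypoints named list (ordered); each element a list of replicate
#'   \code{ensemble}s (>= 1)
#' @param direction direction tag, e.g. \code{"A->B"}
#' @param ... passed to \code{\link{free_energy_of_ensemble}}
#' @return object of class \code{free_energy_profile}: \code{table}
#'   (waypoint, replicate, G1, G2, TS), \code{summaries}, \code{direction}
#' @export
build_profile <- function(waypoints, direction = "A->B", ...) {
  if (length(waypoints) < 2L) stop("need >= 2 waypoints")
  if (is.null(names(waypoints)) || any(!nzchar(names(waypoints))))
    names(waypoints) <- as.character(seq_along(waypoints))
  rows <- list(); summaries <- list()
  for (w in seq_along(waypoints)) {
    reps <- waypoints[[w]]
    if (!length(reps)) stop("missing ensemble(s) for waypoint ", w)
    recs <- lapply(seq_along(reps), function(k)
      free_energy_of_ensemble(reps[[k]], label = names(waypoints)[w],
                              run = k, ...))
    for (r in recs)
      rows[[length(rows) + 1L]] <- data.frame(
        waypoint = w, label = names(waypoints)[w], replicate = r$run,
        g1 = r$g1, g2 = r$g2, ts = r$ts)
    summaries[[w]] <- if (length(recs) >= 2L) summarize_replicates(recs)
                      else recs[[1]]
  }
  structure(list(table = do.call(rbind, rows), summaries = summaries,
                 direction = direction),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free_energy_profile (%s): %d waypoints\n", x$direction,
              length(x$summaries)))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Mean G1/G2 per waypoint of a profile
#' @param profile a \code{free_energy_profile}
#' @return data.frame with \code{waypoint}, \code{g1}, \code{g2}
#' @export
profile_means <- function(profile) {
  tb <- profile$table
  out <- do.call(rbind, lapply(split(tb, tb$waypoint), function(d)
    data.frame(waypoint = d$waypoint[1], label = d$label[1],
               g1 = mean(d$g1), g2 = mean(d$g2), ts = mean(d$ts))))
  rownames(out) <- NULL
  out
}

#' Write a replicate free-energy table as CSV
#'
#' Layout: one row per run with G2, -TS and G1 per form, plus Average and
#' sigma rows. Note the sign convention of the third column: the printed
#' value is minus the TS term, so G1 = G2 + (-TS) row-wise; the header
#' names the column \code{minus_ts} to make this explicit.
#'
#' @param summaries named list of \code{replicate_summary}s (one per form)
#' @param path output CSV path
#' @export
write_free_energy_table <- function(summaries, path) {
  blocks <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    runs <- data.frame(
      form = nm,
      run = vapply(s$records, function(r) as.character(r$run), character(1)),
      g2 = vapply(s$records, function(r) r$g2, numeric(1)),
      minus_ts = -vapply(s$records, function(r) r$ts, numeric(1)),
      g1 = vapply(s$records, function(r) r$g1, numeric(1)))
    rbind(runs,
          data.frame(form = nm, run = "Average", g2 = s$mean["g2"],
                     minus_ts = -s$mean["ts"], g1 = s$mean["g1"]),
          data.frame(form = nm, run = "sigma", g2 = s$sd["g2"],
                     minus_ts = s$sd["ts"], g1 = s$sd["g1"]))
  })
  utils::write.csv(do.call(rbind, blocks), path, row.names = FALSE)
  invisible(path)
}
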
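#' Load and validate a run configuration
#'
#' A configuration is a named list (or a YAML file holding one) with:
#' \describe{
#'   \item{states}{for \code{\link{run_state_compare}}: a list of exactly
#'     two state blocks, each either \code{synthetic} (with
#'     \code{n_torsions}, \code{distribution} = fixed/uniform/vonmises,
#'     \code{mu}, \code{kappa}, \code{n_frames}, optional
#'     \code{energy_offset}) or real inputs (\code{structure} +
#'     \code{topology} paths); exactly one of the two per state.}
#'   \item{endpoints}{for \code{\link{run_pathway}}: two torsion vectors
#'     (synthetic) or two structure paths.}
#'   \item{replicates, seed}{replicate count and base seed (replicate k of
#'     state j uses \code{seed + 100 * j + k}; seeds are always logged).}
#'   \item{entropy_mode, bin_width, temperature, contact_cutoff,
#'     energy_frames, waypoints, output_dir}{analysis parameters with the
#'     package defaults.}
#' }
#'
#' @param config named list or path to a YAML file
#' @return validated config list of class \code{run_config}
#' @export
read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  cfg <- utils::modifyList(list(
    replicates = 2L, seed = 1L, entropy_mode = "differential",
    bin_width = 30, temperature = 300, contact_cutoff = 3.0,
    energy_frames = 200L, waypoints = 10L, morph_frames = 101L,
    waypoint_frames = 100L, waypoint_jitter_kappa = 50,
    output_dir = NULL), config)
  if (!is.null(cfg$states)) {
    if (length(cfg$states) != 2L)
      stop("config field 'states' must list exactly two states")
    for (j in 1:2) {
      st <- cfg$states[[j]]
      has_syn <- !is.null(st$synthetic)
      has_real <- !is.null(st$structure)
      if (has_syn == has_real)
        stop(sprintf(
          "states[[%d]]: exactly one of 'synthetic' or 'structure' required", j))
      if (has_real && is.null(st$topology))
        stop(sprintf("states[[%d]]: real input needs a 'topology' path", j))
    }
  }
  structure(cfg, class = "run_config")
}

state_label <- function(st, j) st$label %||% paste0("state", c("A", "B")[j])

# materialize one replicate ensemble for a state block
state_ensemble <- function(st, cfg, seed) {
  if (!is.null(st$synthetic)) {
    sy <- st$synthetic
    nt <- sy$n_torsions %||% 10L
    top <- make_chain_topology(nt, energy_offset = sy$energy_offset %||% 0,
                               charge = sy$charge %||% 0)
    spec <- switch(sy$distribution %||% "uniform",
      uniform = torsion_spec("uniform"),
      fixed = torsion_spec("fixed", theta0 = sy$theta0 %||% 180),
      vonmises = torsion_spec("vonmises", mu = sy$mu %||% 0,
                              kappa = sy$kappa %||% 1),
      stop("unknown synthetic distribution: ", sy$distribution))
    sample_ensemble(top, spec, sy$n_frames %||% 1000L, seed = seed)
  } else {
    e <- read_structure(st$structure)
    param <- read_topology(st$topology)
    e$topology <- assign_parameters(e$topology, param)
    strip_solvent(e)
  }
}

#' Two-state stability comparison workflow
#'
#' For each of two configured states, generates (or reads) \code{replicates}
#' independent ensembles, computes their GBSA + entropy free-energy
#' records, aggregates them into replicate summaries, and compares the
#' states. When an output directory is set, writes the replicate
#' free-energy table (G2 / -TS / G1 layout with Average and sigma rows),
#' the per-run log of seeds and parameters, and, for ensembles containing
#' a zinc site and waters, the contact series.
#'
#' @param config see \code{\link{read_run_config}}
#' @return list of class \code{compare_report}: \code{summaries} (per
#'   state), \code{comparison}, \code{log}
#' @export
run_state_compare <- function(config) {
  cfg <- read_run_config(config)
  if (is.null(cfg$states)) stop("config lacks the 'states' block")
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  say("run_state_compare: replicates=%d seed=%d entropy_mode=%s bin_width=%g T=%g",
      cfg$replicates, cfg$seed, cfg$entropy_mode, cfg$bin_width,
      cfg$temperature)
  say("defaults in effect: contact_cutoff=%g gamma=%g probe=%g energy_frames=%s",
      cfg$contact_cutoff, sasa_params()$gamma, sasa_params()$probe,
      as.character(cfg$energy_frames))
  summaries <- list()
  for (j in 1:2) {
    st <- cfg$states[[j]]
    lab <- state_label(st, j)
    recs <- list()
    for (k in seq_len(cfg$replicates)) {
      seed <- (st$seed %||% (cfg$seed + 100L * j)) + k
      say("state %s replicate %d: seed %d", lab, k, seed)
      e <- state_ensemble(st, cfg, seed)
      recs[[k]] <- free_energy_of_ensemble(
        e, entropy_mode = cfg$entropy_mode, bin_width = cfg$bin_width,
        temperature = cfg$temperature, energy_frames = cfg$energy_frames,
        label = lab, run = k)
    }
    summaries[[lab]] <- summarize_replicates(recs)
  }
  comparison <- compare_states(summaries[[1]], summaries[[2]])
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_free_energy_table(summaries,
                            file.path(cfg$output_dir, "free_energy_table.csv"))
    writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  }
  structure(list(summaries = summaries, comparison = comparison, log = log),
            class = "compare_report")
}

#' @export
print.compare_report <- function(x, ...) {
  for (s in x$summaries) print(s)
  print(x$comparison)
  invisible(x)
}

#' Pathway free-energy profile workflow
#'
#' Builds a geometric morph between two endpoint conformations, analyzes
#' it by PCA, selects equal-arc-length waypoints on the (PC1, PC2) path,
#' generates per-waypoint replicate ensembles by small-amplitude torsion
#' resampling around each waypoint's torsion values (a stand-in for a
#' restrained simulation at each waypoint), and assembles the G1/G2
#' profile.
#'
#' Endpoints are configured as \code{endpoints$torsionsA/torsionsB}
#' (degrees, on a synthetic chain of \code{n_torsions}) or as two
#' structure paths plus a topology.
#'
#' @param config see \code{\link{read_run_config}}
#' @return list of class \code{pathway_report}: \code{profile},
#'   \code{pca}, \code{waypoint_frames}, \code{log}
#' @export
run_pathway <- function(config) {
  cfg <- read_run_config(config)
  ep <- cfg$endpoints
  if (is.null(ep)) stop("config lacks the 'endpoints' block")
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  if (!is.null(ep$torsionsA)) {
    nt <- length(ep$torsionsA)
    if (length(ep$torsionsB) != nt)
      stop("endpoint torsion vectors differ in length")
    offs <- ep$energy_offsets %||% rep(0, cfg$waypoints)
    top <- make_chain_topology(nt)
    confA <- build_coordinates_from_torsions(top, ep$torsionsA)
    confB <- build_coordinates_from_torsions(top, ep$torsionsB)
  } else {
    eA <- read_structure(ep$structureA); eB <- read_structure(ep$structureB)
    param <- read_topology(ep$topology)
    top <- assign_parameters(eA$topology, param)
    confA <- frame_coords(eA, 1L); confB <- frame_coords(eB, 1L)
    offs <- rep(0, cfg$waypoints)
  }
  say("run_pathway: %d morph frames, %d waypoints, %d frames/waypoint, seed %d",
      cfg$morph_frames, cfg$waypoints, cfg$waypoint_frames, cfg$seed)
  path <- morph(confA, confB, cfg$morph_frames, top)
  aligned <- align_ensemble(path)
  mc <- which(top$atoms$name %in% c("N", "CA", "C", "O"))
  model <- pca_ensemble(aligned, selection = if (length(mc)) mc)
  wp <- select_waypoints(model, n = cfg$waypoints)
  say("waypoint frame indices: %s", paste(wp, collapse = ", "))
  ts <- enumerate_torsions(top)
  # torsions of a morph frame; a Cartesian interpolation can pass through
  # a geometrically degenerate frame, in which case the nearest
  # non-degenerate neighbor frame is used
  frame_torsions <- function(f) {
    for (g in unique(pmin(pmax(f + c(0, 1, -1, 2, -2), 1), n_frames(path)))) {
      out <- tryCatch(
        vapply(seq_len(ts$n), function(q)
          dihedral(frame_coords(path, g), ts$quads[q, ]), numeric(1)),
        error = function(e) NULL)
      if (!is.null(out)) {
        if (g != f) say("waypoint frame %d degenerate; torsions from frame %d",
                        f, g)
        return(out)
      }
    }
    stop("no measurable torsions near morph frame ", f)
  }
  waypoints <- list()
  for (k in seq_along(wp)) {
    base <- frame_torsions(wp[k])
    wtop <- top
    wtop$energy_offset <- offs[k]
    reps <- list()
    for (r in 1:2) {
      seed <- cfg$seed + 1000L * k + r
      specs <- lapply(base, function(th)
        torsion_spec("vonmises", mu = th, kappa = cfg$waypoint_jitter_kappa))
      reps[[r]] <- sample_ensemble(wtop, specs, cfg$waypoint_frames,
                                   seed = seed)
      say("waypoint %d replicate %d: seed %d", k, r, seed)
    }
    waypoints[[as.character(k)]] <- reps
  }
  profile <- build_profile(waypoints, direction = ep$direction %||% "A->B",
                           entropy_mode = cfg$entropy_mode,
                           bin_width = cfg$bin_width,
                           temperature = cfg$temperature,
                           energy_frames = cfg$energy_frames)
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_projections(model, file.path(cfg$output_dir, "projections.csv"),
                      waypoints = wp)
    utils::write.csv(profile$table,
                     file.path(cfg$output_dir, "profile.csv"),
                     row.names = FALSE)
    writeLines(log, file.path(cfg$output_dir, "run_log.txt"))
  }
  structure(list(profile = profile, pca = model, waypoint_frames = wp,
                 log = log), class = "pathway_report")
}

#' @export
print.pathway_report <- function(x, ...) {
  print(x$profile)
  invisible(x)
}
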
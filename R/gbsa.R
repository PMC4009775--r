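#' Generalized-Born model parameters
#'
#' Defaults follow common practice for the Hawkins pairwise-descreening
#' (HCT) GB flavor: interior dielectric 1, solvent dielectric 78.5,
#' electrostatic constant 332.06 kcal A / mol / e^2, dielectric offset
#' 0.09 A. Per-atom intrinsic radii and screening factors come from the
#' topology.
#'
#' @param eps_in interior (solute) dielectric
#' @param eps_out solvent dielectric (must exceed \code{eps_in})
#' @param ke electrostatic constant (kcal A / mol / e^2)
#' @param offset dielectric offset subtracted from intrinsic radii (A)
#' @export
gb_params <- function(eps_in = 1.0, eps_out = 78.5, ke = 332.06,
                      offset = 0.09) {
  stopifnot_scalar_number(eps_in, "eps_in", positive = TRUE)
  stopifnot_scalar_number(eps_out, "eps_out", positive = TRUE)
  if (eps_out <= eps_in) stop("solvent dielectric must exceed interior dielectric")
  structure(list(eps_in = eps_in, eps_out = eps_out, ke = ke,
                 offset = offset), class = "gb_params")
}

#' Surface-area model parameters
#'
#' @param probe probe radius in A (default 1.4, a water-sized probe)
#' @param n_points quasi-uniform sphere sample points per atom (>= 92;
#'   default 960)
#' @param gamma surface-tension coefficient, kcal/mol/A^2 (default 0.005)
#' @param b constant offset, kcal/mol (default 0)
#' @export
sasa_params <- function(probe = 1.4, n_points = 960, gamma = 0.005, b = 0) {
  if (probe < 0) stop("probe radius must be >= 0")
  if (n_points < 92) stop("n_points must be >= 92")
  structure(list(probe = probe, n_points = as.integer(n_points),
                 gamma = gamma, b = b), class = "sasa_params")
}

#' Effective Born radii by Hawkins pairwise descreening (HCT)
#'
#' The inverse effective radius of atom i is its inverse reduced intrinsic
#' radius (intrinsic radius minus the dielectric offset) minus the sum over
#' all other atoms of the closed-form HCT descreening integral with the
#' neighbor's screened reduced radius. HCT radii are not guaranteed to
#' exceed the intrinsic radius; non-positive inverse radii (pathological
#' overlaps) are clamped to the reduced intrinsic radius with a warning and
#' flagged in the \code{clamped} attribute.
#'
#' @param top parameterized \code{topology} (intrinsic radii must exceed the
#'   dielectric offset)
#' @param coords n x 3 coordinates (A)
#' @param params a \code{\link{gb_params}}
#' @return numeric vector of per-atom effective radii (A)
#' @export
effective_born_radii <- function(top, coords, params = gb_params()) {
  coords <- as_coord_matrix(coords)
  n <- n_atoms(top)
  rho <- top$atoms$gb_radius - params$offset
  if (any(is.na(rho))) stop("topology lacks GB radii")
  if (any(rho <= 0)) stop("intrinsic GB radius must exceed the dielectric offset")
  scr <- top$atoms$gb_screen
  if (any(is.na(scr))) stop("topology lacks GB screening factors")
  if (n == 1L) return(rho)
  d2 <- as.matrix(stats::dist(coords))^2
  r <- sqrt(d2)
  sr <- matrix(scr * rho, n, n, byrow = TRUE)   # screened radius of column atom j
  rho_i <- matrix(rho, n, n)                    # radius of row atom i
  U <- r + sr
  L <- pmax(abs(r - sr), rho_i)
  active <- rho_i < U & r > 0
  term <- matrix(0, n, n)
  idx <- which(active)
  rL <- L[idx]; rU <- U[idx]; rr <- r[idx]; rs <- sr[idx]
  term[idx] <- 0.5 * (1 / rL - 1 / rU +
                        (rr / 4) * (1 / rU^2 - 1 / rL^2) +
                        (1 / (2 * rr)) * log(rL / rU) +
                        (rs^2 / (4 * rr)) * (1 / rL^2 - 1 / rU^2))
  diag(term) <- 0
  inv_eff <- 1 / rho - rowSums(term)
  clamped <- inv_eff <= 0
  if (any(clamped)) {
    warning(sprintf("%d atom(s) with non-positive inverse Born radius; clamped to reduced intrinsic radius",
                    sum(clamped)))
    inv_eff[clamped] <- 1 / rho[clamped]
  }
  out <- 1 / inv_eff
  attr(out, "clamped") <- clamped
  out
}

#' GB polar solvation energy (Still pairwise form)
#'
#' \deqn{E = -\frac{k_e}{2}\left(\frac{1}{\epsilon_{in}} -
#'   \frac{1}{\epsilon_{out}}\right) \sum_{i,j}
#'   \frac{q_i q_j}{f_{GB}(r_{ij}, R_i, R_j)}}
#' with \eqn{f_{GB} = \sqrt{r^2 + R_i R_j \exp(-r^2 / (4 R_i R_j))}}. The
#' double sum runs over all ordered pairs including the i = j self terms
#' (diagonal once, off-diagonal twice via the 1/2 prefactor).
#'
#' @param top parameterized \code{topology}
#' @param coords n x 3 coordinates
#' @param radii effective Born radii from \code{\link{effective_born_radii}}
#' @param params a \code{\link{gb_params}}
#' @return energy in kcal/mol
#' @export
gb_polar_energy <- function(top, coords, radii, params = gb_params()) {
  coords <- as_coord_matrix(coords)
  n <- n_atoms(top)
  if (length(radii) != n) stop("radii length does not match atom count")
  q <- top$atoms$charge
  if (any(is.na(q))) stop("topology lacks partial charges")
  pre <- -0.5 * params$ke * (1 / params$eps_in - 1 / params$eps_out)
  if (n == 1L) return(pre * q^2 / radii)
  r2 <- as.matrix(stats::dist(coords))^2
  RR <- outer(radii, radii)
  fgb <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  diag(fgb) <- radii
  pre * sum(outer(q, q) / fgb)
}

#' Surface-area (nonpolar) solvation energy
#'
#' Linear surface-area model: \code{E = gamma * SASA + b}.
#'
#' @param sasa_total total solvent-accessible surface area (A^2, >= 0)
#' @param params a \code{\link{sasa_params}}
#' @return energy in kcal/mol
#' @export
asa_energy <- function(sasa_total, params = sasa_params()) {
  if (sasa_total < 0) stop("SASA must be >= 0")
  params$gamma * sasa_total + params$b
}

#' Vacuum molecular-mechanics energy of one frame
#'
#' AMBER functional form: harmonic bonds \eqn{\sum k_b (b - b_0)^2} and
#' angles \eqn{\sum k_\theta (\theta - \theta_0)^2}, cosine torsions
#' \eqn{\sum (V_n/2)(1 + \cos(n\phi - \gamma))}, 12-6 Lennard-Jones with
#' Rmin/2 + epsilon combination rules, and Coulomb \eqn{k_e q_i q_j / r}.
#' 1-2 and 1-3 pairs are excluded from the nonbonded sums; 1-4 pairs are
#' scaled. No distance cutoffs are applied.
#'
#' @param top parameterized \code{topology}
#' @param coords n x 3 coordinates
#' @param ke electrostatic constant (kcal A / mol / e^2)
#' @param scale14_ee 1-4 electrostatic scale factor (default 1/1.2)
#' @param scale14_lj 1-4 Lennard-Jones scale factor (default 1/2)
#' @return list with components \code{bond}, \code{angle}, \code{torsion},
#'   \code{lj}, \code{coulomb} (kcal/mol)
#' @export
mm_energy <- function(top, coords, ke = 332.06,
                      scale14_ee = 1 / 1.2, scale14_lj = 0.5) {
  coords <- as_coord_matrix(coords)
  a <- top$atoms
  if (any(is.na(a$charge)) || any(is.na(a$rmin2)) || any(is.na(a$eps)))
    stop("topology is not fully parameterized (missing charge/LJ parameters)")
  e_bond <- 0
  if (nrow(top$bonds)) {
    if (is.null(top$bond_params)) stop("missing bond parameters")
    d <- sqrt(rowSums((coords[top$bonds[, 1], , drop = FALSE] -
                         coords[top$bonds[, 2], , drop = FALSE])^2))
    e_bond <- sum(top$bond_params$kb * (d - top$bond_params$b0)^2)
  }
  e_angle <- 0
  if (!is.null(top$angles) && nrow(top$angles)) {
    if (is.null(top$angle_params)) stop("missing angle parameters")
    v1 <- coords[top$angles[, 1], , drop = FALSE] -
      coords[top$angles[, 2], , drop = FALSE]
    v2 <- coords[top$angles[, 3], , drop = FALSE] -
      coords[top$angles[, 2], , drop = FALSE]
    cosang <- rowdot(v1, v2) / sqrt(rowdot(v1, v1) * rowdot(v2, v2))
    th <- acos(pmin(1, pmax(-1, cosang)))
    th0 <- top$angle_params$theta0 * pi / 180
    e_angle <- sum(top$angle_params$ktheta * (th - th0)^2)
  }
  e_torsion <- 0
  if (!is.null(top$torsions) && nrow(top$torsions)) {
    if (is.null(top$torsion_params)) stop("missing torsion parameters")
    phi <- vapply(seq_len(nrow(top$torsions)), function(k)
      dihedral(coords, top$torsions[k, ]), numeric(1)) * pi / 180
    tp <- top$torsion_params
    e_torsion <- sum((tp$vn / 2) *
                       (1 + cos(tp$periodicity * phi - tp$gamma * pi / 180)))
  }
  # nonbonded: all pairs minus exclusions, 1-4 scaled
  n <- nrow(coords)
  e_lj <- 0; e_coul <- 0
  if (n > 1L) {
    ex <- exclusion_lists(top)
    pk <- function(m) if (nrow(m)) m[, 1] + n * (m[, 2] - 1L) else integer(0)
    iu <- which(upper.tri(matrix(0, n, n)))
    ii <- ((iu - 1L) %% n) + 1L
    jj <- ((iu - 1L) %/% n) + 1L
    key <- ii + n * (jj - 1L)
    excl_key <- pk(ex$excluded)
    p14_key <- pk(ex$pairs14)
    use <- !(key %in% excl_key)
    scale_ee <- ifelse(key %in% p14_key, scale14_ee, 1)[use]
    scale_lj <- ifelse(key %in% p14_key, scale14_lj, 1)[use]
    i <- ii[use]; j <- jj[use]
    if (length(i)) {
      d <- sqrt(rowSums((coords[i, , drop = FALSE] -
                           coords[j, , drop = FALSE])^2))
      rmin <- a$rmin2[i] + a$rmin2[j]
      epsij <- sqrt(a$eps[i] * a$eps[j])
      sr6 <- (rmin / d)^6
      e_lj <- sum(scale_lj * epsij * (sr6^2 - 2 * sr6))
      e_coul <- sum(scale_ee * ke * a$charge[i] * a$charge[j] / d)
    }
  }
  list(bond = e_bond, angle = e_angle, torsion = e_torsion,
       lj = e_lj, coulomb = e_coul)
}

#' Full GBSA energy decomposition of one snapshot
#'
#' Evaluates the classical-mechanics terms, the Hawkins GB polar solvation
#' energy and the surface-area term for one frame. \code{E^MM} is the sum
#' of bond, angle, torsion, LJ, Coulomb, GB and the topology's constant
#' offset term; the surface-area energy \code{E^ASA} is kept separate.
#' Solvent should be stripped (\code{\link{strip_solvent}}) before calling;
#' stripping is explicit, never implicit.
#'
#' @param top parameterized \code{topology}
#' @param coords n x 3 coordinates
#' @param gb a \code{\link{gb_params}}
#' @param sa a \code{\link{sasa_params}}
#' @return object of class \code{energy_decomposition}: components
#'   \code{bond}, \code{angle}, \code{torsion}, \code{lj}, \code{coulomb},
#'   \code{gb}, \code{offset}, their sum \code{e_mm}, plus \code{sasa}
#'   (A^2) and \code{e_asa} (kcal/mol)
#' @export
snapshot_energy <- function(top, coords, gb = gb_params(),
                            sa = sasa_params()) {
  coords <- as_coord_matrix(coords)
  mm <- mm_energy(top, coords, ke = gb$ke)
  radii <- effective_born_radii(top, coords, gb)
  e_gb <- gb_polar_energy(top, coords, radii, gb)
  s <- sasa(top, coords, sa)
  dec <- c(mm, list(gb = e_gb, offset = top$energy_offset))
  dec$e_mm <- mm$bond + mm$angle + mm$torsion + mm$lj + mm$coulomb +
    e_gb + top$energy_offset
  dec$sasa <- s$total
  dec$e_asa <- asa_energy(s$total, sa)
  structure(dec, class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf(paste0("energy (kcal/mol): bond %.3f  angle %.3f  torsion %.3f\n",
                     "  LJ %.3f  Coulomb %.3f  GB %.3f  offset %.3f\n",
                     "  E^MM %.3f   SASA %.2f A^2  E^ASA %.3f\n"),
              x$bond, x$angle, x$torsion, x$lj, x$coulomb, x$gb, x$offset,
              x$e_mm, x$sasa, x$e_asa))
  invisible(x)
}

#' Ensemble-averaged GBSA energies
#'
#' Arithmetic means of \code{E^MM} and \code{E^ASA} over frames, with the
#' per-frame series retained for convergence diagnostics. Because snapshot
#' energies are averaged independently, a strided subset of frames
#' (\code{energy_frames}) may be used for the mean when the ensemble is
#' much larger than the energy average needs; the frames actually used are
#' recorded.
#'
#' @param e non-empty \code{ensemble} with a parameterized topology
#' @param gb a \code{\link{gb_params}}
#' @param sa a \code{\link{sasa_params}}
#' @param energy_frames optional cap on the number of frames evaluated
#'   (evenly strided); default all frames
#' @return list: \code{e_mm_mean}, \code{e_asa_mean}, \code{series}
#'   (data.frame of per-frame components), \code{frames_used}
#' @export
ensemble_average <- function(e, gb = gb_params(), sa = sasa_params(),
                             energy_frames = NULL) {
  nf <- n_frames(e)
  if (nf < 1L) stop("empty ensemble")
  use <- seq_len(nf)
  if (!is.null(energy_frames) && energy_frames < nf)
    use <- unique(round(seq(1, nf, length.out = energy_frames)))
  rows <- vector("list", length(use))
  for (k in seq_along(use)) {
    dec <- snapshot_energy(e$topology, frame_coords(e, use[k]), gb, sa)
    rows[[k]] <- data.frame(frame = use[k], bond = dec$bond,
                            angle = dec$angle, torsion = dec$torsion,
                            lj = dec$lj, coulomb = dec$coulomb, gb = dec$gb,
                            offset = dec$offset, e_mm = dec$e_mm,
                            sasa = dec$sasa, e_asa = dec$e_asa)
  }
  series <- do.call(rbind, rows)
  list(e_mm_mean = mean(series$e_mm), e_asa_mean = mean(series$e_asa),
       series = series, frames_used = use)
}

#' Write a per-frame energy series as CSV
#' @param avg result of \code{\link{ensemble_average}}
#' @param path output CSV path
#' @export
write_energy_series <- function(avg, path) {
  utils::write.csv(avg$series, path, row.names = FALSE)
  invisible(path)
}
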
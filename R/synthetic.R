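#' Closed-form differential entropy of a von Mises distribution
#'
#' \deqn{S(\kappa) = \ln(2\pi I_0(\kappa)) - \kappa I_1(\kappa)/I_0(\kappa)}
#' in nats; \eqn{S(0) = \ln 2\pi} (circular uniform).
#'
#' @param kappa concentration parameter (>= 0)
#' @export
von_mises_entropy <- function(kappa) {
  stopifnot(all(kappa >= 0))
  ifelse(kappa == 0, log(2 * pi),
         log(2 * pi * besselI(kappa, 0, expon.scaled = TRUE)) + kappa -
           kappa * besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

# quadrature cross-check of a circular density's entropy: -int p ln p
circular_entropy_quadrature <- function(density_fn, n = 20000L) {
  th <- seq(-pi, pi, length.out = n + 1L)[-(n + 1L)]
  p <- density_fn(th)
  h <- 2 * pi / n
  -sum(ifelse(p > 0, p * log(p), 0)) * h
}

#' Specify a per-torsion sampling distribution with analytic entropy
#'
#' Types: \code{fixed(theta0)} (delta; differential entropy -Inf, discrete
#' histogram entropy 0), \code{uniform} (entropy \eqn{\ln 2\pi}), and
#' \code{vonmises(mu, kappa)} (see \code{\link{von_mises_entropy}}). The
#' stored analytic entropy is verified at construction against a direct
#' quadrature of \eqn{-\int p \ln p} on the circle.
#'
#' @param type \code{"fixed"}, \code{"uniform"} or \code{"vonmises"}
#' @param theta0 fixed angle in degrees (type "fixed")
#' @param mu von Mises mean direction in degrees
#' @param kappa von Mises concentration (>= 0)
#' @return object of class \code{torsion_spec} with element \code{entropy}
#'   (differential, nats)
#' @export
torsion_spec <- function(type = c("uniform", "vonmises", "fixed"),
                         theta0 = 0, mu = 0, kappa = 1) {
  type <- match.arg(type)
  if (kappa < 0) stop("kappa must be >= 0")
  ent <- switch(type,
    fixed = -Inf,
    uniform = log(2 * pi),
    vonmises = von_mises_entropy(kappa))
  if (type == "vonmises" && kappa > 0) {
    dens <- function(th) exp(kappa * (cos(th - mu * pi / 180) - 1)) /
      (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
    q <- circular_entropy_quadrature(dens)
    if (abs(q - ent) > 1e-6)
      stop("internal error: analytic von Mises entropy disagrees with quadrature")
  }
  structure(list(type = type, theta0 = theta0, mu = mu, kappa = kappa,
                 entropy = ent), class = "torsion_spec")
}

#' Sample von Mises angles (Best-Fisher rejection sampler)
#'
#' @param n number of draws
#' @param mu mean direction in radians
#' @param kappa concentration (>= 0); 0 gives the circular uniform
#' @return angles in radians, wrapped to (-pi, pi]
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa < 1e-8) {
    th <- stats::runif(n, -pi, pi)
    return(th)
  }
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  rr <- (1 + rho^2) / (2 * rho)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(32L, ceiling((n - length(out)) * 1.5))
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + rr * z) / (rr + z)
    cc <- kappa * (rr - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    th <- sign(u3[ok] - 0.5) * acos(pmax(-1, pmin(1, f[ok])))
    out <- c(out, th)
  }
  th <- out[seq_len(n)] + mu
  th <- ((th + pi) %% (2 * pi)) - pi
  th[th <= -pi] <- th[th <= -pi] + 2 * pi
  th
}

# draw n angles in degrees from a torsion_spec (uses the current RNG state)
sample_torsion_angles <- function(spec, n) {
  switch(spec$type,
    fixed = rep(wrap_angle(spec$theta0), n),
    uniform = stats::runif(n, -180, 180),
    vonmises = rvonmises(n, mu = spec$mu * pi / 180,
                         kappa = spec$kappa) * 180 / pi)
}

# toy force-field constants for the synthetic chain generators
TOY_PARAMS <- list(
  bond_n_ca = 1.45, bond_ca_c = 1.52, bond_c_n = 1.33, bond_c_o = 1.23,
  angle = 111, angle_o = 120,
  kb = 300, ktheta = 60,
  rmin2 = c(N = 1.55, C = 1.7, O = 1.5, CA = 1.7, X = 1.7),
  eps = c(N = 0.17, C = 0.086, O = 0.21, CA = 0.11, X = 0.1),
  gb_radius = c(N = 1.55, C = 1.7, O = 1.5, CA = 1.7, X = 1.7),
  gb_screen = c(N = 0.79, C = 0.72, O = 0.85, CA = 0.72, X = 0.8))

#' Generate a parameterized toy peptide-like chain topology
#'
#' Builds a serial chain of \code{n_residues} residues with four heavy
#' atoms each (N, CA, C, O): bonds N-CA, CA-C, C-O within each residue and
#' C(i)-N(i+1) between residues (so 3 residues give 12 atoms and 11
#' bonds). Harmonic bond/angle terms are parameterized at the generator's
#' construction geometry (so the built conformations sit at the bonded
#' minimum), small alternating charges sum to zero exactly, and standard
#' heavy-atom LJ/GB radii are assigned. A z-matrix is attached so
#' conformations can be built from torsion values. Deterministic per seed.
#'
#' @param n_residues number of residues (>= 2)
#' @param atoms_per_residue fixed at 4 (N, CA, C, O)
#' @param seed RNG seed recorded in the topology (generation itself is
#'   deterministic)
#' @param charge_scale amplitude of the alternating partial charges
#' @return a parameterized \code{topology}
#' @export
make_toy_topology <- function(n_residues, atoms_per_residue = 4L, seed = 1L,
                              charge_scale = 0.2) {
  if (n_residues < 2) stop("n_residues must be >= 2")
  if (atoms_per_residue != 4L)
    stop("the toy chain generator places 4 heavy atoms per residue")
  names_res <- c("N", "CA", "C", "O")
  n <- 4L * n_residues
  atoms <- data.frame(
    name = rep(names_res, n_residues),
    element = rep(c("N", "C", "C", "O"), n_residues),
    resname = "GLY",
    resid = rep(seq_len(n_residues), each = 4L),
    chain = "A", stringsAsFactors = FALSE)
  # alternating charges, exact zero sum
  q <- rep(c(charge_scale, -charge_scale), length.out = n)
  if (n %% 2L == 1L) q[n] <- 0
  atoms$charge <- q - mean(q)
  atoms$rmin2 <- TOY_PARAMS$rmin2[atoms$name]
  atoms$eps <- TOY_PARAMS$eps[atoms$name]
  atoms$gb_radius <- TOY_PARAMS$gb_radius[atoms$name]
  atoms$gb_screen <- TOY_PARAMS$gb_screen[atoms$name]

  idx <- function(res, nm) (res - 1L) * 4L + match(nm, names_res)
  bonds <- NULL; blen <- NULL
  for (r in seq_len(n_residues)) {
    bonds <- rbind(bonds,
                   c(idx(r, "N"), idx(r, "CA")),
                   c(idx(r, "CA"), idx(r, "C")),
                   c(idx(r, "C"), idx(r, "O")))
    blen <- c(blen, TOY_PARAMS$bond_n_ca, TOY_PARAMS$bond_ca_c,
              TOY_PARAMS$bond_c_o)
    if (r < n_residues) {
      bonds <- rbind(bonds, c(idx(r, "C"), idx(r + 1L, "N")))
      blen <- c(blen, TOY_PARAMS$bond_c_n)
    }
  }
  bond_params <- data.frame(kb = TOY_PARAMS$kb, b0 = blen)

  # angles: every bonded triple
  nbtmp <- list()
  for (k in seq_len(nrow(bonds))) {
    i <- bonds[k, 1]; j <- bonds[k, 2]
    nbtmp[[as.character(i)]] <- c(nbtmp[[as.character(i)]], j)
    nbtmp[[as.character(j)]] <- c(nbtmp[[as.character(j)]], i)
  }
  angles <- NULL
  for (j in seq_len(n)) {
    nbj <- sort(nbtmp[[as.character(j)]])
    if (length(nbj) >= 2L) {
      cmb <- utils::combn(nbj, 2L)
      angles <- rbind(angles, t(rbind(cmb[1, ], j, cmb[2, ])))
    }
  }
  theta0 <- apply(angles, 1, function(tr) {
    if (atoms$name[tr[2]] == "C" && "O" %in% atoms$name[c(tr[1], tr[3])])
      TOY_PARAMS$angle_o else TOY_PARAMS$angle
  })
  angle_params <- data.frame(ktheta = TOY_PARAMS$ktheta, theta0 = theta0)

  zmat <- toy_zmatrix(atoms, bonds, bond_params$b0, n_residues, idx)
  top <- topology(atoms, bonds = bonds, bond_params = bond_params,
                  angles = angles, angle_params = angle_params,
                  torsions = zmat$quads, torsion_params = data.frame(
                    vn = rep(0, nrow(zmat$quads)),
                    periodicity = rep(3L, nrow(zmat$quads)),
                    gamma = rep(0, nrow(zmat$quads))),
                  zmatrix = zmat$z)
  attr(top, "seed") <- seed
  top
}

# internal-coordinate table for the 4-atom-per-residue toy chain.
# Columns: atom, ref1 (bonded), ref2, ref3, length, angle (deg), torsion
# index (0 = fixed), torsion offset (deg). Free torsions map 1:1 to the
# chain's rotatable bonds in enumerate_torsions() order.
toy_zmatrix <- function(atoms, bonds, b0, n_residues, idx) {
  rows <- list(); quads <- list()
  tcount <- 0L
  add <- function(atom, r1, r2, r3, len, ang, tix, toff) {
    rows[[length(rows) + 1L]] <<- data.frame(
      atom = atom, ref1 = r1, ref2 = r2, ref3 = r3, length = len,
      angle = ang, torsion = tix, offset = toff)
  }
  for (r in seq_len(n_residues)) {
    iN <- idx(r, "N"); iCA <- idx(r, "CA"); iC <- idx(r, "C"); iO <- idx(r, "O")
    if (r == 1L) {
      add(iN, 0L, 0L, 0L, 0, 0, 0L, 0)
      add(iCA, iN, 0L, 0L, TOY_PARAMS$bond_n_ca, 0, 0L, 0)
      add(iC, iCA, iN, 0L, TOY_PARAMS$bond_ca_c, TOY_PARAMS$angle, 0L, 0)
    } else {
      iCprev <- idx(r - 1L, "C"); iCAprev <- idx(r - 1L, "CA")
      # omega-like torsion about Cprev-N: quad (CAprev, Cprev, N, CA)
      tcount <- tcount + 1L
      quads[[tcount]] <- c(iCAprev, iCprev, iN, iCA)
      add(iCA, iN, iCprev, iCAprev, TOY_PARAMS$bond_n_ca, TOY_PARAMS$angle,
          tcount, 0)
      # phi-like torsion about N-CA: quad (Cprev, N, CA, C)
      tcount <- tcount + 1L
      quads[[tcount]] <- c(iCprev, iN, iCA, iC)
      add(iC, iCA, iN, iCprev, TOY_PARAMS$bond_ca_c, TOY_PARAMS$angle,
          tcount, 0)
    }
    # psi-like torsion about CA-C: quad (N, CA, C, O); O is the d atom
    tcount <- tcount + 1L
    quads[[tcount]] <- c(iN, iCA, iC, iO)
    add(iO, iC, iCA, iN, TOY_PARAMS$bond_c_o, TOY_PARAMS$angle_o, tcount, 0)
    if (r < n_residues) {
      # next N rides on the same psi-like torsion, offset 180 from O
      iNnext <- idx(r + 1L, "N")
      add(iNnext, iC, iCA, iN, TOY_PARAMS$bond_c_n, TOY_PARAMS$angle, tcount,
          180)
    }
  }
  z <- do.call(rbind, rows)
  z <- z[order(z$atom), ]
  list(z = z, quads = do.call(rbind, quads), n_torsions = tcount)
}

#' Generate a linear-chain topology with an exact torsion count
#'
#' A bare serial chain of \code{n_torsions + 3} atoms (one bond between
#' consecutive atoms) has exactly \code{n_torsions} non-terminal bonds,
#' hence Nd = \code{n_torsions} rotatable torsions. The chain is
#' non-interacting by default (zero charges, zero LJ epsilon) so that two
#' ensembles differing only in torsion distributions have identical
#' enthalpy by construction; an \code{energy_offset} can impose a
#' controlled enthalpy difference.
#'
#' @param n_torsions desired torsion count (>= 1)
#' @param energy_offset constant E^MM offset in kcal/mol (default 0)
#' @param charge per-atom charge amplitude (default 0; alternating signs,
#'   zero total)
#' @return a parameterized \code{topology} with an attached z-matrix
#' @export
make_chain_topology <- function(n_torsions, energy_offset = 0, charge = 0) {
  if (n_torsions < 1) stop("n_torsions must be >= 1")
  n <- n_torsions + 3L
  q <- rep(c(charge, -charge), length.out = n)
  if (n %% 2L == 1L) q[n] <- 0
  atoms <- data.frame(
    name = paste0("C", seq_len(n)), element = "C", resname = "CHN",
    resid = seq_len(n), chain = "A",
    charge = q - mean(q),
    rmin2 = TOY_PARAMS$rmin2[["X"]], eps = 0,
    gb_radius = TOY_PARAMS$gb_radius[["X"]],
    gb_screen = TOY_PARAMS$gb_screen[["X"]],
    stringsAsFactors = FALSE)
  bonds <- cbind(seq_len(n - 1L), 2:n)
  bond_params <- data.frame(kb = TOY_PARAMS$kb,
                            b0 = rep(1.52, n - 1L))
  angles <- if (n >= 3L) cbind(seq_len(n - 2L), 2:(n - 1L), 3:n)
  angle_params <- data.frame(ktheta = TOY_PARAMS$ktheta,
                             theta0 = rep(TOY_PARAMS$angle, n - 2L))
  z <- data.frame(atom = seq_len(n), ref1 = c(0L, 1L, 2L, seq_len(n - 3L) + 2L),
                  ref2 = c(0L, 0L, 1L, seq_len(n - 3L) + 1L),
                  ref3 = c(0L, 0L, 0L, seq_len(n - 3L)),
                  length = c(0, rep(1.52, n - 1L)),
                  angle = c(0, 0, rep(TOY_PARAMS$angle, n - 2L)),
                  torsion = c(0L, 0L, 0L, seq_len(n - 3L)),
                  offset = 0)
  quads <- cbind(seq_len(n - 3L), seq_len(n - 3L) + 1L,
                 seq_len(n - 3L) + 2L, seq_len(n - 3L) + 3L)
  topology(atoms, bonds = bonds, bond_params = bond_params,
           angles = angles, angle_params = angle_params,
           torsions = quads,
           torsion_params = data.frame(vn = rep(0, nrow(quads)),
                                       periodicity = rep(3L, nrow(quads)),
                                       gamma = rep(0, nrow(quads))),
           energy_offset = energy_offset, zmatrix = z)
}

#' Build Cartesian coordinates from torsion values (fixed internal geometry)
#'
#' Sequential internal-to-Cartesian placement (NeRF): bond lengths and
#' angles are fixed at the topology's construction values, so a
#' conformation is fully determined by its torsion vector. Re-measuring
#' the chain torsions with \code{\link{dihedral}} returns the inputs.
#'
#' @param top topology carrying a z-matrix (from the synthetic generators)
#' @param torsion_values torsion angles in degrees, one per free torsion
#' @return n x 3 coordinate matrix
#' @export
build_coordinates_from_torsions <- function(top, torsion_values) {
  xyz <- build_frames(top, matrix(torsion_values, nrow = 1))
  matrix(xyz[1, ], ncol = 3, byrow = TRUE)
}

# vectorized multi-frame NeRF builder: torsion_matrix is frames x Nd
# (degrees); returns frames x 3N coordinate matrix
build_frames <- function(top, torsion_matrix) {
  z <- top$zmatrix
  if (is.null(z)) stop("topology has no z-matrix; use a synthetic generator")
  nt <- max(z$torsion)
  torsion_matrix <- as.matrix(torsion_matrix)
  if (ncol(torsion_matrix) != nt)
    stop(sprintf("expected %d torsion values per frame, got %d",
                 nt, ncol(torsion_matrix)))
  nf <- nrow(torsion_matrix)
  n <- n_atoms(top)
  X <- array(0, dim = c(nf, n, 3))
  getp <- function(i) {
    m <- X[, i, , drop = FALSE]
    dim(m) <- c(nf, 3L)
    m
  }
  for (k in seq_len(nrow(z))) {
    row <- z[k, ]
    i <- row$atom
    if (row$ref1 == 0L) {               # first atom at origin
      X[, i, ] <- 0
    } else if (row$ref2 == 0L) {        # second atom along +x
      X[, i, 1] <- row$length
    } else if (row$ref3 == 0L) {        # third atom in the xy plane
      ang <- row$angle * pi / 180
      B <- getp(row$ref1); A <- getp(row$ref2)
      u <- (A - B) / sqrt(rowSums((A - B)^2))
      # direction from B making the bond angle (at ref1) with the B->A bond
      ca <- cos(pi - ang); sa <- sin(pi - ang)
      d <- cbind(ca * u[, 1] - sa * u[, 2], sa * u[, 1] + ca * u[, 2],
                 rep(0, nf))
      X[, i, ] <- B - row$length * d
    } else {
      th <- wrap_angle(torsion_matrix[, row$torsion] + row$offset) * pi / 180
      ang <- row$angle * pi / 180
      C <- getp(row$ref1); B <- getp(row$ref2); A <- getp(row$ref3)
      bc <- C - B; bc <- bc / sqrt(rowSums(bc^2))
      ab <- B - A
      nvec <- cross3_rows(ab, bc)
      nn <- sqrt(rowSums(nvec^2))
      if (any(nn < 1e-10))
        stop("impossible geometry: collinear reference atoms in chain build")
      nvec <- nvec / nn
      mvec <- cross3_rows(nvec, bc)
      l <- row$length
      d2 <- cbind(-l * cos(ang), l * sin(ang) * cos(th), l * sin(ang) * sin(th))
      X[, i, ] <- C + d2[, 1] * bc + d2[, 2] * mvec + d2[, 3] * nvec
    }
  }
  out <- matrix(0, nf, 3L * n)
  for (i in seq_len(n)) out[, (3 * i - 2):(3 * i)] <- X[, i, ]
  out
}

#' Sample an i.i.d. conformational ensemble from torsion distributions
#'
#' Each frame's torsions are drawn independently per torsion from the
#' given spec(s) and converted to Cartesian coordinates with fixed bond
#' lengths and angles. Reproducible per seed; the seed is recorded in the
#' frame metadata.
#'
#' @param top synthetic topology with a z-matrix
#' @param spec a single \code{\link{torsion_spec}} applied to every
#'   torsion, or a list with one spec per torsion
#' @param n_frames number of frames (>= 1)
#' @param seed RNG seed
#' @return an \code{ensemble}
#' @export
sample_ensemble <- function(top, spec, n_frames, seed = 1L) {
  if (n_frames < 1) stop("n_frames must be >= 1")
  nt <- max(top$zmatrix$torsion)
  specs <- if (inherits(spec, "torsion_spec")) rep(list(spec), nt) else spec
  if (length(specs) != nt)
    stop(sprintf("need %d torsion specs, got %d", nt, length(specs)))
  set.seed(seed)
  tm <- matrix(NA_real_, n_frames, nt)
  for (k in seq_len(nt)) tm[, k] <- sample_torsion_angles(specs[[k]], n_frames)
  xyz <- build_frames(top, tm)
  md <- data.frame(frame = seq_len(n_frames), seed = seed)
  e <- ensemble(top, xyz, md)
  attr(e, "torsion_matrix") <- tm
  e
}

#' Synthetic metal-ion site with a fluctuating water shell
#'
#' One Zn particle at the origin plus \code{n_water} water oxygens per
#' frame. Each water is independently in-shell with probability
#' \code{n_water_mean / n_water} (placed uniformly in distance between
#' \code{shell_min} and \code{cutoff}) and otherwise out of shell
#' (uniform between \code{cutoff + 0.5} and \code{cutoff + 5}); directions
#' are uniform on the sphere. The expected within-cutoff count therefore
#' equals \code{n_water_mean} exactly at the stated cutoff.
#'
#' @param n_water_mean expected in-shell water count (>= 0)
#' @param shell_distance minimum in-shell Zn-O distance (default 1.9 A)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @param cutoff the contact cutoff the mean refers to (default 3.0 A)
#' @param n_water number of candidate waters (default: enough that the
#'   per-water probability is <= 1/2)
#' @return an \code{ensemble} whose topology has one Zn and the water
#'   oxygens (resname HOH)
#' @export
make_metal_site <- function(n_water_mean, shell_distance = 1.9,
                            n_frames = 100L, seed = 1L, cutoff = 3.0,
                            n_water = NULL) {
  if (n_water_mean < 0) stop("n_water_mean must be >= 0")
  if (shell_distance <= 0 || shell_distance >= cutoff)
    stop("need 0 < shell_distance < cutoff")
  if (is.null(n_water)) n_water <- max(2L, ceiling(2 * n_water_mean))
  p_in <- if (n_water_mean > 0) n_water_mean / n_water else 0
  if (p_in > 1) stop("n_water too small for the requested mean")
  atoms <- data.frame(
    name = c("ZN", rep("O", n_water)),
    element = c("ZN", rep("O", n_water)),
    resname = c("ZN", rep("HOH", n_water)),
    resid = seq_len(n_water + 1L), chain = "A",
    charge = 0, rmin2 = 1.5, eps = 0.1, gb_radius = 1.5, gb_screen = 0.8,
    stringsAsFactors = FALSE)
  top <- topology(atoms)
  set.seed(seed)
  xyz <- matrix(0, n_frames, 3L * (n_water + 1L))
  for (f in seq_len(n_frames)) {
    inshell <- stats::runif(n_water) < p_in
    d <- ifelse(inshell,
                stats::runif(n_water, shell_distance, cutoff - 1e-6),
                stats::runif(n_water, cutoff + 0.5, cutoff + 5))
    u <- stats::runif(n_water, -1, 1)
    phi <- stats::runif(n_water, 0, 2 * pi)
    s <- sqrt(1 - u^2)
    pos <- cbind(d * s * cos(phi), d * s * sin(phi), d * u)
    xyz[f, -(1:3)] <- as.numeric(t(pos))
  }
  ensemble(top, xyz, data.frame(frame = seq_len(n_frames), seed = seed))
}

#' Synthetic two-state system with controlled entropy and enthalpy
#'
#' Two ensembles on the same non-interacting linear chain differing only
#' in torsion concentration: state A samples von Mises(0, kappaA) on every
#' torsion (kappa 0 = circular uniform), state B von Mises(0, kappaB).
#' The analytic entropy difference is
#' \code{dS = n_torsions * (S(kappaB) - S(kappaA))} nats (state B minus
#' state A, the \code{\link{compare_states}} convention), with
#' \code{dTS = kB T dS}. An optional enthalpy offset \code{delta_h}
#' (kcal/mol, added to state B's E^MM as a constant term) sets dG2
#' independently of dTS.
#'
#' @param kappaA,kappaB von Mises concentrations (>= 0)
#' @param n_torsions number of torsions (>= 1)
#' @param n_frames frames per state
#' @param temperature temperature in K
#' @param seed RNG seed (state B uses seed + 1)
#' @param delta_h constant enthalpy offset of state B (kcal/mol)
#' @return list: \code{ensembleA}, \code{ensembleB}, \code{truth} (with
#'   \code{ds} in nats and \code{dts} in kcal/mol)
#' @export
make_two_state_system <- function(kappaA, kappaB, n_torsions, n_frames,
                                  temperature = 300, seed = 1L,
                                  delta_h = 0) {
  topA <- make_chain_topology(n_torsions)
  topB <- make_chain_topology(n_torsions, energy_offset = delta_h)
  specA <- if (kappaA == 0) torsion_spec("uniform")
           else torsion_spec("vonmises", mu = 0, kappa = kappaA)
  specB <- if (kappaB == 0) torsion_spec("uniform")
           else torsion_spec("vonmises", mu = 0, kappa = kappaB)
  eA <- sample_ensemble(topA, specA, n_frames, seed = seed)
  eB <- sample_ensemble(topB, specB, n_frames, seed = seed + 1L)
  sA <- if (kappaA == 0) log(2 * pi) else von_mises_entropy(kappaA)
  sB <- if (kappaB == 0) log(2 * pi) else von_mises_entropy(kappaB)
  ds <- n_torsions * (sB - sA)
  truth <- list(ds = ds, dts = KB_KCALMOL * temperature * ds,
                delta_h = delta_h, temperature = temperature,
                kappaA = kappaA, kappaB = kappaB,
                n_torsions = n_torsions, seed = seed)
  list(ensembleA = eA, ensembleB = eB, truth = truth)
}
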
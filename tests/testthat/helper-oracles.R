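# Independent oracles used to cross-check the implementation. These are
# deliberately written with different algorithms than the package code.

# Horn's quaternion method for optimal superposition RMSD: the minimal
# RMSD is sqrt((sum|P|^2 + sum|Q|^2 - 2*lambda_max) / n) where lambda_max
# is the largest eigenvalue of the 4x4 key matrix of the correlation.
quaternion_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  P <- sweep(P, 2, cp); Q <- sweep(Q, 2, cq)
  M <- crossprod(P, Q)
  Sxx <- M[1,1]; Sxy <- M[1,2]; Sxz <- M[1,3]
  Syx <- M[2,1]; Syy <- M[2,2]; Syz <- M[2,3]
  Szx <- M[3,1]; Szy <- M[3,2]; Szz <- M[3,3]
  K <- matrix(c(
    Sxx+Syy+Szz, Syz-Szy,     Szx-Sxz,     Sxy-Syx,
    Syz-Szy,     Sxx-Syy-Szz, Sxy+Syx,     Szx+Sxz,
    Szx-Sxz,     Sxy+Syx,     -Sxx+Syy-Szz, Syz+Szy,
    Sxy-Syx,     Szx+Sxz,     Syz+Szy,     -Sxx-Syy+Szz), 4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# O(n^2) double-loop contact count, one frame
brute_contacts <- function(coords, center, partners, cutoff) {
  cnt <- 0L
  for (p in partners) {
    hit <- FALSE
    for (ce in center) {
      if (sqrt(sum((coords[p, ] - coords[ce, ])^2)) <= cutoff) hit <- TRUE
    }
    if (hit) cnt <- cnt + 1L
  }
  cnt
}

# dihedral sign oracle via the atan2-free vector construction: project
# b1 and b3 into the plane normal to b2 and take the signed angle between
# the projections using the scalar triple product for the sign.
dihedral_oracle <- function(coords, quad) {
  p <- coords[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  b2h <- b2 / sqrt(sum(b2^2))
  # project the 2->1 direction (-b1) and the 3->4 direction (b3) into the
  # plane normal to the central bond; cis (same side) then gives 0
  u <- -b1 + sum(b1 * b2h) * b2h
  v <- b3 - sum(b3 * b2h) * b2h
  ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  tri <- sum(b2h * c(u[2]*v[3]-u[3]*v[2], u[3]*v[1]-u[1]*v[3],
                     u[1]*v[2]-u[2]*v[1]))
  deg <- ang * 180 / pi * ifelse(tri >= 0, 1, -1)
  if (deg <= -180) deg <- deg + 360
  deg
}

# numerical Coulomb-field integration of the HCT descreened volume for a
# pair of atoms: returns the inverse effective radius of atom i whose
# reduced radius is rho_i, descreened by a sphere of radius srj at
# distance d.
hct_inverse_radius_oracle <- function(rho_i, srj, d, n = 200000L) {
  lo <- max(rho_i, d - srj); hi <- d + srj
  if (hi <= lo) return(1 / rho_i)
  r <- seq(lo, hi, length.out = n)
  cost <- pmin(1, pmax(-1, (r^2 + d^2 - srj^2) / (2 * r * d)))
  f <- (1 - cost) / r^2
  integ <- 0.5 * sum((f[-1] + f[-n]) / 2) * (hi - lo) / (n - 1)
  if (d < srj && srj - d > rho_i)
    integ <- integ + (1 / rho_i - 1 / (srj - d))
  1 / rho_i - integ
}

# analytic solvent-accessible area of two intersecting spheres of
# (expanded) radii R1, R2 at center distance d
two_sphere_sasa <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  if (d <= abs(R1 - R2)) return(4 * pi * max(R1, R2)^2)
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# brute-force equal-arc-length waypoint search mirroring the stated rule:
# for each target length pick the nearest unchosen index (ties toward the
# smaller index), then sort and pin the endpoints
waypoints_oracle <- function(pts, n) {
  m <- nrow(pts)
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-m, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  targets <- seq(0, cum[m], length.out = n)
  chosen <- integer(0)
  for (t in targets) {
    best <- NA; bestd <- Inf
    for (i in seq_len(m)) {
      if (i %in% chosen) next
      dd <- abs(cum[i] - t)
      if (dd < bestd - 1e-15) { bestd <- dd; best <- i }
    }
    chosen <- c(chosen, best)
  }
  chosen <- sort(chosen)
  chosen[1] <- 1L; chosen[n] <- m
  chosen
}

flatten_coords_test <- function(m) as.numeric(t(m))

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y)),
        c(2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x)),
        c(2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)))
}

# tiny PDB fixtures written on the fly
write_pdb_lines <- function(lines, path) {
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, name, resname, chain, resid, x, y, z,
                          record = "ATOM  ", altloc = " ", occ = 1,
                          element = "") {
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%s%5d %-4s%s%-4s%s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, altloc, resname, chain, resid, x, y, z, occ, 0,
          element)
}
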
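# deterministic quasi-uniform points on the unit sphere (golden-angle
# spiral); no RNG so SASA values are exactly reproducible
spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  cbind(r * cos(phi), r * sin(phi), z)
}

# connected components of the bond graph (vector of component ids)
bond_components <- function(top) {
  n <- n_atoms(top)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  b <- top$bonds
  for (k in seq_len(nrow(b))) {
    ri <- find(b[k, 1]); rj <- find(b[k, 2])
    if (ri != rj) comp[max(ri, rj)] <- min(ri, rj)
  }
  vapply(seq_len(n), find, integer(1))
}

# covariant orientation frame of one atom group: columns are the
# principal axes of the group's gyration tensor with a deterministic sign
# convention, so a rigid rotation of the group rotates the frame with it.
# Groups too small or too degenerate to orient get the identity.
group_frame <- function(coords) {
  if (nrow(coords) < 3L) return(diag(3))
  ctr <- sweep(coords, 2, colMeans(coords))
  eg <- eigen(crossprod(ctr) / nrow(ctr), symmetric = TRUE)
  if (eg$values[2] < 1e-10 * max(eg$values[1], 1)) return(diag(3))
  V <- eg$vectors
  for (k in 1:3) {
    pr <- ctr %*% V[, k]
    j <- which.max(abs(pr))
    if (pr[j] < 0) V[, k] <- -V[, k]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each atom, a deterministic quasi-uniform point set is placed on its
#' expanded sphere (van der Waals radius, taken as the topology's Rmin/2,
#' plus the probe radius); the accessible fraction is the fraction of
#' points not buried inside any neighbor's expanded sphere, times the
#' sphere area.
#'
#' Each atom's point set is oriented by the principal-axes frame of its
#' bonded molecule (connected component of the bond graph), which rotates
#' with the molecule: the sampled area is therefore exactly invariant
#' under rigid motions of the system and exactly additive over identical
#' non-interacting molecules, instead of merely so to the point-sampling
#' resolution.
#'
#' @param top parameterized \code{topology} (Rmin/2 radii required)
#' @param coords n x 3 coordinates (A)
#' @param params a \code{\link{sasa_params}}
#' @return list: \code{per_atom} (A^2) and \code{total} (A^2)
#' @export
sasa <- function(top, coords, params = sasa_params()) {
  coords <- as_coord_matrix(coords)
  vdw <- top$atoms$rmin2
  if (any(is.na(vdw))) stop("topology lacks van der Waals radii")
  n <- nrow(coords)
  rad <- vdw + params$probe
  pts <- spiral_points(params$n_points)
  comp <- bond_components(top)
  frames <- lapply(unique(comp), function(cid)
    group_frame(coords[comp == cid, , drop = FALSE]))
  names(frames) <- as.character(unique(comp))
  per_atom <- numeric(n)
  d2 <- if (n > 1L) as.matrix(stats::dist(coords))^2 else matrix(0, 1, 1)
  for (i in seq_len(n)) {
    V <- frames[[as.character(comp[i])]]
    sphere <- sweep((pts %*% t(V)) * rad[i], 2, coords[i, ], "+")
    nbr <- if (n > 1L)
      which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i) else integer(0)
    acc <- rep(TRUE, nrow(sphere))
    for (j in nbr) {
      dj2 <- (sphere[, 1] - coords[j, 1])^2 +
        (sphere[, 2] - coords[j, 2])^2 +
        (sphere[, 3] - coords[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
      if (!any(acc)) break
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * mean(acc)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}
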
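#' Least-squares (Kabsch) superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' \code{fit} atoms of \code{mobile} onto \code{reference}. Reflections are
#' excluded (det(R) = +1).
#'
#' @param mobile n x 3 coordinate matrix to be moved
#' @param reference n x 3 coordinate matrix to fit onto
#' @param fit atom indices used for the fit (default: all atoms); must
#'   contain at least 3 non-collinear atoms
#' @return list of class \code{superposition}: \code{rotation} (3 x 3,
#'   orthonormal, det +1), \code{translation} (length-3, Angstrom), and
#'   \code{rmsd} over the fit atoms after superposition
#' @export
kabsch_superpose <- function(mobile, reference, fit = NULL) {
  mobile <- as_coord_matrix(mobile)
  reference <- as_coord_matrix(reference)
  if (is.null(fit)) fit <- seq_len(nrow(mobile))
  fit <- as.integer(fit)
  if (max(fit) > nrow(mobile) || max(fit) > nrow(reference))
    stop("fit selection exceeds coordinate range")
  if (length(fit) < 3L)
    stop("degenerate fit: need at least 3 fit atoms")
  P <- mobile[fit, , drop = FALSE]
  Q <- reference[fit, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_check <- svd(Pc)$d
  if (sv_check[2] < 1e-8 * max(sv_check[1], 1))
    stop("degenerate fit: fit atoms are (nearly) collinear")
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  moved <- P %*% t(R)
  moved <- sweep(moved, 2, -tr)
  fit_rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  structure(list(rotation = R, translation = tr, rmsd = fit_rmsd),
            class = "superposition")
}

#' Apply a superposition transform to coordinates
#' @param coords n x 3 coordinate matrix
#' @param sup a \code{superposition} from \code{\link{kabsch_superpose}}
#' @export
apply_transform <- function(coords, sup) {
  coords <- as_coord_matrix(coords)
  sweep(coords %*% t(sup$rotation), 2, -sup$translation)
}

as_coord_matrix <- function(x) {
  if (inherits(x, "ensemble")) {
    if (n_frames(x) != 1L)
      stop("expected a single frame; extract one with frame_coords()")
    return(frame_coords(x, 1L))
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("coordinates must be an n x 3 matrix")
  x
}

#' RMSD between two frames after superposition
#'
#' Superposes \code{frameA} onto \code{frameB} over the \code{fit} atoms,
#' then evaluates the root-mean-square deviation over the \code{measure}
#' atoms. With \code{fit = measure} (the default) this is the standard
#' global RMSD; with a broader fit (e.g. the whole main chain) and a local
#' \code{measure} region it gives the displacement of that region in the
#' globally aligned frame, the convention used for loop and side-chain
#' mobility tables.
#'
#' @param frameA,frameB n x 3 coordinate matrices over the same topology
#' @param measure atom indices to measure over (default: all atoms)
#' @param fit atom indices to superpose on (default: \code{measure})
#' @return RMSD in Angstrom
#' @export
rmsd <- function(frameA, frameB, measure = NULL, fit = measure) {
  frameA <- as_coord_matrix(frameA)
  frameB <- as_coord_matrix(frameB)
  if (is.null(measure)) measure <- seq_len(nrow(frameA))
  measure <- as.integer(measure)
  if (!length(measure)) stop("empty measure selection")
  if (is.null(fit)) fit <- measure
  sup <- kabsch_superpose(frameA, frameB, fit = fit)
  moved <- apply_transform(frameA, sup)
  sqrt(mean(rowSums((moved[measure, , drop = FALSE] -
                       frameB[measure, , drop = FALSE])^2)))
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: cis = 0, trans = 180 degrees; positive angles
#' correspond to a clockwise rotation of the far bond when viewed from
#' atom 2 towards atom 3. Range (-180, 180].
#'
#' @param coords n x 3 coordinate matrix
#' @param quad integer vector of four distinct atom indices
#' @return angle in degrees
#' @export
dihedral <- function(coords, quad) {
  coords <- as_coord_matrix(coords)
  quad <- as.integer(quad)
  if (length(quad) != 4L || anyDuplicated(quad))
    stop("quad must contain four distinct atom indices")
  p <- coords[quad, , drop = FALSE]
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10)
    stop("undefined dihedral: collinear atoms about the central bond")
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / vec_norm(b2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

# dihedral over all ensemble frames for one quadruple: vectorized across
# frames (xyz is the frames x 3N matrix)
dihedral_series <- function(xyz, quad) {
  cols <- function(i) xyz[, (3 * i - 2):(3 * i), drop = FALSE]
  p1 <- cols(quad[1]); p2 <- cols(quad[2]); p3 <- cols(quad[3]); p4 <- cols(quad[4])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3_rows(b1, b2); n2 <- cross3_rows(b2, b3)
  if (any(rowdot(n1, n1) < 1e-20) || any(rowdot(n2, n2) < 1e-20))
    stop("undefined dihedral in at least one frame (collinear central bond)")
  x <- rowdot(n1, n2)
  y <- rowdot(cross3_rows(n1, n2), b2) / sqrt(rowdot(b2, b2))
  wrap_angle(atan2(y, x) * 180 / pi)
}

#' Measure a set of torsions over every frame of an ensemble
#'
#' @param e an \code{ensemble}
#' @param torsions a \code{torsion_set} (or 4-column index matrix)
#' @return numeric matrix, frames x torsions, angles in degrees
#' @export
measure_torsions <- function(e, torsions) {
  quads <- if (inherits(torsions, "torsion_set")) torsions$quads else
    as.matrix(torsions)
  out <- matrix(NA_real_, nrow = n_frames(e), ncol = nrow(quads))
  for (k in seq_len(nrow(quads))) out[, k] <- dihedral_series(e$xyz, quads[k, ])
  colnames(out) <- if (inherits(torsions, "torsion_set")) torsions$labels
  out
}

#' Enumerate torsion quadruples of a topology
#'
#' Policy \code{"all-rotatable"} (default) emits exactly one quadruple per
#' non-terminal heavy-atom bond: for each bond b-c where both b and c have
#' at least one further neighbor, the flanking atoms a and d are the
#' lowest-index neighbors of b (excluding c) and of c (excluding b).
#' Ordering is deterministic by (b, c). Policy \code{"forcefield-terms"}
#' returns the topology's torsion-term quadruples (deduplicated).
#' \code{"backbone-only"} restricts all-rotatable to bonds between atoms
#' named N, CA or C.
#'
#' @param top a \code{topology} with bonds
#' @param policy one of \code{"all-rotatable"}, \code{"backbone-only"},
#'   \code{"forcefield-terms"}
#' @return object of class \code{torsion_set}: \code{quads} (n x 4 matrix),
#'   \code{labels}, \code{n} (the torsion count Nd)
#' @export
enumerate_torsions <- function(top, policy = c("all-rotatable",
                                               "backbone-only",
                                               "forcefield-terms")) {
  policy <- match.arg(policy)
  if (!nrow(top$bonds)) {
    warning("topology has no bonds; empty torsion set")
    return(torsion_set(matrix(integer(0), ncol = 4), character(0)))
  }
  if (policy == "forcefield-terms") {
    q <- unique(top$torsions)
    labs <- apply(q, 1, paste, collapse = "-")
    return(torsion_set(q, labs))
  }
  nb <- bond_neighbors(top)
  b <- top$bonds
  bc <- cbind(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2]))
  bc <- unique(bc)
  bc <- bc[order(bc[, 1], bc[, 2]), , drop = FALSE]
  quads <- matrix(integer(0), ncol = 4)
  for (k in seq_len(nrow(bc))) {
    bb <- bc[k, 1]; cc <- bc[k, 2]
    if (policy == "backbone-only") {
      nm <- top$atoms$name[c(bb, cc)]
      if (!all(nm %in% c("N", "CA", "C"))) next
    }
    an <- setdiff(nb[[bb]], cc)
    dn <- setdiff(nb[[cc]], bb)
    if (!length(an) || !length(dn)) next  # terminal bond
    quads <- rbind(quads, c(min(an), bb, cc, min(dn)))
  }
  labs <- if (nrow(quads))
    apply(quads, 1, function(q) paste(top$atoms$name[q], collapse = "-"))
  else character(0)
  torsion_set(quads, labs)
}

torsion_set <- function(quads, labels) {
  quads <- matrix(as.integer(quads), ncol = 4)
  structure(list(quads = quads, labels = labels, n = nrow(quads)),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("torsion_set: Nd = %d torsion(s)\n", x$n))
  invisible(x)
}

#' Count partner atoms in contact with a center selection, per frame
#'
#' For each frame, counts the partner atoms lying within \code{cutoff} of
#' any center atom. The time average over frames is the "ligand water
#' count"-style statistic used for metal coordination analyses.
#'
#' @param e an \code{ensemble}
#' @param center non-empty \code{atom_selection} (e.g. the catalytic zinc)
#' @param partners \code{atom_selection} of candidate contact atoms (e.g.
#'   water oxygens)
#' @param cutoff contact distance in Angstrom (> 0); default 3.0, a typical
#'   first-shell Zn-O coordination distance
#' @return object of class \code{contact_series}: per-frame integer
#'   \code{counts}, the \code{average}, and the parameters used
#' @export
count_contacts <- function(e, center, partners, cutoff = 3.0) {
  if (!length(center)) stop("center selection is empty")
  stopifnot_scalar_number(cutoff, "cutoff", positive = TRUE)
  nf <- n_frames(e)
  counts <- integer(nf)
  c2 <- cutoff^2
  for (f in seq_len(nf)) {
    cc <- frame_coords(e, f)
    ctr <- cc[center, , drop = FALSE]
    par <- cc[partners, , drop = FALSE]
    if (!nrow(par)) { counts[f] <- 0L; next }
    # n_partner x n_center squared distances
    d2 <- outer(rowSums(par^2), rowSums(ctr^2), "+") -
      2 * par %*% t(ctr)
    counts[f] <- sum(apply(d2 <= c2, 1, any))
  }
  structure(list(counts = counts, average = mean(counts), cutoff = cutoff,
                 center = center, partners = partners),
            class = "contact_series")
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("contact_series: %d frame(s), cutoff %.2f A, average %.3f\n",
              length(x$counts), x$cutoff, x$average))
  invisible(x)
}

#' Per-region RMSD table against one or more reference structures
#'
#' For every frame, every reference and every region: the frame is first
#' superposed globally on its main-chain atoms (N, CA, C, O), then the RMSD
#' is evaluated over the region's main-chain atoms in that global frame.
#' This is the layout of trajectory-vs-start / trajectory-vs-other-state
#' RMSD tables: local regions (loops, individual residues) can exceed the
#' global RMSD because they are measured without a local re-fit.
#'
#' @param traj an \code{ensemble}
#' @param refs named list of reference coordinate matrices (n x 3) on the
#'   same topology
#' @param regions named list of \code{atom_selection}s
#' @return data.frame with columns \code{region}, \code{reference},
#'   \code{rmsd} (mean over frames); per-frame values in
#'   \code{attr(, "per_frame")}
#' @export
region_rmsd_table <- function(traj, refs, regions) {
  top <- traj$topology
  mc <- which(top$atoms$name %in% c("N", "CA", "C", "O"))
  if (!length(mc)) stop("topology has no main-chain atoms to fit on")
  for (rg in names(regions)) {
    if (!length(regions[[rg]]))
      stop("region '", rg, "' selects no atoms in this topology")
  }
  rows <- list()
  per_frame <- list()
  for (rf in names(refs)) {
    ref <- as_coord_matrix(refs[[rf]])
    for (rg in names(regions)) {
      sel <- as.integer(regions[[rg]])
      sel_mc <- intersect(sel, mc)
      if (!length(sel_mc))
        stop("region '", rg, "' contains no main-chain atoms")
      vals <- vapply(seq_len(n_frames(traj)), function(f) {
        fc <- frame_coords(traj, f)
        sup <- kabsch_superpose(fc, ref, fit = mc)
        moved <- apply_transform(fc, sup)
        sqrt(mean(rowSums((moved[sel_mc, , drop = FALSE] -
                             ref[sel_mc, , drop = FALSE])^2)))
      }, numeric(1))
      rows[[length(rows) + 1L]] <-
        data.frame(region = rg, reference = rf, rmsd = mean(vals))
      per_frame[[paste(rg, rf, sep = "|")]] <- vals
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "per_frame") <- per_frame
  out
}
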
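#' Superpose every frame of an ensemble onto a common reference
#'
#' Mode \code{"to-first"} fits each frame onto the first frame;
#' \code{"iterative-mean"} alternates fitting all frames onto their mean
#' and recomputing the mean until the mean moves less than \code{tol}
#' (max 50 iterations, warning on non-convergence, best iterate
#' returned). Iterative-mean alignment never increases the total
#' coordinate variance relative to to-first alignment.
#'
#' @param e \code{ensemble} with >= 2 frames
#' @param fit \code{atom_selection} to fit on (default all atoms)
#' @param mode \code{"to-first"} or \code{"iterative-mean"}
#' @param tol convergence tolerance on the mean structure (A)
#' @return aligned \code{ensemble}
#' @export
align_ensemble <- function(e, fit = NULL, mode = c("to-first",
                                                   "iterative-mean"),
                           tol = 1e-6) {
  mode <- match.arg(mode)
  if (n_frames(e) < 2L) stop("alignment needs >= 2 frames")
  if (is.null(fit)) fit <- seq_len(n_atoms(e$topology))
  fit <- as.integer(fit)
  xyz <- e$xyz
  nf <- nrow(xyz)
  align_to <- function(xyz, ref) {
    for (f in seq_len(nf)) {
      fc <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      sup <- kabsch_superpose(fc, ref, fit = fit)
      xyz[f, ] <- flatten_coords(apply_transform(fc, sup))
    }
    xyz
  }
  ref <- matrix(xyz[1, ], ncol = 3, byrow = TRUE)
  xyz <- align_to(xyz, ref)
  if (mode == "iterative-mean") {
    converged <- FALSE
    for (it in seq_len(50L)) {
      mref <- matrix(colMeans(xyz), ncol = 3, byrow = TRUE)
      xyz_new <- align_to(xyz, mref)
      shift <- sqrt(max(rowSums(
        (matrix(colMeans(xyz_new), ncol = 3, byrow = TRUE) - mref)^2)))
      xyz <- xyz_new
      if (shift < tol) { converged <- TRUE; break }
    }
    if (!converged)
      warning("iterative-mean alignment did not converge; returning best iterate")
  }
  ensemble(e$topology, xyz, e$metadata)
}

#' Principal component analysis of an aligned ensemble
#'
#' Eigendecomposition of the covariance of the 3N coordinates of the
#' selected atoms over frames. The mean structure is the origin of the
#' component axes, so projections are mean-centered. Eigenvector signs
#' follow a deterministic convention (largest-magnitude component
#' positive), which also breaks eigenvalue ties reproducibly.
#'
#' @param e aligned \code{ensemble} with >= 2 frames
#' @param selection \code{atom_selection} to analyze (default all atoms)
#' @return object of class \code{pca_model}: \code{mean} (3N vector over
#'   the selection), \code{values} (non-increasing eigenvalues, A^2),
#'   \code{vectors} (orthonormal columns), \code{projections} (frames x
#'   components), \code{selection}
#' @export
pca_ensemble <- function(e, selection = NULL) {
  if (n_frames(e) < 2L) stop("PCA needs >= 2 frames")
  if (is.null(selection)) selection <- seq_len(n_atoms(e$topology))
  selection <- as.integer(selection)
  if (!length(selection)) stop("empty PCA selection")
  cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1,
                          3 * selection))
  X <- e$xyz[, cols, drop = FALSE]
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  cv <- crossprod(Xc) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  vecs <- eg$vectors
  for (k in seq_len(ncol(vecs))) {
    j <- which.max(abs(vecs[, k]))
    if (vecs[j, k] < 0) vecs[, k] <- -vecs[, k]
  }
  proj <- Xc %*% vecs
  structure(list(mean = mu, values = vals, vectors = vecs,
                 projections = proj, selection = selection),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  fr <- x$values / sum(x$values)
  cat(sprintf("pca_model: %d frames x %d coordinates; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$projections), length(x$mean), 100 * fr[1],
              100 * ifelse(length(fr) > 1, fr[2], 0)))
  invisible(x)
}

#' Project a frame onto principal components
#'
#' Dot products of the mean-subtracted selected coordinates with the
#' model's eigenvectors. The frame must already be aligned to the model's
#' reference; the mean structure projects to the origin.
#'
#' @param model a \code{pca_model}
#' @param frame n x 3 coordinate matrix over the full topology, or a 3N
#'   vector over the model's selection
#' @param k number of components (default all)
#' @return numeric vector of projections
#' @export
project_frame <- function(model, frame, k = NULL) {
  v <- if (is.matrix(frame) && ncol(frame) == 3L) {
    flatten_coords(frame[model$selection, , drop = FALSE])
  } else as.numeric(frame)
  if (length(v) != length(model$mean))
    stop(sprintf("frame has %d coordinates; model expects %d",
                 length(v), length(model$mean)))
  p <- as.numeric((v - model$mean) %*% model$vectors)
  if (!is.null(k)) p <- p[seq_len(k)]
  p
}

#' Reconstruct selected coordinates from a full projection vector
#' @param model a \code{pca_model}
#' @param scores projection vector (all components)
#' @return 3N coordinate vector over the model's selection
#' @export
reconstruct_frame <- function(model, scores) {
  as.numeric(model$mean + model$vectors %*% scores)
}

#' Select pathway waypoints at equal arc length
#'
#' Given ordered path points in the first two principal components,
#' selects \code{n} frame indices at (approximately) equal cumulative arc
#' length, always including both endpoints. For each arc-length target the
#' nearest not-yet-chosen index is taken, scanning ties toward the smaller
#' index; the result is strictly increasing.
#'
#' @param projections matrix of ordered path points (>= 2 columns used) or
#'   a \code{pca_model}
#' @param n number of waypoints (>= 2, default 10)
#' @return integer frame indices (length n, monotone, endpoints included)
#' @export
select_waypoints <- function(projections, n = 10L) {
  if (inherits(projections, "pca_model")) projections <- projections$projections
  pts <- as.matrix(projections)[, 1:2, drop = FALSE]
  m <- nrow(pts)
  if (n < 2L) stop("need n >= 2 waypoints")
  if (m < n) stop("fewer path points than requested waypoints")
  seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                         pts[-m, , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[m]
  targets <- seq(0, total, length.out = n)
  chosen <- integer(0)
  for (t in targets) {
    cand <- setdiff(order(abs(cum - t)), chosen)
    chosen <- c(chosen, cand[1])
  }
  chosen <- sort(chosen)
  chosen[1] <- 1L; chosen[n] <- m
  chosen
}

#' Linear Cartesian morph between two conformations
#'
#' Desk-scale stand-in for a biased transition simulation: after
#' superposing \code{confB} onto \code{confA}, frames are linearly
#' interpolated at t = 0..1 inclusive. The output is geometric, not
#' physical, and is tagged \code{"interpolated"} in the frame metadata.
#'
#' @param confA,confB n x 3 coordinate matrices on the same topology
#' @param n_frames number of frames (>= 2; 2 gives exactly A and B)
#' @param top the shared \code{topology}
#' @return an \code{ensemble}
#' @export
morph <- function(confA, confB, n_frames, top) {
  confA <- as_coord_matrix(confA); confB <- as_coord_matrix(confB)
  if (!identical(dim(confA), dim(confB)))
    stop("conformations have different atom counts")
  if (nrow(confA) != n_atoms(top))
    stop("coordinates do not match the topology")
  if (n_frames < 2L) stop("need >= 2 morph frames")
  sup <- kabsch_superpose(confB, confA)
  confB <- apply_transform(confB, sup)
  tgrid <- seq(0, 1, length.out = n_frames)
  a <- flatten_coords(confA); b <- flatten_coords(confB)
  xyz <- outer(1 - tgrid, a) + outer(tgrid, b)
  ensemble(top, xyz, data.frame(frame = seq_len(n_frames), t = tgrid,
                                kind = "interpolated"))
}

#' Write PCA projections (with waypoint flags) as CSV
#' @param model a \code{pca_model}
#' @param waypoints optional integer indices from
#'   \code{\link{select_waypoints}}
#' @param path output CSV path
#' @param k number of components to write (default 2)
#' @export
write_projections <- function(model, path, waypoints = NULL, k = 2L) {
  df <- data.frame(frame = seq_len(nrow(model$projections)))
  for (j in seq_len(k)) df[[paste0("pc", j)]] <- model$projections[, j]
  df$waypoint <- df$frame %in% (waypoints %||% integer(0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
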
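#' Construct a conformational ensemble
#'
#' An ensemble is an ordered set of coordinate frames (snapshots) sharing
#' one \code{\link{topology}}. Coordinates are stored as a numeric matrix
#' with one row per frame and 3 columns per atom (x1, y1, z1, x2, ...),
#' in Angstrom.
#'
#' @param top a \code{topology}
#' @param xyz numeric matrix, frames x (3 * n_atoms)
#' @param metadata optional data.frame with one row per frame (time offsets,
#'   run ids, seeds); a \code{frame} column is added if absent.
#' @return object of class \code{ensemble}
#' @export
ensemble <- function(top, xyz, metadata = NULL) {
  stopifnot(inherits(top, "topology"))
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(top))
    stop(sprintf("xyz has %d columns; topology requires %d (3 per atom)",
                 ncol(xyz), 3L * n_atoms(top)))
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one frame")
  if (any(!is.finite(xyz))) stop("ensemble coordinates contain NaN/Inf")
  if (is.null(metadata)) metadata <- data.frame(frame = seq_len(nrow(xyz)))
  if (is.null(metadata$frame)) metadata$frame <- seq_len(nrow(xyz))
  if (nrow(metadata) != nrow(xyz))
    stop("metadata must have one row per frame")
  structure(list(topology = top, xyz = xyz, metadata = metadata),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("ensemble: %d frame(s) x %d atoms\n",
              nrow(x$xyz), n_atoms(x$topology)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param e an \code{ensemble}
#' @export
n_frames <- function(e) nrow(e$xyz)

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param e an \code{ensemble}
#' @param i frame index
#' @export
frame_coords <- function(e, i = 1L) {
  if (i < 1L || i > n_frames(e)) stop("frame index out of range")
  matrix(e$xyz[i, ], ncol = 3, byrow = TRUE)
}

# inverse of frame_coords: flatten an n x 3 matrix to one xyz row
flatten_coords <- function(m) as.numeric(t(m))

# two-letter elements recognized in HETATM records / ionic residues
HETATM_ELEMENTS <- c("ZN", "CL", "NA", "MG", "FE", "BR", "CU", "MN", "CA", "K")
WATER_RESNAMES <- c("HOH", "WAT", "TIP3")

infer_element <- function(name, resname, record) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  if (!nchar(nm)) return("X")
  rn <- toupper(trimws(resname))
  if (rn %in% c("ZN", "CL", "NA", "MG", "FE", "BR", "CU", "MN", "K")) return(rn)
  if (record == "HETATM" && nm %in% HETATM_ELEMENTS && !(rn %in% WATER_RESNAMES))
    return(nm)
  substr(nm, 1, 1)
}

#' Read a (multi-model) PDB file as a conformational ensemble
#'
#' One frame is produced per MODEL record (a single frame if the file has
#' none). The element is taken from columns 77-78 when present, otherwise
#' inferred from the atom name. Alternate locations are reduced to the
#' highest-occupancy conformer. A minimal topology (names, residues,
#' elements) is constructed; force-field parameters stay unset until
#' \code{\link{assign_parameters}} supplies them.
#'
#' @param path path to a PDB file
#' @param format only \code{"pdb"} is supported
#' @return an \code{ensemble}
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("structure file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(lines, "MODEL")
  is_endmdl <- startsWith(lines, "ENDMDL")
  if (!any(is_atom)) stop("no ATOM/HETATM records in ", path)

  # assign each atom line to a model block
  model_id <- cumsum(is_model)
  if (!any(is_model)) model_id[] <- 1L
  atom_lines <- which(is_atom)
  amod <- model_id[atom_lines]
  if (any(is_model) && any(amod == 0L))
    stop("ATOM record before first MODEL at line ",
         atom_lines[which(amod == 0L)[1]])

  parse_block <- function(idx) {
    txt <- lines[idx]
    bad <- nchar(txt) < 54
    if (any(bad))
      stop("malformed ATOM record (too short) at line ", idx[bad][1])
    x <- suppressWarnings(as.numeric(substr(txt, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(txt, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(txt, 47, 54)))
    if (anyNA(x) || anyNA(y) || anyNA(z))
      stop("malformed ATOM record (bad coordinates) at line ",
           idx[which(is.na(x) | is.na(y) | is.na(z))[1]])
    resid <- suppressWarnings(as.integer(substr(txt, 23, 26)))
    if (anyNA(resid))
      stop("malformed ATOM record (bad residue number) at line ",
           idx[which(is.na(resid))[1]])
    occ <- suppressWarnings(as.numeric(substr(txt, 55, 60)))
    occ[is.na(occ)] <- 1
    data.frame(
      record = trimws(substr(txt, 1, 6)),
      name = trimws(substr(txt, 13, 16)),
      altloc = substr(txt, 17, 17),
      resname = trimws(substr(txt, 18, 21)),
      chain = trimws(substr(txt, 22, 22)),
      resid = resid,
      icode = trimws(substr(txt, 27, 27)),
      x = x, y = y, z = z, occ = occ,
      element = trimws(substr(txt, 77, 78)),
      stringsAsFactors = FALSE)
  }

  blocks <- split(atom_lines, amod)
  first <- parse_block(blocks[[1]])

  # alternate locations: keep the highest-occupancy conformer per atom site
  keep <- rep(TRUE, nrow(first))
  has_alt <- first$altloc != " " & first$altloc != ""
  if (any(has_alt)) {
    site <- paste(first$chain, first$resid, first$icode, first$resname,
                  first$name)
    for (s in unique(site[has_alt])) {
      rows <- which(site == s)
      if (length(rows) > 1L) {
        best <- rows[which.max(first$occ[rows])]
        keep[setdiff(rows, best)] <- FALSE
      }
    }
  }
  keep_idx <- which(keep)
  first <- first[keep_idx, , drop = FALSE]

  element <- first$element
  blank <- !nzchar(element)
  if (any(blank))
    element[blank] <- mapply(infer_element, first$name[blank],
                             first$resname[blank], first$record[blank])

  atoms <- data.frame(
    name = first$name, element = element, resname = first$resname,
    resid = first$resid, chain = first$chain, icode = first$icode,
    stringsAsFactors = FALSE)
  top <- topology(atoms)

  xyz <- matrix(NA_real_, nrow = length(blocks), ncol = 3L * nrow(atoms))
  xyz[1, ] <- flatten_coords(as.matrix(first[, c("x", "y", "z")]))
  if (length(blocks) > 1L) {
    for (m in 2:length(blocks)) {
      blk <- parse_block(blocks[[m]])
      blk <- blk[intersect(keep_idx, seq_len(nrow(blk))), , drop = FALSE]
      if (nrow(blk) != nrow(atoms) || !all(blk$name == atoms$name))
        stop(sprintf("MODEL %d atom records do not match MODEL 1 (%d vs %d atoms)",
                     m, nrow(blk), nrow(atoms)))
      xyz[m, ] <- flatten_coords(as.matrix(blk[, c("x", "y", "z")]))
    }
  }
  ensemble(top, xyz)
}

#' Write an ensemble as a multi-model PDB file
#'
#' Coordinates are written at the PDB fixed-width precision (3 decimals);
#' \code{read_structure(write_ensemble(e))} reproduces them to 0.001 A and
#' preserves atom order exactly.
#'
#' @param e an \code{ensemble} (non-empty)
#' @param path output path
#' @export
write_ensemble <- function(e, path) {
  stopifnot(inherits(e, "ensemble"))
  if (n_frames(e) < 1L) stop("cannot write an empty ensemble")
  a <- e$topology$atoms
  het <- a$resname %in% c(WATER_RESNAMES, "ZN", "CL", "NA") |
    toupper(a$element) %in% c("ZN", "CL", "BR", "MG", "FE", "CU", "MN")
  recname <- ifelse(het, "HETATM", "ATOM  ")
  pdbname <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
  pdbname <- formatC(pdbname, width = -4)
  elem <- toupper(substr(a$element, 1, 2))
  con <- file(path, open = "wt")
  on.exit(close(con))
  multi <- n_frames(e) > 1L
  for (m in seq_len(n_frames(e))) {
    if (multi) writeLines(sprintf("MODEL %8d", m), con)
    cc <- frame_coords(e, m)
    writeLines(sprintf(
      "%s%5d %s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      recname, seq_len(nrow(a)) %% 100000L, pdbname, " ",
      a$resname, ifelse(nzchar(a$chain), a$chain, " "),
      a$resid %% 10000L, ifelse(nzchar(a$icode), a$icode, " "),
      cc[, 1], cc[, 2], cc[, 3], 1, 0,
      formatC(elem, width = 2)), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Remove solvent (and optionally counter-ions) from an ensemble
#'
#' Waters are recognized by residue name (HOH/WAT/TIP3), monatomic
#' counter-ions by element (Cl, Na, K). The number of removed atoms is
#' reported via \code{message()}; stripping is never silent.
#'
#' @param e an \code{ensemble}
#' @param ions also strip monatomic counter-ions (default TRUE)
#' @export
strip_solvent <- function(e, ions = TRUE) {
  a <- e$topology$atoms
  drop <- a$resname %in% WATER_RESNAMES
  if (ions) drop <- drop | toupper(a$element) %in% c("CL", "NA", "K")
  if (!any(drop)) {
    message("strip_solvent: nothing to strip (0 atoms removed)")
    return(e)
  }
  message(sprintf("strip_solvent: removed %d atom(s) (%d water, %d ion)",
                  sum(drop), sum(a$resname %in% WATER_RESNAMES),
                  sum(drop) - sum(a$resname %in% WATER_RESNAMES)))
  subset_ensemble(e, which(!drop))
}

# restrict an ensemble (and its topology) to a subset of atoms; bonded terms
# are kept only when all member atoms survive
subset_ensemble <- function(e, idx) {
  top <- e$topology
  map <- integer(n_atoms(top)); map[idx] <- seq_along(idx)
  remap <- function(m, params) {
    if (is.null(m) || !nrow(m)) return(list(m = m, p = params))
    ok <- apply(m, 1, function(r) all(r %in% idx))
    m2 <- matrix(map[m[ok, , drop = FALSE]], ncol = ncol(m))
    list(m = m2, p = if (!is.null(params)) params[ok, , drop = FALSE])
  }
  b <- remap(top$bonds, top$bond_params)
  an <- remap(top$angles, top$angle_params)
  to <- remap(top$torsions, top$torsion_params)
  top2 <- topology(top$atoms[idx, , drop = FALSE],
                   bonds = b$m, bond_params = b$p,
                   angles = an$m, angle_params = an$p,
                   torsions = to$m, torsion_params = to$p,
                   energy_offset = top$energy_offset)
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  ensemble(top2, e$xyz[, cols, drop = FALSE], e$metadata)
}
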
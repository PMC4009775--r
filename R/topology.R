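#' Construct a parameterized molecular topology
#'
#' A \code{topology} describes the atoms of one molecular system together
#' with its force-field parameters: partial charges (elementary charge
#' units), Lennard-Jones parameters (Rmin/2 in Angstrom, epsilon in
#' kcal/mol), intrinsic generalized-Born radii and dimensionless GB
#' screening factors, plus bonded terms (harmonic bonds and angles and
#' cosine torsion terms). Parameters may be left \code{NA} for structures
#' read from coordinate files until \code{\link{assign_parameters}} (or a
#' topology file) supplies them.
#'
#' @param atoms data.frame with columns \code{name}, \code{element},
#'   \code{resname}, \code{resid} (1-based author numbering, kept verbatim),
#'   \code{chain}, and optionally \code{icode}, \code{charge}, \code{rmin2},
#'   \code{eps}, \code{gb_radius}, \code{gb_screen}.
#' @param bonds integer matrix (n x 2) of 1-based atom indices.
#' @param bond_params data.frame with \code{kb} (kcal/mol/A^2), \code{b0} (A),
#'   one row per bond; may be NULL for an unparameterized skeleton.
#' @param angles integer matrix (n x 3); \code{angle_params} has
#'   \code{ktheta} (kcal/mol/rad^2) and \code{theta0} (degrees).
#' @param torsions integer matrix (n x 4) of force-field torsion terms;
#'   \code{torsion_params} has \code{vn} (kcal/mol), \code{periodicity},
#'   \code{gamma} (degrees).
#' @param energy_offset constant energy term (kcal/mol) added to the
#'   molecular-mechanics energy; used by the synthetic two-state generator
#'   to set enthalpy differences exactly.
#' @param zmatrix optional internal-coordinate table used by the synthetic
#'   builders (see \code{\link{build_coordinates_from_torsions}}).
#' @return object of class \code{topology}.
#' @export
topology <- function(atoms, bonds = NULL, bond_params = NULL,
                     angles = NULL, angle_params = NULL,
                     torsions = NULL, torsion_params = NULL,
                     energy_offset = 0, zmatrix = NULL) {
  stopifnot(is.data.frame(atoms), nrow(atoms) >= 1L)
  req <- c("name", "element", "resname", "resid", "chain")
  miss <- setdiff(req, names(atoms))
  if (length(miss))
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  for (col in c("icode", "charge", "rmin2", "eps", "gb_radius", "gb_screen")) {
    if (is.null(atoms[[col]]))
      atoms[[col]] <- if (col == "icode") "" else NA_real_
  }
  n <- nrow(atoms)
  bonds <- check_index_matrix(bonds, 2L, n, "bonds")
  angles <- check_index_matrix(angles, 3L, n, "angles")
  torsions <- check_index_matrix(torsions, 4L, n, "torsions")
  top <- structure(
    list(atoms = atoms, bonds = bonds, bond_params = bond_params,
         angles = angles, angle_params = angle_params,
         torsions = torsions, torsion_params = torsion_params,
         energy_offset = energy_offset, zmatrix = zmatrix),
    class = "topology")
  validate_topology(top)
  top
}

check_index_matrix <- function(m, ncols, natoms, what) {
  if (is.null(m)) return(matrix(integer(0), ncol = ncols))
  m <- as.matrix(m)
  storage.mode(m) <- "integer"
  if (ncol(m) != ncols) stop(sprintf("'%s' must have %d columns", what, ncols))
  if (nrow(m) && (min(m) < 1L || max(m) > natoms))
    stop(sprintf("'%s' references atom indices outside 1..%d", what, natoms))
  m
}

validate_topology <- function(top) {
  b <- top$bonds
  if (nrow(b) && any(b[, 1] == b[, 2]))
    stop("bond references the same atom twice")
  ch <- top$atoms$charge
  if (any(!is.na(ch) & !is.finite(ch))) stop("non-finite partial charge")
  r <- top$atoms$gb_radius
  if (any(!is.na(r) & r <= 0)) stop("all GB radii must be > 0")
  r2 <- top$atoms$rmin2
  if (any(!is.na(r2) & r2 <= 0)) stop("all Rmin/2 radii must be > 0")
  invisible(top)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues, %d bonds, %d angles, %d torsion terms\n",
              nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resid, x$atoms$icode))),
              nrow(x$bonds), nrow(x$angles), nrow(x$torsions)))
  param <- !any(is.na(x$atoms$charge)) && !any(is.na(x$atoms$gb_radius))
  cat(if (param) "fully parameterized" else "coordinates-only (parameters unset)", "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a \code{topology}
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Is every atom fully parameterized?
#' @param top a \code{topology}
#' @export
is_parameterized <- function(top) {
  a <- top$atoms
  !any(is.na(a$charge)) && !any(is.na(a$rmin2)) && !any(is.na(a$eps)) &&
    !any(is.na(a$gb_radius)) && !any(is.na(a$gb_screen))
}

#' Copy force-field parameters onto a structure-derived topology
#'
#' Transfers per-atom parameters and bonded terms from a parameterized
#' topology (e.g. read with \code{\link{read_topology}}) onto a topology
#' built from coordinates, matching by atom order. Atom counts and names
#' must agree.
#'
#' @param target topology lacking parameters
#' @param source fully parameterized topology
#' @export
assign_parameters <- function(target, source) {
  if (n_atoms(target) != n_atoms(source))
    stop("atom count mismatch between target and parameter source")
  if (!all(target$atoms$name == source$atoms$name))
    stop("atom name mismatch between target and parameter source")
  for (col in c("charge", "rmin2", "eps", "gb_radius", "gb_screen"))
    target$atoms[[col]] <- source$atoms[[col]]
  target$bonds <- source$bonds
  target$bond_params <- source$bond_params
  target$angles <- source$angles
  target$angle_params <- source$angle_params
  target$torsions <- source$torsions
  target$torsion_params <- source$torsion_params
  target$energy_offset <- source$energy_offset
  target$zmatrix <- source$zmatrix
  validate_topology(target)
  target
}

# adjacency list (neighbors per atom) from the bond table
bond_neighbors <- function(top) {
  n <- n_atoms(top)
  nb <- vector("list", n)
  b <- top$bonds
  for (k in seq_len(nrow(b))) {
    i <- b[k, 1]; j <- b[k, 2]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  lapply(nb, function(v) sort(unique(v)))
}

# 1-2/1-3 exclusion pairs and 1-4 scaled pairs (each pair once, i < j).
# 1-4 pairs that are also 1-2 or 1-3 (rings) are dropped from the 1-4 list.
exclusion_lists <- function(top) {
  nb <- bond_neighbors(top)
  n <- n_atoms(top)
  key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ex <- character(0); p14 <- character(0)
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (j > i) ex <- c(ex, key(i, j))          # 1-2
      for (k in nb[[j]]) {
        if (k != i && k > i) ex <- c(ex, key(i, k))   # 1-3
        if (k != i) for (l in nb[[k]]) {
          if (l != j && l != i && l > i) p14 <- c(p14, key(i, l))
        }
      }
    }
  }
  ex <- unique(ex)
  p14 <- setdiff(unique(p14), ex)
  parse_pairs <- function(s) {
    if (!length(s)) return(matrix(integer(0), ncol = 2))
    m <- do.call(rbind, strsplit(s, " ", fixed = TRUE))
    matrix(as.integer(m), ncol = 2)
  }
  list(excluded = parse_pairs(ex), pairs14 = parse_pairs(p14))
}

TOPOLOGY_SECTIONS <- c("ATOMS", "BONDS", "ANGLES", "TORSIONS", "OFFSET")

#' Write a topology to a sectioned plain-text file
#'
#' The format is a simple line-oriented text format with \code{\%ATOMS},
#' \code{\%BONDS}, \code{\%ANGLES}, \code{\%TORSIONS} and \code{\%OFFSET}
#' sections; whitespace-separated columns, one record per line.
#' \code{\link{read_topology}} inverts it exactly (values printed with 12
#' significant digits).
#'
#' @param top a fully parameterized \code{topology}
#' @param path output file path
#' @export
write_topology <- function(top, path) {
  if (!is_parameterized(top))
    stop("refusing to write a topology with unset parameters")
  a <- top$atoms
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  lines <- c("%CONFREE_TOPOLOGY 1", "%ATOMS")
  lines <- c(lines, paste(seq_len(nrow(a)), a$name, a$element, a$resname,
                          a$resid, ifelse(a$chain == "", ".", a$chain),
                          fmt(a$charge), fmt(a$rmin2), fmt(a$eps),
                          fmt(a$gb_radius), fmt(a$gb_screen)))
  lines <- c(lines, "%BONDS")
  if (nrow(top$bonds))
    lines <- c(lines, paste(top$bonds[, 1], top$bonds[, 2],
                            fmt(top$bond_params$kb), fmt(top$bond_params$b0)))
  lines <- c(lines, "%ANGLES")
  if (nrow(top$angles))
    lines <- c(lines, paste(top$angles[, 1], top$angles[, 2], top$angles[, 3],
                            fmt(top$angle_params$ktheta),
                            fmt(top$angle_params$theta0)))
  lines <- c(lines, "%TORSIONS")
  if (nrow(top$torsions))
    lines <- c(lines, paste(top$torsions[, 1], top$torsions[, 2],
                            top$torsions[, 3], top$torsions[, 4],
                            fmt(top$torsion_params$vn),
                            top$torsion_params$periodicity,
                            fmt(top$torsion_params$gamma)))
  lines <- c(lines, "%OFFSET", fmt(top$energy_offset))
  writeLines(lines, path)
  invisible(path)
}

#' Read a parameterized topology from a sectioned text file
#'
#' @param path file written by \code{\link{write_topology}} (or assembled by
#'   hand in the same format).
#' @return a fully parameterized \code{topology}
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "%CONFREE_TOPOLOGY"))
    stop("not a confree topology file (missing %CONFREE_TOPOLOGY header)")
  sec_at <- grep("^%", lines)
  sec_names <- sub("^%", "", sub(" .*", "", lines[sec_at]))
  get_section <- function(name) {
    k <- which(sec_names == name)
    if (!length(k)) stop("topology file lacks required section %", name)
    from <- sec_at[k[1]] + 1L
    to <- if (k[1] < length(sec_at)) sec_at[k[1] + 1L] - 1L else length(lines)
    if (to < from) return(character(0))
    out <- trimws(lines[from:to])
    out[nzchar(out)]
  }
  split_fields <- function(recs) strsplit(recs, "[[:space:]]+")
  arecs <- split_fields(get_section("ATOMS"))
  if (!length(arecs)) stop("topology file has zero atoms")
  if (length(unique(lengths(arecs))) != 1L)
    stop("ragged ATOMS section: records differ in field count")
  amat <- do.call(rbind, arecs)
  if (ncol(amat) != 11)
    stop("ATOMS section must have 11 fields per line ",
         "(index name element resname resid chain charge rmin2 eps gb_radius gb_screen)")
  num <- function(x) suppressWarnings(as.numeric(x))
  atoms <- data.frame(
    name = amat[, 2], element = amat[, 3], resname = amat[, 4],
    resid = suppressWarnings(as.integer(amat[, 5])),
    chain = ifelse(amat[, 6] == ".", "", amat[, 6]),
    charge = num(amat[, 7]), rmin2 = num(amat[, 8]),
    eps = num(amat[, 9]), gb_radius = num(amat[, 10]),
    gb_screen = num(amat[, 11]), stringsAsFactors = FALSE)
  if (any(is.na(atoms$gb_radius)))
    stop("atom(s) lacking a GB radius in ATOMS section: ",
         paste(which(is.na(atoms$gb_radius)), collapse = ", "))
  if (any(is.na(atoms$charge)) || any(is.na(atoms$rmin2)) ||
      any(is.na(atoms$eps)) || any(is.na(atoms$gb_screen)))
    stop("incomplete atom parameters in ATOMS section")
  num_section <- function(name, ncols) {
    recs <- split_fields(get_section(name))
    if (!length(recs)) return(NULL)
    m <- do.call(rbind, recs)
    if (ncol(m) != ncols)
      stop(sprintf("%s section must have %d fields per line", name, ncols))
    out <- matrix(suppressWarnings(as.numeric(m)), ncol = ncols)
    if (anyNA(out))
      stop(sprintf("non-numeric field in %s section", name))
    out
  }
  bm <- num_section("BONDS", 4)
  am <- num_section("ANGLES", 5)
  tm <- num_section("TORSIONS", 7)
  off <- get_section("OFFSET")
  top <- topology(
    atoms,
    bonds = if (!is.null(bm)) matrix(as.integer(bm[, 1:2]), ncol = 2),
    bond_params = if (!is.null(bm)) data.frame(kb = bm[, 3], b0 = bm[, 4]),
    angles = if (!is.null(am)) matrix(as.integer(am[, 1:3]), ncol = 3),
    angle_params = if (!is.null(am))
      data.frame(ktheta = am[, 4], theta0 = am[, 5]),
    torsions = if (!is.null(tm)) matrix(as.integer(tm[, 1:4]), ncol = 4),
    torsion_params = if (!is.null(tm))
      data.frame(vn = tm[, 5], periodicity = as.integer(tm[, 6]),
                 gamma = tm[, 7]),
    energy_offset = if (length(off)) as.numeric(off[1]) else 0)
  top
}
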
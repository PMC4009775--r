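#' Select atoms from a topology with a small expression grammar
#'
#' Supported terms, combinable with \code{and}, \code{or}, \code{not} and
#' parentheses (\code{not} binds tightest, then \code{and}, then \code{or}):
#' \itemize{
#'   \item \code{element=Zn} -- by chemical element (case-insensitive)
#'   \item \code{name CA} or \code{name in \{N,CA,C,O\}} -- by atom name
#'   \item \code{resid 207-219} or \code{resid 42} -- by author residue number
#'   \item \code{resname HOH} -- by residue name
#'   \item \code{chain A} -- by chain identifier
#'   \item \code{main-chain} -- atoms named N, CA, C or O
#'   \item \code{water} -- residue name HOH, WAT or TIP3
#'   \item \code{zinc} -- element Zn or residue name ZN
#'   \item \code{all} -- every atom
#' }
#' The result preserves topology atom order. Unparseable input raises a
#' syntax error reporting the character position.
#'
#' @param top a \code{\link{topology}}
#' @param expression selection string
#' @param label optional human-readable label (defaults to the expression)
#' @return an \code{atom_selection}: integer atom indices (1-based) with a
#'   \code{label} attribute
#' @export
select <- function(top, expression, label = expression) {
  stopifnot(inherits(top, "topology"), is.character(expression),
            length(expression) == 1L)
  toks <- tokenize_selection(expression)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L; st$expr <- expression
  mask <- parse_or(st, top)
  if (st$pos <= nrow(st$toks))
    sel_error(st, "unexpected trailing input")
  atom_selection(which(mask), label)
}

#' Construct an atom selection from explicit indices
#' @param indices integer atom indices (1-based, unique, order-preserving)
#' @param label human-readable label
#' @export
atom_selection <- function(indices, label = "selection") {
  indices <- as.integer(indices)
  if (anyDuplicated(indices)) stop("selection indices must be unique")
  structure(indices, label = label, class = "atom_selection")
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("atom_selection '%s': %d atom(s)\n",
              attr(x, "label"), length(x)))
  invisible(x)
}

tokenize_selection <- function(expr) {
  pat <- "[A-Za-z_][A-Za-z0-9_'*-]*|[0-9]+-[0-9]+|[0-9]+|=|\\{|\\}|,|\\(|\\)"
  m <- gregexpr(pat, expr)[[1]]
  if (m[1] == -1L && nzchar(trimws(expr)))
    stop(sprintf("selection syntax error at position 1: '%s'", expr))
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  # anything outside tokens must be whitespace
  covered <- rep(FALSE, nchar(expr))
  for (k in seq_along(starts))
    covered[starts[k]:(starts[k] + lens[k] - 1L)] <- TRUE
  chars <- strsplit(expr, "")[[1]]
  stray <- which(!covered & !grepl("^[[:space:]]$", chars))
  if (length(stray))
    stop(sprintf("selection syntax error at position %d: unexpected '%s'",
                 stray[1], chars[stray[1]]))
  data.frame(tok = toks, pos = starts, stringsAsFactors = FALSE)
}

sel_error <- function(st, msg) {
  pos <- if (st$pos <= nrow(st$toks)) st$toks$pos[st$pos]
         else nchar(st$expr) + 1L
  stop(sprintf("selection syntax error at position %d: %s (in '%s')",
               pos, msg, st$expr))
}

peek <- function(st) if (st$pos <= nrow(st$toks)) st$toks$tok[st$pos] else NA
advance <- function(st) { t <- peek(st); st$pos <- st$pos + 1L; t }
expect <- function(st, tok) {
  if (!identical(peek(st), tok)) sel_error(st, paste0("expected '", tok, "'"))
  advance(st)
}

parse_or <- function(st, top) {
  left <- parse_and(st, top)
  while (identical(tolower(peek(st)), "or")) {
    advance(st)
    left <- left | parse_and(st, top)
  }
  left
}

parse_and <- function(st, top) {
  left <- parse_not(st, top)
  while (identical(tolower(peek(st)), "and")) {
    advance(st)
    left <- left & parse_not(st, top)
  }
  left
}

parse_not <- function(st, top) {
  if (identical(tolower(peek(st)), "not")) {
    advance(st)
    return(!parse_not(st, top))
  }
  parse_primary(st, top)
}

parse_primary <- function(st, top) {
  tok <- peek(st)
  if (is.na(tok)) sel_error(st, "unexpected end of expression")
  a <- top$atoms
  if (tok == "(") {
    advance(st)
    m <- parse_or(st, top)
    expect(st, ")")
    return(m)
  }
  low <- tolower(tok)
  if (low == "all") { advance(st); return(rep(TRUE, nrow(a))) }
  if (low %in% c("main-chain", "mainchain", "backbone")) {
    advance(st); return(a$name %in% c("N", "CA", "C", "O"))
  }
  if (low == "water") { advance(st); return(a$resname %in% WATER_RESNAMES) }
  if (low == "zinc") {
    advance(st)
    return(toupper(a$element) == "ZN" | toupper(a$resname) == "ZN")
  }
  if (low == "element") {
    advance(st); expect(st, "=")
    val <- advance(st)
    if (is.na(val)) sel_error(st, "expected an element symbol after 'element='")
    return(toupper(a$element) == toupper(val))
  }
  if (low == "name") {
    advance(st)
    if (identical(tolower(peek(st)), "in")) {
      advance(st); expect(st, "{")
      vals <- character(0)
      repeat {
        v <- advance(st)
        if (is.na(v) || v %in% c(",", "}")) sel_error(st, "expected atom name")
        vals <- c(vals, v)
        nxt <- advance(st)
        if (identical(nxt, "}")) break
        if (!identical(nxt, ",")) sel_error(st, "expected ',' or '}'")
      }
      return(a$name %in% vals)
    }
    v <- advance(st)
    if (is.na(v)) sel_error(st, "expected an atom name after 'name'")
    return(a$name == v)
  }
  if (low == "resname") {
    advance(st)
    v <- advance(st)
    if (is.na(v)) sel_error(st, "expected a residue name after 'resname'")
    return(toupper(a$resname) == toupper(v))
  }
  if (low == "chain") {
    advance(st)
    v <- advance(st)
    if (is.na(v)) sel_error(st, "expected a chain id after 'chain'")
    return(a$chain == v)
  }
  if (low == "resid") {
    advance(st)
    v <- advance(st)
    if (is.na(v) || !grepl("^[0-9]+(-[0-9]+)?$", v))
      sel_error(st, "expected a residue number or range after 'resid'")
    if (grepl("-", v)) {
      rng <- as.integer(strsplit(v, "-")[[1]])
      return(a$resid >= rng[1] & a$resid <= rng[2])
    }
    return(a$resid == as.integer(v))
  }
  sel_error(st, paste0("unknown term '", tok, "'"))
}
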
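# Atom selection mini-grammar.
#
# Grammar (case-insensitive keywords, whitespace-separated tokens):
#   expr    := term ('or' term)*
#   term    := factor ('and' factor)*
#   factor  := 'not' factor | '(' expr ')' | primary
#   primary := 'all' | 'none' | 'ca' | 'backbone' | 'heavy' | 'hydrogen'
#            | 'ligand' | 'protein'
#            | 'name' LIST | 'resname' LIST | 'chain' LIST | 'resid' RANGES
#            | 'within' DIST 'of' factor
# LIST is a comma-separated list of identifiers ('name OG,CB'); RANGES is a
# comma-separated list of residue numbers or A-B ranges ('resid 182-199').
# 'within R of X' selects atoms within R Angstrom of any atom matched by X,
# including X itself, evaluated on the coordinates supplied to select()
# (default: the structure's own); the evaluation frame is recorded in the
# mask provenance.

.tokenize_selection <- function(expression) {
  expr <- gsub("([()])", " \\1 ", expression)
  tokens <- strsplit(trimws(expr), "\\s+")[[1]]
  if (length(tokens) == 0) stop("empty selection expression")
  tokens
}

new_selection_mask <- function(indices, provenance, frame = "structure") {
  indices <- sort(unique(as.integer(indices)))
  structure(list(indices = indices, provenance = provenance, frame = frame),
            class = "SelectionMask")
}

#' @export
print.SelectionMask <- function(x, ...) {
  cat("SelectionMask:", length(x$indices), "atoms  [", x$provenance, "]\n")
  invisible(x)
}

.match_listed <- function(values, listed, what) {
  hits <- lapply(listed, function(id) {
    idx <- which(values == id)
    if (length(idx) == 0)
      stop("selection refers to unknown ", what, ": '", id, "'")
    idx
  })
  sort(unique(unlist(hits)))
}

.parse_ranges <- function(token) {
  parts <- strsplit(token, ",")[[1]]
  unlist(lapply(parts, function(p) {
    if (grepl("^-?[0-9]+--?[0-9]+$", p)) {
      ab <- as.integer(strsplit(sub("^(-?[0-9]+)-", "\\1 ", p), " ")[[1]])
      ab[1]:ab[2]
    } else if (grepl("^-?[0-9]+$", p)) {
      as.integer(p)
    } else stop("cannot parse residue range '", p, "'")
  }))
}

#' Select atoms of a structure
#'
#' Evaluates a selection expression (see the grammar in the package source
#' and README) against a `Structure` and returns a deterministic, sorted
#' `SelectionMask`.  Distance-based (`within`) clauses are evaluated on
#' `coordinates` and the mask records the frame label they were computed on.
#'
#' @param structure A `Structure`.
#' @param expression Selection string, e.g. `"ca and resid 182-199"`.
#' @param coordinates Optional N x 3 matrix for `within` clauses (default:
#'   the structure's own coordinates).
#' @param frame Label naming the coordinate set used (for provenance).
#' @return A `SelectionMask`.
#' @export
select_atoms <- function(structure, expression, coordinates = NULL,
                         frame = "structure") {
  atoms <- structure$atoms
  xyz <- if (is.null(coordinates)) coords(structure) else as.matrix(coordinates)
  if (nrow(xyz) != nrow(atoms))
    stop("coordinate matrix has ", nrow(xyz), " rows for ", nrow(atoms), " atoms")
  tokens <- .tokenize_selection(expression)
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tolower(tokens[pos]) else ""
  advance <- function() {
    tok <- tokens[pos]; pos <<- pos + 1L; tok
  }
  parse_expr <- function() {
    sel <- parse_term()
    while (peek() == "or") { advance(); sel <- sel | parse_term() }
    sel
  }
  parse_term <- function() {
    sel <- parse_factor()
    while (peek() == "and") { advance(); sel <- sel & parse_factor() }
    sel
  }
  parse_factor <- function() {
    tok <- peek()
    if (tok == "not") { advance(); return(!parse_factor()) }
    if (tok == "(") {
      advance(); sel <- parse_expr()
      if (peek() != ")") stop("unbalanced parentheses in selection")
      advance(); return(sel)
    }
    parse_primary()
  }
  flag <- function(idx) { v <- logical(nrow(atoms)); v[idx] <- TRUE; v }
  parse_primary <- function() {
    tok <- tolower(advance())
    switch(tok,
      all = rep(TRUE, nrow(atoms)),
      none = rep(FALSE, nrow(atoms)),
      ca = atoms$name == "CA" & !atoms$het,
      backbone = atoms$name %in% c("N", "CA", "C", "O") & !atoms$het,
      heavy = toupper(atoms$element) != "H",
      hydrogen = toupper(atoms$element) == "H",
      ligand = atoms$het,
      protein = !atoms$het,
      name = flag(.match_listed(atoms$name, strsplit(advance(), ",")[[1]],
                                "atom name")),
      resname = flag(.match_listed(atoms$resname,
                                   toupper(strsplit(advance(), ",")[[1]]),
                                   "residue name")),
      chain = flag(.match_listed(atoms$chain, strsplit(advance(), ",")[[1]],
                                 "chain")),
      resid = {
        wanted <- .parse_ranges(advance())
        missing <- setdiff(wanted, atoms$resno)
        if (length(missing) == length(wanted))
          stop("selection refers to unknown residue number(s): ",
               paste(missing, collapse = ","))
        atoms$resno %in% wanted
      },
      within = {
        r <- suppressWarnings(as.numeric(advance()))
        if (is.na(r) || r < 0) stop("'within' needs a non-negative distance")
        if (tolower(advance()) != "of") stop("'within <r> of <sel>' expected")
        ref <- parse_factor()
        if (!any(ref)) stop("'within' reference selection is empty")
        d2 <- .min_sq_dist_to_set(xyz, xyz[ref, , drop = FALSE])
        d2 <= r * r
      },
      stop("unknown selection keyword: '", tok, "'")
    )
  }
  sel <- parse_expr()
  if (pos <= length(tokens))
    stop("trailing tokens in selection: '",
         paste(tokens[pos:length(tokens)], collapse = " "), "'")
  frame_label <- if (grepl("within", tolower(expression))) frame else "n/a"
  new_selection_mask(which(sel),
                     provenance = expression,
                     frame = frame_label)
}

# Squared distance from every row of `pts` to its nearest row of `refs`.
.min_sq_dist_to_set <- function(pts, refs) {
  pr <- rowSums(pts^2)
  rr <- rowSums(refs^2)
  cross <- pts %*% t(refs)
  d2 <- outer(pr, rr, "+") - 2 * cross
  pmax(apply(d2, 1, min), 0)
}

#' Define a named residue region
#'
#' @param name Region name (e.g. `"lid"`).
#' @param resno Integer vector of author residue numbers.
#' @param chain Chain identifier.
#' @return A `RegionDefinition`.
#' @export
region_definition <- function(name, resno, chain = "A") {
  if (length(resno) == 0) stop("region '", name, "' is empty")
  structure(list(name = name, resno = as.integer(resno), chain = chain),
            class = "RegionDefinition")
}

# Mask of a region at a given atom level; errors if residues are absent.
region_mask <- function(structure, region, atom_level = c("ca", "heavy", "all")) {
  atom_level <- match.arg(atom_level)
  atoms <- structure$atoms
  present <- atoms$chain == region$chain & atoms$resno %in% region$resno
  missing <- setdiff(region$resno,
                     atoms$resno[atoms$chain == region$chain])
  if (length(missing) > 0)
    stop("region '", region$name, "' refers to absent residue(s): ",
         paste(missing, collapse = ","))
  keep <- switch(atom_level,
                 ca = present & atoms$name == "CA",
                 heavy = present & toupper(atoms$element) != "H",
                 all = present)
  new_selection_mask(which(keep),
                     provenance = sprintf("region %s [%s]", region$name,
                                          atom_level))
}
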
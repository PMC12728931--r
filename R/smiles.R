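# SMILES and MDL connection-table ingestion.
#
# The reader covers the SMILES subset needed for organic molecules: the
# organic subset atoms, bracket atoms with charge/isotope/H-count (stereo and
# isotopes are accepted and ignored), branches, ring closures (including
# %nn), '.'-disconnected components, and aromatic lower-case atoms. Bonds
# between two aromatic atoms default to the aromatic bond-order category;
# this keeps all six benzene ring bonds mutually duplicatable, which is the
# label convention the assembly-index calibration (benzoic acid, MA = 6)
# requires. Directional bonds / and \ are read as single bonds.

ORGANIC_SUBSET <- c("Cl", "Br", "B", "C", "N", "O", "P", "S", "F", "I")
AROMATIC_ORGANIC <- c("b", "c", "n", "o", "p", "s")

#' Parse a SMILES string
#'
#' Produces a hydrogen-suppressed [molgraph()] with deterministic edge
#' indexing (bond input order). Aromatic bonds form their own bond-order
#' category by default; set `kekulize = TRUE` to assign alternating
#' single/double bonds instead.
#'
#' @param text a single SMILES string; `'.'`-disconnected components are
#'   allowed and yield a multi-component graph.
#' @param kekulize replace aromatic bonds by a single/double assignment
#'   (backtracking matching over the aromatic system).
#' @return a `molgraph`.
#' @export
#' @examples
#' parse_smiles("OC(=O)c1ccccc1")  # benzoic acid: 9 atoms, 9 bonds
parse_smiles <- function(text, kekulize = FALSE) {
  stopifnot(is.character(text), length(text) == 1)
  s <- trimws(text)
  if (nchar(s) == 0) stop("empty SMILES string")

  elements <- character()
  charges <- integer()
  arom <- logical()
  hcount <- integer()
  from <- integer(); to <- integer(); order <- character()

  prev <- NA_integer_
  pending <- NA_character_
  stack <- integer()
  rings <- list()  # ring-closure id -> list(atom, bond)

  add_atom <- function(el, aromatic, charge = 0L, h = NA_integer_) {
    elements[length(elements) + 1] <<- el
    charges[length(charges) + 1] <<- charge
    arom[length(arom) + 1] <<- aromatic
    hcount[length(hcount) + 1] <<- h
    length(elements)
  }
  resolve <- function(bond, a1, a2) {
    if (!is.na(bond)) return(bond)
    if (arom[a1] && arom[a2]) "aromatic" else "single"
  }
  add_bond <- function(a1, a2, bond) {
    from[length(from) + 1] <<- a1
    to[length(to) + 1] <<- a2
    order[length(order) + 1] <<- resolve(bond, a1, a2)
  }
  attach_atom <- function(idx) {
    if (!is.na(prev)) add_bond(prev, idx, pending)
    prev <<- idx
    pending <<- NA_character_
  }

  i <- 1
  n <- nchar(s)
  while (i <= n) {
    ch <- substr(s, i, i)
    two <- substr(s, i, i + 1)
    if (two %in% ORGANIC_SUBSET[1:2]) {           # Cl, Br
      attach_atom(add_atom(two, FALSE))
      i <- i + 2
    } else if (ch %in% ORGANIC_SUBSET) {
      attach_atom(add_atom(ch, FALSE))
      i <- i + 1
    } else if (ch %in% AROMATIC_ORGANIC) {
      attach_atom(add_atom(toupper(ch), TRUE))
      i <- i + 1
    } else if (ch == "[") {
      j <- regexpr("]", substr(s, i, n), fixed = TRUE)
      if (j < 0) stop("unclosed bracket atom at position ", i)
      body <- substr(s, i + 1, i + j - 2)
      at <- parse_bracket_atom(body, i)
      if (at$element == "H") {
        # explicit hydrogen atom: suppressed together with its bond
        pending <- NA_character_
        i <- i + j
        next
      }
      attach_atom(add_atom(at$element, at$aromatic, at$charge, at$hcount))
      i <- i + j
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                        ":" = "aromatic", "/" = "single", "\\" = "single")
      i <- i + 1
    } else if (ch == "(") {
      if (is.na(prev)) stop("branch open without preceding atom at position ", i)
      stack <- c(stack, prev)
      i <- i + 1
    } else if (ch == ")") {
      if (length(stack) == 0) stop("unmatched ')' at position ", i)
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1
    } else if (ch == ".") {
      prev <- NA_integer_
      pending <- NA_character_
      i <- i + 1
    } else if (grepl("^[0-9]$", ch) || ch == "%") {
      if (ch == "%") {
        id <- substr(s, i + 1, i + 2)
        if (!grepl("^[0-9]{2}$", id)) stop("malformed %nn ring closure at position ", i)
        i <- i + 3
      } else {
        id <- ch
        i <- i + 1
      }
      if (is.na(prev)) stop("ring closure digit without atom at position ", i)
      if (is.null(rings[[id]])) {
        rings[[id]] <- list(atom = prev, bond = pending)
      } else {
        opened <- rings[[id]]
        bond <- if (!is.na(pending)) pending else opened$bond
        add_bond(opened$atom, prev,
                 if (is.null(bond) || is.na(bond)) NA_character_ else bond)
        rings[[id]] <- NULL
      }
      pending <- NA_character_
    } else if (ch == "@") {
      i <- i + 1  # stereo marker outside brackets: ignore
    } else {
      stop("unrecognised SMILES token '", ch, "' at position ", i)
    }
  }
  open_rings <- names(rings)[!vapply(rings, is.null, TRUE)]
  if (length(open_rings))
    stop("unclosed ring bond(s): ", paste(open_rings, collapse = ", "))

  bonds <- data.frame(from = from, to = to, order = order,
                      stringsAsFactors = FALSE)
  g <- molgraph(elements, bonds, charges, arom)
  g$h_counts <- hcount
  if (kekulize) g <- kekulize_graph(g)
  g
}

# element / charge / H-count of a [...] atom body; stereo and isotope ignored
parse_bracket_atom <- function(body, pos) {
  rest <- sub("^[0-9]*", "", body)               # isotope
  m <- regmatches(rest, regexpr("^([A-Z][a-z]?|[a-z])", rest))
  if (length(m) == 0)
    stop("cannot read element in bracket atom '[", body, "]' at position ", pos)
  el <- m
  aromatic <- el %in% AROMATIC_ORGANIC || (nchar(el) == 1 && el == tolower(el))
  if (aromatic) el <- paste0(toupper(substr(el, 1, 1)), substr(el, 2, 99))
  rest <- substr(rest, nchar(m) + 1, nchar(rest))
  rest <- gsub("@", "", rest)                    # stereo
  h <- 0L
  hm <- regmatches(rest, regexpr("H[0-9]*", rest))
  if (length(hm) == 1) {
    h <- if (nchar(hm) == 1) 1L else as.integer(substr(hm, 2, 99))
    rest <- sub("H[0-9]*", "", rest)
  }
  charge <- 0L
  if (grepl("\\+", rest)) {
    d <- regmatches(rest, regexpr("\\+[0-9]+", rest))
    charge <- if (length(d)) as.integer(substr(d, 2, 99))
              else sum(strsplit(rest, "")[[1]] == "+")
  } else if (grepl("-", rest)) {
    d <- regmatches(rest, regexpr("-[0-9]+", rest))
    charge <- if (length(d)) -as.integer(substr(d, 2, 99))
              else -sum(strsplit(rest, "")[[1]] == "-")
  }
  list(element = el, aromatic = aromatic, charge = charge, hcount = h)
}

# Assign alternating double bonds over the aromatic bond set by backtracking
# matching. Aromatic carbons need exactly one double bond (unless they already
# carry an exocyclic double/triple bond); aromatic N/P with an explicit H or a
# charge are pyrrole-type and need none; aromatic O/S never do.
kekulize_graph <- function(g) {
  ar_edges <- which(g$bonds$order == "aromatic")
  if (length(ar_edges) == 0) return(g)
  nb <- g$bonds
  exo_double <- rep(FALSE, length(g$elements))
  multi <- nb$order %in% c("double", "triple")
  exo_double[nb$from[multi]] <- TRUE
  exo_double[nb$to[multi]] <- TRUE
  h <- if (!is.null(g$h_counts)) g$h_counts else rep(NA_integer_, length(g$elements))
  needs <- function(v) {
    el <- g$elements[v]
    if (!g$aromatic_atoms[v]) return(FALSE)
    if (el == "C") return(!exo_double[v])
    if (el %in% c("N", "P"))
      return(!(isTRUE(h[v] >= 1) || g$charges[v] != 0))
    FALSE
  }
  req <- which(vapply(seq_along(g$elements), needs, TRUE))
  matched_edge <- rep(FALSE, length(ar_edges))
  used <- rep(FALSE, length(g$elements))
  assign_rec <- function(ri) {
    if (ri > length(req)) return(TRUE)
    v <- req[ri]
    if (used[v]) return(assign_rec(ri + 1))
    for (ei in seq_along(ar_edges)) {
      e <- ar_edges[ei]
      u <- if (nb$from[e] == v) nb$to[e] else if (nb$to[e] == v) nb$from[e] else next
      if (used[u] || !(u %in% req)) next
      used[v] <<- TRUE; used[u] <<- TRUE; matched_edge[ei] <<- TRUE
      if (assign_rec(ri + 1)) return(TRUE)
      used[v] <<- FALSE; used[u] <<- FALSE; matched_edge[ei] <<- FALSE
    }
    FALSE
  }
  if (!assign_rec(1))
    stop("cannot kekulize aromatic system")
  g$bonds$order[ar_edges] <- ifelse(matched_edge, "double", "single")
  g$aromatic_atoms[] <- FALSE
  g
}

#' Parse an MDL MOL/SDF block
#'
#' Reads a V2000 connection table through ChemmineR and converts it to the
#' package's graph model: hydrogens are stripped, bond type 4 maps to the
#' aromatic category, and edge indices follow the bond-block order.
#'
#' @param text character: the MOL block (single string or vector of lines).
#' @return a `molgraph`.
#' @export
parse_molblock <- function(text) {
  lines <- if (length(text) == 1) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdf <- tryCatch(ChemmineR::read.SDFset(tf),
                  error = function(e) stop("malformed MOL block: ",
                                           conditionMessage(e)))
  sdf_to_molgraph(sdf[[1]])
}

#' Read molecules from an SDF file
#'
#' @param path SDF file with one or more V2000 records.
#' @return list of `molgraph` objects.
#' @export
read_sdf_molecules <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  lapply(seq_along(ChemmineR::cid(sdf)), function(i) sdf_to_molgraph(sdf[[i]]))
}

sdf_to_molgraph <- function(sdf1) {
  ab <- ChemmineR::atomblock(sdf1)
  bb <- ChemmineR::bondblock(sdf1)
  elements <- sub("_[0-9]+$", "", rownames(ab))
  if (is.null(dim(bb)) || nrow(bb) == 0) {
    bonds <- NULL
  } else {
    ord <- as.integer(bb[, 3])
    if (any(!ord %in% 1:4))
      stop("unsupported bond type in MOL block: ", paste(setdiff(ord, 1:4), collapse = ","))
    bonds <- data.frame(from = as.integer(bb[, 1]), to = as.integer(bb[, 2]),
                        order = BOND_ORDERS[ord], stringsAsFactors = FALSE)
  }
  # strip explicit hydrogens, keep heavy-atom bonds, re-index
  keep <- elements != "H"
  if (!all(keep)) {
    remap <- cumsum(keep)
    if (!is.null(bonds)) {
      hb <- keep[bonds$from] & keep[bonds$to]
      bonds <- bonds[hb, , drop = FALSE]
      bonds$from <- remap[bonds$from]
      bonds$to <- remap[bonds$to]
    }
    elements <- elements[keep]
  }
  molgraph(elements, bonds,
           aromatic_atoms = FALSE)
}
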
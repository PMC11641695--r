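#' Molecular graphs of peptide structural formulae
#'
#' A `mol_graph` is a minimal explicit-hydrogen molecular graph: an atom table
#' (element symbol, ring flag) and a bond table (1-based atom indices plus the
#' bond order). Bond orders are stored for SDF fidelity only; descriptors
#' ignore them.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds two- or three-column matrix/data.frame: atom index `a`, atom
#'   index `b` and optional integer `order` (default 1).
#' @param name molecule name.
#' @return An object of class `mol_graph` with components `atoms`
#'   (data.frame: `element`, `in_ring`) and `bonds` (data.frame: `a`, `b`,
#'   `order`), plus the `name` attribute-like field.
#' @examples
#' water <- molecular_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)), "water")
#' descriptor_set(water, 1)
#' @export
molecular_graph <- function(elements, bonds, name = "") {
  elements <- as.character(elements)
  if (is.null(bonds) || length(bonds) == 0L) {
    bdf <- data.frame(a = integer(), b = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    if (ncol(bonds) == 2L) bonds$order <- 1L
    names(bonds) <- c("a", "b", "order")
    bdf <- data.frame(a = as.integer(bonds$a), b = as.integer(bonds$b),
                      order = as.integer(bonds$order))
  }
  if (any(bdf$a == bdf$b)) stop("self-bonds are not allowed")
  if (nrow(bdf) > 0L) {
    key <- paste(pmin(bdf$a, bdf$b), pmax(bdf$a, bdf$b))
    if (anyDuplicated(key)) stop("duplicate bonds are not allowed")
    if (any(bdf$a < 1L | bdf$b < 1L | bdf$a > length(elements) | bdf$b > length(elements)))
      stop("bond refers to a nonexistent atom")
  }
  g <- structure(list(
    atoms = data.frame(element = elements, in_ring = NA,
                       stringsAsFactors = FALSE),
    bonds = bdf, name = name), class = "mol_graph")
  g$atoms$in_ring <- detect_ring_atoms_flag(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("<mol_graph> %s: %d atoms (%s), %d bonds, %d ring atoms\n",
              if (nzchar(x$name)) x$name else "(unnamed)",
              nrow(x$atoms),
              paste(sprintf("%s%d", names(comp), comp), collapse = " "),
              nrow(x$bonds), sum(x$atoms$in_ring)))
  invisible(x)
}

n_atoms <- function(g) nrow(g$atoms)

# adjacency list over 1-based atom indices
graph_adjacency <- function(g) {
  ends <- c(g$bonds$a, g$bonds$b)
  other <- c(g$bonds$b, g$bonds$a)
  unname(split(other, factor(ends, levels = seq_len(n_atoms(g)))))
}

as_igraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("a", "b")] else data.frame(a = integer(), b = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(g))))
}

# ring-membership flags: an atom lies on a cycle iff it is incident to at
# least one non-bridge edge
detect_ring_atoms_flag <- function(g) {
  flags <- rep(FALSE, n_atoms(g))
  if (nrow(g$bonds) == 0L) return(flags)
  ig <- as_igraph(g)
  br <- igraph::bridges(ig)
  ends <- igraph::ends(ig, igraph::E(ig), names = FALSE)
  keep <- setdiff(seq_len(nrow(ends)), as.integer(br))
  if (length(keep)) flags[unique(as.vector(ends[keep, , drop = FALSE]))] <- TRUE
  flags
}

#' Find atoms lying on a cycle
#'
#' Returns the indices of atoms incident to at least one non-bridge edge,
#' i.e. atoms on at least one ring. Ring membership drives the acyclic "-"
#' prefix of MNA atom labels.
#'
#' @param graph a [molecular_graph()] object.
#' @return Sorted integer vector of 1-based atom indices.
#' @export
detect_ring_atoms <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  which(detect_ring_atoms_flag(graph))
}

.valence_table <- c(C = 4L, N = 3L, O = 2L, S = 2L, H = 1L)

# check connectivity, explicit-hydrogen degrees and standard valences
validate_peptide_graph <- function(g) {
  adj <- graph_adjacency(g)
  deg <- vapply(adj, length, integer(1))
  if (n_atoms(g) > 1L && !igraph::is_connected(as_igraph(g)))
    stop("peptide graph is not connected")
  hyd <- g$atoms$element == "H"
  if (any(deg[hyd] != 1L)) stop("hydrogen atom with degree != 1")
  # valence = sum of incident bond orders
  val <- rep(0L, n_atoms(g))
  for (i in seq_len(nrow(g$bonds))) {
    val[g$bonds$a[i]] <- val[g$bonds$a[i]] + g$bonds$order[i]
    val[g$bonds$b[i]] <- val[g$bonds$b[i]] + g$bonds$order[i]
  }
  want <- .valence_table[g$atoms$element]
  if (any(is.na(want))) stop("unexpected element in peptide graph")
  if (any(val != want))
    stop("valence inconsistency at atom(s) ",
         paste(which(val != want), collapse = ", "))
  invisible(TRUE)
}

#' Build the structural formula of a peptide
#'
#' Converts a one-letter amino-acid sequence into the condensed polypeptide
#' molecular graph: residue templates are joined by peptide bonds (one water
#' eliminated per bond), termini are neutral (N-terminal NH2, C-terminal
#' COOH) and every hydrogen is an explicit graph atom. Atom order is
#' deterministic: residues N-to-C, backbone before side chain, each heavy
#' atom immediately followed by its hydrogens.
#'
#' @param sequence one-letter amino-acid string (20 standard residues).
#' @param name molecule name recorded in the graph (defaults to the sequence).
#' @return A [molecular_graph()] object.
#' @examples
#' g <- build_peptide_graph("G")   # glycine: 10 atoms, 9 bonds
#' table(g$atoms$element)
#' @export
build_peptide_graph <- function(sequence, name = sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      !nzchar(sequence))
    stop("invalid input: sequence must be a non-empty one-letter-code string")
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!(letters1 %in% names(.residue_templates)))
  if (length(bad))
    stop(sprintf("unsupported residue '%s' at position %d", letters1[bad[1]], bad[1]))

  n_res <- length(letters1)
  elements <- character(0)
  bonds_a <- integer(0); bonds_b <- integer(0); bonds_o <- integer(0)
  prev_C <- NA_integer_   # index of previous residue's carbonyl carbon

  add_atom <- function(el) {
    elements[[length(elements) + 1L]] <<- el
    length(elements)
  }
  add_bond <- function(a, b, o = 1L) {
    bonds_a[[length(bonds_a) + 1L]] <<- a
    bonds_b[[length(bonds_b) + 1L]] <<- b
    bonds_o[[length(bonds_o) + 1L]] <<- as.integer(o)
  }
  add_hydrogens <- function(heavy, n) {
    for (k in seq_len(n)) add_bond(heavy, add_atom("H"))
  }

  for (r in seq_len(n_res)) {
    res <- letters1[r]
    tpl <- .residue_templates[[res]]
    is_nterm <- r == 1L
    is_cterm <- r == n_res
    idx <- list()   # name -> atom index for this residue

    # backbone N (proline's ring N carries one H fewer)
    idx$N <- add_atom("N")
    nh_N <- if (res == "P") (if (is_nterm) 1L else 0L) else (if (is_nterm) 2L else 1L)
    add_hydrogens(idx$N, nh_N)
    if (!is_nterm) add_bond(prev_C, idx$N)          # peptide bond

    idx$CA <- add_atom("C")
    add_bond(idx$N, idx$CA)
    add_hydrogens(idx$CA, if (res == "G") 2L else 1L)

    idx$C <- add_atom("C")
    add_bond(idx$CA, idx$C)
    ox <- add_atom("O")                              # carbonyl O
    add_bond(idx$C, ox, 2L)
    if (is_cterm) {
      oxt <- add_atom("O")                           # hydroxyl of COOH
      add_bond(idx$C, oxt)
      add_hydrogens(oxt, 1L)
    }

    for (at in tpl$atoms) {
      idx[[at$name]] <- add_atom(at$element)
      add_hydrogens(idx[[at$name]], at$nh)
    }
    for (bd in tpl$bonds) add_bond(idx[[bd$a]], idx[[bd$b]], bd$order)

    prev_C <- idx$C
  }

  g <- molecular_graph(elements, cbind(bonds_a, bonds_b, bonds_o), name = name)
  validate_peptide_graph(g)
  g
}
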
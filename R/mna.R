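#' MNA atom labels
#'
#' The level-0 building block of multilevel-neighbourhood-of-atoms (MNA)
#' descriptors: the element symbol, prefixed with `-` when the atom does not
#' lie on any ring. Bond orders and charges play no role.
#'
#' @param element element symbol (e.g. `"C"`).
#' @param in_ring logical ring-membership flag.
#' @return Character vector of labels.
#' @examples
#' atom_label("O", FALSE)  # "-O"
#' atom_label("C", TRUE)   # "C"
#' @export
atom_label <- function(element, in_ring) {
  ifelse(in_ring, element, paste0("-", element))
}

# per-atom descriptor strings for every requested level, by dynamic
# programming over stored level-(k-1) strings; byte-order (radix) sort keeps
# the canonical form locale-independent
mna_atom_strings <- function(graph, max_level) {
  stopifnot(inherits(graph, "mol_graph"))
  if (max_level < 0L) stop("invalid argument: level must be >= 0")
  labels <- atom_label(graph$atoms$element, graph$atoms$in_ring)
  n <- length(labels)
  adj <- graph_adjacency(graph)
  out <- vector("list", max_level + 1L)
  ranks <- vector("list", max_level + 1L)
  out[[1L]] <- labels
  ranks[[1L]] <- match(labels, sort(unique(labels), method = "radix"))
  if (max_level >= 1L) {
    # Descriptor strings grow with level, so they are never sorted directly.
    # Their byte order is instead tracked through integer ranks: MNA strings
    # of one level are mutually prefix-free, hence the byte order of
    # "LABEL(D1..Dm)" equals the lexicographic order of
    # (LABEL + "(", ranks of the sorted sub-descriptors, shorter first),
    # which a radix sort of short fixed-width rank codes delivers.
    nbvec <- unlist(adj, use.names = FALSE)
    atom_f <- factor(rep.int(seq_len(n), lengths(adj)), levels = seq_len(n))
    af_nb <- as.integer(atom_f)
    lab_paren <- paste0(labels, "(")
    lab_code <- formatC(match(lab_paren, sort(unique(lab_paren), method = "radix")),
                        width = 3L, flag = "0")
    for (k in seq_len(max_level)) {
      prev <- out[[k]]
      nc <- ranks[[k]][nbvec]
      ord <- order(af_nb, nc, method = "radix")
      grp <- atom_f[ord]
      inner <- vapply(split(prev[nbvec[ord]], grp), paste0,
                      character(1), collapse = "")
      out[[k + 1L]] <- paste0(labels, "(", inner, ")")
      key <- paste0(lab_code,
                    vapply(split(formatC(nc[ord], width = 6L, flag = "0"), grp),
                           paste0, character(1), collapse = ""))
      ranks[[k + 1L]] <- match(key, sort(unique(key), method = "radix"))
    }
  }
  list(strings = out, ranks = ranks)
}

#' MNA descriptor of one atom
#'
#' Level 0 is the atom label; level k wraps the label around the
#' lexicographically sorted level-(k-1) descriptors of all bonded neighbours:
#' `LABEL(D1D2...Dn)`. The result is canonical — independent of atom and bond
#' input order.
#'
#' @param graph a [molecular_graph()].
#' @param atom_index 1-based atom index.
#' @param level neighbourhood depth in bonds, `>= 0`.
#' @return The descriptor string.
#' @examples
#' w <- molecular_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
#' mna_descriptor(w, 1, 1)  # "-O(-H-H)"
#' @export
mna_descriptor <- function(graph, atom_index, level) {
  level <- as.integer(level)
  if (is.na(level) || level < 0L) stop("invalid argument: level must be >= 0")
  stopifnot(atom_index >= 1L, atom_index <= n_atoms(graph))
  mna_atom_strings(graph, level)$strings[[level + 1L]][atom_index]
}

#' MNA descriptor set of a molecule
#'
#' The set of unique level-L descriptors over all atoms (hydrogens included
#' as full atoms). Invariant under any permutation of atom indices.
#'
#' @inheritParams mna_descriptor
#' @param union_levels if `TRUE`, return the union of descriptor sets over
#'   levels `0..level` instead of the single level (off by default: a model
#'   "at level L" uses exactly the level-L set).
#' @return Sorted character vector of unique descriptor strings.
#' @examples
#' w <- molecular_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
#' descriptor_set(w, 1)  # "-H(-O)" "-O(-H-H)"
#' @export
descriptor_set <- function(graph, level, union_levels = FALSE) {
  if (!union_levels) return(descriptor_sets(graph, level)[[1L]])
  sets <- descriptor_sets(graph, 0:level)
  sort(unique(unlist(sets, use.names = FALSE)), method = "radix")
}

#' MNA descriptor sets at several levels in one pass
#'
#' @inheritParams mna_descriptor
#' @param levels integer vector of levels `>= 0`.
#' @return Named list (one element per level) of sorted unique descriptor
#'   vectors.
#' @export
descriptor_sets <- function(graph, levels) {
  levels <- as.integer(levels)
  if (length(levels) == 0L || any(is.na(levels)) || any(levels < 0L))
    stop("invalid argument: levels must be integers >= 0")
  pa <- mna_atom_strings(graph, max(levels))
  out <- lapply(levels, function(l) {
    r <- pa$ranks[[l + 1L]]
    keep <- !duplicated(r)
    pa$strings[[l + 1L]][keep][order(r[keep])]
  })
  names(out) <- as.character(levels)
  out
}

#' Write a plain-text descriptor dump
#'
#' One line per molecule: `name<TAB>level<TAB>space-joined sorted descriptors`.
#'
#' @param graphs list of [molecular_graph()] objects.
#' @param level descriptor level.
#' @param path output file path.
#' @export
write_descriptor_dump <- function(graphs, level, path) {
  lines <- vapply(graphs, function(g) {
    paste(g$name, level, paste(descriptor_set(g, level), collapse = " "),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
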
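# SD file (MDL MOL V3000) reader/writer. The V3000 connection table has no
# atom-count limit, which matters for long peptides; coordinates are written
# as zeros (topology only). Class labels travel in data fields: SSP_TYPE
# (semicolon-separated multi-label) plus optional PDB_ID, CHAIN, RESOLUTION.

.sdf_elements <- c("H", "C", "N", "O", "S", "P", "F", "Cl", "Br", "I",
                   "Se", "B", "Si")

#' Write molecules to an SD file (MOL V3000)
#'
#' @param records list of records, each `list(graph = <mol_graph>,
#'   properties = <named character list>)`; a bare list of
#'   [molecular_graph()]s is also accepted (no properties).
#' @param path output file path or connection.
#' @return The path, invisibly.
#' @export
write_sdf_v3000 <- function(records, path) {
  records <- lapply(records, function(r)
    if (inherits(r, "mol_graph")) list(graph = r, properties = list()) else r)
  blocks <- vapply(records, function(r) {
    g <- r$graph
    stopifnot(inherits(g, "mol_graph"))
    na <- nrow(g$atoms); nb <- nrow(g$bonds)
    lines <- c(
      g$name,
      "  mnapred",
      "",
      "  0  0  0     0  0            999 V3000",
      "M  V30 BEGIN CTAB",
      sprintf("M  V30 COUNTS %d %d 0 0 0", na, nb),
      "M  V30 BEGIN ATOM",
      sprintf("M  V30 %d %s 0 0 0 0", seq_len(na), g$atoms$element),
      "M  V30 END ATOM",
      "M  V30 BEGIN BOND",
      if (nb > 0) sprintf("M  V30 %d %d %d %d", seq_len(nb), g$bonds$order,
                          g$bonds$a, g$bonds$b),
      "M  V30 END BOND",
      "M  V30 END CTAB",
      "M  END")
    props <- r$properties
    for (k in names(props))
      lines <- c(lines, sprintf(">  <%s>", k), as.character(props[[k]]), "")
    paste(c(lines, "$$$$"), collapse = "\n")
  }, character(1))
  writeLines(blocks, path)
  invisible(path)
}

#' Read an SD file (MOL V3000)
#'
#' Round-trips the output of [write_sdf_v3000()]: atoms, bonds, bond orders
#' and data fields are reproduced exactly.
#'
#' @param path input file path.
#' @return List of `list(graph = <mol_graph>, properties = <named list>)`.
#' @export
read_sdf_v3000 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  # split into molecule blocks on "$$$$"
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0L) stop("SDF parse error: no record terminator '$$$$'")
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(function(s, e) parse_sdf_block(lines[s:(e - 1L)], s),
         starts, ends, SIMPLIFY = FALSE)
}

parse_sdf_block <- function(block, offset) {
  err <- function(i, msg)
    stop(sprintf("SDF parse error at line %d: %s", offset + i - 1L, msg))
  name <- if (length(block)) block[1] else ""
  beg <- grep("^M  V30 BEGIN CTAB", block)
  if (length(beg) != 1L) err(1L, "missing 'M  V30 BEGIN CTAB'")
  v30 <- function(i) sub("^M  V30 ", "", block[i])

  cnt_i <- grep("^M  V30 COUNTS", block)
  if (length(cnt_i) != 1L) err(beg, "missing COUNTS line")
  counts <- as.integer(strsplit(trimws(v30(cnt_i)), "\\s+")[[1]][2:3])
  na <- counts[1]; nb <- counts[2]

  a0 <- grep("^M  V30 BEGIN ATOM", block); a1 <- grep("^M  V30 END ATOM", block)
  if (length(a0) != 1L || length(a1) != 1L) err(cnt_i, "malformed ATOM block")
  atom_lines <- if (a1 > a0 + 1L) block[(a0 + 1L):(a1 - 1L)] else character(0)
  if (length(atom_lines) != na) err(a0, "atom count mismatch")
  elements <- character(na)
  for (i in seq_along(atom_lines)) {
    f <- strsplit(trimws(sub("^M  V30 ", "", atom_lines[i])), "\\s+")[[1]]
    if (length(f) < 2L) err(a0 + i, "malformed atom line")
    if (!(f[2] %in% .sdf_elements)) err(a0 + i, paste0("unknown element '", f[2], "'"))
    elements[as.integer(f[1])] <- f[2]
  }

  b0 <- grep("^M  V30 BEGIN BOND", block); b1 <- grep("^M  V30 END BOND", block)
  if (length(b0) != 1L || length(b1) != 1L) err(a1, "malformed BOND block")
  bond_lines <- if (b1 > b0 + 1L) block[(b0 + 1L):(b1 - 1L)] else character(0)
  if (length(bond_lines) != nb) err(b0, "bond count mismatch")
  bonds <- matrix(0L, nrow = nb, ncol = 3L)
  for (i in seq_along(bond_lines)) {
    f <- as.integer(strsplit(trimws(sub("^M  V30 ", "", bond_lines[i])), "\\s+")[[1]])
    if (length(f) < 4L || anyNA(f[1:4])) err(b0 + i, "malformed bond line")
    bonds[f[1], ] <- c(f[3], f[4], f[2])
  }

  if (!any(grepl("^M  END", block))) err(length(block), "missing 'M  END'")

  # data fields: ">  <TAG>" then value lines until a blank line
  props <- list()
  ti <- grep("^>\\s*<", block)
  for (i in ti) {
    tag <- sub("^>\\s*<([^>]*)>.*$", "\\1", block[i])
    if (!nzchar(tag)) err(i, "empty data field name")
    j <- i + 1L; vals <- character(0)
    while (j <= length(block) && nzchar(trimws(block[j])) &&
           !startsWith(block[j], ">")) {
      vals <- c(vals, block[j]); j <- j + 1L
    }
    props[[tag]] <- paste(vals, collapse = "\n")
  }

  list(graph = molecular_graph(elements, if (nb) bonds else NULL, name = name),
       properties = props)
}

#' Read peptide sequences from FASTA or plain text
#'
#' Files containing `>` headers are parsed as FASTA (via Biostrings when
#' available); otherwise every non-empty line is taken as one one-letter
#' sequence.
#'
#' @param path input file path.
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no sequences in ", path)
  if (any(startsWith(lines, ">"))) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      ss <- Biostrings::readAAStringSet(path)
      out <- as.character(ss)
      names(out) <- names(ss)
      return(out)
    }
    hdr <- startsWith(lines, ">")
    ids <- cumsum(hdr)
    out <- vapply(split(lines[!hdr], ids[!hdr]), paste, character(1),
                  collapse = "")
    names(out) <- sub("^>", "", lines[hdr])[unique(ids[!hdr])]
    return(toupper(gsub("\\s", "", out)))
  }
  out <- toupper(gsub("\\s", "", lines))
  names(out) <- out
  out
}

#' Write training records to an SD file
#'
#' Converts each record's sequence to its structural formula and attaches the
#' class labels in the `SSP_TYPE` data field (semicolon-separated).
#'
#' @param records data.frame with columns `sequence` and `labels`
#'   (semicolon-joined class codes), e.g. from [assemble_training_set()] or
#'   [generate_synthetic_set()].
#' @param path output path.
#' @param extra_fields optional named list of constant data fields added to
#'   every record (e.g. seed provenance).
#' @return The path, invisibly.
#' @export
write_training_sdf <- function(records, path, extra_fields = list()) {
  recs <- lapply(seq_len(nrow(records)), function(i) {
    props <- c(list(SSP_TYPE = records$labels[i]), extra_fields)
    if (!is.null(records$pdb_id)) props$PDB_ID <- records$pdb_id[i]
    list(graph = build_peptide_graph(records$sequence[i]), properties = props)
  })
  write_sdf_v3000(recs, path)
}

#' Read training records from an SD file
#'
#' @param path SD file written by [write_training_sdf()] (or any V3000 SDF
#'   whose records carry an `SSP_TYPE` data field and whose molecule name is
#'   the one-letter sequence).
#' @return data.frame with columns `sequence` and `labels`.
#' @export
read_training_sdf <- function(path) {
  recs <- read_sdf_v3000(path)
  data.frame(
    sequence = vapply(recs, function(r) r$graph$name, character(1)),
    labels = vapply(recs, function(r) {
      v <- r$properties$SSP_TYPE
      if (is.null(v)) "" else v
    }, character(1)))
}
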
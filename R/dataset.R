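# Dataset assembly from DSSP output: parse the classic fixed-column format,
# cut per-class segments, apply the published filters (length 4-130, no
# beta-bridge B, resolution <= 2 A) and build multi-label training records.

#' Parse classic DSSP output
#'
#' Reads the fixed-column text produced by DSSP: the amino acid sits at
#' column 14 and the summary structure code at column 17 of each data line
#' after the `#  RESIDUE AA STRUCTURE` header. A blank structure code means
#' unstructured coil and is mapped to `C`; lowercase amino-acid letters
#' (disulfide-bonded cysteines) are mapped to `C` (cysteine); `!` rows mark
#' chain breaks and split the output.
#'
#' @param path a DSSP file path, or a character vector of its lines.
#' @return data.frame with one row per chain: `chain`, `sequence`, `codes`
#'   (equal-length strings of residues and 8/9-state codes).
#' @export
parse_dssp <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path))
    readLines(path, warn = FALSE) else path
  hdr <- grep("#  RESIDUE", lines, fixed = TRUE)
  if (length(hdr) == 0L)
    stop("DSSP parse error: missing '#  RESIDUE AA STRUCTURE' data header")
  data <- lines[seq(hdr[1] + 1L, length(lines))]
  data <- data[nzchar(trimws(data))]
  if (length(data) == 0L)
    return(data.frame(chain = character(), sequence = character(),
                      codes = character()))
  aa <- substring(data, 14L, 14L)
  ss <- substring(data, 17L, 17L)
  chain <- substring(data, 12L, 12L)
  # chain breaks: '!' (and '!*') in the AA column
  brk <- aa == "!"
  seg <- cumsum(brk)
  keep <- !brk
  if (!any(keep))
    return(data.frame(chain = character(), sequence = character(),
                      codes = character()))
  aa <- ifelse(aa %in% letters, "C", aa)          # SS-bonded cysteines
  ss <- ifelse(ss == " " | ss == "", "C", ss)     # blank = coil
  out <- do.call(rbind, lapply(split(which(keep), seg[keep]), function(ii) {
    data.frame(chain = trimws(chain[ii[1]]),
               sequence = paste(aa[ii], collapse = ""),
               codes = paste(ss[ii], collapse = ""))
  }))
  rownames(out) <- NULL
  bad <- nchar(out$sequence) != nchar(out$codes)
  if (any(bad)) stop("DSSP parse error: sequence/code length mismatch")
  out
}

#' Extract secondary-structure segments from a coded chain
#'
#' Maximal runs of an identical structure code become candidate segments;
#' runs shorter than `min_len` or longer than `max_len` are dropped, and the
#' rare beta-bridge code `B` is excluded from modelling altogether.
#'
#' @param sequence one-letter residue string.
#' @param codes equal-length 8/9-state structure string.
#' @param min_len,max_len inclusive length bounds (defaults 4 and 130).
#' @param pdb_id,chain,resolution provenance fields copied onto each segment.
#' @return data.frame with columns `sequence`, `ssp`, `pdb_id`, `chain`,
#'   `start` (1-based), `resolution`.
#' @export
extract_segments <- function(sequence, codes, min_len = 4L, max_len = 130L,
                             pdb_id = "", chain = "",
                             resolution = NA_real_) {
  if (nchar(sequence) != nchar(codes))
    stop("sequence and codes must have equal length")
  r <- rle(strsplit(codes, "")[[1]])
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len & r$lengths <= max_len & r$values != "B"
  nk <- sum(keep)
  data.frame(
    sequence = substring(sequence, starts, ends)[keep],
    ssp = r$values[keep],
    pdb_id = rep_len(pdb_id, nk), chain = rep_len(chain, nk),
    start = starts[keep],
    resolution = rep_len(resolution, nk))
}

#' Filter segments by crystallographic resolution
#'
#' @param segments data.frame from [extract_segments()].
#' @param max_res maximum resolution in angstroms, inclusive (default 2.0).
#' @param keep_missing keep segments lacking a resolution value (default
#'   `FALSE`: dropped).
#' @return The filtered data.frame.
#' @export
filter_by_resolution <- function(segments, max_res = 2.0, keep_missing = FALSE) {
  miss <- is.na(segments$resolution)
  keep <- (!miss & segments$resolution <= max_res) | (miss & keep_missing)
  segments[keep, , drop = FALSE]
}

#' Assemble multi-label training records from segments
#'
#' One record per unique sequence; its label set is the union of structure
#' codes observed for that sequence across all segments (a sequence observed
#' as both 3-10 helix and turn is a positive example of both classes).
#'
#' @param segments data.frame from [extract_segments()].
#' @return data.frame with columns `sequence`, `labels` (semicolon-joined,
#'   sorted), `n_sources` and `sources` (semicolon-joined
#'   `pdb_id:chain:start` triples).
#' @export
assemble_training_set <- function(segments) {
  if (nrow(segments) == 0L)
    return(data.frame(sequence = character(), labels = character(),
                      n_sources = integer(), sources = character()))
  sp <- split(seq_len(nrow(segments)), segments$sequence)
  out <- data.frame(
    sequence = names(sp),
    labels = vapply(sp, function(ii)
      paste(sort(unique(segments$ssp[ii])), collapse = ";"), character(1)),
    n_sources = vapply(sp, length, integer(1)),
    sources = vapply(sp, function(ii)
      paste(sort(sprintf("%s:%s:%d", segments$pdb_id[ii], segments$chain[ii],
                         segments$start[ii])), collapse = ";"), character(1)))
  rownames(out) <- NULL
  out[order(out$sequence), , drop = FALSE]
}

#' Class co-occurrence table of a training set
#'
#' Cell (r, c), r != c, counts unique sequences labelled with both classes;
#' the diagonal counts sequences belonging to only that single class. The
#' percentage form normalizes each non-empty column to 100.
#'
#' @param records data.frame from [assemble_training_set()] (columns
#'   `sequence`, `labels`).
#' @return `list(counts = 8x8 integer matrix, percent = 8x8 numeric matrix)`.
#' @export
cooccurrence_table <- function(records) {
  cls <- SSP_CLASSES
  counts <- matrix(0L, 8L, 8L, dimnames = list(cls, cls))
  if (nrow(records) > 0L) {
    labs <- lapply(records$labels, split_labels)
    for (l in labs) {
      l <- intersect(l, cls)
      if (length(l) == 1L) {
        counts[l, l] <- counts[l, l] + 1L
      } else if (length(l) > 1L) {
        for (a in l) for (b in setdiff(l, a))
          counts[a, b] <- counts[a, b] + 1L
      }
    }
  }
  csums <- colSums(counts)
  percent <- sweep(counts, 2L, ifelse(csums == 0, 1, csums), "/") * 100
  list(counts = counts, percent = percent)
}

#' Read a resolution metadata table
#'
#' Sidecar TSV with at least columns `pdb_id` and `resolution` (angstroms);
#' an optional `method` column is carried through.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_resolution_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pdb_id", "resolution") %in% names(df)))
  df$resolution <- as.numeric(df$resolution)
  df
}
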
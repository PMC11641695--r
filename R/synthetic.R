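# Seeded synthetic labelled peptide sets. The generator emulates the one
# regularity the classifier is meant to pick up from real data: residue
# composition differs between secondary-structure classes (helices are rich
# in A/L/E/K/M, strands in V/I/Y/T/F/W, turns and bends in G/N/P/D/S).
# Sequences are i.i.d. draws from a per-class residue-frequency vector, so
# the sets carry compositional signal but none of the positional or
# physical structure of real segments.

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# baseline weight 1 for every residue, boosted for class-favoured residues
.class_bias <- list(
  H = c(A = 4, L = 4, E = 3, K = 3, M = 2, Q = 2),
  G = c(A = 3, L = 2, E = 2, G = 2, K = 2, S = 2),
  I = c(A = 3, L = 3, I = 2, M = 2, E = 2),
  P = c(P = 6, G = 2, A = 2, Q = 2),
  E = c(V = 4, I = 4, Y = 3, T = 3, F = 2, W = 2),
  C = c(G = 2, S = 2, D = 2, N = 2, P = 2),
  T = c(G = 4, N = 3, D = 3, P = 2, S = 2),
  S = c(G = 3, S = 3, D = 2, N = 2, A = 2)
)

default_class_freqs <- function(classes = ssp_classes()) {
  out <- lapply(classes, function(cl) {
    w <- stats::setNames(rep(1, 20L), .AA20)
    b <- .class_bias[[cl]]
    w[names(b)] <- b
    w / sum(w)
  })
  names(out) <- classes
  out
}

#' Specification of a synthetic labelled peptide set
#'
#' @param classes subset of [ssp_classes()] to generate.
#' @param n_per_class sequences per class.
#' @param length_range inclusive sequence-length bounds, within 4-130
#'   (default 4-20, the typical length range of real helix/strand segments).
#' @param freqs named list of per-class residue-frequency vectors over the
#'   20 standard residues (each summing to 1); defaults to built-in
#'   class-biased compositions.
#' @param contamination fraction of sequences receiving a second random
#'   class label, emulating multi-type sequences (default 0).
#' @param seed integer seed; the generator is fully reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(classes = c("H", "E"), n_per_class = 200L,
                           length_range = c(4L, 20L), freqs = NULL,
                           contamination = 0, seed = 42L) {
  stopifnot(all(classes %in% SSP_CLASSES), n_per_class >= 1L,
            length(length_range) == 2L,
            length_range[1] >= 4L, length_range[2] <= 130L,
            length_range[1] <= length_range[2],
            contamination >= 0, contamination <= 1)
  if (is.null(freqs)) freqs <- default_class_freqs(classes)
  for (cl in classes) {
    f <- freqs[[cl]]
    if (is.null(f) || length(f) != 20L || any(f < 0) ||
        abs(sum(f) - 1) > 1e-8)
      stop("invalid residue-frequency vector for class ", cl)
  }
  structure(list(classes = classes, n_per_class = as.integer(n_per_class),
                 length_range = as.integer(length_range), freqs = freqs,
                 contamination = contamination, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic labelled peptide set
#'
#' Sequences are drawn i.i.d. from the class's residue-frequency vector with
#' lengths uniform in the spec's range; a `contamination` fraction of
#' records gets one extra random class label. Deterministic given the seed.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `sequence`, `labels` (semicolon-joined)
#'   and `class` (the generating class); attribute `seed` records the spec
#'   seed.
#' @export
generate_synthetic_set <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  rows <- lapply(spec$classes, function(cl) {
    f <- spec$freqs[[cl]]
    lens <- sample(seq.int(spec$length_range[1], spec$length_range[2]),
                   spec$n_per_class, replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(names(f), L, replace = TRUE, prob = f), collapse = ""),
      character(1))
    data.frame(sequence = seqs, labels = cl, class = cl)
  })
  out <- do.call(rbind, rows)
  if (spec$contamination > 0 && length(SSP_CLASSES) > 1L) {
    hit <- stats::runif(nrow(out)) < spec$contamination
    extra <- vapply(out$class[hit], function(cl)
      sample(setdiff(SSP_CLASSES, cl), 1L), character(1))
    out$labels[hit] <- paste(out$labels[hit], extra, sep = ";")
  }
  # multi-PDB duplicates are not emulated: one record per generated sequence
  out <- out[!duplicated(out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- spec$seed
  out
}
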
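# Whole-protein annotation: every subsequence of length 4-30 is predicted
# and each residue inherits, per class, the maximum Pa-Pi among the windows
# covering it. The per-residue call is the argmax class of those maxima.

# deterministic tie-break priority for the per-residue argmax
.class_priority <- c("H", "E", "C", "T", "S", "G", "P", "I")

#' Enumerate sliding windows over a sequence
#'
#' All (start, length) pairs with `wmin <= length <= min(wmax, L)`, ordered
#' by start and then length. There are `sum(L - w + 1)` of them.
#'
#' @param sequence one-letter sequence (only its length is used if a single
#'   number is given).
#' @param wmin,wmax inclusive window-length bounds (defaults 4 and 30).
#' @return data.frame with columns `start`, `length`, `sequence` (empty with
#'   a warning when the protein is shorter than `wmin`).
#' @export
enumerate_windows <- function(sequence, wmin = 4L, wmax = 30L) {
  stopifnot(wmin >= 1L, wmax >= wmin)
  L <- if (is.numeric(sequence)) as.integer(sequence) else nchar(sequence)
  if (L < wmin) {
    warning("sequence shorter than the minimum window length; no windows")
    return(data.frame(start = integer(), length = integer(),
                      sequence = character()))
  }
  wmax <- min(wmax, L)
  out <- do.call(rbind, lapply(seq_len(L), function(s) {
    w <- seq.int(wmin, wmax)
    w <- w[s + w - 1L <= L]
    if (length(w) == 0L) return(NULL)
    data.frame(start = s, length = w)
  }))
  out$sequence <- if (is.numeric(sequence)) NA_character_ else
    substring(sequence, out$start, out$start + out$length - 1L)
  out
}

#' Annotate a whole protein residue by residue
#'
#' Every window of length `wmin`-`wmax` is converted to its structural
#' formula, described by MNA descriptors at the model's level and predicted;
#' each residue then receives, for every class, the maximum Pa-Pi over the
#' windows covering it, and its called class is the argmax (ties broken by a
#' fixed priority H>E>C>T>S>G>P>I).
#'
#' @param model an [sspr_train()] model, or — for testing and
#'   experimentation — a function `f(window_sequence)` returning a named
#'   numeric vector of per-class deltas.
#' @param sequence protein sequence of length `>= 4`.
#' @param wmin,wmax window-length bounds (defaults 4 and 30).
#' @param min_delta optional reporting threshold: called classes whose best
#'   delta falls below it are masked to `NA` (raw deltas stay visible).
#' @return data.frame with one row per residue: `position`, `residue`,
#'   `class`, `delta`, plus one `delta_<class>` column per class.
#' @export
annotate_protein <- function(model, sequence, wmin = 4L, wmax = 30L,
                             min_delta = NULL) {
  L <- nchar(sequence)
  if (L < wmin)
    stop("sequence shorter than ", wmin,
         " residues: structure cannot be predicted for segments below the minimum window length")
  win <- enumerate_windows(sequence, wmin, wmax)

  predict_window <- if (is.function(model)) {
    function(s) model(s)
  } else {
    stopifnot(inherits(model, "sspr_model"))
    function(s) {
      dset <- descriptor_set(build_peptide_graph(s), model$level)
      vapply(SSP_CLASSES, function(cl) {
        p <- sspr_pa_pi(model, dset, cl)
        if (is.na(p$delta)) -Inf else p$delta
      }, numeric(1))
    }
  }

  # identical subsequences share one prediction
  uniq <- unique(win$sequence)
  preds <- lapply(uniq, predict_window)
  names(preds) <- uniq

  best <- matrix(-Inf, nrow = L, ncol = length(SSP_CLASSES),
                 dimnames = list(NULL, SSP_CLASSES))
  for (i in seq_len(nrow(win))) {
    d <- preds[[win$sequence[i]]][SSP_CLASSES]
    rows <- win$start[i]:(win$start[i] + win$length[i] - 1L)
    best[rows, ] <- pmax(best[rows, , drop = FALSE],
                         matrix(d, nrow = length(rows), ncol = 8L, byrow = TRUE))
  }

  pick <- apply(best[, .class_priority, drop = FALSE], 1L, function(v)
    .class_priority[which.max(v)])
  delta <- best[cbind(seq_len(L), match(pick, SSP_CLASSES))]
  if (!is.null(min_delta)) pick[delta < min_delta] <- NA_character_
  out <- data.frame(position = seq_len(L),
                    residue = strsplit(sequence, "")[[1]],
                    class = pick, delta = delta)
  colnames(best) <- paste0("delta_", SSP_CLASSES)
  cbind(out, as.data.frame(best))
}

.default_8to3 <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
                   C = "C", T = "C", S = "C", P = "C")

#' Map an 8-state structure string to 3 states
#'
#' Default mapping (the common DSSP convention): helices H, G, I to `H`;
#' strand E and bridge B to `E`; everything else (C, T, S and polyproline
#' P) to coil `C`.
#'
#' @param codes 8-state code string (possibly empty).
#' @param mapping named character vector overriding the default table.
#' @return The 3-state string.
#' @export
map_8_to_3 <- function(codes, mapping = NULL) {
  map <- .default_8to3
  if (!is.null(mapping)) map[names(mapping)] <- mapping
  if (!nzchar(codes)) return("")
  ch <- strsplit(codes, "")[[1]]
  out <- map[ch]
  if (anyNA(out)) stop("unknown structure code: ",
                       paste(unique(ch[is.na(out)]), collapse = ", "))
  paste(out, collapse = "")
}

#' Per-residue prediction accuracy Q8 / Q3
#'
#' `Q = 100 * (1/N) * sum_i d(y_i, yhat_i)` where d is 1 when the true and
#' predicted state of residue i agree and 0 otherwise. With `states = 3`
#' both strings are first collapsed by [map_8_to_3()].
#'
#' @param true_codes,pred_codes equal-length code strings.
#' @param states 8 (default) or 3.
#' @param mapping optional 8-to-3 mapping override.
#' @return `list(Q = <percent>, N =, matches =, confusion = <table>)`.
#' @export
q_score <- function(true_codes, pred_codes, states = 8L, mapping = NULL) {
  if (nchar(true_codes) != nchar(pred_codes))
    stop("true and predicted code strings must have equal length")
  if (nchar(true_codes) == 0L) stop("empty code strings")
  if (states == 3L) {
    true_codes <- map_8_to_3(true_codes, mapping)
    pred_codes <- map_8_to_3(pred_codes, mapping)
  } else if (states != 8L) stop("states must be 3 or 8")
  y <- strsplit(true_codes, "")[[1]]
  yhat <- strsplit(pred_codes, "")[[1]]
  N <- length(y)
  m <- sum(y == yhat)
  list(Q = 100 * m / N, N = N, matches = m,
       confusion = table(true = y, predicted = yhat))
}

#' Suppress predicted runs shorter than a minimum length
#'
#' Optional smoothing pass over a per-residue prediction string: maximal
#' runs shorter than `min_run` are replaced by `NA` placeholders (`-`),
#' reflecting that calls below four residues are not trustworthy.
#'
#' @param codes predicted code string.
#' @param min_run minimum run length kept (default 4).
#' @return The smoothed string with short runs replaced by `-`.
#' @export
smooth_short_runs <- function(codes, min_run = 4L) {
  if (!nzchar(codes)) return(codes)
  r <- rle(strsplit(codes, "")[[1]])
  r$values[r$lengths < min_run] <- "-"
  paste(inverse.rle(r), collapse = "")
}
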
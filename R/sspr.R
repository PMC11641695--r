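#' @title One-vs-rest Bayesian SSP classifier over MNA descriptor sets
#' @description
#' Eight secondary-structure classes are modelled (DSSP codes; the rare
#' beta-bridge state B is excluded from modelling): H (alpha-helix),
#' G (3-10 helix), I (pi-helix), P (polyproline II), E (strand), C (coil),
#' T (turn), S (bend). For each class the model accumulates descriptor
#' counts over the training records: `n` records in total, `n_a` positives,
#' and for every descriptor d the number of records `n_d[d]` and positive
#' records `n_ad[d]` containing it.
#'
#' The evidence score of a query descriptor set D is
#' \deqn{B = \frac{1}{|D|}\sum_{d \in D} (2\hat p(a\mid d) - 1), \qquad
#'       \hat p(a\mid d) = \frac{n_{ad} + c\,p_0}{n_d + c},\quad p_0 = n_a/n,}
#' with smoothing constant c (default 1); descriptors unseen in training
#' contribute \eqn{2p_0-1}. Pa and Pi are read off the empirical
#' distributions of leave-one-out training scores of the positives and
#' negatives respectively (ties counted one half), so Pa is non-decreasing
#' and Pi non-increasing in B and "Pa > Pi" is a per-class threshold rule
#' on B.
#' @name sspr-model
NULL

SSP_CLASSES <- c("H", "G", "I", "P", "E", "C", "T", "S")

#' The eight modelled secondary-structure classes
#' @return Character vector `c("H","G","I","P","E","C","T","S")`.
#' @export
ssp_classes <- function() SSP_CLASSES

# normalize records input: list of list(dset = character, labels = character)
# from either that shape or a data.frame with sequence/labels columns
as_sspr_records <- function(records, level = NULL) {
  if (is.data.frame(records)) {
    stopifnot("sequence" %in% names(records), "labels" %in% names(records))
    records <- lapply(seq_len(nrow(records)), function(i)
      list(sequence = records$sequence[i],
           labels = split_labels(records$labels[i])))
  }
  lapply(records, function(r) {
    if (is.null(r$dset)) {
      if (is.null(level))
        stop("records carry sequences, not descriptor sets: 'level' is required")
      r$dset <- descriptor_set(build_peptide_graph(r$sequence), level)
    }
    r$labels <- intersect(unique(as.character(r$labels)), SSP_CLASSES)
    r
  })
}

split_labels <- function(x) strsplit(as.character(x), ";", fixed = TRUE)[[1]]

# counts shared by train/score/LOO: vocabulary + integer matrices
build_counts <- function(records) {
  vocab <- sort(unique(unlist(lapply(records, `[[`, "dset"), use.names = FALSE)),
                method = "radix")
  n <- length(records)
  idx <- lapply(records, function(r) match(r$dset, vocab))
  n_d <- integer(length(vocab))
  for (ii in idx) n_d[ii] <- n_d[ii] + 1L
  pos <- sapply(SSP_CLASSES, function(cl)
    vapply(records, function(r) cl %in% r$labels, logical(1)))
  pos <- matrix(pos, nrow = n, dimnames = list(NULL, SSP_CLASSES))
  n_ad <- matrix(0L, nrow = length(vocab), ncol = length(SSP_CLASSES),
                 dimnames = list(NULL, SSP_CLASSES))
  for (i in seq_len(n)) {
    cls <- SSP_CLASSES[pos[i, ]]
    if (length(cls)) n_ad[idx[[i]], cls] <- n_ad[idx[[i]], cls] + 1L
  }
  list(vocab = vocab, n = n, n_d = n_d, n_a = colSums(pos), n_ad = n_ad,
       pos = pos, idx = idx)
}

# B score from raw counts; desc_idx NA = descriptor unseen in training
score_from_counts <- function(desc_idx, n, n_a, n_d, n_ad, c_smooth) {
  if (length(desc_idx) == 0L) stop("invalid input: empty descriptor set")
  p0 <- if (n > 0) n_a / n else 0.5
  nd <- ifelse(is.na(desc_idx), 0, n_d[ifelse(is.na(desc_idx), 1L, desc_idx)])
  nad <- ifelse(is.na(desc_idx), 0, n_ad[ifelse(is.na(desc_idx), 1L, desc_idx)])
  p_hat <- (nad + c_smooth * p0) / (nd + c_smooth)
  mean(2 * p_hat - 1)
}

#' Train an SSPR model
#'
#' Builds one-vs-rest descriptor count statistics for each of the eight
#' classes and stores the leave-one-out training-score distributions from
#' which Pa and Pi are later computed. A record labelled with several classes
#' is a positive example for each of them and a negative for the rest.
#' Classes with no positive or no negative record are dropped with a warning.
#'
#' @param records either a list of `list(dset = <character descriptor set>,
#'   labels = <character class codes>)`, a list of
#'   `list(sequence =, labels =)`, or a data.frame with columns `sequence`
#'   and `labels` (semicolon-separated codes). Sequences are converted to
#'   level-`level` descriptor sets.
#' @param level MNA descriptor level of the model (the published optimum for
#'   this method is level 9; small demonstration sets saturate much earlier).
#' @param c_smooth positive smoothing constant c (default 1).
#' @return An object of class `sspr_model`.
#' @export
sspr_train <- function(records, level = 9L, c_smooth = 1) {
  if (length(records) == 0L || (is.data.frame(records) && nrow(records) == 0L))
    stop("invalid input: empty record list")
  stopifnot(c_smooth > 0)
  records <- as_sspr_records(records, level)
  if (length(records) < 2L) stop("invalid input: need at least 2 records")
  cnt <- build_counts(records)

  trainable <- cnt$n_a >= 1L & cnt$n_a <= cnt$n - 1L
  if (any(!trainable))
    warning("untrainable class(es) dropped (no positives or no negatives): ",
            paste(SSP_CLASSES[!trainable], collapse = ", "))

  loo <- sspr_loo_scores(records, level = level, c_smooth = c_smooth,
                         counts = cnt)
  model <- list(
    version = 1L, level = as.integer(level), c_smooth = c_smooth,
    vocab = cnt$vocab, n = cnt$n, n_d = cnt$n_d,
    classes = SSP_CLASSES[trainable],
    n_a = cnt$n_a, n_ad = cnt$n_ad,
    pos_scores = lapply(SSP_CLASSES, function(cl)
      sort(loo[[cl]]$score[loo[[cl]]$is_positive])),
    neg_scores = lapply(SSP_CLASSES, function(cl)
      sort(loo[[cl]]$score[!loo[[cl]]$is_positive]))
  )
  names(model$pos_scores) <- SSP_CLASSES
  names(model$neg_scores) <- SSP_CLASSES
  structure(model, class = "sspr_model")
}

#' @export
print.sspr_model <- function(x, ...) {
  cat(sprintf("<sspr_model> level %d, c = %g, %d records, %d descriptors\n",
              x$level, x$c_smooth, x$n, length(x$vocab)))
  cat("  trainable classes:", paste(x$classes, collapse = " "), "\n")
  invisible(x)
}

#' Evidence score B of a descriptor set for one class
#'
#' @param model an [sspr_train()] model.
#' @param dset character descriptor set (or a [molecular_graph()] /
#'   one-letter sequence, converted at the model's level).
#' @param class one of the eight class codes.
#' @return B in `[-1, 1]`.
#' @export
sspr_score <- function(model, dset, class) {
  stopifnot(inherits(model, "sspr_model"), class %in% SSP_CLASSES)
  dset <- as_dset(model, dset)
  score_from_counts(match(dset, model$vocab), model$n, model$n_a[[class]],
                    model$n_d, model$n_ad[, class], model$c_smooth)
}

as_dset <- function(model, dset) {
  if (inherits(dset, "mol_graph")) return(descriptor_set(dset, model$level))
  as.character(dset)
}

#' Pa/Pi of a descriptor set for one class
#'
#' Pa is the fraction of positive leave-one-out training scores below the
#' query score B, Pi the fraction of negative training scores above it, with
#' ties counted one half.
#'
#' @inheritParams sspr_score
#' @return `list(B =, Pa =, Pi =, delta = Pa - Pi, possible = Pa > Pi)`;
#'   for an untrainable class all numeric fields are `NA`.
#' @export
sspr_pa_pi <- function(model, dset, class) {
  stopifnot(inherits(model, "sspr_model"), class %in% SSP_CLASSES)
  if (!(class %in% model$classes))
    return(list(B = NA_real_, Pa = NA_real_, Pi = NA_real_,
                delta = NA_real_, possible = NA))
  B <- sspr_score(model, dset, class)
  pos <- model$pos_scores[[class]]
  neg <- model$neg_scores[[class]]
  Pa <- (sum(pos < B) + 0.5 * sum(pos == B)) / length(pos)
  Pi <- (sum(neg > B) + 0.5 * sum(neg == B)) / length(neg)
  list(B = B, Pa = Pa, Pi = Pi, delta = Pa - Pi, possible = Pa > Pi)
}

#' Predict all classes for a set of peptides
#'
#' @param model an [sspr_train()] model.
#' @param sequences character vector of one-letter sequences, or a list of
#'   descriptor sets / [molecular_graph()]s.
#' @return data.frame with columns `sequence`, `class`, `B`, `Pa`, `Pi`,
#'   `delta`, `possible` (eight rows per peptide).
#' @export
sspr_predict <- function(model, sequences) {
  if (is.character(sequences)) {
    nm <- sequences
    items <- lapply(sequences, function(s)
      descriptor_set(build_peptide_graph(s), model$level))
  } else {
    items <- sequences
    nm <- vapply(seq_along(items), function(i) {
      if (inherits(items[[i]], "mol_graph") && nzchar(items[[i]]$name))
        items[[i]]$name else paste0("mol", i)
    }, character(1))
  }
  out <- do.call(rbind, lapply(seq_along(items), function(i) {
    dset <- as_dset(model, items[[i]])
    do.call(rbind, lapply(SSP_CLASSES, function(cl) {
      p <- sspr_pa_pi(model, dset, cl)
      data.frame(sequence = nm[i], class = cl, B = p$B, Pa = p$Pa, Pi = p$Pi,
                 delta = p$delta, possible = p$possible)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Leave-one-out training scores
#'
#' Scores each record for a class with its own contributions removed from all
#' counts (n, n_a, n_d, n_ad) — exactly equivalent to retraining without the
#' record, at O(1) extra cost per record.
#'
#' @inheritParams sspr_train
#' @param classes classes to evaluate (default: all eight).
#' @param counts internal precomputed counts (used by [sspr_train()]).
#' @return Named list per class: data.frame with columns `score`,
#'   `is_positive`.
#' @export
sspr_loo_scores <- function(records, level = 9L, c_smooth = 1,
                            classes = ssp_classes(), counts = NULL) {
  records <- as_sspr_records(records, level)
  cnt <- if (is.null(counts)) build_counts(records) else counts
  out <- lapply(classes, function(cl) {
    n_a <- cnt$n_a[[cl]]
    scores <- vapply(seq_len(cnt$n), function(i) {
      ii <- cnt$idx[[i]]
      is_pos <- cnt$pos[i, cl]
      n_d_i <- cnt$n_d[ii] - 1L
      n_ad_i <- cnt$n_ad[ii, cl] - as.integer(is_pos)
      n_i <- cnt$n - 1L
      na_i <- n_a - as.integer(is_pos)
      p0 <- if (n_i > 0) na_i / n_i else 0.5
      p_hat <- (n_ad_i + c_smooth * p0) / (n_d_i + c_smooth)
      mean(2 * p_hat - 1)
    }, numeric(1))
    data.frame(score = scores, is_positive = cnt$pos[, cl])
  })
  names(out) <- classes
  out
}

#' ROC AUC by the Mann–Whitney statistic
#'
#' Probability that a randomly chosen positive outscores a randomly chosen
#' negative, ties counted one half. Numerically equal to the invariant
#' accuracy of prediction (IAP) reported by leave-one-out cross-validation.
#'
#' @param scores numeric scores.
#' @param is_positive logical labels, same length.
#' @return AUC in `[0, 1]`.
#' @export
sspr_auc <- function(scores, is_positive) {
  stopifnot(length(scores) == length(is_positive))
  n_pos <- sum(is_positive); n_neg <- sum(!is_positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined result: AUC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Descriptor-level sweep of leave-one-out AUC
#'
#' Regenerates descriptor sets at each level, computes leave-one-out scores
#' per class and reports the per-class AUC and the unweighted mean over
#' evaluable classes.
#'
#' @param records a data.frame with `sequence`/`labels` columns or a list of
#'   `list(sequence =, labels =)` records.
#' @param levels integer vector of descriptor levels.
#' @param c_smooth smoothing constant.
#' @return data.frame with columns `level`, `class`, `auc` plus rows with
#'   `class == "mean"`; classes that are untrainable or single-labelled at
#'   some level are absent there.
#' @export
evaluate_levels <- function(records, levels, c_smooth = 1) {
  if (length(levels) == 0L) stop("invalid input: levels must be non-empty")
  if (is.data.frame(records)) {
    seqs <- records$sequence
    labels <- lapply(records$labels, split_labels)
  } else {
    seqs <- vapply(records, `[[`, character(1), "sequence")
    labels <- lapply(records, function(r) as.character(r$labels))
  }
  graphs <- lapply(seqs, build_peptide_graph)
  all_sets <- lapply(graphs, descriptor_sets, levels = levels)
  out <- do.call(rbind, lapply(seq_along(levels), function(li) {
    recs <- lapply(seq_along(graphs), function(i)
      list(dset = all_sets[[i]][[li]], labels = labels[[i]]))
    loo <- sspr_loo_scores(recs, level = levels[li], c_smooth = c_smooth)
    aucs <- vapply(SSP_CLASSES, function(cl) {
      df <- loo[[cl]]
      if (sum(df$is_positive) == 0L || sum(!df$is_positive) == 0L)
        return(NA_real_)
      sspr_auc(df$score, df$is_positive)
    }, numeric(1))
    rbind(data.frame(level = levels[li], class = SSP_CLASSES, auc = aucs),
          data.frame(level = levels[li], class = "mean",
                     auc = mean(aucs, na.rm = TRUE)))
  }))
  out[!is.na(out$auc), , drop = FALSE]
}

#' Save / load an SSPR model
#'
#' Portable versioned JSON: level, smoothing, descriptor vocabulary, global
#' and per-class counts and the sorted training-score arrays.
#'
#' @param model an `sspr_model`.
#' @param path file path.
#' @param extra named list of provenance fields stored in the file header
#'   (e.g. seed, tool version).
#' @return `read_sspr_model()` returns the model; `write_sspr_model()` the
#'   path, invisibly.
#' @export
write_sspr_model <- function(model, path, extra = list()) {
  stopifnot(inherits(model, "sspr_model"))
  payload <- unclass(model)
  payload$n_ad <- as.data.frame(payload$n_ad)
  payload$n_a <- as.list(payload$n_a)   # jsonlite drops names of atomic vectors
  payload$format <- "mnapred-sspr-model"
  payload$provenance <- c(list(tool = "mnapred",
                               tool_version = as.character(utils::packageVersion("mnapred"))),
                          extra)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname write_sspr_model
#' @export
read_sspr_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "mnapred-sspr-model"))
    stop("not an mnapred model file: ", path)
  m <- payload[c("version", "level", "c_smooth", "vocab", "n", "n_d",
                 "classes", "n_a", "n_ad", "pos_scores", "neg_scores")]
  m$n_ad <- as.matrix(m$n_ad)
  dimnames(m$n_ad) <- list(NULL, SSP_CLASSES)
  m$n_a <- unlist(m$n_a)[SSP_CLASSES]
  m$pos_scores <- lapply(m$pos_scores, as.numeric)[SSP_CLASSES]
  m$neg_scores <- lapply(m$neg_scores, as.numeric)[SSP_CLASSES]
  names(m$pos_scores) <- SSP_CLASSES
  names(m$neg_scores) <- SSP_CLASSES
  structure(m, class = "sspr_model")
}
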
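# Independent oracles used across the suite. Each deliberately avoids the
# code path it checks: naive recursion instead of dynamic programming,
# edge-removal connectivity instead of bridge detection, pairwise loops
# instead of rank statistics, full retraining instead of count decrements.

# --- MNA oracle: naive recursive expansion with explicit sorting ------------
oracle_mna_atom <- function(graph, atom, level) {
  lab <- atom_label(graph$atoms$element[atom], graph$atoms$in_ring[atom])
  if (level == 0L) return(lab)
  nb <- c(graph$bonds$b[graph$bonds$a == atom], graph$bonds$a[graph$bonds$b == atom])
  subs <- vapply(nb, function(j) oracle_mna_atom(graph, j, level - 1L), character(1))
  paste0(lab, "(", paste(sort(subs, method = "radix"), collapse = ""), ")")
}

oracle_descriptor_set <- function(graph, level) {
  sort(unique(vapply(seq_len(nrow(graph$atoms)), oracle_mna_atom,
                     character(1), graph = graph, level = level)),
       method = "radix")
}

# --- ring oracle: atom on a cycle iff some incident edge survives removal --
oracle_ring_atoms <- function(graph) {
  nb_list <- function(bonds, drop = 0L) {
    adj <- vector("list", nrow(graph$atoms))
    for (i in seq_len(nrow(bonds))) {
      if (i == drop) next
      a <- bonds$a[i]; b <- bonds$b[i]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    adj
  }
  connected_after_drop <- function(i) {
    adj <- nb_list(graph$bonds, drop = i)
    from <- graph$bonds$a[i]; to <- graph$bonds$b[i]
    seen <- rep(FALSE, nrow(graph$atoms)); queue <- from; seen[from] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
    }
    seen[to]
  }
  on_cycle <- vapply(seq_len(nrow(graph$bonds)), connected_after_drop, logical(1))
  sort(unique(c(graph$bonds$a[on_cycle], graph$bonds$b[on_cycle])))
}

# --- AUC oracle: all positive x negative pairs, ties one half ---------------
oracle_auc <- function(scores, is_positive) {
  pos <- scores[is_positive]; neg <- scores[!is_positive]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# --- LOO oracle: literal retrain without record i ---------------------------
oracle_loo_scores <- function(records, class, c_smooth = 1) {
  vapply(seq_along(records), function(i) {
    rest <- records[-i]
    n <- length(rest)
    pos <- vapply(rest, function(r) class %in% r$labels, logical(1))
    n_a <- sum(pos)
    p0 <- if (n > 0) n_a / n else 0.5
    dset <- records[[i]]$dset
    p_hat <- vapply(dset, function(d) {
      n_d <- sum(vapply(rest, function(r) d %in% r$dset, logical(1)))
      n_ad <- sum(vapply(rest[pos], function(r) d %in% r$dset, logical(1)))
      (n_ad + c_smooth * p0) / (n_d + c_smooth)
    }, numeric(1))
    mean(2 * p_hat - 1)
  }, numeric(1))
}

# --- shared fixtures --------------------------------------------------------
water_graph <- function() molecular_graph(c("O", "H", "H"),
                                          rbind(c(1, 2), c(1, 3)), "water")
methane_graph <- function() molecular_graph(c("C", "H", "H", "H", "H"),
                                            cbind(1, 2:5), "methane")

# hand-tabulated free-amino-acid atom counts (from molecular formulae) and
# independent cycle counts, used for closed-form atom/bond checks
residue_atom_counts <- c(
  A = 13, R = 26, N = 17, D = 16, C = 14, Q = 20, E = 19, G = 10, H = 20,
  I = 22, L = 22, K = 24, M = 20, F = 23, P = 17, S = 14, T = 17, W = 27,
  Y = 24, V = 19)
residue_cycle_counts <- c(
  A = 0, R = 0, N = 0, D = 0, C = 0, Q = 0, E = 0, G = 0, H = 1, I = 0,
  L = 0, K = 0, M = 0, F = 1, P = 1, S = 0, T = 0, W = 2, Y = 1, V = 0)

random_sequence <- function(len) {
  paste(sample(amino_acid_codes(), len, replace = TRUE), collapse = "")
}

# random small synthetic records: descriptor sets as letter subsets
random_records <- function(n, n_desc = 12L, classes = ssp_classes()) {
  vocab <- paste0("d", seq_len(n_desc))
  lapply(seq_len(n), function(i) {
    list(dset = sample(vocab, sample(2:6, 1)),
         labels = sample(classes, sample(seq_len(min(3L, length(classes))), 1)))
  })
}

# apply a random atom-index permutation to a graph
permute_graph <- function(g, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  molecular_graph(g$atoms$element[perm],
                  cbind(inv[g$bonds$a], inv[g$bonds$b], g$bonds$order),
                  name = g$name)
}
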
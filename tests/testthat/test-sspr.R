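# worked 4-record example: two positives sharing descriptor x, two
# negatives sharing y
hand_records <- function() list(
  list(dset = "x", labels = "H"), list(dset = "x", labels = "H"),
  list(dset = "y", labels = "E"), list(dset = "y", labels = "E"))

test_that("training counts and B scores match the hand example", {
  m <- suppressWarnings(sspr_train(hand_records(), level = 0))
  expect_equal(m$n, 4L)
  expect_equal(unname(m$n_a["H"]), 2L)
  expect_equal(m$n_d[match("x", m$vocab)], 2L)
  expect_equal(unname(m$n_ad[match("x", m$vocab), "H"]), 2L)
  # p-hat = (2 + 0.5)/3, B = 2*p-hat - 1
  expect_equal(sspr_score(m, "x", "H"), 2 * (2.5 / 3) - 1, tolerance = 1e-12)
  expect_equal(sspr_score(m, "y", "H"), 2 * (0.5 / 3) - 1, tolerance = 1e-12)
  # unseen descriptors fall back to the prior: p0 = 0.5 gives B = 0
  expect_equal(sspr_score(m, "zzz", "H"), 0)
  expect_error(sspr_score(m, character(0), "H"), "empty")
})

test_that("LOO scores and Pa/Pi continue the hand example", {
  loo <- sspr_loo_scores(hand_records(), level = 0, classes = "H")$H
  # positive record {x}: counts 3/1/1/1, p0 = 1/3, p-hat = (1 + 1/3)/2
  expect_equal(loo$score[1], 1 / 3, tolerance = 1e-12)
  expect_equal(sort(loo$score[loo$is_positive]), c(1 / 3, 1 / 3),
               tolerance = 1e-12)
  m <- suppressWarnings(sspr_train(hand_records(), level = 0))
  p <- sspr_pa_pi(m, "x", "H")
  expect_equal(p$Pa, 1); expect_equal(p$Pi, 0); expect_true(p$possible)
  # B below every training score
  q <- sspr_pa_pi(m, "y", "H")
  expect_equal(q$Pa, 0); expect_equal(q$Pi, 1); expect_false(q$possible)
})

test_that("multi-label records are positive for each label, negative otherwise", {
  recs <- list(list(dset = c("a", "b"), labels = c("G", "H", "T")),
               list(dset = c("b", "c"), labels = "E"),
               list(dset = "c", labels = "C"))
  m <- suppressWarnings(sspr_train(recs, level = 0))
  expect_equal(unname(m$n_a[c("G", "H", "T", "E", "C")]),
               c(1L, 1L, 1L, 1L, 1L))
  expect_equal(unname(m$n_a[c("I", "P", "S")]), c(0L, 0L, 0L))
  expect_true(sum(m$n_a) >= length(recs))
  expect_setequal(m$classes, c("G", "H", "T", "E", "C"))
})

test_that("degenerate inputs behave as specified", {
  expect_error(sspr_train(list()), "empty")
  expect_warning(
    sspr_train(list(list(dset = "a", labels = "H"),
                    list(dset = "b", labels = "H"))),
    "untrainable")
  # n = 2 LOO leaves a single-record training set but stays defined
  loo <- sspr_loo_scores(list(list(dset = "a", labels = "H"),
                              list(dset = "b", labels = "E")),
                         level = 0, classes = "H")$H
  expect_true(all(is.finite(loo$score)))
})

test_that("count-decrement LOO equals brute-force retraining", {
  set.seed(21)
  recs <- random_records(30)
  loo <- sspr_loo_scores(recs, level = 0)
  for (cl in ssp_classes()) {
    expect_lt(max(abs(loo[[cl]]$score - oracle_loo_scores(recs, cl))), 1e-12)
  }
})

test_that("AUC matches hand examples and the pairwise oracle", {
  expect_equal(sspr_auc(c(2, 3, 0, 1), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(sspr_auc(c(1, 1), c(TRUE, FALSE)), 0.5)
  expect_equal(sspr_auc(c(3, 1, 2, 0), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(sspr_auc(c(1, 2), c(TRUE, TRUE)), "undefined")
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    sc <- sample(seq(-1, 1, by = 0.25), n, replace = TRUE)  # forces ties
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(lab) || all(lab)) next
    expect_equal(sspr_auc(sc, lab), oracle_auc(sc, lab), tolerance = 1e-12)
  }
})

test_that("Pa is non-decreasing and Pi non-increasing in B", {
  set.seed(31)
  recs <- random_records(40, classes = c("H", "E"))
  m <- suppressWarnings(sspr_train(recs, level = 0))
  pos <- m$pos_scores[["H"]]; neg <- m$neg_scores[["H"]]
  bs <- seq(-1, 1, length.out = 41)
  pa <- vapply(bs, function(b) (sum(pos < b) + 0.5 * sum(pos == b)) / length(pos), 1)
  pi_ <- vapply(bs, function(b) (sum(neg > b) + 0.5 * sum(neg == b)) / length(neg), 1)
  expect_true(all(diff(pa) >= 0))
  expect_true(all(diff(pi_) <= 0))
  # hence the "possible" set is a threshold rule on B
  expect_true(all(diff(pa - pi_) >= 0))
})

test_that("evaluate_levels reports per-class AUC and the unweighted mean", {
  spec <- synthetic_spec(classes = c("H", "E"), n_per_class = 25, seed = 42)
  ds <- generate_synthetic_set(spec)
  ev <- evaluate_levels(ds, levels = c(0, 2))
  expect_setequal(unique(ev$level), c(0, 2))
  m2 <- ev[ev$level == 2, ]
  expect_equal(m2$auc[m2$class == "mean"],
               mean(m2$auc[m2$class != "mean"]), tolerance = 1e-12)
  expect_error(evaluate_levels(ds, integer(0)), "non-empty")
})

test_that("identical descriptor sets on both labels are maximally uninformative", {
  # Exact leave-one-out is conservative under zero signal: removing a
  # record's own counts pushes positives below negatives, so the LOO AUC of
  # an information-free class is 0, not 0.5 (scores are deterministic:
  # every positive gets one value, every negative another, higher).
  recs <- c(lapply(1:5, function(i) list(dset = c("u", "v"), labels = "H")),
            lapply(1:5, function(i) list(dset = c("u", "v"), labels = "E")))
  loo <- sspr_loo_scores(recs, level = 0, classes = "H")$H
  expect_length(unique(loo$score[loo$is_positive]), 1L)
  expect_length(unique(loo$score[!loo$is_positive]), 1L)
  expect_equal(sspr_auc(loo$score, loo$is_positive), 0)
  # without LOO (plain rescoring on full counts) the class carries no signal
  m <- suppressWarnings(sspr_train(recs, level = 0))
  expect_equal(sspr_score(m, c("u", "v"), "H"),
               sspr_score(m, c("u", "v"), "E"))
})

test_that("model serialization round-trips through JSON", {
  set.seed(17)
  recs <- random_records(20, classes = c("H", "E", "T"))
  m <- suppressWarnings(sspr_train(recs, level = 0, c_smooth = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_sspr_model(m, path, extra = list(seed = 17))
  back <- read_sspr_model(path)
  expect_equal(back$level, m$level)
  expect_equal(back$c_smooth, m$c_smooth)
  expect_equal(back$vocab, m$vocab)
  expect_equal(back$n_ad, m$n_ad)
  expect_equal(back$pos_scores, m$pos_scores)
  d <- list(dset = sample(m$vocab, 3))
  for (cl in m$classes)
    expect_equal(sspr_pa_pi(back, d$dset, cl), sspr_pa_pi(m, d$dset, cl))
  expect_error(read_sspr_model(withr::local_tempfile(lines = "{}")), "model file")
})
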
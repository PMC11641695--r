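test_that("DSSP fixed columns are read and blanks map to coil", {
  txt <- make_dssp_text("MKV", "HH ")
  out <- parse_dssp(txt)
  expect_equal(nrow(out), 1L)
  expect_equal(out$sequence, "MKV")
  expect_equal(out$codes, "HHC")   # blank structure column = coil
  expect_equal(out$chain, "A")
})

test_that("lowercase (SS-bonded) cysteines map back to C", {
  out <- parse_dssp(make_dssp_text("AaV", "HHH"))
  expect_equal(out$sequence, "ACV")
})

test_that("chain breaks split the output and the header is required", {
  txt <- make_dssp_text("MK!VW", "HH HH")
  out <- parse_dssp(txt)
  expect_equal(nrow(out), 2L)
  expect_equal(out$sequence, c("MK", "VW"))
  expect_equal(out$codes, c("HH", "HH"))
  expect_error(parse_dssp(make_dssp_text("MK", "HH", header = FALSE)),
               "data header")
})

test_that("run extraction applies length bounds and drops beta-bridges", {
  seg <- extract_segments("ARNDCEQGH", "CCHHHHHCC")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$sequence, "NDCEQ")
  expect_equal(seg$ssp, "H")
  expect_equal(seg$start, 3L)
  expect_equal(nrow(extract_segments("ARNDCE", "HHHEEE")), 0L)  # runs of 3
  expect_equal(nrow(extract_segments("ARND", "BBBB")), 0L)      # B excluded
  expect_error(extract_segments("AR", "HHH"), "equal length")
  # max-length bound
  long <- paste(rep("A", 140), collapse = "")
  expect_equal(nrow(extract_segments(long, paste(rep("H", 140), collapse = ""),
                                     max_len = 130)), 0L)
})

test_that("segment runs partition the code string", {
  set.seed(19)
  for (i in 1:50) {
    L <- sample(10:60, 1)
    codes <- paste(sample(c("H", "E", "C", "T", "B"), L, replace = TRUE,
                          prob = c(.3, .2, .3, .1, .1)), collapse = "")
    seqc <- random_sequence(L)
    seg <- extract_segments(seqc, codes, min_len = 1L, max_len = 130L)
    seg <- seg[order(seg$start), ]
    # non-B segments with min_len 1 cover exactly the non-B positions
    covered <- unlist(mapply(function(s, q) seq(s, s + nchar(q) - 1L),
                             seg$start, seg$sequence, SIMPLIFY = FALSE))
    expect_false(any(duplicated(covered)))
    expect_setequal(covered, which(strsplit(codes, "")[[1]] != "B"))
    # maximality: adjacent kept segments never share a code
    if (nrow(seg) > 1) {
      adjacent <- seg$start[-1] == head(seg$start + nchar(seg$sequence), -1)
      expect_false(any(seg$ssp[-1][adjacent] ==
                         head(seg$ssp, -1)[adjacent]))
    }
  }
})

test_that("resolution filter is inclusive at the cutoff", {
  seg <- extract_segments("AAAAAAAAAAAA", "HHHHEEEETTTT", min_len = 4)
  seg$resolution <- c(1.8, 2.0, 2.3)
  expect_equal(filter_by_resolution(seg)$resolution, c(1.8, 2.0))
  seg$resolution <- NA_real_
  expect_equal(nrow(filter_by_resolution(seg)), 0L)
  expect_equal(nrow(filter_by_resolution(seg, keep_missing = TRUE)), 3L)
  seg$resolution <- c(1.8, 2.0, 2.3)
  expect_equal(nrow(filter_by_resolution(seg, max_res = 99)), 3L)
})

test_that("multi-label assembly reproduces the worked examples", {
  seg <- data.frame(
    sequence = c("AAAS", "AAAS", "AAAS", "QLEE", "QLEE", "QLEE", "NDCE"),
    ssp = c("G", "H", "T", "E", "T", "H", "E"),
    pdb_id = paste0("p", 1:7), chain = "A", start = 1L,
    resolution = 1.5)
  rec <- assemble_training_set(seg)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$labels[rec$sequence == "AAAS"], "G;H;T")
  expect_equal(rec$labels[rec$sequence == "QLEE"], "E;H;T")
  expect_equal(rec$labels[rec$sequence == "NDCE"], "E")
  expect_equal(rec$n_sources[rec$sequence == "AAAS"], 3L)
  # idempotent and order-independent
  rec2 <- assemble_training_set(seg[sample(nrow(seg)), ])
  expect_equal(rec, rec2)
  expect_equal(nrow(assemble_training_set(seg[0, ])), 0L)
})

test_that("co-occurrence table counts singles on the diagonal", {
  rec <- data.frame(sequence = c("AAAA", "LLLL", "VVVV"),
                    labels = c("H", "H;G", "E"))
  tab <- cooccurrence_table(rec)
  expect_equal(tab$counts["H", "H"], 1L)   # only single-label sequences
  expect_equal(tab$counts["H", "G"], 1L)
  expect_equal(tab$counts["G", "H"], 1L)
  expect_equal(tab$counts["E", "E"], 1L)
  expect_equal(sum(tab$counts), 4L)
  # symmetry and column normalization
  expect_true(isSymmetric(unname(tab$counts)))
  nonzero <- colSums(tab$counts) > 0
  expect_true(all(abs(colSums(tab$percent)[nonzero] - 100) < 1e-9))
  expect_true(all(cooccurrence_table(rec[0, ])$counts == 0L))
})

test_that("dssp-to-sdf dataset assembly round-trips through files", {
  dssp <- withr::local_tempfile(fileext = ".dssp")
  writeLines(make_dssp_text("ARNDCEQGHILKWWWW", "CCHHHHHHCCEEEEEE"), dssp)
  file.rename(dssp, file.path(dirname(dssp), "1xyz.dssp"))
  dssp <- file.path(dirname(dssp), "1xyz.dssp")
  meta <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("pdb_id\tresolution\tmethod", "1xyz\t1.7\txray"), meta)
  segs_out <- withr::local_tempfile(fileext = ".tsv")
  sdf_out <- withr::local_tempfile(fileext = ".sdf")
  status <- mnapred_cli(c("build-dataset", "--dssp", dssp, "--meta", meta,
                          "--out-segments", segs_out, "--out-sdf", sdf_out))
  expect_equal(status, 0L)
  segs <- utils::read.delim(segs_out)
  expect_setequal(segs$ssp, c("H", "E"))
  back <- read_training_sdf(sdf_out)
  expect_equal(sort(back$sequence), sort(unique(segs$sequence)))
})
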
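# fixed-column DSSP fixture builder: amino acid at column 14, structure
# code at column 17, chain id at column 12; "!" rows mark chain breaks
make_dssp_text <- function(sequence, codes, chain = "A", header = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  ss <- strsplit(codes, "")[[1]]
  stopifnot(length(aa) == length(ss))
  lines <- sprintf("%5d%5d %s %s  %s", seq_along(aa), seq_along(aa), chain,
                   aa, ss)
  brk <- aa == "!"
  lines[brk] <- sprintf("%5d      %s !", which(brk), " ")
  pre <- if (header)
    c("==== Secondary Structure Definition by the program DSSP ====",
      "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    TCO")
  else character(0)
  c(pre, lines)
}
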
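# small in-code fixtures shared across test files

# the worked 4-sequence toy: haplotypes AAT, AAT, ATT, GTT
toy_alignment <- function() {
  haplotype_alignment(
    individual_id = c("i1", "i2", "i3", "i4"),
    copy_index = rep(0L, 4L),
    sequences = c("AAT", "AAT", "ATT", "GTT"),
    locus_name = "toy", ploidy_mode = "mitochondrial")
}

# brute-force pair-enumeration oracle for mean pairwise differences
oracle_mean_pairwise <- function(seqs) {
  n <- length(seqs)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- strsplit(seqs[i], "")[[1]]
    b <- strsplit(seqs[j], "")[[1]]
    tot <- tot + sum(a != b)
  }
  tot / choose(n, 2)
}

# brute-force dxy oracle (per site)
oracle_dxy <- function(seqsA, seqsB) {
  tot <- 0
  for (a in seqsA) for (b in seqsB)
    tot <- tot + sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  tot / (length(seqsA) * length(seqsB)) / nchar(seqsA[1])
}

# single-locus configuration used by the simulator calibration tests
single_locus <- function(len = 1000L) locus_set("L1", len, 0.01, 1, "nuclear")

one_deme_sizes <- function(n) matrix(as.integer(n), 1, 1,
                                     dimnames = list("L1", "A"))

random_alignment <- function(n, L, seed) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""), "")
  haplotype_alignment(sprintf("i%02d", seq_len(n)), rep(0L, n), seqs,
                      "rand", "mitochondrial")
}
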
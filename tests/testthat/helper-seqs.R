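# Sequence construction helpers for tests.

# random coding sequence with no stop codon in frame 1 (safe under both
# the invertebrate-mitochondrial and standard codes)
make_coding_seq <- function(len, seed = 1) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste,
                  collapse = "")
  safe <- setdiff(codons, c("TAA", "TAG", "TGA"))
  s <- paste(sample(safe, ceiling(len / 3), replace = TRUE), collapse = "")
  substr(s, 1, len)
}

# overwrite a triplet at a 1-based position
poke <- function(seq, pos, triplet) {
  substr(seq, pos, pos + nchar(triplet) - 1L) <- triplet
  seq
}

# substitute n positions of a sequence with a different base
substitute_bases <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1L]]
  for (p in positions) {
    ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
  }
  paste(ch, collapse = "")
}
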
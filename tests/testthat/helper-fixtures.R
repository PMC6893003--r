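# Shared fixtures and independent oracles for the test suite.

AA20_TEST <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# The two-cluster demonstration scheme used throughout:
# [ARNDQEGHKPST | CILMFWYV], representatives A and C.
demo_scheme2 <- function() {
  raac_scheme("t2", 2, c("ARNDQEGHKPST", "CILMFWYV"))
}

curated_registry <- function() {
  read_scheme_table(raackit_table("curated"))
}

random_protein <- function(L) {
  paste(sample(AA20_TEST, L, replace = TRUE), collapse = "")
}

# Independent brute-force window enumerator: tries every start position
# step by step and bounds-checks every index. Kept deliberately naive.
bf_windows <- function(L, K, g, lam) {
  out <- list()
  s <- 1L
  repeat {
    idx <- s + (0:(K - 1L)) * (lam + 1L)
    if (max(idx) > L) break
    out[[length(out) + 1L]] <- idx
    s <- s + g + 1L
  }
  if (length(out) > 0L) {
    do.call(rbind, out)
  } else {
    matrix(integer(0), nrow = 0L, ncol = K)
  }
}

# Independent overlapping k-mer counter over an already-reduced string
# (the lambda = 0, g = 0 reference): substring extraction + table.
kmer_frequencies <- function(reduced_string, K, labels) {
  L <- nchar(reduced_string)
  kmers <- substring(reduced_string, 1:(L - K + 1), K:(L))
  counts <- table(factor(kmers, levels = labels))
  as.numeric(counts) / sum(counts)
}

write_temp_fasta <- function(seqs, dir = tempdir(), name = "tmp.fasta") {
  path <- file.path(dir, name)
  write_fasta(seqs, path)
  path
}
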
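# Independent pure-R oracles: naive dictionary counting and string ops,
# never touching the package's C++ path.

oracle_revcomp <- function(s) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", s))
}

oracle_canonical <- function(s) {
  rc <- oracle_revcomp(s)
  ifelse(s <= rc, s, rc)
}

# naive canonical k-mer counting over sequences (windows never span inputs)
oracle_count <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }), use.names = FALSE)
  can <- oracle_canonical(wins)
  tab <- table(can)
  kmer <- sort(names(tab), method = "radix")
  list(kmer = kmer, count = as.numeric(tab[kmer]),
       total_tokens = length(wins))
}

expect_same_table <- function(tbl, oracle) {
  expect_identical(tbl$kmer, oracle$kmer)
  expect_equal(tbl$count, unname(oracle$count))
  expect_equal(tbl$total_tokens, oracle$total_tokens)
}
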
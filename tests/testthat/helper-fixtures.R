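# Small in-code fixtures shared across tests.

PLECTASIN <- "GFGCNGPWDEDDMQCHNHCKSIKGYKGGYCAKGGFVCKCY"

# A plectasin variant with chosen point substitutions (1-based positions).
plectasin_variant <- function(...) {
  subs <- c(...)
  ch <- strsplit(PLECTASIN, "")[[1]]
  for (p in names(subs)) ch[as.integer(p)] <- subs[[p]]
  paste(ch, collapse = "")
}

# Write a FASTA string to a temp file and return the path.
tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

tmp_tsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# Mature tibble for a set of named sequences (must all carry scaffolds).
mature_of <- function(seqs) {
  trim_to_mature(tibble::tibble(id = names(seqs), sequence = unname(seqs)))
}
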
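# Split a sequence string into a character vector of single residues.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Validate one sequence string against the allowed alphabet; returns the
# offending letters (empty if clean).
illegal_residues <- function(sequence) {
  ch <- unique(seq_chars(sequence))
  setdiff(ch, AA_ALLOWED)
}

assert_peptide_tbl <- function(x, cols = c("id", "sequence"),
                               arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame, not %s.", arg, class(x)[1]))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      arg, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Wrap a sequence at `width` columns for FASTA output.
wrap_seq <- function(x, width = 60) {
  if (nchar(x) <= width) return(x)
  starts <- seq(1, nchar(x), by = width)
  paste(substring(x, starts, pmin(starts + width - 1, nchar(x))),
        collapse = "\n")
}
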
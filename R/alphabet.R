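#' The canonical amino-acid alphabet
#'
#' One-letter codes of the 20 proteinogenic amino acids in alphabetical
#' order.  This fixed order is used for row/column layout of every energy
#' table in the package and, importantly, for deterministic tie-breaking in
#' peptide design: when two residues score an exact tie, the one earlier in
#' this order is chosen (so Ala beats Gly on ties).
#'
#' @return Character vector of length 20.
#' @examples
#' aa_alphabet()
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# internal: stop() with context if `codes` contains non-canonical residues
assert_residues <- function(codes, what = "residue") {
  bad <- setdiff(unique(codes), aa_alphabet())
  if (length(bad) > 0L) {
    stop(sprintf("unknown %s code(s): %s (expected one-letter codes %s)",
                 what, paste(bad, collapse = ", "),
                 paste(aa_alphabet(), collapse = "")), call. = FALSE)
  }
  invisible(codes)
}

# internal: split a sequence string into validated residue characters
split_residues <- function(sequence, context = "sequence") {
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% aa_alphabet()))
  if (length(bad) > 0L) {
    stop(sprintf("illegal residue character '%s' at position %d of %s",
                 chars[bad[1L]], bad[1L], context), call. = FALSE)
  }
  chars
}
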
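# Small shared helpers. Coordinates are 0-based half-open internally; SAM's
# 1-based positions are converted at the I/O boundary only.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# mismatch count between two equal-length ACGT strings
str_mismatches <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("length mismatch")
  sum(charToRaw(a) != charToRaw(b))
}

# reference-consuming width of a cigar string (M/D/N/=/X)
cigar_ref_width <- function(cigar) {
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

cigar_ops <- function(cigar) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  Map(function(o, l) data.frame(op = o, len = l, stringsAsFactors = FALSE),
      ops, lens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_id <- local({
  function(n) seq_len(n)
})
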
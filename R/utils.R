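`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer coding of an alignment for distance work: A=1 C=2 G=3 T=4,
# anything else (ambiguity, gap) = 0 and excluded pairwise.
.code_alignment <- function(aln) {
  stopifnot(is.matrix(aln))
  m <- match(aln, c("A", "C", "G", "T"))
  m[is.na(m)] <- 0L
  matrix(as.integer(m), nrow = nrow(aln), dimnames = dimnames(aln))
}

.alignment_of <- function(x) {
  if (inherits(x, "barcode_library")) {
    if (is.null(x$alignment))
      stop("library has no alignment; run align_to_anchor() first")
    return(x$alignment)
  }
  .as_char_matrix(x)
}
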
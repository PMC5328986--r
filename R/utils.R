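# Internal sequence utilities shared across modules.

BASES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Bacterial/archaeal genetic code (translation table 11; identical amino-acid
# assignments to the standard table, alternative start codons are irrelevant
# here because amplicons are translated mid-gene).
.genetic_code <- function() Biostrings::getGeneticCode("11")

.codon_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) tab <<- .genetic_code()
    tab
  }
})

STOP_CODONS <- c("TAA", "TAG", "TGA")

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

.collapse <- function(x) paste(x, collapse = "")

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
.translate_chars <- function(ch, frame = 1) {
  n <- length(ch)
  if (n < frame + 2) return("")
  usable <- frame:(frame + 3 * ((n - frame + 1) %/% 3) - 1)
  codons <- toupper(vapply(
    split(ch[usable], rep(seq_len(length(usable) / 3), each = 3)),
    paste, character(1), collapse = ""
  ))
  tab <- .codon_table()
  aa <- unname(tab[codons])
  aa[is.na(aa)] <- "X"
  .collapse(aa)
}

#' Translate a DNA string under the bacterial/archaeal genetic code
#'
#' Translation table 11, in a given forward frame; trailing partial codons
#' are dropped and codons containing non-ACGT letters yield `X`. Stop
#' codons are rendered as `*`.
#'
#' @param dna DNA string.
#' @param frame Forward frame, 1-3.
#' @return Amino-acid string.
#' @export
translate_dna <- function(dna, frame = 1) {
  stopifnot(frame %in% 1:3)
  .translate_chars(.chars(toupper(dna)), frame)
}

#' Six-frame translation
#'
#' Three forward frames plus three frames of the reverse complement, under
#' translation table 11.
#' @inheritParams translate_dna
#' @return Character vector of six translations.
#' @export
six_frame_translations <- function(dna) {
  fwd <- toupper(dna)
  rev <- .revcomp(fwd)
  c(
    vapply(1:3, function(f) translate_dna(fwd, f), character(1)),
    vapply(1:3, function(f) translate_dna(rev, f), character(1))
  )
}

.longest_homopolymer <- function(dna) {
  ch <- .chars(dna)
  if (length(ch) == 0) return(0L)
  max(rle(ch)$lengths)
}

.count_ambiguous <- function(dna) {
  sum(!.chars(toupper(dna)) %in% BASES)
}

.is_iupac <- function(x) {
  all(.chars(toupper(x)) %in% names(IUPAC_SETS))
}

# sample() that never interprets a length-1 vector as 1:n
.resample <- function(x, size = length(x)) {
  if (length(x) <= 1L && size >= length(x)) return(x)
  x[sample.int(length(x), size)]
}

# Deterministic RNG scoping: every simulator takes an explicit seed and leaves
# the caller's RNG state untouched.
.with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}
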
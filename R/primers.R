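#' Construct a degenerate primer pair
#'
#' A primer pair records the forward and reverse primer sequences (IUPAC
#' codes allowed) together with the template coordinates they were designed
#' against: the 1-based position where the forward primer binding site starts
#' and the 1-based 3'-most template position of the reverse primer binding
#' site. The numbers embedded in published nitrogenase primer names follow
#' the same convention (positions in the *Azotobacter vinelandii* genes), so
#' the inclusive amplicon span is `reverse_ref_end - forward_ref_start + 1`.
#'
#' @param name Primer pair label.
#' @param forward,reverse Primer sequences, 5'->3', IUPAC degeneracy allowed.
#'   The reverse primer is written as its own strand; it binds the template
#'   as its reverse complement.
#' @param forward_ref_start 1-based reference coordinate of the first
#'   template base covered by the forward primer.
#' @param reverse_ref_end 1-based reference coordinate of the last (3'-most)
#'   template base covered by the reverse primer binding site.
#' @return An object of class `primer_pair`.
#' @examples
#' primer_pair("toy", "ACGTACGT", "TTTTCCCC", 10, 200)
#' @export
primer_pair <- function(name, forward, reverse, forward_ref_start, reverse_ref_end) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  if (!.is_iupac(forward) || !.is_iupac(reverse)) {
    stop("primers must contain only IUPAC nucleotide codes", call. = FALSE)
  }
  forward_ref_start <- as.integer(forward_ref_start)
  reverse_ref_end <- as.integer(reverse_ref_end)
  if (forward_ref_start >= reverse_ref_end) {
    stop("forward_ref_start must be < reverse_ref_end", call. = FALSE)
  }
  structure(
    list(
      name = name, forward = forward, reverse = reverse,
      forward_ref_start = forward_ref_start, reverse_ref_end = reverse_ref_end
    ),
    class = "primer_pair"
  )
}

#' Published nested-PCR primer sets for nifD and anf/vnfD amplicons
#'
#' The nested primer pairs used to amplify the nitrogenase alpha-subunit
#' genes: a nifD set (outer 820F/1389R, inner 820F/1331R, final amplicon
#' 512 bp) and a combined anfD/vnfD set (outer 548F/1337R, inner 548F/1291R,
#' final amplicon 744 bp). Coordinates refer to the *A. vinelandii* nifD and
#' anf/vnfD sequences.
#'
#' @return A list with elements `nifD` and `anfvnfD`, each a list with
#'   `outer` and `inner` [primer_pair()] objects.
#' @export
nitrogenase_primers <- function() {
  list(
    nifD = list(
      outer = primer_pair("nifD820F/nifD1389R",
                          "CACTGCTAYCGBTCGATGAACTAC", "GATGTCRCGSGCGAAGAT",
                          820L, 1389L),
      inner = primer_pair("nifD820F/nifD1331R",
                          "CACTGCTAYCGBTCGATGAACTAC", "CAGGAGTGCATYTGVCGG",
                          820L, 1331L)
    ),
    anfvnfD = list(
      outer = primer_pair("vnfD_anfD548F/vnfD_anfD1337R",
                          "TSAAYATCGSCTGGRTSA", "GCGTTRTAVATRTCKCGSGC",
                          548L, 1337L),
      inner = primer_pair("vnfD_anfD548F/vnfD_anfD1291R",
                          "TSAAYATCGSCTGGRTSA", "TGTANGGRCCRTTGTGRTA",
                          548L, 1291L)
    )
  )
}

#' In-silico PCR with degenerate primers
#'
#' Extracts the amplicon a primer pair would produce from a template:
#' the inclusive span from the first base of the forward-primer match to the
#' last base of the reverse-primer match (the reverse primer is matched as
#' its reverse complement on the template strand). Matching honours IUPAC
#' degeneracy and allows zero mismatches. When `nested_inner` is supplied,
#' the inner pair is applied to the first-round product, emulating nested
#' PCR. When the template is an unmutated reference designed against the
#' primer coordinates, the amplicon length equals
#' `reverse_ref_end - forward_ref_start + 1`.
#'
#' @param template DNA string (the plus strand).
#' @param primers A [primer_pair()].
#' @param nested_inner Optional inner [primer_pair()] for the second round.
#' @return The amplicon as a character string, or `NULL` when either primer
#'   fails to match.
#' @examples
#' p <- nitrogenase_primers()$nifD
#' refs <- generate_reference_set(1, seed = 1)
#' amp <- insilico_pcr(refs$dna[refs$isozyme == "nifD"], p$outer, p$inner)
#' nchar(amp)  # 512
#' @export
insilico_pcr <- function(template, primers, nested_inner = NULL) {
  stopifnot(inherits(primers, "primer_pair"))
  template <- toupper(template)
  if (nchar(template) == 0) stop("template must be non-empty", call. = FALSE)
  subject <- Biostrings::DNAString(template)

  fwd_hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primers$forward), subject, fixed = FALSE
  )
  if (length(fwd_hits) == 0) return(NULL)
  if (length(fwd_hits) > 1) {
    stop(sprintf(
      "forward primer '%s' matches the template at multiple positions: %s",
      primers$name, paste(BiocGenerics::start(fwd_hits), collapse = ", ")
    ), call. = FALSE)
  }
  rev_site <- Biostrings::DNAString(.revcomp(primers$reverse))
  rev_hits <- Biostrings::matchPattern(rev_site, subject, fixed = FALSE)
  if (length(rev_hits) == 0) return(NULL)

  from <- BiocGenerics::start(fwd_hits)[1]
  to <- max(BiocGenerics::end(rev_hits))
  if (to <= from) return(NULL)
  product <- substr(template, from, to)
  if (!is.null(nested_inner)) {
    return(insilico_pcr(product, nested_inner))
  }
  product
}
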
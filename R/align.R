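# Local/global alignment helpers and Karlin-Altschul E-values.
#
# Protein searches use BLOSUM62 with affine gaps 11/1 and the published
# gapped Karlin-Altschul parameters (lambda = 0.267, K = 0.041); nucleotide
# searches use match/mismatch 2/-3 with gaps 5/2 (lambda = 0.625, K = 0.41).
# The search space is query length x total reference length, the
# conventional BLAST parameterization.

KA_PROT <- c(lambda = 0.267, K = 0.041)
KA_NUC <- c(lambda = 0.625, K = 0.41)

.blosum62 <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <<- e$BLOSUM62
    }
    m
  }
})

.nuc_matrix <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -3, baseOnly = FALSE, type = "DNA"
      )
    }
    m
  }
})

.ka_evalue <- function(score, m, n, params) {
  unname(params["K"] * m * n * exp(-params["lambda"] * score))
}

# Best local protein alignment score of one query against a set of subjects.
.best_local_protein_score <- function(query, subjects) {
  if (nchar(query) == 0 || length(subjects) == 0) return(-Inf)
  q <- Biostrings::AAString(gsub("\\*", "X", query))
  max(vapply(subjects, function(s) {
    Biostrings::pairwiseAlignment(
      pattern = q, subject = Biostrings::AAString(s), type = "local",
      substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
  }, numeric(1)))
}

.local_nuc_score <- function(query, subject) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = .nuc_matrix(),
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE
  )
}

# Translated (six-frame) homology E-value of a read against a protein
# reference panel.
.translated_evalue <- function(dna, ref_proteins) {
  frames <- gsub("*", "X", six_frame_translations(dna), fixed = TRUE)
  frames <- frames[nchar(frames) > 0]
  if (length(frames) == 0 || length(ref_proteins) == 0) return(Inf)
  n_db <- sum(nchar(ref_proteins))
  pat <- Biostrings::AAStringSet(frames)
  best <- Inf
  for (rp in ref_proteins) {
    sc <- Biostrings::pairwiseAlignment(
      pattern = pat, subject = Biostrings::AAString(rp), type = "local",
      substitutionMatrix = .blosum62(), gapOpening = 11, gapExtension = 1,
      scoreOnly = TRUE
    )
    best <- min(best, .ka_evalue(sc, nchar(frames), n_db, KA_PROT))
  }
  best
}

# Nucleotide E-value against one reference (both strands).
.nucleotide_evalue <- function(dna, ref_dna) {
  s <- max(.local_nuc_score(dna, ref_dna), .local_nuc_score(.revcomp(dna), ref_dna))
  .ka_evalue(s, nchar(dna), nchar(ref_dna), KA_NUC)
}

# Read-vs-reference semi-global alignments (reads global, reference local),
# vectorized over reads in a single pairwiseAlignment call. Returns one
# record per read: the aligned strings, the reference start offset, the
# score and per-read-base match indicators in read coordinates (insertions
# in the read count as mismatches; deletions are skipped).
.align_reads_to_ref <- function(reads, ref_dna) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(reads),
    subject = Biostrings::DNAString(ref_dna),
    type = "global-local", substitutionMatrix = .nuc_matrix(),
    gapOpening = 5, gapExtension = 2
  )
  ps <- as.character(Biostrings::alignedPattern(pa))
  ss <- as.character(Biostrings::alignedSubject(pa))
  sstarts <- BiocGenerics::start(Biostrings::subject(pa))
  scores <- Biostrings::score(pa)
  lapply(seq_along(reads), function(i) {
    p <- .chars(ps[i])
    s <- .chars(ss[i])
    keep <- p != "-"
    list(p = p, s = s, sstart = sstarts[i], score = scores[i],
         match_vec = (p == s)[keep])
  })
}

.align_read_to_ref <- function(read, ref_dna) {
  .align_reads_to_ref(read, ref_dna)[[1]]
}

# Ungapped divergence between two equal-role sequences via semi-global
# alignment (gap columns excluded).
.aligned_divergence <- function(a, b) {
  al <- .align_read_to_ref(a, b)
  cmp <- al$p != "-" & al$s != "-"
  if (!any(cmp)) return(1)
  mean(al$p[cmp] != al$s[cmp])
}
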
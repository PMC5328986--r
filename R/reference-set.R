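# Synthetic nitrogenase reference sequences.
#
# Each reference gene is built so that it behaves like a real nifD/anfD/vnfD
# template under the published nested primer sets: exact degenerate-primer
# binding sites at the published coordinates, no stop codons in the gene
# reading frame (so the whole-gene translation is a valid protein) nor in
# the amplicon reading frame (frame 1 from the forward primer, the frame in
# which amplicons are translated downstream), and -- for anfD/vnfD -- the
# 13-residue cofactor-ligand window (V at 3, CAR at 6-8, Y at 13) placed
# inside the amplified region in the amplicon frame.

NIFD_GENE_LEN <- 1500L
ANFVNF_GENE_LEN <- 1401L
ANFVNF_MOTIF_START <- 890L # template coord; (890 - 548) %% 3 == 0
MOTIF_13 <- list(anfD = "KIVSGCARGGLDY", vnfD = "RLVTACARNEMSY")
MEMBER_MUTATION_RATE <- 0.065 # per free site, centres pairwise divergence ~12%
FAMILY_DIV_MAX <- 0.15  # whole-gene pairwise divergence ceiling within a family
FAMILY_DIV_MIN <- 0.10  # amplicon-region pairwise divergence floor

.comp_base <- c(A = "T", C = "G", G = "C", T = "A")

.codons_for <- local({
  by_aa <- NULL
  function(aa) {
    if (is.null(by_aa)) by_aa <<- split(names(.codon_table()), unname(.codon_table()))
    by_aa[[aa]]
  }
})

# Allowed-base sets for the template positions covered by a primer site.
.apply_primer_site <- function(allowed, primer_seq, start, reverse = FALSE) {
  ch <- .chars(primer_seq)
  if (reverse) {
    # site on the plus strand is the reverse complement of the primer
    ch <- rev(ch)
    sets <- lapply(ch, function(b) unname(.comp_base[IUPAC_SETS[[b]]]))
  } else {
    sets <- lapply(ch, function(b) IUPAC_SETS[[b]])
  }
  for (i in seq_along(sets)) allowed[[start + i - 1L]] <- sets[[i]]
  allowed
}

.stop_triplets <- function(ch, frame_start, frame_end) {
  n_cod <- (frame_end - frame_start + 1L) %/% 3L
  if (n_cod <= 0) return(integer(0))
  starts <- frame_start + 3L * (seq_len(n_cod) - 1L)
  codons <- paste0(ch[starts], ch[starts + 1L], ch[starts + 2L])
  starts[codons %in% STOP_CODONS]
}

# Resolve stop codons in the listed reading frames by redrawing bases that
# still have freedom (free sites and degenerate primer positions) or by
# synonymously recoding an overlapping motif codon. Returns the repaired
# character vector or NULL when a stop is pinned by fixed positions.
.repair_stops <- function(ch, allowed, frames, motif_slots, max_iter = 1000L) {
  for (iter in seq_len(max_iter)) {
    viol <- unlist(lapply(frames, function(fr) .stop_triplets(ch, fr[1], fr[2])))
    if (length(viol) == 0) return(ch)
    tri <- viol[[1]]
    pos <- tri:(tri + 2L)
    flexible <- pos[vapply(pos, function(p) length(allowed[[p]]) > 1L, logical(1))]
    fixed_ok <- FALSE
    if (length(flexible) > 0) {
      for (p in .resample(flexible)) {
        alt <- setdiff(allowed[[p]], ch[p])
        if (length(alt) > 0) {
          ch[p] <- if (length(alt) == 1L) alt else sample(alt, 1L)
          fixed_ok <- TRUE
          break
        }
      }
    }
    if (!fixed_ok && length(motif_slots) > 0) {
      for (slot in motif_slots) {
        if (any(slot$positions %in% pos)) {
          cods <- .codons_for(slot$aa)
          cur <- .collapse(ch[slot$positions])
          alt <- setdiff(cods, cur)
          if (length(alt) > 0) {
            ch[slot$positions] <- .chars(if (length(alt) == 1L) alt else sample(alt, 1L))
            fixed_ok <- TRUE
            break
          }
        }
      }
    }
    if (!fixed_ok) return(NULL)
  }
  NULL
}

.primer_unique_at <- function(dna, primer_seq, start, reverse = FALSE) {
  pat <- if (reverse) .revcomp(primer_seq) else primer_seq
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pat), Biostrings::DNAString(dna), fixed = FALSE
  )
  length(hits) == 1L && BiocGenerics::start(hits)[1] == start
}

.check_template <- function(dna, primers) {
  inner <- primers$inner
  outer <- primers$outer
  fs <- inner$forward_ref_start
  .primer_unique_at(dna, inner$forward, fs) &&
    .primer_unique_at(dna, inner$reverse,
                      inner$reverse_ref_end - nchar(inner$reverse) + 1L, reverse = TRUE) &&
    .primer_unique_at(dna, outer$reverse,
                      outer$reverse_ref_end - nchar(outer$reverse) + 1L, reverse = TRUE) &&
    .longest_homopolymer(dna) <= 10L
}

.family_scaffold <- function(gene_len, primers, motif = NULL,
                             motif_start = ANFVNF_MOTIF_START) {
  inner <- primers$inner
  outer <- primers$outer
  fs <- inner$forward_ref_start
  allowed <- rep(list(BASES), gene_len)
  allowed <- .apply_primer_site(allowed, inner$forward, fs)
  allowed <- .apply_primer_site(allowed, outer$reverse,
                                outer$reverse_ref_end - nchar(outer$reverse) + 1L,
                                reverse = TRUE)
  allowed <- .apply_primer_site(allowed, inner$reverse,
                                inner$reverse_ref_end - nchar(inner$reverse) + 1L,
                                reverse = TRUE)
  motif_slots <- list()
  if (!is.null(motif)) {
    aa <- .chars(motif)
    for (i in seq_along(aa)) {
      p0 <- motif_start + 3L * (i - 1L)
      motif_slots[[i]] <- list(aa = aa[i], positions = p0:(p0 + 2L))
      for (p in p0:(p0 + 2L)) allowed[[p]] <- "N" # placeholder, set below
    }
  }
  amp_len <- inner$reverse_ref_end - fs + 1L
  frames <- list(
    c(1L, gene_len),                          # gene reading frame
    c(fs, fs + 3L * (amp_len %/% 3L) - 1L)    # amplicon reading frame
  )
  list(allowed = allowed, motif_slots = motif_slots, frames = frames,
       primers = primers)
}

.draw_ancestor <- function(scaffold, max_attempts = 60L) {
  allowed <- scaffold$allowed
  gene_len <- length(allowed)
  for (attempt in seq_len(max_attempts)) {
    ch <- vapply(allowed, function(a) {
      if (identical(a, "N")) "A" else if (length(a) == 1L) a else sample(a, 1L)
    }, character(1))
    for (slot in scaffold$motif_slots) {
      cods <- .codons_for(slot$aa)
      ch[slot$positions] <- .chars(if (length(cods) == 1L) cods else sample(cods, 1L))
    }
    # motif positions are codon-constrained, not base-free
    allowed_run <- allowed
    for (slot in scaffold$motif_slots) {
      for (p in slot$positions) allowed_run[[p]] <- ch[p]
    }
    ch <- .repair_stops(ch, allowed_run, scaffold$frames, scaffold$motif_slots)
    if (is.null(ch)) next
    dna <- .collapse(ch)
    if (.check_template(dna, scaffold$primers)) {
      return(list(ch = ch, allowed = allowed_run))
    }
  }
  stop("failed to construct a reference template satisfying all constraints",
       call. = FALSE)
}

.mutate_member <- function(anc, scaffold, siblings = character(0),
                           rate = MEMBER_MUTATION_RATE, max_attempts = 100L) {
  free <- which(vapply(anc$allowed, function(a) length(a) == 4L, logical(1)))
  inner <- scaffold$primers$inner
  amp_span <- c(inner$forward_ref_start, inner$reverse_ref_end)
  ham <- function(a, b) mean(.chars(a) != .chars(b))
  for (attempt in seq_len(max_attempts)) {
    ch <- anc$ch
    hit <- free[stats::runif(length(free)) < rate]
    if (length(hit) > 0) {
      ch[hit] <- vapply(ch[hit], function(b) sample(setdiff(BASES, b), 1L),
                        character(1), USE.NAMES = FALSE)
    }
    ch <- .repair_stops(ch, anc$allowed, scaffold$frames, scaffold$motif_slots)
    if (is.null(ch)) next
    dna <- .collapse(ch)
    if (!.check_template(dna, scaffold$primers)) next
    # keep within-family divergence in its band: close enough to be one gene
    # family, far enough apart that chimeras between members are detectable
    ok <- all(vapply(siblings, function(s) {
      ham(dna, s) <= FAMILY_DIV_MAX &&
        ham(substr(dna, amp_span[1], amp_span[2]),
            substr(s, amp_span[1], amp_span[2])) >= FAMILY_DIV_MIN
    }, logical(1)))
    if (ok) return(dna)
  }
  stop("failed to derive a family member satisfying all constraints", call. = FALSE)
}

.build_internal_standard <- function(len = 600L, gc_range = c(0.58, 0.62),
                                     primers_all, max_attempts = 60L) {
  primer_seqs <- unlist(lapply(primers_all, function(set)
    lapply(set, function(p) c(p$forward, p$reverse))))
  for (attempt in seq_len(max_attempts)) {
    ch <- sample(BASES, len, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    gc <- function(x) mean(x %in% c("G", "C"))
    while (gc(ch) < gc_range[1]) {
      i <- sample(which(ch %in% c("A", "T")), 1L)
      ch[i] <- sample(c("G", "C"), 1L)
    }
    while (gc(ch) > gc_range[2]) {
      i <- sample(which(ch %in% c("G", "C")), 1L)
      ch[i] <- sample(c("A", "T"), 1L)
    }
    dna <- .collapse(ch)
    subj <- Biostrings::DNAString(dna)
    hit_any <- any(vapply(primer_seqs, function(p) {
      length(Biostrings::matchPattern(Biostrings::DNAString(p), subj, fixed = FALSE)) > 0 ||
        length(Biostrings::matchPattern(Biostrings::DNAString(.revcomp(p)), subj, fixed = FALSE)) > 0
    }, logical(1)))
    if (!hit_any && .longest_homopolymer(dna) <= 10L) return(dna)
  }
  stop("failed to construct internal standard", call. = FALSE)
}

#' Generate a synthetic nitrogenase reference set
#'
#' Builds `n_per_isozyme` reference gene sequences for each of nifD, anfD and
#' vnfD plus exactly one 600 bp internal-standard sequence (60% GC, unrelated
#' to any nitrogenase and free of primer binding sites). Members of the same
#' isozyme family are mutants of a common ancestor (roughly 10-15% pairwise
#' divergent); different isozymes are independent sequences (>= 30%
#' divergent). Every nitrogenase reference carries exact binding sites for
#' its published primer pair at the published coordinates, translates without
#' stop codons in both the gene frame and the amplicon frame, and (for
#' anfD/vnfD) contains the 13-residue cofactor-ligand motif window inside the
#' amplified region.
#'
#' @param n_per_isozyme Number of references per isozyme family (>= 0).
#' @param seed Integer seed; results are byte-identical across reruns.
#' @return A `data.frame` with columns `id`, `isozyme` (one of `nifD`,
#'   `anfD`, `vnfD`, `internal_standard`), `dna`, `protein` (empty for the
#'   internal standard) and `taxon_label`.
#' @examples
#' refs <- generate_reference_set(2, seed = 7)
#' table(refs$isozyme)
#' @export
generate_reference_set <- function(n_per_isozyme, seed) {
  if (length(n_per_isozyme) != 1 || is.na(n_per_isozyme) || n_per_isozyme < 0) {
    stop("n_per_isozyme must be a single non-negative integer", call. = FALSE)
  }
  n_per_isozyme <- as.integer(n_per_isozyme)
  primers <- nitrogenase_primers()
  .with_seed(seed, {
    rows <- list()
    fams <- list(
      nifD = .family_scaffold(NIFD_GENE_LEN, primers$nifD),
      anfD = .family_scaffold(ANFVNF_GENE_LEN, primers$anfvnfD, MOTIF_13$anfD),
      vnfD = .family_scaffold(ANFVNF_GENE_LEN, primers$anfvnfD, MOTIF_13$vnfD)
    )
    for (iso in names(fams)) {
      if (n_per_isozyme == 0) break
      anc <- .draw_ancestor(fams[[iso]])
      members <- character(0)
      for (k in seq_len(n_per_isozyme)) {
        dna <- .mutate_member(anc, fams[[iso]], siblings = members)
        members <- c(members, dna)
        rows[[length(rows) + 1L]] <- data.frame(
          id = sprintf("%s_ref_%02d", iso, k),
          isozyme = iso,
          dna = dna,
          protein = translate_dna(dna),
          taxon_label = sprintf("synthetic %s diazotroph %d", iso, k),
          stringsAsFactors = FALSE
        )
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = "internal_standard", isozyme = "internal_standard",
      dna = .build_internal_standard(primers_all = primers),
      protein = "", taxon_label = "synthetic spike-in control",
      stringsAsFactors = FALSE
    )
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    class(out) <- c("reference_set", "data.frame")
    out
  })
}

#' Reference amplicons under the nested primer sets
#'
#' Applies nested in-silico PCR to each nitrogenase reference and returns the
#' final amplicons together with the trim-window start used by the QC stage
#' (the amplicon position immediately following the forward primer).
#'
#' @param refs A reference set from [generate_reference_set()].
#' @param primers Primer sets as returned by [nitrogenase_primers()].
#' @return `data.frame` with columns `id`, `isozyme`, `dna` (amplicon) and
#'   `window_start`.
#' @export
reference_amplicons <- function(refs, primers = nitrogenase_primers()) {
  nit <- refs[refs$isozyme %in% c("nifD", "anfD", "vnfD"), , drop = FALSE]
  rows <- lapply(seq_len(nrow(nit)), function(i) {
    set <- if (nit$isozyme[i] == "nifD") primers$nifD else primers$anfvnfD
    amp <- insilico_pcr(nit$dna[i], set$outer, set$inner)
    if (is.null(amp)) {
      stop(sprintf("reference %s does not amplify", nit$id[i]), call. = FALSE)
    }
    data.frame(
      id = nit$id[i], isozyme = nit$isozyme[i], dna = amp,
      window_start = nchar(set$inner$forward) + 1L,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
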